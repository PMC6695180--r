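# shared builders and independent oracles

bahrain_freqs <- function() {
  read_frequency_table(system.file("extdata", "bahrain_allele_freqs.csv",
                                   package = "strpopkit"))
}

bahrain_params <- function() {
  df <- read.csv(system.file("extdata", "bahrain_forensic_params.csv",
                             package = "strpopkit"), check.names = FALSE)
  rownames(df) <- df$parameter
  df$parameter <- NULL
  as.matrix(df)
}

# tiny two-sample, one-locus table: calls 8/9 and 8/8
tiny_gt <- function() {
  genotype_table(allele1 = matrix(c("8", "8"), 2, 1),
                 allele2 = matrix(c("9", "8"), 2, 1),
                 sample_ids = c("s1", "s2"), loci = "TPOX")
}

# genotype table with prescribed per-allele counts at one locus, alleles
# paired in sequence (genotype structure arbitrary, counts exact)
gt_from_counts <- function(counts, locus = "L") {
  av <- rep(names(counts), counts)
  stopifnot(length(av) %% 2 == 0)
  n <- length(av) / 2
  genotype_table(matrix(av[seq_len(n)], ncol = 1),
                 matrix(av[n + seq_len(n)], ncol = 1),
                 sample_ids = sprintf("s%04d", seq_len(n)), loci = locus)
}

# genotype-enumeration oracle for the expected-genotype match probability:
# list every genotype, square its HWE probability, sum
pm_enumeration_oracle <- function(p) {
  k <- length(p)
  s <- 0
  for (i in seq_len(k)) for (j in i:k) {
    g <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
    s <- s + g^2
  }
  s
}

# exhaustive exact HWE p-value for tiny samples: enumerate every pairing of
# the 2N observed alleles (all permutations of positions, paired
# consecutively), compare the conditional-probability statistic
hwe_exact_enumeration <- function(a1, a2) {
  av <- c(a1, a2)
  codes <- as.integer(factor(av))
  k <- max(codes)
  n <- length(a1)
  stat <- function(x1, x2) {
    g <- (pmin(x1, x2) - 1L) * k + pmax(x1, x2)
    tab <- tabulate(g, k * k)
    sum(x1 != x2) * log(2) - sum(lgamma(tab[tab > 0] + 1))
  }
  obs <- stat(codes[seq_len(n)], codes[n + seq_len(n)])
  perms <- all_permutations(length(av))
  hits <- 0L
  for (r in seq_len(nrow(perms))) {
    x <- codes[perms[r, ]]
    if (stat(x[seq_len(n)], x[n + seq_len(n)]) <= obs + 1e-9) hits <- hits + 1L
  }
  hits / nrow(perms)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# path-length (cophenetic) matrix of a phylo tree, ordered by tip label
tree_path_lengths <- function(tree, labels) {
  m <- ape::cophenetic.phylo(tree)
  m[labels, labels]
}

# random additive distance matrix from a random topology with positive
# branch lengths
random_additive <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.1, 2)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# stress-1 recomputed from scratch for a configuration (independent of nmds())
stress_from_config <- function(d, points) {
  dd <- as.numeric(as.dist(as.matrix(d)))
  cd <- as.numeric(dist(points))
  o <- order(dd)
  disp <- numeric(length(cd))
  disp[o] <- isoreg(cd[o])$yf
  sqrt(sum((cd - disp)^2) / sum(cd^2))
}
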