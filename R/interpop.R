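#' Align frequency tables on their common locus panel
#'
#' Population comparisons from published tables must be restricted to the
#' loci every study typed (a 21-locus panel against a 15-locus study is
#' compared on the 15 shared loci). Each retained locus gets the union of
#' the populations' allele lists, absent alleles filled with frequency 0.
#'
#' @param tables list of [freq_table()]s (>= 2).
#' @return list of aligned tables (same loci, same allele lists per locus),
#'   with the shared locus names attached as attribute `"loci_used"`. The
#'   aligned tables are plain lists of per-locus frequency vectors keyed by
#'   population (zero frequencies are legitimate after alignment, so they
#'   are no longer `freq_table` objects).
#' @export
align_loci <- function(tables) {
  if (length(tables) < 2L) stop("need at least two frequency tables")
  stopifnot(all(vapply(tables, inherits, TRUE, "freq_table")))
  loci <- Reduce(intersect, lapply(tables, function(t) names(t$freqs)))
  if (!length(loci)) stop("no locus shared by all tables")
  out <- lapply(tables, function(t) {
    al <- lapply(loci, function(l) {
      union_alleles <- sort_alleles(unique(unlist(
        lapply(tables, function(s) names(s$freqs[[l]])))))
      p <- stats::setNames(numeric(length(union_alleles)), union_alleles)
      p[names(t$freqs[[l]])] <- t$freqs[[l]]
      p / sum(p)
    })
    names(al) <- loci
    structure(list(freqs = al, population = t$population,
                   sample_size_2n = t$sample_size_2n[loci]),
              class = "aligned_freqs")
  })
  names(out) <- vapply(tables, function(t) t$population, "")
  attr(out, "loci_used") <- loci
  out
}

get_aligned <- function(tables) {
  if (inherits(tables, "aligned_freqs") ||
      (is.list(tables) && all(vapply(tables, inherits, TRUE, "aligned_freqs"))))
    return(tables)
  align_loci(tables)
}

new_dist_matrix <- function(m, labels, estimator, loci) {
  dimnames(m) <- list(labels, labels)
  stopifnot(max(abs(m - t(m))) < 1e-12, all(diag(m) == 0))
  if (any(m < 0)) {
    message("negative ", estimator, " estimates clamped to 0")
    m[m < 0] <- 0
  }
  structure(m, class = c("dist_matrix", "matrix"), estimator = estimator,
            loci = loci)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %s, %d populations, %d loci\n",
              attr(x, "estimator"), nrow(x), length(attr(x, "loci"))))
  print(round(unclass(x), 4L))
  invisible(x)
}

#' Pairwise FST between populations from allele-frequency tables
#'
#' Two estimators. `nei_gst` (default) needs only the frequencies: for a
#' pair of populations, per locus `GST = (Ht - Hs) / Ht` with `Hs` the mean
#' within-population expected heterozygosity and `Ht` the expected
#' heterozygosity of the mean frequencies; loci are combined by Ht weighting
#' (ratio of sums), so monomorphic loci carry no weight. `weir_cockerham` is
#' the two-level variance-components estimator; published tables carry no
#' genotype data, so its heterozygosity component is taken at its
#' Hardy-Weinberg expectation, and per-pair sample sizes (2N) must be
#' available on the tables. Negative pairwise estimates (possible by
#' sampling noise near FST = 0) are clamped to 0.
#'
#' @param tables list of [freq_table()]s, or the output of [align_loci()].
#' @param estimator `"nei_gst"` or `"weir_cockerham"`.
#' @return a `dist_matrix` (symmetric, zero diagonal) of pairwise FST.
#' @references Nei M (1973) Analysis of gene diversity in subdivided
#'   populations. PNAS 70:3321-3323. Weir BS, Cockerham CC (1984) Estimating
#'   F-statistics for the analysis of population structure. Evolution
#'   38:1358-1370.
#' @export
pairwise_fst <- function(tables, estimator = c("nei_gst", "weir_cockerham")) {
  estimator <- match.arg(estimator)
  al <- get_aligned(tables)
  loci <- attr(al, "loci_used")
  if (is.null(loci)) loci <- names(al[[1L]]$freqs)
  np <- length(al)
  labels <- names(al)
  m <- matrix(0, np, np)
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    m[i, j] <- m[j, i] <- switch(estimator,
      nei_gst = fst_gst_pair(al[[i]]$freqs, al[[j]]$freqs),
      weir_cockerham = fst_wc_pair(al[[i]], al[[j]]))
  }
  new_dist_matrix(m, labels, paste0("fst_", estimator), loci)
}

fst_gst_pair <- function(fx, fy) {
  num <- den <- 0
  for (l in names(fx)) {
    x <- fx[[l]]; y <- fy[[l]]
    hs <- 1 - (sum(x^2) + sum(y^2)) / 2
    ht <- 1 - sum(((x + y) / 2)^2)
    num <- num + (ht - hs)
    den <- den + ht
  }
  if (den == 0) stop("all loci monomorphic across both populations; FST undefined")
  num / den
}

fst_wc_pair <- function(tx, ty) {
  n1 <- tx$sample_size_2n / 2; n2 <- ty$sample_size_2n / 2
  if (anyNA(n1) || anyNA(n2))
    stop("weir_cockerham needs sample sizes (2N) on both tables")
  r <- 2
  sum_a <- sum_all <- 0
  for (l in names(tx$freqs)) {
    x <- tx$freqs[[l]]; y <- ty$freqs[[l]]
    ni <- c(n1[[l]], n2[[l]])
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    for (a in seq_along(x)) {
      p_i <- c(x[a], y[a])
      pbar <- sum(ni * p_i) / sum(ni)
      s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
      # no genotype data: observed heterozygote frequency at its HWE expectation
      h_i <- 2 * p_i * (1 - p_i)
      hbar <- sum(ni * h_i) / sum(ni)
      A <- nbar / nc * (s2 - 1 / (nbar - 1) *
             (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      B <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
             (2 * nbar - 1) / (4 * nbar) * hbar)
      C <- hbar / 2
      sum_a <- sum_a + A
      sum_all <- sum_all + A + B + C
    }
  }
  if (sum_all == 0) stop("all loci monomorphic across both populations; FST undefined")
  sum_a / sum_all
}

#' Nei genetic distances between populations
#'
#' `standard_ds` is Nei's standard distance
#' `Ds = -ln( Jxy / sqrt(Jx Jy) )` with the gene-identity sums
#' `J = sum over loci and alleles` of the frequency products; `da` is the
#' shared-allele distance `DA = 1 - (1/L) sum_l sum_i sqrt(x_i y_i)`. A pair
#' with no shared alleles anywhere has `Jxy = 0` and infinite Ds; it is
#' reported as the largest finite pairwise Ds plus 1 with a message.
#'
#' @param tables list of [freq_table()]s, or the output of [align_loci()].
#' @param variant `"standard_ds"` or `"da"`.
#' @return a `dist_matrix` of pairwise distances.
#' @references Nei M (1972) Genetic distance between populations.
#'   Am Nat 106:283-292. Nei M, Tajima F, Tateno Y (1983) Accuracy of
#'   estimated phylogenetic trees from molecular data. J Mol Evol 19:153-170.
#' @export
nei_distance <- function(tables, variant = c("standard_ds", "da")) {
  variant <- match.arg(variant)
  al <- get_aligned(tables)
  loci <- attr(al, "loci_used")
  if (is.null(loci)) loci <- names(al[[1L]]$freqs)
  np <- length(al)
  m <- matrix(0, np, np)
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    fx <- al[[i]]$freqs; fy <- al[[j]]$freqs
    if (variant == "standard_ds") {
      jx <- sum(vapply(loci, function(l) sum(fx[[l]]^2), 0))
      jy <- sum(vapply(loci, function(l) sum(fy[[l]]^2), 0))
      jxy <- sum(vapply(loci, function(l) sum(fx[[l]] * fy[[l]]), 0))
      m[i, j] <- m[j, i] <- if (jxy == 0) Inf else -log(jxy / sqrt(jx * jy))
    } else {
      m[i, j] <- m[j, i] <-
        1 - mean(vapply(loci, function(l) sum(sqrt(fx[[l]] * fy[[l]])), 0))
    }
  }
  if (any(is.infinite(m))) {
    fin <- max(m[is.finite(m)], 0)
    message("population pair(s) share no alleles; infinite Ds reported as ",
            fin + 1)
    m[is.infinite(m)] <- fin + 1
  }
  new_dist_matrix(m, names(al), paste0("nei_", variant), loci)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties in Q are
#' broken deterministically by the lowest (row, column) index pair. Negative
#' branch-length estimates (possible for non-additive input) are clamped to
#' 0 with the negative amount transferred to the sibling branch, preserving
#' the joined pair's path length. For additive distance matrices the input
#' tree is recovered exactly.
#'
#' @param d a `dist_matrix` (or plain symmetric matrix with dimnames) over
#'   >= 3 populations.
#' @return an unrooted [ape::ape-package] `phylo` tree with branch lengths.
#' @references Saitou N, Nei M (1987) The neighbor-joining method. Mol Biol
#'   Evol 4:406-425.
#' @export
neighbor_joining <- function(d) {
  m <- unclass(as.matrix(d))
  n <- nrow(m)
  if (n < 3L) stop("neighbor-joining needs at least 3 populations")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("t", seq_len(n))
  labels <- rownames(m)
  # active nodes carry ape-style ids: tips 1..n, internals n+1, n+2, ...
  ids <- seq_len(n)
  next_node <- n + 1L
  edge <- matrix(0L, 0L, 2L); elen <- numeric()
  while (length(ids) > 2L) {
    r <- length(ids)
    rs <- rowSums(m)
    q <- (r - 2) * m - outer(rs, rs, `+`)
    diag(q) <- Inf
    w <- which(q == min(q), arr.ind = TRUE)
    w <- w[w[, 1L] < w[, 2L], , drop = FALSE]
    w <- w[order(w[, 1L], w[, 2L]), , drop = FALSE][1L, ]  # lowest index pair
    i <- w[1L]; j <- w[2L]
    li <- m[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- m[i, j] - li
    # clamp negatives, preserving li + lj
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    edge <- rbind(edge, c(next_node, ids[i]), c(next_node, ids[j]))
    elen <- c(elen, li, lj)
    du <- (m[i, ] + m[j, ] - m[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    m2 <- rbind(cbind(m[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    ids <- c(ids[keep], next_node)
    m <- m2
    next_node <- next_node + 1L
  }
  # join the last two nodes by a single edge
  root <- if (ids[2L] > length(labels)) ids[2L] else ids[1L]
  other <- setdiff(ids, root)
  edge <- rbind(edge, c(root, other))
  elen <- c(elen, max(m[1L, 2L], 0))
  # renumber internal nodes into ape convention (root = n+1, preorder-ish)
  internal <- sort(unique(edge[edge > length(labels)]))
  remap <- integer(max(edge))
  remap[seq_along(labels)] <- seq_along(labels)
  remap[rev(internal)] <- length(labels) + seq_along(internal)
  edge[] <- remap[edge]
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = labels,
                       Nnode = length(internal)),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Serialize a tree to Newick text
#'
#' @param tree a `phylo` tree (e.g. from [neighbor_joining()]).
#' @param digits significant digits for branch lengths.
#' @return single Newick string, terminated by `;`.
#' @export
to_newick <- function(tree, digits = 10L) {
  stopifnot(inherits(tree, "phylo"))
  lab <- tree$tip.label
  needs_quote <- grepl("[][ ():,;']", lab)
  if (any(needs_quote)) {
    # placeholders survive write.tree untouched; then substitute the
    # single-quoted labels (internal quotes doubled, per Newick convention)
    ph <- sprintf("STRPOPKITTIP%dX", seq_along(lab))
    tree$tip.label <- ifelse(needs_quote, ph, lab)
    out <- ape::write.tree(tree, digits = digits)
    for (i in which(needs_quote)) {
      quoted <- paste0("'", gsub("'", "''", lab[i]), "'")
      out <- sub(ph[i], quoted, out, fixed = TRUE)
    }
    return(out)
  }
  ape::write.tree(tree, digits = digits)
}

#' Parse Newick text into a tree
#'
#' @param text Newick string.
#' @return a `phylo` tree.
#' @export
read_newick <- function(text) {
  tr <- ape::read.tree(text = text)
  q <- grepl("^'.*'$", tr$tip.label)
  tr$tip.label[q] <- gsub("''", "'",
                          sub("^'(.*)'$", "\\1", tr$tip.label[q]))
  tr
}

#' Nonmetric multidimensional scaling of a population distance matrix
#'
#' Kruskal's nonmetric MDS: the configuration is initialized by classical
#' (Torgerson) scaling and refined by iterative stress-1 minimization with
#' monotone (pool-adjacent-violators) disparities — the optimization is
#' delegated to [MASS::isoMDS()]. Returned stress is the stress-1 fraction
#' in \[0, 1\]; RSQ is the squared Pearson correlation between the isotonic
#' disparities and the configuration distances. Stress is invariant under
#' rigid motions of the configuration.
#'
#' @param d a `dist_matrix` (or symmetric matrix / `dist`) over >= 3
#'   populations; zero off-diagonal distances are nudged to a tiny positive
#'   value, as nonmetric MDS requires positive dissimilarities.
#' @param k target dimension (default 2), must be < number of populations.
#' @param seed integer seed (recorded; the optimization itself is
#'   deterministic given the classical-scaling start).
#' @param max_iter,tol iteration cap and convergence tolerance passed to the
#'   optimizer.
#' @return list with `points` (populations x k coordinates), `stress`
#'   (stress-1 in \[0,1\]), `rsq`, `k` and `seed`.
#' @references Kruskal JB (1964) Multidimensional scaling by optimizing
#'   goodness of fit to a nonmetric hypothesis. Psychometrika 29:1-27.
#' @export
nmds <- function(d, k = 2L, seed = 1L, max_iter = 200L, tol = 1e-6) {
  m <- unclass(as.matrix(d))
  np <- nrow(m)
  if (np < 3L) stop("nonmetric MDS needs at least 3 populations")
  if (k >= np) stop("k must be smaller than the number of populations")
  if (k < 1L) stop("k must be >= 1")
  lab <- rownames(m)
  eps <- max(m) * 1e-9 + 1e-12
  m[m <= 0] <- eps
  diag(m) <- 0
  dd <- stats::as.dist(m)
  fit <- withr_seed(seed, suppressMessages(
    MASS::isoMDS(dd, k = k, maxit = max_iter, tol = tol, trace = FALSE)))
  conf <- fit$points
  rownames(conf) <- lab
  cd <- stats::as.dist(stats::dist(conf))
  disp <- isotonic_disparities(as.numeric(dd), as.numeric(cd))
  stress <- sqrt(sum((as.numeric(cd) - disp)^2) / sum(as.numeric(cd)^2))
  rsq <- if (stats::sd(disp) == 0 || stats::sd(as.numeric(cd)) == 0) 1
         else stats::cor(disp, as.numeric(cd))^2
  list(points = conf, stress = stress, rsq = rsq, k = as.integer(k),
       seed = as.integer(seed))
}

# monotone (PAVA) disparities of configuration distances against the
# rank-order of the input dissimilarities
isotonic_disparities <- function(diss, confd) {
  o <- order(diss)
  fit <- stats::isoreg(confd[o])
  disp <- numeric(length(confd))
  disp[o] <- fit$yf
  disp
}
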