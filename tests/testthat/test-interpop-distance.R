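make_ft <- function(freqs, pop, n2 = 200L) {
  freq_table(freqs, sample_size_2n = n2, population = pop, tol = 1e-9)
}

test_that("locus alignment intersects panels and unions alleles", {
  t1 <- make_ft(list(A = c("8" = 0.5, "9" = 0.5), B = c("10" = 1),
                     C = c("11" = 0.4, "12" = 0.6)), "p1")
  t2 <- make_ft(list(B = c("10" = 0.7, "11" = 0.3), C = c("12" = 1),
                     D = c("13" = 1)), "p2")
  al <- align_loci(list(t1, t2))
  expect_equal(attr(al, "loci_used"), c("B", "C"))
  expect_equal(names(al[[1]]$freqs$B), c("10", "11"))
  expect_equal(unname(al[[1]]$freqs$B), c(1, 0))  # zero-fill for absent alleles
  expect_error(align_loci(list(t1)), "at least two")
  t3 <- make_ft(list(Z = c("8" = 1)), "p3")
  expect_error(align_loci(list(t1, t3)), "no locus shared")
  # identical tables pass through unchanged
  ali <- align_loci(list(t1, make_ft(t1$freqs, "p1b")))
  expect_equal(ali[[1]]$freqs$A, t1$freqs$A)
  # a 21-locus panel against a 15-locus panel runs on the 15 shared loci
  big <- bahrain_freqs()
  small <- freq_table(big$freqs[seq_len(15)], sample_size_2n = 400L,
                      population = "lit", tol = 0.005)
  expect_length(attr(align_loci(list(big, small)), "loci_used"), 15L)
})

test_that("Nei GST matches its closed form and vanishes for identical pops", {
  t1 <- make_ft(list(L = c("8" = 0.2, "9" = 0.8)), "p1")
  t2 <- make_ft(list(L = c("8" = 0.8, "9" = 0.2)), "p2")
  f <- pairwise_fst(list(t1, t2), estimator = "nei_gst")
  expect_equal(f[1, 2], 0.36, tolerance = 1e-12)
  same <- pairwise_fst(list(t1, make_ft(t1$freqs, "p1b")), "nei_gst")
  expect_equal(max(same), 0)
  expect_equal(unclass(f), t(unclass(f)), ignore_attr = TRUE)
  expect_equal(diag(f), c(p1 = 0, p2 = 0))
  mono <- make_ft(list(L = c("8" = 1)), "m1")
  expect_error(pairwise_fst(list(mono, make_ft(mono$freqs, "m2"))),
               "monomorphic")
})

test_that("GST increases monotonically with the divergence parameter", {
  loci <- lapply(stats::setNames(1:10, sprintf("L%02d", 1:10)), function(i) {
    p <- sample_frequency_vector(6, 2, seed = 600 + i)
    names(p) <- as.character(8:13)
    p
  })
  est <- vapply(c(0.01, 0.05, 0.1), function(F) {
    mean(vapply(1:5, function(s) {
      cfg <- sim_config(n_individuals = 400, n_populations = 2, fst = F,
                        seed = 900 + s, loci = loci)
      fts <- lapply(simulate_structured_populations(cfg), estimate_frequencies)
      pairwise_fst(fts, "nei_gst")[1, 2]
    }, 0))
  }, 0)
  expect_true(all(diff(est) > 0))
})

test_that("Nei distances follow their definitions", {
  t1 <- make_ft(list(L = c("8" = 0.5, "9" = 0.5)), "p1")
  expect_equal(max(nei_distance(list(t1, make_ft(t1$freqs, "p2")))), 0)
  expect_equal(max(nei_distance(list(t1, make_ft(t1$freqs, "p2")), "da")), 0)
  # disjoint single-allele pops: DA = 1, Ds infinite (flagged maximal)
  d1 <- make_ft(list(L = c("8" = 1)), "p1")
  d2 <- make_ft(list(L = c("9" = 1)), "p2")
  expect_equal(nei_distance(list(d1, d2), "da")[1, 2], 1)
  expect_message(ds <- nei_distance(list(d1, d2), "standard_ds"), "no alleles")
  expect_true(is.finite(ds[1, 2]) && ds[1, 2] > 0)
  # random Dirichlet pairs: symmetry, nonnegativity, direct-formula oracle
  set.seed(11)
  for (i in 1:100) {
    k <- sample(2:10, 1)
    p <- sample_frequency_vector(k); q <- sample_frequency_vector(k)
    names(p) <- names(q) <- as.character(seq_len(k) + 5)
    ds <- nei_distance(list(make_ft(list(L = p), "x"),
                            make_ft(list(L = q), "y")), "standard_ds")[1, 2]
    oracle <- -log(sum(p * q) / sqrt(sum(p^2) * sum(q^2)))
    expect_equal(ds, oracle, tolerance = 1e-12)
    expect_gte(ds, 0)
  }
})

test_that("neighbor-joining solves the three-point configuration exactly", {
  m <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(m)
  expect_equal(to_newick(tr), "(A:0.5,B:1.5,C:2.5);")
  expect_error(neighbor_joining(m[1:2, 1:2]), "at least 3")
})

test_that("neighbor-joining recovers additive matrices exactly", {
  for (seed in 1:8) {
    n <- sample(4:10, 1)
    ref <- random_additive(n, seed = seed * 13)
    tr <- neighbor_joining(ref$d)
    expect_equal(tree_path_lengths(tr, rownames(ref$d)), ref$d,
                 tolerance = 1e-9)
    # topology agrees with the generating tree
    expect_equal(ape::dist.topo(ape::unroot(ref$tree), ape::unroot(tr)),
                 structure(0, names = NULL), ignore_attr = TRUE)
  }
})

test_that("neighbor-joining agrees with an independent implementation", {
  set.seed(23)
  x <- matrix(rnorm(6 * 4), 6)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(letters[1:6], letters[1:6])
  ours <- neighbor_joining(d)
  theirs <- ape::nj(as.dist(d))
  expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(theirs)),
               structure(0, names = NULL), ignore_attr = TRUE)
  expect_equal(sort(tree_path_lengths(ours, letters[1:6])),
               sort(ape::cophenetic.phylo(theirs)[letters[1:6], letters[1:6]]),
               tolerance = 1e-9)
})

test_that("negative branch estimates are clamped with length transfer", {
  # non-additive matrix known to produce a negative NJ branch estimate
  m <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  m[1, 2] <- m[2, 1] <- 0.0001  # near-duplicate pair
  tr <- neighbor_joining(m)
  expect_true(all(tr$edge.length >= 0))
})

test_that("Newick serialization round-trips topology and lengths", {
  ref <- random_additive(7, seed = 5)
  tr <- neighbor_joining(ref$d)
  back <- read_newick(to_newick(tr))
  expect_equal(tree_path_lengths(back, rownames(ref$d)),
               tree_path_lengths(tr, rownames(ref$d)), tolerance = 1e-9)
  # labels with spaces survive the round trip
  m <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3)
  dimnames(m) <- list(c("pop one", "pop two", "C"), c("pop one", "pop two", "C"))
  nw <- to_newick(neighbor_joining(m))
  back2 <- read_newick(nw)
  expect_setequal(back2$tip.label, c("pop one", "pop two", "C"))
})

test_that("nonmetric MDS embeds, converges and is rigid-motion invariant", {
  # three equidistant populations embed exactly in the plane
  m <- matrix(1, 3, 3) - diag(3)
  dimnames(m) <- list(c("A", "B", "C"), c("A", "B", "C"))
  o <- nmds(m, k = 2, seed = 1)
  expect_lt(o$stress, 1e-6)
  expect_error(nmds(m, k = 3), "smaller")
  # distances generated from planar points are recovered below stress 0.01
  set.seed(2)
  X <- matrix(rnorm(24), 12, 2)
  d <- as.matrix(dist(X)); dimnames(d) <- list(paste0("p", 1:12), paste0("p", 1:12))
  o2 <- nmds(d, k = 2, seed = 3)
  expect_lt(o2$stress, 0.01)
  expect_gte(o2$rsq, 0.99)
  # determinism
  o3 <- nmds(d, k = 2, seed = 3)
  expect_identical(o2$points, o3$points)
  # stress recomputed after a random rigid motion is unchanged
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  moved <- sweep(o2$points %*% R, 2, c(3, -1), `+`)
  expect_equal(stress_from_config(d, moved), stress_from_config(d, o2$points),
               tolerance = 1e-9)
  expect_equal(stress_from_config(d, o2$points), o2$stress, tolerance = 1e-9)
})
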