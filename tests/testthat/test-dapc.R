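test_that("strongly differentiated populations are perfectly re-assigned", {
  sim <- simulate_populations(2, 30, 30, fst = 0.5, seed = test_seed(20))
  m <- fit_dapc(sim$geno, sim$labels, n_pca = 10)
  pred <- predict(m, sim$geno)
  expect_identical(unname(pred$assign), sim$labels)
  # a sample deep inside its group is assigned with near-certain posterior
  expect_gt(min(apply(pred$posterior, 1, max)), 0.9)
})

test_that("discriminant axes are capped at groups - 1", {
  sim <- simulate_populations(3, 15, 40, fst = 0.3, seed = test_seed(21))
  m <- fit_dapc(sim$geno, sim$labels, n_pca = 20)
  expect_identical(m$n_da, 2L)
  m2 <- fit_dapc(sim$geno, sim$labels, n_pca = 20, n_da = 10)
  expect_identical(m2$n_da, 2L)
})

test_that("full-rank DAPC reproduces plain-LDA assignments (MASS oracle)", {
  skip_if_not_installed("MASS")
  sim <- simulate_populations(3, 20, 20, fst = 0.05, seed = test_seed(22))
  x <- mean_fill(sim$geno)                 # 60 x 20
  m <- fit_dapc(x, sim$labels, n_pca = min(nrow(x) - 1, ncol(x)))
  pred <- predict(m, x)
  oracle <- MASS::lda(x, grouping = sim$labels)
  expect_identical(unname(pred$assign),
                   as.character(predict(oracle, x)$class))
})

test_that("posteriors are proper and ties break lexicographically", {
  # mirror-symmetric one-locus data: the midpoint is exactly equidistant
  x <- matrix(c(0, 0, 2, 2), ncol = 1, dimnames = list(NULL, "L1"))
  m <- fit_dapc(x, c("zeta", "zeta", "alpha", "alpha"), n_pca = 1)
  pred <- predict(m, matrix(1, 1, 1, dimnames = list("mid", "L1")))
  expect_equal(unname(pred$posterior[1, ]), c(0.5, 0.5), tolerance = 1e-10)
  expect_identical(unname(pred$assign), "alpha")

  sim <- simulate_populations(4, 10, 50, fst = 0.1, seed = test_seed(23),
                              missing_rate = 0.05)
  m2 <- fit_dapc(sim$geno, sim$labels, n_pca = 15)
  pred2 <- predict(m2, sim$geno)
  expect_equal(rowSums(pred2$posterior), rep(1, 40), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(m2$priors), 1, tolerance = 1e-12)
})

test_that("prediction mean-fills missing and absent loci from the training data", {
  sim <- simulate_populations(2, 25, 60, fst = 0.4, seed = test_seed(24))
  m <- fit_dapc(sim$geno, sim$labels, n_pca = 10)
  # drop a third of the panel entirely and mask some remaining calls
  sub <- sim$geno$tab[, 1:40]
  sub[cbind(1:10, 1:10)] <- NA
  pred <- predict(m, sub)
  expect_gt(mean(pred$assign == sim$labels), 0.95)
  expect_error(predict(m, matrix(0, 1, 1, dimnames = list("s", "nope"))),
               "no overlap")
})

test_that("per-axis contributions are normalized and flag the diagnostic locus", {
  sim <- simulate_planted_panel(2, 30, 50, n_diagnostic = 1,
                                fst_diagnostic = 0.7, fst_background = 0.01,
                                seed = test_seed(25))
  m <- fit_dapc(sim$geno, sim$labels, n_pca = 10)
  expect_equal(colSums(m$contrib), rep(1, m$n_da), tolerance = 1e-10,
               ignore_attr = TRUE)
  # the planted locus tops both the LD-value ranking and the FST oracle
  top <- rank_loci(m)[1]
  fst_by_locus <- wc_fst_per_locus(mean_fill(sim$geno), sim$labels)
  expect_identical(top, sim$diagnostic_loci)
  expect_identical(locus_ids(sim$geno)[which.max(fst_by_locus)],
                   sim$diagnostic_loci)
})

test_that("with permuted labels no locus dominates the contribution ranking", {
  # exchangeable loci (identical frequency, no structure), data redrawn per
  # replicate, so the top-ranked locus is uniform by symmetry
  set.seed(test_seed(27))
  tops <- replicate(200, {
    sim <- simulate_populations(2, 30, 50, fst = 0,
                                freq_range = c(0.5, 0.5))
    perm <- sample(sim$labels)
    which(locus_ids(sim$geno) == rank_loci(
      fit_dapc(sim$geno, perm, n_pca = 10))[1])
  })
  # chi-square uniformity over loci not rejected at alpha = 0.01
  observed <- tabulate(tops, nbins = 50)
  p <- stats::chisq.test(observed, p = rep(1 / 50, 50),
                         simulate.p.value = TRUE, B = 2000)$p.value
  expect_gt(p, 0.01)
})

test_that("model JSON serialization round-trips predictions", {
  sim <- simulate_populations(3, 12, 30, fst = 0.2, seed = test_seed(28))
  m <- fit_dapc(sim$geno, sim$labels, n_pca = 8)
  f <- withr::local_tempfile(fileext = ".json")
  write_dapc(m, f)
  m2 <- read_dapc(f)
  p1 <- predict(m, sim$geno)
  p2 <- predict(m2, sim$geno)
  expect_identical(p1$assign, p2$assign)
  expect_equal(p1$posterior, p2$posterior, tolerance = 1e-12)
})

test_that("cross-validation picks the smallest candidate on separable data", {
  sim <- simulate_populations(2, 30, 40, fst = 0.5, seed = test_seed(29))
  xv <- xval_select_npca(sim$geno, sim$labels, grid = c(5, 10, 20),
                         reps = 5, seed = 7)
  expect_true(all(xv$grid$mean_success == 1))
  expect_identical(xv$chosen, 5L)
  # same seed -> identical report
  xv2 <- xval_select_npca(sim$geno, sim$labels, grid = c(5, 10, 20),
                          reps = 5, seed = 7)
  expect_identical(xv$grid, xv2$grid)
  expect_true(all(xv$grid$mean_success >= 0 & xv$grid$mean_success <= 1))
})

test_that("cross-validation guards degenerate splits", {
  sim <- simulate_populations(2, 3, 20, fst = 0.3, seed = test_seed(30))
  expect_error(xval_select_npca(sim$geno, sim$labels, grid = 5,
                                training_fraction = 0.5, reps = 2),
               "fewer than 2 training samples")
  expect_error(xval_select_npca(sim$geno, sim$labels, grid = 5,
                                training_fraction = 1.5), "training_fraction")
})
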