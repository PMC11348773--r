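test_that("allele frequencies follow the pseudocount formula", {
  g <- genotype_matrix(matrix(c(0, 1, 2), 3, 1,
                              dimnames = list(paste0("s", 1:3), "L1")))
  fr <- estimate_frequencies(g, rep("A", 3), pseudocount = 0)
  expect_equal(unname(fr$freq["A", "L1"]), 0.5)   # 3 alt alleles / 6

  g0 <- genotype_matrix(matrix(0, 10, 1, dimnames = list(paste0("s", 1:10), "L1")))
  fr0 <- estimate_frequencies(g0, rep("A", 10), pseudocount = 0.5)
  expect_equal(unname(fr0$freq["A", "L1"]), 0.5 / 21)

  # monotone in alt-allele count, strictly inside (0,1) with pseudocount
  tabs <- lapply(0:4, function(k) matrix(c(rep(2, k), rep(0, 4 - k)), 4, 1))
  freqs <- vapply(tabs, function(tb)
    estimate_frequencies(genotype_matrix(tb), rep("A", 4))$freq[1, 1],
    numeric(1))
  expect_true(all(diff(freqs) > 0))
  expect_true(all(freqs > 0 & freqs < 1))
})

test_that("likelihood self-assignment is near-perfect at strong differentiation", {
  sim <- simulate_populations(4, 40, 200, fst = 0.2, seed = test_seed(40))
  fr <- estimate_frequencies(sim$geno, sim$labels)
  set.seed(test_seed(41))
  wins <- replicate(500, {
    pop <- sample(rownames(sim$pop_freq), 1)
    s <- stats::setNames(rbinom(200, 2, sim$pop_freq[pop, ]),
                         colnames(fr$freq))
    assign_sample(fr, s, method = "loglik")$winner == pop
  })
  expect_gte(mean(wins), 0.98)
})

test_that("missing loci are skipped and shared-locus checks enforced", {
  sim <- simulate_populations(2, 30, 100, fst = 0.3, seed = test_seed(42))
  fr <- estimate_frequencies(sim$geno, sim$labels)
  s <- sim$geno$tab[1, ]
  s[1:60] <- NA
  res <- assign_sample(fr, s)
  expect_identical(res$n_loci, 40L)
  expect_identical(res$winner, "pop1")
  s_all_na <- s; s_all_na[] <- NA
  expect_error(assign_sample(fr, s_all_na), "no shared non-missing loci")
})

test_that("identical reference populations tie, flagged and broken lexicographically", {
  tab <- matrix(c(0, 1, 2, 0, 1, 2), 6, 2,
                dimnames = list(paste0("s", 1:6), c("L1", "L2")))
  labels <- c("zulu", "zulu", "zulu", "echo", "echo", "echo")
  tab[4:6, ] <- tab[1:3, ]                 # make the populations identical
  fr <- estimate_frequencies(genotype_matrix(tab), labels)
  res <- assign_sample(fr, c(L1 = 1, L2 = 1))
  expect_true(res$ambiguous)
  expect_identical(res$winner, "echo")     # lexicographic tie-break
  res_d <- assign_sample(fr, c(L1 = 1, L2 = 1), method = "distance")
  expect_true(res_d$ambiguous)
  expect_identical(res_d$winner, "echo")
})

test_that("the winner switches when a genetically closer reference is added", {
  # an admixed sample drawn mostly from pop3's gene pool, scored first
  # against references {pop1, pop2} only, then with pop3 added
  sim <- simulate_populations(3, 40, 200, fst = 0.2, seed = test_seed(43),
                              admixture = matrix(c(0.25, 0, 0.75), 1))
  adm_id <- sample_ids(sim$geno)[sim$labels == "admixed"]
  adm <- sim$geno$tab[adm_id, ]
  ref12 <- sim$labels %in% c("pop1", "pop2")
  fr12 <- estimate_frequencies(sim$geno[ref12, ], sim$labels[ref12])
  fr123 <- estimate_frequencies(sim$geno[sim$labels != "admixed", ],
                                sim$labels[sim$labels != "admixed"])
  w_before <- assign_sample(fr12, adm)$winner
  w_after <- assign_sample(fr123, adm)$winner
  expect_identical(w_before, "pop1")       # closest available reference
  expect_identical(w_after, "pop3")        # true main ancestor, once present
})

test_that("self-assignment accuracy rises with differentiation (Monte Carlo)", {
  acc <- vapply(c(0.01, 0.05, 0.1, 0.2), function(f) {
    sim <- simulate_populations(4, 30, 150, fst = f,
                                seed = test_seed(44) + round(1000 * f))
    fr <- estimate_frequencies(sim$geno, sim$labels)
    set.seed(test_seed(45))
    mean(replicate(500, {
      pop <- sample(rownames(sim$pop_freq), 1)
      s <- stats::setNames(rbinom(150, 2, sim$pop_freq[pop, ]),
                           colnames(fr$freq))
      assign_sample(fr, s)$winner == pop
    }))
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
  expect_gt(acc[4], acc[1])
})

test_that("likelihood and distance methods agree on separated populations", {
  sim <- simulate_populations(3, 30, 150, fst = 0.2, seed = test_seed(46))
  fr <- estimate_frequencies(sim$geno, sim$labels)
  both <- vapply(seq_len(nrow(sim$geno$tab)), function(i) {
    a <- assign_sample(fr, sim$geno$tab[i, ], method = "loglik")$winner
    b <- assign_sample(fr, sim$geno$tab[i, ], method = "distance")$winner
    a == b
  }, logical(1))
  expect_gte(mean(both), 0.95)
})

test_that("GenePop files round-trip genotypes and population structure", {
  sim <- simulate_populations(2, 5, 12, fst = 0.3, seed = test_seed(47),
                              missing_rate = 0.1)
  f <- withr::local_tempfile(fileext = ".gen")
  write_genepop(sim$geno, sim$labels, f)
  back <- read_genepop(f)
  expect_identical(back$geno$tab, sim$geno$tab)
  expect_identical(back$labels,
                   c(rep("pop1", 5), rep("pop2", 5)))
})
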