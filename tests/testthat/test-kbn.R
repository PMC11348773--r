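test_that("ward_cluster matches the brute-force minimum-variance oracle", {
  for (s in 1:50) {
    set.seed(test_seed(100 + s))
    n <- sample(6:10, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    d <- ward_cluster(x)
    oracle <- brute_force_ward(x)
    expect_identical(ward_merge_pairs(d), oracle$pairs)
    expect_equal(d$height, oracle$heights, tolerance = 1e-8)
  }
})

test_that("ward heights agree with stats::hclust on squared distances", {
  set.seed(test_seed(150))
  x <- matrix(rnorm(40 * 5), 40, 5)
  d <- ward_cluster(x)
  h <- stats::hclust(stats::dist(x)^2, method = "ward.D")
  expect_equal(sort(d$height), sort(h$height), tolerance = 1e-8)
})

test_that("identical samples merge first at height zero, heights monotone", {
  x <- rbind(c(1, 1), c(5, 0), c(1, 1), c(9, 9))
  d <- ward_cluster(x)
  expect_identical(d$merge[1, ], c(-1L, -3L))
  expect_equal(d$height[1], 0)
  expect_true(all(diff(d$height) >= -1e-12))
})

test_that("dendrogram utilities: members, cutting, newick export", {
  sim <- simulate_populations(2, 10, 80, fst = 0.4, seed = test_seed(151))
  d <- ward_cluster(sim$geno)
  members <- dendro_members(d)
  expect_identical(sort(members[[length(members)]]), sort(sample_ids(sim$geno)))
  expect_identical(length(unique(cut_dendrogram(d, k = 20))), 20L)
  expect_identical(length(unique(cut_dendrogram(d, k = 1))), 1L)
  # k = 2 on well-separated populations recovers the true labels
  cl <- cut_dendrogram(d, k = 2)
  expect_identical(length(unique(tapply(sim$labels, cl, unique))), 2L)
  expect_error(cut_dendrogram(d, h = -1), "non-negative")
  f <- withr::local_tempfile(fileext = ".nwk")
  export_newick(d, f)
  tree <- ape::read.tree(f)
  expect_identical(sort(tree$tip.label), sort(sample_ids(sim$geno)))
})

test_that("node genotype profiles are proportions with the parent identity", {
  g <- genotype_matrix(rbind(s1 = c(0, 2), s2 = c(1, 2),
                             s3 = c(1, NA), s4 = c(2, 0)))
  # single-sample node: indicator profile
  p1 <- node_genotype_profile(g, "s1")
  expect_identical(unname(p1[, 1]), c(1, 0, 0))
  # {0,1,1,2} -> (0.25, 0.5, 0.25)
  p_all <- node_genotype_profile(g, c("s1", "s2", "s3", "s4"))
  expect_equal(unname(p_all[, 1]), c(0.25, 0.5, 0.25))
  expect_equal(colSums(p_all), c(1, 1), ignore_attr = TRUE)

  # parent profile = member-weighted mean of child profiles (complete data)
  set.seed(test_seed(152))
  tab <- matrix(sample(0:2, 12 * 6, replace = TRUE), 12, 6)
  gm <- genotype_matrix(tab)
  left <- sample_ids(gm)[1:5]; right <- sample_ids(gm)[6:12]
  parent <- node_genotype_profile(gm, c(left, right))
  blend <- (5 * node_genotype_profile(gm, left) +
              7 * node_genotype_profile(gm, right)) / 12
  expect_equal(parent, blend, tolerance = 1e-12, ignore_attr = TRUE)

  # all-missing locus is reported undefined
  g2 <- genotype_matrix(rbind(a = c(0, NA), b = c(1, NA)))
  p2 <- node_genotype_profile(g2, c("a", "b"))
  expect_identical(attr(p2, "undefined"), "locus2")
  expect_error(node_genotype_profile(g, character(0)), "empty")
})

test_that("topology constructors validate their shape", {
  expect_error(kbn_node("x"), "children or terminal labels")
  expect_error(kbn_node("x", children = list(kbn_node("y", labels = "A"))),
               "at least 2 children")
  expect_error(kbn_node("x", labels = c("A", "B", "C")), "1 label, or 2")
  dup <- kbn_node("root", children = list(kbn_node("a", labels = "A"),
                                          kbn_node("b", labels = "A")))
  expect_error(build_kbn(matrix(0, 4, 4), rep("A", 4), dup), "two terminals")
  topo <- default_bee_topology()
  expect_s3_class(topo, "kbn_node")
  labs <- snpcascade:::node_labels(topo)
  expect_identical(anyDuplicated(labs), 0L)
  expect_true(all(c("Puerto_Rico", "EU_lig_like", "A_m_scutellata") %in% labs))
})

test_that("a cascade over four simulated populations routes correctly", {
  sim <- simulate_populations(4, 25, 150, fst = 0.2, seed = test_seed(153))
  cent <- rowsum(mean_fill(sim$geno), sim$labels) / 25
  topo <- topology_from_dendrogram(ward_cluster(cent))
  net <- build_kbn(sim$geno, sim$labels, topo, seed = 5,
                   xval_grid = c(5, 10), xval_reps = 3)
  # every node classifier re-assigns its own training samples near-perfectly
  for (id in names(net$models)) {
    m <- net$models[[id]]
    node_sims <- sim$labels %in% snpcascade:::node_labels(
      Find(function(n) n$id == id, snpcascade:::flatten_topology(topo)))
    pr <- predict(m, mean_fill(sim$geno)[node_sims, , drop = FALSE])
    expect_gte(mean(apply(pr$posterior, 1, max) > 0.5), 0.98)
  }
  # reference samples replayed as unknowns come back to their own label
  res <- predict_kbn(net, sim$geno)
  expect_gte(mean(res$assignments$final == sim$labels), 0.99)
  expect_identical(nrow(res$rejected), 0L)
  # routing is deterministic
  res2 <- predict_kbn(net, sim$geno)
  expect_identical(res$assignments, res2$assignments)
  # a fresh sample drawn from pop frequencies starts down the right branch
  fresh <- matrix(rbinom(150, 2, sim$pop_freq["pop1", ]), 1, 150,
                  dimnames = list("fresh", locus_ids(sim$geno)))
  r <- predict_kbn(net, fresh)
  first_hop <- strsplit(r$assignments$path, ">")[[1]][2]
  side <- snpcascade:::node_labels(Find(function(n) n$id == first_hop,
                                        snpcascade:::flatten_topology(topo)))
  expect_true("pop1" %in% side)
  expect_identical(r$assignments$final, "pop1")
})

test_that("double-assignation terminals resolve through the secondary model", {
  sim <- simulate_populations(3, 20, 120, fst = 0.25, seed = test_seed(154),
                              pop_names = c("east", "north", "west"))
  topo <- kbn_node("root", children = list(
    kbn_node("A_1", labels = c("east", "north")),   # resolved in tier II
    kbn_node("A_2", labels = "west")))
  net <- build_kbn(sim$geno, sim$labels, topo, seed = 9,
                   xval_grid = c(5, 10), xval_reps = 3)
  expect_named(net$tier2, "A_1")
  res <- predict_kbn(net, sim$geno)
  expect_gte(mean(res$assignments$final == sim$labels), 0.95)
  expect_true(all(res$assignments$final %in% c("east", "north", "west")))
})

test_that("samples over the missing-loci cutoff are rejected, not labeled", {
  sim <- simulate_populations(2, 20, 150, fst = 0.3, seed = test_seed(155))
  topo <- kbn_node("root", children = list(kbn_node("A_1", labels = "pop1"),
                                           kbn_node("A_2", labels = "pop2")))
  net <- build_kbn(sim$geno, sim$labels, topo, seed = 2,
                   xval_grid = c(5, 10), xval_reps = 3)
  unk <- sim$geno$tab[1:3, ]
  unk[1, 1:97] <- NA                       # over a 96-locus cutoff
  unk[2, ] <- NA                           # everything missing
  res <- predict_kbn(net, unk, max_missing = 96)
  expect_setequal(res$rejected$sample, c("s001", "s002"))
  expect_identical(res$assignments$sample, "s003")
  # absent columns count as missing panel loci too
  narrow <- sim$geno$tab[3, 1:40, drop = FALSE]
  res2 <- predict_kbn(net, narrow, max_missing = 96)
  expect_identical(res2$rejected$n_missing, 110)
  expect_error(predict_kbn(net, matrix(0, 1, 1, dimnames = list("q", "zz"))),
               "not in panel")
})

test_that("rebuilding with the same seed gives identical serialized networks", {
  sim <- simulate_populations(3, 15, 80, fst = 0.25, seed = test_seed(156))
  cent <- rowsum(mean_fill(sim$geno), sim$labels) / 15
  topo <- topology_from_dendrogram(ward_cluster(cent))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  net1 <- build_kbn(sim$geno, sim$labels, topo, seed = 42,
                    xval_grid = c(5, 10), xval_reps = 2)
  net2 <- build_kbn(sim$geno, sim$labels, topo, seed = 42,
                    xval_grid = c(5, 10), xval_reps = 2)
  write_kbn(net1, d1); write_kbn(net2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)))
  }
  # and a deserialized network routes identically
  net3 <- read_kbn(d1)
  expect_identical(predict_kbn(net3, sim$geno)$assignments,
                   predict_kbn(net1, sim$geno)$assignments)
})

test_that("build_kbn enforces label coverage and group sizes", {
  sim <- simulate_populations(2, 10, 40, fst = 0.3, seed = test_seed(157))
  topo <- kbn_node("root", children = list(kbn_node("A_1", labels = "pop1"),
                                           kbn_node("A_2", labels = "pop2")))
  labs <- sim$labels; labs[1] <- "mystery"
  expect_error(build_kbn(sim$geno, labs, topo), "not in topology")
  expect_error(build_kbn(sim$geno$tab[1:12, ], sim$labels[1:12], topo),
               "min_group_size")
})
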