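test_that("Yule trees are reproducible, ultrametric and labelled", {
  tree <- simulate_tree(5, birth_rate = 1, seed = 31)
  expect_s3_class(tree, "phylo")
  expect_equal(length(tree$tip.label), 5L)
  expect_equal(tree$Nnode, 4L)
  expect_setequal(tree$tip.label, sprintf("iso_%d", 1:5))
  expect_true(all(tree$edge.length > 0))
  # ultrametric: all tips at the same depth
  depths <- ape::node.depth.edgelength(tree)[1:5]
  expect_lt(diff(range(depths)), 1e-9)
  # determinism and seed sensitivity
  expect_identical(ape::write.tree(simulate_tree(5, seed = 31)),
                   ape::write.tree(tree))
  expect_false(identical(ape::write.tree(simulate_tree(5, seed = 32)),
                         ape::write.tree(tree)))
  expect_error(simulate_tree(1, seed = 1), "n >= 2")
})

test_that("Brownian profiles carry the expected covariance structure", {
  tree <- simulate_tree(4, seed = 77)
  # zero rates: every leaf inherits the root trait exactly
  still <- simulate_profiles(tree, sigma_phylo = 0, sigma_noise = 0,
                             n_metabolites = 6, root_trait = 0.4,
                             seed = 1)
  expect_true(all(still$trait == 0.4))
  expect_true(all(still$depletion > 0 & still$depletion < 1))
  # E[(trait_i - trait_j)^2] = sigma_p^2 d_ij + 2 sigma_n^2,
  # checked by Monte Carlo across many independent metabolite traits
  sp <- 0.8; sn <- 0.3
  sim <- simulate_profiles(tree, sigma_phylo = sp, sigma_noise = sn,
                           n_metabolites = 20000, seed = 4)
  d <- patristic_distances(tree)
  tips <- rownames(sim$trait)
  for (i in 1:3) for (j in (i + 1):4) {
    obs <- mean((sim$trait[tips[i], ] - sim$trait[tips[j], ])^2)
    expected <- sp^2 * d[tips[i], tips[j]] + 2 * sn^2
    expect_lt(abs(obs - expected) / expected, 0.05)
  }
})

test_that("peak tables reflect ground truth exactly when noiseless", {
  tree <- simulate_tree(3, seed = 8)
  truth <- simulate_profiles(tree, sigma_phylo = 1, sigma_noise = 0.2,
                             n_metabolites = 5, seed = 2)
  # override with hand-chosen fractions for sharp expectations
  truth$depletion[] <- 0
  truth$depletion["iso_1", 1] <- 1
  truth$production[] <- FALSE
  cfg <- sim_config(n_isolates = 3, n_metabolites = 5, replicates = 2,
                    n_controls = 2, n_blanks = 1, abundance_cv = 0,
                    blank_fraction = 0.1, seed = 5)
  pt <- simulate_peak_table(truth, cfg)
  ctrl <- pt$mat[, pt$samples$role == "uninoculated_control"]
  cult1 <- pt$mat[, pt$samples$isolate %in% "iso_1"]
  # full depletion, zero noise: abundance exactly 0
  expect_equal(unname(cult1[1, ]), c(0, 0))
  # zero depletion, zero noise: culture equals control
  expect_equal(cult1[-1, ], ctrl[-1, c(1, 2)], ignore_attr = TRUE)
  # blanks at the configured fraction of control
  blank <- pt$mat[, pt$samples$role == "extraction_blank", drop = FALSE]
  expect_equal(unname(blank[, 1]), unname(0.1 * ctrl[, 1]))
  # reproducibility: identical config gives identical tables
  expect_identical(simulate_peak_table(truth, cfg)$mat, pt$mat)
})

test_that("production cells raise abundance by the configured fold", {
  tree <- simulate_tree(2, seed = 9)
  truth <- simulate_profiles(tree, 0, 0, n_metabolites = 3, seed = 1,
                             production_fold = 4)
  truth$depletion[] <- 0.5
  truth$production[] <- FALSE
  truth$production["iso_1", 2] <- TRUE
  cfg <- sim_config(n_isolates = 2, n_metabolites = 3, replicates = 2,
                    n_controls = 2, n_blanks = 0, abundance_cv = 0,
                    seed = 44)
  pt <- simulate_peak_table(truth, cfg)
  ctrl <- pt$mat[, pt$samples$role == "uninoculated_control"][, 1]
  cult <- pt$mat[, pt$samples$sample_id == "iso_1_rep1"]
  expect_equal(unname(cult[2]), unname(4 * ctrl[2]))
  expect_equal(unname(cult[c(1, 3)]), unname(0.5 * ctrl[c(1, 3)]))
})

test_that("logistic growth curves honour lag, asymptote and seed", {
  s <- simulate_growth(0.5, lag = 4, capacity = 0.9, noise_sd = 0,
                       grid = seq(0, 72, by = 0.25), od0 = 0.02)
  expect_equal(s$od[s$time < 4], rep(0.02, sum(s$time < 4)))
  expect_equal(s$od[length(s$od)], 0.9, tolerance = 1e-6)
  noisy1 <- simulate_growth(0.5, noise_sd = 0.01, seed = 3)
  noisy2 <- simulate_growth(0.5, noise_sd = 0.01, seed = 3)
  expect_identical(noisy1$od, noisy2$od)
})

test_that("family assignment cuts the tree into clades", {
  tree <- simulate_tree(20, seed = 12)
  fams <- tree_families(tree, depth = 0.5)
  expect_equal(length(fams), 20L)
  expect_setequal(names(fams), tree$tip.label)
  expect_gte(length(unique(fams)), 2)
  # family members are monophyletic: their induced subtree contains no
  # tip from another family
  for (f in unique(fams)) {
    members <- names(fams)[fams == f]
    if (length(members) >= 2) {
      anc <- ape::getMRCA(tree, members)
      clade <- ape::extract.clade(tree, anc)$tip.label
      expect_true(all(fams[clade] == f))
    }
  }
})

test_that("a strongly depleted panel is recovered end-to-end", {
  tree <- simulate_tree(3, seed = 21)
  truth <- simulate_profiles(tree, 0, 0, n_metabolites = 64, seed = 1)
  truth$depletion[] <- 0.02
  truth$depletion["iso_1", 1:40] <- 0.95  # 40 strong depletions
  truth$production[] <- FALSE
  cfg <- sim_config(n_isolates = 3, n_metabolites = 64, replicates = 3,
                    n_controls = 18, n_blanks = 3, abundance_cv = 0.2,
                    production_prob = 0, seed = 99)
  pt <- simulate_peak_table(truth, cfg)
  calls <- depletion_test(normalize_peaks(blank_subtract(pt)))
  expect_gte(count_significant(calls, "depleted")[["iso_1"]], 38)
})

test_that("null simulations produce significant calls near alpha", {
  tree <- simulate_tree(2, seed = 2)
  truth <- simulate_profiles(tree, 0, 0, n_metabolites = 500, seed = 3)
  truth$depletion[] <- 0
  truth$production[] <- FALSE
  cfg <- sim_config(n_isolates = 2, n_metabolites = 500, replicates = 3,
                    n_controls = 6, n_blanks = 0, abundance_cv = 0.25,
                    production_prob = 0, seed = 15)
  pt <- simulate_peak_table(truth, cfg)
  calls <- depletion_test(normalize_peaks(pt))
  rate <- mean(calls$p < 0.05, na.rm = TRUE)
  expect_lt(rate, 0.12)
})
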