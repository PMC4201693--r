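test_that("out-of-bag membership matches bootstrap arithmetic", {
  sim <- simulate_cc(sim_spec(100, 100, 40, model = "null", seed = 71))
  fit <- tamw(sim$genotypes, sim$phenotype, n_trees = 100, burnin = 10,
              depth_grid = 2, seed = 3)
  # P(OOB for one tree) = (1 - 1/n)^n ~ e^-1; mean T_i ~ 0.368 * n_trees
  expect_lt(abs(mean(fit$oob_count) / fit$n_trees - exp(-1)), 0.02)
  # conservation: sum_i T_i equals the total OOB set size over trees
  expect_equal(sum(fit$oob_count), sum(lengths(fit$oob)))
})

test_that("a single-tree ensemble still yields a valid test", {
  sim <- simulate_cc(sim_spec(60, 60, 20, model = "null", seed = 72))
  expect_warning(
    fit <- tamw(sim$genotypes, sim$phenotype, n_trees = 1, burnin = 1,
                depth_grid = 2, min_group_size = 5, seed = 4),
    "never out-of-bag")
  expect_s3_class(fit$result, "mwu_result")
  oob <- fit$oob_count > 0
  expect_true(all(is.na(fit$lr_assem[!oob])))
  expect_true(all(is.finite(fit$lr_assem[oob])))
})

test_that("mtry outside [1, n_snps] is rejected", {
  sim <- simulate_cc(sim_spec(30, 30, 10, model = "null", seed = 73))
  expect_error(tamw(sim$genotypes, sim$phenotype, n_trees = 5, mtry = 11,
                    seed = 1),
               class = "treemwu_format_error")
})

test_that("the ensemble is reproducible given the master seed", {
  sim <- simulate_cc(sim_spec(80, 80, 30, model = "epistatic_pair",
                              seed = 74))
  a <- tamw(sim$genotypes, sim$phenotype, n_trees = 40, burnin = 10,
            depth_grid = 2:3, seed = 5)
  b <- tamw(sim$genotypes, sim$phenotype, n_trees = 40, burnin = 10,
            depth_grid = 2:3, seed = 5)
  expect_identical(a$result$U, b$result$U)
  expect_identical(a$tree_depth, b$tree_depth)
  expect_identical(a$lr_assem, b$lr_assem)
  expect_identical(a$selection_freq, b$selection_freq)
})

test_that("tamw_score averages the per-tree assignments", {
  sim <- simulate_cc(sim_spec(60, 60, 20, model = "epistatic_pair",
                              seed = 75))
  suppressWarnings(        # a 10-tree ensemble can leave subjects never-OOB
    fit <- tamw(sim$genotypes, sim$phenotype, n_trees = 10, burnin = 5,
                depth_grid = 2, seed = 6))
  sc <- tamw_score(fit, sim$genotypes, subjects = 1:15)
  manual <- rowMeans(vapply(fit$trees, function(tr) {
    if (is.null(tr)) rep(1, 15)
    else assign_lr(tr, sim$genotypes, subjects = 1:15,
                   depth = min(fit$tree_depth, tr$depth))$lr
  }, numeric(15)))
  expect_equal(sc$lr, manual)
})

test_that("training on permuted phenotypes gives near-chance test AUC", {
  sim <- simulate_cc(sim_spec(150, 150, 60, model = "epistatic_pair",
                              seed = 76))
  set.seed(7)
  ph_perm <- phenotype(sample(sim$phenotype$status))
  se <- split_evaluate(function(g, p) tamw(g, p, n_trees = 60, burnin = 15,
                                           depth_grid = 2:3, seed = 8),
                       sim$genotypes, ph_perm, seed = 9)
  expect_lt(abs(se$test_result$U - 0.5), 0.12)
})

test_that("burn-in picks its depth from the candidate grid", {
  sim <- simulate_cc(sim_spec(100, 100, 40, model = "epistatic_pair",
                              seed = 77))
  fit <- tamw(sim$genotypes, sim$phenotype, n_trees = 30, burnin = 20,
              depth_grid = c(2, 4), seed = 10)
  expect_true(fit$tree_depth %in% c(2L, 4L))
  expect_equal(names(fit$burnin_oob_u), c("2", "4"))
})
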