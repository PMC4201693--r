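test_that("allowed partitions are the dominant/recessive pair, plus het with hz", {
  p2 <- enumerate_partitions(FALSE)
  expect_equal(nrow(p2), 2L)
  expect_equal(p2$low, c("0", "0,1"))
  expect_equal(p2$high, c("1,2", "2"))
  p3 <- enumerate_partitions(TRUE)
  expect_equal(nrow(p3), 3L)
  expect_equal(p3$low[3], "1")
  expect_equal(p3$high[3], "0,2")
})

test_that("level-1 search finds a dominant causal SNP among nulls", {
  hits <- vapply(1:12, function(r) {
    s <- simulate_cc(sim_spec(300, 300, 100, model = "marginal",
                              seed = 400 + r))
    t1 <- grow_tree(s$genotypes, s$phenotype, max_depth = 1)
    t1$snp_ids[1] == "SNP1" && t1$part_codes[1] == 0L
  }, logical(1))
  expect_gte(sum(hits), 10L)
})

test_that("training U is strictly increasing in depth and counts conserve", {
  sim <- simulate_cc(sim_spec(200, 200, 60, model = "epistatic_pair",
                              seed = 51))
  tr <- grow_tree(sim$genotypes, sim$phenotype, max_depth = 6)
  expect_true(all(diff(c(tr$u_root, tr$u_path)) > 0))
  for (d in seq_len(tr$depth)) {           # no missing data: full totals
    expect_equal(sum(tr$levels[[d]]$n_case, na.rm = TRUE), 200)
    expect_equal(sum(tr$levels[[d]]$n_control, na.rm = TRUE), 200)
    expect_true(all(tr$levels[[d]]$n_case + tr$levels[[d]]$n_control >=
                      tr$min_group_size, na.rm = TRUE))
    expect_lte(sum(!is.na(tr$levels[[d]]$lr)), 2^d)
  }
})

test_that("null phenotype never errors and deep unconstrained trees overfit", {
  sim <- simulate_cc(sim_spec(100, 100, 40, model = "null", seed = 52))
  tr <- grow_tree(sim$genotypes, sim$phenotype, max_depth = 3)
  expect_s3_class(tr, "risk_group_tree")
  expect_gte(tr$u_path[1], 0.5)

  sep <- simulate_cc(sim_spec(100, 100, 50, model = "epistatic_pair",
                              seed = 53))
  deep <- grow_tree(sep$genotypes, sep$phenotype, max_depth = 10,
                    min_group_size = 1)
  shallow <- grow_tree(sep$genotypes, sep$phenotype, max_depth = 2)
  expect_gt(max(deep$u_path), max(shallow$u_path))
  expect_gt(max(deep$u_path), 0.9)
})

test_that("min_group_size beyond the sample makes the tree inadmissible", {
  sim <- simulate_cc(sim_spec(30, 30, 10, model = "null", seed = 54))
  expect_error(grow_tree(sim$genotypes, sim$phenotype, max_depth = 2,
                         min_group_size = 100),
               class = "treemwu_empty_tree")
})

test_that("tree growth is deterministic given data and parameters", {
  sim <- simulate_cc(sim_spec(150, 150, 50, model = "epistatic_pair",
                              missing_rate = 0.03, seed = 55))
  a <- grow_tree(sim$genotypes, sim$phenotype, max_depth = 5)
  b <- grow_tree(sim$genotypes, sim$phenotype, max_depth = 5)
  expect_identical(a$snp_ids, b$snp_ids)
  expect_identical(a$u_path, b$u_path)
  expect_identical(a$training$lr, b$training$lr)
})

test_that("rescoring training subjects reproduces the leaf plug-in LRs", {
  sim <- simulate_cc(sim_spec(200, 200, 40, model = "epistatic_pair",
                              missing_rate = 0.05, seed = 56))
  tr <- grow_tree(sim$genotypes, sim$phenotype, max_depth = 4)
  a <- assign_lr(tr, sim$genotypes)
  expect_equal(a$lr, tr$training$lr)
  # subjects frozen in training stop at the same point when rescored
  expect_equal(which(!(a$group == tr$training$group) &
                       !tr$training$frozen), integer(0))
})

test_that("an all-missing subject routes to the root with LR 1", {
  set.seed(58)
  g <- rbind(matrix(sample(0:2, 40 * 3, TRUE), 40, 3), NA, NA)
  gm <- genotype_matrix(g)
  ph <- phenotype(rep_len(0:1, 42))
  tr <- grow_tree(gm, ph, max_depth = 2, min_group_size = 2)
  a <- assign_lr(tr, gm, subjects = 41:42)
  expect_equal(a$lr, c(1, 1))
})

test_that("held-out subjects get a valid LR assignment for the MWU", {
  sim <- simulate_cc(sim_spec(200, 200, 50, model = "epistatic_pair",
                              seed = 57))
  train <- c(1:150, 201:350)               # cases first in the simulator
  held <- setdiff(1:400, train)
  tr <- grow_tree(sim$genotypes, sim$phenotype, subjects = train,
                  max_depth = 3)
  a <- assign_lr(tr, sim$genotypes, subjects = held)
  expect_true(all(is.finite(a$lr)))
  r <- mwu(a$lr, sim$phenotype$status[held])
  expect_true(r$U > 0 && r$U < 1)
})

test_that("depth-2 growth reproduces the four-risk-group scheme", {
  cells <- expand.grid(A = 0:1, B = 0:2)
  cells$n_case <- c(20, 60, 20, 60, 20, 40)
  cells$n_control <- c(60, 20, 60, 20, 20, 5)
  dat <- geno_from_cells(cells)
  tr <- grow_tree(dat$gm, dat$ph, max_depth = 2)
  expect_equal(tr$snp_ids, c("A", "B"))
  expect_equal(tr$part_codes, c(0L, 1L))
  # four groups: {0,(0,1)}, {0,2}, {(1,2),(0,1)}, {(1,2),2}
  expect_equal(tr$partitions$low, c("0", "0,1"))
  expect_equal(tr$partitions$high, c("1,2", "2"))
  expect_equal(sum(!is.na(tr$levels[[2]]$lr)), 4L)
})
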