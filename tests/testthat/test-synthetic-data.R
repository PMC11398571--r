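test_that("clean XOR datasets satisfy the structural invariants", {
  ds <- simulate_xor(2, 20, 1600, seed = 11)
  expect_true(all(ds$genotypes %in% 0:2))
  expect_true(all(ds$labels %in% 0:1))
  expect_identical(dim(ds$genotypes), c(1600L, 20L))
  expect_identical(sum(ds$labels == 1L), 800L)
  expect_length(ds$predictive_ids, 2L)
  expect_true(all(ds$predictive_ids %in% ds$feature_names))
  # regenerating with the same seed is bit-identical
  expect_identical(ds, simulate_xor(2, 20, 1600, seed = 11))
  expect_false(identical(ds, simulate_xor(2, 20, 1600, seed = 12)))
})

test_that("XOR class is the parity of the predictive genotypes (full penetrance)", {
  for (k in 2:4) {
    ds <- simulate_xor(k, k + 3, 400, seed = 5 + k)
    bits <- ds$genotypes[, ds$predictive_ids, drop = FALSE] %% 2L
    expect_identical(as.integer(rowSums(bits) %% 2L), ds$labels)
  }
})

test_that("XOR configuration errors are raised", {
  expect_error(simulate_xor(5, 3, 100, seed = 1), "order")
  expect_error(simulate_xor(2, 20, 101, seed = 1), "even")
})

test_that("proper subsets of XOR predictive loci are uninformative", {
  ds <- simulate_xor(3, 3, 20000, seed = 21)
  for (j in 1:3)
    expect_lt(joint_mi(ds, j, base = 2), 0.005)
  for (pair in list(1:2, c(1, 3), 2:3))
    expect_lt(joint_mi(ds, pair, base = 2), 0.005)
  expect_gt(joint_mi(ds, 1:3, base = 2), 0.99)
})

test_that("emitted penetrance models are pure, strict and on-target", {
  m <- build_penetrance_model(2, maf = 0.25, heritability = 0.05,
                              prevalence = 0.5, difficulty = "H",
                              seed = 3, n_candidates = 20)
  expect_lt(max(abs(marginal_penetrance_deviation(m))), 1e-9)
  expect_lt(abs(model_heritability(m) - 0.05), 1e-6)
  expect_lt(abs(model_prevalence(m) - 0.5), 1e-9)
  expect_true(all(m$table >= 0 & m$table <= 1))
})

test_that("difficulty selects architectures by the table-variance proxy", {
  e <- build_penetrance_model(2, 0.2, 0.1, difficulty = "E", seed = 9,
                              n_candidates = 40)
  h <- build_penetrance_model(2, 0.2, 0.1, difficulty = "H", seed = 9,
                              n_candidates = 40)
  expect_lt(var(e$table), var(h$table))
})

test_that("infeasible model requests raise explicit errors", {
  expect_error(build_penetrance_model(1, 0.2, 1), "simulate_main_or_additive")
  # strict 3-way h2 = 0.4 is unattainable at any prevalence
  expect_error(
    build_penetrance_model(3, 0.2, 0.4, seed = 1, n_candidates = 5,
                           max_attempts = 200),
    "infeasible")
  # at fixed K = 0.5 even 2-way h2 = 0.4 is out of reach for MAF 0.2
  expect_error(
    build_penetrance_model(2, 0.2, 0.4, prevalence = 0.5, seed = 1,
                           n_candidates = 5, max_attempts = 500),
    "infeasible")
})

test_that("sample_from_model draws balanced data from the model law", {
  m <- xor_penetrance_model(2)
  ds <- sample_from_model(m, 10, 100000, seed = 31)
  expect_identical(sum(ds$labels == 1L), 50000L)
  # empirical genotype-combo x class counts match the conditional law
  combos <- expand.grid(g1 = 0:2, g2 = 0:2)
  idx <- combos$g1 * 3 + combos$g2
  obs_idx <- ds$genotypes[, "M0P0"] * 3 + ds$genotypes[, "M0P1"]
  f <- as.vector(outer(hwe_freqs(0.5), hwe_freqs(0.5))[cbind(combos$g1 + 1,
                                                             combos$g2 + 1)])
  parity <- (combos$g1 + combos$g2) %% 2
  for (cls in 0:1) {
    w <- f * (if (cls == 1) parity else 1 - parity)
    obs <- tabulate(match(obs_idx[ds$labels == cls], idx), length(idx))
    keep <- w > 0
    expect_gt(suppressWarnings(
      chisq.test(obs[keep], p = w[keep] / sum(w[keep]))$p.value), 0.001)
    expect_true(all(obs[!keep] == 0))
  }
})

test_that("near-zero heritability models carry near-zero signal", {
  m <- build_penetrance_model(2, 0.3, 0.005, seed = 13, n_candidates = 10)
  ds <- sample_from_model(m, 4, 4000, seed = 14)
  expect_lt(joint_mi(ds, ds$predictive_ids), 0.01)
})

test_that("heterogeneous datasets have four predictive features and exact balance", {
  ds <- simulate_heterogeneous(c(0.75, 0.25), 20, 800, 0.4, seed = 41,
                               n_candidates = 20)
  expect_identical(ds$predictive_ids, c("M0P0", "M0P1", "M1P0", "M1P1"))
  expect_identical(sum(ds$labels == 1L), 400L)
  expect_error(simulate_heterogeneous(c(0.6, 0.6), 20, 800, 0.4, seed = 1),
               "sum to 1")
})

test_that("the minority-subgroup pair carries less signal than the majority pair", {
  ds <- simulate_heterogeneous(c(0.75, 0.25), 4, 40000, 0.4, seed = 43,
                               n_candidates = 20)
  mi_major <- joint_mi(ds, c("M0P0", "M0P1"))
  mi_minor <- joint_mi(ds, c("M1P0", "M1P1"))
  expect_gt(mi_major, mi_minor)
  expect_gt(mi_minor, 0)
})

test_that("a 100:0 split degenerates to a plain 2-way dataset", {
  ds <- simulate_heterogeneous(c(1, 0), 6, 2000, 0.4, seed = 47,
                               n_candidates = 20)
  expect_identical(sum(ds$labels), 1000L)
  expect_gt(joint_mi(ds, c("M0P0", "M0P1")), 0.05)
  expect_lt(joint_mi(ds, c("M1P0", "M1P1")), 0.01)
})

test_that("main-effect and additive loci are individually informative", {
  ds1 <- simulate_main_or_additive(1, 20, 0.4, "E", seed = 51,
                                   n_instances = 1600, n_candidates = 20)
  expect_identical(ds1$predictive_ids, "M0P0")
  expect_gt(joint_mi(ds1, "M0P0"), 0.02)
  ds2 <- simulate_main_or_additive(2, 20, 0.4, "E", seed = 53,
                                   n_instances = 1600, n_candidates = 20)
  expect_gt(joint_mi(ds2, "M0P0"), 0.005)
  expect_gt(joint_mi(ds2, "M1P0"), 0.005)
})

test_that("additive models hit the target heritability exactly", {
  for (h2 in c(0.1, 0.4)) {
    ds <- simulate_main_or_additive(2, 4, h2, "E", seed = 57,
                                    n_instances = 100, n_candidates = 10)
    m <- attr(ds, "model")
    expect_lt(abs(model_heritability(m) - h2), 1e-6)
    expect_lt(abs(model_prevalence(m) - m$prevalence), 1e-9)
  }
})

test_that("the benchmark grid reproduces the study's configuration counts", {
  grid <- benchmark_grid()
  expect_identical(nrow(grid), 70L)
  expect_identical(sum(grid$family == "xor"), 20L)
  expect_identical(sum(grid$family == "core_2way"), 32L)
  expect_identical(sum(grid$family == "feature_sweep_2way"), 4L)
  expect_false(anyDuplicated(grid$config_id) > 0)
  jobs <- expand_grid_jobs(grid, n_replicates = 30, base_seed = 1)
  expect_identical(nrow(jobs), 2100L)
  xor_jobs <- expand_grid_jobs(benchmark_grid("xor"), 30, 1)
  expect_identical(nrow(xor_jobs), 600L)
  empty <- expand_grid_jobs(grid[integer(0), ], 30, 1)
  expect_identical(nrow(empty), 0L)
})

test_that("job seeds are deterministic, distinct and within integer range", {
  jobs <- expand_grid_jobs(benchmark_grid("xor"), 5, base_seed = 99)
  jobs2 <- expand_grid_jobs(benchmark_grid("xor"), 5, base_seed = 99)
  expect_identical(jobs, jobs2)
  expect_true(all(jobs$seed >= 0 & jobs$seed < 2^31))
  expect_gt(length(unique(jobs$seed)) / nrow(jobs), 0.99)
  expect_false(identical(
    jobs$seed, expand_grid_jobs(benchmark_grid("xor"), 5, base_seed = 100)$seed))
})

test_that("generate_dataset dispatches every family in the grid", {
  grid <- benchmark_grid()
  picks <- grid[!duplicated(grid$family) &
                  grid$n_features <= 100 & grid$n_instances <= 1600, ]
  for (ci in seq_len(nrow(picks))) {
    config <- picks[ci, ]
    ds <- generate_dataset(config, seed = 7, n_candidates = 10)
    expect_s3_class(ds, "snp_dataset")
    expect_identical(ncol(ds$genotypes), config$n_features)
    expect_identical(nrow(ds$genotypes), config$n_instances)
    expect_length(ds$predictive_ids, config$n_predictive)
    expect_identical(sum(ds$labels == 1L), config$n_instances %/% 2L)
  }
})
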