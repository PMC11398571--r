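test_that("power curves follow the cumulative weakest-link definition", {
  # perfect 2-way detection in every replicate
  pc <- power_curve(rep(2, 30), 5)
  expect_equal(pc, c(0, 100, 100, 100, 100))
  # split outcomes
  pc <- power_curve(c(rep(5, 15), rep(50, 15)), 60)
  expect_equal(pc[4], 0)
  expect_true(all(pc[5:49] == 50))
  expect_true(all(pc[50:60] == 100))
  expect_error(power_curve(c(2, 61), 60), "1..n_features")
})

test_that("the strict comparison shifts the curve by one position", {
  wl <- c(2, 2, 3, 7)
  inc <- power_curve(wl, 8)
  strict <- power_curve(wl, 8, strict = TRUE)
  expect_equal(strict, c(0, inc[-8]))
})

test_that("power curves are monotone and end at 100", {
  set.seed(20)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    wl <- sample(n, 20, replace = TRUE)
    pc <- power_curve(wl, n)
    expect_true(all(diff(pc) >= 0))
    expect_equal(pc[n], 100)
    expect_true(all(pc >= 0 & pc <= 100))
  }
})

test_that("the shuffle heatmap row converges to the analytic null curve", {
  ds <- random_dataset(10, 20, seed = 30)
  ds$predictive_ids <- ds$feature_names[1:2]
  wl <- vapply(1:2000, function(s)
    weakest_link(shuffle_ranking(ds, s), ds$predictive_ids), numeric(1))
  pc <- power_curve(wl, 20)
  for (pos in c(2, 5, 10, 19)) {
    q <- choose(pos, 2) / choose(20, 2)
    se <- 100 * sqrt(q * (1 - q) / 2000)
    expect_lt(abs(pc[pos] - 100 * q), 3 * se)
  }
})

test_that("run_experiment produces a reproducible tidy table and heatmaps", {
  grid <- benchmark_grid("xor")
  grid <- grid[grid$config_id == "xor_k2_f20", ]
  rows <- c("ReliefF-10NN", "ReliefF-10NN_ABS", "MI", "Shuffle")
  ex <- run_experiment(grid, n_replicates = 3, base_seed = 5, rows = rows)
  expect_identical(nrow(ex$results), 3L * 4L)
  expect_setequal(unique(ex$results$row), rows)
  expect_true(all(ex$results$weakest_link >= 2 &
                    ex$results$weakest_link <= 20))
  hm <- ex$heatmaps[["xor_k2_f20"]]
  expect_identical(dim(hm), c(4L, 20L))
  expect_true(all(hm[, 20] == 100))
  # RBA detection beats the controls on clean 2-way XOR
  expect_equal(unname(hm["ReliefF-10NN", 2]), 100)
  # end-to-end determinism
  ex2 <- run_experiment(grid, n_replicates = 3, base_seed = 5, rows = rows)
  expect_identical(ex, ex2)
})

test_that("a zero-replicate experiment yields empty results without error", {
  grid <- benchmark_grid("xor")[1, ]
  ex <- run_experiment(grid, n_replicates = 0)
  expect_identical(nrow(ex$results), 0L)
})

test_that("experiment outputs round-trip through TSV files", {
  grid <- benchmark_grid("xor")
  grid <- grid[grid$config_id == "xor_k2_f20", ]
  ex <- run_experiment(grid, n_replicates = 2, base_seed = 5,
                       rows = c("MultiSURF", "Shuffle"))
  dir <- withr::local_tempdir()
  write_experiment(ex, dir)
  res <- read.delim(file.path(dir, "results.tsv"))
  expect_identical(nrow(res), nrow(ex$results))
  hm <- read.delim(file.path(dir, "heatmap_xor_k2_f20.tsv"),
                   check.names = FALSE)
  expect_identical(hm$row, rownames(ex$heatmaps[[1]]))
  expect_equal(unname(as.matrix(hm[, -1])), unname(ex$heatmaps[[1]]))
})
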