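test_that("genotype_diff is the 0/1 mismatch indicator", {
  expect_identical(genotype_diff(1, 1), 0)
  expect_identical(genotype_diff(0, 2), 1)
  expect_identical(genotype_diff(c(0, 1, 2), c(0, 2, 2)), c(0, 1, 0))
  expect_error(genotype_diff(3, 0), "genotypes")
})

test_that("pairwise distances are symmetric Hamming counts", {
  ds <- random_dataset(5, 4, seed = 1)
  D <- pairwise_distances(ds)
  expect_identical(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_identical(D, ref_distances(ds$genotypes))
  # duplicate instances sit at distance zero
  x <- rbind(c(0L, 1L), c(0L, 1L), c(2L, 2L), c(2L, 0L))
  dup <- snp_dataset(x, c(0, 0, 1, 1), c("a", "b"), "a")
  expect_identical(pairwise_distances(dup)[1, 2], 0)
})

test_that("ReliefF scores hand-checkable datasets correctly", {
  # all-identical instances: no differences anywhere, all scores zero
  x <- matrix(1L, 4, 3)
  ds <- snp_dataset(x, c(0, 0, 1, 1), c("a", "b", "c"), "a")
  expect_identical(unname(relieff_scores(ds, 1)$scores), c(0, 0, 0))
  # a feature equal to the class bit scores exactly +1
  x <- cbind(c(0L, 0L, 1L, 1L))
  ds <- snp_dataset(x, c(0, 0, 1, 1), "f1", "f1")
  expect_identical(unname(relieff_scores(ds, 1)$scores), 1)
})

test_that("ReliefF caps nn at the available neighbors with a warning", {
  ds <- random_dataset(8, 3, seed = 2)
  expect_warning(s1 <- relieff_scores(ds, 50), "capped")
  s2 <- suppressWarnings(relieff_scores(ds, 50))
  expect_identical(s1$scores, s2$scores)
})

test_that("MultiSURF degenerate geometries give all-zero scores", {
  # identical instances: all distances zero, near and far sets empty
  x <- matrix(2L, 6, 4)
  ds <- snp_dataset(x, rep(0:1, 3), paste0("f", 1:4), "f1")
  expect_identical(unname(multisurf_scores(ds)$scores), numeric(4))
  expect_identical(unname(multisurf_star_scores(ds)$scores), numeric(4))
  # equidistant instances (pairwise distance 2): dead-band removes everyone
  x <- diag(6L) * 2L
  ds <- snp_dataset(x, rep(0:1, 3), paste0("f", 1:6), "f1")
  expect_true(all(pairwise_distances(ds)[upper.tri(diag(6))] == 2))
  expect_identical(unname(multisurf_scores(ds)$scores), numeric(6))
  expect_identical(unname(multisurf_star_scores(ds)$scores), numeric(6))
})

test_that("vectorized scorers match the naive references exactly", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(8:40, 1)
    f <- sample(2:10, 1)
    nn <- sample(1:5, 1)
    ds <- random_dataset(n, f, seed = s + 500)
    x <- ds$genotypes
    y <- ds$labels
    expect_identical(
      unname(suppressWarnings(relieff_scores(ds, nn))$scores),
      ref_relieff(x, y, nn))
    expect_identical(unname(multisurf_scores(ds)$scores),
                     ref_surf(x, y, far = FALSE))
    expect_identical(unname(multisurf_star_scores(ds)$scores),
                     ref_surf(x, y, far = TRUE))
  }
})

test_that("RBA scores are bounded in [-1, 1] on random inputs", {
  for (s in 1:100) {
    ds <- random_dataset(sample(6:25, 1), sample(2:8, 1), seed = s)
    for (fs in list(suppressWarnings(relieff_scores(ds, sample(1:6, 1))),
                    multisurf_scores(ds), multisurf_star_scores(ds))) {
      expect_true(all(fs$scores >= -1 & fs$scores <= 1))
    }
  }
})

test_that("scores are a pure function of the dataset", {
  ds <- random_dataset(30, 6, seed = 77)
  expect_identical(relieff_scores(ds, 5)$scores, relieff_scores(ds, 5)$scores)
  expect_identical(multisurf_star_scores(ds)$scores,
                   multisurf_star_scores(ds)$scores)
})

test_that("permuting columns permutes scores identically", {
  ds <- random_dataset(30, 8, seed = 88)
  perm <- sample(8)
  ds_p <- snp_dataset(ds$genotypes[, perm], ds$labels,
                      ds$feature_names[perm], ds$feature_names[perm][1])
  for (pair in list(
    list(relieff_scores(ds, 4), relieff_scores(ds_p, 4)),
    list(multisurf_scores(ds), multisurf_scores(ds_p)),
    list(multisurf_star_scores(ds), multisurf_star_scores(ds_p)))) {
    expect_identical(pair[[1]]$scores[ds$feature_names[perm]],
                     pair[[2]]$scores)
  }
})

test_that("label permutation drives mean scores to zero", {
  # balanced classes and nn well below the pool size: in this regime the
  # hit/miss neighbor pools are symmetric and the permutation null is
  # centered (with nn near the pool size the known Relief update asymmetry
  # gives random features a small negative drift)
  set.seed(99)
  x <- matrix(sample(0:2, 40 * 5, TRUE), 40, 5)
  ds <- snp_dataset(x, rep(0:1, each = 20), paste0("f", 1:5), "f1")
  set.seed(4242)
  reps <- 100
  for (scorer in list(function(d) relieff_scores(d, 3),
                      function(d) multisurf_scores(d))) {
    mats <- vapply(seq_len(reps), function(r) {
      ds_s <- ds
      ds_s$labels <- sample(ds$labels)
      unname(scorer(ds_s)$scores)
    }, numeric(5))
    means <- rowMeans(mats)
    ses <- apply(mats, 1, sd) / sqrt(reps)
    expect_true(all(abs(means) <= 3 * ses + 1e-12))
  }
})
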