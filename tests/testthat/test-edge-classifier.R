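hand_example <- function() {
  x <- matrix(c(2, 0, -2, 0), 1, 4,
              dimnames = list("e1", sprintf("s%d", 1:4)))
  list(x = x, g = factor(c("A", "A", "B", "B")))
}

test_that("the single-edge hand example reproduces every intermediate", {
  h <- hand_example()
  m <- nsc_fit(h$x, h$g, delta = 0.2)
  expect_equal(unname(m$overall), 0)
  expect_equal(unname(m$centroids[1, ]), c(1, -1))
  expect_equal(unname(m$s), sqrt(2))
  expect_equal(m$s0, sqrt(2))
  expect_equal(unname(m$mk), c(0.5, 0.5))
  expect_equal(unname(m$d[1, ]), c(1, -1) / sqrt(2), tolerance = 1e-9)
  expect_equal(unname(m$d_shrunk[1, "A"]), 1 / sqrt(2) - 0.2,
               tolerance = 1e-9)
  expect_equal(unname(m$centroids_shrunk[1, "A"]), 1 - 0.2 * sqrt(2),
               tolerance = 1e-9)  # ~0.7172
  # training samples classify correctly at delta = 0; the two zero-valued
  # samples sit exactly between the centroids (+1/-1) and tie to the first
  # class level by convention
  m0 <- nsc_fit(h$x, h$g, delta = 0)
  pr <- predict(m0, h$x)
  expect_equal(as.character(pr$class)[c(1, 3)], c("A", "B"))
  expect_equal(unname(pr$posterior[2, ]), c(0.5, 0.5))
  expect_equal(unname(pr$posterior[4, ]), c(0.5, 0.5))
})

test_that("all model quantities match the brute-force oracle", {
  withr::with_seed(101, {
    for (rep in 1:60) {
      m <- sample(1:5, 1)
      K <- sample(2:3, 1)
      nk <- sample(2:3, K, replace = TRUE)
      n <- sum(nk)
      x <- matrix(rnorm(m * n), m, n,
                  dimnames = list(sprintf("e%d", 1:m), sprintf("s%d", 1:n)))
      g <- factor(rep(LETTERS[1:K], nk))
      delta <- runif(1, 0, 1.5)
      mkv <- sample(c("exact", "plus"), 1)
      pri <- sample(c("empirical", "uniform"), 1)
      fit <- nsc_fit(x, g, delta, prior = pri, mk_variant = mkv)
      ref <- brute_nsc(x, g, delta, prior = pri, mk_variant = mkv)
      expect_equal(unname(fit$overall), ref$overall, tolerance = 1e-10)
      expect_equal(unname(fit$centroids), unname(ref$centroids),
                   tolerance = 1e-10)
      expect_equal(unname(fit$s), ref$s, tolerance = 1e-10)
      expect_equal(fit$s0, ref$s0, tolerance = 1e-10)
      expect_equal(unname(fit$mk), ref$mk, tolerance = 1e-10)
      expect_equal(unname(fit$d), unname(ref$d), tolerance = 1e-10)
      expect_equal(unname(fit$d_shrunk), unname(ref$d_shrunk),
                   tolerance = 1e-10)
      expect_equal(unname(fit$centroids_shrunk),
                   unname(ref$centroids_shrunk), tolerance = 1e-10)
      expect_equal(unname(fit$prior), ref$prior, tolerance = 1e-10)
      xnew <- matrix(rnorm(m * 3), m, dimnames = list(rownames(x), NULL))
      colnames(xnew) <- sprintf("t%d", 1:3)
      pr <- predict(fit, xnew)
      pref <- brute_nsc_predict(ref, xnew)
      expect_equal(as.character(pr$class), pref$class)
      expect_equal(unname(pr$posterior), pref$posterior, tolerance = 1e-10)
    }
  })
})

test_that("soft-threshold limits behave as expected", {
  withr::with_seed(103, {
    x <- matrix(rnorm(8 * 10), 8, 10,
                dimnames = list(sprintf("e%d", 1:8), sprintf("s%d", 1:10)))
  })
  g <- factor(rep(c("A", "B"), 5))
  m0 <- nsc_fit(x, g, delta = 0)
  expect_equal(m0$d_shrunk, m0$d)
  expect_equal(unname(m0$centroids_shrunk), unname(m0$centroids),
               tolerance = 1e-12)
  dmax <- max(abs(m0$d))
  mfull <- nsc_fit(x, g, delta = dmax + 0.01)
  expect_true(all(mfull$d_shrunk == 0))
  expect_equal(unname(mfull$centroids_shrunk[, 1]), unname(mfull$overall))
  # fully shrunken + equal priors -> posteriors are the priors
  mfull_u <- nsc_fit(x, g, delta = dmax + 0.01, prior = "uniform")
  pr <- predict(mfull_u, x)
  expect_true(all(abs(pr$posterior - 0.5) < 1e-12))
  # posteriors always sum to 1
  pr0 <- predict(m0, x)
  expect_equal(unname(rowSums(pr0$posterior)), rep(1, 10))
  expect_error(nsc_fit(x, g, delta = -1), "delta")
})

test_that("selected-edge count is non-increasing in the threshold", {
  withr::with_seed(107, {
    x <- matrix(rnorm(50 * 12), 50, 12,
                dimnames = list(sprintf("e%d", 1:50), sprintf("s%d", 1:12)))
  })
  g <- factor(rep(c("A", "B"), 6))
  m0 <- nsc_fit(x, g, 0)
  counts <- vapply(seq(0, max(abs(m0$d)) + 0.1, length.out = 25),
                   function(d) sum(rowSums(abs(nsc_shrink(m0, d)$d_shrunk)) > 0),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("class relabeling permutes centroids and posteriors", {
  withr::with_seed(109, {
    x <- matrix(rnorm(6 * 9), 6, 9,
                dimnames = list(sprintf("e%d", 1:6), sprintf("s%d", 1:9)))
  })
  g <- factor(rep(c("A", "B", "C"), 3))
  g2 <- factor(c(A = "C", B = "A", C = "B")[as.character(g)])
  f1 <- nsc_fit(x, g, 0.3)
  f2 <- nsc_fit(x, g2, 0.3)
  expect_equal(f1$centroids[, "A"], f2$centroids[, "C"])
  expect_equal(f1$d_shrunk[, "B"], f2$d_shrunk[, "A"])
  p1 <- predict(f1, x); p2 <- predict(f2, x)
  expect_equal(p1$posterior[, "A"], p2$posterior[, "C"])
})

test_that("prediction refuses incomplete edge sets", {
  h <- hand_example()
  m <- nsc_fit(h$x, h$g, 0)
  bad <- matrix(0, 1, 2, dimnames = list("other_edge", c("t1", "t2")))
  expect_error(predict(m, bad), "lacks")
})

test_that("cross-validation is deterministic and exports fold assignments", {
  withr::with_seed(113, {
    x <- matrix(rnorm(30 * 17), 30, 17,
                dimnames = list(sprintf("e%d", 1:30), sprintf("s%d", 1:17)))
  })
  g <- factor(rep(c("A", "B"), c(9, 8)))
  cv1 <- nsc_cv(x, g, n_repeats = 3, n_folds = 5, seed = 77)
  cv2 <- nsc_cv(x, g, n_repeats = 3, n_folds = 5, seed = 77)
  expect_identical(cv1$errors, cv2$errors)
  expect_identical(cv1$best_delta, cv2$best_delta)
  expect_identical(cv1$folds, cv2$folds)
  # folds are stratified: every fold contains both classes in training
  for (f in cv1$folds) {
    expect_equal(sort(unique(f)), 1:5)
    for (k in 1:5) expect_true(all(table(g[f != k]) >= 2))
  }
  expect_error(nsc_cv(x, g, grid = numeric(0)), "grid")
})

test_that("CV finds strong planted signal and stays honest on noise", {
  cfg <- synthetic_config(n_mirna = 60, n_protein = 150, n_ppi = 80,
                          n_signal_edges = 20, n_ppi_signal = 0,
                          delta_mirna = 3, delta_protein = 3, seed = 13)
  net <- generate_networks(cfg)
  ch <- generate_cohort(cfg, net)
  es <- edge_scores(net, zscore(ch$mirna), zscore(ch$protein))
  cv <- nsc_cv(es, n_repeats = 5, n_folds = 5, seed = 13)
  expect_lte(cv$best_error, 0.1)
  expect_gt(cv$best_delta, 0)
  sub <- extract_subnetwork(cv$model, net)
  planted <- ch$truth$signal_edges
  expect_gte(mean(planted %in% sub$edges$edge_id), 0.8)
  expect_lte(mean(!(sub$edges$edge_id %in% planted)), 0.2)

  # pure noise: errors hover around chance across the whole grid
  cfg0 <- synthetic_config(n_mirna = 60, n_protein = 150, n_ppi = 80,
                           n_signal_edges = 0, n_ppi_signal = 0,
                           delta_mirna = 0, delta_protein = 0, seed = 17)
  net0 <- generate_networks(cfg0)
  ch0 <- generate_cohort(cfg0, net0)
  es0 <- edge_scores(net0, zscore(ch0$mirna), zscore(ch0$protein))
  cv0 <- nsc_cv(es0, n_repeats = 5, n_folds = 5, seed = 17)
  # chance-level on average over the grid; individual grid points sit a
  # little above 1/2 because a held-out sample is excluded from its own
  # class centroid (the usual exclusion bias of CV on null data)
  expect_gte(mean(cv0$mean_error), 0.35)
  expect_lte(mean(cv0$mean_error), 0.65)
  expect_true(all(cv0$mean_error >= 0.3 & cv0$mean_error <= 0.75))
})

test_that("subnetwork extraction matches the d' support and edge-type split", {
  cfg <- synthetic_config(n_mirna = 20, n_protein = 50, n_ppi = 25,
                          n_signal_edges = 3, n_ppi_signal = 2, seed = 31)
  net <- generate_networks(cfg)
  ch <- generate_cohort(cfg, net)
  es <- edge_scores(net, zscore(ch$mirna), zscore(ch$protein))
  m0 <- nsc_fit(es, delta = 0)
  sub0 <- extract_subnetwork(m0, net)
  expect_equal(sub0$counts$total, nrow(net$edges))  # delta 0 keeps all
  expect_equal(sub0$counts$total,
               sub0$counts$mirna_protein + sub0$counts$ppi)
  mmax <- nsc_fit(es, delta = max(abs(m0$d)) + 1)
  expect_warning(sube <- extract_subnetwork(mmax, net), "empty")
  expect_true(sube$empty)
  # selected edges are exactly those with a nonzero shrunken difference
  m1 <- nsc_fit(es, delta = 1)
  sub1 <- extract_subnetwork(m1, net)
  expect_setequal(sub1$edges$edge_id,
                  m1$features[rowSums(abs(m1$d_shrunk)) > 0])
})
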