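make_plate <- function(cts, a = 30, b = -log2(10), ntc = 36) {
  # cts: mirna x sample matrix of averaged-duplicate target Cts (each rep
  # gets the same value so the duplicate average equals the input)
  mir <- rownames(cts); smp <- colnames(cts)
  long <- expand.grid(mirna = mir, sample = smp,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$ct <- as.vector(cts)
  samples <- rbind(cbind(long, rep = 1L), cbind(long, rep = 2L))
  standards <- expand.grid(mirna = mir, copies = 10^(1:6),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  standards$ct <- a + b * log10(standards$copies)
  ntc_df <- data.frame(mirna = rep(mir, 2), rep = rep(1:2, each = length(mir)),
                       ct = ntc)
  structure(list(samples = samples, standards = standards, ntc = ntc_df,
                 groups = factor(rep(c("A", "B"), length.out = length(smp))),
                 sample_ids = smp, params = list()),
            class = "qpcr_plate")
}

test_that("qPCR quantification inverts the fitted standard line", {
  ct <- matrix(30 - log2(10) * 5.5, 1, 1, dimnames = list("miR-1", "s1"))
  out <- quantify_qpcr(make_plate(ct))
  expect_equal(2^out$values["miR-1", "s1"], 10^5.5, tolerance = 1e-9)
})

test_that("duplicate Cts are averaged before interpolation", {
  mir <- "miR-1"; smp <- "s1"
  plate <- make_plate(matrix(0, 1, 1, dimnames = list(mir, smp)))
  plate$samples$ct <- c(20, 21)  # two reps
  out <- quantify_qpcr(plate)
  expect_equal(out$values[1, 1], (20.5 - 30) / -log2(10) * log2(10),
               tolerance = 1e-9)
})

test_that("samples with Ct later than the NTC are censored", {
  ct <- matrix(c(38, 20), 1, 2, dimnames = list("miR-1", c("s1", "s2")))
  out <- quantify_qpcr(make_plate(ct, ntc = 36))
  expect_true(is.na(out$values["miR-1", "s1"]))
  expect_false(is.na(out$values["miR-1", "s2"]))
  expect_true(attr(out, "undetected")["miR-1", "s1"])
})

test_that("broken standard series are rejected", {
  plate <- make_plate(matrix(20, 1, 1, dimnames = list("miR-1", "s1")))
  plate$standards$copies <- 100  # single level
  expect_error(quantify_qpcr(plate), "fewer than 2 levels")
  plate2 <- make_plate(matrix(20, 1, 1, dimnames = list("miR-1", "s1")))
  plate2$standards$ct <- 10 + log10(plate2$standards$copies)  # rising slope
  expect_error(quantify_qpcr(plate2), "slope")
})

test_that("plate round trip recovers true copies within noise bounds", {
  cfg <- synthetic_config(n_mirna = 20, n_protein = 10, n_ppi = 0,
                          n_signal_edges = 0, n_ppi_signal = 0, seed = 3)
  truth <- rand_abundance(20, rep(c("A", "B"), c(9, 8)), "mirna", seed = 3)
  rownames(truth$values) <- sprintf("miR-%d", 1:20)
  truth$values <- truth$values + 14  # realistic copy range
  plate <- generate_qpcr_plate(truth, cfg, ct_sd = 0.1)
  rec <- quantify_qpcr(plate)
  err <- abs(rec$values - truth$values) / log2(10)  # log10 error
  expect_false(anyNA(rec$values))
  expect_lt(mean(err), 0.05)
  expect_lt(stats::quantile(err, 0.9), 0.05)
})

test_that("undetected cells are imputed at the per-miRNA detected minimum", {
  x <- rbind(m1 = c(5, NA, 7), m2 = c(4, 6, NA))
  colnames(x) <- c("s1", "s2", "s3")
  a <- abundance_matrix(x, factor(c("A", "A", "B")), "mirna")
  out <- impute_undetected(a)
  expect_equal(out$values["m1", "s2"], 5)   # min detected of (5, 7)
  expect_equal(out$values["m2", "s3"], 4)
  out2 <- impute_undetected(a, method = "half_min")
  expect_equal(out2$values["m1", "s2"], 4)  # one log2 unit lower
})

test_that("miRNA normalization equalizes medians and SDs and is idempotent", {
  a <- rand_abundance(50, rep(c("A", "B"), c(9, 8)), "mirna", seed = 8)
  a$values <- sweep(a$values, 2, seq_len(17))  # force unequal samples
  n1 <- normalize_mirna(a)
  med <- apply(n1$values, 2, median)
  sds <- apply(n1$values, 2, sd)
  expect_lt(diff(range(med)), 1e-9)
  expect_lt(diff(range(sds)), 1e-9)
  n2 <- normalize_mirna(n1)
  expect_equal(n2$values, n1$values, tolerance = 1e-9)
  # affine map check: (0,1,2) and (10,11,12) meet at the mean median 6
  bx <- cbind(s1 = c(0, 1, 2), s2 = c(10, 11, 12))
  rownames(bx) <- letters[1:3]
  b <- abundance_matrix(bx, factor(c("A", "B")), "mirna")
  nb <- normalize_mirna(b)
  expect_equal(unname(nb$values[, "s1"]), c(5, 6, 7))
  expect_equal(unname(nb$values[, "s2"]), c(5, 6, 7))
})

test_that("peptide filtering applies the inclusive 25% rule", {
  nsmp <- 17
  x <- matrix(1, 3, nsmp,
              dimnames = list(c("p5", "p4", "pexact"),
                              sprintf("s%d", 1:nsmp)))
  x["p5", 1:5] <- NA       # 5/17 = 29.4% -> removed
  x["p4", 1:4] <- NA       # 4/17 = 23.5% -> kept
  pm <- peptide_matrix(x, data.frame(peptide = rownames(x),
                                     protein = c("P1", "P1", "P2")),
                       factor(rep(c("A", "B"), length.out = nsmp)))
  out <- filter_peptides(pm)
  expect_setequal(rownames(out$intensities), c("p4", "pexact"))
  # exactly 25% missing is removed (boundary inclusive)
  y <- matrix(1, 1, 4, dimnames = list("q", sprintf("s%d", 1:4)))
  y[1, 1] <- NA
  pm2 <- peptide_matrix(y, data.frame(peptide = "q", protein = "P"),
                        factor(c("A", "A", "B", "B")))
  expect_equal(nrow(filter_peptides(pm2)$intensities), 0)
  # idempotent
  expect_identical(filter_peptides(out)$intensities, out$intensities)
})

test_that("KNN imputation fills cells from nearest peptides", {
  x <- rbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, NA), C = c(9, 9, 9, 9))
  colnames(x) <- sprintf("s%d", 1:4)
  pm <- peptide_matrix(x, data.frame(peptide = c("A", "B", "C"),
                                     protein = c("P1", "P1", "P2")),
                       factor(c("A", "A", "B", "B")))
  out <- impute_knn(pm, k = 1)
  expect_equal(out$intensities["B", "s4"], 4)  # zero-distance neighbour A
  expect_false(anyNA(out$intensities))
  # all-constant matrix imputes the constant
  xc <- matrix(7, 4, 4, dimnames = list(letters[1:4], sprintf("s%d", 1:4)))
  xc[2, 3] <- NA
  pmc <- peptide_matrix(xc, data.frame(peptide = letters[1:4],
                                       protein = rep("P", 4)),
                        factor(c("A", "A", "B", "B")))
  expect_equal(impute_knn(pmc, k = 2)$intensities[2, 3], 7)
  expect_error(impute_knn(pm, k = 0), "k")
  expect_error(impute_knn(pm, k = 3), "k")
})

test_that("mask-and-recover imputation error is near the noise floor", {
  withr::with_seed(11, {
    base <- matrix(rnorm(8 * 12, 10, 4), 8, 12)   # 8 cluster profiles
    x <- base[rep(1:8, each = 6), ] + rnorm(8 * 6 * 12, 0, 0.1)
    dimnames(x) <- list(sprintf("pep%02d", 1:48), sprintf("s%d", 1:12))
    mask <- matrix(runif(length(x)) < 0.05, nrow(x), ncol(x))
  })
  xm <- x; xm[mask] <- NA
  pm <- peptide_matrix(xm, data.frame(peptide = rownames(x),
                                      protein = rep(sprintf("P%d", 1:8),
                                                    each = 6)),
                       factor(rep(c("A", "B"), 6)))
  out <- impute_knn(pm, k = 5)
  rmse <- sqrt(mean((out$intensities[mask] - x[mask])^2))
  expect_lt(rmse, 0.2)               # close to the 0.1 noise floor
  expect_lt(rmse, 0.1 * sd(x))       # far below raw cell variability
  # filtering after imputation changes nothing
  expect_identical(filter_peptides(out)$intensities, out$intensities)
})

test_that("median normalization equalizes sample medians and is idempotent", {
  x <- rbind(a = c(50, 100), b = c(100, 200), c = c(150, 300))
  colnames(x) <- c("s1", "s2")
  pm <- peptide_matrix(x, data.frame(peptide = rownames(x),
                                     protein = rep("P", 3)),
                       factor(c("A", "B")))
  out <- normalize_median(pm)
  med <- apply(out$intensities, 2, median)
  expect_equal(unname(med), c(150, 150))
  out2 <- normalize_median(out)
  expect_equal(out2$intensities, out$intensities, tolerance = 1e-12)
  expect_lt(diff(range(apply(out$intensities, 2, median))) / med[1], 1e-9)
})

test_that("protein roll-up sums peptides on the linear scale", {
  x <- rbind(p1 = c(10, 20), p2 = c(30, 40), q1 = c(5, 5))
  colnames(x) <- c("s1", "s2")
  pm <- peptide_matrix(x, data.frame(peptide = rownames(x),
                                     protein = c("P", "P", "Q")),
                       factor(c("A", "B")))
  out <- rollup_protein(pm)
  expect_equal(out$values["P", "s1"], log2(40))
  expect_equal(out$values["Q", ], log2(c(s1 = 5, s2 = 5)))
  # conservation: per-sample totals match
  expect_equal(colSums(2^out$values), colSums(x))
})

test_that("Z-scores have unit row stats and drop constant features", {
  x <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 10, 20))
  colnames(x) <- sprintf("s%d", 1:3)
  a <- abundance_matrix(x, factor(c("A", "A", "B")), "protein")
  expect_warning(z <- zscore(a), "zero-variance")
  expect_equal(z$values["a", ], c(s1 = -1, s2 = 0, s3 = 1))
  expect_false("b" %in% rownames(z$values))
  expect_lt(max(abs(rowMeans(z$values))), 1e-9)
  expect_lt(max(abs(apply(z$values, 1, sd) - 1)), 1e-9)
})

test_that("Z-scores are invariant to positive affine rescaling per feature", {
  a <- rand_abundance(20, rep(c("A", "B"), each = 4), seed = 21)
  z1 <- zscore(a)
  b <- a
  withr::with_seed(22, {
    slope <- runif(20, 0.5, 3)
    shift <- rnorm(20, 0, 10)
  })
  b$values <- a$values * slope + shift
  z2 <- zscore(b)
  expect_equal(z1$values, z2$values, tolerance = 1e-9)
})
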