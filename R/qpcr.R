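#' Simulate an RT-qPCR plate from true miRNA copy numbers
#'
#' Emits, per miRNA: duplicate sample Ct values, a standard series of six
#' 10-fold dilutions of synthetic template with known copy numbers, and two
#' no-template controls (NTCs).  Ct values follow the amplification line
#' `Ct = a + b * log10(copies)` plus Gaussian noise; `b = -log2(10)`
#' (about -3.32 Ct per decade) corresponds to 100% amplification
#' efficiency.  True copy numbers of exactly zero are emitted as Ct later
#' than the NTC so the quantifier censors them.
#'
#' @param truth_mirna miRNA [abundance_matrix()] of log2 copy numbers.
#' @param config A [synthetic_config()] (supplies the seed).
#' @param a Intercept of the Ct line (Ct at 1 copy); default 30.
#' @param b Slope per log10 copies; must be negative; default `-log2(10)`.
#' @param ct_sd Gaussian Ct noise SD; default 0.15.
#' @param ntc_ct Mean NTC Ct; default 38.
#' @param standard_copies Copy numbers of the standard series; default
#'   `10^(1:6)`.
#' @return Object of class `qpcr_plate` with elements `samples`
#'   (mirna/sample/rep/ct), `standards` (mirna/copies/ct), `ntc`
#'   (mirna/rep/ct), `groups`, `params`.
#' @export
generate_qpcr_plate <- function(truth_mirna, config,
                                a = 30, b = -log2(10), ct_sd = 0.15,
                                ntc_ct = 38, standard_copies = 10^(1:6)) {
  stopifnot(inherits(truth_mirna, "abundance_matrix"),
            inherits(config, "synthetic_config"))
  if (b >= 0) stop("`b` must be negative (Ct decreases with template)")
  copies <- 2^truth_mirna$values
  copies[truth_mirna$values == -Inf] <- 0
  if (any(copies < 0)) stop("copy numbers must be nonnegative")
  mir <- rownames(copies)
  smp <- colnames(copies)

  withr::with_seed(config$seed + 3L, {
    ct_true <- a + b * log10(copies)           # -Inf rows handled below
    long <- expand.grid(mirna = mir, sample = smp,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ct1 <- as.vector(ct_true) + stats::rnorm(nrow(long), 0, ct_sd)
    ct2 <- as.vector(ct_true) + stats::rnorm(nrow(long), 0, ct_sd)
    zero <- as.vector(copies) == 0
    ct1[zero] <- ntc_ct + 2
    ct2[zero] <- ntc_ct + 2
    samples <- rbind(cbind(long, rep = 1L, ct = ct1),
                     cbind(long, rep = 2L, ct = ct2))
    standards <- expand.grid(mirna = mir, copies = standard_copies,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    standards$ct <- a + b * log10(standards$copies) +
      stats::rnorm(nrow(standards), 0, ct_sd)
    ntc <- expand.grid(mirna = mir, rep = 1:2,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ntc$ct <- stats::rnorm(nrow(ntc), ntc_ct, ct_sd)
  })
  structure(list(samples = samples, standards = standards, ntc = ntc,
                 groups = truth_mirna$groups,
                 sample_ids = smp,
                 params = list(a = a, b = b, ct_sd = ct_sd, ntc_ct = ntc_ct)),
            class = "qpcr_plate")
}

#' @export
print.qpcr_plate <- function(x, ...) {
  cat(sprintf("<qpcr_plate> %d miRNAs x %d samples, %d-point standards, duplicates + NTC\n",
              length(unique(x$samples$mirna)), length(x$sample_ids),
              length(unique(x$standards$copies))))
  invisible(x)
}

#' Standard-curve quantification of a qPCR plate
#'
#' Duplicate sample Ct values are averaged; per miRNA an ordinary
#' least-squares line `Ct = a + b * log10(copies)` is fitted to the
#' standard series and inverted to interpolate sample copy numbers,
#' `copies = 10^((Ct - a) / b)`.  Any sample whose averaged Ct is strictly
#' later (larger) than that miRNA's earliest NTC Ct is deemed undetectable
#' and returned as `NA` (flagged in the `undetected` attribute).
#'
#' @param plate A `qpcr_plate`.
#' @return miRNA [abundance_matrix()] of log2 copy numbers with `NA` for
#'   undetected cells; attribute `undetected` is the logical flag matrix.
#' @export
quantify_qpcr <- function(plate) {
  stopifnot(inherits(plate, "qpcr_plate"))
  mir <- unique(plate$standards$mirna)
  smp <- plate$sample_ids

  # averaged duplicate Cts, miRNA x sample
  agg <- stats::aggregate(ct ~ mirna + sample, data = plate$samples,
                          FUN = mean)
  ct <- matrix(NA_real_, length(mir), length(smp),
               dimnames = list(mir, smp))
  ct[cbind(agg$mirna, agg$sample)] <- agg$ct

  ntc_min <- tapply(plate$ntc$ct, plate$ntc$mirna, min)

  log2copies <- matrix(NA_real_, length(mir), length(smp),
                       dimnames = list(mir, smp))
  undetected <- matrix(FALSE, length(mir), length(smp),
                       dimnames = list(mir, smp))
  for (m in mir) {
    std <- plate$standards[plate$standards$mirna == m, ]
    lc <- log10(std$copies)
    if (length(unique(lc)) < 2)
      stop(sprintf("standard series for %s has fewer than 2 levels", m))
    b <- stats::cov(lc, std$ct) / stats::var(lc)
    a <- mean(std$ct) - b * mean(lc)
    if (b >= 0)
      stop(sprintf("nonnegative standard-curve slope for %s: broken assay", m))
    cts <- ct[m, ]
    und <- !is.finite(cts) | cts > ntc_min[[m]]
    lg10 <- (cts - a) / b
    log2copies[m, ] <- ifelse(und, NA_real_, lg10 * log2(10))
    undetected[m, ] <- und
  }
  out <- abundance_matrix(log2copies, plate$groups, "mirna")
  attr(out, "undetected") <- undetected
  out
}

#' Resolve undetected miRNA measurements
#'
#' Fills `NA` (undetected) cells so normalization can proceed.  The default
#' imputes each miRNA's minimum detected log2 copy number across samples —
#' a rank-preserving floor that does not fabricate between-group signal.
#' miRNAs undetected in every sample are dropped with a warning.
#'
#' @param m miRNA [abundance_matrix()] with `NA` cells allowed.
#' @param method `"min_detected"` (default) or `"half_min"` (minimum
#'   detected copies halved, i.e. minus one log2 unit).
#' @return [abundance_matrix()] with no missing cells.
#' @export
impute_undetected <- function(m, method = c("min_detected", "half_min")) {
  stopifnot(inherits(m, "abundance_matrix"))
  method <- match.arg(method)
  x <- m$values
  all_na <- rowSums(!is.na(x)) == 0
  if (any(all_na)) {
    warning(sprintf("dropping %d miRNA(s) undetected in all samples",
                    sum(all_na)))
    x <- x[!all_na, , drop = FALSE]
  }
  fill <- apply(x, 1, min, na.rm = TRUE)
  if (method == "half_min") fill <- fill - 1
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- fill[idx[, 1]]
  abundance_matrix(x, m$groups, m$omics)
}
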