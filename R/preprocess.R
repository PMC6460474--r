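#' Median/SD normalization of miRNA log2 copy numbers
#'
#' Affinely transforms each sample so that the per-sample median and
#' standard deviation of log2 copy numbers are identical across samples.
#' The common targets are the means of the per-sample medians and SDs
#' before normalization, so the operation is idempotent.
#'
#' @param m miRNA [abundance_matrix()] (log2 scale, no missing cells;
#'   resolve undetected cells first, see [impute_undetected()]).
#' @return Normalized [abundance_matrix()].
#' @export
normalize_mirna <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  x <- m$values
  if (anyNA(x))
    stop("undetected cells must be resolved before normalization")
  med <- apply(x, 2, stats::median)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) stop("sample with zero standard deviation")
  target_med <- mean(med)
  target_sd <- mean(sds)
  y <- sweep(sweep(x, 2, med), 2, sds, "/") * target_sd + target_med
  abundance_matrix(y, m$groups, m$omics)
}

#' Remove peptides with high missingness
#'
#' Drops every peptide whose fraction of missing cells is 25% or higher
#' (the boundary is inclusive).  The removal log is attached as attribute
#' `removed` (data frame peptide / missing_frac).
#'
#' @param p A [peptide_matrix()].
#' @param max_missing Missingness threshold; default 0.25, removal when
#'   `missing fraction >= max_missing`.
#' @return Filtered [peptide_matrix()].
#' @export
filter_peptides <- function(p, max_missing = 0.25) {
  stopifnot(inherits(p, "peptide_matrix"))
  frac <- rowMeans(is.na(p$intensities))
  drop <- frac >= max_missing
  removed <- data.frame(peptide = rownames(p$intensities)[drop],
                        missing_frac = frac[drop], row.names = NULL)
  out <- peptide_matrix(p$intensities[!drop, , drop = FALSE],
                        p$map[!drop, , drop = FALSE],
                        p$groups)
  attr(out, "removed") <- removed
  out
}

#' K-nearest-neighbour imputation of missing peptide intensities
#'
#' Each missing cell is filled with the (optionally distance-weighted) mean
#' of the `k` nearest peptides, where distance is root-mean-square Euclidean
#' distance over the samples observed in both peptides, and only neighbours
#' observed in the target sample are eligible.
#'
#' @param p A [peptide_matrix()] (pre-filtered; see [filter_peptides()]).
#' @param k Number of neighbours; default 6.
#' @param weighted Distance-weighted mean (weights `1/(d + eps)`)?
#'   Default `TRUE`.
#' @return [peptide_matrix()] with no missing cells.
#' @export
impute_knn <- function(p, k = 6, weighted = TRUE) {
  stopifnot(inherits(p, "peptide_matrix"))
  x <- p$intensities
  n_pep <- nrow(x)
  if (k < 1 || k >= n_pep)
    stop("`k` must satisfy 1 <= k < number of peptides")
  miss_rows <- which(rowSums(is.na(x)) > 0)
  eps <- 1e-12
  for (i in miss_rows) {
    xi <- x[i, ]
    obs <- !is.na(xi)
    if (!any(obs))
      stop("peptide with no observed values cannot be imputed")
    diffs <- sweep(x[, obs, drop = FALSE], 2, xi[obs])
    d2 <- rowMeans(diffs^2, na.rm = TRUE)          # shared-sample RMS distance
    d2[i] <- Inf
    d2[rowSums(!is.na(diffs)) == 0] <- Inf          # no shared samples
    for (j in which(!obs)) {
      dj <- d2
      dj[is.na(x[, j])] <- Inf                      # neighbour must be observed at j
      ord <- order(dj)[seq_len(k)]
      ord <- ord[is.finite(dj[ord])]
      if (!length(ord))
        stop("no usable neighbours for imputation; reduce k or missingness")
      w <- if (weighted) 1 / (sqrt(dj[ord]) + eps) else rep(1, length(ord))
      x[i, j] <- sum(w * x[ord, j]) / sum(w)
    }
  }
  peptide_matrix(x, p$map, p$groups)
}

#' Median normalization of peptide intensities
#'
#' Multiplicatively scales each sample (linear scale) so that all
#' per-sample median intensities equal the grand median of the per-sample
#' medians; idempotent.
#'
#' @param p A [peptide_matrix()] with no missing cells.
#' @return Normalized [peptide_matrix()].
#' @export
normalize_median <- function(p) {
  stopifnot(inherits(p, "peptide_matrix"))
  x <- p$intensities
  if (anyNA(x)) stop("impute missing cells before median normalization")
  med <- apply(x, 2, stats::median)
  if (any(med <= 0)) stop("sample with nonpositive median intensity")
  target <- stats::median(med)
  y <- sweep(x, 2, target / med, "*")
  peptide_matrix(y, p$map, p$groups)
}

#' Roll peptides up to protein intensities
#'
#' Protein intensity per sample is the sum of its peptides' linear-scale
#' intensities; the result is returned on the log2 scale.  Proteins left
#' with zero peptides after filtering are dropped with a warning.
#'
#' @param p A [peptide_matrix()] with no missing cells.
#' @return Protein [abundance_matrix()] (log2 scale).
#' @export
rollup_protein <- function(p) {
  stopifnot(inherits(p, "peptide_matrix"))
  x <- p$intensities
  if (anyNA(x)) stop("impute missing cells before roll-up")
  prot <- rowsum(x, group = p$map$protein)
  lost <- setdiff(unique(p$map$protein), rownames(prot))
  if (length(lost))
    warning(sprintf("%d protein(s) had no peptides left and were dropped",
                    length(lost)))
  abundance_matrix(log2(prot), p$groups, "protein")
}

#' Per-feature Z-score transformation
#'
#' `z_ij = (x_ij - mean_i) / sd_i` across all samples, with the sample
#' (n-1) SD denominator by default.  Zero-variance features are dropped
#' with a warning reporting the count.
#'
#' @param a An [abundance_matrix()] with no missing cells and >= 2 samples.
#' @param denom `"n-1"` (default) or `"n"` SD denominator.
#' @return Object of class `zscore_matrix` (same shape as
#'   `abundance_matrix`: `values`, `groups`, `omics`).
#' @export
zscore <- function(a, denom = c("n-1", "n")) {
  stopifnot(inherits(a, "abundance_matrix"))
  denom <- match.arg(denom)
  x <- a$values
  if (anyNA(x)) stop("no missing cells allowed")
  n <- ncol(x)
  if (n < 2) stop("need >= 2 samples")
  mu <- rowMeans(x)
  sd_i <- sqrt(rowSums((x - mu)^2) / (n - 1))
  if (denom == "n") sd_i <- sd_i * sqrt((n - 1) / n)
  zero <- sd_i == 0
  if (any(zero)) {
    warning(sprintf("dropping %d zero-variance feature(s)", sum(zero)))
    x <- x[!zero, , drop = FALSE]
    mu <- mu[!zero]
    sd_i <- sd_i[!zero]
  }
  z <- (x - mu) / sd_i
  structure(list(values = z, groups = a$groups, omics = a$omics),
            class = c("zscore_matrix", "abundance_matrix"))
}
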