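#' Per-feature two-sample t-tests
#'
#' Welch (unequal-variance) two-sided t-test per feature by default;
#' pooled-variance Student test optional.  Degenerate features follow the
#' usual conventions: zero variance in both groups with equal means gives
#' `t = 0, p = 1`; zero variance with unequal means gives `p = 0` with a
#' warning.
#'
#' @param a An [abundance_matrix()] whose `groups` factor has exactly two
#'   levels, each with >= 2 samples.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return Data frame with one row per feature: `feature`, per-group means,
#'   `log2fc` (group2 - group1), `t`, `df`, `p`.
#' @export
ttest_two_sample <- function(a, variant = c("welch", "pooled")) {
  stopifnot(inherits(a, "abundance_matrix"))
  variant <- match.arg(variant)
  g <- droplevels(a$groups)
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (any(table(g) < 2)) stop("each group needs >= 2 samples")
  x <- a$values
  i1 <- g == levels(g)[1]
  i2 <- g == levels(g)[2]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- rowSums((x[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((x[, i2, drop = FALSE] - m2)^2) / (n2 - 1)
  if (variant == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(se2))
  }
  tstat <- (m2 - m1) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & m1 == m2
    tstat[eq] <- 0; p[eq] <- 1; df[eq] <- n1 + n2 - 2
    uneq <- degen & m1 != m2
    if (any(uneq)) {
      warning(sprintf("%d feature(s) with zero variance but unequal means; p set to 0",
                      sum(uneq)))
      tstat[uneq] <- sign(m2[uneq] - m1[uneq]) * Inf
      p[uneq] <- 0; df[uneq] <- n1 + n2 - 2
    }
  }
  out <- data.frame(feature = rownames(x), m1, m2,
                    log2fc = m2 - m1, t = tstat, df = df, p = p,
                    row.names = NULL)
  names(out)[2:3] <- paste0("mean_", levels(g))
  out
}

#' Two-sample tests with q-value correction
#'
#' Convenience wrapper: [ttest_two_sample()] followed by
#' [estimate_qvalues()]; the fitted q-value model is attached as attribute
#' `qvalue_model`.
#'
#' @inheritParams ttest_two_sample
#' @param ... Passed to [estimate_qvalues()].
#' @return The test table with an extra `q` column.
#' @export
diff_test <- function(a, variant = c("welch", "pooled"), ...) {
  tab <- ttest_two_sample(a, variant)
  qv <- estimate_qvalues(tab$p, ...)
  tab$q <- qv$q
  attr(tab, "qvalue_model") <- qv$model
  tab
}

#' Flag candidate features at the study thresholds
#'
#' miRNAs are selected at nominal `p < mirna_p` (the q-value decomposition
#' is typically unstable when a large share of miRNAs shift); proteins at
#' `q < protein_q` (strict inequality).  Direction records whether the
#' feature is up or down in the second group level.
#'
#' @param mirna Test table for miRNAs (needs columns `p`, `log2fc`).
#' @param protein Test table for proteins (needs columns `q`, `log2fc`).
#' @param mirna_p Nominal p threshold for miRNAs; default 0.01.
#' @param protein_q q threshold for proteins; default 0.05.
#' @return List with elements `mirna` and `protein`: the input tables with
#'   `selected` (logical) and `direction` (`"up"`/`"down"` in group 2)
#'   columns.
#' @export
select_candidates <- function(mirna, protein,
                              mirna_p = 0.01, protein_q = 0.05) {
  stopifnot(all(c("p", "log2fc") %in% names(mirna)),
            all(c("q", "log2fc") %in% names(protein)))
  mirna$selected <- mirna$p < mirna_p
  mirna$direction <- ifelse(mirna$log2fc > 0, "up", "down")
  protein$selected <- protein$q < protein_q
  protein$direction <- ifelse(protein$log2fc > 0, "up", "down")
  list(mirna = mirna, protein = protein)
}

#' PCA variance decomposition of a feature-by-sample matrix
#'
#' Principal component analysis of the sample vectors with feature
#' centering and no unit-variance scaling (via [stats::prcomp()]).
#' Components are 1-based and reported in decreasing variance order.
#'
#' @param a An [abundance_matrix()] with >= 2 samples.
#' @return Object of class `pca_summary`: list with `var_frac` (named,
#'   non-increasing, sums to 1), `scores` (samples x components) and
#'   `sdev`.
#' @export
pca_variance <- function(a) {
  stopifnot(inherits(a, "abundance_matrix"))
  if (ncol(a$values) < 2) stop("need >= 2 samples")
  pc <- stats::prcomp(t(a$values), center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  structure(list(var_frac = stats::setNames(v / sum(v),
                                            paste0("PC", seq_along(v))),
                 scores = pc$x, sdev = pc$sdev),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  cat("<pca_summary> variance fractions:\n")
  print(round(utils::head(x$var_frac, 5), 3))
  invisible(x)
}
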