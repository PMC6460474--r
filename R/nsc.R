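#' Fit a nearest shrunken centroid model on edge scores
#'
#' Prediction-analysis-style classifier operating on the edge co-expression
#' matrix.  Per edge `i` and class `k` it computes the overall centroid
#' `xbar_i`, class centroids `xbar_ik`, pooled within-class SD `s_i`
#' (within-class sum of squares divided by `n - K`), fudge constant
#' `s0 = median(s_i)`, class size factor `m_k = sqrt(1/n_k - 1/n)`
#' (the exact SE factor of class minus overall centroid; a
#' `sqrt(1/n_k + 1/n)` variant is available), standardized differences
#' `d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))`, soft-thresholded
#' `d'_ik = sign(d_ik) max(|d_ik| - delta, 0)` and shrunken centroids
#' `xbar'_ik = xbar_i + m_k (s_i + s0) d'_ik`.
#'
#' @param x Numeric matrix (features/edges x samples) or an
#'   [edge_scores()] result.
#' @param groups Class factor per sample (>= 2 classes, each >= 2 samples);
#'   taken from the edge-score object when omitted.
#' @param delta Soft threshold `Delta >= 0`.
#' @param prior `"empirical"` (`n_k / n`, default) or `"uniform"`.
#' @param mk_variant `"exact"` (`sqrt(1/n_k - 1/n)`, default) or `"plus"`
#'   (`sqrt(1/n_k + 1/n)`).
#' @return Object of class `nsc_model` with fields `overall`, `centroids`,
#'   `s`, `s0`, `mk`, `d`, `d_shrunk`, `centroids_shrunk`, `delta`,
#'   `prior`, `n_k`, `features`, `classes`.
#' @export
nsc_fit <- function(x, groups = NULL, delta = 0,
                    prior = c("empirical", "uniform"),
                    mk_variant = c("exact", "plus")) {
  if (inherits(x, "edge_score_matrix")) {
    if (is.null(groups)) groups <- x$groups
    x <- x$scores
  }
  prior <- match.arg(prior)
  mk_variant <- match.arg(mk_variant)
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix")
  if (is.null(rownames(x))) rownames(x) <- sprintf("f%d", seq_len(nrow(x)))
  groups <- droplevels(as.factor(groups))
  if (length(groups) != ncol(x)) stop("`groups` must have one entry per sample")
  if (delta < 0) stop("`delta` must be >= 0")
  K <- nlevels(groups)
  if (K < 2) stop("need >= 2 classes")
  n_k <- table(groups)
  if (any(n_k < 2)) stop("each class needs >= 2 samples")
  n <- ncol(x)

  overall <- rowMeans(x)
  centroids <- matrix(
    vapply(levels(groups),
           function(g) rowMeans(x[, groups == g, drop = FALSE]),
           numeric(nrow(x))),
    nrow = nrow(x), dimnames = list(rownames(x), levels(groups)))
  wss <- matrix(
    vapply(levels(groups), function(g) {
      xi <- x[, groups == g, drop = FALSE]
      rowSums((xi - rowMeans(xi))^2)
    }, numeric(nrow(x))),
    nrow = nrow(x))
  s <- sqrt(rowSums(wss) / (n - K))
  s0 <- stats::median(s)
  mk <- if (mk_variant == "exact") sqrt(1 / as.numeric(n_k) - 1 / n)
        else sqrt(1 / as.numeric(n_k) + 1 / n)
  names(mk) <- levels(groups)

  denom <- outer(s + s0, mk)                 # (s_i + s0) m_k
  d <- (centroids - overall) / denom
  d_shrunk <- sign(d) * pmax(abs(d) - delta, 0)
  centroids_shrunk <- overall + denom * d_shrunk
  dimnames(d) <- dimnames(d_shrunk) <- dimnames(centroids_shrunk) <-
    list(rownames(x), levels(groups))

  pi_k <- if (prior == "empirical") as.numeric(n_k) / n
          else rep(1 / K, K)
  names(pi_k) <- levels(groups)

  structure(list(overall = overall, centroids = centroids,
                 s = s, s0 = s0, mk = mk,
                 d = d, d_shrunk = d_shrunk,
                 centroids_shrunk = centroids_shrunk,
                 delta = delta, prior = pi_k,
                 n_k = as.numeric(n_k),
                 features = rownames(x), classes = levels(groups),
                 mk_variant = mk_variant, prior_type = prior),
            class = "nsc_model")
}

# re-threshold an existing fit at a new delta without refitting
nsc_shrink <- function(model, delta) {
  stopifnot(inherits(model, "nsc_model"), delta >= 0)
  denom <- outer(model$s + model$s0, model$mk)
  model$d_shrunk <- sign(model$d) * pmax(abs(model$d) - delta, 0)
  model$centroids_shrunk <- model$overall + denom * model$d_shrunk
  dimnames(model$d_shrunk) <- dimnames(model$centroids_shrunk) <-
    dimnames(model$d)
  model$delta <- delta
  model
}

#' @export
print.nsc_model <- function(x, ...) {
  cat(sprintf(
    "<nsc_model> %d features, classes %s, delta = %.4g, %d feature(s) active\n",
    length(x$features), paste(x$classes, collapse = "/"), x$delta,
    sum(rowSums(abs(x$d_shrunk)) > 0)))
  invisible(x)
}

#' Classify samples with a fitted shrunken-centroid model
#'
#' Uses the discriminant
#' `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log pi_k`;
#' the predicted class minimizes it and posterior probabilities are
#' `exp(-delta_k / 2)` normalized over classes.
#'
#' @param object An `nsc_model`.
#' @param newdata Matrix (features x samples) or [edge_scores()] result
#'   covering all model features.
#' @param ... Unused.
#' @return List with `class` (factor) and `posterior`
#'   (samples x classes matrix).
#' @export
predict.nsc_model <- function(object, newdata, ...) {
  if (inherits(newdata, "edge_score_matrix")) newdata <- newdata$scores
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = 1,
                                               dimnames = list(object$features, "s1"))
  missing <- setdiff(object$features, rownames(newdata))
  if (length(missing))
    stop(sprintf("newdata lacks %d model edge(s): %s",
                 length(missing),
                 paste(utils::head(missing, 5), collapse = ", ")))
  x <- newdata[object$features, , drop = FALSE]
  w <- 1 / (object$s + object$s0)^2
  disc <- vapply(seq_along(object$classes), function(k) {
    colSums(w * (x - object$centroids_shrunk[, k])^2) -
      2 * log(object$prior[k])
  }, numeric(ncol(x)))
  disc <- matrix(disc, ncol = length(object$classes),
                 dimnames = list(colnames(x), object$classes))
  lp <- -disc / 2
  lp <- lp - apply(lp, 1, max)
  post <- exp(lp) / rowSums(exp(lp))
  cls <- factor(object$classes[apply(disc, 1, which.min)],
                levels = object$classes)
  names(cls) <- colnames(x)
  list(class = cls, posterior = post)
}

#' Repeated stratified cross-validation for threshold selection
#'
#' Runs `n_repeats` independent rounds of stratified `n_folds`-fold
#' cross-validation; in each fold the model is fitted on the training folds
#' once and re-thresholded over the whole grid, recording held-out
#' misclassification and posterior log-loss.  The chosen threshold has the
#' smallest mean misclassification error across all repeats and folds.
#' With small cohorts the zero-one error often ties over a wide threshold
#' plateau (any strongly separating edge keeps the error at zero), so with
#' `tie_break = "confident"` (default) the tied set is first restricted to
#' thresholds where classification remains essentially certain — mean
#' cross-validated posterior probability of the true class at least
#' `confidence` (mean log-loss at most `-log(confidence)`) — and the
#' largest such threshold is chosen; when no tied threshold is that
#' confident (e.g. uninformative data) the rule reduces to
#' `tie_break = "largest"`, the plain largest-threshold (sparsest
#' subnetwork) tie-break.  Per-sample cross-validated posteriors at the
#' chosen threshold are averaged over repeats.
#'
#' @inheritParams nsc_fit
#' @param grid Numeric vector of candidate thresholds; default 30 evenly
#'   spaced values from 0 to `max |d_ik|` of the full-data fit.
#' @param n_repeats Number of CV repeats; default 10.
#' @param n_folds Folds per repeat; default 5, reduced with a warning when
#'   a class has fewer samples.
#' @param seed Integer seed controlling fold assignment.
#' @param tie_break `"confident"` (default) or `"largest"`.
#' @param confidence Mean true-class posterior required for a tied
#'   threshold to count as confidently classifying; default 0.95.
#' @return Object of class `nsc_cv`: `grid`, `errors`
#'   (repeat-fold x grid), `mean_error`, `mean_logloss`, `best_delta`,
#'   `best_error`, `cv_posterior`, `cv_class`, `folds` (list of per-repeat
#'   assignments), `model` (full-data fit at `best_delta`).
#' @export
nsc_cv <- function(x, groups = NULL, grid = NULL,
                   n_repeats = 10, n_folds = 5, seed = 1L,
                   prior = c("empirical", "uniform"),
                   mk_variant = c("exact", "plus"),
                   tie_break = c("confident", "largest"),
                   confidence = 0.95) {
  if (inherits(x, "edge_score_matrix")) {
    if (is.null(groups)) groups <- x$groups
    x <- x$scores
  }
  prior <- match.arg(prior)
  mk_variant <- match.arg(mk_variant)
  tie_break <- match.arg(tie_break)
  groups <- droplevels(as.factor(groups))
  n <- ncol(x)
  full <- nsc_fit(x, groups, delta = 0, prior = prior,
                  mk_variant = mk_variant)
  if (is.null(grid))
    grid <- seq(0, max(abs(full$d)), length.out = 30)
  if (!length(grid)) stop("threshold grid is empty")
  grid <- sort(unique(grid))
  min_class <- min(table(groups))
  if (min_class < n_folds) {
    warning(sprintf("reducing folds from %d to %d (smallest class size)",
                    n_folds, min_class))
    n_folds <- min_class
  }
  if (n_folds < 2) stop("need >= 2 folds")

  folds <- withr::with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      f <- integer(n)
      for (g in levels(groups)) {
        idx <- sample(which(groups == g))
        f[idx] <- rep_len(sample.int(n_folds), length(idx))
      }
      f
    })
  })

  errors <- matrix(NA_real_, n_repeats * n_folds, length(grid))
  logloss <- matrix(NA_real_, n_repeats * n_folds, length(grid))
  post_sum <- matrix(0, n, nlevels(groups),
                     dimnames = list(colnames(x), levels(groups)))
  row <- 0L
  for (r in seq_len(n_repeats)) {
    f <- folds[[r]]
    for (k in seq_len(n_folds)) {
      row <- row + 1L
      test <- f == k
      fit <- nsc_fit(x[, !test, drop = FALSE], groups[!test],
                     delta = 0, prior = prior, mk_variant = mk_variant)
      truth_idx <- cbind(seq_len(sum(test)),
                         as.integer(factor(groups[test],
                                           levels = levels(groups))))
      for (gi in seq_along(grid)) {
        pr <- predict(nsc_shrink(fit, grid[gi]), x[, test, drop = FALSE])
        errors[row, gi] <- mean(pr$class != groups[test])
        logloss[row, gi] <- mean(-log(pmax(pr$posterior[truth_idx], 1e-300)))
      }
    }
  }
  mean_error <- colMeans(errors)
  mean_logloss <- colMeans(logloss)
  tied <- which(mean_error <= min(mean_error) + 1e-12)
  if (tie_break == "confident" && length(tied) > 1) {
    confident <- tied[mean_logloss[tied] <= -log(confidence)]
    if (length(confident)) tied <- confident
  }
  best <- max(grid[tied])
  best_error <- min(mean_error)

  # second pass: held-out posteriors at the chosen threshold
  for (r in seq_len(n_repeats)) {
    f <- folds[[r]]
    for (k in seq_len(n_folds)) {
      test <- f == k
      fit <- nsc_fit(x[, !test, drop = FALSE], groups[!test],
                     delta = best, prior = prior, mk_variant = mk_variant)
      pr <- predict(fit, x[, test, drop = FALSE])
      post_sum[test, ] <- post_sum[test, ] + pr$posterior
    }
  }
  cv_posterior <- post_sum / n_repeats
  cv_class <- factor(levels(groups)[apply(cv_posterior, 1, which.max)],
                     levels = levels(groups))
  names(cv_class) <- colnames(x)

  structure(list(grid = grid, errors = errors, mean_error = mean_error,
                 mean_logloss = mean_logloss,
                 best_delta = best, best_error = best_error,
                 cv_posterior = cv_posterior, cv_class = cv_class,
                 folds = folds, n_repeats = n_repeats, n_folds = n_folds,
                 seed = seed,
                 model = nsc_shrink(full, best)),
            class = "nsc_cv")
}

#' @export
print.nsc_cv <- function(x, ...) {
  cat(sprintf(
    "<nsc_cv> %d repeats x %d folds; best delta = %.4g (mean error %.3f)\n",
    x$n_repeats, x$n_folds, x$best_delta, x$best_error))
  invisible(x)
}

#' Extract the predictive subnetwork from a fitted model
#'
#' The predictive subnetwork consists of the edges whose shrunken
#' standardized difference `d'_ik` is nonzero for at least one class at the
#' model's threshold, annotated with per-class shrunken differences and
#' summarized by edge sign (miRNA->protein regulation vs PPI).
#'
#' @param model An `nsc_model` (typically the `model` element of
#'   [nsc_cv()]).
#' @param net The [signed_network()] the edge scores were built from.
#' @return Object of class `predictive_subnetwork`: `edges` (edge table
#'   with `d_shrunk_<class>` columns), `nodes` (node/omics-type table),
#'   `counts` (`total`, `mirna_protein`, `ppi`), `empty` flag, `delta`.
#' @export
extract_subnetwork <- function(model, net) {
  stopifnot(inherits(model, "nsc_model"), inherits(net, "signed_network"))
  sel <- rowSums(abs(model$d_shrunk)) > 0
  ids <- model$features[sel]
  e <- net$edges[match(ids, net$edges$edge_id), , drop = FALSE]
  if (anyNA(e$edge_id))
    stop("model features are not edges of the supplied network")
  ds <- model$d_shrunk[sel, , drop = FALSE]
  colnames(ds) <- paste0("d_shrunk_", model$classes)
  e <- cbind(e, as.data.frame(ds))
  rownames(e) <- NULL
  nodes <- unique(c(e$node1, e$node2))
  counts <- list(total = nrow(e),
                 mirna_protein = sum(e$sign == -1L),
                 ppi = sum(e$sign == 1L))
  empty <- nrow(e) == 0
  if (empty) warning("predictive subnetwork is empty at this threshold")
  structure(list(edges = e,
                 nodes = data.frame(node = nodes,
                                    type = unname(net$node_type[nodes])),
                 counts = counts, empty = empty, delta = model$delta),
            class = "predictive_subnetwork")
}

#' @export
print.predictive_subnetwork <- function(x, ...) {
  cat(sprintf(
    "<predictive_subnetwork> %d relationships (%d miRNA-protein regulation, %d PPIs) at delta = %.4g\n",
    x$counts$total, x$counts$mirna_protein, x$counts$ppi, x$delta))
  invisible(x)
}
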