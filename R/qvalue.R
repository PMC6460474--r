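#' Storey q-values with smoother pi0 estimation
#'
#' Estimates the null proportion `pi0` on a lambda grid,
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))`, extrapolates to
#' `lambda -> 1` with a cubic smoothing spline (df = 3), clips to `[0, 1]`,
#' and computes `q_i = min over t >= p_i of pi0 * m * t / #\{p <= t\}`.
#' With `pi0` forced to 1 (`pi0_method = "bh"`) the result equals
#' Benjamini-Hochberg adjusted p-values.
#'
#' When the raw pi0 estimate falls below 0.05 — the regime where the
#' p-value distribution is dominated by the alternative and cannot be
#' decomposed reliably — a structured warning of class
#' `omicsPAM_pi0_unstable` is emitted and the model's `unstable` flag is
#' set; callers should then fall back to nominal-p selection.
#'
#' @param p Numeric vector of p-values in `[0, 1]`; must be non-empty.
#' @param pi0_method `"smoother"` (default), `"fixed"` (single
#'   lambda = 0.5) or `"bh"` (pi0 := 1, Benjamini-Hochberg).
#' @param lambda Grid for pi0 estimation; default `seq(0.05, 0.95, 0.05)`.
#' @return List with `q` (q-values, same order as `p`) and `model` (class
#'   `qvalue_model`: `pi0`, `pi0_raw`, `pi0_lambda`, `lambda`, `method`,
#'   `unstable`).
#' @export
estimate_qvalues <- function(p, pi0_method = c("smoother", "fixed", "bh"),
                             lambda = seq(0.05, 0.95, 0.05)) {
  pi0_method <- match.arg(pi0_method)
  if (length(p) == 0) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)

  pi0_lambda <- NULL
  pi0_raw <- 1
  method <- pi0_method
  if (pi0_method == "bh") {
    pi0_raw <- 1
  } else {
    lambda <- sort(unique(lambda))
    pi0_lambda <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)),
                         numeric(1))
    if (pi0_method == "smoother" && length(lambda) >= 4 &&
        all(is.finite(pi0_lambda))) {
      spl <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
      pi0_raw <- stats::predict(spl, x = max(lambda))$y
    } else {
      method <- "fixed"
      l0 <- if (0.5 %in% lambda) 0.5 else lambda[ceiling(length(lambda) / 2)]
      pi0_raw <- sum(p > l0) / (m * (1 - l0))
    }
  }
  pi0 <- min(max(pi0_raw, 0), 1)
  unstable <- pi0_raw < 0.05
  if (unstable && pi0_method != "bh")
    warning(structure(
      class = c("omicsPAM_pi0_unstable", "warning", "condition"),
      list(message = paste0(
             "pi0 estimate ", signif(pi0_raw, 3),
             " < 0.05: p-value distribution cannot be decomposed reliably; ",
             "consider nominal p-value selection"),
           call = sys.call(-1))))

  ord <- order(p, decreasing = TRUE)
  r <- rank(p, ties.method = "max")
  q0 <- pi0 * m * p / r
  q <- numeric(m)
  q[ord] <- cummin(q0[ord])
  q <- pmin(q, 1)

  model <- structure(list(pi0 = pi0, pi0_raw = pi0_raw,
                          pi0_lambda = pi0_lambda, lambda = lambda,
                          method = method, unstable = unstable),
                     class = "qvalue_model")
  list(q = q, model = model)
}

#' @export
print.qvalue_model <- function(x, ...) {
  cat(sprintf("<qvalue_model> pi0 = %.3f (%s%s)\n", x$pi0, x$method,
              if (x$unstable) ", UNSTABLE" else ""))
  invisible(x)
}
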