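# SLIM (sliding linear model) q-values: estimate the null proportion pi0
# from the shape of the p-value distribution, then Storey-style step-up
# q-values q_(i) = min_{j >= i} pi0 * m * p_(j) / j.

#' Estimate the null proportion pi0 by a sliding linear model
#'
#' The survival curve of the p-values, `1 - ECDF(lambda)`, is evaluated on
#' the grid lambda = 0.01, 0.02, ..., 0.95. Under a pure null it is the
#' straight line `pi0 * (1 - lambda)`; true effects bend it upward near 0 but
#' leave the right-hand tail linear with slope `-pi0`. For every candidate
#' cut point on the grid an ordinary least-squares line is fitted to the
#' points at `lambda >= cut`; the cut with the smallest mean squared residual
#' is taken as the start of the linear regime and pi0 is the negated slope
#' there, clamped to \[0, 1\].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param lambda_grid Evaluation grid (default `seq(0.01, 0.95, 0.01)`).
#' @param min_points Minimum number of grid points a candidate fit may use
#'   (default 10).
#' @return Estimated pi0 in \[0, 1\].
#' @export
estimate_pi0_slim <- function(p, lambda_grid = seq(0.01, 0.95, by = 0.01),
                              min_points = 10L) {
  check_pvalues(p)
  surv <- 1 - stats::ecdf(p)(lambda_grid)
  ncand <- length(lambda_grid) - min_points + 1L
  if (ncand < 1L) stop("lambda grid too short for min_points")
  best_mse <- Inf
  best_slope <- -1
  for (k in seq_len(ncand)) {
    lam <- lambda_grid[k:length(lambda_grid)]
    y <- surv[k:length(lambda_grid)]
    lam_c <- lam - mean(lam)
    slope <- sum(lam_c * y) / sum(lam_c^2)
    resid <- y - mean(y) - slope * lam_c
    mse <- mean(resid^2)
    if (mse < best_mse) {
      best_mse <- mse
      best_slope <- slope
    }
  }
  min(1, max(0, -best_slope))
}

#' q-values via SLIM (or plain Benjamini-Hochberg)
#'
#' Converts p-values to q-values with `pi0` estimated by
#' [estimate_pi0_slim()] and the step-up rule
#' `q_(i) = min_{j >= i} (pi0 * m * p_(j) / j)`, capped at 1. With
#' `pi0 = 1` (or `method = "bh"`) this is exactly Benjamini-Hochberg.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"slim"` (estimate pi0) or `"bh"` (pi0 = 1).
#' @param pi0 Optional fixed pi0 overriding estimation.
#' @return q-values in the original order of `p`; a monotone non-decreasing
#'   transform of `p`.
#' @export
slim_qvalues <- function(p, method = c("slim", "bh"), pi0 = NULL) {
  method <- match.arg(method)
  check_pvalues(p)
  m <- length(p)
  if (m == 0L) return(numeric())
  if (is.null(pi0)) {
    pi0 <- if (method == "bh") 1 else estimate_pi0_slim(p)
  }
  o <- order(p)
  ps <- p[o]
  q <- pi0 * m * ps / seq_len(m)
  q <- rev(cummin(rev(q)))  # step-up: q_(i) = min_{j >= i} ...
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

check_pvalues <- function(p) {
  if (length(p) < 1L) return(invisible(p))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  invisible(p)
}
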