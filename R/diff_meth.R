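# Per-window differential-methylation testing: binomial logistic regression
# fitted by IRLS, chi-square likelihood-ratio test of the group (age) term,
# per-window overdispersion correction, and DMR calling.

# Binomial logistic IRLS on a fixed design matrix.
# y = successes (n_meth), n = trials; X = design matrix (n_samples x p).
# Coefficients are clamped to |beta| <= clamp to keep complete separation
# finite; returns convergence status so callers can report p = 1.
irls_binom <- function(y, n, X, max_iter = 100L, tol = 1e-8, clamp = 20) {
  p <- ncol(X)
  prop <- (y + 0.5) / (n + 1)
  eta <- log(prop / (1 - prop))
  beta <- rep(0, p)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    mu <- stats::plogis(eta)
    w <- n * mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - n * mu) / w
    fit <- tryCatch(
      stats::lm.wfit(X, z, w),
      error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) break
    beta <- pmin(pmax(fit$coefficients, -clamp), clamp)
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    ll <- binom_loglik(y, n, mu)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + tol)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  mu <- stats::plogis(drop(X %*% beta))
  list(beta = beta, fitted = mu, loglik = binom_loglik(y, n, mu),
       converged = converged)
}

# log-likelihood without the binomial coefficient term (cancels in LRTs,
# and Pearson residuals do not need it)
binom_loglik <- function(y, n, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  sum(y * log(mu) + (n - y) * log(1 - mu))
}

#' Likelihood-ratio test of the group term for one window
#'
#' Fits two binomial logistic models to the per-sample methylated counts of a
#' window — null: intercept + covariates; alternative: null + group
#' indicator — and returns the likelihood-ratio statistic
#' `2 * (loglik_alt - loglik_null)` on 1 degree of freedom. With no
#' covariates this equals the classic 2x2 G-test of pooled counts.
#'
#' @param n_meth,n_unmeth Integer vectors of per-sample counts.
#' @param treatment 0/1 vector (reference group = 0, e.g. young).
#' @param covariates Optional data.frame of per-sample factors
#'   (e.g. sequencing run), or NULL.
#' @param max_iter Maximum IRLS iterations before the window is flagged
#'   non-converged (conservatively reported as p = 1 downstream).
#' @return List: `lrt_stat`, `df` (= 1), `phi` (Pearson overdispersion of the
#'   alternative model, floored at 1), `fitted_alt`, `converged`.
#' @export
fit_window_lrt <- function(n_meth, n_unmeth, treatment, covariates = NULL,
                           max_iter = 100L) {
  n <- n_meth + n_unmeth
  ns <- length(n)
  stopifnot(length(n_unmeth) == ns, length(treatment) == ns)
  if (length(unique(treatment)) < 2L) stop("both treatment levels required")
  X0 <- matrix(1, ns, 1L)
  if (!is.null(covariates)) {
    mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    X0 <- mm  # includes intercept
  }
  X1 <- cbind(X0, treatment = as.numeric(treatment))
  fit0 <- irls_binom(n_meth, n, X0, max_iter = max_iter)
  fit1 <- irls_binom(n_meth, n, X1, max_iter = max_iter)
  lrt <- 2 * (fit1$loglik - fit0$loglik)
  lrt <- max(lrt, 0)  # numerical guard; true LRT is >= 0
  phi <- pearson_phi(n_meth, n, fit1$fitted, ncol(X1))
  list(lrt_stat = lrt, df = 1L, phi = phi, fitted_alt = fit1$fitted,
       converged = fit0$converged && fit1$converged)
}

# Pearson X^2 / residual df, floored at 1. Residual df <= 0 => phi = 1 with
# a warning (the correction is undefined there).
pearson_phi <- function(y, n, mu, n_params) {
  rdf <- length(y) - n_params
  if (rdf <= 0L) {
    warning("residual df <= 0; overdispersion set to 1")
    return(1)
  }
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  x2 <- sum((y - n * mu)^2 / (n * mu * (1 - mu)))
  max(1, x2 / rdf)
}

#' Per-window overdispersion factor
#'
#' Pearson chi-square of the fitted alternative model divided by its residual
#' degrees of freedom, floored at 1. The corrected test statistic is
#' `lrt_stat / phi`, referred to chi-square(1): flooring guarantees the
#' correction never inflates significance.
#'
#' @inheritParams fit_window_lrt
#' @return Numeric scalar >= 1.
#' @export
overdispersion_phi <- function(n_meth, n_unmeth, treatment,
                               covariates = NULL) {
  fit_window_lrt(n_meth, n_unmeth, treatment, covariates)$phi
}

#' Pooled methylation difference in percentage points
#'
#' `100 * (pooled proportion, group 1) - 100 * (pooled proportion, group 0)`,
#' pooling counts across the samples of each group. Positive values mean
#' hypermethylation in group 1 (old).
#'
#' @inheritParams fit_window_lrt
#' @return Numeric scalar in \[-100, 100\]; `NA` if either group has zero
#'   total coverage.
#' @export
meth_diff <- function(n_meth, n_unmeth, treatment) {
  n <- n_meth + n_unmeth
  t1 <- treatment == 1
  n1 <- sum(n[t1]); n0 <- sum(n[!t1])
  if (n1 == 0 || n0 == 0) return(NA_real_)
  100 * (sum(n_meth[t1]) / n1 - sum(n_meth[!t1]) / n0)
}

#' Test every window for differential methylation
#'
#' Runs the logistic-regression likelihood-ratio test with overdispersion
#' correction on each retained window, then converts p-values to q-values.
#' Windows where either group has zero coverage are dropped with a warning;
#' non-converged fits are conservatively assigned p = 1.
#'
#' @param wc A `window_counts` object from [tile_and_aggregate()].
#' @param meta Sample metadata containing `sample_id` and `age_group`
#'   (plus the covariate columns).
#' @param covariates Character vector of metadata columns to adjust for
#'   (default `"run"`; use `NULL` for none).
#' @param correction Multiple-testing method: `"slim"` (default) or `"bh"`.
#' @param max_iter IRLS iteration cap.
#' @return `data.table` with one row per tested window: `chrom`, `start`,
#'   `end`, `meth_diff`, `lrt_stat`, `phi`, `pvalue`, `qvalue`, `direction`,
#'   `converged`.
#' @export
test_windows <- function(wc, meta, covariates = "run",
                         correction = c("slim", "bh"), max_iter = 100L) {
  correction <- match.arg(correction)
  stopifnot(inherits(wc, "window_counts"))
  meta <- as.data.frame(meta)
  idx <- match(wc$samples, meta$sample_id)
  if (anyNA(idx)) {
    stop("metadata missing sample(s): ",
         paste(wc$samples[is.na(idx)], collapse = ", "))
  }
  meta <- meta[idx, , drop = FALSE]
  if (!all(meta$age_group %in% c("young", "old"))) {
    stop("age_group must be 'young' or 'old'")
  }
  treatment <- as.numeric(meta$age_group == "old")
  if (length(unique(treatment)) < 2L) stop("both age groups required")
  cov_df <- NULL
  if (!is.null(covariates) && length(covariates) > 0L) {
    cov_df <- meta[, covariates, drop = FALSE]
    cov_df[] <- lapply(cov_df, factor)
    cov_df <- cov_df[, vapply(cov_df, function(x) nlevels(x) > 1L,
                              logical(1L)), drop = FALSE]
    if (ncol(cov_df) == 0L) cov_df <- NULL
  }
  nw <- nrow(wc$windows)
  md <- lrt <- phi <- pval <- rep(NA_real_, nw)
  conv <- rep(TRUE, nw)
  for (i in seq_len(nw)) {
    y <- wc$n_meth[i, ]; u <- wc$n_unmeth[i, ]
    md[i] <- meth_diff(y, u, treatment)
    if (is.na(md[i])) next
    fit <- fit_window_lrt(y, u, treatment, cov_df, max_iter = max_iter)
    lrt[i] <- fit$lrt_stat
    phi[i] <- fit$phi
    conv[i] <- fit$converged
    pval[i] <- if (fit$converged) {
      stats::pchisq(fit$lrt_stat / fit$phi, df = 1L, lower.tail = FALSE)
    } else 1
  }
  keep <- !is.na(md)
  if (any(!keep)) {
    warning(sum(!keep), " window(s) dropped: zero coverage in one group")
  }
  if (any(!conv[keep])) {
    warning(sum(!conv[keep]), " window(s) did not converge; p set to 1")
  }
  res <- data.table::data.table(
    wc$windows[keep],
    meth_diff = md[keep], lrt_stat = lrt[keep], phi = phi[keep],
    pvalue = pval[keep],
    qvalue = slim_qvalues(pval[keep], method = correction),
    direction = ifelse(md[keep] > 0, "hyper", "hypo"),
    converged = conv[keep])
  res[]
}

#' Apply DMR thresholds
#'
#' Flags windows with `qvalue < q_max` and `|meth_diff| > min_abs_diff`
#' (strict inequalities) as differentially methylated regions.
#'
#' @param results Output of [test_windows()].
#' @param q_max q-value threshold (default 0.05).
#' @param min_abs_diff Minimum absolute methylation difference in percentage
#'   points (default 10).
#' @return `results` with an added logical `pass` column and the thresholds
#'   stored as attributes.
#' @export
call_dmrs <- function(results, q_max = 0.05, min_abs_diff = 10) {
  out <- data.table::copy(data.table::as.data.table(results))
  out$pass <- out$qvalue < q_max & abs(out$meth_diff) > min_abs_diff
  data.table::setattr(out, "q_max", q_max)
  data.table::setattr(out, "min_abs_diff", min_abs_diff)
  out[]
}
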