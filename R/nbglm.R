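# Negative-binomial GLM with log link and a fixed unit-coefficient
# offset on log total UMIs:
#
#   U_L1,i ~ NB(mu_i, theta),  mu_i = exp(log U_total,i + a . X_i + b)
#
# so exp(a) is the fold-change in the per-molecule LINE-1 rate between
# predictor levels and exp(b) the baseline rate. Detection of lowly
# expressed LINE-1 scales with cell depth; the fixed offset removes that
# bias, which rank tests on log-normalized expression do not. Fitting
# alternates IRLS for (a, b) with profile-likelihood updates of the
# dispersion theta.

THETA_MIN <- 1e-4
THETA_MAX <- 1e6

nb_loglik <- function(y, mu, theta) {
  if (is.infinite(theta)) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
}

nb_weights <- function(mu, theta) {
  if (is.infinite(theta)) mu else mu / (1 + mu / theta)
}

# One IRLS solve of the coefficients for fixed theta, with step-halving
# so the likelihood never decreases. Non-intercept coefficients are
# capped at |coef| <= cap to guard against perfect separation.
irls_beta <- function(y, M, off, beta, theta, cap = 30, max_iter = 50L,
                      tol = 1e-12) {
  clamp <- function(b) {
    if (ncol(M) > 1L) b[-1L] <- pmin(pmax(b[-1L], -cap), cap)
    b
  }
  eta <- off + drop(M %*% beta)
  ll <- nb_loglik(y, exp(eta), theta)
  capped <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- pmax(exp(eta), 1e-12)
    w <- nb_weights(mu, theta)
    z <- (eta - off) + (y - mu) / mu
    fit <- stats::lm.wfit(M, z, w)
    beta_new <- clamp(fit$coefficients)
    step <- 1
    repeat {
      cand <- beta + step * (beta_new - beta)
      eta_cand <- off + drop(M %*% cand)
      ll_cand <- nb_loglik(y, pmax(exp(eta_cand), 1e-300), theta)
      if (is.finite(ll_cand) && ll_cand >= ll - 1e-10) break
      step <- step / 2
      if (step < 1e-6) { cand <- beta; eta_cand <- eta; ll_cand <- ll; break }
    }
    delta <- max(abs(cand - beta))
    beta <- cand; eta <- eta_cand; ll <- ll_cand
    if (delta < tol) break
  }
  if (ncol(M) > 1L && any(abs(beta[-1L]) >= cap - 1e-8)) capped <- TRUE
  list(beta = beta, eta = eta, loglik = ll, capped = capped)
}

# Profile-likelihood update of theta on the log scale, keeping the
# better of the old and proposed value.
update_theta <- function(y, mu, theta_old) {
  f <- function(lt) nb_loglik(y, mu, exp(lt))
  opt <- stats::optimize(f, c(log(THETA_MIN), log(THETA_MAX)), maximum = TRUE,
                         tol = 1e-10)
  cand <- exp(opt$maximum)
  if (is.finite(theta_old) && f(log(theta_old)) >= opt$objective) theta_old
  else cand
}

#' Fit the offset negative-binomial GLM
#'
#' Maximizes the NB likelihood of per-cell LINE-1 UMI counts with mean
#' `mu_i = exp(log(u_total_i) + a.X_i + b)` and a dispersion `theta`
#' shared across cells. The coefficient on `log(u_total)` is fixed at 1
#' (an offset), so `a` is a log fold-change in the per-molecule LINE-1
#' rate. Coefficients and theta are updated alternately (IRLS /
#' profile-likelihood) until the log-likelihood changes by less than
#' `tol`; the likelihood is non-decreasing across iterations by
#' construction. Wald standard errors come from the observed information
#' at convergence with theta held fixed.
#'
#' @param u_l1 Non-negative integer response (LINE-1 UMIs per cell).
#' @param u_total Positive per-cell total UMIs (offset = `log(u_total)`).
#' @param X Optional predictor: vector or matrix (columns named);
#'   omitted for an intercept-only model.
#' @param theta `NULL` to estimate the dispersion; a positive number (or
#'   `Inf` for the Poisson limit) to fix it.
#' @param max_outer Maximum coefficient/dispersion alternations.
#' @param tol Convergence tolerance on the log-likelihood.
#' @return An `NbGlmFit` list: `coefficients` (intercept `b` first, then
#'   `a`), `se`, `theta`, `theta_fixed`, `loglik`, `converged`, `iter`,
#'   `n`, `separation_warning`, `vcov`, `fitted`.
#' @examples
#' set.seed(1)
#' tot <- round(10^rnorm(300, 3.5, 0.3))
#' x <- rep(0:1, each = 150)
#' y <- rnbinom(300, size = 0.7, mu = tot * exp(log(3) * x + log(1e-3)))
#' fit <- fit_nb_glm(y, tot, X = x)
#' exp(coef(fit)[["X"]])   # ~ 3-fold
#' @export
fit_nb_glm <- function(u_l1, u_total, X = NULL, theta = NULL,
                       max_outer = 50L, tol = 1e-8) {
  y <- as.numeric(u_l1)
  stopifnot(length(u_total) == length(y), all(u_total >= 1), all(y >= 0))
  if (sum(y) == 0) stop("degenerate response: all LINE-1 counts are zero")
  off <- log(as.numeric(u_total))
  if (is.null(X)) {
    M <- matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    Xm <- as.matrix(X)
    if (is.null(colnames(Xm)))
      colnames(Xm) <- if (ncol(Xm) == 1L) "X" else paste0("X", seq_len(ncol(Xm)))
    if (anyNA(Xm)) stop("missing values in predictors")
    if (any(apply(Xm, 2, function(v) length(unique(v))) < 2L))
      stop("predictor with a single distinct value")
    M <- cbind("(Intercept)" = 1, Xm)
  }
  beta <- stats::lm.wfit(M, log(pmax(y, 0.5)) - off, rep(1, length(y)))$coefficients

  est_theta <- is.null(theta)
  if (est_theta) {
    mu0 <- pmax(exp(off + drop(M %*% beta)), 1e-12)
    denom <- sum((y - mu0)^2 - mu0)
    theta <- if (denom <= 0) THETA_MAX else
      min(max(sum(mu0^2) / denom, THETA_MIN), THETA_MAX)
  }

  ll <- -Inf; converged <- FALSE; capped <- FALSE; it <- 0L
  ll_trace <- numeric(0)
  for (it in seq_len(max_outer)) {
    step <- irls_beta(y, M, off, beta, theta)
    beta <- step$beta; capped <- capped || step$capped
    mu <- pmax(exp(step$eta), 1e-300)
    if (est_theta) theta <- update_theta(y, mu, theta)
    ll_new <- nb_loglik(y, mu, theta)
    ll_trace <- c(ll_trace, ll_new)
    if (is.finite(ll) && abs(ll_new - ll) < tol) { ll <- ll_new; converged <- TRUE; break }
    ll <- ll_new
    if (!est_theta && it >= 2L) { converged <- TRUE; break }
  }
  if (capped)
    warning("possible perfect separation: coefficient capped at |a| = 30")

  mu <- pmax(exp(off + drop(M %*% beta)), 1e-300)
  w <- nb_weights(mu, theta)
  info <- crossprod(M, M * w)
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, ncol(M), ncol(M)))
  se <- sqrt(pmax(diag(vc), 0))
  names(se) <- colnames(M)
  structure(list(coefficients = stats::setNames(beta, colnames(M)),
                 se = se, theta = theta, theta_fixed = !est_theta,
                 loglik = ll, ll_trace = ll_trace,
                 converged = converged, iter = it,
                 n = length(y), separation_warning = capped,
                 vcov = vc, fitted = mu),
            class = "NbGlmFit")
}

#' @export
coef.NbGlmFit <- function(object, ...) object$coefficients

#' @export
logLik.NbGlmFit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) +
              !object$theta_fixed, class = "logLik")
}

#' @export
print.NbGlmFit <- function(x, ...) {
  cat("Offset NB GLM fit (n =", x$n, ")\n")
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    fold_change = exp(x$coefficients))
  print(tab, digits = 4)
  cat("theta =", format(x$theta, digits = 4),
      if (x$theta_fixed) "(fixed)" else "(estimated)",
      " logLik =", format(x$loglik, digits = 8),
      " converged =", x$converged, "\n")
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' The analysis-of-deviance p-value for dropping the predictors that are
#' in `full` but not in `reduced`: statistic `2 * (logLik_full -
#' logLik_reduced)` against a chi-square with the difference in
#' coefficient count as degrees of freedom. Each fit keeps its own
#' estimated theta (the `anova` convention for NB fits).
#'
#' @param full,reduced `NbGlmFit` objects on the same cells; `reduced`'s
#'   predictors must be a subset of `full`'s.
#' @return An `LrtResult` list: `statistic`, `df`, `p_value`.
#' @export
lrt_pvalue <- function(full, reduced) {
  stopifnot(inherits(full, "NbGlmFit"), inherits(reduced, "NbGlmFit"))
  if (full$n != reduced$n)
    stop("fits are on different numbers of cells")
  if (!all(names(reduced$coefficients) %in% names(full$coefficients)))
    stop("models are not nested")
  df <- length(full$coefficients) - length(reduced$coefficients)
  if (df < 0L) stop("models are not nested")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p),
            class = "LrtResult")
}

#' @export
print.LrtResult <- function(x, ...) {
  cat("LRT: statistic =", format(x$statistic, digits = 6), " df =", x$df,
      " p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Estimate LINE-1 transcripts per million from a fit
#'
#' `TPM(x) = 1e6 * exp(a.x + b)`: the model's per-molecule LINE-1 rate at
#' predictor value `x`, scaled to transcripts per million. The ratio
#' `TPM(1) / TPM(0)` equals `exp(a)` exactly.
#'
#' @param fit An `NbGlmFit`.
#' @param x Predictor value(s), matched by position to the non-intercept
#'   coefficients (scalar recycled).
#' @return Numeric TPM estimate.
#' @export
estimate_tpm <- function(fit, x = 0) {
  stopifnot(inherits(fit, "NbGlmFit"))
  a <- fit$coefficients[-1L]
  if (length(a) == 0L) {
    lin <- 0
  } else {
    x <- rep_len(x, length(a))
    lin <- sum(a * x)
  }
  unname(1e6 * exp(lin + fit$coefficients[[1L]]))
}

#' Differential LINE-1 expression for one contrast
#'
#' Convenience driver on an [attach_totals()] table: builds a binary (or
#' numeric) predictor from a column, fits the full and intercept-only
#' offset NB GLM, and reports fold change, LRT p-value and per-level
#' TPM.
#'
#' @param counts An `L1CountTable` data.frame with columns `u_l1`,
#'   `u_total`, plus the predictor column.
#' @param predictor Name of the predictor column; character/factor
#'   columns need `level` to define the indicator.
#' @param level For categorical predictors, the level coded 1.
#' @return A list: `fit`, `null_fit`, `lrt`, and a one-row `summary`
#'   data.frame (`coef`, `se`, `fold_change`, `p_value`, `tpm_at_0`,
#'   `tpm_at_1`).
#' @export
l1_glm <- function(counts, predictor, level = NULL) {
  stopifnot(predictor %in% names(counts))
  v <- counts[[predictor]]
  x <- if (is.numeric(v)) v else {
    if (is.null(level)) stop("categorical predictor needs `level`")
    as.numeric(v == level)
  }
  X <- matrix(x, ncol = 1L,
              dimnames = list(NULL, if (is.null(level)) predictor
                              else paste0(predictor, "==", level)))
  fit <- fit_nb_glm(counts$u_l1, counts$u_total, X = X)
  null_fit <- fit_nb_glm(counts$u_l1, counts$u_total)
  lrt <- lrt_pvalue(fit, null_fit)
  a <- fit$coefficients[[2L]]
  list(fit = fit, null_fit = null_fit, lrt = lrt,
       summary = data.frame(
         predictor = colnames(X), coef = a, se = fit$se[[2L]],
         fold_change = exp(a), p_value = lrt$p_value,
         tpm_at_0 = estimate_tpm(fit, 0), tpm_at_1 = estimate_tpm(fit, 1)))
}
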