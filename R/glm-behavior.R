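#' Hierarchical logistic regression of choices
#'
#' Fits the random-intercept logistic model of upward choice with fixed
#' effects for signed coherence (numeric), reward context (binary factor),
#' run (5-level factor, treatment contrasts), and the context-by-run and
#' coherence-by-run interactions; the intercept varies by participant. The
#' marginal likelihood integrates the random intercept by adaptive
#' Gauss-Hermite quadrature so that deviances of nested fits are directly
#' comparable.
#'
#' Reduced models drop one interaction block (4 df each under 5 runs),
#' enabling the likelihood-ratio tests of whether bias (context-by-run) or
#' discrimination (coherence-by-run) changed over the session.
#'
#' @param data trial table with columns `participant`, `run`, `context`,
#'   `coherence`, `choice`.
#' @param drop which interaction to remove: `"none"` (full model),
#'   `"context_by_run"`, or `"coherence_by_run"`.
#' @param nagq number of adaptive Gauss-Hermite quadrature nodes
#'   (default 15).
#' @return the fitted `glmerMod` object (from \pkg{lme4}).
#' @export
fit_hierarchical_logistic <- function(data,
                                      drop = c("none", "context_by_run",
                                               "coherence_by_run"),
                                      nagq = 15) {
  drop <- match.arg(drop)
  if (length(unique(data$participant)) < 2)
    stop("need at least 2 participants for a random intercept", call. = FALSE)
  d <- data.frame(
    choice_up = as.integer(data$choice == "up"),
    coherence = as.numeric(data$coherence),
    context = factor(data$context),
    run = factor(data$run),
    participant = factor(data$participant))
  terms <- c("coherence", "context", "run",
             if (drop != "context_by_run") "context:run",
             if (drop != "coherence_by_run") "coherence:run")
  f <- stats::reformulate(c(terms, "(1 | participant)"),
                          response = "choice_up")
  fit <- lme4::glmer(f, data = d, family = stats::binomial(), nAGQ = nagq,
                     control = lme4::glmerControl(calc.derivs = FALSE))
  if (any(abs(lme4::fixef(fit)) > 30))
    stop("complete or quasi-complete separation suspected: ",
         "fixed-effect estimates diverged", call. = FALSE)
  fit
}

#' Likelihood-ratio test between nested hierarchical logistic fits
#'
#' The statistic is the deviance difference `-2 (logLik reduced - logLik
#' full)`, referred to a chi-squared distribution with degrees of freedom
#' equal to the difference in parameter counts.
#'
#' @param full,reduced `glmerMod` fits of the full and a nested reduced
#'   model on the same data.
#' @return A list of class `lrt_result`: `chi_sq`, `df`, `p_value`, plus the
#'   two deviances.
#' @export
lrt_compare <- function(full, reduced) {
  ll_f <- logLik(full); ll_r <- logLik(reduced)
  df <- attr(ll_f, "df") - attr(ll_r, "df")
  if (df < 0)
    stop("`reduced` must be nested in `full` (fewer parameters)", call. = FALSE)
  if (stats::nobs(full) != stats::nobs(reduced))
    stop("models were fitted to different numbers of observations", call. = FALSE)
  fix_f <- colnames(stats::model.matrix(full))
  fix_r <- colnames(stats::model.matrix(reduced))
  if (!all(fix_r %in% fix_f))
    stop("`reduced` has fixed-effect terms absent from `full`; not nested",
         call. = FALSE)
  chi <- max(0, as.numeric(-2 * (ll_r - ll_f)))
  # a chi-squared with 0 df is a point mass at 0: identical models give p = 1
  p <- if (df == 0) 1 else pchisq(chi, df = df, lower.tail = FALSE)
  structure(list(chi_sq = chi, df = df, p_value = p,
                 deviance_full = as.numeric(-2 * ll_f),
                 deviance_reduced = as.numeric(-2 * ll_r)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("chi-squared(%d) = %.4g, p = %.4g\n", x$df, x$chi_sq, x$p_value))
  invisible(x)
}
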