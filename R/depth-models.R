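#' Fisher-style contingency test for class-by-depth tables
#'
#' For a 2 x 2 table, the exact two-sided hypergeometric (Fisher) p-value.
#' For larger tables, a Monte-Carlo estimate of the Fisher exact p: tables
#' are sampled with fixed margins (via [stats::r2dtable()]) and the p-value
#' is the fraction of tables at most as probable as the observed one, with
#' the (1 + k) / (1 + B) correction and a binomial Monte-Carlo standard
#' error.
#'
#' @param counts A matrix of non-negative integer counts.
#' @param n_mc Number of Monte-Carlo tables for r x c input (default 1e5).
#' @param seed Integer seed for the Monte-Carlo sampler.
#' @return A tibble with `p_value`, `method` (`"exact"` or `"monte-carlo"`),
#'   `n_mc` and `mc_se` (`NA` for exact).
#' @examples
#' contingency_test(matrix(c(5, 5, 5, 5), 2))
#' @export
contingency_test <- function(counts, n_mc = 1e5, seed = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)) || any(!is.finite(counts))) {
    abort("counts must be non-negative integers", class = "introshell_parameter_error")
  }
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    abort("need at least a 2 x 2 table after dropping empty rows/columns",
          class = "introshell_parameter_error")
  }
  if (nrow(counts) == 2 && ncol(counts) == 2) {
    p <- stats::fisher.test(counts)$p.value
    return(tibble(p_value = p, method = "exact", n_mc = NA_integer_, mc_se = NA_real_))
  }
  n_mc <- check_count(n_mc, "n_mc", min = 1)
  # under fixed margins, P(table) is proportional to 1 / prod(cells!), so
  # -sum(lfactorial(cells)) orders tables by probability
  score <- function(tab) -sum(lfactorial(tab))
  obs <- score(counts)
  with_seed(child_seed(seed, "fisher-mc"), {
    sims <- stats::r2dtable(n_mc, rowSums(counts), colSums(counts))
    k <- sum(vapply(sims, score, numeric(1)) <= obs + 1e-7)
  })
  p <- (1 + k) / (1 + n_mc)
  tibble(p_value = p, method = "monte-carlo", n_mc = n_mc,
         mc_se = sqrt(p * (1 - p) / n_mc))
}

new_grouped_fit <- function(fit, successes, totals, x, family) {
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(0.975)
  ll <- if (family == "binomial") as.numeric(stats::logLik(fit)) else NA_real_
  # dispersion by its definition, Pearson chi-squared over residual df
  phi <- if (family == "quasibinomial") {
    sum(stats::residuals(fit, type = "pearson")^2) / stats::df.residual(fit)
  } else NA_real_
  structure(list(
    fit = fit, family = family,
    coefficients = est, se = se,
    ci_low = est - z * se, ci_high = est + z * se,
    odds_factor = exp(est[["x"]]),
    odds_factor_ci = exp(est[["x"]] + c(-z, z) * se[["x"]]),
    dispersion = phi,
    loglik = ll,
    AIC = if (family == "binomial") stats::AIC(fit) else NA_real_,
    p_values = stats::coef(summary(fit))[, 4],
    fitted_odds = tibble(x = x, p = stats::fitted(fit),
                         odds = stats::fitted(fit) / (1 - stats::fitted(fit))),
    n = length(totals), n_total = sum(totals)
  ), class = "grouped_glm_fit")
}

check_grouped_args <- function(successes, totals, x) {
  if (length(successes) != length(totals) || length(x) != length(totals)) {
    abort("`successes`, `totals` and `x` must have equal length",
          class = "introshell_parameter_error")
  }
  if (any(successes < 0 | successes > totals)) {
    abort("need 0 <= successes <= totals", class = "introshell_parameter_error")
  }
  if (length(unique(x)) < 2) {
    abort("need at least 2 distinct covariate values",
          class = "introshell_parameter_error")
  }
}

#' Grouped binomial logistic regression
#'
#' Maximum-likelihood logit fit of grouped successes/totals on a single
#' covariate, reporting the slope as a multiplicative odds factor per unit of
#' the covariate with a Wald 95% CI. Used to model the odds of carrying MT
#' alleles as a function of cultivation depth.
#'
#' @param successes,totals Integer vectors of group successes and sizes.
#' @param x Covariate values (e.g. depth in metres), one per group.
#' @return An object of class `grouped_glm_fit`; see [tidy.grouped_glm_fit()].
#' @examples
#' fit_logistic_grouped(c(21, 22, 22, 11), c(116, 118, 118, 83), c(1, 3, 5, 7))
#' @export
fit_logistic_grouped <- function(successes, totals, x) {
  check_grouped_args(successes, totals, x)
  fit <- stats::glm(cbind(successes, totals - successes) ~ x, family = stats::binomial())
  if (!fit$converged || any(abs(stats::coef(fit)) > 50) ||
      any(stats::fitted(fit) > 1 - 1e-10) || any(stats::fitted(fit) < 1e-10)) {
    abort("logistic fit did not converge (complete or quasi-complete separation?)",
          class = "introshell_separation_error")
  }
  new_grouped_fit(fit, successes, totals, x, "binomial")
}

#' Grouped quasibinomial regression
#'
#' Same mean model (and hence identical point estimates) as
#' [fit_logistic_grouped()], but with the dispersion parameter phi estimated
#' as Pearson chi-squared / residual df and standard errors scaled by
#' sqrt(phi) — the usual treatment of over- or under-dispersed proportions.
#'
#' @inheritParams fit_logistic_grouped
#' @return An object of class `grouped_glm_fit` with a `dispersion` element.
#' @export
fit_quasibinomial_grouped <- function(successes, totals, x) {
  check_grouped_args(successes, totals, x)
  if (length(totals) - 2 <= 0) {
    abort("no residual degrees of freedom for the dispersion estimate",
          class = "introshell_parameter_error")
  }
  fit <- stats::glm(cbind(successes, totals - successes) ~ x,
                    family = stats::quasibinomial())
  new_grouped_fit(fit, successes, totals, x, "quasibinomial")
}

#' @export
print.grouped_glm_fit <- function(x, ...) {
  cat(sprintf("<grouped_glm_fit: %s> n = %d groups (%d individuals)\n",
              x$family, x$n, x$n_total))
  cat(sprintf("  odds factor per unit x: %.3f (95%% CI %.3f, %.3f)\n",
              x$odds_factor, x$odds_factor_ci[1], x$odds_factor_ci[2]))
  if (x$family == "quasibinomial") {
    cat(sprintf("  dispersion phi = %.4g\n", x$dispersion))
  }
  invisible(x)
}

#' Tidy a grouped GLM fit
#'
#' @param x A `grouped_glm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `estimate`, `std_error`,
#'   `ci_low`, `ci_high`, `odds_factor`, `p_value`.
#' @method tidy grouped_glm_fit
#' @export
tidy.grouped_glm_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std_error = unname(x$se),
         ci_low = unname(x$ci_low),
         ci_high = unname(x$ci_high),
         odds_factor = exp(unname(x$coefficients)),
         p_value = unname(x$p_values))
}

#' @method glance grouped_glm_fit
#' @export
glance.grouped_glm_fit <- function(x, ...) {
  tibble(family = x$family, n_groups = x$n, n_total = x$n_total,
         odds_factor = x$odds_factor,
         odds_ci_low = x$odds_factor_ci[1], odds_ci_high = x$odds_factor_ci[2],
         dispersion = x$dispersion, loglik = x$loglik, AIC = x$AIC)
}
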