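#' Normalize puncture force by shell length
#'
#' Shell strength normalized for shell length, in kg per cm of SL:
#' `force / (SL / 10)`.
#'
#' @param force_kg Puncture force (kg), >= 0.
#' @param SL_mm Shell length (mm), > 0.
#' @return Normalized strength (kg cm^-1 SL); vectorized.
#' @examples
#' normalize_strength(10, 50)  # 2.0
#' @export
normalize_strength <- function(force_kg, SL_mm) {
  if (any(!is.finite(SL_mm)) || any(SL_mm <= 0)) {
    abort("`SL_mm` must be positive", class = "introshell_parameter_error")
  }
  if (any(force_kg < 0)) {
    abort("`force_kg` must be >= 0", class = "introshell_parameter_error")
  }
  force_kg / (SL_mm / 10)
}

#' Fit and compare linear models by AIC
#'
#' Ordinary least squares for each candidate formula, ranked by Gaussian AIC
#' (the variance counts as a parameter, as in [stats::AIC()]). The best-AIC
#' model is returned together with the full comparison table and simple
#' residual diagnostics (Shapiro-Wilk normality p and a Breusch-Pagan-style
#' homoscedasticity p from regressing squared residuals on fitted values).
#'
#' @param data A data frame holding response and predictors.
#' @param candidate_models A list of model formulas; the first response on
#'   the left-hand side is the common response.
#' @return An object of class `linear_selection`: `best` (an `lm`),
#'   `aic_table` (tibble: formula, df, AIC, delta_AIC, r_squared),
#'   `diagnostics`, `fits` (all `lm` objects).
#' @examples
#' d <- data.frame(y = 1:10 * 2 + 3, x = 1:10)
#' fit_linear(d, list(y ~ x, y ~ 1))
#' @export
fit_linear <- function(data, candidate_models) {
  if (!length(candidate_models)) {
    abort("need at least one candidate model", class = "introshell_parameter_error")
  }
  if (inherits(candidate_models, "formula")) candidate_models <- list(candidate_models)
  fits <- purrr::map(candidate_models, function(f) {
    fit <- stats::lm(f, data = data)
    if (any(is.na(stats::coef(fit)))) {
      abort(sprintf("rank-deficient design in `%s`: collinear column(s) %s",
                    deparse(f),
                    paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                          collapse = ", ")),
            class = "introshell_collinearity_error")
    }
    if (stats::nobs(fit) < length(stats::coef(fit)) + 2) {
      abort("too few observations for the candidate model",
            class = "introshell_parameter_error")
    }
    fit
  })
  aic <- vapply(fits, stats::AIC, numeric(1))
  tab <- tibble(
    formula = vapply(candidate_models, function(f) paste(deparse(f), collapse = ""),
                     character(1)),
    df = vapply(fits, function(f) length(stats::coef(f)) + 1, numeric(1)),
    AIC = aic,
    delta_AIC = aic - min(aic),
    r_squared = vapply(fits, function(f) suppressWarnings(summary(f)$r.squared),
                       numeric(1))
  )
  best_i <- which.min(aic)
  best <- fits[[best_i]]
  res <- stats::residuals(best)
  shapiro_p <- if (length(res) >= 3 && length(res) <= 5000 && stats::sd(res) > 0) {
    stats::shapiro.test(res)$p.value
  } else NA_real_
  bp <- if (stats::sd(res) > 0) {
    aux <- stats::lm(I(res^2) ~ stats::fitted(best))
    f <- suppressWarnings(summary(aux)$fstatistic)
    if (is.null(f)) NA_real_ else stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
  } else NA_real_
  structure(list(best = best, best_index = best_i, aic_table = tab,
                 diagnostics = tibble(shapiro_p = shapiro_p,
                                      homoscedasticity_p = unname(bp)),
                 fits = fits),
            class = "linear_selection")
}

#' @export
print.linear_selection <- function(x, ...) {
  cat("<linear_selection> best model:",
      x$aic_table$formula[x$best_index], "\n")
  print(x$aic_table)
  invisible(x)
}

#' Tidy the best model of an AIC selection
#'
#' @param x A `linear_selection`.
#' @param ... Unused.
#' @return Coefficient tibble (`term`, `estimate`, `std_error`, `ci_low`,
#'   `ci_high`, `p_value`) of the best-AIC model.
#' @method tidy linear_selection
#' @export
tidy.linear_selection <- function(x, ...) {
  s <- stats::coef(summary(x$best))
  ci <- stats::confint(x$best)
  tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
         ci_low = ci[, 1], ci_high = ci[, 2], p_value = s[, 4])
}

#' @method glance linear_selection
#' @export
glance.linear_selection <- function(x, ...) {
  tibble(formula = x$aic_table$formula[x$best_index],
         AIC = x$aic_table$AIC[x$best_index],
         r_squared = x$aic_table$r_squared[x$best_index],
         sigma = summary(x$best)$sigma,
         n = stats::nobs(x$best),
         shapiro_p = x$diagnostics$shapiro_p,
         homoscedasticity_p = x$diagnostics$homoscedasticity_p)
}

#' Collinearity screen for shell-trait predictors
#'
#' Pairwise correlations among candidate predictors, principal-component
#' variance shares, and drop recommendations for pairs whose |r| exceeds the
#' threshold. Constant columns are excluded from the correlations with a
#' warning.
#'
#' @param predictors A data frame of numeric predictors (>= 2 columns,
#'   >= 3 rows).
#' @param threshold Absolute correlation above which a pair is flagged
#'   (default 0.8).
#' @return A list of class `collinearity_report`: `pairs` (tibble `var1`,
#'   `var2`, `r`, `flagged`), `pc_variance` (tibble of PC variance shares),
#'   `drop_recommendation` (character), `constant` (excluded columns).
#' @export
collinearity_screen <- function(predictors, threshold = 0.8) {
  predictors <- as_tibble(predictors)
  if (ncol(predictors) < 2 || nrow(predictors) < 3) {
    abort("need >= 2 predictors and >= 3 observations",
          class = "introshell_parameter_error")
  }
  check_fraction(threshold, "threshold", 0, 1, open_lo = TRUE)
  sds <- vapply(predictors, stats::sd, numeric(1))
  constant <- names(predictors)[sds == 0 | !is.finite(sds)]
  if (length(constant)) {
    warn(sprintf("constant column(s) excluded from correlations: %s",
                 paste(constant, collapse = ", ")))
  }
  keep <- setdiff(names(predictors), constant)
  cm <- stats::cor(predictors[, keep, drop = FALSE])
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- tibble(var1 = keep[idx[, 1]], var2 = keep[idx[, 2]],
                  r = cm[idx], flagged = abs(cm[idx]) > threshold)
  pc <- stats::prcomp(predictors[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  shares <- pc$sdev^2 / sum(pc$sdev^2)
  drop <- if (any(pairs$flagged)) {
    # drop the member of each flagged pair involved in most flagged pairs
    flagged_vars <- c(pairs$var1[pairs$flagged], pairs$var2[pairs$flagged])
    names(sort(table(flagged_vars), decreasing = TRUE))[1]
  } else character(0)
  structure(list(pairs = pairs,
                 pc_variance = tibble(pc = paste0("PC", seq_along(shares)),
                                      variance_share = shares),
                 drop_recommendation = drop,
                 constant = constant,
                 threshold = threshold),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat(sprintf("<collinearity_report> threshold |r| > %g\n", x$threshold))
  print(x$pairs)
  if (length(x$drop_recommendation)) {
    cat("suggest dropping:", paste(x$drop_recommendation, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Practical weak-shell flag
#'
#' Flags shells that are both weak and elongated: normalized strength
#' strictly below 2 kg cm^-1 SL and SL:SH ratio strictly above 2 — the
#' combination characteristic of heavily MT-introgressed mussels.
#'
#' @param strength_norm Normalized shell strength (kg cm^-1 SL).
#' @param SL_mm,SH_mm Shell length and height (mm), > 0.
#' @param strength_max,ratio_min Thresholds (defaults 2 and 2).
#' @return Logical vector.
#' @examples
#' weak_shell_flag(1.8, 66, 30)  # TRUE (ratio 2.2)
#' weak_shell_flag(2.0, 66, 30)  # FALSE: comparisons are strict
#' @export
weak_shell_flag <- function(strength_norm, SL_mm, SH_mm,
                            strength_max = 2, ratio_min = 2) {
  if (any(!is.finite(SH_mm)) || any(SH_mm <= 0)) {
    abort("`SH_mm` must be positive", class = "introshell_parameter_error")
  }
  if (any(SL_mm <= 0) || any(strength_norm < 0)) {
    abort("inputs must be positive", class = "introshell_parameter_error")
  }
  strength_norm < strength_max & SL_mm / SH_mm > ratio_min
}
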