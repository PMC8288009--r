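#' Principal component analysis of EFA coefficients
#'
#' Centred (unscaled) PCA of a normalized coefficient table. Columns that are
#' constant by construction after first-harmonic normalization (`a1`, `b1`,
#' `c1`) carry no shape information and are dropped automatically, as is any
#' other zero-variance column. The number of retained components is the
#' smallest set whose cumulative variance share exceeds `threshold`.
#'
#' @param coefs A tibble from [efa_coef_table()] (`individual_id` plus
#'   numeric coefficient columns), or a bare numeric matrix/data frame.
#' @param threshold Cumulative variance share for retention (default 0.95).
#' @return An object of class `shape_pca`: `scores` (tibble with
#'   `individual_id` and `PC*` columns), `loadings`, `variance_share`,
#'   `n_retained`, `prcomp`.
#' @export
shape_pca <- function(coefs, threshold = 0.95) {
  coefs <- as_tibble(coefs)
  ids <- if ("individual_id" %in% names(coefs)) coefs$individual_id else
    sprintf("ind%04d", seq_len(nrow(coefs)))
  m <- as.matrix(coefs[, setdiff(names(coefs), "individual_id"), drop = FALSE])
  if (nrow(m) < 3) {
    abort("need at least 3 individuals for a shape PCA",
          class = "introshell_parameter_error")
  }
  check_fraction(threshold, "threshold", 0, 1, open_lo = TRUE, open_hi = TRUE)
  keep <- apply(m, 2, stats::sd) > 1e-12
  m <- m[, keep, drop = FALSE]
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  shares <- pc$sdev^2 / sum(pc$sdev^2)
  n_retained <- which(cumsum(shares) > threshold)[1]
  scores <- as_tibble(pc$x)
  scores <- dplyr::bind_cols(tibble(individual_id = ids), scores)
  structure(list(scores = scores, loadings = pc$rotation,
                 variance_share = shares, n_retained = n_retained,
                 threshold = threshold, prcomp = pc),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("<shape_pca> %d individuals, %d PCs retained (> %g%% variance)\n",
              nrow(x$scores), x$n_retained, 100 * x$threshold))
  cat("variance shares:", paste(sprintf("%.1f%%", 100 * utils::head(x$variance_share, 5)),
                                collapse = " "), "...\n")
  invisible(x)
}

#' @method glance shape_pca
#' @export
glance.shape_pca <- function(x, ...) {
  tibble(n = nrow(x$scores), n_retained = x$n_retained,
         pc1_share = x$variance_share[1],
         pc2_share = if (length(x$variance_share) > 1) x$variance_share[2] else NA_real_,
         cum_share_retained = sum(x$variance_share[seq_len(x$n_retained)]))
}

retained_scores <- function(pca) {
  as.matrix(pca$scores[, paste0("PC", seq_len(pca$n_retained)), drop = FALSE])
}

#' MANOVA on shape variables (Wilks' lambda)
#'
#' One-term multivariate analysis of variance of the retained PC scores on a
#' grouping factor or a continuous covariate, reported as Wilks' lambda with
#' Rao's F approximation. Lambda is 1 when group means are identical and
#' approaches 0 with separation.
#'
#' @param scores A `shape_pca` object, or a numeric matrix/data frame of
#'   response variables.
#' @param group A factor/character vector (grouping) or numeric vector
#'   (continuous covariate), one value per individual.
#' @return A one-row tibble: `term`, `wilks_lambda`, `approx_f`, `df1`,
#'   `df2`, `p_value`, `n`.
#' @export
manova_wilks <- function(scores, group) {
  y <- if (inherits(scores, "shape_pca")) retained_scores(scores) else as.matrix(scores)
  if (nrow(y) != length(group)) {
    abort("`group` must have one value per individual",
          class = "introshell_parameter_error")
  }
  x <- if (is.numeric(group)) group else factor(group)
  if (!is.numeric(x) && nlevels(x) < 2) {
    abort("need at least 2 groups", class = "introshell_parameter_error")
  }
  fit <- stats::lm(y ~ x)
  if (ncol(y) == 1) {
    # a single response: Wilks reduces to RSS_full / RSS_null, and the exact
    # F of the one-way ANOVA / simple regression is the "approximation"
    a <- stats::anova(fit)
    ss_x <- a["x", "Sum Sq"]
    ss_res <- a["Residuals", "Sum Sq"]
    return(tibble(term = "x",
                  wilks_lambda = ss_res / (ss_res + ss_x),
                  approx_f = a["x", "F value"],
                  df1 = a["x", "Df"], df2 = a["Residuals", "Df"],
                  p_value = a["x", "Pr(>F)"],
                  n = nrow(y)))
  }
  res <- tryCatch(
    stats::anova(fit, test = "Wilks"),
    error = function(e) {
      abort(paste0("MANOVA failed (singular within-group matrix? ",
                   "try fewer PCs): ", conditionMessage(e)),
            class = "introshell_manova_error")
    }
  )
  row <- res["x", ]
  tibble(term = "x",
         wilks_lambda = row$Wilks,
         approx_f = row$`approx F`,
         df1 = row$`num Df`, df2 = row$`den Df`,
         p_value = row$`Pr(>F)`,
         n = nrow(y))
}

#' @rdname manova_wilks
#' @param groups Grouping vector for the pairwise mode.
#' @param bonferroni Add a Bonferroni-adjusted p column (the raw pairwise
#'   statistics are reported either way).
#' @return For `pairwise_manova()`: a tibble with one row per group pair.
#' @export
pairwise_manova <- function(scores, groups, bonferroni = TRUE) {
  y <- if (inherits(scores, "shape_pca")) retained_scores(scores) else as.matrix(scores)
  g <- factor(groups)
  if (nlevels(g) < 2) {
    abort("need at least 2 groups", class = "introshell_parameter_error")
  }
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    sel <- g %in% pr
    r <- manova_wilks(y[sel, , drop = FALSE], droplevels(g[sel]))
    dplyr::bind_cols(tibble(group1 = pr[1], group2 = pr[2]),
                     r[, setdiff(names(r), "term")])
  })
  if (bonferroni) out$p_bonferroni <- pmin(out$p_value * nrow(out), 1)
  out
}

#' Group mean shapes from normalized EFA coefficients
#'
#' Arithmetic mean of the normalized coefficients per group, reconstructed at
#' `n_points`.
#'
#' @param coefs Coefficient table from [efa_coef_table()].
#' @param groups Group label per individual.
#' @param n_points Points per reconstructed outline.
#' @return A tibble with `group`, `x`, `y` (stacked mean outlines).
#' @export
mean_shape <- function(coefs, groups, n_points = 300) {
  coefs <- as_tibble(coefs)
  m <- as.matrix(coefs[, setdiff(names(coefs), "individual_id"), drop = FALSE])
  if (nrow(m) != length(groups)) {
    abort("`groups` must have one label per individual",
          class = "introshell_parameter_error")
  }
  g <- factor(groups)
  if (any(table(g) == 0)) {
    abort("empty group", class = "introshell_parameter_error")
  }
  n_h <- ncol(m) / 4
  purrr::map_dfr(levels(g), function(lev) {
    mu <- colMeans(m[g == lev, , drop = FALSE])
    e <- structure(list(an = mu[seq(1, length(mu), 4)],
                        bn = mu[seq(2, length(mu), 4)],
                        cn = mu[seq(3, length(mu), 4)],
                        dn = mu[seq(4, length(mu), 4)],
                        A0 = 0, C0 = 0, n_harmonics = n_h,
                        normalized = TRUE, scale = 1),
                   class = "efa")
    rec <- efa_reconstruct(e, n_points = n_points)
    dplyr::bind_cols(tibble(group = lev), rec)
  })
}
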