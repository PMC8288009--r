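#' Shell-trait generative parameters
#'
#' Parameters of the generative model for length-normalized shell strength and
#' shell dimensions. Normalized strength (kg per cm of shell length, SL) is
#' linear in depth and MT allele frequency with Gaussian residuals:
#' `strength = baseline + depth_slope * (depth - 1) + mt_effect * MT_AF + N(0, residual_sd)`.
#' The length:height ratio (SL:SH, elongation) increases with MT ancestry and
#' decreases with depth:
#' `SL:SH = elong_base + elong_mt * MT_AF + elong_depth * (depth - 1) + N(0, elong_sd)`.
#'
#' Defaults place the baseline at 2.03 kg cm^-1 SL at 1 m with a depth slope of
#' 0.135 kg cm^-1 SL per metre, an MT effect of -1.37 kg cm^-1 SL per unit
#' MT_AF and residual sd 0.65, so heavily introgressed shallow-grown mussels
#' fall below the 2 kg cm^-1 SL practical threshold while their SL:SH ratio
#' exceeds 2.
#'
#' @param baseline_strength_at_1m kg cm^-1 SL at 1 m depth and MT_AF = 0.
#' @param depth_slope kg cm^-1 SL per metre of depth.
#' @param mt_effect kg cm^-1 SL per unit MT allele frequency.
#' @param residual_sd Residual sd of normalized strength (> 0, or 0 for a
#'   noiseless generator).
#' @param length_mean,length_sd Shell length distribution (mm).
#' @param elong_base,elong_mt,elong_depth,elong_sd SL:SH ratio model.
#' @return A list of class `shell_trait_params`.
#' @export
shell_trait_params <- function(baseline_strength_at_1m = 2.03,
                               depth_slope = 0.135,
                               mt_effect = -1.37,
                               residual_sd = 0.65,
                               length_mean = 60, length_sd = 8,
                               elong_base = 1.50, elong_mt = 0.75,
                               elong_depth = -0.02, elong_sd = 0.07) {
  p <- list(baseline_strength_at_1m = baseline_strength_at_1m,
            depth_slope = depth_slope, mt_effect = mt_effect,
            residual_sd = residual_sd,
            length_mean = length_mean, length_sd = length_sd,
            elong_base = elong_base, elong_mt = elong_mt,
            elong_depth = elong_depth, elong_sd = elong_sd)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), TRUE))) {
    abort("all shell-trait parameters must be single finite numbers",
          class = "introshell_parameter_error")
  }
  if (p$residual_sd < 0 || p$elong_sd < 0 || p$length_sd < 0) {
    abort("standard deviations must be >= 0", class = "introshell_parameter_error")
  }
  structure(p, class = "shell_trait_params")
}

#' Simulate shell phenotypes for a cohort
#'
#' Generates shell length/height, wet weights, normalized shell strength and
#' the raw puncture force for every individual, from its depth and realised
#' MT allele frequency (computed from the genotype matrix). Raw force is
#' back-computed as `strength * SL(cm)` so that [normalize_strength()]
#' recovers the generated value.
#'
#' @param cohort A `mussel_cohort`.
#' @param params A [shell_trait_params()] list.
#' @param seed Integer seed.
#' @return A tibble with `individual_id`, `depth_m`, `mt_af`, `SL_mm`,
#'   `SH_mm`, `TWW_g`, `WWS_g`, `force_kg`, `strength_norm`.
#' @export
simulate_shell_traits <- function(cohort, params = shell_trait_params(), seed = 1) {
  if (!inherits(params, "shell_trait_params")) params <- do.call(shell_trait_params, params)
  prof <- introgression_profile(cohort$genotypes)
  d <- dplyr::left_join(cohort$meta[, c("individual_id", "depth_m")],
                        prof[, c("individual_id", "MT_AF")], by = "individual_id")
  n <- nrow(d)
  with_seed(child_seed(seed, "shell"), {
    SL <- pmax(stats::rnorm(n, params$length_mean, params$length_sd), 15)
    ratio <- pmax(params$elong_base + params$elong_mt * d$MT_AF +
                    params$elong_depth * (d$depth_m - 1) +
                    stats::rnorm(n, 0, params$elong_sd), 0.5)
    strength <- params$baseline_strength_at_1m +
      params$depth_slope * (d$depth_m - 1) +
      params$mt_effect * d$MT_AF +
      stats::rnorm(n, 0, params$residual_sd)
    strength <- pmax(strength, 0.05)
    # shell and total wet weight: simple allometry with lognormal scatter
    WWS <- 0.0004 * SL^2.6 * exp(stats::rnorm(n, 0, 0.1))
    TWW <- 2.4 * WWS * exp(stats::rnorm(n, 0, 0.08))
    tibble(
      individual_id = d$individual_id,
      depth_m = d$depth_m,
      mt_af = d$MT_AF,
      SL_mm = SL,
      SH_mm = SL / ratio,
      TWW_g = TWW,
      WWS_g = WWS,
      strength_norm = strength,
      force_kg = strength * SL / 10
    )
  })
}

#' Simulate a mussel-like closed valve outline
#'
#' A fixed mussel-like polar template is perturbed by smooth random harmonics
#' of relative amplitude `noise_sd`, then anisotropically scaled so the
#' bounding-box length:height ratio equals `elongation` exactly.
#'
#' @param elongation Target bounding-box length:height ratio (> 0).
#' @param n_points Number of outline points (>= 32).
#' @param noise_sd Relative amplitude of smooth radial noise (0 = none).
#' @param seed Integer seed.
#' @return A tibble with columns `x`, `y` (closed outline, first point not
#'   repeated, counterclockwise).
#' @export
simulate_outline <- function(elongation, n_points = 300, noise_sd = 0, seed = 1) {
  if (!is.numeric(elongation) || length(elongation) != 1 || !(elongation > 0)) {
    abort("`elongation` must be a single positive number",
          class = "introshell_parameter_error")
  }
  n_points <- check_count(n_points, "n_points", min = 1)
  if (n_points < 32) {
    abort("`n_points` must be >= 32", class = "introshell_parameter_error")
  }
  check_fraction(noise_sd, "noise_sd", 0, 1)
  th <- 2 * pi * (seq_len(n_points) - 1) / n_points
  r <- 1 + 0.18 * cos(th) + 0.06 * cos(2 * th) - 0.04 * sin(th)
  if (noise_sd > 0) {
    with_seed(child_seed(seed, "outline"), {
      g <- rep(0, n_points)
      for (k in 3:8) {
        g <- g + stats::rnorm(1, 0, 1 / k) * cos(k * th) +
          stats::rnorm(1, 0, 1 / k) * sin(k * th)
      }
      r <- r * (1 + noise_sd * g / stats::sd(g))
    })
  }
  x <- r * cos(th)
  y <- r * sin(th)
  # anisotropic scaling to the requested bounding box (height 1)
  x <- (x - min(x)) / (max(x) - min(x)) * elongation
  y <- (y - min(y)) / (max(y) - min(y))
  tibble(x = x - mean(x), y = y - mean(y))
}

#' Rasterize a closed outline to a binary mask
#'
#' Even-odd scanline fill over pixel centers; pixel (0, 0) is the centre of
#' the lower-left pixel and the y axis points up (row 1 of the returned matrix
#' is the bottom row).
#'
#' @param outline Tibble/data frame with `x`, `y`.
#' @param px_per_unit Pixels per coordinate unit.
#' @param pad Margin in pixels around the shape.
#' @return An integer matrix (rows = y, bottom first; columns = x) of 0/1.
#' @export
rasterize_outline <- function(outline, px_per_unit = 100, pad = 3) {
  x <- outline$x * px_per_unit
  y <- outline$y * px_per_unit
  x <- x - min(x) + pad
  y <- y - min(y) + pad
  w <- ceiling(max(x)) + pad
  h <- ceiling(max(y)) + pad
  img <- matrix(0L, nrow = h, ncol = w)
  n <- length(x)
  xj <- c(x, x[1]); yj <- c(y, y[1])
  for (row in seq_len(h)) {
    yc <- row - 1  # pixel-center y
    crossings <- numeric(0)
    for (i in seq_len(n)) {
      y1 <- yj[i]; y2 <- yj[i + 1]
      if ((y1 <= yc && y2 > yc) || (y2 <= yc && y1 > yc)) {
        t <- (yc - y1) / (y2 - y1)
        crossings <- c(crossings, xj[i] + t * (xj[i + 1] - xj[i]))
      }
    }
    crossings <- sort(crossings)
    if (length(crossings) >= 2) {
      for (k in seq(1, length(crossings) - 1, by = 2)) {
        cols <- which(seq_len(w) - 1 >= crossings[k] & seq_len(w) - 1 <= crossings[k + 1])
        img[row, cols] <- 1L
      }
    }
  }
  img
}

#' Simulate per-depth salinity series
#'
#' Gaussian fluctuations around a per-depth mean, truncated at zero. In a
#' stratified water column the shallow depths are configured with the lower
#' mean and larger variance.
#'
#' @param depths Vector of depths (m).
#' @param mean_by_depth,var_by_depth Numeric vectors matching `depths`.
#' @param n_steps Number of time steps per depth (>= 1).
#' @param seed Integer seed.
#' @return A tibble `depth_m`, `t`, `S`.
#' @export
simulate_salinity <- function(depths, mean_by_depth, var_by_depth, n_steps = 1000, seed = 1) {
  if (length(mean_by_depth) != length(depths) || length(var_by_depth) != length(depths)) {
    abort("`mean_by_depth` and `var_by_depth` must match `depths` in length",
          class = "introshell_parameter_error")
  }
  if (any(var_by_depth < 0)) {
    abort("variances must be >= 0", class = "introshell_parameter_error")
  }
  n_steps <- check_count(n_steps, "n_steps", min = 1)
  with_seed(child_seed(seed, "salinity"), {
    purrr::pmap_dfr(list(depths, mean_by_depth, var_by_depth), function(d, m, v) {
      tibble(depth_m = d, t = seq_len(n_steps),
             S = pmax(stats::rnorm(n_steps, m, sqrt(v)), 0))
    })
  })
}

#' Write a cohort to CSV files
#'
#' Writes `genotypes.csv` (rows = individuals, columns = loci, dosages in
#' {0, 0.5, 1, NA}), `metadata.csv` and, when given, `shell.csv` and
#' `salinity.csv` into `dir`.
#'
#' @param cohort A `mussel_cohort`.
#' @param dir Output directory (created if absent).
#' @param shell,salinity Optional tibbles from [simulate_shell_traits()] /
#'   [simulate_salinity()].
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, shell = NULL, salinity = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genotypes = file.path(dir, "genotypes.csv"),
             metadata = file.path(dir, "metadata.csv"))
  readr::write_csv(cohort$genotypes, paths[["genotypes"]])
  meta <- cohort$meta
  if (!is.null(shell)) {
    meta <- dplyr::left_join(meta, shell[, setdiff(names(shell), c("depth_m", "mt_af"))],
                             by = "individual_id")
  }
  readr::write_csv(meta, paths[["metadata"]])
  if (!is.null(salinity)) {
    paths[["salinity"]] <- file.path(dir, "salinity.csv")
    readr::write_csv(salinity, paths[["salinity"]])
  }
  invisible(paths)
}
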