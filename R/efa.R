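#' Elliptic Fourier decomposition of a closed outline
#'
#' Kuhl–Giardina elliptic Fourier analysis: the outline's x(t) and y(t) are
#' expanded over the closed contour as truncated Fourier series with
#' per-harmonic coefficients (a_n, b_n, c_n, d_n) and offsets (A0, C0). The
#' contour parameter t is either the cumulative chord length (`"chord"`, the
#' classic chain-code formulation appropriate for raw pixel traces) or the
#' sample index (`"uniform"`, appropriate for points sampled uniformly in an
#' underlying curve parameter; under it an exact ellipse is exactly
#' harmonic 1). The two coincide for outlines resampled to uniform arc
#' length, as [preprocess_outline()] produces.
#'
#' @param outline Tibble/data frame with `x`, `y` (closed; first point not
#'   repeated).
#' @param n_harmonics Number of harmonics, `1 <= n_harmonics <= n_points / 2`.
#' @param parametrization `"chord"` (default) or `"uniform"`.
#' @return An object of class `efa`: list with `an`, `bn`, `cn`, `dn`
#'   (length `n_harmonics`), `A0`, `C0`, `n_harmonics`, `normalized = FALSE`.
#' @export
efa_decompose <- function(outline, n_harmonics = 20,
                          parametrization = c("chord", "uniform")) {
  parametrization <- match.arg(parametrization)
  x <- outline$x
  y <- outline$y
  K <- length(x)
  n_harmonics <- check_count(n_harmonics, "n_harmonics", min = 1)
  if (n_harmonics > K / 2) {
    abort("`n_harmonics` must be <= n_points / 2", class = "introshell_parameter_error")
  }
  xc <- c(x, x[1])
  yc <- c(y, y[1])
  dx <- diff(xc)
  dy <- diff(yc)
  dt <- switch(parametrization,
               chord = sqrt(dx^2 + dy^2),
               uniform = rep(1, K))
  # trapezoid means of x(t), y(t): the series offsets
  Tfull <- sum(dt)
  A0 <- sum((xc[-1] + xc[-(K + 1)]) / 2 * dt) / Tfull
  C0 <- sum((yc[-1] + yc[-(K + 1)]) / 2 * dt) / Tfull
  if (any(dt == 0)) {
    keep <- dt > 0
    dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  }
  t1 <- cumsum(dt)
  T <- t1[length(t1)]
  t0 <- c(0, t1[-length(t1)])

  an <- bn <- cn <- dn <- numeric(n_harmonics)
  for (n in seq_len(n_harmonics)) {
    w <- 2 * pi * n / T
    const <- T / (2 * n^2 * pi^2)
    cos1 <- cos(w * t1); cos0 <- cos(w * t0)
    sin1 <- sin(w * t1); sin0 <- sin(w * t0)
    an[n] <- const * sum(dx / dt * (cos1 - cos0))
    bn[n] <- const * sum(dx / dt * (sin1 - sin0))
    cn[n] <- const * sum(dy / dt * (cos1 - cos0))
    dn[n] <- const * sum(dy / dt * (sin1 - sin0))
  }
  structure(list(an = an, bn = bn, cn = cn, dn = dn, A0 = A0, C0 = C0,
                 n_harmonics = n_harmonics, normalized = FALSE, scale = NA_real_),
            class = "efa")
}

#' @export
print.efa <- function(x, ...) {
  cat(sprintf("<efa> %d harmonics%s\n", x$n_harmonics,
              if (isTRUE(x$normalized)) " (normalized)" else ""))
  invisible(x)
}

# rotate harmonic matrices: starting-point phase shift theta (right rotation
# by angle n * theta per harmonic) and spatial rotation of the plane by psi
# (left rotation); A_n'' = R(psi) A_n R(n theta)
rotate_efa <- function(e, theta = 0, psi = 0) {
  Rm <- function(a) matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, byrow = TRUE)
  for (n in seq_len(e$n_harmonics)) {
    A <- matrix(c(e$an[n], e$bn[n], e$cn[n], e$dn[n]), 2, byrow = TRUE)
    A <- Rm(psi) %*% A %*% Rm(n * theta)
    e$an[n] <- A[1, 1]; e$bn[n] <- A[1, 2]; e$cn[n] <- A[2, 1]; e$dn[n] <- A[2, 2]
  }
  e
}

#' Normalize elliptic Fourier coefficients
#'
#' Standard first-harmonic normalization: the starting point is rotated to
#' the first-harmonic semi-major axis, the outline is rotated so that axis
#' lies along x, and all coefficients are divided by the semi-major axis
#' length. After normalization `a1 = 1 > 0` and `b1 = c1 = 0`, and the
#' coefficients are invariant to rotation, translation, isotropic scaling and
#' starting point of the input outline. The residual two-fold ambiguity
#' (which end of the major axis the parameter starts from) is resolved
#' deterministically by the sign of the first non-negligible even-harmonic
#' coefficient.
#'
#' @param coeffs An `efa` object from [efa_decompose()].
#' @return A normalized `efa` object (offsets dropped to 0; `scale` holds
#'   the semi-major axis length).
#' @export
efa_normalize <- function(coeffs) {
  e <- coeffs
  a1 <- e$an[1]; b1 <- e$bn[1]; c1 <- e$cn[1]; d1 <- e$dn[1]
  if (a1^2 + b1^2 + c1^2 + d1^2 < 1e-20) {
    abort("degenerate first harmonic", class = "introshell_parameter_error")
  }
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)
  # semi-axis magnitudes at theta and theta + pi/2; pick the major axis
  mag <- function(th) {
    (a1 * cos(th) + b1 * sin(th))^2 + (c1 * cos(th) + d1 * sin(th))^2
  }
  if (mag(theta + pi / 2) > mag(theta)) theta <- theta + pi / 2

  cand <- purrr::map(c(0, pi), function(extra) {
    th <- theta + extra
    a1s <- a1 * cos(th) + b1 * sin(th)
    c1s <- c1 * cos(th) + d1 * sin(th)
    psi <- atan2(c1s, a1s)
    E <- sqrt(a1s^2 + c1s^2)
    out <- rotate_efa(e, theta = th, psi = -psi)
    out$an <- out$an / E; out$bn <- out$bn / E
    out$cn <- out$cn / E; out$dn <- out$dn / E
    out$scale <- E
    out
  })
  # the two candidates differ by a sign flip of all even harmonics; pick the
  # one whose first non-negligible even-harmonic coefficient is positive
  pick <- cand[[1]]
  even <- seq(2, pick$n_harmonics, by = 2)
  if (length(even)) {
    v <- as.vector(rbind(pick$an[even], pick$bn[even], pick$cn[even], pick$dn[even]))
    i <- which(abs(v) > 1e-7)
    if (length(i) && v[i[1]] < 0) pick <- cand[[2]]
  }
  pick$A0 <- 0; pick$C0 <- 0
  pick$normalized <- TRUE
  pick
}

#' Per-harmonic power and harmonic truncation rule
#'
#' Harmonic power is `(a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2`;
#' `choose_harmonics()` returns the smallest number of leading harmonics
#' whose cumulative share of total power exceeds `threshold`.
#'
#' @param coeffs An `efa` object.
#' @return For `harmonic_power()`: a tibble `harmonic`, `power`, `share`,
#'   `cumulative_share`.
#' @export
harmonic_power <- function(coeffs) {
  p <- (coeffs$an^2 + coeffs$bn^2 + coeffs$cn^2 + coeffs$dn^2) / 2
  tibble(harmonic = seq_along(p), power = p, share = p / sum(p),
         cumulative_share = cumsum(p) / sum(p))
}

#' @rdname harmonic_power
#' @param shares Either an `efa` object or the tibble from [harmonic_power()].
#' @param threshold Cumulative-power threshold in (0, 1); default 0.95.
#' @return For `choose_harmonics()`: the chosen harmonic count.
#' @export
choose_harmonics <- function(shares, threshold = 0.95) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      !(threshold > 0 && threshold < 1)) {
    abort("`threshold` must lie in (0, 1)", class = "introshell_parameter_error")
  }
  if (inherits(shares, "efa")) shares <- harmonic_power(shares)
  which(shares$cumulative_share > threshold)[1]
}

#' Reconstruct an outline from elliptic Fourier coefficients
#'
#' Inverse Fourier synthesis at `n_points` uniformly spaced parameter values.
#'
#' @param coeffs An `efa` object.
#' @param n_points Number of points to synthesize.
#' @param n_harmonics Number of harmonics to use (default: all present).
#' @return A tibble with `x`, `y`.
#' @export
efa_reconstruct <- function(coeffs, n_points = 300, n_harmonics = coeffs$n_harmonics) {
  n_points <- check_count(n_points, "n_points", min = 3)
  n_harmonics <- min(check_count(n_harmonics, "n_harmonics", min = 1),
                     coeffs$n_harmonics)
  t <- 2 * pi * (seq_len(n_points) - 1) / n_points
  x <- rep(coeffs$A0, n_points)
  y <- rep(coeffs$C0, n_points)
  for (n in seq_len(n_harmonics)) {
    x <- x + coeffs$an[n] * cos(n * t) + coeffs$bn[n] * sin(n * t)
    y <- y + coeffs$cn[n] * cos(n * t) + coeffs$dn[n] * sin(n * t)
  }
  tibble(x = x, y = y)
}

#' Root-mean-square round-trip error of an EFA truncation
#'
#' Decomposes and reconstructs the outline at `n_harmonics` and reports the
#' RMS distance between original and reconstructed points (same sampling),
#' relative to the outline scale (half the bounding-box diagonal).
#'
#' @param outline A preprocessed outline (uniform arc-length sampling).
#' @param n_harmonics Harmonic count.
#' @param ... Passed to [efa_decompose()].
#' @return A single number: relative RMS error.
#' @export
efa_roundtrip_error <- function(outline, n_harmonics, ...) {
  e <- efa_decompose(outline, n_harmonics = n_harmonics, ...)
  rec <- efa_reconstruct(e, n_points = nrow(outline))
  scale <- sqrt(diff(range(outline$x))^2 + diff(range(outline$y))^2) / 2
  sqrt(mean((rec$x - outline$x)^2 + (rec$y - outline$y)^2)) / scale
}

#' Flatten a list of EFA objects to a coefficient table
#'
#' @param efas A list of `efa` objects (same harmonic count).
#' @param ids Individual identifiers (default `ind1..n`).
#' @return A tibble `individual_id` plus columns `a1, b1, c1, d1, a2, ...`.
#' @export
efa_coef_table <- function(efas, ids = sprintf("ind%04d", seq_along(efas))) {
  rows <- purrr::map2(efas, ids, function(e, id) {
    v <- as.vector(rbind(e$an, e$bn, e$cn, e$dn))
    names(v) <- paste0(rep(c("a", "b", "c", "d"), e$n_harmonics),
                       rep(seq_len(e$n_harmonics), each = 4))
    dplyr::bind_cols(tibble(individual_id = id), as_tibble(as.list(v)))
  })
  dplyr::bind_rows(rows)
}
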