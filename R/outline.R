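#' Trace the outer boundary of a binary mask
#'
#' Moore-neighbourhood boundary tracing (with Jacob's stopping criterion) of
#' the single foreground connected component of a binary image. The image is
#' a matrix of 0/1 with row 1 the bottom row, so pixel (x, y) = (col - 1,
#' row - 1) with the y axis pointing up. Interior holes are ignored; the
#' returned outline is closed (first point not repeated) and
#' counterclockwise.
#'
#' @param img Binary matrix (0/1 or logical); rows = y (bottom first),
#'   columns = x.
#' @return A tibble with `x`, `y` pixel-center coordinates.
#' @export
trace_outline <- function(img) {
  img <- matrix(as.integer(img != 0), nrow(img), ncol(img))
  n_comp <- count_components(img)
  if (n_comp != 1) {
    abort(sprintf("expected exactly 1 foreground component, found %d", n_comp),
          class = "introshell_parameter_error")
  }
  h <- nrow(img); w <- ncol(img)
  inside <- function(r, c) r >= 1 && r <= h && c >= 1 && c <= w && img[r, c] == 1L
  # start: lowest row (lowest y), then lowest column
  rows <- which(img == 1L, arr.ind = TRUE)
  r0 <- min(rows[, 1])
  c0 <- min(rows[rows[, 1] == r0, 2])
  # Moore neighbourhood in clockwise order when viewed with y up, starting
  # from the backtrack direction; offsets are (dr, dc)
  nb <- matrix(c(-1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1),
               ncol = 2, byrow = TRUE)
  # walk until a (pixel, backtrack) state recurs; the traversal is a
  # deterministic map on states, so the recurring segment is the boundary
  # cycle
  steps <- matrix(NA_integer_, 4 * h * w, 2)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  cur <- c(r0, c0)
  back <- c(r0 - 1, c0)  # background: r0 is the lowest foreground row
  n_steps <- 0L
  first <- NA_integer_
  repeat {
    key <- paste(cur[1], cur[2], back[1], back[2])
    if (!is.null(seen[[key]])) {
      first <- seen[[key]]
      break
    }
    n_steps <- n_steps + 1L
    if (n_steps > nrow(steps)) {
      abort("boundary tracing failed to terminate", class = "introshell_internal_error")
    }
    seen[[key]] <- n_steps
    steps[n_steps, ] <- cur
    d <- back - cur
    bi <- which(nb[, 1] == d[1] & nb[, 2] == d[2])
    found <- FALSE
    prev <- back
    for (k in seq_len(8)) {
      idx <- ((bi - 1 + k - 1) %% 8) + 1
      cand <- cur + nb[idx, ]
      if (inside(cand[1], cand[2])) {
        back <- prev
        cur <- cand
        found <- TRUE
        break
      }
      prev <- cand
    }
    if (!found) break  # isolated pixel: no neighbours at all
  }
  boundary <- if (is.na(first)) steps[seq_len(n_steps), , drop = FALSE] else
    steps[first:n_steps, , drop = FALSE]
  if (nrow(boundary) < 32) {
    abort(sprintf("boundary has %d pixels; need >= 32", nrow(boundary)),
          class = "introshell_parameter_error")
  }
  out <- tibble(x = boundary[, 2] - 1, y = boundary[, 1] - 1)
  ensure_ccw(out)
}

# 8-connected component count by iterative flood fill
count_components <- function(img) {
  h <- nrow(img); w <- ncol(img)
  seen <- matrix(FALSE, h, w)
  n <- 0L
  fg <- which(img == 1L)
  for (p in fg) {
    r <- (p - 1) %% h + 1; c <- (p - 1) %/% h + 1
    if (seen[r, c]) next
    n <- n + 1L
    stack <- list(c(r, c)); seen[r, c] <- TRUE
    while (length(stack)) {
      q <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        rr <- q[1] + dr; cc <- q[2] + dc
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            img[rr, cc] == 1L && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          stack[[length(stack) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  n
}

signed_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

ensure_ccw <- function(outline) {
  if (signed_area(outline$x, outline$y) < 0) {
    outline <- outline[rev(seq_len(nrow(outline))), ]
  }
  tibble(x = outline$x, y = outline$y)
}

#' Resample, centre and orient a closed outline
#'
#' Uniform arc-length resampling to `n_points`, centering on the point
#' centroid (so the output centroid is exactly the origin) and
#' counterclockwise orientation.
#'
#' @param outline Tibble/data frame with `x`, `y` (closed; first point not
#'   repeated).
#' @param n_points Number of output points (>= 32).
#' @return A tibble with `x`, `y`.
#' @export
preprocess_outline <- function(outline, n_points = 300) {
  n_points <- check_count(n_points, "n_points", min = 32)
  x <- c(outline$x, outline$x[1])
  y <- c(outline$y, outline$y[1])
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  per <- sum(seg)
  if (!is.finite(per) || per <= 0) {
    abort("degenerate outline with zero perimeter", class = "introshell_parameter_error")
  }
  s <- c(0, cumsum(seg))
  target <- per * (seq_len(n_points) - 1) / n_points
  xs <- stats::approx(s, x, target, ties = "ordered")$y
  ys <- stats::approx(s, y, target, ties = "ordered")$y
  out <- ensure_ccw(tibble(x = xs, y = ys))
  tibble(x = out$x - mean(out$x), y = out$y - mean(out$y))
}

outline_perimeter <- function(outline) {
  x <- c(outline$x, outline$x[1])
  y <- c(outline$y, outline$y[1])
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Bounding-box length:height ratio of an outline
#'
#' @param outline Tibble with `x`, `y`.
#' @return `diff(range(x)) / diff(range(y))`.
#' @export
outline_elongation <- function(outline) {
  diff(range(outline$x)) / diff(range(outline$y))
}
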