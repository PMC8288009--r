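#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Deterministic child seed for a named substream, so each simulation stage can
# be re-run independently of the others under one global seed. Kept below
# 2^31 - 1 (R integers are 32-bit).
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 2654435761) %% 2147483647
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_fraction <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  bad <- !is.numeric(x) | !is.finite(x) |
    (if (open_lo) x <= lo else x < lo) |
    (if (open_hi) x >= hi else x > hi)
  if (any(bad)) {
    abort(sprintf("`%s` must lie in %s%s, %s%s", name,
                  if (open_lo) "(" else "[", format(lo),
                  format(hi), if (open_hi) ")" else "]"),
          class = "introshell_parameter_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "introshell_parameter_error")
  }
  as.integer(x)
}

# Fragment sizes (bp) of the Me15/16 PCR marker, one per species
ME_FRAGMENT <- 180
MT_FRAGMENT <- 168
MG_FRAGMENT <- 126

SPECIES_FRAGMENTS <- c(ME = 180, MT = 168, MG = 126)

ANCESTRY_CLASSES <- c("PURE_ME", "PURE_MG", "PURE_MT",
                      "F1_ME_MG", "F1_ME_MT",
                      "BC_ME_MT_ME", "BC_ME_MG_ME")
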