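#' Simulate a taxon-diagnostic SNP panel
#'
#' Builds a panel of biallelic loci whose one allele is (near-)fixed in
#' *Mytilus trossulus* (MT) and rare or absent in *M. edulis* (ME) and
#' *M. galloprovincialis* (MG). A "strictly diagnostic" locus carries the
#' diagnostic allele at frequency 1 in MT and 0 in ME/MG; the remaining loci
#' leak the diagnostic allele into ME/MG at a low frequency, emulating markers
#' ascertained from a small discovery sample in which rare shared variants
#' escape detection.
#'
#' @param n_loci Number of loci in the panel.
#' @param n_strict Number of strictly diagnostic loci (`0 <= n_strict <= n_loci`).
#' @param leak_freq Frequency of the MT-diagnostic allele in pure ME and MG at
#'   the non-strict loci. Must satisfy `0 <= leak_freq < 0.5`.
#' @param seed Integer seed; the panel is deterministic given the seed.
#' @return A tibble of class `panel_spec` with one row per locus and columns
#'   `locus_id`, `diag_freq_MT`, `leak_freq_ME`, `leak_freq_MG`,
#'   `ambiguous_flag`, `cluster_fail_flag`, `false_call_flag`.
#' @examples
#' simulate_panel(33, 28, leak_freq = 0.014, seed = 1)
#' @export
simulate_panel <- function(n_loci, n_strict = n_loci, leak_freq = 0, seed = 1) {
  n_loci <- check_count(n_loci, "n_loci", min = 1)
  n_strict <- check_count(n_strict, "n_strict", min = 0)
  if (n_strict > n_loci) {
    abort("`n_strict` must not exceed `n_loci`", class = "introshell_parameter_error")
  }
  check_fraction(leak_freq, "leak_freq", 0, 0.5, open_hi = TRUE)

  with_seed(child_seed(seed, "panel"), {
    n_leaky <- n_loci - n_strict
    # leaky loci placed at random panel positions so downstream code cannot
    # rely on ordering
    leaky <- if (n_leaky > 0) sample.int(n_loci, n_leaky) else integer(0)
    leak <- numeric(n_loci)
    leak[leaky] <- leak_freq
    panel <- tibble(
      locus_id = sprintf("L%02d", seq_len(n_loci)),
      diag_freq_MT = 1,
      leak_freq_ME = leak,
      leak_freq_MG = leak,
      ambiguous_flag = FALSE,
      cluster_fail_flag = FALSE,
      false_call_flag = FALSE
    )
    validate_panel_spec(panel)
  })
}

#' Construct or validate a panel specification
#'
#' @param panel A data frame with one row per locus; see [simulate_panel()] for
#'   the required columns. Missing flag columns default to `FALSE`.
#' @return The validated `panel_spec` tibble.
#' @export
panel_spec <- function(panel) {
  panel <- as_tibble(panel)
  for (fl in c("ambiguous_flag", "cluster_fail_flag", "false_call_flag")) {
    if (is.null(panel[[fl]])) panel[[fl]] <- FALSE
  }
  validate_panel_spec(panel)
}

validate_panel_spec <- function(panel) {
  req <- c("locus_id", "diag_freq_MT", "leak_freq_ME", "leak_freq_MG")
  miss <- setdiff(req, names(panel))
  if (length(miss)) {
    abort(paste0("panel is missing columns: ", paste(miss, collapse = ", ")),
          class = "introshell_parameter_error")
  }
  check_fraction(panel$diag_freq_MT, "diag_freq_MT")
  check_fraction(panel$leak_freq_ME, "leak_freq_ME")
  check_fraction(panel$leak_freq_MG, "leak_freq_MG")
  if (any(panel$diag_freq_MT < panel$leak_freq_ME |
          panel$diag_freq_MT < panel$leak_freq_MG)) {
    abort("diagnostic-allele frequency in MT must be >= its leak frequency in ME/MG",
          class = "introshell_parameter_error")
  }
  if (anyDuplicated(panel$locus_id)) {
    abort("duplicated locus ids in panel", class = "introshell_parameter_error")
  }
  class(panel) <- c("panel_spec", class(setdiff_class(panel)))
  panel
}

setdiff_class <- function(x) {
  class(x) <- setdiff(class(x), "panel_spec")
  x
}

is_strict_locus <- function(panel) {
  panel$diag_freq_MT == 1 & panel$leak_freq_ME == 0 & panel$leak_freq_MG == 0
}
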