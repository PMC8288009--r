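#' Species classification from Me15/16 PCR fragments
#'
#' Maps the fragment sizes observed at the Me15/16 marker to a species class:
#' one fragment identifies a pure species (180 bp = ME, 168 bp = MT,
#' 126 bp = MG), two fragments a putative hybrid, and zero or all three
#' fragments are `UNDETERMINED` (reported, never an error).
#'
#' @param fragments A numeric vector of fragment sizes, or a list of such
#'   vectors for vectorized use. Values must come from {180, 168, 126}.
#' @return A character vector of species classes among
#'   `ME, MG, MT, ME x MG, ME x MT, MG x MT, UNDETERMINED`.
#' @examples
#' call_me1516(c(180))        # "ME"
#' call_me1516(c(180, 168))   # "ME x MT"
#' call_me1516(numeric(0))    # "UNDETERMINED"
#' @export
call_me1516 <- function(fragments) {
  if (!is.list(fragments)) fragments <- list(fragments)
  purrr::map_chr(fragments, function(fr) {
    fr <- unique(fr)
    if (length(setdiff(fr, SPECIES_FRAGMENTS))) {
      abort(sprintf("unknown fragment size(s): %s",
                    paste(setdiff(fr, SPECIES_FRAGMENTS), collapse = ", ")),
            class = "introshell_parameter_error")
    }
    sp <- sort(names(SPECIES_FRAGMENTS)[SPECIES_FRAGMENTS %in% fr])
    if (length(sp) == 1) sp else if (length(sp) == 2) paste(sp, collapse = " x ")
    else "UNDETERMINED"
  })
}

me1516_classes <- c("ME", "MG", "MT", "ME x MG", "ME x MT", "MG x MT")

species_in_class <- function(class) {
  strsplit(class, " x ", fixed = TRUE)[[1]]
}

#' Per-depth species composition and allele frequencies (Table-1-style)
#'
#' Tabulates species-class proportions and Me15/16 allele frequencies per
#' depth and pooled over depths. `UNDETERMINED` individuals are excluded from
#' all denominators. The allele frequency of species *k* at a depth is
#' `(2 * n_pure_k + n_hybrids_carrying_k) / (2 n)`.
#'
#' @param calls A data frame with `individual_id` and `species_class` (e.g.
#'   from [simulate_me1516()]).
#' @param depths A data frame with `individual_id` and `depth_m`.
#' @return A tibble with one row per depth plus a pooled row (`depth` is a
#'   character column, `"pooled"` for the pooled row): `n`, one `prop_*`
#'   column per observed class, and `af_ME`, `af_MG`, `af_MT`.
#' @export
tabulate_classes <- function(calls, depths) {
  d <- dplyr::inner_join(as_tibble(calls)[, c("individual_id", "species_class")],
                         as_tibble(depths)[, c("individual_id", "depth_m")],
                         by = "individual_id")
  d <- dplyr::filter(d, .data$species_class != "UNDETERMINED")
  if (nrow(d) == 0) {
    abort("no classified individuals to tabulate", class = "introshell_parameter_error")
  }
  if (any(table(d$depth_m) == 0)) {
    abort("empty depth stratum", class = "introshell_parameter_error")
  }
  one_stratum <- function(dd, label) {
    n <- nrow(dd)
    props <- table(factor(dd$species_class, levels = me1516_classes)) / n
    af <- vapply(c("ME", "MG", "MT"), function(sp) {
      carriers <- purrr::map_lgl(dd$species_class, ~ sp %in% species_in_class(.x))
      pure <- dd$species_class == sp
      (2 * sum(pure) + sum(carriers & !pure)) / (2 * n)
    }, numeric(1))
    out <- tibble(depth = label, n = n)
    for (cl in me1516_classes) {
      out[[paste0("prop_", gsub(" x ", "_", cl))]] <- unname(props[cl])
    }
    out$af_ME <- af[["ME"]]; out$af_MG <- af[["MG"]]; out$af_MT <- af[["MT"]]
    out
  }
  strata <- d %>%
    dplyr::group_by(.data$depth_m) %>%
    dplyr::group_map(~ one_stratum(.x, as.character(.y$depth_m))) %>%
    dplyr::bind_rows()
  dplyr::bind_rows(strata, one_stratum(d, "pooled"))
}

#' Concordance between Me15/16 species calls and SNP introgression
#'
#' Cross-tabulates the Me15/16 species class against bands of the SNP-based MT
#' allele frequency (`< 0.1`, `0.1–0.3`, `> 0.3`) and lists discordant
#' individuals: MT allele frequency >= 0.3 without an MT fragment, or an MT
#' fragment with MT allele frequency < 0.1.
#'
#' @param calls Data frame with `individual_id`, `species_class`.
#' @param profiles Data frame with `individual_id`, `MT_AF` (see
#'   [introgression_profile()]).
#' @return A list with `table` (tibble `species_class` x `band` counts) and
#'   `discordant` (tibble of flagged individuals with a `reason` column).
#' @export
concordance_me1516_snp <- function(calls, profiles) {
  calls <- as_tibble(calls)
  profiles <- as_tibble(profiles)
  unmatched <- c(setdiff(calls$individual_id, profiles$individual_id),
                 setdiff(profiles$individual_id, calls$individual_id))
  if (length(unmatched)) {
    abort(sprintf("unmatched individual ids: %s", paste(unmatched, collapse = ", ")),
          class = "introshell_parameter_error")
  }
  d <- dplyr::inner_join(calls[, c("individual_id", "species_class")],
                         profiles[, c("individual_id", "MT_AF")],
                         by = "individual_id")
  if (nrow(d) == 0) {
    return(list(table = tibble(species_class = character(), band = character(),
                               n = integer()),
                discordant = tibble(individual_id = character(),
                                    species_class = character(),
                                    MT_AF = numeric(), reason = character())))
  }
  d$band <- cut(d$MT_AF, c(-Inf, 0.1, 0.3, Inf),
                labels = c("<0.1", "0.1-0.3", ">0.3"), right = FALSE)
  d$has_mt <- purrr::map_lgl(d$species_class, ~ "MT" %in% species_in_class(.x))
  tab <- dplyr::count(d, .data$species_class, .data$band, .drop = FALSE)
  disc <- dplyr::bind_rows(
    dplyr::mutate(dplyr::filter(d, .data$MT_AF >= 0.3, !.data$has_mt),
                  reason = "MT_AF >= 0.3 but no MT fragment"),
    dplyr::mutate(dplyr::filter(d, .data$MT_AF < 0.1, .data$has_mt),
                  reason = "MT fragment but MT_AF < 0.1")
  )
  list(table = tab,
       discordant = disc[, c("individual_id", "species_class", "MT_AF", "reason")])
}

#' Enumerate integer class counts consistent with a printed composition row
#'
#' Given a stratum size and species-class proportions plus allele frequencies
#' printed to a fixed number of decimals, exhaustively enumerates the integer
#' class-count vectors whose exact proportions and allele frequencies round to
#' the printed values (within half a unit in the last printed digit). Useful
#' for reconstructing raw counts from published composition tables.
#'
#' @param n Stratum size.
#' @param props Named numeric vector of printed class proportions (classes
#'   among `ME, MG, MT, ME x MG, ME x MT, MG x MT`); classes printed as absent
#'   are fixed at zero.
#' @param allele_freqs Optional named vector (`ME`, `MG`, `MT`) of printed
#'   allele frequencies used as an extra constraint.
#' @param digits Number of printed decimals (default 2).
#' @return A tibble of solutions, one row per consistent count vector, with
#'   one column per class.
#' @export
enumerate_class_counts <- function(n, props, allele_freqs = NULL, digits = 2) {
  n <- check_count(n, "n", min = 1)
  classes <- names(props)
  bad <- setdiff(classes, me1516_classes)
  if (length(bad)) {
    abort(sprintf("unknown class(es): %s", paste(bad, collapse = ", ")),
          class = "introshell_parameter_error")
  }
  tol <- 0.5 * 10^(-digits) + 1e-9
  cand <- lapply(props, function(p) {
    k <- 0:n
    k[abs(k / n - p) <= tol]
  })
  grid <- expand.grid(cand[-length(cand)], KEEP.OUT.ATTRS = FALSE)
  sols <- list()
  last <- classes[length(classes)]
  for (i in seq_len(max(nrow(grid), 1))) {
    counts <- if (ncol(grid)) unlist(grid[i, , drop = TRUE]) else numeric(0)
    rest <- n - sum(counts)
    if (rest < 0 || !(rest %in% cand[[last]])) next
    full <- stats::setNames(numeric(length(me1516_classes)), me1516_classes)
    full[classes] <- c(counts, rest)
    if (!is.null(allele_freqs)) {
      af <- vapply(names(allele_freqs), function(sp) {
        carriers <- purrr::map_lgl(me1516_classes, ~ sp %in% species_in_class(.x))
        pure <- me1516_classes == sp
        (2 * sum(full[pure]) + sum(full[carriers & !pure])) / (2 * n)
      }, numeric(1))
      if (any(abs(af - allele_freqs) > tol)) next
    }
    sols[[length(sols) + 1]] <- as_tibble(as.list(full))
  }
  if (!length(sols)) {
    return(as_tibble(stats::setNames(rep(list(integer(0)), length(me1516_classes)),
                                     me1516_classes)))
  }
  dplyr::distinct(dplyr::bind_rows(sols))
}
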