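#' Describe a synthetic cohort: depth strata and ancestry mixtures
#'
#' A cohort design gives, for each cultivation depth, the number of individuals
#' and the mixture of ancestry classes from which they are drawn. Supported
#' classes are the pure species (`PURE_ME`, `PURE_MG`, `PURE_MT`), first
#' generation hybrids (`F1_ME_MG`, `F1_ME_MT`) and first backcrosses to ME
#' (`BC_ME_MT_ME`, `BC_ME_MG_ME`).
#'
#' @param strata A data frame with columns `depth_m`, `n` and one column per
#'   ancestry class giving its mixture proportion at that depth (proportions
#'   must sum to 1 per row; absent classes default to 0).
#' @param seed Integer seed stored with the design.
#' @return A tibble of class `cohort_design`.
#' @export
cohort_design <- function(strata, seed = 1) {
  strata <- as_tibble(strata)
  if (!all(c("depth_m", "n") %in% names(strata))) {
    abort("strata needs `depth_m` and `n` columns", class = "introshell_parameter_error")
  }
  if (any(strata$n <= 0 | strata$n != round(strata$n))) {
    abort("per-depth counts must be positive integers", class = "introshell_parameter_error")
  }
  for (cl in ANCESTRY_CLASSES) if (is.null(strata[[cl]])) strata[[cl]] <- 0
  mix <- as.matrix(strata[, ANCESTRY_CLASSES])
  if (any(mix < 0) || any(abs(rowSums(mix) - 1) > 1e-8)) {
    abort("ancestry mixture proportions must be non-negative and sum to 1 per depth",
          class = "introshell_parameter_error")
  }
  attr(strata, "seed") <- as.integer(seed)
  class(strata) <- c("cohort_design", class(strata))
  strata
}

#' Default study-like cohort design
#'
#' Four depth strata (1/3/5/7 m) with sample sizes 116/118/118/83, a stock
#' dominated by pure ME with ME x MG hybrids, and a small ME x MT / pure MT
#' component that declines with depth, so that the mean per-individual MT
#' allele frequency falls from roughly 0.04 at 1 m to below 0.01 at 7 m.
#'
#' @param seed Integer seed.
#' @return A `cohort_design` tibble.
#' @export
default_cohort_design <- function(seed = 1) {
  strata <- tibble(
    depth_m = c(1, 3, 5, 7),
    n = c(116L, 118L, 118L, 83L),
    PURE_MT     = c(0.025, 0.017, 0.008, 0.000),
    F1_ME_MT    = c(0.017, 0.008, 0.008, 0.000),
    BC_ME_MT_ME = c(0.017, 0.017, 0.008, 0.012),
    F1_ME_MG    = c(0.090, 0.170, 0.150, 0.150),
    BC_ME_MG_ME = c(0.050, 0.050, 0.050, 0.050),
    PURE_MG     = c(0, 0, 0, 0)
  )
  strata$PURE_ME <- 1 - rowSums(strata[, setdiff(ANCESTRY_CLASSES, "PURE_ME")])
  cohort_design(strata, seed = seed)
}

#' Default 33-locus diagnostic panel
#'
#' 28 strictly diagnostic loci plus 5 loci at which the MT-diagnostic allele
#' leaks into ME/MG at frequency 0.014 — the detection floor implied by a
#' discovery sample of 72 ME/MG chromosomes.
#'
#' @param seed Integer seed.
#' @return A `panel_spec` tibble.
#' @export
default_panel <- function(seed = 1) {
  simulate_panel(33, n_strict = 28, leak_freq = 0.014, seed = seed)
}

# gamete pools per ancestry class: each gamete is drawn from a species allele
# pool; F1 gametes are one pool each; BC gametes pick one of the F1's two
# pools with probability 1/2, independently per locus
class_gametes <- function(class) {
  switch(class,
    PURE_ME = list("ME", "ME"),
    PURE_MG = list("MG", "MG"),
    PURE_MT = list("MT", "MT"),
    F1_ME_MG = list("ME", "MG"),
    F1_ME_MT = list("ME", "MT"),
    BC_ME_MT_ME = list(c("ME", "MT"), "ME"),
    BC_ME_MG_ME = list(c("ME", "MG"), "ME"),
    abort(sprintf("unknown ancestry class '%s'", class),
          class = "introshell_parameter_error")
  )
}

species_freq <- function(panel, species) {
  switch(species,
    MT = panel$diag_freq_MT,
    ME = panel$leak_freq_ME,
    MG = panel$leak_freq_MG
  )
}

#' Simulate a genotyped cohort
#'
#' Draws, for every individual, two alleles per locus from the gamete pools of
#' its ancestry class: pure classes take both alleles from one species' allele
#' frequencies, F1s take one from each parental species, and first backcrosses
#' take one allele from an F1 gamete (a per-locus coin flip between the two
#' parental pools) and one from the recurrent parent. The per-cell genotype is
#' recorded as the diagnostic-allele dosage 0 / 0.5 / 1. Each individual also
#' carries two species-of-origin alleles at a simulated Me15/16 locus,
#' inherited under the same law, which [simulate_me1516()] converts to PCR
#' fragments.
#'
#' @param design A [cohort_design()].
#' @param panel A [panel_spec()].
#' @return A list of class `mussel_cohort` with elements `genotypes` (tibble:
#'   `individual_id` plus one dosage column per locus), `meta` (tibble:
#'   `individual_id`, `depth_m`, `ancestry`, `me_allele_1`, `me_allele_2`)
#'   and `panel`.
#' @export
simulate_cohort <- function(design, panel) {
  if (!inherits(design, "cohort_design")) design <- cohort_design(design)
  panel <- validate_panel_spec(as_tibble(panel))
  seed <- attr(design, "seed")

  with_seed(child_seed(seed, "cohort"), {
    rows <- purrr::pmap(design, function(depth_m, n, ...) {
      mix <- unlist(list(...)[ANCESTRY_CLASSES])
      classes <- sample(ANCESTRY_CLASSES, n, replace = TRUE, prob = mix)
      tibble(depth_m = depth_m, ancestry = classes)
    })
    meta <- dplyr::bind_rows(rows)
    n_ind <- nrow(meta)
    meta$individual_id <- sprintf("ind%04d", seq_len(n_ind))

    n_loc <- nrow(panel)
    freq_by_species <- list(ME = panel$leak_freq_ME,
                            MG = panel$leak_freq_MG,
                            MT = panel$diag_freq_MT)
    geno <- matrix(NA_real_, n_ind, n_loc, dimnames = list(meta$individual_id, panel$locus_id))
    me_alleles <- matrix(NA_character_, n_ind, 2)
    for (cl in unique(meta$ancestry)) {
      rows <- which(meta$ancestry == cl)
      nc <- length(rows)
      pools <- class_gametes(cl)
      alleles <- matrix(0L, nc, n_loc)
      for (g in 1:2) {
        pool <- pools[[g]]
        # per-(individual, locus) species of origin of this gamete's allele
        freq <- if (length(pool) == 1) {
          matrix(freq_by_species[[pool]], nc, n_loc, byrow = TRUE)
        } else {
          pick <- matrix(stats::rbinom(nc * n_loc, 1, 0.5), nc, n_loc)
          f1 <- matrix(freq_by_species[[pool[1]]], nc, n_loc, byrow = TRUE)
          f2 <- matrix(freq_by_species[[pool[2]]], nc, n_loc, byrow = TRUE)
          f1 * (1 - pick) + f2 * pick
        }
        alleles <- alleles + matrix(stats::rbinom(nc * n_loc, 1, freq), nc, n_loc)
        # Me15/16 species allele from the same gamete law (one extra locus)
        me_alleles[rows, g] <- if (length(pool) == 1) pool else
          pool[1 + stats::rbinom(nc, 1, 0.5)]
      }
      geno[rows, ] <- alleles / 2
    }
    meta$me_allele_1 <- me_alleles[, 1]
    meta$me_allele_2 <- me_alleles[, 2]

    genotypes <- dplyr::bind_cols(tibble(individual_id = meta$individual_id),
                                  as_tibble(geno))
    new_cohort(genotypes,
               meta[, c("individual_id", "depth_m", "ancestry",
                        "me_allele_1", "me_allele_2")],
               panel)
  })
}

new_cohort <- function(genotypes, meta, panel) {
  structure(list(genotypes = genotypes, meta = meta, panel = panel),
            class = "mussel_cohort")
}

#' @export
print.mussel_cohort <- function(x, ...) {
  cat(sprintf("<mussel_cohort> %d individuals x %d loci; depths: %s m\n",
              nrow(x$genotypes), ncol(x$genotypes) - 1,
              paste(sort(unique(x$meta$depth_m)), collapse = "/")))
  print(utils::head(dplyr::count(x$meta, .data$depth_m, .data$ancestry), 12))
  invisible(x)
}

#' Inject missing genotype calls
#'
#' Marks calls missing at per-locus and per-individual rates; a cell is set
#' missing with probability `1 - (1 - locus_rate) * (1 - individual_rate)`,
#' so with only one kind of rate active the realised missing fraction matches
#' the requested rate in expectation. Calls are flagged `NA`, never dropped.
#'
#' @param cohort A `mussel_cohort`.
#' @param locus_rates Single rate or vector named by locus id.
#' @param indiv_rates Single rate or vector named by individual id.
#' @param seed Integer seed.
#' @return The cohort with `NA` dosages injected.
#' @export
inject_missingness <- function(cohort, locus_rates = 0, indiv_rates = 0, seed = 1) {
  check_fraction(locus_rates, "locus_rates")
  check_fraction(indiv_rates, "indiv_rates")
  g <- cohort$genotypes
  loci <- names(g)[-1]
  ids <- g$individual_id
  lr <- expand_rates(locus_rates, loci, "locus_rates")
  ir <- expand_rates(indiv_rates, ids, "indiv_rates")
  with_seed(child_seed(seed, "missingness"), {
    p <- 1 - outer(1 - ir, 1 - lr)  # individuals x loci
    miss <- matrix(stats::runif(length(p)) < p, nrow(p), ncol(p))
    m <- as.matrix(g[, loci])
    m[miss] <- NA_real_
    cohort$genotypes <- dplyr::bind_cols(tibble(individual_id = ids), as_tibble(m))
    cohort
  })
}

expand_rates <- function(rates, ids, name) {
  if (length(rates) == 1 && is.null(names(rates))) {
    return(stats::setNames(rep(rates, length(ids)), ids))
  }
  out <- stats::setNames(rep(0, length(ids)), ids)
  unknown <- setdiff(names(rates), ids)
  if (length(unknown)) {
    abort(sprintf("`%s` names unknown ids: %s", name, paste(unknown, collapse = ", ")),
          class = "introshell_parameter_error")
  }
  out[names(rates)] <- rates
  out
}

#' Simulate Me15/16 PCR fragments for a cohort
#'
#' Converts each individual's two species-of-origin alleles at the Me15/16
#' locus to the species-specific fragment sizes (ME 180 bp, MT 168 bp,
#' MG 126 bp): pure individuals show one fragment, heterozygous individuals
#' two.
#'
#' @param cohort A `mussel_cohort`.
#' @return A tibble with `individual_id`, logical `f180`/`f168`/`f126`, a
#'   `fragments` list-column and the `species_class` from [call_me1516()].
#' @export
simulate_me1516 <- function(cohort) {
  meta <- cohort$meta
  bad <- setdiff(unique(meta$ancestry), ANCESTRY_CLASSES)
  if (length(bad)) {
    abort(sprintf("unknown ancestry label(s): %s", paste(bad, collapse = ", ")),
          class = "introshell_parameter_error")
  }
  frags <- purrr::map2(meta$me_allele_1, meta$me_allele_2, function(a, b) {
    sort(unique(unname(SPECIES_FRAGMENTS[c(a, b)])), decreasing = TRUE)
  })
  tibble(
    individual_id = meta$individual_id,
    f180 = purrr::map_lgl(frags, ~ ME_FRAGMENT %in% .x),
    f168 = purrr::map_lgl(frags, ~ MT_FRAGMENT %in% .x),
    f126 = purrr::map_lgl(frags, ~ MG_FRAGMENT %in% .x),
    fragments = frags,
    species_class = call_me1516(frags)
  )
}
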