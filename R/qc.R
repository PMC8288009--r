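#' Quality-control filtering of a diagnostic-SNP genotype table
#'
#' Applies the two-stage filter used for diagnostic panels: loci are removed
#' first (assay flags, then missing-data threshold computed over all
#' individuals), and individuals second (QC flags, then missing-data threshold
#' computed over the *retained* loci). Every exclusion is recorded with its
#' reason.
#'
#' @param genotypes A tibble: `individual_id` plus one dosage column per locus
#'   (values 0 / 0.5 / 1 / `NA`).
#' @param locus_flags Optional data frame with `locus_id` and any of the
#'   logical columns `cluster_fail`, `false_call`, `ambiguous`.
#' @param individual_flags Optional data frame with `individual_id` and a
#'   logical `qc_fail` column.
#' @param missing_threshold Maximum tolerated missing fraction, in (0, 1];
#'   default 0.2.
#' @return A list of class `qc_result`: `genotypes` (the filtered tibble),
#'   `loci` (per-locus report: missing fraction, flags, `retained`, `reason`),
#'   `individuals` (per-individual report).
#' @examples
#' g <- tibble::tibble(individual_id = c("a", "b"), L1 = c(0, 0.5), L2 = c(NA, 1))
#' qc_filter(g, missing_threshold = 0.6)
#' @export
qc_filter <- function(genotypes, locus_flags = NULL, individual_flags = NULL,
                      missing_threshold = 0.2) {
  check_fraction(missing_threshold, "missing_threshold", 0, 1, open_lo = TRUE)
  genotypes <- as_tibble(genotypes)
  loci <- setdiff(names(genotypes), "individual_id")
  g <- as.matrix(genotypes[, loci, drop = FALSE])
  rownames(g) <- genotypes$individual_id

  fl <- tibble(locus_id = loci, cluster_fail = FALSE, false_call = FALSE,
               ambiguous = FALSE)
  if (!is.null(locus_flags)) {
    locus_flags <- as_tibble(locus_flags)
    for (col in c("cluster_fail", "false_call", "ambiguous")) {
      if (!is.null(locus_flags[[col]])) {
        idx <- match(locus_flags$locus_id, fl$locus_id)
        fl[[col]][idx[!is.na(idx)]] <- locus_flags[[col]][!is.na(idx)]
      }
    }
  }
  fl$missing_fraction <- colMeans(is.na(g))
  fl$reason <- dplyr::case_when(
    fl$cluster_fail ~ "poor clustering performance",
    fl$false_call ~ "false positives/negatives",
    fl$ambiguous ~ "ambiguous genotypes",
    fl$missing_fraction > missing_threshold ~
      sprintf("missing fraction > %g", missing_threshold),
    TRUE ~ NA_character_
  )
  fl$retained <- is.na(fl$reason)
  if (!any(fl$retained)) {
    abort("empty panel: all loci removed by QC", class = "introshell_qc_error")
  }
  kept_loci <- fl$locus_id[fl$retained]

  ind <- tibble(individual_id = genotypes$individual_id, qc_fail = FALSE)
  if (!is.null(individual_flags)) {
    individual_flags <- as_tibble(individual_flags)
    idx <- match(individual_flags$individual_id, ind$individual_id)
    ind$qc_fail[idx[!is.na(idx)]] <- individual_flags$qc_fail[!is.na(idx)]
  }
  ind$missing_fraction <- rowMeans(is.na(g[, kept_loci, drop = FALSE]))
  ind$reason <- dplyr::case_when(
    ind$qc_fail ~ "failed quality control",
    ind$missing_fraction > missing_threshold ~
      sprintf("missing fraction > %g over retained loci", missing_threshold),
    TRUE ~ NA_character_
  )
  ind$retained <- is.na(ind$reason)

  out <- genotypes[ind$retained, c("individual_id", kept_loci)]
  structure(list(genotypes = out, loci = fl, individuals = ind,
                 missing_threshold = missing_threshold),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> retained %d/%d loci, %d/%d individuals (threshold %g)\n",
              sum(x$loci$retained), nrow(x$loci),
              sum(x$individuals$retained), nrow(x$individuals),
              x$missing_threshold))
  excl <- dplyr::filter(x$loci, !.data$retained)
  if (nrow(excl)) print(dplyr::count(excl, .data$reason))
  invisible(x)
}

#' Tidy the exclusion ledger of a QC result
#'
#' @param x A `qc_result`.
#' @param ... Unused.
#' @return A tibble with one row per excluded locus or individual
#'   (`unit`, `id`, `missing_fraction`, `reason`).
#' @method tidy qc_result
#' @export
tidy.qc_result <- function(x, ...) {
  dplyr::bind_rows(
    x$loci %>% dplyr::filter(!.data$retained) %>%
      dplyr::transmute(unit = "locus", id = .data$locus_id,
                       missing_fraction = .data$missing_fraction,
                       reason = .data$reason),
    x$individuals %>% dplyr::filter(!.data$retained) %>%
      dplyr::transmute(unit = "individual", id = .data$individual_id,
                       missing_fraction = .data$missing_fraction,
                       reason = .data$reason)
  )
}

#' @method glance qc_result
#' @export
glance.qc_result <- function(x, ...) {
  tibble(n_loci_in = nrow(x$loci), n_loci_retained = sum(x$loci$retained),
         n_individuals_in = nrow(x$individuals),
         n_individuals_retained = sum(x$individuals$retained),
         missing_threshold = x$missing_threshold)
}
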