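#' Per-individual introgression statistics
#'
#' For each individual, over its genotyped (non-missing) retained loci M:
#' `H_O = nXY / M` (observed heterozygosity for the MT-diagnostic allele),
#' `HI = (nXY + nXX) / M` (hybrid index: fraction of loci showing the MT
#' allele in any dosage) and `MT_AF = (nXY + 2 nXX) / (2 M)` (per-individual
#' MT allele frequency), where `nXY` / `nXX` count loci heterozygous /
#' homozygous for the MT allele. The identity `MT_AF = HI - H_O / 2` holds
#' exactly. Individuals are binned on MT_AF (`NONE` when no MT allele is
#' carried, then `(0, 0.10)`, `[0.10, 0.50)`, `[0.50, 0.75)`, `[0.75, 1]`)
#' and flagged `f1_like` when `0.35 <= MT_AF <= 0.5` and at least 80% of
#' their MT-carrying loci are heterozygous — the pattern expected of a
#' first-generation hybrid.
#'
#' @param genotypes A tibble: `individual_id` plus one dosage column per
#'   locus (0 / 0.5 / 1 / `NA`).
#' @return A tibble with columns `individual_id`, `M`, `nXY`, `nXX`, `H_O`,
#'   `HI`, `MT_AF`, `bin`, `f1_like`.
#' @examples
#' g <- tibble::tibble(individual_id = "a",
#'                     !!!stats::setNames(as.list(c(rep(0, 30), 0.5, 0.5, 1)),
#'                                        sprintf("L%02d", 1:33)))
#' introgression_profile(g)
#' @export
introgression_profile <- function(genotypes) {
  genotypes <- as_tibble(genotypes)
  loci <- setdiff(names(genotypes), "individual_id")
  g <- as.matrix(genotypes[, loci, drop = FALSE])
  vals <- g[!is.na(g)]
  if (length(setdiff(unique(vals), c(0, 0.5, 1)))) {
    abort("dosages must be 0, 0.5, 1 or NA", class = "introshell_parameter_error")
  }
  M <- rowSums(!is.na(g))
  if (any(M == 0)) {
    abort(sprintf("uninformative individual(s) with no genotyped loci: %s",
                  paste(genotypes$individual_id[M == 0], collapse = ", ")),
          class = "introshell_parameter_error")
  }
  nXY <- rowSums(g == 0.5, na.rm = TRUE)
  nXX <- rowSums(g == 1, na.rm = TRUE)
  mt_af <- (nXY + 2 * nXX) / (2 * M)
  bin <- dplyr::case_when(
    nXY + nXX == 0 ~ "NONE",
    mt_af < 0.10 ~ "LT10",
    mt_af < 0.50 ~ "10_50",
    mt_af < 0.75 ~ "50_75",
    TRUE ~ "GT75"
  )
  tibble(
    individual_id = genotypes$individual_id,
    M = as.integer(M), nXY = as.integer(nXY), nXX = as.integer(nXX),
    H_O = nXY / M,
    HI = (nXY + nXX) / M,
    MT_AF = mt_af,
    bin = factor(bin, levels = c("NONE", "LT10", "10_50", "50_75", "GT75")),
    f1_like = mt_af >= 0.35 & mt_af <= 0.5 &
      (nXY + nXX) > 0 & nXY / pmax(nXY + nXX, 1) >= 0.8
  )
}

#' Per-depth introgression summary (Table-2-style)
#'
#' @param profiles Output of [introgression_profile()].
#' @param depths Data frame with `individual_id` and `depth_m`.
#' @return A tibble with one row per depth plus a pooled row: `n`,
#'   `pct_mt_positive` (individuals carrying at least one MT allele, as a
#'   percentage of the stratum), bin counts `n_lt10`, `n_10_50`, `n_50_75`,
#'   `n_gt75`, and the stratum means `mean_mt_af`, `mean_ho`, `mean_hi`
#'   (over all individuals, including those with no MT alleles).
#' @export
summarize_introgression <- function(profiles, depths) {
  profiles <- as_tibble(profiles)
  profiles <- profiles[, setdiff(names(profiles), "depth_m")]
  d <- dplyr::inner_join(profiles,
                         as_tibble(depths)[, c("individual_id", "depth_m")],
                         by = "individual_id")
  if (nrow(d) == 0) {
    abort("no profiles to summarize", class = "introshell_parameter_error")
  }
  one <- function(dd, label) {
    tibble(
      depth = label,
      n = nrow(dd),
      pct_mt_positive = 100 * mean(dd$bin != "NONE"),
      n_lt10 = sum(dd$bin == "LT10"),
      n_10_50 = sum(dd$bin == "10_50"),
      n_50_75 = sum(dd$bin == "50_75"),
      n_gt75 = sum(dd$bin == "GT75"),
      mean_mt_af = mean(dd$MT_AF),
      mean_ho = mean(dd$H_O),
      mean_hi = mean(dd$HI)
    )
  }
  strata <- d %>%
    dplyr::group_by(.data$depth_m) %>%
    dplyr::group_map(~ one(.x, as.character(.y$depth_m))) %>%
    dplyr::bind_rows()
  dplyr::bind_rows(strata, one(d, "pooled"))
}

#' Minor-allele-frequency detection limit of a discovery sample
#'
#' The lowest allele frequency at which a single allele copy is expected in a
#' discovery sample of `n_chromosomes` sequenced chromosomes: `1/n`. Alleles
#' rarer than this are liable to be missed when a marker panel is ascertained,
#' which is how "diagnostic" loci come to leak.
#'
#' @param n_chromosomes Number of chromosomes in the discovery sample (>= 1).
#' @return The detection-limit frequency.
#' @examples
#' maf_detection_limit(72)  # 0.0139: 2 * (21 ME + 15 MG) chromosomes
#' maf_detection_limit(8)   # 0.125:  2 * 4 MT chromosomes
#' @export
maf_detection_limit <- function(n_chromosomes) {
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes", min = 1)
  1 / n_chromosomes
}

#' Hierarchical-clustering display order for a genotype heatmap
#'
#' Clusters individuals (rows) and loci (columns) by agglomerative
#' hierarchical clustering with Euclidean distance and complete linkage;
#' missing dosages are imputed as 0 for the distance computation only.
#' Leaf order is deterministic given input order (ties broken by position).
#'
#' @param genotypes A tibble: `individual_id` plus dosage columns.
#' @return A list with `row_order` and `col_order` (ids in display order) and
#'   the underlying `hclust` objects (`NULL` for single-row/column input).
#' @export
cluster_heatmap_order <- function(genotypes) {
  genotypes <- as_tibble(genotypes)
  loci <- setdiff(names(genotypes), "individual_id")
  if (nrow(genotypes) == 0 || length(loci) == 0) {
    abort("empty genotype matrix", class = "introshell_parameter_error")
  }
  g <- as.matrix(genotypes[, loci, drop = FALSE])
  g[is.na(g)] <- 0
  rownames(g) <- genotypes$individual_id
  order_of <- function(m) {
    if (nrow(m) < 2) return(list(order = rownames(m), hclust = NULL))
    hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
    list(order = rownames(m)[hc$order], hclust = hc)
  }
  ro <- order_of(g)
  co <- order_of(t(g))
  list(row_order = ro$order, col_order = co$order,
       row_hclust = ro$hclust, col_hclust = co$hclust)
}
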