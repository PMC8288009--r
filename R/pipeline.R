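#' Read a genotype table from CSV
#'
#' Expects a header row of locus ids with the first column holding individual
#' ids. Cells must be diagnostic-allele dosages in {0, 0.5, 1, NA}; a table
#' coded as allele counts {0, 1, 2, NA} is accepted and converted by halving
#' (the dialect used is recorded in the `dialect` attribute and logged).
#'
#' @param path Path to a CSV file.
#' @return A genotype tibble (`individual_id` plus one column per locus).
#' @export
read_genotype_table <- function(path) {
  g <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(g)[1] <- "individual_id"
  g$individual_id <- as.character(g$individual_id)
  if (anyDuplicated(g$individual_id)) {
    abort(sprintf("duplicated individual id(s): %s",
                  paste(unique(g$individual_id[duplicated(g$individual_id)]),
                        collapse = ", ")),
          class = "introshell_parameter_error")
  }
  loci <- setdiff(names(g), "individual_id")
  if (anyDuplicated(loci)) {
    abort("duplicated locus ids", class = "introshell_parameter_error")
  }
  m <- as.matrix(g[, loci, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(g[, loci], 2, as.numeric))) &
                   !is.na(as.matrix(g[, loci])), arr.ind = TRUE)
    loc <- if (length(bad)) sprintf(" (e.g. row %d, column '%s')",
                                    bad[1, 1], loci[bad[1, 2]]) else ""
    abort(paste0("non-numeric genotype cells", loc),
          class = "introshell_parameter_error")
  }
  vals <- unique(m[!is.na(m)])
  dialect <- if (all(vals %in% c(0, 0.5, 1))) "dosage"
  else if (all(vals %in% c(0, 1, 2)) && any(vals == 2)) "count"
  else {
    bad <- which(!(m %in% c(0, 0.5, 1, 2)) & !is.na(m), arr.ind = TRUE)
    abort(sprintf("invalid genotype value %s at row %d, column '%s'",
                  format(m[bad[1, 1], bad[1, 2]]), bad[1, 1], loci[bad[1, 2]]),
          class = "introshell_parameter_error")
  }
  if (dialect == "count") m <- m / 2
  message(sprintf("read %d individuals x %d loci (%s-coded)",
                  nrow(m), ncol(m), dialect))
  out <- dplyr::bind_cols(tibble(individual_id = g$individual_id), as_tibble(m))
  attr(out, "dialect") <- dialect
  out
}

#' Pipeline run configuration
#'
#' Collects the knobs of a full analysis run. Either `scenario = "synthetic"`
#' (the default synthetic cohort) or input paths for genotypes/metadata may
#' be given.
#'
#' @param scenario `"synthetic"` or `"files"`.
#' @param genotypes_path,metadata_path CSV paths when `scenario = "files"`.
#' @param qc_threshold Missing-data threshold in (0, 1); default 0.2.
#' @param efa_points Outline points for morphometrics (default 300).
#' @param efa_power_threshold Harmonic-power threshold (default 0.95).
#' @param pca_threshold PC retention threshold (default 0.95).
#' @param with_morpho Run the morphometrics stage (default TRUE).
#' @param seed Integer seed recorded in every output.
#' @param outdir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(scenario = c("synthetic", "files"),
                       genotypes_path = NULL, metadata_path = NULL,
                       qc_threshold = 0.2,
                       efa_points = 300, efa_power_threshold = 0.95,
                       pca_threshold = 0.95,
                       with_morpho = TRUE,
                       seed = 1, outdir = tempfile("introshell_run_")) {
  scenario <- match.arg(scenario)
  check_fraction(qc_threshold, "qc_threshold", 0, 1, open_lo = TRUE, open_hi = TRUE)
  check_fraction(efa_power_threshold, "efa_power_threshold", 0, 1,
                 open_lo = TRUE, open_hi = TRUE)
  structure(list(scenario = scenario, genotypes_path = genotypes_path,
                 metadata_path = metadata_path, qc_threshold = qc_threshold,
                 efa_points = efa_points,
                 efa_power_threshold = efa_power_threshold,
                 pca_threshold = pca_threshold, with_morpho = with_morpho,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load) -> QC -> introgression summaries -> depth
#' models -> strength models -> morphometrics (optional) -> report. All
#' tabular artifacts are written as CSV into `config$outdir`; re-running with
#' the same configuration and seed is byte-identical for the deterministic
#' stages. A stage failure aborts with the stage name; artifacts written so
#' far are retained next to a `FAILED` marker file.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report`: per-stage tibble of counts and
#'   headline statistics, plus the key result tables.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  geno <- meta <- me_calls <- qc <- prof <- NULL
  table1 <- table2 <- dm <- strength_fit <- pca <- NULL
  stages <- list()
  note <- function(stage, n_in, n_out, headline = "") {
    stages[[length(stages) + 1]] <<- tibble(
      stage = stage, n_in = n_in, n_out = n_out,
      n_excluded = n_in - n_out, headline = headline)
  }
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e) {
      writeLines(c(stage, conditionMessage(e)), file.path(config$outdir, "FAILED"))
      abort(sprintf("pipeline failed at stage '%s': %s", stage,
                    conditionMessage(e)),
            class = "introshell_pipeline_error")
    })
  }

  # -- inputs ---------------------------------------------------------------
  shell <- NULL
  if (config$scenario == "synthetic") {
    run_stage("simulate", {
      design <- default_cohort_design(seed = config$seed)
      panel <- default_panel(seed = config$seed)
      cohort <- simulate_cohort(design, panel)
      cohort <- inject_missingness(cohort, locus_rates = 0.02,
                                   indiv_rates = 0.02, seed = config$seed)
      me <- simulate_me1516(cohort)
      shell <- simulate_shell_traits(cohort, seed = config$seed)
      write_cohort(cohort, config$outdir, shell = shell)
      geno <- cohort$genotypes
      meta <- cohort$meta
      me_calls <- me
      note("simulate", nrow(geno), nrow(geno),
           sprintf("seed %d", config$seed))
    })
  } else {
    run_stage("load", {
      geno <- read_genotype_table(config$genotypes_path)
      meta <- readr::read_csv(config$metadata_path, show_col_types = FALSE)
      me_calls <- NULL
      note("load", nrow(geno), nrow(geno), basename(config$genotypes_path))
    })
  }

  # -- QC -------------------------------------------------------------------
  run_stage("qc", {
    qc <- qc_filter(geno, missing_threshold = config$qc_threshold)
    readr::write_csv(tidy(qc), file.path(config$outdir, "qc_exclusions.csv"))
    note("qc", nrow(geno), nrow(qc$genotypes),
         sprintf("%d/%d loci retained", sum(qc$loci$retained), nrow(qc$loci)))
  })

  # -- introgression --------------------------------------------------------
  run_stage("introgression", {
    prof <- introgression_profile(qc$genotypes)
    table2 <- summarize_introgression(prof, meta)
    readr::write_csv(table2, file.path(config$outdir, "introgression_by_depth.csv"))
    if (!is.null(me_calls)) {
      table1 <- tabulate_classes(me_calls, meta)
      readr::write_csv(table1, file.path(config$outdir, "species_by_depth.csv"))
    } else table1 <- NULL
    note("introgression", nrow(qc$genotypes), nrow(prof),
         sprintf("%.1f%% MT-positive overall",
                 table2$pct_mt_positive[table2$depth == "pooled"]))
  })

  # -- depth models ---------------------------------------------------------
  run_stage("depth-models", {
    strata <- dplyr::filter(table2, .data$depth != "pooled")
    succ <- round(strata$n * strata$pct_mt_positive / 100)
    dm <- fit_logistic_grouped(succ, strata$n, as.numeric(strata$depth))
    dmq <- fit_quasibinomial_grouped(succ, strata$n, as.numeric(strata$depth))
    coefs <- dplyr::bind_rows(
      dplyr::mutate(tidy(dm), model = "binomial"),
      dplyr::mutate(tidy(dmq), model = "quasibinomial"))
    readr::write_csv(coefs, file.path(config$outdir, "depth_model_coefficients.csv"))
    note("depth-models", nrow(strata), nrow(strata),
         sprintf("odds factor %.3f per metre", dm$odds_factor))
  })

  # -- strength models ------------------------------------------------------
  run_stage("strength", {
    if (is.null(shell)) {
      strength_fit <- NULL
      note("strength", 0, 0, "no shell data")
    } else {
      d <- dplyr::inner_join(shell, prof[, c("individual_id", "MT_AF")],
                             by = "individual_id")
      d$strength <- normalize_strength(d$force_kg, d$SL_mm)
      strength_fit <- fit_linear(
        d, list(strength ~ MT_AF * depth_m, strength ~ MT_AF + depth_m,
                strength ~ MT_AF, strength ~ depth_m))
      readr::write_csv(tidy(strength_fit),
                       file.path(config$outdir, "strength_coefficients.csv"))
      readr::write_csv(strength_fit$aic_table,
                       file.path(config$outdir, "strength_aic.csv"))
      note("strength", nrow(d), stats::nobs(strength_fit$best),
           strength_fit$aic_table$formula[strength_fit$best_index])
    }
  })

  # -- morphometrics --------------------------------------------------------
  if (config$with_morpho && !is.null(shell)) {
    run_stage("morpho", {
      d <- dplyr::inner_join(shell, prof[, c("individual_id", "MT_AF")],
                             by = "individual_id")
      efas <- purrr::map(seq_len(nrow(d)), function(i) {
        o <- simulate_outline(max(d$SL_mm[i] / d$SH_mm[i], 0.6),
                              n_points = config$efa_points, noise_sd = 0.02,
                              seed = child_seed(config$seed, d$individual_id[i]))
        efa_normalize(efa_decompose(preprocess_outline(o, config$efa_points),
                                    n_harmonics = 16))
      })
      coefs <- efa_coef_table(efas, ids = d$individual_id)
      pca <- shape_pca(coefs, threshold = config$pca_threshold)
      readr::write_csv(pca$scores, file.path(config$outdir, "shape_pc_scores.csv"))
      mw <- manova_wilks(pca, d$depth_m)
      readr::write_csv(mw, file.path(config$outdir, "shape_manova.csv"))
      note("morpho", nrow(d), nrow(pca$scores),
           sprintf("Wilks lambda %.3f vs depth", mw$wilks_lambda))
    })
  } else {
    note("morpho", 0, 0, "skipped")
  }

  report <- structure(list(stages = dplyr::bind_rows(stages),
                           table1 = table1, table2 = table2,
                           depth_fit = dm, strength_fit = strength_fit,
                           pca = pca, config = config),
                      class = "run_report")
  write_report(report, config$outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$stages)
  invisible(x)
}

#' Write a run report to disk
#'
#' Machine-readable stage summary (CSV) plus a human-readable text report.
#'
#' @param report A `run_report`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir) && inherits(try(dir.create(dir, recursive = TRUE),
                                       silent = TRUE), "try-error")) {
    abort(sprintf("cannot write to '%s'", dir), class = "introshell_parameter_error")
  }
  stage_path <- file.path(dir, "run_stages.csv")
  readr::write_csv(report$stages, stage_path)
  txt <- c(sprintf("introshell run (seed %d)", report$config$seed),
           strrep("-", 40),
           utils::capture.output(as.data.frame(report$stages)))
  txt_path <- file.path(dir, "run_report.txt")
  writeLines(txt, txt_path)
  invisible(c(stage_path, txt_path))
}
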