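# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# 65-locus, 440-individual genotype table with the assay-flag structure of a
# diagnostic-panel QC ledger: 5 poor-clustering + 2 false-call + 21 ambiguous
# loci, 4 additional unflagged loci pushed above the missing threshold, and
# 4 QC-flagged individuals plus 1 individual missing most retained loci.
make_qc_fixture <- function(seed = 42) {
  withr::with_seed(seed, {
    n_ind <- 440
    loci <- sprintf("S%02d", 1:65)
    g <- matrix(sample(c(0, 0.5, 1), n_ind * 65, TRUE, c(0.9, 0.07, 0.03)), n_ind)
    colnames(g) <- loci
    flags <- tibble::tibble(
      locus_id = loci,
      cluster_fail = c(rep(TRUE, 5), rep(FALSE, 60)),
      false_call = c(rep(FALSE, 5), rep(TRUE, 2), rep(FALSE, 58)),
      ambiguous = c(rep(FALSE, 7), rep(TRUE, 21), rep(FALSE, 37))
    )
    for (j in 29:32) g[sample(n_ind, 100), j] <- NA  # > 20% missing
    ids <- sprintf("i%03d", seq_len(n_ind))
    gt <- dplyr::bind_cols(tibble::tibble(individual_id = ids),
                           tibble::as_tibble(g))
    gt[5, 1 + 33:65] <- NA  # all retained loci missing for individual 5
    ind_flags <- tibble::tibble(individual_id = ids[1:4], qc_fail = TRUE)
    list(genotypes = gt, locus_flags = flags, individual_flags = ind_flags)
  })
}

# Integer class-by-depth counts reconstructed from the printed per-depth
# composition (rows: 1/3/5/7 m; columns: ME, MT, ME x MG, ME x MT); the
# reconstruction itself is exercised in test-me1516.R via
# enumerate_class_counts().
table1_counts <- matrix(
  c(100, 0, 11, 7,
    93, 2, 21, 4,
    96, 0, 18, 3,
    69, 0, 13, 1),
  nrow = 4, byrow = TRUE,
  dimnames = list(c("1", "3", "5", "7"), c("ME", "MT", "ME x MG", "ME x MT"))
)

# Depth-stratified MT-positive counts and totals of the introgression summary
table2_mt_positive <- c(21, 22, 22, 11)
table2_n <- c(116, 118, 118, 83)
table2_depths <- c(1, 3, 5, 7)
table2_bins <- matrix(c(14, 2, 2, 3,
                        15, 4, 1, 2,
                        18, 1, 2, 1,
                        10, 1, 0, 0),
                      nrow = 4, byrow = TRUE,
                      dimnames = list(c("1", "3", "5", "7"),
                                      c("lt10", "b10_50", "b50_75", "gt75")))

# calls + depth tibbles from a count matrix, for tabulate_classes()
calls_from_counts <- function(counts) {
  rows <- list()
  k <- 0
  for (d in rownames(counts)) {
    for (cl in colnames(counts)) {
      nc <- counts[d, cl]
      if (nc == 0) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        individual_id = sprintf("x%04d", k + seq_len(nc)),
        species_class = cl, depth_m = as.numeric(d))
      k <- k + nc
    }
  }
  dplyr::bind_rows(rows)
}

# exact parametric ellipse sampled uniformly in the curve parameter
make_ellipse <- function(a = 2, b = 1, K = 360, phase = 0, angle = 0) {
  t <- 2 * pi * (seq_len(K) - 1) / K + phase
  x <- a * cos(t)
  y <- b * sin(t)
  tibble::tibble(x = x * cos(angle) - y * sin(angle),
                 y = x * sin(angle) + y * cos(angle))
}

rotate_outline <- function(o, angle) {
  tibble::tibble(x = o$x * cos(angle) - o$y * sin(angle),
                 y = o$x * sin(angle) + o$y * cos(angle))
}

# cyclic start-point shift of the discrete point set
shift_outline <- function(o, k) {
  n <- nrow(o)
  idx <- c((k + 1):n, seq_len(k))
  tibble::tibble(x = o$x[idx], y = o$y[idx])
}

efa_vector <- function(e) c(e$an, e$bn, e$cn, e$dn)

# binary disc mask by the pixel-center distance criterion (rows = y)
make_disc_mask <- function(r, pad = 3) {
  w <- ceiling(2 * r) + 2 * pad
  cx <- r + pad
  xx <- matrix(rep(0:(w - 1), each = w), w)
  yy <- t(xx)
  m <- matrix(0L, w, w)
  m[(xx - cx)^2 + (yy - cx)^2 <= r^2] <- 1L
  m
}

# MT_AF values distributed as the depth-stratified bin counts above: zeros
# for non-carriers, uniform draws within each bin range
draw_mt_af_by_bins <- function() {
  vals <- numeric(0)
  ranges <- list(c(0.015, 0.1), c(0.1, 0.5), c(0.5, 0.75), c(0.75, 1))
  for (d in seq_len(nrow(table2_bins))) {
    n_zero <- table2_n[d] - sum(table2_bins[d, ])
    v <- rep(0, n_zero)
    for (b in 1:4) {
      nb <- table2_bins[d, b]
      if (nb > 0) v <- c(v, stats::runif(nb, ranges[[b]][1], ranges[[b]][2]))
    }
    vals <- c(vals, v)
  }
  tibble::tibble(depth_m = rep(table2_depths, table2_n), mt_af = vals)
}

# one replicate of the strength parameter-recovery experiment: simulate n
# individuals under the additive generative model and refit by OLS
strength_recovery_fit <- function(n = 430, depth_slope = 0.135,
                                  mt_effect = -1.37, sd = 0.65) {
  d <- draw_mt_af_by_bins()
  d <- d[sample(nrow(d), n), ]
  d$strength <- 2.03 + depth_slope * (d$depth_m - 1) + mt_effect * d$mt_af +
    stats::rnorm(n, 0, sd)
  stats::coef(stats::lm(strength ~ mt_af + depth_m, data = d))
}
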