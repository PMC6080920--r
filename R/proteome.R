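# Label-free proteomics harmonization (LFQ with median-adjusted iBAQ
# fallback), max-normalization, differential expression, z-scores, and
# RNA-protein correlation by peptide-count quantiles.

#' Read a protein-group table
#'
#' Tab-separated with header: `group_id`, `gene_symbol`, `n_peptides`,
#' then `lfq_<sample>` and `ibaq_<sample>` columns. Zero intensities are
#' treated as missing at this stage (MaxQuant writes 0 for non-detects).
#' Groups with fewer than `min_peptides` peptides are dropped.
#'
#' @param path Path to the TSV.
#' @param min_peptides Minimum peptide count to retain a group. Default 2.
#' @return A tibble of retained protein groups.
#' @export
read_protein_groups <- function(path, min_peptides = 2) {
  x <- readr::read_tsv(path, show_col_types = FALSE, na = c("NA", "."))
  need <- c("group_id", "gene_symbol", "n_peptides")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(paste("protein table missing:", paste(missing, collapse = ", ")))
  }
  for (col in grep("^(lfq|ibaq)_", names(x), value = TRUE)) {
    x[[col]][!is.na(x[[col]]) & x[[col]] == 0] <- NA_real_
  }
  dplyr::filter(x, .data$n_peptides >= min_peptides)
}

#' Harmonize protein abundances from LFQ and iBAQ intensities
#'
#' Protein groups with an LFQ value in every sample use LFQ verbatim. For
#' groups missing LFQ in one or more samples, iBAQ intensities are used
#' instead, scaled per sample to the LFQ scale by the ratio
#' `median(LFQ) / median(iBAQ)` computed over the LFQ-complete groups.
#' Any abundance still missing or zero afterwards is floored to 1.
#'
#' @param records Protein-group tibble with `lfq_<sample>` and
#'   `ibaq_<sample>` columns (zeros already treated as missing).
#' @param samples Sample names; inferred from the `lfq_` columns when
#'   `NULL`.
#' @return `records` with `abundance_<sample>` columns (all >= 1) and a
#'   logical `lfq_complete` column.
#' @export
harmonize_abundance <- function(records, samples = NULL) {
  if (is.null(samples)) {
    samples <- intersect(sample_columns(records, "lfq"),
                         sample_columns(records, "ibaq"))
  }
  if (length(samples) == 0) abort("no lfq_/ibaq_<sample> column pairs found")
  lfq <- as.matrix(records[, paste0("lfq_", samples), drop = FALSE])
  ibaq <- as.matrix(records[, paste0("ibaq_", samples), drop = FALSE])
  complete <- rowSums(is.na(lfq)) == 0
  records$lfq_complete <- complete
  if (!any(complete)) {
    warn("no LFQ-complete records to anchor medians; iBAQ scale factor 1")
    scale <- rep(1, length(samples))
  } else {
    scale <- vapply(seq_along(samples), function(j) {
      med_l <- stats::median(lfq[complete, j], na.rm = TRUE)
      med_i <- stats::median(ibaq[complete, j], na.rm = TRUE)
      if (is.na(med_i) || med_i == 0) 1 else med_l / med_i
    }, numeric(1))
  }
  ab <- lfq
  for (j in seq_along(samples)) {
    fill <- !complete
    ab[fill, j] <- ibaq[fill, j] * scale[j]
  }
  ab[is.na(ab) | ab < 1] <- 1
  for (j in seq_along(samples)) {
    records[[paste0("abundance_", samples[j])]] <- unname(ab[, j])
  }
  records
}

#' Max-normalize harmonized abundances
#'
#' Each protein's abundance in each sample is divided by its maximum
#' abundance over samples, so every row has maximum 1.
#'
#' @param records Tibble with `abundance_<sample>` columns.
#' @param samples Sample names; inferred from the `abundance_` columns
#'   when `NULL`.
#' @return `records` with added `norm_abundance_<sample>` columns.
#' @export
normalize_max <- function(records, samples = NULL) {
  if (is.null(samples)) samples <- sample_columns(records, "abundance")
  ab <- as.matrix(records[, paste0("abundance_", samples), drop = FALSE])
  mx <- apply(ab, 1, max)
  for (j in seq_along(samples)) {
    records[[paste0("norm_abundance_", samples[j])]] <-
      unname(ab[, j] / mx)
  }
  records
}

#' Differential protein expression between two groups
#'
#' The fold change is the ratio of group means of harmonized abundance
#' (log2 reported); the p-value is a two-sided Welch t-test on log2
#' abundances. Proteins detected in only one group -- every abundance in
#' the other group floored at 1 while the detected group has at least one
#' value above 1 -- are exempt from the test and flagged via
#' `detected_only_in`; they are always part of the differential set.
#' Otherwise a protein is differential when `|log2fc| >= log2(fc_min)` and
#' `p < p_max`.
#'
#' @param records Tibble with `abundance_<sample>` columns.
#' @param groups Named character vector mapping sample name to cell type
#'   (two types; >= 2 samples per type for the t-test).
#' @param fc_min Minimum linear fold change. Default 2.
#' @param p_max Strict p-value cutoff. Default 0.05.
#' @return A tibble: `group_id`, `gene_symbol`, `log2fc` (first group over
#'   second), `p`, `q`, `detected_only_in` (`NA`, or a cell type), and
#'   `is_differential`.
#' @export
differential_proteins <- function(records, groups, fc_min = 2,
                                  p_max = 0.05) {
  types <- unique(unname(groups))
  if (length(types) != 2) abort("need exactly two cell types")
  cols1 <- paste0("abundance_", names(groups)[groups == types[1]])
  cols2 <- paste0("abundance_", names(groups)[groups == types[2]])
  a1 <- as.matrix(records[, cols1, drop = FALSE])
  a2 <- as.matrix(records[, cols2, drop = FALSE])
  mean1 <- rowMeans(a1)
  mean2 <- rowMeans(a2)
  log2fc <- log2(mean1 / mean2)
  only1 <- apply(a2, 1, function(v) all(v == 1)) & apply(a1, 1, max) > 1
  only2 <- apply(a1, 1, function(v) all(v == 1)) & apply(a2, 1, max) > 1
  detected_only_in <- dplyr::case_when(
    only1 ~ types[1], only2 ~ types[2], TRUE ~ NA_character_)
  p <- vapply(seq_len(nrow(records)), function(i) {
    x <- log2(a1[i, ]); y <- log2(a2[i, ])
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    }
    stats::t.test(x, y)$p.value
  }, numeric(1))
  p[!is.na(detected_only_in)] <- NA_real_
  q <- p
  tested <- !is.na(p)
  q[tested] <- benjamini_hochberg(p[tested])
  tibble(
    group_id = records$group_id,
    gene_symbol = records$gene_symbol,
    log2fc = log2fc, p = p, q = q,
    detected_only_in = detected_only_in,
    is_differential = !is.na(detected_only_in) |
      (tested & abs(log2fc) >= log2(fc_min) & !is.na(p) & p < p_max)
  )
}

#' Row-wise z-scores
#'
#' Each row is centred and scaled to `(x - mean) / sd` using the sample
#' standard deviation. Constant rows are emitted as all zeros and flagged.
#'
#' @param matrix Numeric matrix (or data frame), >= 2 columns.
#' @return A list: `z` (matrix of z-scores) and `constant` (logical vector
#'   flagging zero-variance rows).
#' @export
zscore_rows <- function(matrix) {
  m <- as.matrix(matrix)
  if (ncol(m) < 2) abort("z-scores need >= 2 columns")
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  constant <- sd == 0
  z <- (m - mu) / ifelse(constant, 1, sd)
  z[constant, ] <- 0
  list(z = z, constant = constant)
}

#' RNA-protein fold-change correlation by peptide-count quantiles
#'
#' Spearman rank correlation (average ranks for ties) between RNA and
#' protein log2 fold changes, globally and within peptide-count quantiles.
#' Quantile boundaries are the empirical quartiles of the peptide counts;
#' genes on a boundary go to the lower quantile.
#'
#' @param data Tibble with `rna_log2fc`, `protein_log2fc` and
#'   `n_peptides` columns (one row per matched gene).
#' @param n_quantiles Number of quantile bins. Default 4.
#' @return A list: `global` (Spearman rho over all genes) and
#'   `by_quantile` (tibble `quantile`, `n`, `rho`, `count_min`,
#'   `count_max`). Bins collapsing onto identical boundaries are merged
#'   with a warning.
#' @export
rna_protein_correlation <- function(data, n_quantiles = 4) {
  need <- c("rna_log2fc", "protein_log2fc", "n_peptides")
  stopifnot(all(need %in% names(data)))
  rho <- function(x, y) stats::cor(x, y, method = "spearman")
  probs <- seq_len(n_quantiles - 1) / n_quantiles
  brk <- stats::quantile(data$n_peptides, probs, type = 7)
  if (anyDuplicated(brk)) {
    warn("tied quantile boundaries: merging quantiles")
    brk <- unique(brk)
  }
  bin <- rowSums(outer(data$n_peptides, brk, ">")) + 1L
  by_q <- data |>
    dplyr::mutate(quantile = paste0("Q", bin)) |>
    dplyr::group_by(.data$quantile) |>
    dplyr::summarise(
      n = dplyr::n(),
      rho = rho(.data$rna_log2fc, .data$protein_log2fc),
      count_min = min(.data$n_peptides),
      count_max = max(.data$n_peptides),
      .groups = "drop"
    )
  list(global = rho(data$rna_log2fc, data$protein_log2fc),
       by_quantile = by_q)
}
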