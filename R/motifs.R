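# PWM scanning over genomic regions, the log2-ratio TFBS enrichment score
# with hypergeometric significance, and integration of hypomethylated
# TFBS hits with open-chromatin proximity and expression.

#' Scan regions for PWM matches on both strands
#'
#' Every window of motif length within each region is scored as the sum of
#' `log2(p_base / background_base)` over positions (bits), on the forward
#' sequence and its reverse complement. Windows scoring at or above the
#' motif's `score_threshold` are reported; reverse-strand hits are given
#' forward-axis coordinates.
#'
#' @param regions Tibble of intervals (`chrom`, `start`, `end`).
#' @param genome A named [Biostrings::DNAStringSet] (one entry per
#'   chromosome) or a path to a FASTA file.
#' @param pwm A [pwm()] object.
#' @param max_n_fraction Regions with more than this fraction of non-ACGT
#'   bases are skipped with a warning. Default 0.5.
#' @return A tibble of hits: `motif_id`, `chrom`, `start`, `end`,
#'   `strand`, `score`.
#' @export
scan_pwm <- function(regions, genome, pwm, max_n_fraction = 0.5) {
  stopifnot(inherits(pwm, "pwm"))
  genome <- load_genome(genome)
  check_intervals(regions, "scan regions")
  L <- ncol(pwm$matrix)
  lodds <- log2(pwm$matrix / pwm$background)
  hits <- vector("list", nrow(regions))
  n_skipped <- 0L
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    if (!chrom %in% names(genome)) abort(sprintf("chromosome %s not in genome",
                                                 chrom))
    clen <- length(genome[[chrom]])
    s0 <- regions$start[i]
    e0 <- regions$end[i]
    if (s0 < 0 || e0 > clen) abort("region out of sequence bounds")
    if (e0 - s0 < L) next
    seq <- as.character(Biostrings::subseq(genome[[chrom]], s0 + 1L, e0))
    base <- strsplit(seq, "")[[1]]
    code <- match(base, c("A", "C", "G", "T"))
    if (mean(is.na(code)) > max_n_fraction) {
      n_skipped <- n_skipped + 1L
      next
    }
    fwd <- window_scores(code, lodds)
    rev_code <- rev(5L - code)  # complement: A<->T (1<->4), C<->G (2<->3)
    rev <- window_scores(rev_code, lodds)
    n_win <- length(code) - L + 1L
    keep_f <- which(!is.na(fwd) & fwd >= pwm$score_threshold)
    keep_r <- which(!is.na(rev) & rev >= pwm$score_threshold)
    # reverse-strand window j (1-based on the RC) occupies forward window
    # n_win - j + 1.
    res <- dplyr::bind_rows(
      tibble(offset = keep_f, strand = "+", score = fwd[keep_f]),
      tibble(offset = n_win - keep_r + 1L, strand = "-",
             score = rev[keep_r])
    )
    if (nrow(res) > 0) {
      hits[[i]] <- tibble(
        motif_id = pwm$motif_id, chrom = chrom,
        start = s0 + res$offset - 1L, end = s0 + res$offset - 1L + L,
        strand = res$strand, score = res$score
      )
    }
  }
  out <- dplyr::bind_rows(hits)
  if (n_skipped > 0) {
    warn(sprintf("%d region(s) skipped: > %.0f%% non-ACGT bases",
                 n_skipped, 100 * max_n_fraction))
  }
  if (nrow(out) == 0) {
    out <- tibble(motif_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  strand = character(), score = numeric())
  }
  dplyr::distinct(out)
}

# Sliding-window log-odds scores for an integer-coded sequence; NA where a
# window contains a non-ACGT base.
window_scores <- function(code, lodds) {
  L <- ncol(lodds)
  n_win <- length(code) - L + 1L
  if (n_win < 1) return(numeric(0))
  vapply(seq_len(n_win), function(j) {
    idx <- code[j:(j + L - 1L)]
    if (anyNA(idx)) return(NA_real_)
    sum(lodds[cbind(idx, seq_len(L))])
  }, numeric(1))
}

load_genome <- function(genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(inherits(genome, "DNAStringSet"))
  genome
}

#' Windows around differentially methylated cytosines
#'
#' One window of `2 * flank` bp centred on each DMC position, clipped at
#' the chromosome start. With the default flank these are the 300-bp
#' windows used as TFBS scanning targets.
#'
#' @param dmcs Tibble with `chrom` and `pos` columns.
#' @param flank Half-window size in bp (> 0). Default 150.
#' @return Tibble of intervals, one per DMC, in input order.
#' @export
dmc_windows <- function(dmcs, flank = 150) {
  if (flank <= 0) abort("flank must be positive")
  tibble(chrom = dmcs$chrom,
         start = as.integer(pmax(dmcs$pos - flank, 0L)),
         end = as.integer(dmcs$pos + flank))
}

#' TFBS enrichment of target over background regions
#'
#' For each motif, the percentage of target and of background regions
#' containing at least one hit is computed; the enrichment score is
#' `log2(pct_target / pct_background)`. Significance is the upper
#' hypergeometric tail of the target hit count when drawing
#' `n_target` regions from the combined pool, with hit-bearing regions as
#' successes; q-values are Benjamini-Hochberg across motifs.
#'
#' @param target,background Tibbles of regions (`chrom`, `start`, `end`).
#' @param motifs List of [pwm()] objects.
#' @param genome DNAStringSet or FASTA path.
#' @return A tibble: `motif_id`, `n_target`, `n_background`, `pct_target`,
#'   `pct_background`, `enrichment` (`Inf` sentinel with `infinite` flag
#'   when only the background percentage is zero), `p`, `q`. Motifs with
#'   no hits anywhere are dropped with a warning.
#' @export
motif_enrichment <- function(target, background, motifs, genome) {
  stopifnot(nrow(target) > 0, nrow(background) > 0)
  genome <- load_genome(genome)
  rows <- purrr::map(motifs, function(pw) {
    th <- region_hit_count(target, genome, pw)
    bh <- region_hit_count(background, genome, pw)
    tibble(motif_id = pw$motif_id,
           hits_target = th, hits_background = bh)
  })
  out <- dplyr::bind_rows(rows)
  out <- motif_enrichment_stats(out, nrow(target), nrow(background))
  if (nrow(out) == 0) return(out)
  out$q <- benjamini_hochberg(out$p)
  out
}

# Enrichment score and hypergeometric tail from per-motif hit counts.
# Kept separate from the scanner so the arithmetic is checkable on
# constructed counts.
motif_enrichment_stats <- function(counts, n_target, n_background) {
  out <- counts
  out$n_target <- n_target
  out$n_background <- n_background
  out$pct_target <- 100 * out$hits_target / n_target
  out$pct_background <- 100 * out$hits_background / n_background
  both_zero <- out$pct_target == 0 & out$pct_background == 0
  if (any(both_zero)) {
    warn(sprintf("%d motif(s) dropped: no hits in target or background",
                 sum(both_zero)))
    out <- out[!both_zero, , drop = FALSE]
  }
  if (nrow(out) == 0) return(out)
  out$infinite <- out$pct_background == 0 & out$pct_target > 0
  out$enrichment <- ifelse(out$infinite, Inf,
                           log2(out$pct_target / out$pct_background))
  # Upper hypergeometric tail P(X >= hits_target): draws = n_target from
  # the combined pool, successes = combined hit-bearing regions.
  out$p <- stats::phyper(out$hits_target - 1,
                         out$hits_target + out$hits_background,
                         (n_target - out$hits_target) +
                           (n_background - out$hits_background),
                         n_target, lower.tail = FALSE)
  out
}

region_hit_count <- function(regions, genome, pw) {
  hits <- scan_pwm(regions, genome, pw)
  if (nrow(hits) == 0) return(0L)
  sum(overlaps_any(regions, hits))
}

#' Integrate TFBS hits with open chromatin, genes and expression
#'
#' Keeps motif hits lying within `max_dist` bp of the nearest ATAC peak
#' (any restriction; 0 when overlapping), assigns them to genes with the
#' promoter-extended window rule of [assign_peaks_to_genes()], and filters
#' to protein-coding genes present in the expression table. Returns
#' per-motif gene summaries and a per-gene count of distinct motifs.
#'
#' @param hits Tibble of motif hits from [scan_pwm()].
#' @param peaks Tibble of ATAC peaks (`chrom`, `start`, `end`).
#' @param ann An [annotation_set()].
#' @param expression Tibble with `gene_id`, `rna_log2fc`, `q` columns.
#' @param proteome Optional tibble with `gene_id`, `protein_log2fc`.
#' @param max_dist Maximum hit-to-peak distance in bp. Default 250.
#' @param sig_q Significance threshold on the expression q-value.
#'   Default 0.05.
#' @param upstream Gene-window upstream extension (bp). Default 2500.
#' @return A list with class `proximal_gene_summary`:
#'   `by_motif` (`motif_id`, `n_genes`, `n_significant`,
#'   `mean_rna_log2fc`, `genes` list-column) and `by_gene` (`gene_id`,
#'   `n_motifs`, `rna_log2fc`, `significant`, `protein_log2fc`).
#' @export
proximal_gene_integration <- function(hits, peaks, ann, expression,
                                      proteome = NULL, max_dist = 250,
                                      sig_q = 0.05, upstream = 2500) {
  stopifnot(inherits(ann, "annotation_set"))
  if (nrow(peaks) == 0) {
    warn("empty peak set: all hits dropped")
    hits <- hits[0, , drop = FALSE]
  } else {
    d <- distance_to_nearest(hits, peaks)
    hits <- hits[!is.na(d) & d <= max_dist, , drop = FALSE]
  }
  assigned <- assign_peaks_to_genes(hits, ann, upstream = upstream)
  assigned <- dplyr::filter(assigned, !is.na(.data$gene_id))
  coding <- ann$genes$gene_id[ann$genes$is_protein_coding]
  assigned <- dplyr::filter(assigned,
                            .data$gene_id %in% coding,
                            .data$gene_id %in% expression$gene_id)
  pairs <- dplyr::distinct(assigned[, c("motif_id", "gene_id")])
  pairs <- dplyr::left_join(pairs,
                            expression[, c("gene_id", "rna_log2fc", "q")],
                            by = "gene_id")
  pairs$significant <- pairs$q < sig_q
  if (!is.null(proteome)) {
    pairs <- dplyr::left_join(
      pairs, proteome[, c("gene_id", "protein_log2fc")], by = "gene_id")
  } else {
    pairs$protein_log2fc <- NA_real_
  }
  by_motif <- pairs |>
    dplyr::group_by(.data$motif_id) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_significant = sum(.data$significant),
      mean_rna_log2fc = mean(.data$rna_log2fc),
      genes = list(dplyr::pick("gene_id", "rna_log2fc", "significant",
                               "protein_log2fc")),
      .groups = "drop"
    )
  by_gene <- pairs |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_motifs = dplyr::n_distinct(.data$motif_id),
      rna_log2fc = .data$rna_log2fc[1],
      significant = .data$significant[1],
      protein_log2fc = .data$protein_log2fc[1],
      .groups = "drop"
    )
  structure(list(by_motif = by_motif, by_gene = by_gene),
            class = "proximal_gene_summary")
}

#' @export
print.proximal_gene_summary <- function(x, ...) {
  cat(sprintf("<proximal_gene_summary> %d motifs, %d genes\n",
              nrow(x$by_motif), nrow(x$by_gene)))
  invisible(x)
}
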