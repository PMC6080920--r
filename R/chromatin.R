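# Lineage-restricted vs shared open-chromatin peaks and per-gene peak
# counting within a strand-aware promoter-extended window.

#' Classify peaks as lineage-restricted or shared
#'
#' A peak is `shared` iff it overlaps (>= 1 bp, half-open intervals) at
#' least one peak called in the other cell type; otherwise it is
#' `<cell_type>_only`. The relation is symmetric: every overlap partner is
#' also shared.
#'
#' @param peaks_basal,peaks_luminal Tibbles of peak intervals (`chrom`,
#'   `start`, `end`); either may be empty.
#' @param cell_types Length-2 character vector naming the two inputs.
#' @return One tibble with all peaks, columns `cell_type` and
#'   `restriction` (`basal_only`, `luminal_only`, or `shared`).
#' @export
classify_restriction <- function(peaks_basal, peaks_luminal,
                                 cell_types = c("basal", "luminal")) {
  check_intervals(peaks_basal, "basal peaks")
  check_intervals(peaks_luminal, "luminal peaks")
  shared_b <- overlaps_any(peaks_basal, peaks_luminal)
  shared_l <- overlaps_any(peaks_luminal, peaks_basal)
  b <- dplyr::mutate(as_tibble(peaks_basal),
                     cell_type = rep(cell_types[1], nrow(peaks_basal)),
                     restriction = ifelse(shared_b, "shared",
                                          paste0(cell_types[1], "_only")))
  l <- dplyr::mutate(as_tibble(peaks_luminal),
                     cell_type = rep(cell_types[2], nrow(peaks_luminal)),
                     restriction = ifelse(shared_l, "shared",
                                          paste0(cell_types[2], "_only")))
  b$restriction <- as.character(b$restriction)
  l$restriction <- as.character(l$restriction)
  dplyr::bind_rows(b, l)
}

# Strand-aware gene window: gene body extended `upstream` bp beyond the
# TSS end only ([TSS - upstream, body end) for +, [body start,
# TSS + upstream + 1) for -).
gene_windows <- function(genes, upstream = 2500) {
  start <- ifelse(genes$strand == "+", pmax(genes$start - upstream, 0L),
                  genes$start)
  end <- ifelse(genes$strand == "+", genes$end, genes$end + upstream)
  tibble(gene_id = genes$gene_id, chrom = genes$chrom,
         start = as.integer(start), end = as.integer(end))
}

#' Assign peaks to genes by window overlap
#'
#' A peak is assigned to every gene whose window -- the gene body extended
#' `upstream` bp upstream of the strand-aware TSS -- it overlaps by at
#' least 1 bp. A peak can map to several genes; peaks mapping to none are
#' retained with `gene_id = NA`.
#'
#' @param peaks Tibble of peaks (typically from [classify_restriction()]).
#' @param ann An [annotation_set()].
#' @param upstream Upstream extension in bp. Default 2500.
#' @return A tibble with one row per (peak, gene) pair plus one row per
#'   unassigned peak; carries a `peak_id` row index into `peaks`.
#' @export
assign_peaks_to_genes <- function(peaks, ann, upstream = 2500) {
  stopifnot(inherits(ann, "annotation_set"))
  peaks <- dplyr::mutate(as_tibble(peaks), peak_id = dplyr::row_number())
  windows <- gene_windows(ann$genes, upstream)
  if (nrow(peaks) == 0) {
    return(dplyr::mutate(peaks, gene_id = character(0)))
  }
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(peaks), as_granges(windows),
                                ignore.strand = TRUE))
  assigned <- peaks[S4Vectors::queryHits(hits), , drop = FALSE]
  assigned$gene_id <- windows$gene_id[S4Vectors::subjectHits(hits)]
  orphan <- peaks[!peaks$peak_id %in% assigned$peak_id, , drop = FALSE]
  if (nrow(orphan) > 0) orphan$gene_id <- NA_character_
  dplyr::arrange(dplyr::bind_rows(assigned, orphan), .data$peak_id)
}

#' Count assigned peaks per gene and cell type
#'
#' @param assignments Output of [assign_peaks_to_genes()]; must carry
#'   `cell_type` and `restriction` columns.
#' @param ann An [annotation_set()] supplying the full gene universe
#'   (genes with no peaks get zero counts).
#' @param restriction_filter `"all"` to count every assigned peak or
#'   `"restricted_only"` to drop shared peaks from both counts.
#' @param cell_types Length-2 character vector of cell-type labels.
#' @return A tibble `gene_id`, `n_peaks_<type>` for both types.
#' @export
count_peaks_per_gene <- function(assignments, ann,
                                 restriction_filter = c("all",
                                                        "restricted_only"),
                                 cell_types = c("basal", "luminal")) {
  restriction_filter <- rlang::arg_match(restriction_filter)
  x <- dplyr::filter(assignments, !is.na(.data$gene_id))
  if (restriction_filter == "restricted_only") {
    x <- dplyr::filter(x, .data$restriction != "shared")
  }
  counts <- dplyr::count(x, .data$gene_id, .data$cell_type)
  wide <- tidyr::pivot_wider(counts, names_from = "cell_type",
                             values_from = "n", values_fill = 0L)
  for (ct in cell_types) {
    if (!ct %in% names(wide)) wide[[ct]] <- 0L
  }
  out <- tibble(gene_id = ann$genes$gene_id)
  out <- dplyr::left_join(out, wide, by = "gene_id")
  for (ct in cell_types) {
    col <- paste0("n_peaks_", ct)
    out[[col]] <- as.integer(dplyr::coalesce(out[[ct]], 0L))
    out[[ct]] <- NULL
  }
  out
}
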