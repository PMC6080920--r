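# Readers and writers for the external formats consumed by the pipeline,
# plus the shared annotation container. All genomic coordinates are held
# 0-based half-open (BED convention); 1-based inputs are converted at the
# parser boundary.

#' Read a BED file of genomic intervals
#'
#' Parses a 3-6 column BED file into a tibble of 0-based half-open
#' intervals. `track` and `browser` lines and `#` comments are skipped;
#' input order is preserved.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present
#'   in the file, `name`, `score`, `strand`.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tpk1\t0\t+", f)
#' read_bed(f)
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    abort(sprintf("malformed BED line %d: fewer than 3 columns",
                  lineno[which(ncol < 3)[1]]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
  bad <- is.na(start) | is.na(end) | start < 0 | end <= start
  if (any(bad)) {
    abort(sprintf(
      "malformed BED line %d: non-integer coordinates or end <= start",
      lineno[which(bad)[1]]))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  if (all(ncol >= 4)) out$name <- vapply(fields, `[[`, character(1), 4)
  if (all(ncol >= 5)) {
    out$score <- suppressWarnings(
      as.numeric(vapply(fields, `[[`, character(1), 5)))
  }
  if (all(ncol >= 6)) out$strand <- vapply(fields, `[[`, character(1), 6)
  out
}

#' Write intervals to a BED file
#'
#' Inverse of [read_bed()]: the first three columns round-trip
#' byte-identically.
#'
#' @param x Tibble with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x, "BED intervals")
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED columns are positional: keep the longest unbroken prefix.
  want <- c("chrom", "start", "end", "name", "score", "strand")
  keep <- want[seq_len(match(FALSE, want %in% cols, nomatch = 7) - 1)]
  mat <- do.call(cbind, lapply(keep, function(k) as.character(x[[k]])))
  writeLines(apply(mat, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a per-sample CpG methylation count table
#'
#' Expects a tab-separated file with header columns `chrom`, `pos`,
#' `strand`, then one `meth_<sample>` / `unmeth_<sample>` pair per sample.
#' `pos` is 1-based in the file and converted to a 0-based position.
#' Beta-values (methylated / coverage) are computed per sample; samples
#' with zero coverage at a site get `NA`.
#'
#' @param path Path to the TSV.
#' @return A tibble with `chrom`, `pos` (0-based), `strand`, the count
#'   columns, and `beta_<sample>` columns.
#' @export
read_beta_table <- function(path) {
  stopifnot(file.exists(path))
  x <- readr::read_tsv(path, show_col_types = FALSE, na = c("NA", "."))
  missing <- setdiff(c("chrom", "pos"), names(x))
  if (length(missing) > 0) {
    abort(paste("beta table missing columns:", paste(missing, collapse = ", ")))
  }
  samples <- sample_columns(x, "meth")
  if (length(samples) == 0 ||
      !all(paste0("unmeth_", samples) %in% names(x))) {
    abort("beta table needs paired meth_<sample>/unmeth_<sample> columns")
  }
  counts <- as.matrix(x[, c(paste0("meth_", samples),
                            paste0("unmeth_", samples))])
  if (any(counts < 0, na.rm = TRUE) ||
      any(counts != floor(counts), na.rm = TRUE)) {
    abort("beta table: counts must be non-negative integers")
  }
  x$pos <- as.integer(x$pos) - 1L
  if (!"strand" %in% names(x)) x$strand <- "."
  compute_beta(x)
}

#' Add beta-value columns to a methylation count table
#'
#' @param sites Tibble with `meth_<sample>` and `unmeth_<sample>` columns.
#' @return `sites` with one `beta_<sample>` column per sample; `NA` where
#'   coverage is zero.
#' @export
compute_beta <- function(sites) {
  samples <- sample_columns(sites, "meth")
  for (s in samples) {
    m <- sites[[paste0("meth_", s)]]
    u <- sites[[paste0("unmeth_", s)]]
    cov <- m + u
    sites[[paste0("beta_", s)]] <- ifelse(cov > 0, m / cov, NA_real_)
  }
  sites
}

#' Read position weight matrices from JASPAR-like text
#'
#' Blocks start with a `>motif_id` header followed by four rows (A, C, G, T)
#' of counts or probabilities. Counts are converted to column probabilities
#' with a pseudocount of 0.25 added to every cell; columns already summing
#' to 1 are kept as-is. Rows may carry the `A [ 1 2 3 ]` JASPAR decoration.
#'
#' @param path Path to the PWM text file.
#' @param background Background base frequencies (A, C, G, T); must sum
#'   to 1. Default uniform.
#' @param threshold_fraction Per-motif log-odds score threshold as a
#'   fraction of the maximum achievable score. Default 0.8.
#' @return A named list of `pwm` objects (see [pwm()]).
#' @export
read_pwm <- function(path, background = rep(0.25, 4),
                     threshold_fraction = 0.8) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warn("empty PWM file; returning no motifs")
    return(list())
  }
  starts <- grep("^>", lines)
  if (length(starts) == 0) abort("PWM file has no '>' headers")
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    id <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) != 4) {
      abort(sprintf("PWM block '%s': expected 4 rows, got %d",
                    id, length(body)))
    }
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1) {
      abort(sprintf("PWM block '%s': ragged rows", id))
    }
    mat <- do.call(rbind, rows)
    rownames(mat) <- c("A", "C", "G", "T")
    out[[id]] <- pwm(id, mat, background = background,
                     threshold_fraction = threshold_fraction)
  }
  out
}

#' Construct a position weight matrix object
#'
#' Count matrices are converted to per-column probabilities with a +0.25
#' pseudocount per cell; probability matrices (columns summing to 1) pass
#' through unchanged.
#'
#' @param motif_id Motif name.
#' @param matrix 4 x L numeric matrix, rows A, C, G, T.
#' @param background Base frequencies summing to 1.
#' @param threshold_fraction Score threshold as a fraction of the maximum
#'   log-odds score; overridable per motif.
#' @param score_threshold Absolute log2-odds threshold (bits); overrides
#'   `threshold_fraction` when supplied.
#' @return An object of class `pwm`: list with `motif_id`, `matrix`
#'   (probabilities), `background`, `score_threshold`, `max_score`.
#' @export
pwm <- function(motif_id, matrix, background = rep(0.25, 4),
                threshold_fraction = 0.8, score_threshold = NULL) {
  stopifnot(is.matrix(matrix), nrow(matrix) == 4)
  if (ncol(matrix) < 4) abort("PWM must have length >= 4")
  if (any(matrix < 0)) abort("PWM entries must be non-negative")
  if (abs(sum(background) - 1) > 1e-9) abort("background must sum to 1")
  sums <- colSums(matrix)
  if (any(abs(sums - 1) > 1e-9)) {
    matrix <- sweep(matrix + 0.25, 2, sums + 1, "/")
  }
  rownames(matrix) <- c("A", "C", "G", "T")
  max_score <- sum(log2(apply(matrix, 2, max) / background[
    apply(matrix, 2, which.max)]))
  if (is.null(score_threshold)) {
    score_threshold <- threshold_fraction * max_score
  }
  structure(
    list(motif_id = motif_id, matrix = matrix,
         background = stats::setNames(background, c("A", "C", "G", "T")),
         score_threshold = score_threshold, max_score = max_score),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s: %d positions, threshold %.2f / max %.2f bits\n",
              x$motif_id, ncol(x$matrix), x$score_threshold, x$max_score))
  invisible(x)
}

#' Read a gene annotation table
#'
#' Tab-separated with header: `gene_id`, `name`, `chrom`, `start`, `end`
#' (0-based half-open gene body), `strand` (+/-), `is_protein_coding`
#' (TRUE/FALSE), and optional `exon_starts`/`exon_ends` (comma-separated,
#' 0-based). The strand-aware TSS is derived: `start` on + genes,
#' `end - 1` on - genes.
#'
#' @param path Path to the TSV.
#' @return A tibble of gene models with a `tss` column and `exons`
#'   list-column.
#' @export
read_gene_table <- function(path) {
  # exon lists are comma-separated and must not be parsed as grouped
  # numbers
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         exon_starts = readr::col_character(),
                         exon_ends = readr::col_character(),
                         .default = readr::col_guess()))
  need <- c("gene_id", "chrom", "start", "end", "strand")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(paste("gene table missing:", paste(missing, collapse = ", ")))
  }
  if (!"name" %in% names(x)) x$name <- x$gene_id
  if (!"is_protein_coding" %in% names(x)) x$is_protein_coding <- TRUE
  if (anyDuplicated(x$gene_id)) abort("gene_id values must be unique")
  x$is_protein_coding <- as.logical(x$is_protein_coding)
  if ("exon_starts" %in% names(x) && "exon_ends" %in% names(x)) {
    x$exons <- purrr::map2(x$exon_starts, x$exon_ends, function(s, e) {
      if (is.na(s) || !nzchar(s)) return(tibble(start = integer(),
                                                end = integer()))
      tibble(start = as.integer(strsplit(s, ",")[[1]]),
             end = as.integer(strsplit(e, ",")[[1]]))
    })
    x$exon_starts <- NULL
    x$exon_ends <- NULL
  } else {
    x$exons <- purrr::map2(x$start, x$end,
                           function(s, e) tibble(start = s, end = e))
  }
  gene_models(x)
}

#' Finalize a tibble of gene models
#'
#' Validates invariants and adds the strand-aware `tss` column.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `is_protein_coding`, and optional `exons` list-column.
#' @return The validated tibble with `tss`.
#' @export
gene_models <- function(genes) {
  check_intervals(genes, "gene bodies")
  stopifnot(all(genes$strand %in% c("+", "-")))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tss <- as.integer(genes$tss)
  if ("exons" %in% names(genes) && nrow(genes) > 0) {
    ok <- purrr::pmap_lgl(
      list(genes$exons, genes$start, genes$end),
      function(ex, s, e) {
        if (nrow(ex) == 0) return(TRUE)
        ex <- ex[order(ex$start), ]
        all(ex$start >= s) && all(ex$end <= e) &&
          all(ex$start[-1] >= ex$end[-nrow(ex)])
      })
    if (!all(ok)) abort("exons must be non-overlapping and nested in body")
  }
  as_tibble(genes)
}

#' Bundle gene models and CpG islands into an annotation set
#'
#' @param genes Gene-model tibble (see [gene_models()]).
#' @param cgi Tibble of CpG-island intervals (`chrom`, `start`, `end`).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(genes, cgi) {
  genes <- gene_models(genes)
  check_intervals(cgi, "CpG islands")
  structure(list(genes = genes, cgi = as_tibble(cgi)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d genes (%d protein-coding), %d CpG islands\n",
              nrow(x$genes), sum(x$genes$is_protein_coding), nrow(x$cgi)))
  invisible(x)
}

# Shared TSV writer: tab-delimited, UTF-8, '.' for missing.
write_tsv_dot <- function(x, path) {
  x <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
  readr::write_tsv(x, path, na = ".")
  invisible(path)
}
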