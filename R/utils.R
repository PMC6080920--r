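# Internal helpers shared across modules.

#' @importFrom rlang %||% abort warn .data :=
#' @importFrom tibble tibble as_tibble
NULL

# Round half away from zero (printed percentages in reports use this, not
# banker's rounding).
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Validate a tibble of genomic intervals (0-based half-open).
check_intervals <- function(x, what = "intervals") {
  stopifnot(is.data.frame(x))
  missing <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s must have columns %s", what,
                  paste(missing, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(x$start < 0)) abort(sprintf("%s: negative start", what))
    if (any(x$end <= x$start)) abort(sprintf("%s: end <= start", what))
  }
  invisible(x)
}

# Convert an interval tibble to GRanges. Internal coordinates are 0-based
# half-open; GRanges is 1-based closed, so start+1.
as_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  } else "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

# Row indices of `x` overlapping any interval in `y` (>= 1 shared bp,
# strand-ignorant).
overlaps_any <- function(x, y) {
  if (nrow(x) == 0) return(logical(0))
  if (nrow(y) == 0) return(rep(FALSE, nrow(x)))
  # disjoint seqlevels (a site on an unannotated chromosome) are an
  # expected no-overlap case, not a user-facing warning
  suppressWarnings(
    IRanges::overlapsAny(as_granges(x), as_granges(y),
                         ignore.strand = TRUE))
}

# Gap (bp) from each interval in x to the nearest interval in y; 0 when
# overlapping, NA when y is empty or on an absent chromosome.
distance_to_nearest <- function(x, y) {
  if (nrow(x) == 0) return(integer(0))
  if (nrow(y) == 0) return(rep(NA_integer_, nrow(x)))
  gx <- as_granges(x)
  gy <- as_granges(y)
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(gx, gy, ignore.strand = TRUE))
  out <- rep(NA_integer_, nrow(x))
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out
}

# Sample column names for a wide per-sample table given a column prefix.
sample_columns <- function(x, prefix) {
  nm <- grep(paste0("^", prefix, "_"), names(x), value = TRUE)
  sub(paste0("^", prefix, "_"), "", nm)
}
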