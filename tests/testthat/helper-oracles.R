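# Independent oracles and fixture builders used across the suite. Every
# oracle is deliberately brute-force / closed-form and shares no code
# with the implementation it checks.

# O(n*m) pairwise overlap of 0-based half-open intervals.
bf_overlaps_any <- function(x, y) {
  vapply(seq_len(nrow(x)), function(i) {
    any(y$chrom == x$chrom[i] & y$start < x$end[i] & y$end > x$start[i])
  }, logical(1))
}

# Brute-force gap distance to the nearest interval (0 when overlapping).
bf_distance <- function(x, y) {
  vapply(seq_len(nrow(x)), function(i) {
    same <- y[y$chrom == x$chrom[i], , drop = FALSE]
    if (nrow(same) == 0) return(NA_integer_)
    gaps <- ifelse(same$start < x$end[i] & same$end > x$start[i], 0L,
                   pmax(same$start - x$end[i], x$start[i] - same$end))
    as.integer(min(gaps))
  }, integer(1))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"),
                             max_pos = 10000, max_width = 300) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_width, n, replace = TRUE)
  )
}

# Exact two-sided Fisher p for a 2x2 table by enumerating the
# hypergeometric support and summing probabilities <= p(observed).
exact_fisher_2x2 <- function(a, b, c, d) {
  rs1 <- a + b
  cs1 <- a + c
  n <- a + b + c + d
  support <- max(0, cs1 - (n - rs1)):min(rs1, cs1)
  probs <- stats::dhyper(support, rs1, n - rs1, cs1)
  p_obs <- stats::dhyper(a, rs1, n - rs1, cs1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact upper hypergeometric tail P(X >= q) by direct summation.
exact_hyper_tail <- function(q, n_success, n_total, n_draw) {
  hi <- min(n_draw, n_success)
  if (q > hi) return(0)
  sum(stats::dhyper(q:hi, n_success, n_total - n_success, n_draw))
}

# Grid-search maximizer of the single-hit LDA likelihood over ln f:
# coarse pass over the full range, then a dense pass around the best
# coarse point, so the oracle frequency is accurate to ~1e-7 relative.
grid_lda_fit <- function(doses, n_grid = 10000) {
  ll_at <- function(v) {
    f <- exp(v)
    p <- pmin(pmax(1 - exp(-f * doses$dose), 1e-12), 1 - 1e-12)
    sum(doses$positive * log(p) + (doses$n - doses$positive) * log(1 - p))
  }
  lf <- seq(log(1e-8), log(0.5), length.out = n_grid)
  ll <- vapply(lf, ll_at, numeric(1))
  step <- lf[2] - lf[1]
  centre <- lf[which.max(ll)]
  fine <- seq(centre - 2 * step, centre + 2 * step, length.out = n_grid)
  ll_fine <- vapply(fine, ll_at, numeric(1))
  list(frequency = exp(fine[which.max(ll_fine)]),
       loglik = max(ll_fine), grid_ll = ll, grid_lf = lf)
}

# Minimal two-gene annotation used by feature-annotation tests.
# Layout on chr1 (0-based):
#   gene A: + strand, body [10000, 16000), exons [10000,11000) and
#           [15000,16000); promoter [7500, 10000)
#   gene B: - strand, body [30000, 36000), single exon = body;
#           promoter [36000, 38500)
#   CGI: [20000, 20800)
tiny_annotation <- function() {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"),
    name = c("GA", "GB"),
    chrom = "chr1",
    start = c(10000L, 30000L),
    end = c(16000L, 36000L),
    strand = c("+", "-"),
    is_protein_coding = TRUE,
    exons = list(
      tibble::tibble(start = c(10000L, 15000L), end = c(11000L, 16000L)),
      tibble::tibble(start = 30000L, end = 36000L)
    )
  )
  cgi <- tibble::tibble(chrom = "chr1", start = 20000L, end = 20800L)
  annotation_set(genes, cgi)
}

two_group_labels <- function() {
  stats::setNames(c("basal", "basal", "luminal", "luminal"),
                  c("basal_1", "basal_2", "luminal_1", "luminal_2"))
}

# Shared small study bundle (memoized; built once per test run).
.bundle_cache <- new.env(parent = emptyenv())
get_test_bundle <- function() {
  if (is.null(.bundle_cache$bundle)) {
    .bundle_cache$bundle <- simulate_study(simulation_config(
      seed = 424242L,
      n_chroms = 2L, chrom_length = 700000L, n_genes = 60L,
      n_cpg_background = 4000L, n_peaks = 200L
    ))
  }
  .bundle_cache$bundle
}

# DMC calls for the shared bundle (memoized).
get_test_dmcs <- function() {
  if (is.null(.bundle_cache$dmcs)) {
    b <- get_test_bundle()
    .bundle_cache$dmcs <- call_dmcs(b$cpg_sites, two_group_labels())
  }
  .bundle_cache$dmcs
}
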