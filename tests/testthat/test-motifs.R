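# Build a genome from explicit sequence strings.
string_genome <- function(...) {
  g <- Biostrings::DNAStringSet(c(...))
  g
}

sharp_pwm <- function(cons, p = 0.97, id = "m") {
  mat <- matrix((1 - p) / 3, nrow = 4, ncol = nchar(cons),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(nchar(cons))) {
    mat[substr(cons, j, j), j] <- p
  }
  pwm(id, mat)
}

test_that("consensus scoring matches the closed-form log-odds sum", {
  pw <- sharp_pwm("ACGT")
  g <- string_genome(chr1 = "TTTACGTTTT")
  hits <- scan_pwm(tibble::tibble(chrom = "chr1", start = 0L, end = 10L),
                   g, pw)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$start, 3L)
  expect_equal(fwd$end, 7L)
  expect_equal(fwd$score, 4 * log2(0.97 / 0.25), tolerance = 1e-12)
})

test_that("a uniform PWM scores every window zero", {
  pw <- pwm("flat", matrix(0.25, 4, 4))
  g <- string_genome(chr1 = "ACGTACGTAC")
  hits <- scan_pwm(tibble::tibble(chrom = "chr1", start = 0L, end = 10L),
                   g, pw)
  expect_true(all(hits$score == 0))
})

test_that("palindromic motifs hit identically on both strands", {
  pw <- sharp_pwm("ACGT")  # reverse complement of ACGT is ACGT
  g <- string_genome(chr1 = "GGACGTGGACGTGG")
  hits <- scan_pwm(tibble::tibble(chrom = "chr1", start = 0L, end = 14L),
                   g, pw)
  f <- hits[hits$strand == "+", c("start", "end")]
  r <- hits[hits$strand == "-", c("start", "end")]
  expect_equal(f[order(f$start), ], r[order(r$start), ],
               ignore_attr = TRUE)
})

test_that("reverse-strand hits are reported on the forward axis", {
  pw <- sharp_pwm("AACCG")  # RC: CGGTT
  g <- string_genome(chr1 = "TTTTCGGTTTTT")
  hits <- scan_pwm(tibble::tibble(chrom = "chr1", start = 0L, end = 12L),
                   g, pw)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 4L)
  expect_equal(hits$end, 9L)
})

test_that("regions dominated by non-ACGT bases are skipped with warning", {
  pw <- sharp_pwm("ACGT")
  g <- string_genome(chr1 = "NNNNNNNNAC")
  expect_warning(
    hits <- scan_pwm(tibble::tibble(chrom = "chr1", start = 0L, end = 10L),
                     g, pw),
    "non-ACGT")
  expect_equal(nrow(hits), 0)
  expect_error(
    scan_pwm(tibble::tibble(chrom = "chr1", start = 0L, end = 50L), g, pw),
    "bounds")
})

test_that("dmc_windows builds clipped 300-bp windows", {
  d <- tibble::tibble(chrom = "chr1", pos = c(1000L, 50L, 7000L))
  w <- dmc_windows(d)
  expect_equal(nrow(w), 3)
  expect_equal(w$start[1], 850L)
  expect_equal(w$end[1], 1150L)
  expect_equal(w$start[2], 0L)
  expect_equal(w$end[2], 200L)
  expect_error(dmc_windows(d, flank = 0), "positive")
})

test_that("enrichment score and hypergeometric tail match the examples", {
  counts <- tibble::tibble(motif_id = "m", hits_target = 40L,
                           hits_background = 100L)
  res <- mammomics:::motif_enrichment_stats(counts, 80L, 400L)
  expect_equal(res$pct_target, 50)
  expect_equal(res$pct_background, 25)
  expect_equal(res$enrichment, 1)
  expect_equal(res$p, exact_hyper_tail(40, 140, 480, 80),
               tolerance = 1e-12)

  eq <- mammomics:::motif_enrichment_stats(
    tibble::tibble(motif_id = "m", hits_target = 20L,
                   hits_background = 100L), 80L, 400L)
  expect_equal(eq$enrichment, 0)
})

test_that("hypergeometric tails match exact enumeration, totals <= 200", {
  withr::local_seed(13)
  for (i in 1:30) {
    n_t <- sample(5:100, 1)
    n_b <- sample(5:100, 1)
    h_t <- sample(0:n_t, 1)
    h_b <- sample(0:n_b, 1)
    if (h_t + h_b == 0) next
    res <- mammomics:::motif_enrichment_stats(
      tibble::tibble(motif_id = "m", hits_target = h_t,
                     hits_background = h_b), n_t, n_b)
    expect_equal(res$p, exact_hyper_tail(h_t, h_t + h_b, n_t + n_b, n_t),
                 tolerance = 1e-10)
  }
})

test_that("enrichment is antisymmetric under target/background swap", {
  a <- mammomics:::motif_enrichment_stats(
    tibble::tibble(motif_id = "m", hits_target = 30L,
                   hits_background = 12L), 60L, 80L)
  b <- mammomics:::motif_enrichment_stats(
    tibble::tibble(motif_id = "m", hits_target = 12L,
                   hits_background = 30L), 80L, 60L)
  expect_equal(a$enrichment, -b$enrichment)
})

test_that("a zero-hit background yields the infinite sentinel", {
  res <- mammomics:::motif_enrichment_stats(
    tibble::tibble(motif_id = "m", hits_target = 5L,
                   hits_background = 0L), 20L, 20L)
  expect_true(res$infinite)
  expect_equal(res$enrichment, Inf)
  expect_warning(
    drop <- mammomics:::motif_enrichment_stats(
      tibble::tibble(motif_id = "m", hits_target = 0L,
                     hits_background = 0L), 20L, 20L),
    "dropped")
  expect_equal(nrow(drop), 0)
})

test_that("planted 60%/20% consensus recovers enrichment near log2(3)", {
  withr::local_seed(31)
  n_win <- 120
  width <- 300L
  cons <- "TGTTTACGC"
  seqs <- vapply(seq_len(2 * n_win), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
          collapse = "")
  }, character(1))
  plant <- c(stats::runif(n_win) < 0.6, stats::runif(n_win) < 0.2)
  for (i in which(plant)) {
    substr(seqs[i], 100, 100 + nchar(cons) - 1) <- cons
  }
  g <- string_genome(chr1 = paste(seqs, collapse = ""))
  starts <- (seq_len(2 * n_win) - 1L) * width
  regions <- tibble::tibble(chrom = "chr1", start = starts,
                            end = starts + width)
  target <- regions[1:n_win, ]
  background <- regions[(n_win + 1):(2 * n_win), ]
  res <- motif_enrichment(target, background,
                          list(sharp_pwm(cons, id = "planted")), g)
  expect_equal(res$enrichment, log2(3), tolerance = 0.3 / log2(3))
  expect_lt(res$q, 0.01)
})

test_that("proximal integration applies the distance and coding filters", {
  ann <- tiny_annotation()
  hits <- tibble::tibble(
    motif_id = c("m1", "m1", "m2", "m3"),
    chrom = "chr1",
    start = c(10100L, 12000L, 10150L, 10200L),
    end = c(10110L, 12010L, 10160L, 10210L),
    strand = "+", score = 10
  )
  # peak at [10300,10500): hit1 is 190 bp away (kept), hit2 ~1.5 kb
  # (dropped), hits 3-4 within 250 bp (kept)
  peaks <- tibble::tibble(chrom = "chr1", start = 10300L, end = 10500L)
  expr <- tibble::tibble(gene_id = c("gA", "gB"),
                         rna_log2fc = c(1, 3), q = c(0.01, 0.2))
  res <- proximal_gene_integration(hits, peaks, ann, expr)
  expect_setequal(res$by_motif$motif_id, c("m1", "m2", "m3"))
  expect_equal(res$by_gene$n_motifs[res$by_gene$gene_id == "gA"], 3)
  # m1 keeps only the near hit -> single gene gA with rna_log2fc 1
  m1 <- res$by_motif[res$by_motif$motif_id == "m1", ]
  expect_equal(m1$n_genes, 1)
  expect_equal(m1$mean_rna_log2fc, 1)
  expect_equal(m1$n_significant, 1)
})

test_that("mean fold change averages over proximal genes", {
  ann <- tiny_annotation()
  hits <- tibble::tibble(
    motif_id = "m1", chrom = "chr1",
    start = c(10100L, 31000L), end = c(10110L, 31010L),
    strand = "+", score = 10)
  peaks <- tibble::tibble(chrom = "chr1", start = c(10100L, 31000L),
                          end = c(10200L, 31100L))
  expr <- tibble::tibble(gene_id = c("gA", "gB"),
                         rna_log2fc = c(1, 3), q = c(0.01, 0.01))
  res <- proximal_gene_integration(hits, peaks, ann, expr)
  expect_equal(res$by_motif$mean_rna_log2fc, 2)
  expect_equal(res$by_motif$n_genes, 2)
})

test_that("an empty peak set drops all hits with a warning", {
  ann <- tiny_annotation()
  hits <- tibble::tibble(motif_id = "m1", chrom = "chr1", start = 10100L,
                         end = 10110L, strand = "+", score = 10)
  expr <- tibble::tibble(gene_id = "gA", rna_log2fc = 1, q = 0.01)
  expect_warning(
    res <- proximal_gene_integration(
      hits, tibble::tibble(chrom = character(), start = integer(),
                           end = integer()), ann, expr),
    "empty")
  expect_equal(nrow(res$by_motif), 0)
})
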