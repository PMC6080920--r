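make_sites <- function(m1, u1, m2, u2) {
  # one replicate per group carries the pooled counts, the other zeros
  tibble::tibble(
    chrom = "chr1", pos = seq_along(m1) * 100L,
    meth_basal_1 = m1, unmeth_basal_1 = u1,
    meth_basal_2 = 0L, unmeth_basal_2 = 0L,
    meth_luminal_1 = m2, unmeth_luminal_1 = u2,
    meth_luminal_2 = 0L, unmeth_luminal_2 = 0L
  )
}

test_that("call_dmcs matches the exact hypergeometric oracle", {
  sites <- make_sites(5L, 95L, 30L, 70L)
  res <- call_dmcs(sites, two_group_labels())
  expect_equal(res$delta_beta, -0.25)
  expect_equal(res$direction, "hypo_in_basal")
  expect_equal(res$p, exact_fisher_2x2(5, 95, 30, 70), tolerance = 1e-10)
  # q = p for a single site; significant here
  expect_true(res$is_dmc)
})

test_that("symmetric counts are never DMCs and thresholds are strict", {
  same <- call_dmcs(make_sites(10L, 30L, 10L, 30L), two_group_labels())
  expect_equal(same$delta_beta, 0)
  expect_false(same$is_dmc)

  # |delta beta| just under 0.15 with overwhelming significance
  near <- call_dmcs(make_sites(851L, 149L, 1000L, 0L), two_group_labels())
  expect_lt(abs(near$delta_beta), 0.15)
  expect_lt(near$q, 1e-6)
  expect_false(near$is_dmc)
})

test_that("Fisher p agrees with exhaustive enumeration for totals <= 60", {
  withr::local_seed(5)
  for (i in 1:40) {
    tot <- sample(8:60, 1)
    a <- sample(0:tot, 1)
    b <- sample(0:(tot - a), 1)
    c <- sample(0:(tot - a - b), 1)
    d <- tot - a - b - c
    if ((a + b) == 0 || (c + d) == 0) next
    got <- mammomics:::fisher_p_2x2(a, b, c, d)
    expect_equal(got, min(exact_fisher_2x2(a, b, c, d), 1),
                 tolerance = 1e-8,
                 label = sprintf("table %d %d %d %d", a, b, c, d))
  }
})

test_that("benjamini_hochberg reproduces the hand-computed step-up", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(0.04, 5)), rep(0.04, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("select_top_variance keeps the right rows", {
  m <- matrix(stats::runif(300), nrow = 100)
  expect_length(select_top_variance(m, 0.15), 15)

  m2 <- rbind(c(0.5, 0.5, 0.5), c(0.1, 0.5, 0.9))
  expect_equal(select_top_variance(m2, 0.5), 2L)

  m3 <- rbind(c(0.1, 0.5), c(0.3, 0.5))  # variances 0.08 and 0.02
  expect_equal(select_top_variance(m3, 0.5), 1L)
  expect_error(select_top_variance(m3, 0), "fraction")
})

test_that("site features follow the documented precedence", {
  ann <- tiny_annotation()
  sites <- tibble::tibble(
    chrom = "chr1",
    pos = c(9000L,   # 1 kb upstream of + TSS -> promoter
            10500L,  # inside exon 1
            12000L,  # intron
            50000L,  # intergenic
            37000L,  # 1 kb upstream of - gene TSS (right side) -> promoter
            20400L,  # inside CGI
            23000L,  # 2.2 kb from island edge -> shelf? no: 2.2 <= 2 kb?
            26000L)  # > 4 kb -> open sea? 26000 - 20800 = 5200 -> open sea
  )
  res <- annotate_site_features(sites, ann)
  expect_equal(res$genic_feature[1:5],
               c("promoter", "exon", "intron", "intergenic", "promoter"))
  expect_equal(res$cgi_context[6], "cgi")
  # 23000 is 2,200 bp past the island edge (20800): shelf band
  expect_equal(res$cgi_context[7], "shelf")
  expect_equal(res$cgi_context[8], "open_sea")
  # 1 kb from the edge: shore
  shore <- annotate_site_features(
    tibble::tibble(chrom = "chr1", pos = 21800L), ann)
  expect_equal(shore$cgi_context, "shore")
})

test_that("sites on unknown chromosomes fall back to intergenic/open sea", {
  res <- annotate_site_features(
    tibble::tibble(chrom = "chrZ", pos = 100L), tiny_annotation())
  expect_equal(res$genic_feature, "intergenic")
  expect_equal(res$cgi_context, "open_sea")
})

test_that("permutation enrichment handles the at-the-mean and tail cases", {
  # normal-tail arithmetic is checked against pnorm directly
  ann <- tiny_annotation()
  withr::local_seed(42)
  bg <- tibble::tibble(chrom = "chr1",
                       pos = sample.int(60000L, 800L))
  dmc <- bg[sample.int(800L, 120L), ]
  res <- permutation_feature_enrichment(dmc, bg, ann, n_perm = 300,
                                        seed = 9)
  expect_setequal(res$feature,
                  c("promoter", "exon", "intron", "intergenic", "cgi",
                    "shore", "shelf", "open_sea"))
  ok <- !res$degenerate
  expect_equal(
    res$log_p[ok],
    stats::pnorm(res$observed[ok], res$expected_mean[ok],
                 res$expected_sd[ok],
                 lower.tail = res$observed[ok] <= res$expected_mean[ok],
                 log.p = TRUE))
  expect_true(all(is.finite(res$log_p[ok])))
  # negative-reciprocal rule
  expect_true(all(abs(res$fold_change) >= 1))
  under <- res$observed < res$expected_mean & ok
  expect_equal(res$fold_change[under],
               -res$expected_mean[under] / res$observed[under])
})

test_that("permutation enrichment is deterministic given a seed", {
  ann <- tiny_annotation()
  withr::local_seed(1)
  bg <- tibble::tibble(chrom = "chr1", pos = sample.int(60000L, 500L))
  dmc <- bg[1:60, ]
  a <- permutation_feature_enrichment(dmc, bg, ann, n_perm = 100, seed = 4)
  b <- permutation_feature_enrichment(dmc, bg, ann, n_perm = 100, seed = 4)
  expect_equal(a, b)
  c <- permutation_feature_enrichment(dmc, bg, ann, n_perm = 100, seed = 5)
  expect_false(identical(a$expected_mean, c$expected_mean))
})

test_that("expected overlap converges to |dmcs| x feature fraction", {
  ann <- tiny_annotation()
  withr::local_seed(2)
  bg <- tibble::tibble(chrom = "chr1", pos = sample.int(60000L, 1000L))
  dmc <- bg[sample.int(1000L, 200L), ]
  res <- permutation_feature_enrichment(dmc, bg, ann, n_perm = 2000,
                                        seed = 3)
  feat <- annotate_site_features(bg, ann)
  f_prom <- mean(feat$genic_feature == "promoter")
  row <- res[res$feature == "promoter", ]
  expect_equal(row$expected_mean, 200 * f_prom,
               tolerance = 3 * row$expected_sd / sqrt(2000) /
                 (200 * f_prom))
})

test_that("complementing a feature flips the fold-change sign", {
  # A one-feature world: sites either in promoters or not; enrich the
  # promoter side, then check its complement (intergenic) is depleted.
  ann <- tiny_annotation()
  withr::local_seed(7)
  bg <- tibble::tibble(chrom = "chr1", pos = sample.int(60000L, 1000L))
  feat <- annotate_site_features(bg, ann)
  in_prom <- feat$genic_feature == "promoter"
  dmc <- dplyr::bind_rows(bg[in_prom, ][1:20, ],
                          bg[!in_prom, ][1:20, ])
  res <- permutation_feature_enrichment(dmc, bg, ann, n_perm = 400,
                                        seed = 8)
  prom_fc <- res$fold_change[res$feature == "promoter"]
  expect_gt(prom_fc, 1)
  # promoter share among DMCs is 50% vs ~4% background, so every other
  # genic class must be depleted
  other <- res$fold_change[res$feature %in% c("intergenic")]
  expect_lt(other, 0)
})

test_that("dmcs outside the background are rejected", {
  bg <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L))
  expect_error(
    permutation_feature_enrichment(
      tibble::tibble(chrom = "chr1", pos = 300L), bg, tiny_annotation(),
      n_perm = 10),
    "subset")
})
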