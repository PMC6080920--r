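layer_row <- function(gene_id = "g1", pb = 0L, pl = 0L, db = 0L, dl = 0L,
                      rb = 1, rl = 1, prb = 1, prl = 1) {
  tibble::tibble(gene_id = gene_id, n_peaks_basal = pb,
                 n_peaks_luminal = pl, n_hypo_dmc_basal = db,
                 n_hypo_dmc_luminal = dl, rna_basal = rb, rna_luminal = rl,
                 protein_basal = prb, protein_luminal = prl)
}

test_that("layer states use strict dominance and strict twofold rules", {
  d <- dplyr::bind_rows(
    layer_row("g1", pb = 3L, pl = 1L),
    layer_row("g2", pb = 2L, pl = 2L),
    layer_row("g3", rb = 8, rl = 2),      # ratio 4
    layer_row("g4", rb = 4, rl = 2),      # ratio exactly 2
    layer_row("g5", dl = 2L),
    layer_row("g6")
  )
  st <- assign_layer_states(d)
  expect_equal(as.character(st$chromatin[1:2]), c("up_basal", "neutral"))
  expect_equal(as.character(st$rna[3:4]), c("up_basal", "neutral"))
  expect_equal(as.character(st$methylation[5]), "up_luminal")
  expect_true(all(as.character(unlist(st[6, -1])) == "neutral"))
})

test_that("genes missing a layer are excluded and counted", {
  d <- dplyr::bind_rows(layer_row("g1"), layer_row("g2", rb = NA))
  st <- assign_layer_states(d)
  expect_equal(st$gene_id, "g1")
  expect_equal(attr(st, "n_excluded"), 1L)
})

test_that("state enumeration conserves genes and ranks by frequency", {
  d <- dplyr::bind_rows(
    layer_row("g1"), layer_row("g2"), layer_row("g3"),
    layer_row("g4", pb = 2L), layer_row("g5", pb = 2L)
  )
  st <- assign_layer_states(d)
  tab <- enumerate_states(st)
  expect_equal(sum(tab$n), 5)
  expect_equal(tab$n[tab$is_reference], 3L)
  expect_true(all(diff(tab$n) <= 0))
  # permutation invariance
  tab2 <- enumerate_states(st[sample.int(5), ])
  expect_equal(tab, tab2)
})

test_that("association log-odds equals the contingency closed form", {
  # counts n11=30 n10=20 n01=10 n00=40 for the up_basal direction
  states <- dplyr::bind_rows(
    tidyr::uncount(tibble::tibble(chromatin = "up_basal", rna = "up_basal"), 30),
    tidyr::uncount(tibble::tibble(chromatin = "up_basal", rna = "neutral"), 20),
    tidyr::uncount(tibble::tibble(chromatin = "neutral", rna = "up_basal"), 10),
    tidyr::uncount(tibble::tibble(chromatin = "neutral", rna = "neutral"), 40)
  )
  states$gene_id <- paste0("g", seq_len(nrow(states)))
  states$chromatin <- factor(states$chromatin,
                             c("up_basal", "up_luminal", "neutral"))
  states$rna <- factor(states$rna, c("up_basal", "up_luminal", "neutral"))
  states$methylation <- factor("neutral",
                               c("up_basal", "up_luminal", "neutral"))
  states$protein <- states$methylation
  res <- fit_layer_association(states, "chromatin", "rna")
  row <- res[res$category == "up_basal", ]
  expect_equal(row$log_odds, log(6), tolerance = 1e-12)
  expect_equal(row$se, sqrt(1 / 30 + 1 / 20 + 1 / 10 + 1 / 40),
               tolerance = 1e-12)
  expect_equal(row$p, 2 * stats::pnorm(-abs(log(6) / row$se)),
               tolerance = 1e-12)
})

test_that("closed-form log-odds equals a multinomial logit fit", {
  skip_if_not_installed("nnet")
  st <- simulate_layer_states(1500, log_odds = 1.2, seed = 77)
  ours <- fit_layer_association(st, "chromatin", "rna")
  for (d in c("up_basal", "up_luminal")) {
    y <- stats::relevel(factor(as.character(st$rna)), ref = "neutral")
    x <- as.integer(st$chromatin == d)
    fit <- nnet::multinom(y ~ x, trace = FALSE, reltol = 1e-14,
                          maxit = 1000)
    coef_d <- stats::coef(fit)[d, "x"]
    expect_equal(ours$log_odds[ours$category == d], coef_d,
                 tolerance = 1e-6)
  }
})

test_that("empty cells trigger the flagged Haldane correction", {
  st <- simulate_layer_states(60, log_odds = 0, seed = 5)
  st$rna <- factor(ifelse(as.character(st$chromatin) == "up_basal",
                          "up_basal", "neutral"),
                   levels(st$rna))  # perfect association: zero cells
  res <- fit_layer_association(st, "chromatin", "rna")
  row <- res[res$category == "up_basal", ]
  expect_true(row$haldane)
  expect_true(is.finite(row$log_odds))
})

test_that("a constant predictor is flagged degenerate", {
  st <- simulate_layer_states(50, log_odds = 0, seed = 6)
  st$chromatin <- factor("neutral", levels(st$chromatin))
  res <- fit_layer_association(st, "chromatin", "rna")
  expect_true(all(res$degenerate))
  expect_true(all(is.na(res$p)))
})

test_that("swapping lineage labels negates every log-odds", {
  st <- simulate_layer_states(2000, log_odds = 1.5, seed = 42)
  swap <- function(f) {
    factor(dplyr::case_match(as.character(f),
                             "up_basal" ~ "up_luminal",
                             "up_luminal" ~ "up_basal",
                             .default = "neutral"),
           levels(f))
  }
  st2 <- dplyr::mutate(st, dplyr::across(
    c("chromatin", "methylation", "rna", "protein"), swap))
  a <- fit_layer_association(st, "chromatin", "rna")
  b <- fit_layer_association(st2, "chromatin", "rna")
  merged <- merge(a, b, by = "category")
  # up_basal in the swapped data mirrors up_luminal in the original
  a_b <- a$log_odds[a$category == "up_basal"]
  b_l <- b$log_odds[b$category == "up_luminal"]
  expect_equal(a_b, b_l, tolerance = 1e-12)
  expect_equal(a$log_odds[a$category == "up_luminal"],
               b$log_odds[b$category == "up_basal"], tolerance = 1e-12)
})

test_that("state assignment is total on the complete universe", {
  b <- get_test_bundle()
  truth <- b$ground_truth$gene_states
  d <- tibble::tibble(
    gene_id = truth$gene_id,
    n_peaks_basal = 1L, n_peaks_luminal = 1L,
    n_hypo_dmc_basal = 0L, n_hypo_dmc_luminal = 0L,
    rna_basal = 2^(truth$rna_log2fc / 2),
    rna_luminal = 2^(-truth$rna_log2fc / 2),
    protein_basal = 2^(truth$protein_log2fc / 2),
    protein_luminal = 2^(-truth$protein_log2fc / 2)
  )
  st <- assign_layer_states(d)
  expect_equal(nrow(st), nrow(d))
  expect_false(any(is.na(st$rna)))
  # and the realized RNA states match the planted ternary truth
  expect_equal(as.character(st$rna), truth$rna)
})

test_that("concordance percentages reproduce printed ratio summaries", {
  # RNA-up gene sets whose peak associations split 662/880 and 589/822
  mk <- function(n_match, n_other, dir, prefix) {
    other <- setdiff(c("basal", "luminal"), dir)
    tibble::tibble(
      gene_id = paste0(prefix, seq_len(n_match + n_other)),
      kind = "peak",
      direction = c(rep(dir, n_match), rep(other, n_other))
    )
  }
  assoc <- dplyr::bind_rows(mk(662, 880 - 662, "basal", "b"),
                            mk(589, 822 - 589, "luminal", "l"))
  up <- tibble::tibble(
    gene_id = assoc$gene_id,
    layer = "rna",
    direction = rep(c("basal", "luminal"), c(880, 822))
  )
  res <- concordance_table(up, assoc)
  expect_equal(res$percent[res$direction == "basal"], 75)
  expect_equal(res$numerator[res$direction == "basal"], 662)
  expect_equal(res$denominator[res$direction == "basal"], 880)
  expect_equal(res$percent[res$direction == "luminal"], 72)
})

test_that("concordance handles zero numerators and denominators", {
  up <- tibble::tibble(gene_id = c("g1", "g2"), layer = "rna",
                       direction = "basal")
  assoc <- tibble::tibble(gene_id = "g1", kind = "peak",
                          direction = "luminal")
  res <- concordance_table(up, assoc)
  expect_equal(res$percent, 0)
  res2 <- concordance_table(up, assoc[0, ])
  expect_equal(nrow(res2), 0)  # no association kinds at all
  assoc3 <- tibble::tibble(gene_id = "gX", kind = "dmc",
                           direction = "basal")
  res3 <- concordance_table(up, assoc3)
  expect_true(is.na(res3$percent))
})

test_that("marker report reproduces the signature fractions", {
  genes <- sprintf("m%02d", 1:22)
  st <- tibble::tibble(
    gene_id = genes,
    chromatin = factor("up_basal", c("up_basal", "up_luminal", "neutral")),
    methylation = factor("neutral", c("up_basal", "up_luminal", "neutral")),
    rna = factor("up_basal", c("up_basal", "up_luminal", "neutral")),
    protein = factor("up_basal", c("up_basal", "up_luminal", "neutral"))
  )
  pk <- tibble::tibble(gene_id = genes,
                       n_peaks_basal = c(rep(3L, 20), 0L, 0L),
                       n_peaks_luminal = c(rep(1L, 20), 3L, 3L))
  z <- matrix(0, nrow = 22, ncol = 4, dimnames = list(genes, NULL))
  rep_out <- marker_signature_report(
    genes, st, z, z, hypomethylated = genes[1:6], peak_counts = pk)
  s <- rep_out$summary
  expect_equal(s$percent[s$measure == "chromatin_concordant"], 91)
  expect_equal(s$numerator[s$measure == "chromatin_concordant"], 20)
  expect_equal(s$percent[s$measure == "unmethylated"], 73)
  expect_equal(s$numerator[s$measure == "unmethylated"], 16)
  expect_equal(s$percent[s$measure == "rna_protein_concordant"], 100)

  empty <- marker_signature_report(character(0), st, z, z, character(0),
                                   pk)
  expect_equal(nrow(empty$markers), 0)
})

test_that("markers outside the universe are listed with missing fields", {
  st <- tibble::tibble(
    gene_id = "g1",
    chromatin = factor("neutral", c("up_basal", "up_luminal", "neutral")),
    methylation = factor("neutral", c("up_basal", "up_luminal", "neutral")),
    rna = factor("neutral", c("up_basal", "up_luminal", "neutral")),
    protein = factor("neutral", c("up_basal", "up_luminal", "neutral"))
  )
  z <- matrix(0, 1, 2, dimnames = list("g1", NULL))
  pk <- tibble::tibble(gene_id = "g1", n_peaks_basal = 1L,
                       n_peaks_luminal = 0L)
  rep_out <- marker_signature_report(c("g1", "absent"), st, z, z,
                                     character(0), pk)
  expect_false(rep_out$markers$in_universe[2])
  expect_true(is.na(rep_out$markers$rna_state[2]))
})
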