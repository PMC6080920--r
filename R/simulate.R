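# Seeded synthetic study generator: genome, gene models, CpG methylome
# with planted DMCs, open-chromatin peaks, motifs, expression, proteome
# and limiting-dilution tables, with recorded ground truth. The defaults
# emulate the study design the pipeline is built for: two cell types
# (basal, luminal), two bisulfite/ATAC/proteome replicates per type, four
# expression replicates, planted promoter-biased DMCs, lineage-restricted
# peaks, planted motif sites, correlated RNA/protein fold changes with
# LFQ missingness backed by iBAQ, and single-hit limiting-dilution
# outcomes.

#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulate_study()]. Defaults
#' are the package's reference study conditions.
#'
#' @param seed Integer RNG seed; recorded in the ground truth.
#' @param n_chroms Number of chromosomes. Default 2.
#' @param chrom_length Chromosome length in bp. Default 3500000.
#' @param n_genes Number of genes. Default 240.
#' @param n_cpg_background Number of background CpG sites (covered in all
#'   samples). Default 8000.
#' @param dmc_rate Fraction of background CpGs planted as DMCs.
#'   Default 0.06.
#' @param promoter_enrichment_fold Planted observed/expected ratio of
#'   promoter DMC overlap (the permutation statistic's target).
#'   Default 3.
#' @param n_peaks Open-chromatin peaks per cell type. Default 500.
#' @param peak_shared_fraction Fraction of peaks shared between cell
#'   types. Default 0.4.
#' @param motif_plant_rates Named list per motif: numeric `c(target,
#'   background)` planting rates for consensus embedding.
#' @param layer_log_odds Named numeric: planted association log-odds for
#'   `chromatin_rna` and `rna_protein`. Default 1.5 each.
#' @param rna_protein_rho_by_quantile Length-4 numeric; true Spearman
#'   correlation of RNA vs protein fold change per peptide-count
#'   quantile. Default c(0.2, 0.35, 0.45, 0.6).
#' @param lfq_missing_rate Per-cell probability that an LFQ intensity is
#'   missing (backed by iBAQ). Default 0.15.
#' @param protein_floor_fraction Fraction of protein groups detected in
#'   only one cell type (other type floored). Default 0.05.
#' @param lda_true_frequency True repopulating-unit frequency.
#'   Default 1/2000.
#' @param lda_doses Cells-per-injection schedule. Default
#'   c(500, 2000, 10000).
#' @param lda_n_per_dose Injections per dose. Default 12.
#' @return A validated list with class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 2L,
                              chrom_length = 3500000L,
                              n_genes = 240L,
                              n_cpg_background = 8000L,
                              dmc_rate = 0.06,
                              promoter_enrichment_fold = 3,
                              n_peaks = 500L,
                              peak_shared_fraction = 0.4,
                              motif_plant_rates = list(
                                FOXA1_like = c(0.6, 0.2),
                                TP63_like = c(0.45, 0.15)),
                              layer_log_odds = c(chromatin_rna = 1.5,
                                                 rna_protein = 1.5),
                              rna_protein_rho_by_quantile =
                                c(0.2, 0.35, 0.45, 0.6),
                              lfq_missing_rate = 0.15,
                              protein_floor_fraction = 0.05,
                              lda_true_frequency = 1 / 2000,
                              lda_doses = c(500, 2000, 10000),
                              lda_n_per_dose = 12L) {
  cfg <- as.list(environment())
  rates <- c(cfg$dmc_rate, cfg$peak_shared_fraction, cfg$lfq_missing_rate,
             cfg$protein_floor_fraction, unlist(cfg$motif_plant_rates))
  if (any(rates < 0 | rates > 1)) abort("rates/fractions must lie in [0,1]")
  if (cfg$lda_true_frequency <= 0 || cfg$lda_true_frequency >= 1) {
    abort("lda_true_frequency must be in (0,1)")
  }
  if (cfg$dmc_rate > 0.5) abort("dmc_rate implausibly large")
  if (cfg$dmc_rate * cfg$n_cpg_background > cfg$n_cpg_background) {
    abort("more DMCs than CpGs requested")
  }
  if (cfg$n_genes * 22000 > cfg$n_chroms * cfg$chrom_length) {
    abort("genome too small for the requested number of genes")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a complete synthetic study
#'
#' Generates every input layer the pipeline consumes, deterministically
#' for a given seed, together with the planted ground truth.
#'
#' @param cfg A [simulation_config()].
#' @return A list with class `study_bundle`: `genome` (DNAStringSet),
#'   `annotation` ([annotation_set()]), `cpg_sites` (count table),
#'   `peaks_basal`, `peaks_luminal`, `motifs` (list of [pwm()]),
#'   `expression`, `proteins`, `lda` (two-group dose table),
#'   `ground_truth` (list recording every planted parameter and
#'   membership), `config`.
#' @export
simulate_study <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::with_seed(cfg$seed, {
    genome <- sim_genome(cfg)
    ann <- sim_annotation(cfg)
    motifs <- sim_motifs()
    meth <- sim_methylome(cfg, ann)
    chrom_state <- sample(STATE_LEVELS, nrow(ann$genes), replace = TRUE,
                          prob = c(0.2, 0.2, 0.6))
    peaks <- sim_peaks(cfg, ann, chrom_state)
    expr_prot <- sim_expression_proteome(cfg, ann, chrom_state)
    genome <- plant_motifs(genome, motifs, meth, cfg)
    lda <- sim_lda(cfg)
    truth <- list(
      seed = cfg$seed,
      dmc_positions = meth$truth$dmc_positions,
      n_dmc = nrow(meth$truth$dmc_positions),
      promoter_enrichment_fold = cfg$promoter_enrichment_fold,
      planted_delta_beta = meth$truth$planted_delta_beta,
      peak_shared_fraction = cfg$peak_shared_fraction,
      layer_log_odds = as.list(cfg$layer_log_odds),
      gene_states = expr_prot$truth$gene_states,
      motif_plant_rates = cfg$motif_plant_rates,
      motif_planted_windows = attr(genome, "planted_windows"),
      rna_protein_rho_by_quantile = cfg$rna_protein_rho_by_quantile,
      lda_true_frequency = cfg$lda_true_frequency,
      lda_doses = cfg$lda_doses
    )
    structure(
      list(genome = genome, annotation = ann, cpg_sites = meth$sites,
           peaks_basal = peaks$basal, peaks_luminal = peaks$luminal,
           motifs = motifs, expression = expr_prot$expression,
           proteins = expr_prot$proteins, lda = lda,
           ground_truth = truth, config = cfg),
      class = "study_bundle"
    )
  })
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(paste0(
    "<study_bundle> seed %d: %d CpGs (%d planted DMCs), %d+%d peaks,\n",
    "  %d genes, %d protein groups, %d motifs, %d LDA rows\n"),
    x$config$seed, nrow(x$cpg_sites), x$ground_truth$n_dmc,
    nrow(x$peaks_basal), nrow(x$peaks_luminal), nrow(x$annotation$genes),
    nrow(x$proteins), length(x$motifs), nrow(x$lda)))
  invisible(x)
}

sim_genome <- function(cfg) {
  seqs <- vapply(seq_len(cfg$n_chroms), function(i) {
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE),
          collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- paste0("chr", seq_len(cfg$n_chroms))
  out
}

# Non-overlapping gene bodies 2-20 kb with 3-8 exons, both strands; CGIs
# at 30% of promoters plus scattered extras.
sim_annotation <- function(cfg) {
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  slot <- floor(cfg$chrom_length / (per_chrom + 1))
  genes <- purrr::map(seq_len(cfg$n_chroms), function(ci) {
    n <- min(per_chrom, cfg$n_genes - (ci - 1) * per_chrom)
    if (n <= 0) return(NULL)
    len <- sample(2000:20000, n, replace = TRUE)
    start <- (seq_len(n) - 1L) * slot + 4000L
    start <- pmin(start, cfg$chrom_length - len - 4000L)
    tibble(
      gene_id = sprintf("g%02d%03d", ci, seq_len(n)),
      chrom = paste0("chr", ci),
      start = as.integer(start),
      end = as.integer(start + len),
      strand = sample(c("+", "-"), n, replace = TRUE),
      is_protein_coding = stats::runif(n) < 0.9
    )
  }) |> dplyr::bind_rows()
  genes$name <- toupper(genes$gene_id)
  genes$exons <- purrr::map2(genes$start, genes$end, function(s, e) {
    k <- sample(3:8, 1)
    # Split the body into 2k+1 alternating segments; exons at odd slots.
    cuts <- sort(sample((s + 1):(e - 1), 2 * k))
    bounds <- c(s, cuts, e)
    tibble(start = bounds[seq(1, 2 * k + 1, by = 2)],
           end = bounds[seq(2, 2 * k + 2, by = 2)])
  })
  promoters <- promoter_windows(gene_models(genes), 2500)
  cgi_idx <- which(stats::runif(nrow(promoters)) < 0.3)
  cgi_prom <- tibble(
    chrom = promoters$chrom[cgi_idx],
    start = pmax(promoters$start[cgi_idx], promoters$end[cgi_idx] - 1200L),
    end = promoters$end[cgi_idx]
  )
  n_extra <- max(4L, round(0.1 * nrow(promoters)))
  extra <- tibble(
    chrom = sample(paste0("chr", seq_len(cfg$n_chroms)), n_extra,
                   replace = TRUE),
    start = sample.int(cfg$chrom_length - 2000L, n_extra)
  )
  extra$end <- extra$start + sample(500:1500, n_extra, replace = TRUE)
  annotation_set(genes, dplyr::bind_rows(cgi_prom, extra))
}

# Two small planted PWMs with sharp consensus columns.
sim_motifs <- function() {
  sharp <- function(cons) {
    mat <- matrix(0.04, nrow = 4, ncol = length(cons),
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_along(cons)) mat[cons[j], j] <- 0.88
    mat <- sweep(mat, 2, colSums(mat), "/")
    mat
  }
  list(
    FOXA1_like = pwm("FOXA1_like", sharp(c("T", "G", "T", "T", "T", "A",
                                           "C"))),
    TP63_like = pwm("TP63_like", sharp(c("C", "A", "T", "G", "G", "G",
                                         "T", "G")))
  )
}

# CpG background with planted DMCs: promoter overlap count planted at
# promoter_enrichment_fold x the uniform expectation, beta-binomial
# counts (dispersion rho = 0.05) with a >= 0.2 group beta shift at
# planted sites.
sim_methylome <- function(cfg, ann, coverage = 30, rho = 0.05) {
  n <- cfg$n_cpg_background
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  # CpGs are spaced >= 320 bp apart so the 300-bp scan windows around
  # them never overlap and per-window motif rates stay interpretable.
  per_chrom <- ceiling(n / cfg$n_chroms)
  sites <- purrr::map(chroms, function(ch) {
    cand <- sort(sample.int(cfg$chrom_length - 400L, min(
      3L * per_chrom, cfg$chrom_length - 400L)) + 200L)
    gap_ok <- logical(length(cand))
    last <- -1e9
    for (i in seq_along(cand)) {
      if (cand[i] - last >= 320L) {
        gap_ok[i] <- TRUE
        last <- cand[i]
      }
    }
    pos <- cand[gap_ok]
    tibble(chrom = ch, pos = pos[seq_len(min(per_chrom, length(pos)))])
  }) |> dplyr::bind_rows() |> dplyr::arrange(.data$chrom, .data$pos)
  n <- nrow(sites)
  feat <- annotate_site_features(sites, ann)
  is_prom <- feat$genic_feature == "promoter"
  f_prom <- mean(is_prom)
  n_dmc <- round(cfg$dmc_rate * n)
  n_prom_dmc <- min(round(cfg$promoter_enrichment_fold * f_prom * n_dmc),
                    sum(is_prom), n_dmc)
  prom_pick <- sample(which(is_prom), n_prom_dmc)
  rest_pick <- sample(which(!is_prom), n_dmc - n_prom_dmc)
  dmc_idx <- sort(c(prom_pick, rest_pick))
  is_dmc <- seq_len(n) %in% dmc_idx
  # Site-level overdispersion: one beta-binomial methylation level per
  # site shared by all samples, so non-DMC sites are identical between
  # groups (an exactly calibrated null) while site-to-site variation is
  # overdispersed. Planted DMCs shift the group levels apart by >= 0.25.
  base_mu <- ifelse(stats::runif(n) < 0.5, 0.15, 0.85)
  shape <- 1 / rho - 1
  p_site <- stats::rbeta(n, base_mu * shape, (1 - base_mu) * shape)
  delta <- stats::runif(n, 0.25, 0.5) * ifelse(stats::runif(n) < 0.5, 1, -1)
  # Re-centre DMC sites so the full planted shift always fits in
  # [0.02, 0.98] and |group difference| is exactly |delta| (>= 0.25).
  centre <- pmin(pmax(p_site, 0.02 + abs(delta) / 2),
                 0.98 - abs(delta) / 2)
  mu_basal <- ifelse(is_dmc, centre + delta / 2, p_site)
  mu_luminal <- ifelse(is_dmc, centre - delta / 2, p_site)
  draw <- function(p) {
    cov <- stats::rpois(n, coverage) + 5L
    m <- stats::rbinom(n, cov, p)
    list(meth = m, unmeth = cov - m)
  }
  for (s in c("basal_1", "basal_2")) {
    d <- draw(mu_basal)
    sites[[paste0("meth_", s)]] <- d$meth
    sites[[paste0("unmeth_", s)]] <- d$unmeth
  }
  for (s in c("luminal_1", "luminal_2")) {
    d <- draw(mu_luminal)
    sites[[paste0("meth_", s)]] <- d$meth
    sites[[paste0("unmeth_", s)]] <- d$unmeth
  }
  list(
    sites = sites,
    truth = list(
      dmc_positions = sites[is_dmc, c("chrom", "pos")],
      planted_delta_beta = mu_basal[is_dmc] - mu_luminal[is_dmc]
    )
  )
}

# Peaks per cell type, conditioned on the planted chromatin state: every
# gene gets an equal base count in both types plus an excess on the "up"
# side, so recomputing per-gene counts recovers the planted ternary
# state. A shared fraction is additionally placed (jittered) in both
# types, which preserves dominance.
sim_peaks <- function(cfg, ann, chrom_state) {
  windows <- gene_windows(ann$genes, 2500)
  n_genes <- nrow(windows)
  n_shared <- round(cfg$peak_shared_fraction * cfg$n_peaks)
  lambda <- max(0.3, (cfg$n_peaks - n_shared) / n_genes)
  base <- stats::rpois(n_genes, lambda)
  bonus <- 1L + stats::rpois(n_genes, 0.5)
  n_basal <- base + ifelse(chrom_state == "up_basal", bonus, 0L)
  n_luminal <- base + ifelse(chrom_state == "up_luminal", bonus, 0L)
  place_in <- function(counts) {
    idx <- rep(seq_len(n_genes), counts)
    w <- windows[idx, , drop = FALSE]
    k <- length(idx)
    width <- sample(200:600, k, replace = TRUE)
    start <- w$start + vapply(
      pmax(w$end - w$start - width, 1L),
      function(m) sample.int(m, 1), integer(1))
    tibble(chrom = w$chrom, start = as.integer(start),
           end = as.integer(start + width))
  }
  shared_idx <- sample.int(n_genes, n_shared, replace = TRUE)
  shared <- place_in(tabulate(shared_idx, n_genes))
  shared_l <- dplyr::mutate(shared, start = .data$start + 25L,
                            end = .data$end + 25L)
  basal <- dplyr::bind_rows(place_in(n_basal), shared)
  luminal <- dplyr::bind_rows(place_in(n_luminal), shared_l)
  list(basal = basal, luminal = luminal, n_shared = n_shared)
}

# Ternary layer states with planted chromatin->RNA and RNA->protein
# log-odds, realized as RNA/protein abundances and peptide-quantile
# correlated fold changes.
sim_expression_proteome <- function(cfg, ann, chrom_state) {
  genes <- ann$genes
  n <- nrow(genes)
  beta_cr <- cfg$layer_log_odds[["chromatin_rna"]]
  beta_rp <- cfg$layer_log_odds[["rna_protein"]]
  rna_state <- draw_conditioned_states(chrom_state, beta_cr,
                                       base = c(0.15, 0.15, 0.7))
  protein_state <- draw_conditioned_states(rna_state, beta_rp,
                                           base = c(0.15, 0.15, 0.7))
  # RNA abundances: neutral |log2fc| < 1, up states > 1 (ratio > 2).
  rna_l2fc <- ifelse(
    rna_state == "neutral", stats::runif(n, -0.9, 0.9),
    (1.2 + stats::rexp(n, 2)) * ifelse(rna_state == "up_basal", 1, -1))
  rna_base <- 2^stats::runif(n, 4, 10)
  expression <- tibble(
    gene_id = genes$gene_id,
    rna_basal = rna_base * 2^(rna_l2fc / 2),
    rna_luminal = rna_base * 2^(-rna_l2fc / 2),
    rna_log2fc = rna_l2fc,
    q = ifelse(rna_state == "neutral",
               stats::runif(n, 0.05, 1), stats::runif(n, 0, 0.049))
  )
  # Protein log2fc correlated with RNA log2fc, correlation rising with
  # peptide-count quantile.
  n_peptides <- pmax(2L, stats::rpois(n, 6L))
  qbin <- rowSums(outer(n_peptides,
                        stats::quantile(n_peptides, c(0.25, 0.5, 0.75)),
                        ">")) + 1L
  rho <- cfg$rna_protein_rho_by_quantile[qbin]
  z_r <- scale(rna_l2fc)[, 1]
  prot_l2fc_corr <- rho * z_r + sqrt(1 - rho^2) * stats::rnorm(n)
  # Magnitude honors the ternary protein state; correlated component used
  # for the neutral bulk so per-quantile rho is recoverable.
  prot_l2fc <- ifelse(
    protein_state == "neutral", 0.9 * tanh(prot_l2fc_corr / 2),
    (1.2 + stats::rexp(n, 2)) * ifelse(protein_state == "up_basal", 1, -1))
  prot_base <- 2^stats::runif(n, 14, 24)
  ab_basal <- prot_base * 2^(prot_l2fc / 2)
  ab_luminal <- prot_base * 2^(-prot_l2fc / 2)
  floor_only <- stats::runif(n) < cfg$protein_floor_fraction
  floor_side <- sample(c("basal", "luminal"), n, replace = TRUE)
  ab_basal[floor_only & floor_side == "luminal"] <- NA
  ab_luminal[floor_only & floor_side == "basal"] <- NA
  jitter <- function(x) x * 2^stats::rnorm(n, 0, 0.15)
  proteins <- tibble(
    group_id = paste0("PG_", genes$gene_id),
    gene_symbol = genes$name,
    gene_id = genes$gene_id,
    n_peptides = n_peptides,
    lfq_basal_1 = jitter(ab_basal), lfq_basal_2 = jitter(ab_basal),
    lfq_luminal_1 = jitter(ab_luminal), lfq_luminal_2 = jitter(ab_luminal)
  )
  for (col in c("lfq_basal_1", "lfq_basal_2", "lfq_luminal_1",
                "lfq_luminal_2")) {
    ib <- paste0("ibaq_", sub("^lfq_", "", col))
    proteins[[ib]] <- proteins[[col]] / 12  # iBAQ on its own scale
    drop <- !is.na(proteins[[col]]) &
      stats::runif(n) < cfg$lfq_missing_rate
    proteins[[col]][drop] <- NA
  }
  list(
    expression = expression,
    proteins = proteins,
    truth = list(gene_states = tibble(
      gene_id = genes$gene_id, chromatin = chrom_state,
      rna = rna_state, protein = protein_state,
      rna_log2fc = rna_l2fc, protein_log2fc = prot_l2fc,
      n_peptides = n_peptides, peptide_quantile = qbin))
  )
}

# Draw outcome states given predictor states: for each direction d the
# odds of outcome d (vs neutral) are multiplied by exp(beta) when the
# predictor is d, which plants exactly the contingency log-odds the
# association fit estimates.
draw_conditioned_states <- function(predictor, beta, base) {
  out <- character(length(predictor))
  for (p in unique(predictor)) {
    w <- base
    if (p == "up_basal") w[1] <- w[1] * exp(beta)
    if (p == "up_luminal") w[2] <- w[2] * exp(beta)
    idx <- predictor == p
    out[idx] <- sample(STATE_LEVELS, sum(idx), replace = TRUE,
                       prob = w / sum(w))
  }
  out
}

# Embed motif consensus sequences into the genome: in a configured
# fraction of hypomethylated-DMC target windows and of background
# (non-DMC) windows.
plant_motifs <- function(genome, motifs, meth, cfg) {
  truth_rows <- list()
  dmc_pos <- meth$truth$dmc_positions
  # background planting covers every non-DMC CpG window, so any draw of
  # non-DMC background windows sees the configured rate
  bg_pos <- dplyr::anti_join(meth$sites[, c("chrom", "pos")], dmc_pos,
                             by = c("chrom", "pos"))
  # Edit chromosomes as character vectors: one split/paste per chromosome
  # instead of one full-string copy per planted site.
  chars <- lapply(as.character(genome), function(s) strsplit(s, "")[[1]])
  embed <- function(windows, rate, motif, role, offset) {
    pick <- which(stats::runif(nrow(windows)) < rate)
    cons <- strsplit(consensus_string(motif), "")[[1]]
    for (i in pick) {
      at <- windows$pos[i] + offset - floor(length(cons) / 2)
      chrom <- windows$chrom[i]
      chars[[chrom]][(at + 1L):(at + length(cons))] <<- cons
      truth_rows[[length(truth_rows) + 1L]] <<-
        tibble(motif_id = motif$motif_id, chrom = chrom, start = at,
               end = at + length(cons), role = role)
    }
  }
  # Distinct per-motif offsets inside the 300-bp window keep plantings of
  # different motifs from overwriting each other.
  offsets <- c(-45L, 45L, -95L, 95L, 0L)
  for (k in seq_along(motifs)) {
    m <- names(motifs)[k]
    rates <- cfg$motif_plant_rates[[m]]
    if (is.null(rates)) next
    off <- offsets[((k - 1L) %% length(offsets)) + 1L]
    embed(dmc_pos, rates[1], motifs[[m]], "target", off)
    embed(bg_pos, rates[2], motifs[[m]], "background", off)
  }
  out <- Biostrings::DNAStringSet(
    vapply(chars, paste, character(1), collapse = ""))
  names(out) <- names(genome)
  attr(out, "planted_windows") <- dplyr::bind_rows(truth_rows)
  out
}

consensus_string <- function(pw) {
  paste(rownames(pw$matrix)[apply(pw$matrix, 2, which.max)], collapse = "")
}

#' Simulate two-group limiting-dilution outcomes
#'
#' @param cfg A [simulation_config()]; group "treated" uses a quarter of
#'   the vehicle frequency.
#' @return Tibble `group`, `dose`, `n`, `positive`.
#' @export
sim_lda <- function(cfg) {
  one <- function(f, label) {
    tibble(group = label, dose = cfg$lda_doses,
           n = cfg$lda_n_per_dose,
           positive = stats::rbinom(length(cfg$lda_doses),
                                    cfg$lda_n_per_dose,
                                    -expm1(-f * cfg$lda_doses)))
  }
  dplyr::bind_rows(one(cfg$lda_true_frequency, "vehicle"),
                   one(cfg$lda_true_frequency / 4, "treated"))
}

#' Simulate layer states alone
#'
#' Lightweight generator for association-recovery studies: chromatin
#' states drawn independently, RNA states conditioned on chromatin with
#' the planted log-odds.
#'
#' @param n_genes Number of genes.
#' @param log_odds Planted chromatin to RNA log-odds.
#' @param seed RNG seed.
#' @return A tibble compatible with [fit_layer_association()] (chromatin
#'   and rna columns; methylation and protein neutral).
#' @export
simulate_layer_states <- function(n_genes, log_odds, seed = 1L) {
  withr::with_seed(seed, {
    chrom <- sample(STATE_LEVELS, n_genes, replace = TRUE,
                    prob = c(0.2, 0.2, 0.6))
    rna <- draw_conditioned_states(chrom, log_odds,
                                   base = c(0.15, 0.15, 0.7))
    tibble(
      gene_id = paste0("g", seq_len(n_genes)),
      chromatin = factor(chrom, STATE_LEVELS),
      methylation = factor("neutral", STATE_LEVELS),
      rna = factor(rna, STATE_LEVELS),
      protein = factor("neutral", STATE_LEVELS)
    )
  })
}

#' Simulate matched RNA/protein fold changes by peptide quantile
#'
#' @param n_genes Number of genes.
#' @param rho_by_quantile Length-4 true correlations, Q1 to Q4.
#' @param seed RNG seed.
#' @return Tibble `gene_id`, `rna_log2fc`, `protein_log2fc`,
#'   `n_peptides`, `quantile`.
#' @export
simulate_rna_protein <- function(n_genes,
                                 rho_by_quantile = c(0.2, 0.35, 0.45, 0.6),
                                 seed = 1L) {
  withr::with_seed(seed, {
    # Draw peptide counts from a continuous-ish range so quartiles are
    # well separated.
    n_peptides <- sample(1:40, n_genes, replace = TRUE)
    qbin <- rowSums(outer(n_peptides,
                          stats::quantile(n_peptides, c(0.25, 0.5, 0.75)),
                          ">")) + 1L
    rho <- rho_by_quantile[qbin]
    x <- stats::rnorm(n_genes)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n_genes)
    tibble(gene_id = paste0("g", seq_len(n_genes)),
           rna_log2fc = x, protein_log2fc = y,
           n_peptides = n_peptides, quantile = qbin)
  })
}

#' Write a study bundle to disk
#'
#' Emits the exact file formats the readers consume: FASTA genome, BED
#' peak files, TSV tables (CpG counts with 1-based `pos`, genes, CGIs,
#' expression, protein groups, LDA) and `ground_truth.json`.
#'
#' @param bundle A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(bundle$genome, p("genome.fa"))
  write_bed(bundle$peaks_basal, p("peaks_basal.bed"))
  write_bed(bundle$peaks_luminal, p("peaks_luminal.bed"))
  cpg <- bundle$cpg_sites
  cpg$pos <- cpg$pos + 1L  # 1-based on disk
  cpg$strand <- "+"
  cpg <- cpg[, c("chrom", "pos", "strand",
                 setdiff(names(cpg), c("chrom", "pos", "strand")))]
  write_tsv_dot(cpg, p("cpg_counts.tsv"))
  genes <- bundle$annotation$genes
  genes$exon_starts <- vapply(genes$exons,
                              function(e) paste(e$start, collapse = ","),
                              character(1))
  genes$exon_ends <- vapply(genes$exons,
                            function(e) paste(e$end, collapse = ","),
                            character(1))
  write_tsv_dot(genes[, c("gene_id", "name", "chrom", "start", "end",
                          "strand", "is_protein_coding", "exon_starts",
                          "exon_ends")], p("genes.tsv"))
  write_bed(bundle$annotation$cgi, p("cgi.bed"))
  write_tsv_dot(bundle$expression, p("expression.tsv"))
  write_tsv_dot(bundle$proteins, p("protein_groups.tsv"))
  write_tsv_dot(bundle$lda, p("lda.tsv"))
  write_pwm_file(bundle$motifs, p("motifs.pwm"))
  truth <- bundle$ground_truth
  jsonlite::write_json(truth, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  files <- c(genome = p("genome.fa"), peaks_basal = p("peaks_basal.bed"),
             peaks_luminal = p("peaks_luminal.bed"),
             cpg = p("cpg_counts.tsv"), genes = p("genes.tsv"),
             cgi = p("cgi.bed"), expression = p("expression.tsv"),
             proteins = p("protein_groups.tsv"), lda = p("lda.tsv"),
             motifs = p("motifs.pwm"),
             ground_truth = p("ground_truth.json"))
  invisible(files)
}

#' Write PWMs in the JASPAR-like text format read by [read_pwm()]
#'
#' @param motifs Named list of [pwm()] objects.
#' @param path Output path.
#' @export
write_pwm_file <- function(motifs, path) {
  lines <- unlist(lapply(motifs, function(pw) {
    c(paste0(">", pw$motif_id),
      vapply(1:4, function(r) {
        paste(c(rownames(pw$matrix)[r],
                sprintf("%.6f", pw$matrix[r, ])), collapse = " ")
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}
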