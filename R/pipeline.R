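# Run configuration and the staged pipeline entry point. Each stage reads
# the on-disk bundle produced by `simulate` (or user-supplied files with
# the same formats), writes its outputs atomically into the output
# directory, and can be run alone or chained via "all".

#' Default run configuration
#'
#' Thresholds default to the analysis' reference values: delta-beta 0.15,
#' adjusted-p 0.01, twofold expression changes, 2,500 bp upstream
#' windows, 250 bp TFBS-to-peak distance, 150 bp DMC flanks, 1,000
#' permutations.
#'
#' @param input_dir Directory holding the input bundle (as written by
#'   [write_study_bundle()]).
#' @param output_dir Directory for stage outputs.
#' @param seed Integer seed used by stochastic stages.
#' @param overrides Named list of values overriding the defaults
#'   (last-wins).
#' @return A named list with class `run_config`.
#' @export
run_config <- function(input_dir = NULL, output_dir = NULL, seed = 1L,
                       overrides = list()) {
  cfg <- list(
    input_dir = input_dir,
    output_dir = output_dir,
    seed = as.integer(seed),
    delta_min = 0.15,
    q_max = 0.01,
    fold_min = 2,
    upstream = 2500,
    tfbs_dist = 250,
    flank = 150,
    n_perm = 1000,
    rna_q_max = 0.05,
    protein_p_max = 0.05,
    criteria = "statemap",
    sim = list()  # simulation_config() overrides for the simulate stage
  )
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  chk01 <- function(name, lo = 0, hi = 1, strict_lo = TRUE) {
    v <- cfg[[name]]
    ok <- is.numeric(v) && length(v) == 1 &&
      (if (strict_lo) v > lo else v >= lo) && v <= hi
    if (!ok) abort(sprintf("invalid threshold %s = %s", name,
                           format(cfg[[name]])), class = "config_error")
  }
  chk01("q_max")
  chk01("rna_q_max")
  chk01("protein_p_max")
  chk01("delta_min", strict_lo = FALSE)
  if (!is.numeric(cfg$fold_min) || cfg$fold_min < 1) {
    abort("fold_min must be >= 1", class = "config_error")
  }
  for (nm in c("upstream", "tfbs_dist", "flank", "n_perm")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0) {
      abort(sprintf("%s must be non-negative", nm), class = "config_error")
    }
  }
  if (!cfg$criteria %in% c("statemap", "tabular")) {
    abort("criteria must be 'statemap' or 'tabular'", class = "config_error")
  }
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' @param path YAML file of configuration values.
#' @param overrides Named list applied after the file (last-wins).
#' @return A `run_config` object.
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  run_config(input_dir = vals$input_dir, output_dir = vals$output_dir,
             seed = vals$seed %||% 1L,
             overrides = vals[setdiff(names(vals),
                                      c("input_dir", "output_dir", "seed"))])
}

#' Write the resolved configuration to YAML
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

bundle_paths <- function(dir) {
  list(genome = file.path(dir, "genome.fa"),
       peaks_basal = file.path(dir, "peaks_basal.bed"),
       peaks_luminal = file.path(dir, "peaks_luminal.bed"),
       cpg = file.path(dir, "cpg_counts.tsv"),
       genes = file.path(dir, "genes.tsv"),
       cgi = file.path(dir, "cgi.bed"),
       expression = file.path(dir, "expression.tsv"),
       proteins = file.path(dir, "protein_groups.tsv"),
       lda = file.path(dir, "lda.tsv"),
       motifs = file.path(dir, "motifs.pwm"))
}

require_inputs <- function(paths, names) {
  for (nm in names) {
    if (!file.exists(paths[[nm]])) {
      abort(sprintf("missing input file: %s", paths[[nm]]),
            class = "input_error")
    }
  }
}

load_bundle_annotation <- function(paths) {
  genes <- read_gene_table(paths$genes)
  cgi <- read_bed(paths$cgi)
  annotation_set(genes, cgi)
}

#' Run pipeline stages
#'
#' Dispatches one stage (or `"all"`, which chains every stage in
#' dependency order) over a run configuration. Outputs are written to
#' `cfg$output_dir` via temp-file-then-rename so partial files never
#' appear; the resolved configuration and a run log are written
#' alongside.
#'
#' @param stage One of `"simulate"`, `"dmc"`, `"enrich"`, `"atac"`,
#'   `"motif"`, `"proteome"`, `"integrate"`, `"lda"`, `"all"`.
#' @param cfg A [run_config()].
#' @return Named character vector of output files written, invisibly.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "dmc", "enrich",
                                   "atac", "motif", "proteome",
                                   "integrate", "lda"),
                         cfg = run_config()) {
  stage <- rlang::arg_match(stage)
  validate_run_config(cfg)
  if (is.null(cfg$output_dir)) abort("output_dir is required",
                                     class = "config_error")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cfg$input_dir)) {
    cfg$input_dir <- file.path(cfg$output_dir, "bundle")
  }
  write_run_config(cfg, file.path(cfg$output_dir, "run_config.yaml"))
  log_path <- file.path(cfg$output_dir, "run.log")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)), file = log_path, append = TRUE)
  }
  log_line("stage=%s seed=%d package=%s %s", stage, cfg$seed, "mammomics",
           as.character(utils::packageVersion("mammomics")))
  stages <- if (stage == "all") {
    c("simulate", "dmc", "enrich", "atac", "motif", "proteome",
      "integrate", "lda")
  } else stage
  outputs <- character(0)
  for (st in stages) {
    log_line("running %s", st)
    outputs <- c(outputs, run_stage(st, cfg))
  }
  invisible(outputs)
}

# Write a tibble atomically.
emit <- function(x, dir, name) {
  tmp <- tempfile(tmpdir = dir)
  write_tsv_dot(x, tmp)
  target <- file.path(dir, name)
  file.rename(tmp, target)
  stats::setNames(target, sub("\\.tsv$", "", name))
}

run_stage <- function(st, cfg) {
  out <- cfg$output_dir
  paths <- bundle_paths(cfg$input_dir)
  switch(
    st,
    simulate = {
      bundle <- simulate_study(
        do.call(simulation_config,
                c(list(seed = cfg$seed), cfg$sim %||% list())))
      write_study_bundle(bundle, cfg$input_dir)
      stats::setNames(cfg$input_dir, "bundle")
    },
    dmc = {
      require_inputs(paths, c("cpg"))
      sites <- read_beta_table(paths$cpg)
      groups <- infer_groups(sample_columns(sites, "meth"))
      dmcs <- call_dmcs(sites, groups, delta_min = cfg$delta_min,
                        q_max = cfg$q_max)
      emit(dmcs, out, "dmcs.tsv")
    },
    enrich = {
      require_inputs(paths, c("cpg", "genes", "cgi"))
      ann <- load_bundle_annotation(paths)
      sites <- read_beta_table(paths$cpg)
      groups <- infer_groups(sample_columns(sites, "meth"))
      dmcs <- call_dmcs(sites, groups, delta_min = cfg$delta_min,
                        q_max = cfg$q_max)
      enr <- permutation_feature_enrichment(
        dmcs[dmcs$is_dmc, c("chrom", "pos")],
        dmcs[, c("chrom", "pos")], ann,
        n_perm = cfg$n_perm, seed = cfg$seed,
        promoter_upstream = cfg$upstream)
      emit(enr, out, "feature_enrichment.tsv")
    },
    atac = {
      require_inputs(paths, c("peaks_basal", "peaks_luminal", "genes",
                              "cgi"))
      ann <- load_bundle_annotation(paths)
      peaks <- classify_restriction(read_bed(paths$peaks_basal),
                                    read_bed(paths$peaks_luminal))
      assigned <- assign_peaks_to_genes(peaks, ann,
                                        upstream = cfg$upstream)
      counts <- count_peaks_per_gene(assigned, ann, "all")
      pk_out <- dplyr::mutate(peaks, name = .data$restriction)
      bed <- file.path(out, "peaks_classified.bed")
      write_bed(pk_out[, c("chrom", "start", "end", "name")], bed)
      c(emit(counts, out, "gene_peak_counts.tsv"),
        stats::setNames(bed, "peaks_classified"))
    },
    motif = {
      require_inputs(paths, c("cpg", "genes", "cgi", "genome", "motifs",
                              "peaks_basal", "peaks_luminal",
                              "expression"))
      ann <- load_bundle_annotation(paths)
      genome <- load_genome(paths$genome)
      motifs <- read_pwm(paths$motifs)
      sites <- read_beta_table(paths$cpg)
      groups <- infer_groups(sample_columns(sites, "meth"))
      dmcs <- call_dmcs(sites, groups, delta_min = cfg$delta_min,
                        q_max = cfg$q_max)
      hypo <- dmcs[dmcs$is_dmc, , drop = FALSE]
      target <- dmc_windows(hypo, flank = cfg$flank)
      bg_sites <- dmcs[!dmcs$is_dmc, , drop = FALSE]
      bg_pick <- withr::with_seed(cfg$seed, {
        bg_sites[sample.int(nrow(bg_sites),
                            min(nrow(hypo), nrow(bg_sites))), ]
      })
      background <- dmc_windows(bg_pick, flank = cfg$flank)
      enr <- motif_enrichment(target, background, motifs, genome)
      hits <- dplyr::bind_rows(
        purrr::map(motifs, ~scan_pwm(target, genome, .x)))
      peaks <- dplyr::bind_rows(read_bed(paths$peaks_basal),
                                read_bed(paths$peaks_luminal))
      expression <- readr::read_tsv(paths$expression,
                                    show_col_types = FALSE)
      prox <- proximal_gene_integration(
        hits, peaks, ann, expression, max_dist = cfg$tfbs_dist,
        sig_q = cfg$rna_q_max, upstream = cfg$upstream)
      c(emit(enr, out, "motif_enrichment.tsv"),
        emit(prox$by_motif[, c("motif_id", "n_genes", "n_significant",
                               "mean_rna_log2fc")],
             out, "motif_gene_summary.tsv"),
        emit(prox$by_gene, out, "gene_motif_counts.tsv"))
    },
    proteome = {
      require_inputs(paths, "proteins")
      prot <- read_protein_groups(paths$proteins)
      samples <- sample_columns(prot, "lfq")
      groups <- infer_groups(samples)
      prot <- normalize_max(harmonize_abundance(prot))
      diff <- differential_proteins(prot, groups,
                                    fc_min = cfg$fold_min,
                                    p_max = cfg$protein_p_max)
      outs <- c(emit(prot, out, "protein_abundance.tsv"),
                emit(diff, out, "differential_proteins.tsv"))
      if (file.exists(paths$expression)) {
        expression <- readr::read_tsv(paths$expression,
                                      show_col_types = FALSE)
        merged <- dplyr::inner_join(
          dplyr::transmute(diff,
                           gene_id = prot$gene_id %||% prot$gene_symbol,
                           protein_log2fc = .data$log2fc),
          expression[, c("gene_id", "rna_log2fc")], by = "gene_id")
        merged$n_peptides <- prot$n_peptides[
          match(merged$gene_id, prot$gene_id %||% prot$gene_symbol)]
        corr <- rna_protein_correlation(merged)
        corr_tbl <- dplyr::bind_rows(
          tibble(quantile = "global", n = nrow(merged),
                 rho = corr$global, count_min = NA_integer_,
                 count_max = NA_integer_),
          corr$by_quantile)
        outs <- c(outs, emit(corr_tbl, out, "rna_protein_correlation.tsv"))
      }
      outs
    },
    integrate = {
      require_inputs(paths, c("cpg", "genes", "cgi", "peaks_basal",
                              "peaks_luminal", "expression", "proteins"))
      ann <- load_bundle_annotation(paths)
      gene_data <- build_gene_layer_table(paths, ann, cfg)
      states <- assign_layer_states(gene_data, fold_min = cfg$fold_min)
      freq <- enumerate_states(states)
      assoc <- fit_all_associations(states)
      c(emit(states, out, "gene_states.tsv"),
        emit(freq, out, "state_frequencies.tsv"),
        emit(assoc, out, "layer_associations.tsv"))
    },
    lda = {
      require_inputs(paths, "lda")
      tab <- readr::read_tsv(paths$lda, show_col_types = FALSE)
      groups <- split(tab[, c("dose", "n", "positive")], tab$group)
      fits <- purrr::imap(groups, function(g, nm) {
        dplyr::mutate(tidy(fit_single_hit(lda_experiment(g, nm))),
                      group = nm)
      })
      res <- dplyr::bind_rows(fits)
      if (length(groups) == 2) {
        cmp <- compare_groups(groups[[1]], groups[[2]])
        res$comparison_p <- cmp$p
      }
      emit(res, out, "lda_results.tsv")
    },
    abort(sprintf("unknown stage %s", st))
  )
}

# Infer the two cell-type groups from sample names of the form
# <type>_<replicate>.
infer_groups <- function(samples) {
  types <- sub("_[^_]*$", "", samples)
  stats::setNames(types, samples)
}

# Assemble the per-gene layer table from the bundle files.
build_gene_layer_table <- function(paths, ann, cfg) {
  sites <- read_beta_table(paths$cpg)
  groups <- infer_groups(sample_columns(sites, "meth"))
  dmcs <- call_dmcs(sites, groups, delta_min = cfg$delta_min,
                    q_max = cfg$q_max)
  types <- unique(unname(groups))
  peaks <- classify_restriction(read_bed(paths$peaks_basal),
                                read_bed(paths$peaks_luminal),
                                cell_types = types)
  assigned <- assign_peaks_to_genes(peaks, ann, upstream = cfg$upstream)
  counts <- count_peaks_per_gene(assigned, ann, "all", cell_types = types)
  hypo <- dmcs[dmcs$is_dmc, , drop = FALSE]
  dmc_counts <- purrr::map(types, function(ct) {
    sub <- hypo[hypo$direction == paste0("hypo_in_", ct), , drop = FALSE]
    win <- tibble(chrom = sub$chrom, start = sub$pos, end = sub$pos + 1L)
    asg <- assign_peaks_to_genes(win, ann, upstream = cfg$upstream)
    cnt <- dplyr::count(dplyr::filter(asg, !is.na(.data$gene_id)),
                        .data$gene_id)
    stats::setNames(cnt, c("gene_id", paste0("n_hypo_dmc_", ct)))
  }) |> purrr::reduce(dplyr::full_join, by = "gene_id")
  expression <- readr::read_tsv(paths$expression, show_col_types = FALSE)
  prot <- read_protein_groups(paths$proteins)
  prot <- harmonize_abundance(prot)
  samples <- sample_columns(prot, "abundance")
  pg <- infer_groups(samples)
  prot_means <- purrr::map(types, function(ct) {
    cols <- paste0("abundance_", names(pg)[pg == ct])
    tibble(gene_id = prot$gene_id %||% prot$gene_symbol,
           !!paste0("protein_", ct) :=
             rowMeans(as.matrix(prot[, cols, drop = FALSE])))
  }) |> purrr::reduce(dplyr::inner_join, by = "gene_id")
  out <- tibble(gene_id = ann$genes$gene_id)
  out <- dplyr::left_join(out, counts, by = "gene_id")
  out <- dplyr::left_join(out, dmc_counts, by = "gene_id")
  for (ct in types) {
    col <- paste0("n_hypo_dmc_", ct)
    out[[col]] <- dplyr::coalesce(out[[col]], 0L)
  }
  out <- dplyr::left_join(
    out, expression[, c("gene_id", paste0("rna_", types))], by = "gene_id")
  out <- dplyr::left_join(out, prot_means, by = "gene_id")
  out
}
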