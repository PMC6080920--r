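# Per-gene ternary layer states across chromatin, methylation, RNA and
# protein; relationship-state enumeration; contingency-form multinomial
# association statistics; concordance and marker-signature reports.

LAYERS <- c("chromatin", "methylation", "rna", "protein")
STATE_LEVELS <- c("up_basal", "up_luminal", "neutral")

#' Assign ternary layer states to every gene
#'
#' Chromatin is `up_<type>` when the peak count is strictly greater for
#' that type; methylation is `up_<type>` when the count of DMCs
#' hypomethylated in that type is strictly greater (more hypomethylation
#' counts as "up"); RNA and protein are `up_<type>` when the linear-scale
#' abundance ratio exceeds `fold_min`. Ties and sub-threshold differences
#' are `neutral`. Genes missing any layer are excluded; the exclusion
#' count is recorded in the `n_excluded` attribute.
#'
#' @param gene_data Tibble with one row per gene: `gene_id`,
#'   `n_peaks_basal`, `n_peaks_luminal`, `n_hypo_dmc_basal`,
#'   `n_hypo_dmc_luminal`, `rna_basal`, `rna_luminal`, `protein_basal`,
#'   `protein_luminal`. `NA` in a column marks the layer as missing for
#'   that gene.
#' @param fold_min Strict linear fold-change threshold for RNA and
#'   protein. Default 2.
#' @param cell_types Length-2 character vector. Default basal, luminal.
#' @return A tibble `gene_id`, `chromatin`, `methylation`, `rna`,
#'   `protein`, each a factor with levels `up_basal`, `up_luminal`,
#'   `neutral` (for the default cell types).
#' @export
assign_layer_states <- function(gene_data, fold_min = 2,
                                cell_types = c("basal", "luminal")) {
  up <- paste0("up_", cell_types)
  levels <- c(up, "neutral")
  count_state <- function(a, b) {
    dplyr::case_when(a > b ~ up[1], b > a ~ up[2], TRUE ~ "neutral")
  }
  ratio_state <- function(a, b) {
    dplyr::case_when(a / b > fold_min ~ up[1],
                     b / a > fold_min ~ up[2],
                     TRUE ~ "neutral")
  }
  need <- c(paste0("n_peaks_", cell_types), paste0("n_hypo_dmc_", cell_types),
            paste0("rna_", cell_types), paste0("protein_", cell_types))
  missing <- setdiff(c("gene_id", need), names(gene_data))
  if (length(missing) > 0) {
    abort(paste("gene_data missing:", paste(missing, collapse = ", ")))
  }
  complete <- stats::complete.cases(gene_data[, need])
  n_excluded <- sum(!complete)
  x <- gene_data[complete, , drop = FALSE]
  out <- tibble(
    gene_id = x$gene_id,
    chromatin = count_state(x[[paste0("n_peaks_", cell_types[1])]],
                            x[[paste0("n_peaks_", cell_types[2])]]),
    methylation = count_state(x[[paste0("n_hypo_dmc_", cell_types[1])]],
                              x[[paste0("n_hypo_dmc_", cell_types[2])]]),
    rna = ratio_state(x[[paste0("rna_", cell_types[1])]],
                      x[[paste0("rna_", cell_types[2])]]),
    protein = ratio_state(x[[paste0("protein_", cell_types[1])]],
                          x[[paste0("protein_", cell_types[2])]])
  )
  out <- dplyr::mutate(out, dplyr::across(dplyr::all_of(LAYERS),
                                          ~factor(.x, levels = levels)))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Tabulate relationship-state frequencies
#'
#' Counts genes in each observed 4-layer relationship state, sorted by
#' decreasing frequency. The all-neutral reference state is always listed
#' (count 0 if unobserved) and flagged.
#'
#' @param states Output of [assign_layer_states()].
#' @return A tibble: the four layer columns, `n`, and `is_reference`.
#' @export
enumerate_states <- function(states) {
  tab <- dplyr::count(states, dplyr::across(dplyr::all_of(LAYERS)),
                      name = "n")
  ref <- vapply(tab[LAYERS], function(col) col == "neutral",
                logical(nrow(tab)))
  tab$is_reference <- rowSums(ref) == length(LAYERS)
  if (!any(tab$is_reference)) {
    zero <- tibble(chromatin = factor("neutral", levels(states$chromatin)),
                   methylation = factor("neutral", levels(states$chromatin)),
                   rna = factor("neutral", levels(states$chromatin)),
                   protein = factor("neutral", levels(states$chromatin)),
                   n = 0L, is_reference = TRUE)
    tab <- dplyr::bind_rows(tab, zero)
  }
  dplyr::arrange(tab, dplyr::desc(.data$n))
}

#' Pairwise layer association by multinomial log-odds
#'
#' For each direction (up in either cell type), genes are scored with a
#' binary predictor (predictor layer in that direction or not) and a
#' binary outcome (outcome layer in the same direction vs neutral; genes
#' with the outcome layer in the opposite direction are excluded, which is
#' the per-category comparison of a multinomial logit against the
#' all-neutral reference). With one binary predictor, the maximum
#' likelihood log-odds equals the contingency closed form
#' `ln[(n11 / n10) / (n01 / n00)]`; the Wald standard error is
#' `sqrt(sum(1 / n))` over the four cells. When any cell is empty the
#' Haldane-Anscombe +0.5 correction is applied to all four cells and
#' flagged.
#'
#' @param states Output of [assign_layer_states()].
#' @param predictor_layer,outcome_layer Layer names (distinct), each one
#'   of `"chromatin"`, `"methylation"`, `"rna"`, `"protein"`.
#' @return A tibble with one row per direction: `predictor_layer`,
#'   `outcome_layer`, `category`, `log_odds`, `se`, `p` (two-sided Wald),
#'   `haldane`, `degenerate` (constant predictor). Directions whose
#'   outcome category is empty are omitted.
#' @export
fit_layer_association <- function(states, predictor_layer, outcome_layer) {
  stopifnot(predictor_layer %in% LAYERS, outcome_layer %in% LAYERS,
            predictor_layer != outcome_layer)
  lv <- levels(states[[predictor_layer]])
  directions <- setdiff(lv, "neutral")
  rows <- purrr::map(directions, function(d) {
    x <- states[[predictor_layer]] == d
    y_raw <- states[[outcome_layer]]
    keep <- y_raw %in% c(d, "neutral")
    x <- x[keep]
    y <- y_raw[keep] == d
    if (sum(y) == 0) return(NULL)
    n11 <- sum(x & y); n10 <- sum(x & !y)
    n01 <- sum(!x & y); n00 <- sum(!x & !y)
    cells <- c(n11, n10, n01, n00)
    haldane <- any(cells == 0)
    if (haldane) cells <- cells + 0.5
    log_odds <- log((cells[1] / cells[2]) / (cells[3] / cells[4]))
    se <- sqrt(sum(1 / cells))
    degenerate <- all(x) || !any(x)
    p <- if (degenerate) NA_real_ else
      2 * stats::pnorm(-abs(log_odds / se))
    tibble(predictor_layer = predictor_layer,
           outcome_layer = outcome_layer, category = d,
           log_odds = log_odds, se = se, p = p,
           haldane = haldane, degenerate = degenerate)
  })
  dplyr::bind_rows(rows)
}

#' Fit all ordered layer-pair associations
#'
#' @param states Output of [assign_layer_states()].
#' @return Row-bound [fit_layer_association()] results for every ordered
#'   pair of distinct layers.
#' @export
fit_all_associations <- function(states) {
  pairs <- expand.grid(predictor = LAYERS, outcome = LAYERS,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$predictor != pairs$outcome, ]
  purrr::pmap(list(pairs$predictor, pairs$outcome),
              function(p, o) fit_layer_association(states, p, o)) |>
    dplyr::bind_rows()
}

#' Concordance of up-regulated genes with epigenomic associations
#'
#' For each (layer, direction) set of up-regulated genes and each kind of
#' epigenomic association (lineage-restricted peak or hypomethylated DMC),
#' the denominator is the number of up genes carrying any association of
#' that kind and the numerator the number whose association matches the
#' up direction. Percentages are rounded half away from zero to integers.
#'
#' @param up_genes Tibble `gene_id`, `layer` (e.g. `"rna"`, `"protein"`),
#'   `direction` (cell type).
#' @param associations Tibble `gene_id`, `kind` (e.g. `"peak"`, `"dmc"`),
#'   `direction` (cell type of the association).
#' @return A tibble: `layer`, `direction`, `kind`, `numerator`,
#'   `denominator`, `percent` (`NA` when the denominator is zero).
#' @export
concordance_table <- function(up_genes, associations) {
  combos <- tidyr::expand_grid(
    dplyr::distinct(up_genes[, c("layer", "direction")]),
    kind = unique(associations$kind)
  )
  purrr::pmap(combos, function(layer, direction, kind) {
    genes <- up_genes$gene_id[up_genes$layer == layer &
                                up_genes$direction == direction]
    assoc <- associations[associations$kind == kind &
                            associations$gene_id %in% genes, ]
    den <- dplyr::n_distinct(assoc$gene_id)
    num <- dplyr::n_distinct(assoc$gene_id[assoc$direction == direction])
    tibble(layer = layer, direction = direction, kind = kind,
           numerator = num, denominator = den,
           percent = if (den > 0) round_half_up(100 * num / den) else
             NA_real_)
  }) |> dplyr::bind_rows()
}

#' Marker-gene signature report
#'
#' Summarizes a user-supplied ordered marker panel: per-gene RNA and
#' protein z-scores, hypomethylation flag, basal:luminal peak proportion,
#' and a chromatin-expression concordance flag (more peaks on the side
#' where RNA or protein is up). Markers absent from the state table are
#' listed with missing fields. Summary fractions report chromatin
#' concordance, unmethylated markers, and RNA-protein concordance.
#'
#' @param marker_genes Character vector of gene ids, in display order.
#' @param states Output of [assign_layer_states()].
#' @param rna_z,protein_z Numeric matrices of z-scores with rownames
#'   containing the marker gene ids (e.g. from [zscore_rows()]).
#' @param hypomethylated Character vector of gene ids flagged as carrying
#'   hypomethylated DMCs.
#' @param peak_counts Tibble `gene_id`, `n_peaks_basal`,
#'   `n_peaks_luminal`.
#' @return A list with class `marker_signature`: `markers` (per-gene
#'   tibble) and `summary` (tibble of `measure`, `numerator`,
#'   `denominator`, `percent`).
#' @export
marker_signature_report <- function(marker_genes, states, rna_z, protein_z,
                                    hypomethylated, peak_counts) {
  if (length(marker_genes) == 0) {
    return(structure(list(markers = tibble(gene_id = character()),
                          summary = tibble(measure = character(),
                                           numerator = integer(),
                                           denominator = integer(),
                                           percent = numeric())),
                     class = "marker_signature"))
  }
  rows <- purrr::map(marker_genes, function(g) {
    st <- states[states$gene_id == g, ]
    pk <- peak_counts[peak_counts$gene_id == g, ]
    in_universe <- nrow(st) == 1
    nb <- if (nrow(pk) == 1) pk$n_peaks_basal else NA_integer_
    nl <- if (nrow(pk) == 1) pk$n_peaks_luminal else NA_integer_
    rna_state <- if (in_universe) as.character(st$rna) else NA_character_
    prot_state <- if (in_universe) as.character(st$protein) else
      NA_character_
    expr_dir <- dplyr::case_when(
      !is.na(rna_state) & rna_state != "neutral" ~ rna_state,
      !is.na(prot_state) & prot_state != "neutral" ~ prot_state,
      TRUE ~ NA_character_
    )
    chrom_concordant <- if (!is.na(expr_dir) && !is.na(nb)) {
      (expr_dir == "up_basal" && nb > nl) ||
        (expr_dir == "up_luminal" && nl > nb)
    } else NA
    tibble(
      gene_id = g,
      in_universe = in_universe,
      rna_z = list(if (g %in% rownames(rna_z)) rna_z[g, ] else NULL),
      protein_z = list(if (g %in% rownames(protein_z)) protein_z[g, ] else
        NULL),
      hypomethylated = g %in% hypomethylated,
      n_peaks_basal = nb, n_peaks_luminal = nl,
      peak_proportion_basal = if (!is.na(nb) && (nb + nl) > 0)
        nb / (nb + nl) else NA_real_,
      rna_state = rna_state, protein_state = prot_state,
      chromatin_concordant = chrom_concordant,
      # Discordant only when RNA and protein point to opposite lineages.
      rna_protein_concordant = if (in_universe)
        !(rna_state != "neutral" && prot_state != "neutral" &&
            rna_state != prot_state) else NA
    )
  })
  markers <- dplyr::bind_rows(rows)
  frac <- function(measure, x) {
    ok <- !is.na(x)
    tibble(measure = measure, numerator = sum(x[ok]),
           denominator = length(x),
           percent = if (length(x) > 0)
             round_half_up(100 * sum(x[ok]) / length(x)) else NA_real_)
  }
  summary <- dplyr::bind_rows(
    frac("chromatin_concordant", markers$chromatin_concordant),
    frac("unmethylated", !markers$hypomethylated),
    frac("rna_protein_concordant", markers$rna_protein_concordant)
  )
  structure(list(markers = markers, summary = summary),
            class = "marker_signature")
}

#' @export
print.marker_signature <- function(x, ...) {
  cat(sprintf("<marker_signature> %d markers\n", nrow(x$markers)))
  print(x$summary)
  invisible(x)
}
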