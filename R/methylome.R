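# Differential-methylation calling, genic/CpG-island feature annotation,
# and constrained-permutation feature enrichment with a normal-tail
# p-value computed in log space.

#' Call differentially methylated cytosines between two cell types
#'
#' Replicate counts are pooled within each group at every CpG, a Fisher
#' exact test is applied to the pooled 2x2 table (methylated/unmethylated
#' by group), and p-values are Benjamini-Hochberg adjusted over all tested
#' sites. A site is a DMC when `|delta_beta| >= delta_min` and
#' `q < q_max`. `delta_beta` is pooled beta(group 1) minus pooled
#' beta(group 2) where group 1 is the first level of `group_labels`
#' (conventionally basal); the group with the lower beta is hypomethylated
#' in that group.
#'
#' @param sites Tibble from [read_beta_table()] (count columns
#'   `meth_<sample>`, `unmeth_<sample>`).
#' @param group_labels Named character vector mapping sample name to cell
#'   type; exactly two distinct types.
#' @param delta_min Minimum absolute pooled beta difference (inclusive).
#'   Default 0.15.
#' @param q_max Strict upper bound on the adjusted p-value. Default 0.01.
#' @return A tibble of all tested sites: `chrom`, `pos`, `delta_beta`,
#'   `p`, `q`, `direction` (`hypo_in_<type>`, `NA` when `delta_beta` is 0)
#'   and `is_dmc`. Sites with zero pooled coverage in a group are skipped;
#'   the number skipped is recorded in the `n_skipped` attribute.
#' @export
call_dmcs <- function(sites, group_labels, delta_min = 0.15, q_max = 0.01) {
  groups <- unique(unname(group_labels))
  if (length(groups) != 2) {
    abort("call_dmcs needs exactly two groups")
  }
  if (delta_min < 0 || delta_min > 1 || q_max <= 0 || q_max > 1) {
    abort("delta_min must be in [0,1] and q_max in (0,1]")
  }
  pooled <- function(prefix, grp) {
    cols <- paste0(prefix, "_", names(group_labels)[group_labels == grp])
    rowSums(as.matrix(sites[, cols, drop = FALSE]), na.rm = TRUE)
  }
  m1 <- pooled("meth", groups[1]); u1 <- pooled("unmeth", groups[1])
  m2 <- pooled("meth", groups[2]); u2 <- pooled("unmeth", groups[2])
  covered <- (m1 + u1) > 0 & (m2 + u2) > 0
  n_skipped <- sum(!covered)
  sites <- sites[covered, , drop = FALSE]
  m1 <- m1[covered]; u1 <- u1[covered]
  m2 <- m2[covered]; u2 <- u2[covered]
  beta1 <- m1 / (m1 + u1)
  beta2 <- m2 / (m2 + u2)
  p <- fisher_p_2x2(m1, u1, m2, u2)
  out <- tibble(
    chrom = sites$chrom, pos = sites$pos,
    beta_1 = beta1, beta_2 = beta2,
    delta_beta = beta1 - beta2,
    p = p, q = benjamini_hochberg(p)
  )
  names(out)[names(out) == "beta_1"] <- paste0("beta_", groups[1])
  names(out)[names(out) == "beta_2"] <- paste0("beta_", groups[2])
  out$direction <- dplyr::case_when(
    out$delta_beta < 0 ~ paste0("hypo_in_", groups[1]),
    out$delta_beta > 0 ~ paste0("hypo_in_", groups[2]),
    TRUE ~ NA_character_
  )
  out$is_dmc <- abs(out$delta_beta) >= delta_min & out$q < q_max
  attr(out, "n_skipped") <- n_skipped
  attr(out, "groups") <- groups
  out
}

# Vectorized two-sided Fisher exact p for 2x2 tables given as four count
# vectors. Uses the standard "sum of probabilities <= p(observed)" rule.
fisher_p_2x2 <- function(a, b, c, d) {
  p <- vapply(seq_along(a), function(i) {
    m <- matrix(c(a[i], b[i], c[i], d[i]), nrow = 2, byrow = TRUE)
    stats::fisher.test(m)$p.value
  }, numeric(1))
  pmin(pmax(p, 0), 1)  # guard floating-point overshoot past 1
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment; input order preserved, values capped
#' at 1 with monotonicity enforced.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Select the highest-variance rows of a beta matrix
#'
#' @param beta_matrix Numeric matrix (or data frame) of beta-values,
#'   sites x samples, no missing values.
#' @param fraction Proportion of rows to keep, in (0, 1\]. Default 0.15.
#' @return Integer row indices of the `ceiling(fraction * nrow)` rows with
#'   the largest sample variance, ties broken by original row order.
#' @export
select_top_variance <- function(beta_matrix, fraction = 0.15) {
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  m <- as.matrix(beta_matrix)
  if (ncol(m) < 2) abort("need >= 2 samples to compute variance")
  if (anyNA(m)) abort("beta matrix must not contain missing values")
  v <- apply(m, 1, stats::var)
  k <- ceiling(fraction * nrow(m))
  sort(order(-v, seq_along(v))[seq_len(k)])
}

#' Annotate positions with genic and CpG-island context features
#'
#' Genic label precedence: promoter (strand-aware `[TSS - promoter_upstream,
#' TSS)` window) > exon > intron (inside a gene body but not an exon) >
#' intergenic. CpG context precedence: island > shore (within `shore_bp` of
#' an island edge) > shelf (between `shore_bp` and `shore_bp + shelf_bp`) >
#' open sea.
#'
#' @param sites Tibble with `chrom` and `pos` (0-based) columns.
#' @param ann An [annotation_set()].
#' @param promoter_upstream Promoter window size upstream of the TSS (bp).
#'   Default 2500.
#' @param shore_bp Shore band width from the island edge (bp). Default 2000.
#' @param shelf_bp Shelf band width beyond the shore (bp). Default 2000.
#' @return `sites` with `genic_feature` and `cgi_context` columns.
#' @export
annotate_site_features <- function(sites, ann, promoter_upstream = 2500,
                                   shore_bp = 2000, shelf_bp = 2000) {
  stopifnot(inherits(ann, "annotation_set"))
  pts <- tibble(chrom = sites$chrom, start = sites$pos,
                end = sites$pos + 1L)
  genes <- ann$genes
  promoters <- promoter_windows(genes, promoter_upstream)
  exons <- tidyr::unnest(genes[, c("chrom", "exons")], "exons")
  in_promoter <- overlaps_any(pts, promoters)
  in_exon <- overlaps_any(pts, exons)
  in_body <- overlaps_any(pts, genes[, c("chrom", "start", "end")])
  sites$genic_feature <- dplyr::case_when(
    in_promoter ~ "promoter",
    in_exon ~ "exon",
    in_body ~ "intron",
    TRUE ~ "intergenic"
  )
  cgi <- ann$cgi
  shore <- expand_intervals(cgi, shore_bp)
  shelf <- expand_intervals(cgi, shore_bp + shelf_bp)
  in_island <- overlaps_any(pts, cgi)
  in_shore <- overlaps_any(pts, shore)
  in_shelf <- overlaps_any(pts, shelf)
  sites$cgi_context <- dplyr::case_when(
    in_island ~ "cgi",
    in_shore ~ "shore",
    in_shelf ~ "shelf",
    TRUE ~ "open_sea"
  )
  sites
}

# Strand-aware promoter windows [TSS - upstream, TSS) for + genes,
# (TSS, TSS + upstream] for - genes; clipped at 0.
promoter_windows <- function(genes, upstream) {
  start <- ifelse(genes$strand == "+",
                  pmax(genes$tss - upstream, 0L), genes$tss + 1L)
  end <- ifelse(genes$strand == "+", genes$tss, genes$tss + 1L + upstream)
  keep <- end > start
  tibble(chrom = genes$chrom[keep],
         start = as.integer(start[keep]), end = as.integer(end[keep]))
}

expand_intervals <- function(x, by) {
  tibble(chrom = x$chrom, start = pmax(x$start - by, 0L),
         end = x$end + by)
}

#' Feature enrichment of DMCs by constrained permutation
#'
#' For each genic and CpG-island feature the observed count of DMCs in the
#' feature is compared with counts from `n_perm` uniform draws (without
#' replacement) of the same number of sites from the background of all
#' tested CpGs. The p-value is the normal tail at the observed count under
#' `N(expected_mean, expected_sd)` -- the upper tail when the observation
#' exceeds the permutation mean, otherwise the lower tail -- computed in
#' natural-log space so it never underflows to zero. The fold change is
#' observed / expected mean; ratios below 1 are reported as the negative
#' reciprocal, so positive values are enrichments and negative values
#' depletions.
#'
#' @param dmcs Tibble of DMC positions (`chrom`, `pos`); must be a subset
#'   of `background`.
#' @param background Tibble of all tested CpG positions (`chrom`, `pos`).
#' @param ann An [annotation_set()].
#' @param n_perm Number of permutations (>= 2). Default 1000.
#' @param seed Integer RNG seed; recorded in the output attributes.
#' @param promoter_upstream,shore_bp,shelf_bp Passed to
#'   [annotate_site_features()].
#' @return A tibble with one row per feature: `feature`, `observed`,
#'   `expected_mean`, `expected_sd`, `fold_change`, `log_p` (natural log),
#'   `p`, `degenerate` (TRUE when the permutation SD is zero).
#' @export
permutation_feature_enrichment <- function(dmcs, background, ann,
                                           n_perm = 1000, seed = 1L,
                                           promoter_upstream = 2500,
                                           shore_bp = 2000, shelf_bp = 2000) {
  if (n_perm < 2) abort("n_perm must be >= 2")
  key <- function(x) paste(x$chrom, x$pos)
  idx <- match(key(dmcs), key(background))
  if (anyNA(idx)) abort("dmcs must be a subset of the background CpGs")
  if (nrow(dmcs) > nrow(background)) abort("more DMCs than background sites")
  bg <- annotate_site_features(background, ann,
                               promoter_upstream = promoter_upstream,
                               shore_bp = shore_bp, shelf_bp = shelf_bp)
  features <- list(
    genic = c("promoter", "exon", "intron", "intergenic"),
    cgi = c("cgi", "shore", "shelf", "open_sea")
  )
  # Membership matrix: background site x feature.
  feat_names <- c(features$genic, features$cgi)
  member <- cbind(
    vapply(features$genic, function(f) bg$genic_feature == f,
           logical(nrow(bg))),
    vapply(features$cgi, function(f) bg$cgi_context == f, logical(nrow(bg)))
  )
  observed <- colSums(member[idx, , drop = FALSE])
  n_dmc <- nrow(dmcs)
  perm_counts <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      draw <- sample.int(nrow(bg), n_dmc)
      colSums(member[draw, , drop = FALSE])
    }, numeric(length(feat_names)))
  })
  exp_mean <- rowMeans(perm_counts)
  exp_sd <- apply(perm_counts, 1, stats::sd)
  upper <- observed > exp_mean
  log_p <- rep(0, length(feat_names))
  degenerate <- exp_sd == 0
  ok <- !degenerate
  log_p[ok] <- stats::pnorm(observed[ok], mean = exp_mean[ok],
                            sd = exp_sd[ok], lower.tail = !upper[ok],
                            log.p = TRUE)
  log_p[degenerate & observed != exp_mean] <- -Inf
  fold <- observed / exp_mean
  fold <- ifelse(is.nan(fold), 1, fold)
  fold_change <- ifelse(fold >= 1, fold, -1 / fold)
  out <- tibble(
    feature = feat_names,
    observed = unname(as.numeric(observed)),
    expected_mean = unname(exp_mean),
    expected_sd = unname(exp_sd),
    fold_change = unname(fold_change),
    log_p = unname(log_p),
    p = unname(exp(log_p)),
    degenerate = unname(degenerate)
  )
  attr(out, "seed") <- seed
  attr(out, "n_perm") <- n_perm
  attr(out, "n_dmc") <- n_dmc
  out
}
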