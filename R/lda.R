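# Single-hit Poisson estimation of repopulating-unit frequency from
# limiting-dilution transplant outcomes, with profile-likelihood 95%
# confidence intervals and a likelihood-ratio two-group comparison.

#' Construct a limiting-dilution experiment
#'
#' @param doses Tibble with columns `dose` (cells injected, > 0), `n`
#'   (injections at that dose, > 0), `positive` (positive outgrowths,
#'   between 0 and `n`).
#' @param group_label Optional label for the experiment.
#' @return A validated tibble with attribute `group_label`.
#' @export
lda_experiment <- function(doses, group_label = NULL) {
  stopifnot(all(c("dose", "n", "positive") %in% names(doses)))
  if (nrow(doses) < 1) abort("need at least one dose")
  if (any(doses$dose <= 0) || any(doses$n <= 0)) {
    abort("dose and n must be positive")
  }
  if (any(doses$positive < 0 | doses$positive > doses$n)) {
    abort("positive must lie in [0, n]")
  }
  out <- as_tibble(doses)
  attr(out, "group_label") <- group_label
  out
}

# Binomial log-likelihood of the single-hit model at log-frequency `lf`:
# P(positive | dose d) = 1 - exp(-exp(lf) * d).
lda_loglik <- function(lf, doses) {
  f <- exp(lf)
  p <- -expm1(-f * doses$dose)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(doses$positive * log(p) + (doses$n - doses$positive) * log1p(-p))
}

#' Fit the single-hit Poisson model to limiting-dilution data
#'
#' Models the probability of a positive outgrowth at dose `d` as
#' `1 - exp(-f * d)` where `f` is the repopulating-unit frequency (units:
#' stem cells per cell), and maximizes the binomial log-likelihood over
#' `ln f`. The 95% confidence interval is the profile-likelihood interval
#' on `ln f` at the chi-squared(1) cutoff 3.841. With all outcomes
#' positive (or all negative) the frequency is unbounded on one side; the
#' attainable bound is returned and flagged.
#'
#' @param doses An [lda_experiment()] or a tibble with `dose`, `n`,
#'   `positive` columns.
#' @return An object of class `lda_fit`: list with `frequency`,
#'   `one_in` (1 / frequency), `ci_low`, `ci_high` (frequencies),
#'   `loglik`, `boundary` (`"none"`, `"all_positive"`, or
#'   `"all_negative"`), `doses`, `group_label`.
#' @export
fit_single_hit <- function(doses) {
  doses <- lda_experiment(doses, attr(doses, "group_label"))
  tot_pos <- sum(doses$positive)
  tot <- sum(doses$n)
  boundary <- if (tot_pos == 0) "all_negative" else
    if (tot_pos == tot) "all_positive" else "none"
  # Search ln f over a range generous enough for any realistic assay.
  lo <- log(1 / (max(doses$dose) * 1e6))
  hi <- log(50 / min(doses$dose))
  chi_cut <- stats::qchisq(0.95, df = 1) / 2
  if (boundary == "none") {
    opt <- stats::optimize(lda_loglik, c(lo, hi), doses = doses,
                           maximum = TRUE, tol = 1e-10)
    lf_hat <- opt$maximum
    ll_hat <- opt$objective
    prof <- function(lf) lda_loglik(lf, doses) - ll_hat + chi_cut
    ci_lo <- if (prof(lo) < 0) {
      stats::uniroot(prof, c(lo, lf_hat), tol = 1e-10)$root
    } else lo
    ci_hi <- if (prof(hi) < 0) {
      stats::uniroot(prof, c(lf_hat, hi), tol = 1e-10)$root
    } else hi
    freq <- exp(lf_hat)
  } else if (boundary == "all_negative") {
    # Likelihood decreases in f; only an upper bound is identified.
    ll_hat <- lda_loglik(lo, doses)
    prof <- function(lf) lda_loglik(lf, doses) - ll_hat + chi_cut
    ci_lo <- lo
    ci_hi <- if (prof(hi) < 0) {
      stats::uniroot(prof, c(lo, hi), tol = 1e-10)$root
    } else hi
    freq <- NA_real_
    lf_hat <- NA_real_
  } else {
    ll_hat <- lda_loglik(hi, doses)
    prof <- function(lf) lda_loglik(lf, doses) - ll_hat + chi_cut
    ci_hi <- hi
    ci_lo <- if (prof(lo) < 0) {
      stats::uniroot(prof, c(lo, hi), tol = 1e-10)$root
    } else lo
    freq <- NA_real_
    lf_hat <- NA_real_
  }
  structure(
    list(frequency = freq,
         one_in = if (is.na(freq)) NA_real_ else 1 / freq,
         ci_low = exp(ci_lo), ci_high = exp(ci_hi),
         loglik = ll_hat, boundary = boundary, doses = doses,
         group_label = attr(doses, "group_label")),
    class = "lda_fit"
  )
}

#' @export
print.lda_fit <- function(x, ...) {
  lab <- if (is.null(x$group_label)) "" else paste0(" [", x$group_label, "]")
  if (x$boundary == "none") {
    cat(sprintf(
      "<lda_fit>%s frequency 1 in %.0f (95%% CI 1 in %.0f - 1 in %.0f)\n",
      lab, x$one_in, 1 / x$ci_high, 1 / x$ci_low))
  } else {
    cat(sprintf("<lda_fit>%s degenerate (%s); 95%% bound: 1 in %.0f\n",
                lab, x$boundary,
                1 / if (x$boundary == "all_negative") x$ci_high else
                  x$ci_low))
  }
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.lda_fit <- function(x, ...) {
  tibble(term = "frequency", estimate = x$frequency,
         one_in = x$one_in, conf.low = x$ci_low, conf.high = x$ci_high,
         boundary = x$boundary)
}

#' @export
#' @importFrom generics glance
glance.lda_fit <- function(x, ...) {
  tibble(logLik = x$loglik, n_doses = nrow(x$doses),
         n_injected = sum(x$doses$n),
         n_positive = sum(x$doses$positive), boundary = x$boundary)
}

#' Compare repopulating-unit frequency between two experiments
#'
#' Likelihood-ratio test of a common frequency against separate
#' frequencies: `2 * (ll_a + ll_b - ll_pooled)` against chi-squared with
#' one degree of freedom.
#'
#' @param a,b [lda_experiment()] tibbles (or tibbles with `dose`, `n`,
#'   `positive`).
#' @return An object of class `lda_comparison`: list with `p`,
#'   `statistic`, `fit_a`, `fit_b`, `fit_pooled`.
#' @export
compare_groups <- function(a, b) {
  fit_a <- fit_single_hit(a)
  fit_b <- fit_single_hit(b)
  pooled <- dplyr::bind_rows(a[, c("dose", "n", "positive")],
                             b[, c("dose", "n", "positive")])
  fit_p <- fit_single_hit(pooled)
  stat <- max(2 * (fit_a$loglik + fit_b$loglik - fit_p$loglik), 0)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(p = p, statistic = stat, fit_a = fit_a, fit_b = fit_b,
                 fit_pooled = fit_p,
                 degenerate = fit_a$boundary != "none" ||
                   fit_b$boundary != "none"),
            class = "lda_comparison")
}

#' @export
print.lda_comparison <- function(x, ...) {
  cat(sprintf("<lda_comparison> LR statistic %.3f, p = %.3g\n",
              x$statistic, x$p))
  invisible(x)
}

#' @export
tidy.lda_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$fit_a), group = "a"),
    dplyr::mutate(tidy(x$fit_b), group = "b")
  )
}

#' @export
glance.lda_comparison <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p,
         df = 1, degenerate = x$degenerate)
}
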