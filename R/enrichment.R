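#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact P by the sum-of-smaller-probabilities convention: with margins
#' fixed, sum the hypergeometric probabilities of every table whose
#' probability does not exceed that of the observed table (a relative
#' tolerance of 1e-7 guards ties against floating-point noise).
#'
#' @param tab 2x2 matrix (or object coercible to one) of non-negative
#'   integer counts.
#' @return the two-tailed P-value.
#' @export
fisher_exact_two_tailed <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    abort_input("fisher_exact_two_tailed: need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    abort_input("fisher_exact_two_tailed: cells must be non-negative integers")
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0L, k - n); hi <- min(k, m)
  support <- lo:hi
  logp <- stats::dhyper(support, m, n, k, log = TRUE)
  obs <- logp[support == a]
  sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
}

#' Per-base logistic enrichment of variants in a pathway class
#'
#' Treats every callable base as a Bernoulli trial (variant observed there
#' or not) with the pathway membership of the base as the single predictor.
#' For this saturated one-predictor design the maximum-likelihood
#' coefficient is the closed-form log odds ratio
#' `log((k1/(n1-k1)) / (k0/(n0-k0)))`; the Wald P comes from its asymptotic
#' standard error.  A zero cell triggers the Haldane-Anscombe 0.5 correction
#' (with a warning).
#'
#' @param k1,n1 variant-carrying and total callable bases in the pathway
#'   class.
#' @param k0,n0 same for the complement class.
#' @return list: `log_odds`, `se`, `wald_p`, `corrected`.
#' @export
per_base_logistic <- function(k1, n1, k0, n0) {
  stopifnot(k1 >= 0, k0 >= 0, n1 >= k1, n0 >= k0)
  cells <- c(k1, n1 - k1, k0, n0 - k0)
  corrected <- any(cells == 0)
  if (corrected) {
    warning("per_base_logistic: zero cell, applying Haldane-Anscombe 0.5",
            call. = FALSE)
    cells <- cells + 0.5
  }
  log_odds <- log(cells[1] / cells[2]) - log(cells[3] / cells[4])
  se <- sqrt(sum(1 / cells))
  wald_p <- 2 * pnorm(abs(log_odds) / se, lower.tail = FALSE)
  list(log_odds = log_odds, se = se, wald_p = wald_p, corrected = corrected)
}

#' Fold enrichment of tandem substitutions over the de novo background
#'
#' @param n_tandem tandem (dinucleotide) variants observed.
#' @param n_total total variants observed.
#' @param background_rate background tandem fraction of the de novo
#'   single-nucleotide rate (default 0.003, i.e. ~0.3%).
#' @return fold enrichment `(n_tandem / n_total) / background_rate`.
#' @export
tandem_enrichment <- function(n_tandem, n_total, background_rate = 0.003) {
  if (n_total <= 0)
    abort_input("tandem_enrichment: n_total must be positive")
  if (n_tandem > n_total)
    abort_input("tandem_enrichment: n_tandem exceeds n_total")
  if (background_rate <= 0 || background_rate >= 1)
    abort_input("tandem_enrichment: background_rate must lie in (0, 1)")
  (n_tandem / n_total) / background_rate
}

#' Pathway enrichment report for a candidate set
#'
#' Builds the 2x2 variant-by-pathway table from candidates and panel
#' callable footprints, and computes the Fisher, per-base logistic and
#' tandem statistics.
#'
#' @param candidates candidate table with `chrom, pos, ref, alt` (tandem
#'   candidates have two-base `ref`).
#' @param panel the panel (pathway labels and callable bp).
#' @param pathway pathway class treated as "selected" (default
#'   `"RAS_MAPK"`).
#' @param tandem_background_rate see [tandem_enrichment()].
#' @return list of class `clonescan_enrichment`: `table` (2x2), `fisher_p`,
#'   `logistic` (list), `tandem_fold`, `n_tandem`, `n_total`.
#' @export
pathway_enrichment <- function(candidates, panel, pathway = "RAS_MAPK",
                               tandem_background_rate = 0.003) {
  cand <- as.data.table(candidates)
  sel_pathway <- pathway
  bp <- as.data.frame(callable_bp(panel))
  bp1 <- sum(bp$callable_bp[bp$pathway == sel_pathway])
  bp0 <- sum(bp$callable_bp[bp$pathway != sel_pathway])
  if (bp1 == 0 || bp0 == 0)
    abort_input("pathway_enrichment: both pathway classes need callable bp")
  if (nrow(cand)) {
    site <- panel[, .(pos = seq.int(callable_start, callable_end - 1L),
                      pathway = pathway[1]), by = .(amplicon_id, chrom)]
    site <- unique(site[, .(chrom, pos, pathway)])
    cand_path <- merge(cand[, .(chrom, pos)], site, by = c("chrom", "pos"),
                       all.x = TRUE)
    k1 <- sum(cand_path$pathway == sel_pathway, na.rm = TRUE)
    k0 <- sum(cand_path$pathway != sel_pathway, na.rm = TRUE)
  } else k1 <- k0 <- 0L
  tab <- matrix(c(k1, bp1 - k1, k0, bp0 - k0), 2, 2, byrow = TRUE,
                dimnames = list(c(sel_pathway, "other"),
                                c("variant", "no_variant")))
  n_tandem <- if (nrow(cand)) sum(nchar(cand$ref) >= 2L) else 0L
  n_total <- nrow(cand)
  structure(list(
    table = tab,
    fisher_p = fisher_exact_two_tailed(tab),
    logistic = per_base_logistic(k1, bp1, k0, bp0),
    tandem_fold = if (n_total > 0)
      tandem_enrichment(n_tandem, n_total, tandem_background_rate) else NA_real_,
    n_tandem = n_tandem, n_total = n_total),
    class = "clonescan_enrichment")
}
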