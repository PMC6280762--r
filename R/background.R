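#' Long-format allele fraction matrix from a pileup
#'
#' Expands each pileup row into one row per non-reference allele, carrying
#' the alt count, total depth, and the variance-stabilized transform
#' `t = logit((alt + 0.5) / (depth + 1))`.  Rows with zero depth are dropped
#' (no observation exists there).
#'
#' @param pileup a `clonescan_pileup` table.
#' @return `data.table`: `sample_id, amplicon_id, chrom, pos, ref, alt,
#'   alt_count, depth, t`.
#' @export
allele_fraction_matrix <- function(pileup) {
  dt <- as.data.table(pileup)
  dt[, depth := A + C + G + T]
  long <- rbindlist(lapply(DNA_BASES, function(b) {
    sub <- dt[ref != b,
              .(sample_id, amplicon_id, chrom, pos, ref, alt = b,
                alt_count = get(b), depth)]
    sub
  }))
  long <- long[depth > 0L]
  long[, t := vaf_logit(alt_count, depth)]
  setorder(long, amplicon_id, pos, alt, sample_id)
  long[]
}

.design_matrix <- function(cov) {
  terms <- list()
  dropped <- character(0)
  for (f in c("flow_cell", "lane")) {
    v <- factor(cov[[f]])
    if (nlevels(v) >= 2L) terms[[f]] <- v else dropped <- c(dropped, f)
  }
  q <- cov$mean_base_quality
  if (length(unique(q)) >= 2L) terms$quality <- q - mean(q)
  else dropped <- c(dropped, "quality")
  if (length(dropped))
    warning("normalize_background: dropped constant covariate(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  if (!length(terms)) return(matrix(1, nrow(cov), 1,
                                    dimnames = list(NULL, "(Intercept)")))
  df <- as.data.frame(terms)
  stats::model.matrix(~ ., data = df)
}

# batch coefficients from winsorized per-sample aggregate counts: immune to
# the low-count attenuation of the per-observation logit transform, and to
# contamination by genuine clonal spikes (winsorization)
.aggregate_coefs <- function(sub, cov) {
  caps <- sub[, .(cap = {
    q <- quantile(alt_count, c(0.25, 0.75), names = FALSE, type = 1)
    ceiling(q[2] + 3 * (q[2] - q[1])) + 2L
  }), by = .(pos, alt)]
  s2 <- merge(sub, caps, by = c("pos", "alt"))
  agg <- s2[, .(alt_sum = sum(pmin(alt_count, cap)), depth_sum = sum(depth)),
            by = sample_id]
  agg <- merge(agg, cov, by = "sample_id")
  agg[, y := log((alt_sum + 0.5) / (depth_sum + 1))]
  X <- suppressWarnings(.design_matrix(agg))
  fit <- stats::lm.fit(X, agg$y)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  data.table(term = names(co), estimate = unname(co))
}

#' Normalize allele fractions for batch covariates
#'
#' Removes flow-cell, lane and mean-base-quality structure from the
#' transformed allele-fraction matrix.  Per amplicon, the residual matrix is
#' the fixed point of alternating (a) column-wise least-squares projection
#' off the covariate design and (b) per-(position, allele, lane) median
#' removal; iterating to a fixed point makes the operation idempotent.
#' Batch coefficients reported for diagnostics are estimated separately from
#' winsorized per-sample aggregate counts, which is unbiased at low counts
#' where the per-observation transform is not.
#'
#' @param afm an [allele_fraction_matrix()].
#' @param sheet the sample sheet (covariate source).
#' @param quality optional per-(sample, amplicon) mean base quality table
#'   (`sample_id, amplicon_id, mean_base_quality`), e.g. the `quality`
#'   attribute of a simulated pileup; defaults to the sheet's per-sample
#'   value.
#' @param max_iter,tol fixed-point iteration controls.
#' @return the input table with an added `resid` column; attributes
#'   `coefficients` (`data.table`: `amplicon_id, term, estimate`) and
#'   `iterations`.
#' @export
normalize_background <- function(afm, sheet, quality = NULL,
                                 max_iter = 100L, tol = 1e-11) {
  afm <- copy(as.data.table(afm))
  coefs <- list(); iters <- integer(0)
  afm[, resid := NA_real_]
  for (a in unique(afm$amplicon_id)) {
    idx <- which(afm$amplicon_id == a)
    sub <- afm[idx]
    samples <- sort(unique(sub$sample_id))
    if (length(samples) < 8L)
      abort_input("normalize_background: amplicon %s has %d samples (< 8)",
                  a, length(samples))
    cov <- sheet[sheet$sample_id %in% samples,
                 .(sample_id, flow_cell, lane, mean_base_quality)]
    if (!is.null(quality)) {
      qs <- as.data.table(quality)[amplicon_id == a,
                                   .(sample_id, q = mean_base_quality)]
      cov <- merge(cov, qs, by = "sample_id", all.x = TRUE)
      cov[!is.na(q), mean_base_quality := q][, q := NULL]
    }
    setorder(cov, sample_id)

    coefs[[a]] <- .aggregate_coefs(sub, cov)

    key <- paste(sub$pos, sub$alt)
    cols <- unique(key)
    Y <- matrix(NA_real_, length(samples), length(cols),
                dimnames = list(samples, cols))
    Y[cbind(match(sub$sample_id, samples), match(key, cols))] <- sub$t
    miss <- is.na(Y)
    if (any(miss)) { # impute column medians for the projection only
      cm <- matrixStats::colMedians(Y, na.rm = TRUE)
      Y[miss] <- cm[col(Y)[miss]]
    }

    X <- .design_matrix(cov)
    qx <- qr(X)
    lane_rows <- split(seq_along(samples), cov$lane)

    R <- Y; it <- 0L
    repeat {
      it <- it + 1L
      R_new <- qr.resid(qx, R)
      for (rows in lane_rows) {
        med <- matrixStats::colMedians(R_new[rows, , drop = FALSE])
        R_new[rows, ] <- sweep(R_new[rows, , drop = FALSE], 2L, med)
      }
      delta <- max(abs(R_new - R))
      R <- R_new
      if (delta < tol || it >= max_iter) break
    }
    iters <- c(iters, it)
    R[miss] <- NA_real_
    data.table::set(afm, idx, "resid",
                    R[cbind(match(sub$sample_id, samples), match(key, cols))])
  }
  out <- afm[!is.na(resid)]
  cf <- rbindlist(coefs, idcol = "amplicon_id")
  setattr(out, "coefficients", cf)
  setattr(out, "iterations", iters)
  out[]
}

#' Average fitted batch coefficients across amplicons
#'
#' Each amplicon yields an independent estimate of every batch coefficient;
#' averaging across amplicons gives the study-level estimate (used, e.g., to
#' verify recovery of a known injected lane effect).
#'
#' @param normalized output of [normalize_background()].
#' @return `data.table`: `term, estimate, sd, n_amplicons`.
#' @export
batch_coefficients <- function(normalized) {
  cf <- attr(normalized, "coefficients")
  cf[, .(estimate = mean(estimate), sd = sd(estimate), n_amplicons = .N),
     by = term]
}

#' Leave-one-out robust z-scores of a numeric vector
#'
#' For each element, `z = (x_s - median(x_-s)) / max(1.4826 * MAD(x_-s),
#' min_scale)`: location and scale are computed on the other elements only,
#' so a genuine outlier cannot mask itself.  Implemented via order-statistic
#' bookkeeping (two sorts per vector, not n median calls).
#'
#' @param x numeric vector (length >= 3 for a meaningful scale).
#' @param min_scale floor on the scale estimate; prevents infinite z on
#'   degenerate (near-constant) vectors.  Units: logit.
#' @return numeric vector of z-scores.
#' @export
loo_robust_z <- function(x, min_scale = 0.05) {
  n <- length(x)
  if (n < 3L) return(rep(NA_real_, n))
  ord <- order(x)
  rnk <- integer(n); rnk[ord] <- seq_len(n)
  sx <- x[ord]
  m <- n - 1L
  loo_med_sorted <- function(sv, ranks) {
    # median of sv (sorted, length n) with the element of rank r removed
    if (m %% 2L == 1L) {
      k <- (m + 1L) %/% 2L
      ifelse(ranks <= k, sv[k + 1L], sv[k])
    } else {
      k <- m %/% 2L
      a <- ifelse(ranks <= k, sv[k + 1L], sv[k])
      b <- ifelse(ranks <= k + 1L, sv[k + 2L], sv[k + 1L])
      (a + b) / 2
    }
  }
  med <- loo_med_sorted(sx, rnk)
  mad_loo <- numeric(n)
  for (v in unique(med)) {
    sel <- med == v
    d <- abs(x - v)
    ordd <- order(d)
    rnkd <- integer(n); rnkd[ordd] <- seq_len(n)
    mad_loo[sel] <- loo_med_sorted(d[ordd], rnkd[sel])
  }
  scale <- pmax(1.4826 * mad_loo, min_scale)
  (x - med) / scale
}

#' Moment fit of a beta-binomial null
#'
#' Kleinman moment estimator of the pooled success probability and
#' intra-class correlation `rho` from per-sample `(alt, depth)` counts.
#'
#' @param alt_count,depth integer vectors.
#' @return list `p`, `rho` (`rho = 0` collapses to binomial).
#' @export
fit_betabinom <- function(alt_count, depth) {
  keep <- depth > 0
  x <- alt_count[keep]; w <- depth[keep]
  n <- length(x)
  p <- sum(x) / sum(w)
  if (p <= 0 || p >= 1 || n < 2L) return(list(p = max(p, 1e-12), rho = 0))
  pi <- x / w
  S <- sum(w * (pi - p)^2)
  denom <- p * (1 - p) * (sum(w) - sum(w^2) / sum(w) - (n - 1))
  rho <- if (denom > 0) (S - (n - 1) * p * (1 - p)) / denom else 0
  list(p = p, rho = min(max(rho, 0), 0.99))
}

#' Upper-tail probability of a beta-binomial distribution
#'
#' `P(X >= x)` for `X ~ BetaBinomial(size, a, b)`, computed in log space by
#' summation from `x` upward with early termination once terms are
#' negligible.
#'
#' @param x observed count (vectorized).
#' @param size number of trials.
#' @param a,b beta shape parameters.
#' @return numeric vector of tail probabilities.
#' @export
betabinom_tail <- function(x, size, a, b) {
  vapply(seq_along(x), function(i) {
    xi <- x[i]; ni <- if (length(size) > 1L) size[i] else size
    if (xi <= 0) return(1)
    if (xi > ni) return(0)
    lc <- lbeta(a, b)
    # chunked summation from x upward; once past the pmf mode the terms
    # decay monotonically, so stop when a whole chunk is negligible
    mode_k <- min(ni, max(0, floor(ni * a / (a + b))))
    lcum <- -Inf
    k0 <- xi
    while (k0 <= ni) {
      k <- k0:min(k0 + 255L, ni)
      lt <- lchoose(ni, k) + lbeta(k + a, ni - k + b) - lc
      mx <- max(lt, lcum)
      lcum <- mx + log(exp(lcum - mx) + sum(exp(lt - mx)))
      k0 <- k0 + 256L
      if (k0 > mode_k && max(lt) < lcum - 40) break
    }
    exp(lcum)
  }, numeric(1))
}

#' Leave-one-out beta-binomial outlier P for one sample
#'
#' Fits the background null to the other samples' counts — after trimming
#' the samples above the `trim_q` quantile of alt fraction, so that
#' co-occurring true clones (the same clone in several biopsies) cannot
#' mask each other by inflating the fitted null mean and overdispersion —
#' and returns the exact upper-tail probability of the held-out sample's
#' count.  The trim makes the null slightly anti-conservative, which is
#' immaterial at the default `-log10 P > 20` emission threshold.
#'
#' @param alt_count,depth count vectors over samples at one
#'   (amplicon, position, allele).
#' @param s index of the sample under test.
#' @param trim_q fraction quantile above which background samples are
#'   excluded from the null fit (1 disables trimming).
#' @return the upper-tail P-value.
#' @export
betabinom_loo_p <- function(alt_count, depth, s, trim_q = 0.85) {
  x <- alt_count[-s]; w <- depth[-s]
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  if (!length(x)) return(NA_real_)
  if (trim_q < 1) {
    frac <- x / w
    cut <- quantile(frac, trim_q, names = FALSE, type = 1)
    keep <- frac <= cut
    x <- x[keep]; w <- w[keep]
  }
  fit <- fit_betabinom(x, w)
  if (fit$rho <= 1e-12) {
    stats::pbinom(alt_count[s] - 1, depth[s], fit$p, lower.tail = FALSE)
  } else {
    a <- fit$p * (1 - fit$rho) / fit$rho
    b <- (1 - fit$p) * (1 - fit$rho) / fit$rho
    betabinom_tail(alt_count[s], depth[s], a, b)
  }
}

#' Call per-sample outlier variants against the position-specific background
#'
#' For every (amplicon, position, alt allele), each sample is tested against
#' the background formed by the other samples.  In `robust_z` mode (default)
#' the statistic is the leave-one-out robust z of the normalized residual,
#' with a one-sided upper-tail normal P — mosaic signal can only raise the
#' alt fraction.  In `betabinom` mode a beta-binomial null is fitted to the
#' other samples' raw counts and the exact upper tail is used.  A call is
#' emitted iff `-log10(P) > p_cutoff` and `alt_count >= min_alt_reads`.
#'
#' @param normalized output of [normalize_background()] (`robust_z` mode
#'   reads its `resid` column; `betabinom` mode only needs the counts).
#' @param p_cutoff `-log10(P)` emission threshold (default 20).
#' @param min_alt_reads minimum supporting reads (default 10).
#' @param mode `"betabinom"` (operational default: exact tail, reaches the
#'   default cutoff for genuine spikes) or `"robust_z"` (the normalized
#'   robust rank statistic; its normal tail cannot reach `-log10 P > 20` at
#'   Poisson-level background counts, so use it with a lower cutoff or for
#'   ranking).
#' @param min_scale MAD floor for `robust_z` mode (logit units).
#' @param trim_q trimming quantile for the `betabinom` leave-one-out null
#'   fit; prevents co-clonal samples from masking each other.
#' @param p_for_all in `betabinom` mode, compute the exact P for every
#'   sample (slow) instead of only where `alt_count >= min_alt_reads`.
#' @return `data.table` of variant calls: `sample_id, amplicon_id, chrom,
#'   pos, ref, alt, alt_count, depth, vaf, neg_log10_p`.
#' @export
call_outliers <- function(normalized, p_cutoff = 20, min_alt_reads = 10L,
                          mode = c("betabinom", "robust_z"),
                          min_scale = 0.05, trim_q = 0.85,
                          p_for_all = FALSE) {
  mode <- match.arg(mode)
  dt <- as.data.table(normalized)
  grp <- c("amplicon_id", "chrom", "pos", "ref", "alt")
  dt[, n_samp := .N, by = grp]
  if (any(dt$n_samp < 8L)) {
    warning("call_outliers: dropping positions with < 8 informative samples",
            call. = FALSE)
    dt <- dt[n_samp >= 8L]
  }
  if (mode == "robust_z") {
    if (is.null(dt$resid))
      abort_input("call_outliers: robust_z mode needs normalized residuals")
    dt[, neg_log10_p := {
      z <- loo_robust_z(resid, min_scale = min_scale)
      -pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10)
    }, by = grp]
  } else {
    dt[, neg_log10_p := {
      cand <- if (p_for_all) seq_len(.N) else which(alt_count >= min_alt_reads)
      nlp <- rep(NA_real_, .N)
      for (s in cand) {
        p <- betabinom_loo_p(alt_count, depth, s, trim_q = trim_q)
        nlp[s] <- -log10(max(p, 1e-320))
      }
      nlp
    }, by = grp]
  }
  calls <- dt[neg_log10_p > p_cutoff & alt_count >= min_alt_reads,
              .(sample_id, amplicon_id, chrom, pos, ref, alt,
                alt_count, depth, vaf = alt_count / depth, neg_log10_p)]
  setorder(calls, amplicon_id, pos, alt, sample_id)
  calls[]
}

#' Per-amplicon coverage quality control
#'
#' An amplicon passes QC iff the median (across samples) of its per-sample
#' mean depth reaches `min_amplicon_depth`; chronically under-covered
#' amplicons produce unstable background estimates and are excluded.
#'
#' @param pileup a pileup table.
#' @param min_amplicon_depth threshold (default 5000).
#' @param panel optional panel; amplicons absent from the pileup entirely
#'   (zero reads) are then reported as failing.
#' @return `data.table`: `amplicon_id, median_depth, pass`.
#' @export
amplicon_qc <- function(pileup, min_amplicon_depth = 5000, panel = NULL) {
  dt <- as.data.table(pileup)
  dt[, depth := A + C + G + T]
  per_sample <- dt[, .(mean_depth = mean(depth)), by = .(amplicon_id, sample_id)]
  qc <- per_sample[, .(median_depth = median(mean_depth)), by = amplicon_id]
  if (!is.null(panel)) {
    missing <- setdiff(panel$amplicon_id, qc$amplicon_id)
    if (length(missing))
      qc <- rbind(qc, data.table(amplicon_id = missing, median_depth = 0))
  }
  qc[, pass := median_depth >= min_amplicon_depth]
  setorder(qc, amplicon_id)
  qc[]
}
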