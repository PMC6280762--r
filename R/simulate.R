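#' Background error model configuration
#'
#' Per-(amplicon, position, alt allele) background error rates are drawn
#' log-normal — heavy right tail, which is what makes per-position (rather
#' than global) background estimation necessary — and shifted additively on
#' the logit scale by flow-cell, lane and mean-base-quality batch effects.
#' Count noise beyond binomial sampling is beta-binomial.
#'
#' @param median_error median per-position background error rate.
#' @param sigma log-scale standard deviation of the log-normal error rates.
#' @param max_error hard ceiling on background error rates (exclusive bound
#'   0.01; positions at germline-like error would not be callable anyway).
#' @param flow_cell_effects,lane_effects named numeric vectors of additive
#'   logit-scale effects per batch level, or `NULL` to draw them
#'   `N(0, 0.2)` / `N(0, 0.3)` at simulation time.
#' @param quality_coef additive logit-scale effect per Phred unit of
#'   (sample, amplicon) mean base quality, centred on the cohort mean.
#'   Negative: better quality, lower error.
#' @param rho beta-binomial overdispersion of count sampling; `0` = binomial.
#' @return a list of class `error_model_config`.
#' @export
error_model_config <- function(median_error = 1e-4,
                               sigma = 0.8,
                               max_error = 0.0099,
                               flow_cell_effects = NULL,
                               lane_effects = NULL,
                               quality_coef = -0.05,
                               rho = 1e-5) {
  stopifnot(median_error > 0, median_error < 0.01, max_error < 0.01,
            rho >= 0, rho < 1)
  structure(list(median_error = median_error, sigma = sigma,
                 max_error = max_error,
                 flow_cell_effects = flow_cell_effects,
                 lane_effects = lane_effects,
                 quality_coef = quality_coef, rho = rho),
            class = "error_model_config")
}

#' Sequencing depth / template bottleneck configuration
#'
#' @param mean_depth mean per-position read depth.
#' @param depth_size negative-binomial size (dispersion) of depth draws;
#'   larger = tighter around the mean.
#' @param n_templates number of input template molecules per (sample,
#'   amplicon): a clone's true VAF is resampled through a binomial bottleneck
#'   of this many molecules before amplification, capturing droplet-PCR
#'   template sampling noise.
#' @return a list of class `depth_config`.
#' @export
depth_config <- function(mean_depth = 15000, depth_size = 30,
                         n_templates = 1000L) {
  stopifnot(mean_depth >= 0, depth_size > 0, n_templates >= 1)
  structure(list(mean_depth = mean_depth, depth_size = depth_size,
                 n_templates = as.integer(n_templates)),
            class = "depth_config")
}

.rbetabinom <- function(n, size, prob, rho) {
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  if (rho <= 0) return(rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  rbinom(n, size, rbeta(n, a, b))
}

#' Simulate a pileup matrix from panel, layout and ground truth
#'
#' For each (sample, amplicon, callable position): depth is drawn negative
#' binomial; each of the three non-reference alleles receives a count drawn
#' beta-binomial around `error rate + realized clone VAF`, where the clone
#' VAF has first been resampled through a binomial bottleneck of
#' `n_templates` molecules per (sample, amplicon); the reference allele
#' absorbs the remainder so counts always sum to depth.
#'
#' @param panel a [build_panel()] result.
#' @param layout a [build_layout()] result.
#' @param truth a [place_clones()] result (may contain zero clones).
#' @param error_model an [error_model_config()].
#' @param depth_cfg a [depth_config()].
#' @param seed integer seed.
#' @return a `data.table` of class `clonescan_pileup`, long format, one row
#'   per (sample, amplicon, callable position): `sample_id, amplicon_id,
#'   chrom, pos, ref, A, C, G, T`.  Attributes: `quality` (per
#'   (sample, amplicon) mean base quality), `error_rates` (true background
#'   rates, for diagnostics), `batch_effects`.
#' @export
simulate_pileups <- function(panel, layout, truth,
                             error_model = error_model_config(),
                             depth_cfg = depth_config(),
                             seed = 1L) {
  stopifnot(inherits(panel, "clonescan_panel"),
            inherits(layout, "clonescan_layout"),
            inherits(error_model, "error_model_config"),
            inherits(depth_cfg, "depth_config"))
  sheet <- layout$sheet
  with_seed(substream_seed(seed, "pileups"), {
    pos_tab <- panel[, .(chrom = chrom[1],
                         pos = seq.int(callable_start, callable_end - 1L)),
                     by = amplicon_id]
    pos_tab[, ref := reference_base(panel, chrom, pos)]

    # per-(amplicon, position, alt) baseline error, log-normal, capped
    err <- pos_tab[, .(alt = DNA_BASES[DNA_BASES != ref]),
                   by = .(amplicon_id, chrom, pos, ref)]
    err[, e_rate := pmin(exp(rnorm(.N, log(error_model$median_error),
                                   error_model$sigma)),
                         error_model$max_error)]

    fc_lv <- sort(unique(sheet$flow_cell))
    ln_lv <- sort(unique(sheet$lane))
    fc_eff <- error_model$flow_cell_effects %||%
      stats::setNames(rnorm(length(fc_lv), 0, 0.2), fc_lv)
    ln_eff <- error_model$lane_effects %||%
      stats::setNames(rnorm(length(ln_lv), 0, 0.3), ln_lv)
    if (!all(sheet$flow_cell %in% names(fc_eff)) ||
        !all(sheet$lane %in% names(ln_eff)))
      abort_input("simulate_pileups: batch effect vectors must name every level")

    # (sample, amplicon) mean base quality: sample-level quality + wiggle
    qual <- CJ(sample_id = sheet$sample_id, amplicon_id = panel$amplicon_id)
    qual <- merge(qual, sheet[, .(sample_id, mean_base_quality)], by = "sample_id")
    qual[, mean_base_quality := mean_base_quality + rnorm(.N, 0, 0.3)]

    # per-sample logit-scale shift
    shift <- merge(qual, sheet[, .(sample_id, flow_cell, lane)], by = "sample_id")
    qbar <- mean(shift$mean_base_quality)
    shift[, shift := fc_eff[flow_cell] + ln_eff[lane] +
            error_model$quality_coef * (mean_base_quality - qbar)]

    # full grid: sample x (amplicon, position)
    grid <- pos_tab[, {
      n <- .N
      data.table(sample_id = rep(sheet$sample_id, each = n),
                 chrom = rep(chrom, times = nrow(sheet)),
                 pos = rep(pos, times = nrow(sheet)),
                 ref = rep(ref, times = nrow(sheet)))
    }, by = amplicon_id]
    grid[, depth := rnbinom(.N, mu = depth_cfg$mean_depth,
                            size = depth_cfg$depth_size)]

    # spiked clone VAFs, bottlenecked per (sample, amplicon)
    spike <- truth_by_sample(truth, sheet)
    if (nrow(spike)) {
      spike <- merge(spike, pos_tab[, .(amplicon_id, chrom, pos)],
                     by = c("chrom", "pos"), allow.cartesian = TRUE)
      spike[, true_vaf := rbinom(.N, depth_cfg$n_templates, true_vaf) /
              depth_cfg$n_templates]
      spike <- spike[, .(true_vaf = sum(true_vaf)),
                     by = .(sample_id, amplicon_id, chrom, pos, alt)]
    }

    # alt-allele counts
    cnt <- err[, {
      n <- .N
      data.table(sample_id = rep(sheet$sample_id, each = n),
                 chrom = rep(chrom, times = nrow(sheet)),
                 pos = rep(pos, times = nrow(sheet)),
                 alt = rep(alt, times = nrow(sheet)),
                 e_rate = rep(e_rate, times = nrow(sheet)))
    }, by = amplicon_id]
    cnt <- merge(cnt, shift[, .(sample_id, amplicon_id, shift)],
                 by = c("sample_id", "amplicon_id"))
    cnt[, e_rate := pmin(inv_logit(log(e_rate / (1 - e_rate)) + shift),
                         error_model$max_error)]
    if (nrow(truth$clones)) {
      cnt <- merge(cnt, spike, all.x = TRUE,
                   by = c("sample_id", "amplicon_id", "chrom", "pos", "alt"))
      cnt[is.na(true_vaf), true_vaf := 0]
    } else cnt[, true_vaf := 0]
    cnt <- merge(cnt, grid[, .(sample_id, amplicon_id, pos, depth)],
                 by = c("sample_id", "amplicon_id", "pos"))
    cnt[, alt_count := .rbetabinom(.N, depth, pmin(e_rate + true_vaf, 0.999),
                                   error_model$rho)]

    wide <- data.table::dcast(cnt, sample_id + amplicon_id + chrom + pos ~ alt,
                              value.var = "alt_count", fill = 0L)
    for (b in DNA_BASES) if (!b %in% names(wide)) wide[, (b) := 0L]
    pile <- merge(grid, wide,
                  by = c("sample_id", "amplicon_id", "chrom", "pos"))
    # reference allele absorbs the remaining depth (conservation)
    alt_sum <- pile[, A + C + G + T]
    over <- alt_sum > pile$depth
    if (any(over)) { # pathological: clip alts proportionally (never at defaults)
      pile[over, `:=`(A = 0L, C = 0L, G = 0L, T = 0L)]
      alt_sum[over] <- 0L
    }
    for (b in DNA_BASES) {
      sel <- pile$ref == b
      data.table::set(pile, which(sel), b,
                      pile[[b]][sel] + pile$depth[sel] - alt_sum[sel])
    }
    pile[, depth := NULL]
    setorder(pile, sample_id, amplicon_id, pos)
    setcolorder(pile, c("sample_id", "amplicon_id", "chrom", "pos", "ref",
                        "A", "C", "G", "T"))
    setattr(pile, "quality", qual[])
    setattr(pile, "error_rates", err[])
    setattr(pile, "batch_effects",
            list(flow_cell = fc_eff, lane = ln_eff,
                 quality_coef = error_model$quality_coef))
    setattr(pile, "class", c("clonescan_pileup", class(pile)))
    pile[]
  })
}

#' Per-row depth of a pileup (sum of the four allele counts)
#' @param pileup a pileup table.
#' @return integer vector.
#' @export
pileup_depth <- function(pileup) pileup[, A + C + G + T]
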