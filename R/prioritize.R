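#' Post-call filter configuration
#'
#' @param min_alt_reads minimum supporting reads per call (re-checked here).
#' @param min_median_depth minimum median depth across all samples at a
#'   called position.
#' @param max_vaf_cap variants whose maximum VAF across samples reaches this
#'   value are removed entirely: at >= 3% the signal reads as constitutional
#'   (germline) rather than mosaic.
#' @param primer_proximal_bp calls within this many bases of a primer 3' end
#'   are removed (mispriming artifacts).
#' @param excess_k multiplier in the excess-call rule: a sample (or
#'   amplicon) is excluded when its raw call count exceeds
#'   `max(Q3 + excess_k * IQR, excess_floor)` of the respective call-count
#'   distribution.
#' @param excess_floor minimum count before the excess rule can trigger;
#'   prevents the rule from firing on sparse, clean runs where Q3 = IQR = 0.
#' @param tier2_min_vaf,tier3_min_vaf VAF boundaries of Tiers 2 and 3
#'   (boundaries are inclusive: exactly 0.2% is Tier 2, exactly 0.1% is
#'   Tier 3).
#' @param tandem_cor minimum per-biopsy VAF correlation for merging adjacent
#'   calls into one tandem (dinucleotide) candidate.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(min_alt_reads = 10L,
                          min_median_depth = 5000,
                          max_vaf_cap = 0.03,
                          primer_proximal_bp = 1L,
                          excess_k = 3,
                          excess_floor = 10L,
                          tier2_min_vaf = 0.002,
                          tier3_min_vaf = 0.001,
                          tandem_cor = 0.9) {
  stopifnot(tier3_min_vaf < tier2_min_vaf, tier2_min_vaf < max_vaf_cap)
  structure(list(min_alt_reads = as.integer(min_alt_reads),
                 min_median_depth = min_median_depth,
                 max_vaf_cap = max_vaf_cap,
                 primer_proximal_bp = as.integer(primer_proximal_bp),
                 excess_k = excess_k, excess_floor = as.integer(excess_floor),
                 tier2_min_vaf = tier2_min_vaf, tier3_min_vaf = tier3_min_vaf,
                 tandem_cor = tandem_cor),
            class = "filter_config")
}

.variant_key <- function(dt) dt[, paste(chrom, pos, ref, alt, sep = ":")]

#' Apply the post-call artifact filter cascade
#'
#' Removes, in order: calls from samples or amplicons with an excessive raw
#' call count; calls adjacent to a primer 3' end; whole variants whose
#' maximum VAF reaches the constitutional cap; and calls at positions whose
#' median depth across all samples is insufficient.
#'
#' @param calls raw [call_outliers()] output.
#' @param pileup the pileup (source of position median depths).
#' @param panel the panel (primer geometry).
#' @param cfg a [filter_config()].
#' @return filtered calls; attribute `stages` records the call count after
#'   each filter.
#' @export
filter_calls <- function(calls, pileup, panel, cfg = filter_config()) {
  calls <- as.data.table(calls)
  stages <- c(raw = nrow(calls))

  # (a) excess-variant rule, samples then amplicons: a sample or amplicon
  # with an outlying number of *distinct variants* is artifact-prone and is
  # excluded wholesale.  Distinct variants, not raw calls: a clone spanning
  # many biopsies is still one variant.  Zero-count samples/amplicons from
  # the pileup anchor the distribution.
  excess_cut <- function(counts) {
    q <- quantile(counts, c(0.25, 0.75), names = FALSE)
    max(q[2] + cfg$excess_k * (q[2] - q[1]), cfg$excess_floor)
  }
  pudt <- as.data.table(pileup)
  if (nrow(calls)) {
    per_sample <- calls[, .(n = data.table::uniqueN(paste(chrom, pos, ref, alt))),
                        by = sample_id]
    all_s <- unique(pudt$sample_id)
    cnt_s <- per_sample$n[match(all_s, per_sample$sample_id)]
    cnt_s[is.na(cnt_s)] <- 0L
    bad_s <- all_s[cnt_s > excess_cut(cnt_s)]
    calls <- calls[!sample_id %in% bad_s]
    per_amp <- calls[, .(n = data.table::uniqueN(paste(chrom, pos, ref, alt))),
                     by = amplicon_id]
    all_a <- unique(pudt$amplicon_id)
    cnt_a <- per_amp$n[match(all_a, per_amp$amplicon_id)]
    cnt_a[is.na(cnt_a)] <- 0L
    bad_a <- all_a[cnt_a > excess_cut(cnt_a)]
    calls <- calls[!amplicon_id %in% bad_a]
  }
  stages <- c(stages, excess = nrow(calls))

  # (b) primer-proximal positions
  calls <- merge(calls, panel[, .(amplicon_id, callable_start, callable_end)],
                 by = "amplicon_id", sort = FALSE)
  calls <- calls[pos >= callable_start + cfg$primer_proximal_bp &
                   pos < callable_end - cfg$primer_proximal_bp]
  calls[, c("callable_start", "callable_end") := NULL]
  stages <- c(stages, primer = nrow(calls))

  # (c) constitutional-VAF cap: drop the variant everywhere
  if (nrow(calls)) {
    calls[, max_vaf := max(vaf), by = .(chrom, pos, ref, alt)]
    calls <- calls[max_vaf < cfg$max_vaf_cap][, max_vaf := NULL]
  }
  stages <- c(stages, vaf_cap = nrow(calls))

  # (d) position median depth across all samples
  dt <- as.data.table(pileup)
  med <- dt[, .(med_depth = median(as.numeric(A + C + G + T))),
            by = .(amplicon_id, pos)]
  calls <- merge(calls, med, by = c("amplicon_id", "pos"), sort = FALSE)
  calls <- calls[med_depth >= cfg$min_median_depth][, med_depth := NULL]
  stages <- c(stages, depth = nrow(calls))

  calls <- calls[alt_count >= cfg$min_alt_reads]
  stages <- c(stages, min_reads = nrow(calls))
  setorder(calls, chrom, pos, alt, sample_id)
  setattr(calls, "stages", stages)
  calls[]
}

#' Keep only variants with two or more independent calls
#'
#' A variant survives if it was called in two or more samples, or in two or
#' more (overlapping) amplicons of one sample; singleton calls are far more
#' likely to be PCR or sequencing artifacts.  Replicate-pair support is a
#' special case of the two-sample route and is additionally flagged.
#'
#' @param calls filtered calls.
#' @param sheet sample sheet (for replicate-pair flags; optional).
#' @return calls restricted to surviving variants, with per-variant support
#'   columns `n_samples, n_amplicons_max, overlap_support,
#'   replicate_support`.
#' @export
require_independent <- function(calls, sheet = NULL) {
  calls <- as.data.table(calls)
  if (!nrow(calls)) {
    calls[, `:=`(n_samples = integer(0), n_amplicons_max = integer(0),
                 overlap_support = logical(0), replicate_support = logical(0))]
    return(calls[])
  }
  key <- c("chrom", "pos", "ref", "alt")
  calls[, n_samples := length(unique(sample_id)), by = key]
  # largest number of distinct amplicons calling this variant in one sample
  calls[, n_amplicons_max := max(vapply(split(amplicon_id, sample_id),
                                        function(a) length(unique(a)),
                                        integer(1))), by = key]
  rep_support <- function(sids) {
    if (is.null(sheet)) return(FALSE)
    s <- sheet[sheet$sample_id %in% sids]
    any(!is.na(s$replicate_of) & s$replicate_of %in% sids)
  }
  calls[, replicate_support := rep_support(unique(sample_id)), by = key]
  calls[, overlap_support := n_amplicons_max >= 2L]
  out <- calls[n_samples >= 2L | overlap_support | replicate_support]
  out[]
}

#' Aggregate call VAFs to per-sample and per-biopsy means
#'
#' Where a variant is covered by more than one amplicon, or a biopsy was
#' amplified in duplicate, the reported VAF is the arithmetic mean of the
#' called VAFs.
#'
#' @param calls calls for surviving variants (with support columns).
#' @param sheet sample sheet (maps samples to biopsies).
#' @return `data.table`, one row per (variant, biopsy): `chrom, pos, ref,
#'   alt, biopsy_id, testis_id, slice_id, vaf, n_calls`.
#' @export
aggregate_vaf <- function(calls, sheet) {
  calls <- as.data.table(calls)
  key <- c("chrom", "pos", "ref", "alt")
  per_sample <- calls[, .(vaf = mean(vaf), n_calls = .N),
                      by = c(key, "sample_id")]
  per_sample <- merge(per_sample,
                      sheet[, .(sample_id, biopsy_id, testis_id, slice_id)],
                      by = "sample_id")
  per_biopsy <- per_sample[, .(vaf = mean(vaf), n_calls = sum(n_calls)),
                           by = c(key, "biopsy_id", "testis_id", "slice_id")]
  setorder(per_biopsy, chrom, pos, alt, biopsy_id)
  per_biopsy[]
}

#' Merge adjacent, VAF-correlated calls into tandem candidates
#'
#' Adjacent substitutions called in the same biopsies with tightly
#' correlated per-biopsy VAFs almost certainly arose as one dinucleotide
#' mutational event and are merged into a single candidate (the two VAFs
#' are averaged per biopsy).
#'
#' @param per_biopsy output of [aggregate_vaf()].
#' @param tandem_cor Pearson correlation threshold (with >= 3 shared
#'   biopsies); with exactly 2 shared biopsies the VAF profiles must agree
#'   within 20% relative at both.
#' @return `per_biopsy` with dinucleotide rows replaced by merged rows whose
#'   `ref`/`alt` are two-base strings; attribute `n_merged`.
#' @export
merge_tandem <- function(per_biopsy, tandem_cor = 0.9) {
  pb <- copy(as.data.table(per_biopsy))
  vars <- unique(pb[, .(chrom, pos, ref, alt)])
  setorder(vars, chrom, pos)
  n_merged <- 0L
  for (i in seq_len(nrow(vars))) {
    v1 <- vars[i]
    if (nchar(v1$ref) > 1L) next
    j <- which(vars$chrom == v1$chrom & vars$pos == v1$pos + 1L &
                 nchar(vars$ref) == 1L)
    for (jj in j) {
      v2 <- vars[jj]
      a <- pb[chrom == v1$chrom & pos == v1$pos & ref == v1$ref & alt == v1$alt]
      b <- pb[chrom == v2$chrom & pos == v2$pos & ref == v2$ref & alt == v2$alt]
      shared <- intersect(a$biopsy_id, b$biopsy_id)
      if (length(shared) < 2L) next
      va <- a[match(shared, biopsy_id)]$vaf
      vb <- b[match(shared, biopsy_id)]$vaf
      ok <- if (length(shared) >= 3L) {
        r <- suppressWarnings(cor(va, vb))
        (!is.na(r) && r > tandem_cor) ||
          (is.na(r) && max(abs(va - vb) / pmax(va, vb)) < 0.2)
      } else max(abs(va - vb) / pmax(va, vb)) < 0.2
      if (!ok) next
      merged <- merge(a, b, by = c("biopsy_id", "testis_id", "slice_id"))
      merged <- merged[, .(chrom = v1$chrom, pos = v1$pos,
                           ref = paste0(v1$ref, v2$ref),
                           alt = paste0(v1$alt, v2$alt),
                           biopsy_id, testis_id, slice_id,
                           vaf = (vaf.x + vaf.y) / 2,
                           n_calls = n_calls.x + n_calls.y)]
      pb <- pb[!(chrom == v1$chrom & ref %in% c(v1$ref, v2$ref) &
                   alt %in% c(v1$alt, v2$alt) & pos %in% c(v1$pos, v2$pos))]
      pb <- rbind(pb, merged)
      n_merged <- n_merged + 1L
      break
    }
  }
  setorder(pb, chrom, pos, alt, biopsy_id)
  setattr(pb, "n_merged", n_merged)
  pb[]
}

#' Assign confidence tiers to candidate variants
#'
#' Tier 1: independent support from overlapping amplicons or a replicate
#' pair.  Otherwise, by maximum per-biopsy VAF: Tier 2 at >= `tier2_min_vaf`
#' (default 0.2%), Tier 3 in `[tier3_min_vaf, tier2_min_vaf)`, Tier 4 below.
#' Tiers are exhaustive and mutually exclusive.
#'
#' @param per_biopsy aggregated per-biopsy VAFs (possibly tandem-merged).
#' @param support per-variant support table (from [require_independent()]
#'   output, columns `chrom, pos, ref, alt, overlap_support,
#'   replicate_support`); tandem-merged candidates inherit support from
#'   either member.
#' @param cfg a [filter_config()].
#' @return `data.table`, one row per candidate: `chrom, pos, ref, alt,
#'   n_biopsies, n_amplicons, max_vaf, mean_vaf, overlap_support,
#'   replicate_support, tier`.
#' @export
assign_tier <- function(per_biopsy, support, cfg = filter_config()) {
  pb <- as.data.table(per_biopsy)
  key <- c("chrom", "pos", "ref", "alt")
  if (!nrow(pb)) {
    return(data.table(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      n_biopsies = integer(0), max_vaf = numeric(0),
                      mean_vaf = numeric(0), overlap_support = logical(0),
                      replicate_support = logical(0),
                      n_amplicons = integer(0), tier = integer(0)))
  }
  cand <- pb[, .(n_biopsies = length(unique(biopsy_id)),
                 max_vaf = max(vaf), mean_vaf = mean(vaf)), by = key]
  sup <- unique(as.data.table(support)[, .(
    chrom, pos, ref, alt, n_amplicons_max, overlap_support, replicate_support)])
  # tandem candidates match either constituent position/allele
  cand[, `:=`(overlap_support = FALSE, replicate_support = FALSE,
              n_amplicons = 1L)]
  for (i in seq_len(nrow(cand))) {
    width <- nchar(cand$ref[i])
    hit <- sup[chrom == cand$chrom[i] &
                 pos %in% (cand$pos[i] + seq_len(width) - 1L)]
    if (width == 1L) hit <- hit[ref == cand$ref[i] & alt == cand$alt[i]]
    if (nrow(hit)) {
      data.table::set(cand, i, "overlap_support", any(hit$overlap_support))
      data.table::set(cand, i, "replicate_support", any(hit$replicate_support))
      data.table::set(cand, i, "n_amplicons", max(hit$n_amplicons_max))
    }
  }
  cand[, tier := ifelse(overlap_support | replicate_support, 1L,
                        ifelse(max_vaf >= cfg$tier2_min_vaf, 2L,
                               ifelse(max_vaf >= cfg$tier3_min_vaf, 3L, 4L)))]
  setorder(cand, tier, chrom, pos)
  cand[]
}

#' Run the full prioritization cascade
#'
#' Filters raw calls, enforces the two-independent-calls rule, aggregates
#' VAFs, merges tandem substitutions and assigns tiers.
#'
#' @param calls raw [call_outliers()] output.
#' @param pileup the pileup.
#' @param panel the panel.
#' @param sheet the sample sheet.
#' @param cfg a [filter_config()].
#' @return list of class `clonescan_candidates`: `candidates` (one row per
#'   candidate with tier), `by_biopsy` (per-biopsy VAFs), `calls` (surviving
#'   calls), `stages` (named call counts along the cascade).
#' @export
prioritize <- function(calls, pileup, panel, sheet, cfg = filter_config()) {
  f <- filter_calls(calls, pileup, panel, cfg)
  stages <- attr(f, "stages")
  ind <- require_independent(f, sheet)
  stages <- c(stages, independent = nrow(ind))
  pb <- aggregate_vaf(ind, sheet)
  pb <- merge_tandem(pb, cfg$tandem_cor)
  cand <- assign_tier(pb, ind, cfg)
  structure(list(candidates = cand, by_biopsy = pb, calls = ind,
                 stages = stages),
            class = "clonescan_candidates")
}
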