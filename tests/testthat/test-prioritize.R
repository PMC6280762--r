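# hand-crafted calls/pileup world for the filter cascade: one amplicon,
# callable [110, 190), 12 samples, deep coverage
mk_world <- function() {
  panel <- toy_panel(fwd = 10L, rev = 10L, len = 100L)
  sheet <- data.table::data.table(
    sample_id = sprintf("S%02d", 1:12),
    biopsy_id = c(sprintf("B%02d", 1:11), "B11"), # S12 replicates B11
    testis_id = 1L, slice_id = 1L, slice_position = c(1:11, 11L),
    flow_cell = "FC1", lane = rep(c("L1", "L2"), 6),
    mean_base_quality = 34,
    replicate_of = c(rep(NA_character_, 11), "S11"))
  pu <- data.table::CJ(sample_id = sheet$sample_id, pos = 110:189)
  pu[, `:=`(amplicon_id = "AMP001", chrom = "chrT", A = 0L, C = 0L, G = 0L,
            T = 0L)]
  ref <- attr(panel, "reference")
  pu[, ref := ref$base[match(pos, ref$pos)]]
  for (b in c("A", "C", "G", "T")) pu[ref == b, (b) := 15000L]
  list(panel = panel, sheet = sheet, pileup = pu)
}

mk_call <- function(w, sample_id, pos, alt_count = 50L, depth = 15000L,
                    amplicon_id = "AMP001") {
  ref <- attr(w$panel, "reference")
  rb <- ref$base[ref$pos == pos]
  data.table::data.table(
    sample_id = sample_id, amplicon_id = amplicon_id, chrom = "chrT",
    pos = pos, ref = rb, alt = setdiff(c("A", "C", "G", "T"), rb)[1],
    alt_count = alt_count, depth = depth, vaf = alt_count / depth,
    neg_log10_p = 50)
}

test_that("constitutional-VAF cap removes whole variants at >= 3%", {
  w <- mk_world()
  calls <- rbind(
    mk_call(w, "S01", 150L, alt_count = 480L),  # 3.2% -> variant removed
    mk_call(w, "S02", 150L, alt_count = 30L),   # same variant, low VAF
    mk_call(w, "S03", 160L, alt_count = 442L),  # 2.95% -> retained
    mk_call(w, "S04", 160L, alt_count = 30L))
  f <- filter_calls(calls, w$pileup, w$panel, filter_config())
  expect_false(any(f$pos == 150L))
  expect_equal(sort(f$sample_id[f$pos == 160L]), c("S03", "S04"))
})

test_that("primer-proximal calls are removed", {
  w <- mk_world() # callable [110, 190)
  calls <- rbind(mk_call(w, "S01", 110L), mk_call(w, "S02", 110L),
                 mk_call(w, "S01", 189L), mk_call(w, "S02", 189L),
                 mk_call(w, "S01", 111L), mk_call(w, "S02", 111L))
  f <- filter_calls(calls, w$pileup, w$panel, filter_config())
  expect_setequal(unique(f$pos), 111L)
})

test_that("low-median-depth positions are removed", {
  w <- mk_world()
  thin <- data.table::copy(w$pileup)
  sel <- thin$pos == 170L
  for (b in c("A", "C", "G", "T")) thin[sel & ref == b, (b) := 4000L]
  calls <- rbind(mk_call(w, "S01", 170L, depth = 4000L),
                 mk_call(w, "S02", 170L, depth = 4000L),
                 mk_call(w, "S01", 171L), mk_call(w, "S02", 171L))
  f <- filter_calls(calls, thin, w$panel, filter_config())
  expect_setequal(unique(f$pos), 171L)
})

test_that("excess-call rule drops hypermutated samples but spares clean runs", {
  w <- mk_world()
  clean <- rbind(mk_call(w, "S01", 150L), mk_call(w, "S02", 150L))
  f <- filter_calls(clean, w$pileup, w$panel, filter_config())
  expect_equal(nrow(f), 2L) # sparse run untouched (floor)
  noisy <- data.table::rbindlist(c(
    list(clean),
    lapply(seq(120L, 168L, by = 2L), function(p) mk_call(w, "S07", p))))
  f2 <- filter_calls(noisy, w$pileup, w$panel, filter_config())
  expect_false("S07" %in% f2$sample_id)
  expect_setequal(f2$sample_id, c("S01", "S02"))
})

test_that("independence rule: two samples, overlapping amplicons, or replicates", {
  w <- mk_world()
  singleton <- mk_call(w, "S01", 150L)
  expect_equal(nrow(require_independent(singleton, w$sheet)), 0L)

  two_samples <- rbind(mk_call(w, "S01", 150L), mk_call(w, "S02", 150L))
  expect_equal(nrow(require_independent(two_samples, w$sheet)), 2L)

  two_amps <- rbind(mk_call(w, "S01", 150L),
                    mk_call(w, "S01", 150L, amplicon_id = "AMP002"))
  ind <- require_independent(two_amps, w$sheet)
  expect_equal(nrow(ind), 2L)
  expect_true(all(ind$overlap_support))

  reps <- rbind(mk_call(w, "S11", 150L), mk_call(w, "S12", 150L))
  indr <- require_independent(reps, w$sheet)
  expect_equal(nrow(indr), 2L)
  expect_true(all(indr$replicate_support))
})

test_that("VAF aggregation means over amplicons and replicates", {
  w <- mk_world()
  # overlapping amplicons at 0.2% and 0.4% -> 0.3%
  ca <- rbind(mk_call(w, "S01", 150L, alt_count = 30L),  # 0.2%
              mk_call(w, "S01", 150L, alt_count = 60L,   # 0.4%
                      amplicon_id = "AMP002"),
              mk_call(w, "S02", 150L, alt_count = 75L))  # 0.5% single call
  ind <- require_independent(ca, w$sheet)
  pb <- aggregate_vaf(ind, w$sheet)
  expect_equal(pb$vaf[pb$biopsy_id == "B01"], 0.003)
  expect_equal(pb$vaf[pb$biopsy_id == "B02"], 0.005)

  # replicate pair at 1.0% / 1.2% -> biopsy VAF 1.1%
  cr <- rbind(mk_call(w, "S11", 150L, alt_count = 150L),
              mk_call(w, "S12", 150L, alt_count = 180L))
  pbr <- aggregate_vaf(require_independent(cr, w$sheet), w$sheet)
  expect_equal(nrow(pbr), 1L)
  expect_equal(pbr$vaf, 0.011)
})

test_that("tier assignment follows the confidence hierarchy", {
  w <- mk_world()
  cfg <- filter_config()
  tiers_of <- function(calls) {
    ind <- require_independent(calls, w$sheet)
    pb <- aggregate_vaf(ind, w$sheet)
    assign_tier(pb, ind, cfg)
  }
  # overlapping-amplicon support at max VAF 0.12% -> Tier 1
  t1 <- tiers_of(rbind(mk_call(w, "S01", 150L, alt_count = 18L),
                       mk_call(w, "S01", 150L, alt_count = 18L,
                               amplicon_id = "AMP002")))
  expect_equal(t1$tier, 1L)
  # single amplicon, 3 biopsies, max VAF 0.25% -> Tier 2
  t2 <- tiers_of(rbind(mk_call(w, "S01", 150L, alt_count = 38L),
                       mk_call(w, "S02", 150L, alt_count = 30L),
                       mk_call(w, "S03", 150L, alt_count = 20L)))
  expect_equal(t2$tier, 2L)
  # exactly 0.2% -> Tier 2 (inclusive boundary)
  tb <- tiers_of(rbind(mk_call(w, "S01", 150L, alt_count = 30L),
                       mk_call(w, "S02", 150L, alt_count = 20L)))
  expect_equal(tb$tier, 2L)
  # 0.1%-0.2% -> Tier 3; exactly 0.1% inclusive
  t3 <- tiers_of(rbind(mk_call(w, "S01", 150L, alt_count = 15L),
                       mk_call(w, "S02", 150L, alt_count = 15L)))
  expect_equal(t3$tier, 3L)
  # < 0.1% -> Tier 4
  t4 <- tiers_of(rbind(mk_call(w, "S01", 150L, alt_count = 10L),
                       mk_call(w, "S02", 150L, alt_count = 10L)))
  expect_equal(t4$tier, 4L)
})

test_that("tiers partition every candidate exactly once", {
  w <- mk_world()
  set.seed(8)
  calls <- data.table::rbindlist(lapply(1:30, function(i) {
    pos <- sample(seq(115L, 185L, 5L), 1)
    n <- sample(2:4, 1)
    data.table::rbindlist(lapply(sample(w$sheet$sample_id, n), function(s)
      mk_call(w, s, pos, alt_count = sample(c(12L, 25L, 40L, 150L), 1))))
  }))
  ind <- require_independent(calls, w$sheet)
  pb <- aggregate_vaf(ind, w$sheet)
  cand <- assign_tier(pb, ind, filter_config())
  expect_true(all(cand$tier %in% 1:4))
  expect_equal(anyDuplicated(cand[, c("chrom", "pos", "ref", "alt")]), 0L)
})

test_that("raising any threshold never enlarges the surviving call set", {
  calls <- fx_calls()
  pu <- fx_pileup(); panel <- fx_panel(); sheet <- fx_layout()$sheet
  base_cfg <- filter_config()
  surv <- function(cfg) {
    f <- filter_calls(calls, pu, panel, cfg)
    paste(f$sample_id, f$amplicon_id, f$pos, f$alt)
  }
  base <- surv(base_cfg)
  grids <- list(
    filter_config(min_alt_reads = 20L),
    filter_config(min_median_depth = 12000),
    filter_config(max_vaf_cap = 0.01),
    filter_config(primer_proximal_bp = 5L),
    filter_config(excess_floor = 1L))
  for (cfg in grids) expect_true(all(surv(cfg) %in% base))
})

test_that("adjacent correlated calls merge into one tandem candidate", {
  w <- mk_world()
  calls <- rbind(
    mk_call(w, "S01", 150L, alt_count = 60L),
    mk_call(w, "S02", 150L, alt_count = 40L),
    mk_call(w, "S03", 150L, alt_count = 30L),
    mk_call(w, "S01", 151L, alt_count = 60L),
    mk_call(w, "S02", 151L, alt_count = 40L),
    mk_call(w, "S03", 151L, alt_count = 30L))
  ind <- require_independent(calls, w$sheet)
  pb <- aggregate_vaf(ind, w$sheet)
  merged <- merge_tandem(pb)
  expect_equal(attr(merged, "n_merged"), 1L)
  expect_equal(nrow(unique(merged[, c("chrom", "pos", "ref", "alt")])), 1L)
  expect_equal(nchar(unique(merged$ref)), 2L)
  cand <- assign_tier(merged, ind, filter_config())
  expect_equal(nrow(cand), 1L)
  # uncorrelated neighbours stay separate
  calls2 <- rbind(
    mk_call(w, "S01", 150L, alt_count = 60L),
    mk_call(w, "S02", 150L, alt_count = 40L),
    mk_call(w, "S03", 150L, alt_count = 30L),
    mk_call(w, "S04", 151L, alt_count = 200L),
    mk_call(w, "S05", 151L, alt_count = 15L))
  pb2 <- aggregate_vaf(require_independent(calls2, w$sheet), w$sheet)
  merged2 <- merge_tandem(pb2)
  expect_equal(attr(merged2, "n_merged"), 0L)
})
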