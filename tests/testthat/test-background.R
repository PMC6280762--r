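test_that("loo_robust_z matches the naive leave-one-out implementation", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(c(3:8, 12, 47, 48), 1)
    x <- switch(sample(3, 1),
                rnorm(n),
                round(rnorm(n, 0, 2)), # heavy ties
                c(rnorm(n - 1), 10))   # gross outlier
    expect_equal(loo_robust_z(x), naive_loo_z(x), tolerance = 1e-12)
  }
  # degenerate constant vector: MAD floor engaged, z = 0 everywhere
  expect_equal(loo_robust_z(rep(1.5, 10)), rep(0, 10))
})

test_that("normalization removes lane structure and is idempotent", {
  norm <- fx_norm()
  sheet <- fx_layout()$sheet
  dt <- data.table::as.data.table(norm)
  dt <- merge(dt, sheet[, c("sample_id", "lane")], by = "sample_id")
  # per-(position, allele, lane) median residual is zero by construction
  med <- dt[, .(m = median(resid)), by = .(amplicon_id, pos, alt, lane)]
  expect_lt(max(abs(med$m)), 1e-8)
  # overall mean residual ~ 0
  expect_lt(abs(mean(dt$resid)), 0.05)

  # idempotence: re-normalizing the residual matrix changes nothing
  renorm <- data.table::copy(norm)
  renorm[, t := resid][, resid := NULL]
  norm2 <- suppressWarnings(normalize_background(
    renorm, sheet, quality = attr(fx_pileup(), "quality")))
  expect_equal(norm2$resid, norm$resid, tolerance = 1e-9)
})

test_that("an injected lane shift is recovered by the batch coefficients", {
  # the fixture pileup carries lane effects (0, 0.3, -0.1, 0.15)
  co <- batch_coefficients(fx_norm())
  expect_lt(abs(co$estimate[co$term == "laneL2"] - 0.3), 0.05)
  expect_lt(abs(co$estimate[co$term == "laneL3"] + 0.1), 0.05)
})

test_that("a hand-built lane shift has zero post-normalization lane median", {
  # 16 samples, one amplicon, flat background + 0.4 shift on lane L2
  sheet <- data.table::data.table(
    sample_id = sprintf("S%02d", 1:16),
    biopsy_id = sprintf("B%02d", 1:16), testis_id = 1L, slice_id = 1L,
    slice_position = 1:16, flow_cell = "FC1",
    lane = rep(c("L1", "L2"), each = 8),
    mean_base_quality = 34, replicate_of = NA_character_)
  set.seed(1)
  afm <- data.table::CJ(sample_id = sheet$sample_id, pos = 1:30)
  afm[, `:=`(amplicon_id = "AMP001", chrom = "chr1", ref = "A", alt = "C",
             alt_count = 1L, depth = 10000L)]
  afm[, t := rnorm(.N, -9, 0.5) + ifelse(sample_id %in% sheet$sample_id[9:16],
                                         0.4, 0)]
  norm <- suppressWarnings(normalize_background(afm, sheet))
  dt <- merge(norm, sheet[, c("sample_id", "lane")], by = "sample_id")
  med <- dt[, .(m = median(resid)), by = .(pos, lane)]
  expect_lt(max(abs(med$m)), 1e-9)
})

test_that("betabinom tail matches the naive full-support summation", {
  grid <- expand.grid(size = c(50L, 200L), a = c(0.8, 3, 20),
                      b = c(50, 400, 5000))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    xs <- c(0:3, 10L, 25L, g$size)
    expect_equal(betabinom_tail(xs, g$size, g$a, g$b),
                 vapply(xs, naive_bb_tail, numeric(1), size = g$size,
                        a = g$a, b = g$b),
                 tolerance = 1e-10)
  }
})

test_that("moment fit recovers beta-binomial parameters roughly", {
  set.seed(11)
  n <- 500; size <- 2000L; p <- 0.002; rho <- 0.002
  a <- p * (1 - rho) / rho; b <- (1 - p) * (1 - rho) / rho
  x <- rbinom(n, size, rbeta(n, a, b))
  fit <- fit_betabinom(x, rep(size, n))
  expect_equal(fit$p, p, tolerance = 0.15)
  expect_equal(fit$rho, rho, tolerance = 0.5)
  # pure binomial data: rho pinned at ~0
  xb <- rbinom(n, size, p)
  expect_lt(fit_betabinom(xb, rep(size, n))$rho, 1e-4)
})

test_that("a spiked sample is called; background samples are not", {
  calls <- fx_calls()
  tbs <- truth_by_sample(fx_truth(), fx_layout()$sheet)
  strong <- tbs[tbs$true_vaf >= 0.005, ]
  # every strong spike is recovered by the exact mode
  found <- merge(strong, calls, by = c("sample_id", "chrom", "pos", "alt"))
  expect_gte(nrow(found), floor(0.9 * nrow(strong)))
  # and every call corresponds to a true spiked (sample, site)
  chk <- merge(calls, tbs, by = c("sample_id", "chrom", "pos", "alt"))
  expect_equal(nrow(chk), nrow(calls))
  expect_true(all(calls$alt_count >= 10L))
  expect_true(all(calls$neg_log10_p > 20))
})

test_that("robust_z ranks the spiked sample first at its true position", {
  norm <- fx_norm()
  tbs <- truth_by_sample(fx_truth(), fx_layout()$sheet)
  top <- tbs[which.max(tbs$true_vaf), ]
  sub <- norm[norm$chrom == top$chrom & norm$pos == top$pos &
                norm$alt == top$alt, ]
  z <- loo_robust_z(sub$resid)
  spiked <- sub$sample_id %in% tbs$sample_id[
    tbs$pos == top$pos & tbs$true_vaf > 0.003]
  expect_true(which.max(z) %in% which(spiked))
  expect_gt(max(z[spiked]), 4)
})

test_that("emission contract: alt_count 9 is never called regardless of P", {
  sheet <- data.table::data.table(
    sample_id = sprintf("S%02d", 1:12),
    biopsy_id = sprintf("B%02d", 1:12), testis_id = 1L, slice_id = 1L,
    slice_position = 1:12, flow_cell = "FC1", lane = "L1",
    mean_base_quality = 34, replicate_of = NA_character_)
  afm <- data.table::data.table(
    sample_id = sheet$sample_id, amplicon_id = "AMP001", chrom = "chr1",
    pos = 10L, ref = "A", alt = "C",
    alt_count = c(rep(0L, 11), 9L), depth = 20000L)
  afm[, t := vaf_logit(alt_count, depth)]
  afm[, resid := t - mean(t)]
  calls <- call_outliers(afm, mode = "betabinom", p_for_all = TRUE)
  expect_equal(nrow(calls), 0L)
  # the same excess with one more read is called
  afm2 <- data.table::copy(afm)[sample_id == "S12", alt_count := 10L]
  calls2 <- call_outliers(afm2, mode = "betabinom", p_for_all = TRUE)
  expect_equal(calls2$sample_id, "S12")
})

test_that("calling is invariant to sample ordering", {
  norm <- fx_norm()
  set.seed(3)
  shuf <- norm[sample(nrow(norm)), ]
  calls1 <- fx_calls()
  calls2 <- call_outliers(shuf, mode = "betabinom")
  data.table::setorder(calls2, amplicon_id, pos, alt, sample_id)
  expect_equal(as.data.frame(calls1), as.data.frame(calls2))
})

test_that("amplicon QC thresholds behave per the coverage rule", {
  pu <- data.table::rbindlist(list(
    data.table::CJ(sample_id = sprintf("S%d", 1:9), amplicon_id = "LOW",
                   pos = 1:5)[, `:=`(chrom = "chr1", ref = "A", A = 4000L,
                                     C = 0L, G = 0L, T = 0L)],
    data.table::CJ(sample_id = sprintf("S%d", 1:9), amplicon_id = "HIGH",
                   pos = 1:5)[, `:=`(chrom = "chr1", ref = "A", A = 20000L,
                                     C = 0L, G = 0L, T = 0L)]))
  panel <- data.table::data.table(amplicon_id = c("LOW", "HIGH", "EMPTY"))
  qc <- amplicon_qc(pu, min_amplicon_depth = 5000, panel = panel)
  expect_equal(qc$pass[qc$amplicon_id == "LOW"], FALSE)
  expect_equal(qc$pass[qc$amplicon_id == "HIGH"], TRUE)
  expect_equal(qc$pass[qc$amplicon_id == "EMPTY"], FALSE)
})
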