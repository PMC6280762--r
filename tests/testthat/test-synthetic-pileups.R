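test_that("simulated pileups are deterministic and cover callable space", {
  pu <- fx_pileup()
  pu2 <- simulate_pileups(
    fx_panel(), fx_layout(), fx_truth(),
    error_model_config(lane_effects = c(L1 = 0, L2 = 0.3, L3 = -0.1,
                                        L4 = 0.15)),
    depth_config(mean_depth = 15000), seed = 7)
  expect_equal(as.data.frame(pu), as.data.frame(pu2))

  panel <- fx_panel()
  callable <- sum(panel$callable_end - panel$callable_start)
  expect_equal(nrow(pu), callable * nrow(fx_layout()$sheet))
  # counts are non-negative integers and reference carries the depth
  counts <- as.matrix(pu[, c("A", "C", "G", "T")])
  expect_true(all(counts >= 0))
  expect_equal(mean(pileup_depth(pu)), 15000, tolerance = 0.02)
})

test_that("null background alt fractions track the configured error rate", {
  # no clones: mean alt fraction per position should sit near the log-normal
  # mean exp(sigma^2/2) * median ~ 1.38e-4 per alt allele, well inside the
  # [5e-5, 2e-4] Monte-Carlo band
  lay <- build_layout(layout_config(n_testes = 1, slices_per_testis = 2,
                                    biopsies_per_slice = 24,
                                    n_replicates = 0), seed = 31)
  tr <- place_clones(fx_panel(), lay, clone_config(n_clones = 0), seed = 31)
  pu <- simulate_pileups(fx_panel(), lay, tr,
                         error_model_config(median_error = 1e-4, sigma = 0.8),
                         depth_config(mean_depth = 15000), seed = 31)
  afm <- allele_fraction_matrix(pu)
  per_pos <- afm[, .(frac = sum(alt_count) / sum(depth)),
                 by = .(amplicon_id, pos, alt)]
  expect_gt(mean(per_pos$frac), 5e-5)
  expect_lt(mean(per_pos$frac), 2e-4)
})

test_that("spiked VAF produces the expected mean alt count", {
  # VAF 0.01 at depth 15000 with near-zero error -> mean alt count ~ 150;
  # the template bottleneck (1000 molecules) adds ~32% per-sample noise
  lay <- build_layout(layout_config(n_testes = 1, slices_per_testis = 2,
                                    biopsies_per_slice = 20,
                                    n_replicates = 0), seed = 13)
  panel <- fx_panel()
  site <- panel[1, ]
  refb <- reference_base(panel, site$chrom, site$callable_start + 5L)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  binfo <- map_biopsies(lay$map)
  tr <- structure(list(
    clones = data.table::data.table(
      clone_id = "CL001", kind = "CLONAL", tandem_id = NA_character_,
      testis_id = 1L, chrom = site$chrom, pos = site$callable_start + 5L,
      ref = refb, alt = altb),
    occupancy = data.table::data.table(
      clone_id = "CL001", biopsy_id = binfo$biopsy_id, vaf = 0.01)),
    class = "clonescan_truth")
  pu <- simulate_pileups(panel, lay, tr,
                         error_model_config(median_error = 1e-6, rho = 0),
                         depth_config(mean_depth = 15000, n_templates = 1000),
                         seed = 13)
  at <- pu[pu$chrom == site$chrom & pu$pos == site$callable_start + 5L, ]
  alt_counts <- at[[altb]]
  expect_equal(mean(alt_counts), 150, tolerance = 0.18)
})

test_that("template bottleneck: ~exp(-1) of samples carry zero molecules", {
  # true VAF 0.001 through 1000 templates: P(0 mutant templates) ~ e^-1
  lay <- build_layout(layout_config(n_testes = 1, slices_per_testis = 10,
                                    biopsies_per_slice = 20,
                                    n_replicates = 0), seed = 17)
  panel <- fx_panel()
  site <- panel[2, ]
  target <- site$callable_start + 3L
  refb <- reference_base(panel, site$chrom, target)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  binfo <- map_biopsies(lay$map)
  tr <- structure(list(
    clones = data.table::data.table(
      clone_id = "CL001", kind = "CLONAL", tandem_id = NA_character_,
      testis_id = 1L, chrom = site$chrom, pos = target, ref = refb,
      alt = altb),
    occupancy = data.table::data.table(
      clone_id = "CL001", biopsy_id = binfo$biopsy_id, vaf = 0.001)),
    class = "clonescan_truth")
  pu <- simulate_pileups(panel, lay, tr,
                         error_model_config(median_error = 1e-7, sigma = 0.1,
                                            rho = 0),
                         depth_config(mean_depth = 15000, n_templates = 1000),
                         seed = 17)
  at <- pu[as.data.frame(pu)$chrom == site$chrom &
             as.data.frame(pu)$pos == target, ]
  # zero templates -> alt count is pure error (<< 8); one template -> ~15
  zero_frac <- mean(at[[altb]] < 8)
  expect_equal(zero_frac, exp(-1), tolerance = 0.25)
})

test_that("realized VAF variance matches the bottleneck + sampling formula", {
  # Var(alt/depth) ~ p(1-p)/n_templates + p/depth, checked within 20%
  lay <- build_layout(layout_config(n_testes = 1, slices_per_testis = 25,
                                    biopsies_per_slice = 20,
                                    n_replicates = 0), seed = 23)
  panel <- fx_panel()
  site <- panel[3, ]
  target <- site$callable_start + 2L
  refb <- reference_base(panel, site$chrom, target)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  binfo <- map_biopsies(lay$map)
  p <- 0.01; Tm <- 1000L; d <- 15000
  tr <- structure(list(
    clones = data.table::data.table(
      clone_id = "CL001", kind = "CLONAL", tandem_id = NA_character_,
      testis_id = 1L, chrom = site$chrom, pos = target, ref = refb,
      alt = altb),
    occupancy = data.table::data.table(
      clone_id = "CL001", biopsy_id = binfo$biopsy_id, vaf = p)),
    class = "clonescan_truth")
  pu <- simulate_pileups(panel, lay, tr,
                         error_model_config(median_error = 1e-7, sigma = 0.1,
                                            rho = 0),
                         depth_config(mean_depth = d, depth_size = 1e6,
                                      n_templates = Tm),
                         seed = 23)
  at <- pu[as.data.frame(pu)$chrom == site$chrom &
             as.data.frame(pu)$pos == target, ]
  vafs <- at[[altb]] / pileup_depth(at)
  analytic <- p * (1 - p) / Tm + p / d
  expect_equal(var(vafs), analytic, tolerance = 0.2)
})
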