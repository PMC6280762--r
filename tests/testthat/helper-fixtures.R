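# shared fixtures, built once per test run (everything is generated in code;
# no files ship with the package)

.fx <- new.env(parent = emptyenv())

fx_panel <- function() {
  if (is.null(.fx$panel))
    .fx$panel <- build_panel(panel_config(n_amplicons = 30,
                                          overlap_fraction = 0.1), seed = 7)
  .fx$panel
}

fx_layout <- function() {
  # 48 samples: 1 testis, 2 slices x 23 biopsies, 2 replicates
  if (is.null(.fx$layout))
    .fx$layout <- build_layout(layout_config(
      n_testes = 1, slices_per_testis = 2, biopsies_per_slice = 23,
      n_replicates = 2, n_flow_cells = 1, lanes_per_flow_cell = 4), seed = 7)
  .fx$layout
}

fx_truth <- function() {
  if (is.null(.fx$truth))
    .fx$truth <- place_clones(fx_panel(), fx_layout(),
                              clone_config(n_clones = 4), seed = 7)
  .fx$truth
}

fx_pileup <- function() {
  if (is.null(.fx$pileup))
    .fx$pileup <- simulate_pileups(
      fx_panel(), fx_layout(), fx_truth(),
      error_model_config(lane_effects = c(L1 = 0, L2 = 0.3, L3 = -0.1,
                                          L4 = 0.15)),
      depth_config(mean_depth = 15000), seed = 7)
  .fx$pileup
}

fx_norm <- function() {
  if (is.null(.fx$norm)) {
    afm <- allele_fraction_matrix(fx_pileup())
    .fx$norm <- suppressWarnings(normalize_background(
      afm, fx_layout()$sheet, quality = attr(fx_pileup(), "quality")))
  }
  .fx$norm
}

fx_calls <- function() {
  if (is.null(.fx$calls))
    .fx$calls <- call_outliers(fx_norm(), mode = "betabinom")
  .fx$calls
}

# a tiny hand-made layout whose graph is easy to reason about:
# 1 testis, 3 slices x 8 biopsies
fx_small_map <- function() {
  if (is.null(.fx$small))
    .fx$small <- build_layout(layout_config(
      n_testes = 1, slices_per_testis = 3, biopsies_per_slice = 8,
      n_replicates = 0), seed = 1)
  .fx$small
}

# strip everything but core data.frame attributes, for content comparisons
plain <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "class", "row.names")]
  x
}

# naive reference implementation of the leave-one-out robust z
naive_loo_z <- function(x, min_scale = 0.05) {
  n <- length(x)
  vapply(seq_len(n), function(s) {
    others <- x[-s]
    m <- median(others)
    sc <- max(1.4826 * median(abs(others - m)), min_scale)
    (x[s] - m) / sc
  }, numeric(1))
}

# naive full-support summation of the beta-binomial upper tail
naive_bb_tail <- function(x, size, a, b) {
  k <- 0:size
  pmf <- choose(size, k) * beta(k + a, size - k + b) / beta(a, b)
  sum(pmf[k >= x])
}

# enumeration oracle for the two-tailed Fisher test
naive_fisher2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(a) {
    choose(m, a) * choose(n, k - a) / choose(m + n, k)
  }, numeric(1))
  obs <- probs[(lo:hi) == tab[1, 1]]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# minimal hand-rolled panel for read-level tests: one amplicon, known
# reference, controllable primers
toy_panel <- function(fwd = 5L, rev = 5L, len = 60L, refbases = NULL) {
  p <- data.table::data.table(
    amplicon_id = "AMP001", gene = "KRAS", pathway = "RAS_MAPK",
    chrom = "chrT", start = 100L, end = 100L + len,
    fwd_primer_len = fwd, rev_primer_len = rev,
    callable_start = 100L + fwd, callable_end = 100L + len - rev)
  set.seed(404)
  ref <- data.table::data.table(
    chrom = "chrT", pos = 100L + seq_len(len) - 1L,
    base = if (is.null(refbases)) sample(c("A", "C", "G", "T"), len, TRUE)
    else refbases)
  data.table::setattr(p, "reference", ref)
  data.table::setattr(p, "class", c("clonescan_panel", class(p)))
  p
}

# build a read record row
toy_read <- function(sample_id, amplicon_id, pair_id, mate, start, bases,
                     quals = NULL) {
  if (is.null(quals)) quals <- strrep(rawToChar(as.raw(30 + 33)), nchar(bases))
  data.table::data.table(sample_id = sample_id, amplicon_id = amplicon_id,
                         pair_id = pair_id, mate = mate, start = start,
                         bases = bases, quals = quals)
}

# phred+33 string from integer qualities
qstr <- function(q) intToUtf8(q + 33L, multiple = FALSE)
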