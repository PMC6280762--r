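#' Assemble a full run configuration
#'
#' Bundles every module's configuration plus the global seed.  Unknown keys
#' in any section are rejected, so a typo in a YAML file fails loudly
#' rather than silently using a default.
#'
#' @param seed global integer seed; all module substreams derive from it.
#' @param panel,layout,clones,error_model,depth named lists of arguments for
#'   [panel_config()], [layout_config()], [clone_config()],
#'   [error_model_config()], [depth_config()].
#' @param calling list: `p_cutoff`, `min_alt_reads`, `mode`,
#'   `min_amplicon_depth`, `min_scale`.
#' @param filters arguments for [filter_config()].
#' @param postzygotic arguments for [postzygotic_config()].
#' @param enrichment list: `pathway`, `tandem_background_rate`.
#' @return nested list of class `run_config`.
#' @export
run_config <- function(seed = 1L, panel = list(), layout = list(),
                       clones = list(), error_model = list(),
                       depth = list(), calling = list(), filters = list(),
                       postzygotic = list(), enrichment = list()) {
  check_args <- function(given, fn, section) {
    ok <- names(formals(fn))
    bad <- setdiff(names(given), ok)
    if (length(bad))
      abort_input("run_config: unknown key(s) in '%s': %s", section,
                  paste(bad, collapse = ", "))
    given
  }
  calling_defaults <- list(p_cutoff = 20, min_alt_reads = 10L,
                           mode = "betabinom", min_amplicon_depth = 5000,
                           min_scale = 0.05)
  enrich_defaults <- list(pathway = "RAS_MAPK", tandem_background_rate = 0.003)
  bad <- setdiff(names(calling), names(calling_defaults))
  if (length(bad))
    abort_input("run_config: unknown key(s) in 'calling': %s",
                paste(bad, collapse = ", "))
  bad <- setdiff(names(enrichment), names(enrich_defaults))
  if (length(bad))
    abort_input("run_config: unknown key(s) in 'enrichment': %s",
                paste(bad, collapse = ", "))
  structure(list(
    seed = as.integer(seed),
    panel = check_args(panel, panel_config, "panel"),
    layout = check_args(layout, layout_config, "layout"),
    clones = check_args(clones, clone_config, "clones"),
    error_model = check_args(error_model, error_model_config, "error_model"),
    depth = check_args(depth, depth_config, "depth"),
    calling = utils::modifyList(calling_defaults, calling),
    filters = check_args(filters, filter_config, "filters"),
    postzygotic = check_args(postzygotic, postzygotic_config, "postzygotic"),
    enrichment = utils::modifyList(enrich_defaults, enrichment)),
    class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @param config a `run_config`.
#' @return `read_config`: a validated `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    abort_input("%s: unknown top-level key(s): %s", path,
                paste(bad, collapse = ", "))
  do.call(run_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# ---- pipeline stages -------------------------------------------------------
# Each stage reads its inputs from `outdir` (except simulate) and writes its
# outputs there, so CLI subcommands chained over one directory reproduce
# run_pipeline() exactly.

#' @rdname run_pipeline
#' @export
stage_simulate <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  panel <- build_panel(do.call(panel_config, config$panel), config$seed)
  layout <- build_layout(do.call(layout_config, config$layout), config$seed)
  truth <- place_clones(panel, layout, do.call(clone_config, config$clones),
                        config$seed)
  pileup <- simulate_pileups(panel, layout, truth,
                             do.call(error_model_config, config$error_model),
                             do.call(depth_config, config$depth), config$seed)
  write_panel(panel, outdir)
  write_sheet(layout$sheet, file.path(outdir, "sheet.tsv"))
  write_map(layout$map, outdir)
  write_truth(truth, outdir)
  write_pileup(pileup, file.path(outdir, "pileup.tsv"))
  invisible(outdir)
}

#' @rdname run_pipeline
#' @export
stage_call <- function(config, outdir) {
  panel <- read_panel(outdir)
  sheet <- read_sheet(file.path(outdir, "sheet.tsv"))
  pileup <- read_pileup(file.path(outdir, "pileup.tsv"))
  qc <- amplicon_qc(pileup, config$calling$min_amplicon_depth, panel)
  .fwrite(qc, file.path(outdir, "amplicon_qc.tsv"))
  keep <- qc[qc$pass]$amplicon_id
  pu <- pileup[pileup$amplicon_id %in% keep]
  afm <- allele_fraction_matrix(pu)
  norm <- normalize_background(afm, sheet, quality = attr(pileup, "quality"))
  .fwrite(attr(norm, "coefficients"), file.path(outdir, "coefficients.tsv"))
  calls <- call_outliers(norm, p_cutoff = config$calling$p_cutoff,
                         min_alt_reads = config$calling$min_alt_reads,
                         mode = config$calling$mode,
                         min_scale = config$calling$min_scale)
  write_calls(calls, file.path(outdir, "calls_raw.tsv"))
  invisible(outdir)
}

#' @rdname run_pipeline
#' @export
stage_prioritize <- function(config, outdir) {
  panel <- read_panel(outdir)
  sheet <- read_sheet(file.path(outdir, "sheet.tsv"))
  pileup <- read_pileup(file.path(outdir, "pileup.tsv"))
  calls <- read_calls(file.path(outdir, "calls_raw.tsv"))
  cfg <- do.call(filter_config, config$filters)
  res <- prioritize(calls, pileup, panel, sheet, cfg)
  write_candidates(res, outdir)
  write_calls(res$calls[, .(sample_id, amplicon_id, chrom, pos, ref, alt,
                            alt_count, depth, vaf, neg_log10_p)],
              file.path(outdir, "calls_filtered.tsv"))
  write_vcf(res$candidates, file.path(outdir, "candidates.vcf"))
  jsonlite::write_json(as.list(res$stages),
                       file.path(outdir, "stage_counts.json"),
                       auto_unbox = TRUE)
  invisible(outdir)
}

#' @rdname run_pipeline
#' @export
stage_clones <- function(config, outdir) {
  map <- read_map(outdir)
  cand <- read_candidates(outdir)
  pz_cfg <- do.call(postzygotic_config, config$postzygotic)
  if (nrow(cand$by_biopsy)) {
    events <- build_events(cand$by_biopsy, map)
    flags <- flag_postzygotic(cand$by_biopsy, map, pz_cfg)
    events <- merge(events, flags[, .(chrom, pos, ref, alt, testis_id,
                                      postzygotic)],
                    by = c("chrom", "pos", "ref", "alt", "testis_id"))
    n_events <- count_independent_events(cand$by_biopsy)
  } else {
    events <- data.table(chrom = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         testis_id = integer(0), component = integer(0),
                         members = character(0), n_biopsies = integer(0),
                         span_slices = integer(0), n_components = integer(0),
                         lower_bound = integer(0), connected = logical(0),
                         postzygotic = logical(0))
    n_events <- 0L
  }
  write_events(events, file.path(outdir, "events.tsv"))
  jsonlite::write_json(list(independent_events = n_events),
                       file.path(outdir, "events_summary.json"),
                       auto_unbox = TRUE)
  invisible(outdir)
}

#' @rdname run_pipeline
#' @export
stage_enrich <- function(config, outdir) {
  panel <- read_panel(outdir)
  cand <- read_candidates(outdir)
  enr <- pathway_enrichment(cand$candidates, panel,
                            pathway = config$enrichment$pathway,
                            tandem_background_rate =
                              config$enrichment$tandem_background_rate)
  jsonlite::write_json(list(
    table = as.vector(enr$table), fisher_p = enr$fisher_p,
    log_odds = enr$logistic$log_odds, wald_p = enr$logistic$wald_p,
    tandem_fold = enr$tandem_fold, n_tandem = enr$n_tandem,
    n_total = enr$n_total),
    file.path(outdir, "enrichment.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Run the full pipeline end to end
#'
#' Simulate (or ingest), call, prioritize, map clonal events, compute
#' enrichment, and write a run manifest with the seed, package version and
#' the call count at each stage of the filter cascade.  Deterministic under
#' a fixed configuration; partial outputs are removed on failure.
#'
#' @param config a [run_config()].
#' @param outdir output directory.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  created <- !dir.exists(outdir)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(outdir, recursive = TRUE))
  stage_simulate(config, outdir)
  stage_call(config, outdir)
  stage_prioritize(config, outdir)
  stage_clones(config, outdir)
  stage_enrich(config, outdir)

  stages <- jsonlite::read_json(file.path(outdir, "stage_counts.json"))
  cand <- read_candidates(outdir)
  ev <- jsonlite::read_json(file.path(outdir, "events_summary.json"))
  manifest <- list(
    package = "clonescan",
    version = as.character(utils::packageVersion("clonescan")),
    seed = config$seed,
    stage_counts = stages,
    n_candidates = nrow(cand$candidates),
    tier_counts = as.list(table(factor(cand$candidates$tier, levels = 1:4))),
    independent_events = ev$independent_events)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}
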