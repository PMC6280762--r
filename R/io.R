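#' @name io
#' @title On-disk formats
#' @description
#' Every artifact round-trips through plain-text formats: BED + TSV for the
#' panel (0-based half-open, BED convention), TSVs for sample sheet, biopsy
#' map, ground truth, pileups, calls, candidates and events, a VCF-like file
#' for candidates (1-based POS), YAML for run configuration and JSON for
#' reports.  All readers validate their schema and name the offending file
#' and field on failure.
NULL

.check_cols <- function(dt, cols, path) {
  miss <- setdiff(cols, names(dt))
  if (length(miss))
    abort_input("%s: missing required column(s): %s", path,
                paste(miss, collapse = ", "))
}

.fwrite <- function(dt, path) fwrite(dt, path, sep = "\t", quote = FALSE)

#' Write / read an amplicon panel
#'
#' Writes three files under `dir`: `panel.bed` (BED6-minus: chrom, start,
#' end, amplicon_id), `panel_meta.tsv` (full amplicon metadata) and
#' `reference.tsv` (per-position reference base).
#'
#' @param panel a `clonescan_panel`.
#' @param dir output directory (created if needed).
#' @return `write_panel`: invisibly, the paths written. `read_panel`: the
#'   reconstructed panel.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed <- panel[, .(chrom, start, end, amplicon_id)]
  fwrite(bed, file.path(dir, "panel.bed"), sep = "\t", quote = FALSE,
         col.names = FALSE) # BED has no header line
  .fwrite(as.data.table(panel), file.path(dir, "panel_meta.tsv"))
  .fwrite(attr(panel, "reference"), file.path(dir, "reference.tsv"))
  invisible(file.path(dir, c("panel.bed", "panel_meta.tsv", "reference.tsv")))
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  meta_path <- file.path(dir, "panel_meta.tsv")
  ref_path <- file.path(dir, "reference.tsv")
  meta <- fread(meta_path)
  .check_cols(meta, c("amplicon_id", "gene", "pathway", "chrom", "start",
                      "end", "fwd_primer_len", "rev_primer_len",
                      "callable_start", "callable_end"), meta_path)
  ref <- fread(ref_path)
  .check_cols(ref, c("chrom", "pos", "base"), ref_path)
  setattr(meta, "reference", ref)
  setattr(meta, "class", c("clonescan_panel", class(meta)))
  meta[]
}

#' Write / read a sample sheet
#' @param sheet the sample sheet `data.table`.
#' @param path TSV path.
#' @return `read_sheet`: the sheet.
#' @export
write_sheet <- function(sheet, path) .fwrite(sheet, path)

#' @rdname write_sheet
#' @export
read_sheet <- function(path) {
  s <- fread(path, colClasses = list(character = "replicate_of"))
  .check_cols(s, c("sample_id", "biopsy_id", "testis_id", "slice_id",
                   "slice_position", "flow_cell", "lane",
                   "mean_base_quality", "replicate_of"), path)
  s[replicate_of == "", replicate_of := NA_character_]
  s[]
}

#' Write / read a biopsy adjacency map
#'
#' Two TSVs under `dir`: `biopsies.tsv` (vertex metadata) and
#' `map_edges.tsv` (undirected edges).
#'
#' @param map an igraph biopsy map.
#' @param dir directory.
#' @return `read_map`: the reconstructed igraph object.
#' @export
write_map <- function(map, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .fwrite(map_biopsies(map), file.path(dir, "biopsies.tsv"))
  e <- igraph::as_edgelist(map)
  .fwrite(data.table(biopsy_a = e[, 1], biopsy_b = e[, 2]),
          file.path(dir, "map_edges.tsv"))
  invisible(dir)
}

#' @rdname write_map
#' @export
read_map <- function(dir) {
  b <- fread(file.path(dir, "biopsies.tsv"))
  .check_cols(b, c("biopsy_id", "testis_id", "slice_id", "slice_position"),
              file.path(dir, "biopsies.tsv"))
  e <- fread(file.path(dir, "map_edges.tsv"))
  .check_cols(e, c("biopsy_a", "biopsy_b"), file.path(dir, "map_edges.tsv"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(b), name = b$biopsy_id,
                            testis_id = b$testis_id, slice_id = b$slice_id,
                            slice_position = b$slice_position)
  if (nrow(e)) g <- igraph::add_edges(g, as.vector(t(as.matrix(e))))
  g
}

#' Write / read ground truth
#' @param truth a `clonescan_truth`.
#' @param dir directory (`truth_clones.tsv`, `truth_occupancy.tsv`).
#' @return `read_truth`: the reconstructed truth object.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .fwrite(truth$clones, file.path(dir, "truth_clones.tsv"))
  .fwrite(truth$occupancy, file.path(dir, "truth_occupancy.tsv"))
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  cl <- fread(file.path(dir, "truth_clones.tsv"),
              colClasses = list(character = "tandem_id"))
  .check_cols(cl, c("clone_id", "kind", "tandem_id", "testis_id", "chrom",
                    "pos", "ref", "alt"), file.path(dir, "truth_clones.tsv"))
  cl[tandem_id == "", tandem_id := NA_character_]
  occ <- fread(file.path(dir, "truth_occupancy.tsv"))
  .check_cols(occ, c("clone_id", "biopsy_id", "vaf"),
              file.path(dir, "truth_occupancy.tsv"))
  structure(list(clones = cl[], occupancy = occ[]), class = "clonescan_truth")
}

#' Write / read a pileup matrix (long TSV)
#' @param pileup a `clonescan_pileup`.
#' @param path TSV path; the per-(sample, amplicon) quality table, if
#'   attached, is written next to it as `<path>.quality.tsv`.
#' @return `read_pileup`: the pileup (quality re-attached when present).
#' @export
write_pileup <- function(pileup, path) {
  .fwrite(as.data.table(pileup), path)
  q <- attr(pileup, "quality")
  if (!is.null(q)) .fwrite(q, paste0(path, ".quality.tsv"))
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  p <- fread(path)
  .check_cols(p, c("sample_id", "amplicon_id", "chrom", "pos", "ref",
                   "A", "C", "G", "T"), path)
  qp <- paste0(path, ".quality.tsv")
  if (file.exists(qp)) setattr(p, "quality", fread(qp))
  setattr(p, "class", c("clonescan_pileup", class(p)))
  p[]
}

#' Write / read variant calls
#' @param calls a calls `data.table`.
#' @param path TSV path.
#' @return `read_calls`: the calls.
#' @export
write_calls <- function(calls, path) .fwrite(calls, path)

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  cc <- fread(path)
  .check_cols(cc, c("sample_id", "amplicon_id", "chrom", "pos", "ref", "alt",
                    "alt_count", "depth", "vaf", "neg_log10_p"), path)
  cc[]
}

#' Write / read prioritized candidates
#'
#' `candidates.tsv` (one row per candidate, with tier) and
#' `candidates_by_biopsy.tsv` (per-biopsy mean VAFs).
#'
#' @param result a `clonescan_candidates` (from [prioritize()]).
#' @param dir directory.
#' @return `read_candidates`: list with `candidates` and `by_biopsy`.
#' @export
write_candidates <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .fwrite(result$candidates, file.path(dir, "candidates.tsv"))
  .fwrite(result$by_biopsy, file.path(dir, "candidates_by_biopsy.tsv"))
  invisible(dir)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(dir) {
  cand <- fread(file.path(dir, "candidates.tsv"))
  .check_cols(cand, c("chrom", "pos", "ref", "alt", "n_biopsies", "max_vaf",
                      "tier"), file.path(dir, "candidates.tsv"))
  pb <- fread(file.path(dir, "candidates_by_biopsy.tsv"))
  .check_cols(pb, c("chrom", "pos", "ref", "alt", "biopsy_id", "testis_id",
                    "vaf"), file.path(dir, "candidates_by_biopsy.tsv"))
  list(candidates = cand[], by_biopsy = pb[])
}

#' Export candidates as a VCF-like file
#'
#' One record per candidate; internal 0-based positions become 1-based POS
#' per VCF convention.  INFO carries `TIER`, `NBIOPSY` and `MAXVAF`.
#'
#' @param candidates candidate table (with `tier, n_biopsies, max_vaf`).
#' @param path output path.
#' @return `read_vcf`: a `data.table` with 0-based `pos` restored.
#' @export
write_vcf <- function(candidates, path) {
  cand <- as.data.table(candidates)
  lines <- c("##fileformat=VCFv4.2",
             "##source=clonescan",
             paste0("##INFO=<ID=TIER,Number=1,Type=Integer,",
                    "Description=\"Confidence tier (1-4)\">"),
             paste0("##INFO=<ID=NBIOPSY,Number=1,Type=Integer,",
                    "Description=\"Positive biopsies\">"),
             paste0("##INFO=<ID=MAXVAF,Number=1,Type=Float,",
                    "Description=\"Maximum per-biopsy mean VAF\">"),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(cand)) {
    setorder(cand, chrom, pos, alt)
    recs <- cand[, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tTIER=%d;NBIOPSY=%d;MAXVAF=%.6g",
                           chrom, pos + 1L, ref, alt, tier, n_biopsies, max_vaf)]
    lines <- c(lines, recs)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.table(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      tier = integer(0), n_biopsies = integer(0),
                      max_vaf = numeric(0)))
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  info <- f[[8]]
  grab <- function(key) sub(sprintf(".*%s=([^;]+).*", key), "\\1", info)
  data.table(chrom = f[[1]], pos = as.integer(f[[2]]) - 1L,
             ref = f[[4]], alt = f[[5]],
             tier = as.integer(grab("TIER")),
             n_biopsies = as.integer(grab("NBIOPSY")),
             max_vaf = as.numeric(grab("MAXVAF")))
}

#' Write / read read records
#' @param reads read record table.
#' @param path TSV path.
#' @return `read_reads`: the records.
#' @export
write_reads <- function(reads, path) .fwrite(reads, path)

#' @rdname write_reads
#' @export
read_reads <- function(path) {
  r <- fread(path)
  .check_cols(r, c("sample_id", "amplicon_id", "pair_id", "mate", "start",
                   "bases", "quals"), path)
  r[]
}

#' Write / read clonal events
#' @param events events table from [build_events()] (optionally merged with
#'   post-zygotic flags).
#' @param path TSV path.
#' @return `read_events`: the table.
#' @export
write_events <- function(events, path) .fwrite(events, path)

#' @rdname write_events
#' @export
read_events <- function(path) {
  e <- fread(path)
  .check_cols(e, c("chrom", "pos", "ref", "alt", "testis_id", "component",
                   "members"), path)
  e[]
}
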