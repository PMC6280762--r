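#' Configuration for a synthetic biopsy layout
#'
#' Emulates whole-organ dissection: each testis is cut into parallel slices,
#' each slice into a ring of radially arranged biopsies.  Samples inherit
#' batch covariates (flow cell, lane, mean base quality) and a subset of
#' biopsies is amplified in duplicate.
#'
#' @param n_testes number of testes.
#' @param slices_per_testis slices per testis (recycled across testes).
#' @param biopsies_per_slice biopsies per slice ring.
#' @param n_replicates number of biopsies amplified in duplicate (across the
#'   whole study).
#' @param n_flow_cells,lanes_per_flow_cell batch structure; samples are dealt
#'   into `(flow_cell, lane)` cells in balanced round-robin order after a
#'   seeded shuffle.
#' @param base_quality_mean,base_quality_sd per-sample mean base quality
#'   (Phred); per-sample values are drawn normal and shared downstream.
#' @return a list of class `layout_config`.
#' @export
layout_config <- function(n_testes = 1L,
                          slices_per_testis = 2L,
                          biopsies_per_slice = 24L,
                          n_replicates = 2L,
                          n_flow_cells = 1L,
                          lanes_per_flow_cell = 4L,
                          base_quality_mean = 34,
                          base_quality_sd = 1.5) {
  cfg <- list(n_testes = as.integer(n_testes),
              slices_per_testis = as.integer(slices_per_testis),
              biopsies_per_slice = as.integer(biopsies_per_slice),
              n_replicates = as.integer(n_replicates),
              n_flow_cells = as.integer(n_flow_cells),
              lanes_per_flow_cell = as.integer(lanes_per_flow_cell),
              base_quality_mean = base_quality_mean,
              base_quality_sd = base_quality_sd)
  n_biopsies <- cfg$n_testes * cfg$slices_per_testis * cfg$biopsies_per_slice
  if (cfg$n_replicates > n_biopsies)
    abort_input("layout_config: more replicates (%d) than biopsies (%d)",
                cfg$n_replicates, n_biopsies)
  structure(cfg, class = "layout_config")
}

#' Build a synthetic sample sheet and biopsy adjacency map
#'
#' The adjacency graph connects ring-neighbouring biopsies within a slice and
#' same-index biopsies of adjacent slices of the same testis — the two routes
#' along which a clone confined to a seminiferous tubule can appear in more
#' than one biopsy.  Testes are disconnected components by construction.
#'
#' @param config a [layout_config()].
#' @param seed integer seed.
#' @return a list of class `clonescan_layout` with elements
#'   \describe{
#'     \item{sheet}{`data.table`: `sample_id, biopsy_id, testis_id, slice_id,
#'       slice_position, flow_cell, lane, mean_base_quality, replicate_of`}
#'     \item{map}{an [igraph::graph] over `biopsy_id` vertices, with vertex
#'       attributes `testis_id`, `slice_id`, `slice_position`}
#'   }
#' @export
build_layout <- function(config = layout_config(), seed = 1L) {
  stopifnot(inherits(config, "layout_config"))
  with_seed(substream_seed(seed, "layout"), {
    biopsies <- data.table(expand.grid(
      slice_position = seq_len(config$biopsies_per_slice),
      slice_id = seq_len(config$slices_per_testis),
      testis_id = seq_len(config$n_testes)))
    biopsies[, biopsy_id := sprintf("T%d_S%d_B%02d",
                                    testis_id, slice_id, slice_position)]

    edges <- character(0)
    B <- config$biopsies_per_slice
    for (t in seq_len(config$n_testes)) {
      for (s in seq_len(config$slices_per_testis)) {
        ids <- biopsies[testis_id == t & slice_id == s][order(slice_position)]$biopsy_id
        if (B == 2L) {
          edges <- c(edges, ids[1], ids[2])
        } else if (B >= 3L) {
          ring <- c(rbind(ids, ids[c(2:B, 1L)]))
          edges <- c(edges, ring)
        }
        if (s > 1L) {
          prev <- biopsies[testis_id == t & slice_id == s - 1L][order(slice_position)]$biopsy_id
          edges <- c(edges, c(rbind(prev, ids)))
        }
      }
    }
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, nrow(biopsies), name = biopsies$biopsy_id,
                              testis_id = biopsies$testis_id,
                              slice_id = biopsies$slice_id,
                              slice_position = biopsies$slice_position)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    g <- igraph::simplify(g)

    # replicated biopsies get a second sample entry pointing at the first
    rep_biopsies <- if (config$n_replicates > 0L)
      sample(biopsies$biopsy_id, config$n_replicates) else character(0)
    sheet <- copy(biopsies)
    sheet[, sample_id := sprintf("SAMP%03d", seq_len(.N))]
    sheet[, replicate_of := NA_character_]
    if (length(rep_biopsies)) {
      reps <- sheet[biopsy_id %in% rep_biopsies]
      reps[, replicate_of := sample_id]
      reps[, sample_id := sprintf("SAMP%03d", nrow(sheet) + seq_len(.N))]
      sheet <- rbind(sheet, reps)
    }

    # balanced batch assignment over (flow_cell, lane) cells
    cells <- data.table(expand.grid(
      lane = seq_len(config$lanes_per_flow_cell),
      flow_cell = seq_len(config$n_flow_cells)))
    ord <- sample(nrow(sheet))
    sheet[ord, `:=`(
      flow_cell = sprintf("FC%d", cells$flow_cell[((seq_len(.N) - 1L) %% nrow(cells)) + 1L]),
      lane = sprintf("L%d", cells$lane[((seq_len(.N) - 1L) %% nrow(cells)) + 1L]))]
    sheet[, mean_base_quality := pmax(
      2, rnorm(.N, config$base_quality_mean, config$base_quality_sd))]

    setcolorder(sheet, c("sample_id", "biopsy_id", "testis_id", "slice_id",
                         "slice_position", "flow_cell", "lane",
                         "mean_base_quality", "replicate_of"))
    setorder(sheet, sample_id)
    structure(list(sheet = sheet[], map = g, config = config, seed = seed),
              class = "clonescan_layout")
  })
}

#' Biopsy metadata table of a layout's adjacency map
#' @param map an igraph biopsy map.
#' @return `data.table` of `biopsy_id, testis_id, slice_id, slice_position`.
#' @export
map_biopsies <- function(map) {
  data.table(biopsy_id = igraph::V(map)$name,
             testis_id = igraph::V(map)$testis_id,
             slice_id = igraph::V(map)$slice_id,
             slice_position = igraph::V(map)$slice_position)
}
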