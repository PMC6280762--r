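#' Count independent mutational events
#'
#' The conservative lower-bound convention: one event per variant per testis.
#' A variant observed in biopsies of k different testes must have arisen at
#' least k times independently (clones cannot cross between testes), whereas
#' multiple patches within one testis may still be one clone threading a
#' tubule, so they count once.
#'
#' @param occurrences `data.table` with columns `chrom, pos, ref, alt,
#'   testis_id` (one row per variant-positive biopsy or any finer grain).
#' @return integer event count.
#' @export
count_independent_events <- function(occurrences) {
  occ <- as.data.table(occurrences)
  if (!nrow(occ)) return(0L)
  per_variant <- occ[, .(n_testes = length(unique(testis_id))),
                     by = .(chrom, pos, ref, alt)]
  sum(per_variant$n_testes)
}

#' Decompose a candidate's positive biopsies into clonal events
#'
#' Within each testis, the connected components of the candidate's positive
#' biopsies on the adjacency graph give an upper bound on the number of
#' distinct mutational events; the conservative lower bound is one event per
#' testis (the experiment cannot exclude that separated patches are one
#' clone dipping below detection in between).
#'
#' @param occurrences per-biopsy occurrences of one or more variants
#'   (`chrom, pos, ref, alt, biopsy_id, testis_id, vaf`).
#' @param map the biopsy adjacency graph.
#' @return `data.table`, one row per (variant, testis, component):
#'   `chrom, pos, ref, alt, testis_id, component, members, n_biopsies,
#'   span_slices, n_components, lower_bound, connected`.
#' @export
build_events <- function(occurrences, map) {
  occ <- as.data.table(occurrences)
  missing <- setdiff(occ$biopsy_id, igraph::V(map)$name)
  if (length(missing))
    abort_input("build_events: biopsy '%s' absent from the adjacency map",
                missing[1])
  binfo <- map_biopsies(map)
  out <- occ[, {
    ids <- unique(biopsy_id)
    sub <- igraph::induced_subgraph(map, ids)
    comp <- igraph::components(sub)
    memb <- comp$membership[ids]
    rbindlist(lapply(seq_len(comp$no), function(ci) {
      m <- ids[memb == ci]
      data.table(component = ci,
                 members = paste(sort(m), collapse = ","),
                 n_biopsies = length(m),
                 span_slices = length(unique(
                   binfo[biopsy_id %in% m]$slice_id)),
                 n_components = comp$no,
                 lower_bound = 1L,
                 connected = comp$no == 1L)
    }))
  }, by = .(chrom, pos, ref, alt, testis_id)]
  setorder(out, chrom, pos, alt, testis_id, component)
  out[]
}

#' Configuration for the post-zygotic flag
#'
#' @param min_slices minimum distinct slices spanned.
#' @param min_components minimum connected components of positive biopsies.
#' @param min_biopsies minimum positive biopsies.
#' @return list of class `postzygotic_config`.
#' @export
postzygotic_config <- function(min_slices = 3L, min_components = 2L,
                               min_biopsies = 6L) {
  structure(list(min_slices = as.integer(min_slices),
                 min_components = as.integer(min_components),
                 min_biopsies = as.integer(min_biopsies)),
            class = "postzygotic_config")
}

#' Flag candidate early post-zygotic variants
#'
#' A clone confined to a seminiferous tubule appears as one contiguous run
#' of biopsies; a mutation that instead peppers many disconnected biopsies
#' across several slices is better explained by an early embryonic
#' (post-zygotic) origin that seeded the whole tissue.  Flag iff, within a
#' testis, the positive biopsies span `>= min_slices` slices AND fall in
#' `>= min_components` connected components AND number `>= min_biopsies`.
#'
#' @param occurrences per-biopsy occurrences (`chrom, pos, ref, alt,
#'   biopsy_id, testis_id`).
#' @param map the biopsy adjacency graph.
#' @param cfg a [postzygotic_config()].
#' @return `data.table`, one row per (variant, testis):
#'   `chrom, pos, ref, alt, testis_id, n_biopsies, span_slices,
#'   n_components, postzygotic`.
#' @export
flag_postzygotic <- function(occurrences, map, cfg = postzygotic_config()) {
  ev <- build_events(occurrences, map)
  binfo <- map_biopsies(map)
  per <- ev[, .(n_biopsies = sum(n_biopsies),
                span_slices = {
                  b <- unlist(strsplit(members, ","))
                  length(unique(binfo[biopsy_id %in% b]$slice_id))
                },
                n_components = n_components[1]),
            by = .(chrom, pos, ref, alt, testis_id)]
  per[, postzygotic := span_slices >= cfg$min_slices &
        n_components >= cfg$min_components &
        n_biopsies >= cfg$min_biopsies]
  per[]
}

#' Ring-diagram plot of variant-positive biopsies in a testis
#'
#' Draws each slice of the testis as a ring of biopsy segments and marks
#' positive biopsies with filled circles scaled by VAF, connecting members
#' of a clonal event.
#'
#' @param occurrences per-biopsy occurrences with `vaf`.
#' @param map the adjacency graph.
#' @param testis testis id to draw.
#' @param main plot title.
#' @return invisibly, the plotting coordinates used.
#' @export
plot_slice_map <- function(occurrences, map, testis, main = NULL) {
  binfo <- map_biopsies(map)[testis_id == testis]
  slices <- sort(unique(binfo$slice_id))
  occ <- as.data.table(occurrences)
  occ <- occ[testis_id == testis]
  graphics::plot.new()
  graphics::plot.window(xlim = c(0.5, length(slices) + 0.5), ylim = c(-1.3, 1.3),
                        asp = 1)
  coords <- rbindlist(lapply(seq_along(slices), function(si) {
    b <- binfo[slice_id == slices[si]][order(slice_position)]
    theta <- 2 * pi * (seq_len(nrow(b)) - 1) / nrow(b)
    data.table(biopsy_id = b$biopsy_id, x = si + 0.42 * cos(theta),
               y = 0.42 * sin(theta))
  }))
  graphics::symbols(rep(seq_along(slices), 1), rep(0, length(slices)),
                    circles = rep(0.45, length(slices)), inches = FALSE,
                    add = TRUE, fg = "grey70")
  graphics::points(coords$x, coords$y, pch = 21, bg = "white", cex = 0.6)
  if (nrow(occ)) {
    vars <- unique(occ[, .(chrom, pos, ref, alt)])
    cols <- grDevices::hcl.colors(max(nrow(vars), 2L), "Dark 3")
    for (i in seq_len(nrow(vars))) {
      o <- merge(occ[vars[i], on = c("chrom", "pos", "ref", "alt")],
                 coords, by = "biopsy_id")
      if (nrow(o) > 1L) {
        oo <- o[order(x, y)]
        graphics::lines(oo$x, oo$y, col = cols[i], lwd = 1)
      }
      graphics::points(o$x, o$y, pch = 21, bg = cols[i],
                       cex = 0.6 + 40 * sqrt(o$vaf))
    }
  }
  graphics::title(main = main %||% sprintf("Testis %s", testis))
  invisible(coords)
}
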