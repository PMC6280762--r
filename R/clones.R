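#' Configuration for synthetic clone placement
#'
#' Clones model mutant spermatogonial lineages expanding along a seminiferous
#' tubule: each clone is one variant present in a connected walk of biopsies,
#' with VAF decaying geometrically away from a peak biopsy.  A configurable
#' fraction are tandem (dinucleotide) events mutating two adjacent positions
#' with identical per-biopsy VAFs, and optionally one broadly scattered
#' early post-zygotic variant is added.
#'
#' @param n_clones number of tubule-confined clones.
#' @param walk_len_range closed integer range of clone walk lengths (biopsies).
#' @param vaf_range peak-VAF range; drawn log-uniform over `(vaf_range[1],
#'   vaf_range[2]]`.  Values must lie in `(0, 0.03)`: VAFs at or above 3% are
#'   indistinguishable from constitutional heterozygous signal and are
#'   rejected.
#' @param decay geometric per-step VAF decay factor along the walk.
#' @param tandem_fraction fraction of clones that are tandem substitutions.
#' @param n_postzygotic number of early post-zygotic variants (0 or 1
#'   typical); each is scattered over `>= 6` biopsies across `>= 3` slices in
#'   `>= 2` disconnected patches.
#' @return a list of class `clone_config`.
#' @export
clone_config <- function(n_clones = 6L,
                         walk_len_range = c(2L, 5L),
                         vaf_range = c(0.005, 0.029),
                         decay = 0.6,
                         tandem_fraction = 0,
                         n_postzygotic = 0L) {
  cfg <- list(n_clones = as.integer(n_clones),
              walk_len_range = as.integer(walk_len_range),
              vaf_range = vaf_range, decay = decay,
              tandem_fraction = tandem_fraction,
              n_postzygotic = as.integer(n_postzygotic))
  if (any(vaf_range <= 0) || any(vaf_range >= 0.03))
    abort_input("clone_config: VAFs must lie in (0, 0.03); >= 3%% reads as constitutional")
  structure(cfg, class = "clone_config")
}

# self-avoiding random walk of `len` vertices starting anywhere in `testis`
.random_walk <- function(map, testis, len) {
  verts <- igraph::V(map)[igraph::V(map)$testis_id == testis]$name
  start <- sample(verts, 1L)
  path <- start
  while (length(path) < len) {
    nb <- setdiff(names(igraph::neighbors(map, tail(path, 1L))), path)
    if (!length(nb)) break
    path <- c(path, sample(nb, 1L))
  }
  path
}

# sample a callable single position (tandem = FALSE) or adjacent callable
# pair (tandem = TRUE) avoiding positions already used
.sample_site <- function(panel, used, tandem) {
  ref <- attr(panel, "reference")
  cal <- panel[, .(pos = seq.int(callable_start, callable_end - 1L)),
               by = .(chrom, amplicon_id)]
  cal <- unique(cal[, .(chrom, pos)])
  if (tandem) {
    # both members of the pair must be callable
    setkey(cal, chrom, pos)
    nxt <- cal[, .(chrom, pos = pos + 1L)]
    cal <- cal[nxt, on = c("chrom", "pos"), nomatch = NULL][, .(chrom, pos = pos - 1L)]
  }
  cal <- cal[!used, on = c("chrom", "pos")]
  if (tandem) cal <- cal[!used[, .(chrom, pos = pos - 1L)], on = c("chrom", "pos")]
  if (!nrow(cal)) abort_input("place_clones: panel exhausted, no free sites left")
  cal[sample(.N, 1L)]
}

.alt_for <- function(refbase) sample(setdiff(DNA_BASES, refbase), 1L)

#' Place synthetic clones and return the ground truth
#'
#' @param panel a [build_panel()] result.
#' @param layout a [build_layout()] result (its `map` is used for walks).
#' @param config a [clone_config()].
#' @param seed integer seed.
#' @return a list of class `clonescan_truth`:
#'   \describe{
#'     \item{clones}{`data.table`: `clone_id, kind, tandem_id, testis_id,
#'       chrom, pos, ref, alt`}
#'     \item{occupancy}{`data.table`: `clone_id, biopsy_id, vaf` — per-biopsy
#'       true VAF of every clone (exhaustive; absent rows mean VAF 0)}
#'   }
#' @export
place_clones <- function(panel, layout, config = clone_config(), seed = 1L) {
  stopifnot(inherits(panel, "clonescan_panel"),
            inherits(layout, "clonescan_layout"),
            inherits(config, "clone_config"))
  map <- layout$map
  with_seed(substream_seed(seed, "clones"), {
    clones <- list(); occupancy <- list()
    used <- data.table(chrom = character(0), pos = integer(0))
    testes <- unique(igraph::V(map)$testis_id)
    n_tandem <- round(config$tandem_fraction * config$n_clones)
    is_tandem <- rep(c(TRUE, FALSE), c(n_tandem, config$n_clones - n_tandem))
    cid <- 0L

    add_clone <- function(kind, tandem, testis, biopsies, vafs) {
      cid <<- cid + 1L
      site <- .sample_site(panel, used, tandem)
      n_pos <- if (tandem) 2L else 1L
      pos <- site$pos + seq_len(n_pos) - 1L
      refb <- reference_base(panel, rep(site$chrom, n_pos), pos)
      altb <- vapply(refb, .alt_for, character(1))
      used <<- rbind(used, data.table(chrom = site$chrom, pos = pos))
      clones[[cid]] <<- data.table(
        clone_id = sprintf("CL%03d", cid), kind = kind,
        tandem_id = if (tandem) sprintf("TD%03d", cid) else NA_character_,
        testis_id = testis, chrom = site$chrom, pos = pos,
        ref = refb, alt = altb)
      occupancy[[cid]] <<- data.table(
        clone_id = sprintf("CL%03d", cid), biopsy_id = biopsies, vaf = vafs)
    }

    for (i in seq_len(config$n_clones)) {
      testis <- sample(testes, 1L)
      len <- sample(config$walk_len_range[1]:config$walk_len_range[2], 1L)
      path <- .random_walk(map, testis, len)
      peak_vaf <- exp(runif(1, log(config$vaf_range[1]), log(config$vaf_range[2])))
      peak_at <- sample(seq_along(path), 1L)
      vafs <- peak_vaf * config$decay^abs(seq_along(path) - peak_at)
      add_clone("CLONAL", is_tandem[i], testis, path, vafs)
    }

    for (i in seq_len(config$n_postzygotic)) {
      # an early embryonic mosaic: seeds several disconnected patches across
      # at least three slices of one testis, at relatively high uniform VAF
      binfo <- map_biopsies(map)
      cand_testes <- binfo[, .(ns = length(unique(slice_id))), by = testis_id][ns >= 3L]
      if (!nrow(cand_testes))
        abort_input("place_clones: post-zygotic clone needs a testis with >= 3 slices")
      testis <- sample(cand_testes$testis_id, 1L)
      slices <- sort(sample(unique(binfo[testis_id == testis]$slice_id), 3L))
      picks <- rbindlist(lapply(slices, function(s) {
        b <- binfo[testis_id == testis & slice_id == s]
        b[sample(.N, min(.N, sample(2:3, 1L)))]
      }))
      vaf <- runif(1, 0.008, 0.015)
      add_clone("POSTZYGOTIC", FALSE, testis, picks$biopsy_id,
                vaf * runif(nrow(picks), 0.7, 1.3))
    }

    clones <- if (length(clones)) rbindlist(clones) else
      data.table(clone_id = character(0), kind = character(0),
                 tandem_id = character(0), testis_id = integer(0),
                 chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0))
    occupancy <- if (length(occupancy)) rbindlist(occupancy) else
      data.table(clone_id = character(0), biopsy_id = character(0),
                 vaf = numeric(0))
    structure(list(clones = clones, occupancy = occupancy,
                   config = config, seed = seed),
              class = "clonescan_truth")
  })
}

#' Expand ground truth to per-sample expected VAF per variant position
#'
#' Joins clone occupancy onto the sample sheet (replicate samples of a biopsy
#' share its true VAF).
#'
#' @param truth a [place_clones()] result.
#' @param sheet the sample sheet.
#' @return `data.table`: `sample_id, biopsy_id, clone_id, chrom, pos, ref,
#'   alt, true_vaf`.
#' @export
truth_by_sample <- function(truth, sheet) {
  occ <- merge(truth$occupancy, sheet[, .(sample_id, biopsy_id)],
               by = "biopsy_id", allow.cartesian = TRUE)
  out <- merge(occ, truth$clones, by = "clone_id", allow.cartesian = TRUE)
  out[, .(sample_id, biopsy_id, clone_id, chrom, pos, ref, alt, true_vaf = vaf)]
}
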