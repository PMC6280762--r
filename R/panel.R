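#' Configuration for a synthetic amplicon panel
#'
#' The defaults emulate, at reduced scale, a simplex-PCR hotspot panel in
#' which growth-signalling (RTK/RAS-MAPK) targets make up a stated share of
#' the callable sequence, a minority of amplicons overlap a neighbour on the
#' same gene, and primer-binding sequence is excluded from calling.
#'
#' @param n_amplicons number of amplicons in the panel.
#' @param len_range closed integer range of total amplicon lengths (bp),
#'   primers included.
#' @param fwd_primer_range,rev_primer_range integer ranges for primer lengths.
#' @param overlap_fraction fraction of amplicons that are "partner" amplicons
#'   overlapping another amplicon of the same gene; `round(overlap_fraction *
#'   n_amplicons)` overlapping pairs are created.
#' @param pathway_share target share of unique callable base pairs labelled
#'   `RAS_MAPK` (default 0.419).
#' @param pathway_tol tolerance on the achieved `RAS_MAPK` callable share.
#' @param neutral_fraction fraction of non-RAS_MAPK loci labelled `NEUTRAL`
#'   (negative-control regions) rather than `OTHER`.
#' @return a list of class `panel_config`.
#' @export
panel_config <- function(n_amplicons = 30L,
                         len_range = c(120L, 180L),
                         fwd_primer_range = c(18L, 25L),
                         rev_primer_range = c(18L, 25L),
                         overlap_fraction = 0.1,
                         pathway_share = 0.419,
                         pathway_tol = 0.02,
                         neutral_fraction = 0.15) {
  cfg <- list(n_amplicons = as.integer(n_amplicons),
              len_range = as.integer(len_range),
              fwd_primer_range = as.integer(fwd_primer_range),
              rev_primer_range = as.integer(rev_primer_range),
              overlap_fraction = overlap_fraction,
              pathway_share = pathway_share,
              pathway_tol = pathway_tol,
              neutral_fraction = neutral_fraction)
  if (cfg$n_amplicons < 1L)
    abort_input("panel_config: n_amplicons must be >= 1")
  if (max(cfg$fwd_primer_range) + max(cfg$rev_primer_range) >= min(cfg$len_range))
    abort_input("panel_config: amplicon length range leaves no callable bases")
  structure(cfg, class = "panel_config")
}

# gene-name pools per pathway class (recycled with numeric suffix if exhausted)
.gene_pools <- list(
  RAS_MAPK = c("FGFR2", "FGFR3", "KRAS", "PTPN11", "RET", "HRAS", "BRAF",
               "MAP2K1", "MAP2K2", "RAF1", "SOS1", "CBL", "NRAS", "FGFR1"),
  OTHER    = c("APC", "AKT3", "LRP5", "SMAD4", "SKI", "SETBP1", "AKT1",
               "GNAS", "SMO", "CTNNB1"),
  NEUTRAL  = sprintf("NEUT%02d", 1:12)
)

# greedy subset-sum + single-move local search: pick locus groups whose
# unique callable bp share approaches `target`
.select_share <- function(sizes, target) {
  total <- sum(sizes)
  in_set <- logical(length(sizes))
  for (i in order(sizes, decreasing = TRUE)) {
    if ((sum(sizes[in_set]) + sizes[i]) / total <= target) in_set[i] <- TRUE
  }
  obj <- function(sel) abs(sum(sizes[sel]) / total - target)
  repeat {
    best <- obj(in_set); move <- 0L
    for (i in seq_along(sizes)) {
      cand <- in_set; cand[i] <- !cand[i]
      if (obj(cand) < best - 1e-12) { best <- obj(cand); move <- i }
    }
    if (move == 0L) break
    in_set[move] <- !in_set[move]
  }
  in_set
}

#' Build a synthetic amplicon panel
#'
#' Generates amplicon intervals with primer geometry, per-amplicon gene and
#' pathway labels, and a random reference base for every covered genomic
#' position (overlapping amplicons share the reference).  Coordinates are
#' 0-based half-open; the callable interval of an amplicon excludes both
#' primer-binding tracts.
#'
#' @param config a [panel_config()].
#' @param seed integer seed; identical `(config, seed)` yield byte-identical
#'   panels.
#' @return a `data.table` of class `clonescan_panel` with columns
#'   `amplicon_id, gene, pathway, chrom, start, end, fwd_primer_len,
#'   rev_primer_len, callable_start, callable_end`, and attributes
#'   `reference` (a `data.table` of `chrom, pos, base`) and `seed`.
#' @export
build_panel <- function(config = panel_config(), seed = 1L) {
  stopifnot(inherits(config, "panel_config"))
  with_seed(substream_seed(seed, "panel"), {
    n <- config$n_amplicons
    k <- as.integer(round(config$overlap_fraction * n))
    if (2L * k > n) abort_input("build_panel: overlap_fraction too large")
    n_primary <- n - k

    lens <- sample(config$len_range[1]:config$len_range[2], n, replace = TRUE)
    fwd  <- sample(config$fwd_primer_range[1]:config$fwd_primer_range[2], n, TRUE)
    rev  <- sample(config$rev_primer_range[1]:config$rev_primer_range[2], n, TRUE)

    # lay primaries out over per-gene loci, ~6 amplicons per gene
    n_genes <- max(1L, ceiling(n_primary / 6L))
    gene_of_primary <- sort(rep_len(seq_len(n_genes), n_primary))
    chrom_of_gene <- sprintf("chr%d", ((seq_len(n_genes) - 1L) %% 22L) + 1L)
    offset_of_gene <- sample(1e6:2e8, n_genes)

    start <- integer(n); end <- integer(n); chrom <- character(n)
    gene_idx <- integer(n)
    cursor <- offset_of_gene
    for (i in seq_len(n_primary)) {
      g <- gene_of_primary[i]
      # gap floor 150 bp: a partner amplicon extends at most ~120 bp past its
      # primary, so partners can never collide with the next locus amplicon
      start[i] <- cursor[g] + sample(150:500, 1L)
      end[i] <- start[i] + lens[i]
      cursor[g] <- end[i]
      chrom[i] <- chrom_of_gene[g]
      gene_idx[i] <- g
    }
    # partner amplicons overlap a distinct primary by roughly half its length
    partner_of <- if (k > 0L) sample(seq_len(n_primary), k) else integer(0)
    for (j in seq_len(k)) {
      i <- n_primary + j; p <- partner_of[j]
      shift <- as.integer(round(lens[p] / 2))
      start[i] <- start[p] + shift
      end[i] <- start[i] + lens[i]
      chrom[i] <- chrom[p]
      gene_idx[i] <- gene_idx[p]
    }

    callable_start <- start + fwd
    callable_end <- end - rev
    if (any(callable_end <= callable_start))
      abort_input("build_panel: zero-length callable region (primers exceed amplicon)")

    # unique callable bp per locus group (primary + its partners)
    groups <- split(seq_len(n), gene_idx * (n + 1L) +
                      c(seq_len(n_primary), partner_of))
    grp_bp <- vapply(groups, function(idx) {
      iv <- unique(unlist(lapply(idx, function(i)
        callable_start[i]:(callable_end[i] - 1L))))
      length(iv)
    }, integer(1))

    ras_grp <- .select_share(grp_bp, config$pathway_share)
    rest <- which(!ras_grp)
    n_neut <- round(config$neutral_fraction * length(rest))
    neut_grp <- logical(length(groups))
    if (n_neut > 0L) neut_grp[sample(rest, n_neut)] <- TRUE

    pathway <- character(n); grp_gene <- character(length(groups))
    cls <- ifelse(ras_grp, "RAS_MAPK", ifelse(neut_grp, "NEUTRAL", "OTHER"))
    for (p in unique(cls)) {
      idx <- which(cls == p)
      pool <- .gene_pools[[p]]
      nm <- if (length(idx) <= length(pool)) pool[seq_along(idx)] else
        make.unique(rep_len(pool, length(idx)), sep = "_")
      grp_gene[idx] <- nm
    }
    for (gi in seq_along(groups)) {
      pathway[groups[[gi]]] <- cls[gi]
    }
    gene <- character(n)
    for (gi in seq_along(groups)) gene[groups[[gi]]] <- grp_gene[gi]

    panel <- data.table(
      amplicon_id = sprintf("AMP%03d", seq_len(n)),
      gene = gene, pathway = pathway, chrom = chrom,
      start = start, end = end,
      fwd_primer_len = fwd, rev_primer_len = rev,
      callable_start = callable_start, callable_end = callable_end)
    setorder(panel, chrom, start, amplicon_id)
    panel[, amplicon_id := sprintf("AMP%03d", seq_len(.N))]

    # one reference base per covered genomic position, shared across overlaps
    cov <- panel[, .(pos = seq.int(start, end - 1L)), by = .(chrom, amplicon_id)]
    ref <- unique(cov[, .(chrom, pos)])
    setorder(ref, chrom, pos)
    ref[, base := sample(DNA_BASES, .N, replace = TRUE)]

    setattr(panel, "reference", ref)
    setattr(panel, "seed", seed)
    setattr(panel, "config", config)
    setattr(panel, "class", c("clonescan_panel", class(panel)))
    panel[]
  })
}

#' Total and per-pathway unique callable base pairs of a panel
#'
#' @param panel a [build_panel()] result.
#' @return a `data.table` with columns `pathway, callable_bp, share`.
#' @export
callable_bp <- function(panel) {
  stopifnot(inherits(panel, "clonescan_panel"))
  cov <- panel[, .(pos = seq.int(callable_start, callable_end - 1L)),
               by = .(chrom, pathway, amplicon_id)]
  u <- unique(cov[, .(chrom, pos, pathway)])
  out <- u[, .(callable_bp = .N), by = pathway]
  out[, share := callable_bp / sum(callable_bp)]
  out[]
}

#' Reference base lookup for panel positions
#'
#' @param panel a panel; @param chrom,pos vectors of positions (0-based).
#' @return character vector of reference bases (`NA` if uncovered).
#' @export
reference_base <- function(panel, chrom, pos) {
  ref <- attr(panel, "reference")
  q <- data.table(chrom = chrom, pos = as.integer(pos))
  ref[q, on = c("chrom", "pos")]$base
}

#' Count pairs of overlapping amplicons in a panel
#' @param panel a panel.
#' @return integer number of unordered amplicon pairs with overlapping
#'   genomic intervals.
#' @export
count_overlap_pairs <- function(panel) {
  n <- 0L
  for (cc in unique(panel$chrom)) {
    p <- panel[chrom == cc]
    if (nrow(p) < 2L) next
    cmb <- utils::combn(nrow(p), 2L)
    n <- n + sum(p$start[cmb[1, ]] < p$end[cmb[2, ]] &
                   p$start[cmb[2, ]] < p$end[cmb[1, ]])
  }
  n
}
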