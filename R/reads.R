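#' Simulate paired-end read records over a panel
#'
#' A light-weight read generator for exercising the pileup builder: for each
#' amplicon and sample it emits `n_pairs` read pairs, R1 anchored at the
#' amplicon's left edge, R2 at the right edge (2 x `read_len`).  Each pair is
#' drawn from a template molecule; with probability equal to the template's
#' true VAF the template carries the spiked variant, in which case both mates
#' report the alternate base wherever they cover the site.  Per-base
#' sequencing errors are added independently.
#'
#' @param panel a [build_panel()] result.
#' @param sample_ids character vector of samples to simulate.
#' @param truth optional per-sample spike table as from [truth_by_sample()]
#'   (columns `sample_id, chrom, pos, alt, true_vaf`).
#' @param n_pairs read pairs per (sample, amplicon).
#' @param read_len read length in bases.
#' @param base_error per-base sequencing error probability.
#' @param seed integer seed.
#' @return `data.table` of read records: `sample_id, amplicon_id, pair_id,
#'   mate, start, bases, quals` (`start` 0-based genomic; `quals` Phred+33).
#' @export
simulate_reads <- function(panel, sample_ids, truth = NULL,
                           n_pairs = 100L, read_len = 100L,
                           base_error = 0.001, seed = 1L) {
  stopifnot(inherits(panel, "clonescan_panel"))
  with_seed(substream_seed(seed, "reads"), {
    out <- vector("list", nrow(panel) * length(sample_ids))
    k <- 0L
    for (s in sample_ids) {
      for (i in seq_len(nrow(panel))) {
        amp <- panel[i]
        len1 <- min(read_len, amp$end - amp$start)
        r1_start <- amp$start
        r2_start <- max(amp$start, amp$end - read_len)
        spikes <- if (!is.null(truth))
          truth[truth$sample_id == s & truth$chrom == amp$chrom &
                  truth$pos >= amp$start & truth$pos < amp$end, ] else NULL
        mk <- function(mate, st, n) {
          pos <- st + seq_len(n) - 1L
          refb <- reference_base(panel, rep(amp$chrom, n), pos)
          m <- matrix(rep(refb, n_pairs), nrow = n_pairs, byrow = TRUE)
          if (!is.null(spikes) && nrow(spikes)) {
            for (j in seq_len(nrow(spikes))) {
              cover <- which(pos == spikes$pos[j])
              if (length(cover)) {
                mut <- runif(n_pairs) < spikes$true_vaf[j]
                m[mut, cover] <- spikes$alt[j]
              }
            }
          }
          err <- matrix(runif(n_pairs * n) < base_error, nrow = n_pairs)
          if (any(err)) {
            idx <- which(err, arr.ind = TRUE)
            m[err] <- vapply(m[err], .alt_for, character(1))
          }
          q <- matrix(sample(25:40, n_pairs * n, TRUE), nrow = n_pairs)
          data.table(sample_id = s, amplicon_id = amp$amplicon_id,
                     pair_id = sprintf("%s_%s_P%04d", s, amp$amplicon_id,
                                       seq_len(n_pairs)),
                     mate = mate, start = st,
                     bases = apply(m, 1, paste0, collapse = ""),
                     quals = apply(q + 33L, 1, function(x)
                       intToUtf8(x, multiple = FALSE)))
        }
        k <- k + 1L
        out[[k]] <- rbind(mk("R1", r1_start, len1),
                          mk("R2", r2_start, min(read_len, amp$end - r2_start)))
      }
    }
    rbindlist(out)
  })
}

.read_end <- function(reads) reads$start + nchar(reads$bases)

#' Trim primer-derived bases off read records
#'
#' Bases overlapping the forward primer tract `[start, start +
#' fwd_primer_len)` or the reverse tract `[end - rev_primer_len, end)` are
#' removed: primer bases are synthesised from the primer oligo, not the
#' template, so they carry no variant information.  Reads left empty are
#' dropped.
#'
#' @param reads read record `data.table`.
#' @param panel the amplicon panel.
#' @return trimmed read records (possibly fewer rows); attribute
#'   `n_dropped` counts reads removed entirely.
#' @export
trim_primers <- function(reads, panel) {
  unknown <- setdiff(reads$amplicon_id, panel$amplicon_id)
  if (length(unknown))
    abort_input("trim_primers: unknown amplicon_id '%s'", unknown[1])
  r <- merge(reads, panel[, .(amplicon_id, callable_start, callable_end)],
             by = "amplicon_id", sort = FALSE)
  new_start <- pmax(r$start, r$callable_start)
  new_end <- pmin(.read_end(r), r$callable_end)
  keep <- new_end > new_start
  r_keep <- r[keep]
  from <- new_start[keep] - r_keep$start + 1L
  to <- new_end[keep] - r_keep$start
  r_keep[, `:=`(bases = substr(bases, from, to),
                quals = substr(quals, from, to),
                start = new_start[keep])]
  r_keep[, c("callable_start", "callable_end") := NULL]
  setattr(r_keep, "n_dropped", sum(!keep))
  r_keep[]
}

#' Count non-reference bases of each read record
#' @param reads read records (typically after [trim_primers()]).
#' @param panel the panel (source of the reference).
#' @return integer vector of mismatch counts, one per read.
#' @export
count_mismatches <- function(reads, panel) {
  if (!nrow(reads)) return(integer(0))
  vapply(seq_len(nrow(reads)), function(i) {
    n <- nchar(reads$bases[i])
    pos <- reads$start[i] + seq_len(n) - 1L
    amp <- panel[panel$amplicon_id == reads$amplicon_id[i], ]
    refb <- reference_base(panel, rep(amp$chrom, n), pos)
    sum(strsplit(reads$bases[i], "")[[1]] != refb)
  }, integer(1))
}

#' Remove reads with an excessive number of non-reference bases
#'
#' Reads carrying more than `max_mismatches` mismatches are presumed
#' mis-mapped or chimeric and are discarded; the boundary count itself is
#' kept.
#'
#' @param reads read records.
#' @param panel the panel.
#' @param max_mismatches maximum tolerated mismatch count (default 10).
#' @return filtered read records; attribute `n_discarded`.
#' @export
filter_reads <- function(reads, panel, max_mismatches = 10L) {
  mm <- count_mismatches(reads, panel)
  out <- reads[mm <= max_mismatches]
  setattr(out, "n_discarded", sum(mm > max_mismatches))
  out[]
}

#' Build a pileup matrix from read records
#'
#' Applies the full read-level rule set: primer trimming, the mismatch
#' filter, then per-pair overlap resolution — at positions covered by both
#' mates only the base with the higher quality contributes (quality tie:
#' R1 wins), so a pair is never counted twice at one position.
#'
#' @param reads read records.
#' @param panel the panel.
#' @param max_mismatches mismatch filter threshold.
#' @return a `clonescan_pileup` `data.table` (`sample_id, amplicon_id, chrom,
#'   pos, ref, A, C, G, T`) restricted to callable positions with coverage.
#' @export
build_pileup <- function(reads, panel, max_mismatches = 10L) {
  unknown <- setdiff(reads$amplicon_id, panel$amplicon_id)
  if (length(unknown))
    abort_input("build_pileup: unknown amplicon_id '%s'", unknown[1])
  r <- trim_primers(reads, panel)
  r <- filter_reads(r, panel, max_mismatches)
  if (!nrow(r)) {
    out <- data.table(sample_id = character(0), amplicon_id = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), A = integer(0), C = integer(0),
                      G = integer(0), T = integer(0))
    setattr(out, "class", c("clonescan_pileup", class(out)))
    return(out[])
  }
  # explode to one row per aligned base
  n <- nchar(r$bases)
  long <- r[rep(seq_len(.N), n),
            .(sample_id, amplicon_id, pair_id, mate, start)]
  long[, offset := sequence(n) - 1L]
  long[, pos := start + offset]
  long[, base := unlist(strsplit(r$bases, ""))]
  long[, qual := utf8ToInt(paste0(r$quals, collapse = "")) - 33L]
  # overlap resolution: one base per (pair, position)
  setorder(long, sample_id, amplicon_id, pair_id, pos, -qual, mate)
  best <- long[, .SD[1L], by = .(sample_id, amplicon_id, pair_id, pos)]
  tal <- best[, .(n = .N), by = .(sample_id, amplicon_id, pos, base)]
  wide <- data.table::dcast(tal, sample_id + amplicon_id + pos ~ base,
                            value.var = "n", fill = 0L)
  for (b in DNA_BASES) if (!b %in% names(wide)) wide[, (b) := 0L]
  wide <- merge(wide, panel[, .(amplicon_id, chrom)], by = "amplicon_id")
  wide[, ref := reference_base(panel, chrom, pos)]
  setcolorder(wide, c("sample_id", "amplicon_id", "chrom", "pos", "ref",
                      "A", "C", "G", "T"))
  setorder(wide, sample_id, amplicon_id, pos)
  setattr(wide, "class", c("clonescan_pileup", class(wide)))
  wide[]
}
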