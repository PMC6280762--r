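#' @importFrom data.table data.table as.data.table setDT setkey setkeyv := .N .SD setorder rbindlist fread fwrite copy setnames setcolorder setattr CJ
#' @importFrom stats median mad qnorm pnorm rbinom rbeta rnbinom runif rnorm quantile IQR complete.cases cor sd
#' @importFrom utils head tail
NULL

# silence R CMD check notes for data.table NSE symbols
utils::globalVariables(c(
  ".", "alt", "alt_count", "amplicon_id", "biopsy_id", "callable_end",
  "callable_start", "chrom", "depth", "flow_cell", "gene", "lane",
  "mean_base_quality", "n_amp", "n_samp", "neg_log10_p", "pathway", "pos",
  "ref", "replicate_of", "sample_id", "slice_id", "slice_position",
  "testis_id", "tier", "vaf", "variant_id", "A", "C", "G", "T", "med_depth",
  "max_vaf", "clone_id", "kind", "tandem_id", "n_calls", "qual", "keep",
  "component", "n_testes", "start", "end", "mean_vaf", "i.vaf", "true_vaf",
  "e_rate", "n_biopsies", "vaf_biopsy", "is_tier1", "x", "y", "base",
  "offset", "N", "cap", "alt_sum", "depth_sum", "q", "members",
  "n_components", "postzygotic", "pass", "median_depth", "mean_depth",
  "n_samples", "n_amplicons_max", "overlap_support", "replicate_support",
  "vaf.x", "vaf.y", "n_calls.x", "n_calls.y", "span_slices", "mate",
  "pair_id", "bases", "quals", "term", "estimate"
))

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a reproducible substream seed from a root seed
#'
#' All randomness in the package flows from a single root seed; each module
#' draws from its own named substream so that, e.g., regenerating the panel
#' does not perturb the clone placement.
#'
#' @param seed integer root seed.
#' @param stream character scalar naming the substream.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Logit transform of an allele fraction with pseudocounts
#'
#' `logit((alt + 0.5) / (depth + 1))` — defined at zero alt counts and
#' approximately variance-stabilizing for small fractions.
#'
#' @param alt_count non-negative alt read counts.
#' @param depth total read depths (> 0 for a defined value).
#' @return numeric vector of transformed values.
#' @export
vaf_logit <- function(alt_count, depth) {
  p <- (alt_count + 0.5) / (depth + 1)
  log(p / (1 - p))
}

inv_logit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_input <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)
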