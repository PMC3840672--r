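# Paired-read sanitization: mean-quality, adapter and base-composition
# filters, then a seeded order randomization that keeps mates together.
# Reads are discarded whole, never trimmed.

#' Sanitization configuration
#'
#' @param mean_quality_min minimum mean Phred quality per mate; a pair is
#'   discarded if either mate falls below it. Default 28 (a conventional
#'   strict threshold; assemblies typically re-filter at
#'   \code{assembly_quality_min}).
#' @param assembly_quality_min the stricter threshold applied when
#'   filtering reads destined for assembly. Default 33.
#' @param comp_low,comp_high base-composition bounds: a read is skewed if
#'   any of A,C,G,T has frequency strictly below \code{comp_low} or
#'   strictly above \code{comp_high} among its non-N bases. Defaults
#'   0.05 and 0.60.
#' @param adapters character vector of adapter sequences; defaults to
#'   the small bundled set of common Illumina adapters
#'   (\code{default_adapters()}).
#' @param adapter_prefix_len if set, only the first k bases of each
#'   adapter are searched for; default uses the full adapter.
#' @param seed integer seed controlling the output permutation.
#' @return A list of class \code{sanitize_config}.
#' @export
sanitize_config <- function(mean_quality_min = 28,
                            assembly_quality_min = 33,
                            comp_low = 0.05, comp_high = 0.60,
                            adapters = default_adapters(),
                            adapter_prefix_len = NULL,
                            seed = 1L) {
  stopifnot(comp_low >= 0, comp_low < comp_high, comp_high <= 1,
            mean_quality_min >= 0)
  if (!is.null(adapter_prefix_len))
    adapters <- substr(adapters, 1L, adapter_prefix_len)
  structure(list(mean_quality_min = mean_quality_min,
                 assembly_quality_min = assembly_quality_min,
                 comp_low = comp_low, comp_high = comp_high,
                 adapters = toupper(adapters), seed = as.integer(seed)),
            class = "sanitize_config")
}

#' Bundled common Illumina adapter sequences
#'
#' A small default adapter set (TruSeq universal/indexed stems), fully
#' overridable via the \code{adapters} argument of [sanitize_config].
#'
#' @return Named character vector of adapter sequences.
#' @export
default_adapters <- function() {
  path <- system.file("extdata", "adapters.fa", package = "mfx",
                      mustWork = TRUE)
  set <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(set)), names(set))
}

#' Test base-composition skew
#'
#' A sequence is skewed when any single base accounts for less than
#' \code{comp_low} or more than \code{comp_high} of its non-N bases
#' (strict inequalities). All-N sequences are degenerate and treated as
#' skewed.
#'
#' @param sequence character vector of nucleotide strings.
#' @param comp_low,comp_high frequency bounds.
#' @return Logical vector.
#' @export
base_composition_skewed <- function(sequence, comp_low = 0.05,
                                    comp_high = 0.60) {
  if (any(!nzchar(sequence))) stop("empty sequence")
  counts <- vapply(c("A", "C", "G", "T"), function(b)
    nchar(sequence) - nchar(gsub(b, "", sequence, fixed = TRUE)),
    numeric(length(sequence)))
  counts <- matrix(counts, ncol = 4L)
  denom <- rowSums(counts)
  freq <- counts / denom           # NaN rows are all-N
  skewed <- rowSums(freq < comp_low | freq > comp_high) > 0L
  skewed[denom == 0L] <- TRUE
  unname(skewed)
}

# Exact substring adapter containment for either mate.
has_adapter <- function(seqs, adapters) {
  hit <- rep(FALSE, length(seqs))
  for (ad in adapters) hit <- hit | grepl(ad, seqs, fixed = TRUE)
  hit
}

#' Classify read pairs for sanitization
#'
#' Applies the three filters to both mates of every pair. A pair is
#' discarded when either mate fails any test; the recorded reason is the
#' first failing test in the fixed order quality, adapter, composition.
#'
#' @param pairs a [read_pairs] object.
#' @param cfg a [sanitize_config].
#' @return Character vector over \code{{"keep","quality","adapter",
#'   "composition"}}, one element per pair.
#' @export
filter_read_pairs <- function(pairs, cfg = sanitize_config()) {
  stopifnot(inherits(pairs, "read_pairs"))
  if (length(pairs) == 0L) return(character())
  lowq <- mean_qual(pairs$fwd_qual) < cfg$mean_quality_min |
    mean_qual(pairs$rev_qual) < cfg$mean_quality_min
  adap <- has_adapter(pairs$fwd_seq, cfg$adapters) |
    has_adapter(pairs$rev_seq, cfg$adapters)
  skew <- base_composition_skewed(pairs$fwd_seq, cfg$comp_low, cfg$comp_high) |
    base_composition_skewed(pairs$rev_seq, cfg$comp_low, cfg$comp_high)
  reason <- rep("keep", length(pairs))
  reason[skew] <- "composition"
  reason[adap] <- "adapter"
  reason[lowq] <- "quality"
  reason
}

#' Sanitize a set of read pairs
#'
#' Filters pairs with [filter_read_pairs], then randomizes the order of
#' the surviving pairs (mates are never separated) with a permutation
#' determined solely by \code{cfg$seed}, to facilitate downstream
#' prefix subsetting.
#'
#' @param pairs a [read_pairs] object.
#' @param cfg a [sanitize_config].
#' @return A list with elements \code{kept} (a [read_pairs] object in
#'   randomized order) and \code{stats} (class \code{sanitize_stats}:
#'   input/kept counts, per-reason discard counts, and the seed).
#' @export
sanitize_pairs <- function(pairs, cfg = sanitize_config()) {
  reason <- filter_read_pairs(pairs, cfg)
  keep <- which(reason == "keep")
  perm <- if (length(keep))
    with_seed(cfg$seed, sample.int(length(keep))) else integer()
  kept <- pairs[keep[perm]]
  discards <- c(quality = sum(reason == "quality"),
                adapter = sum(reason == "adapter"),
                composition = sum(reason == "composition"))
  stats <- structure(list(n_input_pairs = length(pairs),
                          n_kept_pairs = length(kept),
                          discards = discards, seed = cfg$seed),
                     class = "sanitize_stats")
  stopifnot(stats$n_input_pairs == stats$n_kept_pairs + sum(discards))
  list(kept = kept, stats = stats)
}

#' @export
print.sanitize_stats <- function(x, ...) {
  cat(sprintf("sanitize: %d pairs in, %d kept (%.1f%%)\n",
              x$n_input_pairs, x$n_kept_pairs,
              if (x$n_input_pairs) 100 * x$n_kept_pairs / x$n_input_pairs
              else NA_real_))
  cat(sprintf("  discarded: quality %d, adapter %d, composition %d (seed %d)\n",
              x$discards[["quality"]], x$discards[["adapter"]],
              x$discards[["composition"]], x$seed))
  invisible(x)
}
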