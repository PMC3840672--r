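# Screening stages: insert-size estimation from paired-mapping template
# lengths, rRNA/vector screening by canonical k-mer containment,
# longest-ORF annotation, and exemplar-isoform selection.

#' Estimate insert size from template lengths
#'
#' The insert size (fragment length between the sequencing adapters) is
#' summarized by its arithmetic mean and unbiased sample variance. It is
#' important feedback on library preparation and feeds downstream
#' assembly steps.
#'
#' @param template_lengths positive integer template (fragment) lengths,
#'   e.g. from [read_template_lengths].
#' @return A list of class \code{insert_size_estimate} with \code{mean},
#'   \code{variance} (0 when n = 1) and \code{n_observations}.
#' @export
estimate_insert_size <- function(template_lengths) {
  tl <- template_lengths[!is.na(template_lengths)]
  if (length(tl) == 0L) stop("no proper pairs")
  stopifnot(all(tl > 0))
  structure(list(mean = mean(tl),
                 variance = if (length(tl) > 1L) stats::var(tl) else 0,
                 n_observations = length(tl)),
            class = "insert_size_estimate")
}

#' @export
print.insert_size_estimate <- function(x, ...) {
  cat(sprintf("insert size: mean %.1f bp, sd %.1f bp (n = %d proper pairs)\n",
              x$mean, sqrt(x$variance), x$n_observations))
  invisible(x)
}

#' Extract template lengths from a SAM file
#'
#' Reads the template-length (TLEN) field of a paired mapping. Only the
#' positive entry of each pair is kept (each proper pair stores +/- the
#' same length); zero/unmapped entries are skipped.
#'
#' @param sam_path path to a SAM file.
#' @return Integer vector of template lengths.
#' @export
read_template_lengths <- function(sam_path) {
  if (!file.exists(sam_path)) stop("no such file: ", sam_path)
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = "isize"))
  tl <- res[[1L]]$isize
  tl <- tl[!is.na(tl) & tl > 0L]
  as.integer(tl)
}

## ---- k-mer containment matcher ------------------------------------------

#' Build a canonical k-mer matcher from reference sequences
#'
#' Screening decisions (is this read/transcript derived from rRNA? does
#' it contain vector sequence?) are made by canonical k-mer containment:
#' a query matches when at least \code{min_shared_fraction} of its
#' k-mers occur in the reference set. Canonicalization (a k-mer and its
#' reverse complement are identified) makes the test strand-insensitive.
#' The matcher is deterministic and self-contained; a mapping-based
#' screener can be substituted behind the same interface.
#'
#' @param reference sequences to index: a [gene_seqs] data frame, named
#'   character vector, or FASTA path.
#' @param k k-mer length (default 25; must be at least 11).
#' @param min_shared_fraction fraction of query k-mers that must be
#'   shared for a match (default 0.5, compared with \code{>=}).
#' @return A list of class \code{kmer_matcher}.
#' @export
kmer_matcher <- function(reference, k = 25L, min_shared_fraction = 0.5) {
  stopifnot(k >= 11L, min_shared_fraction > 0, min_shared_fraction <= 1)
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference) && is.null(names(reference)))
    reference <- read_fasta(reference)
  seqs <- if (is.data.frame(reference)) reference$sequence else
    as.character(reference)
  kmers <- unique(unlist(lapply(toupper(seqs), canonical_seq_kmers, k = k)))
  if (length(kmers) == 0L)
    stop("reference yields no k-mers (all sequences shorter than k?)")
  structure(list(k = as.integer(k), kmers = kmers,
                 min_shared_fraction = min_shared_fraction),
            class = "kmer_matcher")
}

seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  substring(seq, 1:(n - k + 1L), k:n)
}

# Canonical k-mers of one sequence: each k-mer is identified with its
# reverse complement and represented by the lexicographically smaller of
# the two. The k-mers of the reverse complement, read back-to-front,
# line up positionally with the forward k-mers, so one revcomp of the
# whole sequence canonicalizes every k-mer at once.
canonical_seq_kmers <- function(seq, k) {
  km <- seq_kmers(seq, k)
  if (length(km) == 0L) return(character())
  kmrc <- rev(seq_kmers(revcomp(seq), k))
  pmin(km, kmrc)
}

#' Fraction of a query's k-mers shared with the reference
#'
#' @param matcher a [kmer_matcher].
#' @param sequences character vector of query sequences.
#' @return Numeric vector of shared fractions (0 for sequences shorter
#'   than k).
#' @export
kmer_shared_fraction <- function(matcher, sequences) {
  vapply(toupper(sequences), function(s) {
    km <- canonical_seq_kmers(s, matcher$k)
    if (length(km) == 0L) return(0)
    mean(km %in% matcher$kmers)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Remove rRNA-derived read pairs
#'
#' A pair is removed when either mate shares at least the matcher's
#' \code{min_shared_fraction} of its k-mers with the rRNA reference set.
#' The fraction of reads that derive from rRNA is reported to aid in
#' improving library preparations.
#'
#' @param pairs a [read_pairs] object (non-empty).
#' @param matcher a [kmer_matcher] built from rRNA transcripts (a
#'   reference set or screening subassemblies).
#' @return List with \code{retained} and \code{removed} ([read_pairs])
#'   and \code{rrna_fraction} = removed/total.
#' @export
remove_rrna_reads <- function(pairs, matcher) {
  stopifnot(inherits(pairs, "read_pairs"), inherits(matcher, "kmer_matcher"))
  if (length(pairs) == 0L) stop("empty read stream: rRNA fraction undefined")
  hit <- kmer_shared_fraction(matcher, pairs$fwd_seq) >=
    matcher$min_shared_fraction |
    kmer_shared_fraction(matcher, pairs$rev_seq) >=
    matcher$min_shared_fraction
  list(retained = pairs[!hit], removed = pairs[hit],
       rrna_fraction = sum(hit) / length(pairs))
}

#' Take nested read subsets
#'
#' Returns prefixes of the (already randomized) stream, so larger
#' subsets contain smaller ones; subset assembly across a range of sizes
#' is used because the optimal read count for assembling a given rRNA
#' transcript varies with rRNA fraction and coverage uniformity.
#'
#' @param pairs a [read_pairs] object (randomize first with
#'   [sanitize_pairs]).
#' @param subset_sizes integer vector of subset sizes; sizes exceeding
#'   the available pairs are clamped with a warning.
#' @return List of [read_pairs] prefixes, one per requested size.
#' @export
subset_reads <- function(pairs, subset_sizes) {
  stopifnot(inherits(pairs, "read_pairs"))
  lapply(subset_sizes, function(s) {
    if (s > length(pairs)) {
      warning(sprintf("requested subset of %d exceeds %d available pairs; clamped",
                      s, length(pairs)))
      s <- length(pairs)
    }
    pairs[seq_len(s)]
  })
}

#' Flag transcripts matching a reference set
#'
#' Sets \code{is_rrna} or \code{is_vector} per transcript by the same
#' k-mer containment rule used for reads. Transcripts are only flagged
#' here, never deleted; downstream exemplar selection excludes them.
#'
#' @param transcripts a [gene_seqs] data frame.
#' @param matcher a [kmer_matcher] built from the reference (rRNA set or
#'   vector/contaminant database).
#' @param flag which annotation column to set.
#' @return The annotated [gene_seqs] data frame.
#' @export
flag_transcripts <- function(transcripts, matcher,
                             flag = c("is_rrna", "is_vector")) {
  flag <- match.arg(flag)
  hit <- kmer_shared_fraction(matcher, transcripts$sequence) >=
    matcher$min_shared_fraction
  transcripts[[flag]] <- hit
  transcripts
}

## ---- open reading frames -------------------------------------------------

stop_codons <- c("TAA", "TAG", "TGA")

#' Find the longest open reading frame across six frames
#'
#' An ORF here is a maximal stop-free codon run (stop-to-stop); a start
#' codon is not required, because transcriptome fragments are often
#' 5'-truncated. All six frames are scanned; partial terminal codons are
#' ignored. Ties are broken by frame order +1,+2,+3,-1,-2,-3, then by
#' smaller forward-strand start. Coordinates are 0-based half-open on
#' the forward strand.
#'
#' @param sequence a single nucleotide string, length at least 3.
#' @return List with \code{frame} (one of +1,+2,+3,-1,-2,-3),
#'   \code{start}, \code{end} and \code{length} (nt).
#' @export
find_longest_orf <- function(sequence) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 3L) stop("sequence shorter than 3 nt")
  rc <- revcomp(sequence)
  cand <- list()
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    s <- if (fr > 0L) sequence else rc
    off <- abs(fr) - 1L
    ncod <- (L - off) %/% 3L
    if (ncod == 0L) next
    starts <- off + 3L * (seq_len(ncod) - 1L)
    codons <- substring(s, starts + 1L, starts + 3L)
    is_stop <- codons %in% stop_codons
    runs <- stopfree_runs(is_stop)        # codon-index runs [i0, i1]
    if (nrow(runs) == 0L) next
    for (r in seq_len(nrow(runs))) {
      s0 <- off + 3L * (runs[r, 1L] - 1L)       # 0-based on scanned strand
      e0 <- off + 3L * runs[r, 2L]
      if (fr > 0L) { fs <- s0; fe <- e0 } else { fs <- L - e0; fe <- L - s0 }
      cand[[length(cand) + 1L]] <-
        c(frame = fr, start = fs, end = fe, len = e0 - s0)
    }
  }
  if (length(cand) == 0L)      # every codon in every frame is a stop
    stop("no stop-free codon run found")
  m <- do.call(rbind, cand)
  frame_rank <- match(m[, "frame"], c(1L, 2L, 3L, -1L, -2L, -3L))
  ord <- order(-m[, "len"], frame_rank, m[, "start"])
  best <- m[ord[1L], ]
  list(frame = unname(best["frame"]), start = unname(best["start"]),
       end = unname(best["end"]), length = unname(best["len"]))
}

# Maximal runs of FALSE in a logical vector, as a 2-column matrix of
# 1-based [first, last] indices.
stopfree_runs <- function(is_stop) {
  r <- rle(is_stop)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !r$values
  cbind(starts[keep], ends[keep])
}

#' Annotate each sequence with its longest ORF
#'
#' @param seqs a [gene_seqs] data frame.
#' @return The data frame with \code{orf_frame}, \code{orf_start},
#'   \code{orf_end} filled in (sequences shorter than 3 nt are left
#'   unannotated).
#' @export
annotate_orfs <- function(seqs) {
  for (i in seq_len(nrow(seqs))) {
    if (nchar(seqs$sequence[i]) < 3L) next
    orf <- tryCatch(find_longest_orf(seqs$sequence[i]),
                    error = function(e) NULL)
    if (is.null(orf)) next
    seqs$orf_frame[i] <- orf$frame
    seqs$orf_start[i] <- orf$start
    seqs$orf_end[i] <- orf$end
  }
  seqs
}

## ---- exemplar selection --------------------------------------------------

#' Select one exemplar transcript per gene
#'
#' Per gene (isoform group), the splice variant with the highest
#' expression is selected; ties go to the longest sequence, remaining
#' ties to the lexicographically smallest \code{seq_id}. Transcripts
#' flagged \code{is_rrna} or \code{is_vector} are excluded before
#' selection; genes whose transcripts are all flagged are dropped (with
#' a message).
#'
#' @param transcripts a [gene_seqs] data frame; missing expression is
#'   treated as 0.
#' @return A [gene_seqs] data frame with exactly one row per surviving
#'   \code{gene_id}.
#' @export
select_exemplars <- function(transcripts) {
  stopifnot(is.data.frame(transcripts))
  ok <- !(transcripts$is_rrna | transcripts$is_vector)
  dropped_genes <- setdiff(unique(transcripts$gene_id),
                           unique(transcripts$gene_id[ok]))
  if (length(dropped_genes))
    message("dropping ", length(dropped_genes),
            " gene(s) whose transcripts are all flagged: ",
            paste(head(dropped_genes, 5L), collapse = ", "))
  tr <- transcripts[ok, , drop = FALSE]
  expr <- ifelse(is.na(tr$expression), 0, tr$expression)
  ord <- order(tr$gene_id, -expr, -nchar(tr$sequence), tr$seq_id)
  tr <- tr[ord, , drop = FALSE]
  out <- tr[!duplicated(tr$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
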