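# Cluster refinement ahead of alignment and tree inference: sampling and
# length filters, trimming of sequence ends unsupported by intra-cluster
# similarity (possible chimeric regions), a simplified gap-block
# alignment cleaner, and in-frame codon translation. The multiple
# aligner itself is an external interface: clusters go out as unaligned
# FASTA and come back aligned; a trivial pad-to-length aligner is
# built in for self-contained runs on indel-free data.

#' Apply sampling and length filters to homolog clusters
#'
#' Sequences shorter than \code{min_seq_len} are removed first; then
#' clusters spanning fewer than \code{min_taxa} distinct taxa, or having
#' more than \code{max_seqs} members, are dropped. Defaults are
#' deliberately permissive knobs, all exposed on the command line.
#'
#' @param clusters named list of character vectors of (namespaced)
#'   seq_ids.
#' @param seqs a [gene_seqs] data frame resolving every member id.
#' @param min_taxa minimum distinct taxa per cluster (default 4).
#' @param min_seq_len minimum member length in nt (default 60).
#' @param max_seqs maximum members per cluster (default 100).
#' @return List with \code{clusters} (the survivors, member lists
#'   possibly shortened) and \code{log} (data frame of dropped clusters
#'   and reasons).
#' @export
filter_clusters <- function(clusters, seqs, min_taxa = 4L,
                            min_seq_len = 60L, max_seqs = 100L) {
  if (is.null(names(clusters)))
    names(clusters) <- paste0("c", seq_along(clusters))
  len <- setNames(nchar(seqs$sequence), seqs$seq_id)
  out <- list(); log <- list()
  for (cid in names(clusters)) {
    members <- clusters[[cid]]
    members <- members[!is.na(len[members]) & len[members] >= min_seq_len]
    n_taxa <- length(unique(taxon_of(members)))
    if (n_taxa < min_taxa) {
      log[[cid]] <- "taxa"
    } else if (length(members) > max_seqs) {
      log[[cid]] <- "size"
    } else {
      out[[cid]] <- members
    }
  }
  list(clusters = out,
       log = data.frame(cluster_id = names(log),
                        reason = unlist(log) %||% character(),
                        row.names = NULL))
}

#' Trim sequence ends unsupported by intra-cluster similarity
#'
#' For each member, the union of its query-side hit spans against
#' \emph{other} members of the same cluster defines a support envelope
#' \code{[min_start, max_end]}; the sequence is trimmed to that envelope
#' (interior gaps in support are kept). Members with no qualifying hits
#' are removed — their whole length is unsupported and could be chimeric.
#' ORF annotations are shifted to the trimmed coordinates.
#'
#' @param members a [gene_seqs] data frame: the cluster's sequences.
#' @param intra_hits hit data frame restricted to pairs within the
#'   cluster (hits touching non-members or self-hits are ignored).
#' @return The trimmed [gene_seqs] data frame (possibly fewer rows).
#' @export
trim_ends <- function(members, intra_hits) {
  ids <- members$seq_id
  h <- intra_hits[intra_hits$query_id %in% ids &
                    intra_hits$subject_id %in% ids &
                    intra_hits$query_id != intra_hits$subject_id, ,
                  drop = FALSE]
  keep <- logical(nrow(members))
  for (i in seq_len(nrow(members))) {
    id <- ids[i]
    spans <- h[h$query_id == id, , drop = FALSE]
    if (nrow(spans) == 0L) next
    s1 <- min(spans$q_start)               # 1-based inclusive
    e1 <- max(spans$q_end)
    if (e1 < s1) next
    start0 <- s1 - 1L                      # 0-based half-open envelope
    end0 <- e1
    members$sequence[i] <- substr(members$sequence[i], s1, e1)
    if (!is.na(members$orf_start[i])) {
      members$orf_start[i] <- max(members$orf_start[i] - start0, 0L)
      members$orf_end[i] <- min(members$orf_end[i] - start0, end0 - start0)
      if (members$orf_end[i] <= members$orf_start[i]) {
        members$orf_frame[i] <- NA_integer_
        members$orf_start[i] <- NA_integer_
        members$orf_end[i] <- NA_integer_
      }
    }
    keep[i] <- TRUE
  }
  out <- members[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- alignments ----------------------------------------------------------

# An alignment is a named character vector (seq_id -> aligned row) with
# all rows the same length, alphabet {A,C,G,T,N,-} or amino acids + '-'.
check_alignment <- function(aln) {
  stopifnot(is.character(aln), !is.null(names(aln)))
  if (length(aln) && length(unique(nchar(aln))) != 1L)
    stop("alignment rows have unequal lengths")
  aln
}

#' Trivial built-in aligner: right-pad to equal length
#'
#' Pads every sequence with \code{-} to the length of the longest. Only
#' adequate when the input rows are already columnwise homologous (no
#' indels), as with this package's synthetic gene families; real data
#' should go through an external translation-aware aligner via
#' [write_cluster_fasta]/[read_alignment_fasta].
#'
#' @param seqs named character vector of unaligned sequences.
#' @return An alignment (named character vector, equal row lengths).
#' @export
pad_align <- function(seqs) {
  w <- max(nchar(seqs))
  check_alignment(vapply(seqs, function(s)
    paste0(s, strrep("-", w - nchar(s))), character(1)))
}

#' Align a cluster with an external mafft binary
#'
#' Writes the sequences to a temporary FASTA, runs \code{mafft --auto},
#' and reads the alignment back. Requires \code{mafft} on the PATH.
#'
#' @param seqs named character vector of unaligned sequences.
#' @return An alignment (named character vector).
#' @export
align_mafft <- function(seqs) {
  infile <- tempfile(fileext = ".fa"); outfile <- tempfile(fileext = ".fa")
  write_fasta(seqs, infile)
  status <- system2("mafft", c("--auto", "--quiet", infile),
                    stdout = outfile)
  if (status != 0L) stop("mafft failed with status ", status)
  read_alignment_fasta(outfile)
}

#' Per-cluster FASTA out / aligned FASTA in
#'
#' The boundary to external multiple aligners: \code{write_cluster_fasta}
#' emits one unaligned FASTA per cluster; \code{read_alignment_fasta}
#' reads an aligned FASTA back as an alignment.
#'
#' @param members a [gene_seqs] data frame or named character vector.
#' @param path FASTA path.
#' @return \code{read_alignment_fasta} returns a named character vector
#'   with equal row lengths.
#' @export
write_cluster_fasta <- function(members, path) write_fasta(members, path)

#' @rdname write_cluster_fasta
#' @export
read_alignment_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment FASTA: ", path)
  check_alignment(setNames(toupper(as.character(set)),
                           sub("\\s.*$", "", names(set))))
}

#' Clean an alignment by gap-fraction and block length
#'
#' A simplified gap-block filter (in the spirit of classic alignment
#' cleaners, not a reimplementation of any): columns whose gap fraction
#' exceeds \code{max_gap_fraction} are removed; the surviving columns
#' are grouped into maximal runs (relative to the original coordinates)
#' and runs shorter than \code{min_block_len} are removed too. Row order
#' is preserved. Externally cleaned alignments can be supplied instead.
#'
#' @param aln an alignment (named character vector).
#' @param max_gap_fraction maximum fraction of gap characters per kept
#'   column (default 0.5; \code{-} and \code{?} count as gaps).
#' @param min_block_len minimum run length of kept columns (default 10).
#' @return The cleaned alignment, with attribute \code{kept_columns}
#'   (integer indices into the input columns). Empty result warns.
#' @export
clean_alignment <- function(aln, max_gap_fraction = 0.5,
                            min_block_len = 10L) {
  check_alignment(aln)
  w <- nchar(aln[1L])
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  gapfrac <- colMeans(m == "-" | m == "?")
  keep <- gapfrac <= max_gap_fraction
  if (any(keep)) {
    r <- rle(keep)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths < min_block_len))
      keep[starts[j]:ends[j]] <- FALSE
  }
  cols <- which(keep)
  if (length(cols) == 0L) {
    warning("alignment cleaning removed every column")
    out <- setNames(rep("", length(aln)), names(aln))
  } else {
    out <- setNames(apply(m[, cols, drop = FALSE], 1L, paste, collapse = ""),
                    names(aln))
  }
  attr(out, "kept_columns") <- cols
  out
}

#' Translate an in-frame nucleotide alignment to protein
#'
#' Standard genetic code, codon by codon. All-gap codons \code{"---"}
#' become \code{"-"}; codons containing a partial gap or ambiguity
#' become \code{"X"}; stop codons become \code{"X"} with a warning
#' (internal stops usually indicate frame damage).
#'
#' @param aln an in-frame nucleotide alignment whose row lengths are
#'   divisible by 3.
#' @return The protein alignment (rows of length nt/3).
#' @export
translate_alignment <- function(aln) {
  check_alignment(aln)
  if (nchar(aln[1L]) %% 3L != 0L)
    stop("alignment length not divisible by 3")
  code <- Biostrings::GENETIC_CODE
  n_stops <- 0L
  out <- vapply(aln, function(row) {
    n <- nchar(row) %/% 3L
    codons <- substring(row, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    aa <- character(n)
    aa[codons == "---"] <- "-"
    todo <- which(aa == "")
    known <- code[codons[todo]]
    stops <- !is.na(known) & known == "*"
    n_stops <<- n_stops + sum(stops)
    known[stops] <- "X"
    known[is.na(known)] <- "X"      # partial gaps / ambiguity codes
    aa[todo] <- known
    paste(aa, collapse = "")
  }, character(1))
  if (n_stops > 0L)
    warning(n_stops, " internal stop codon(s) translated as 'X'")
  check_alignment(out)
}
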