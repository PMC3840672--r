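# Domain containers and standard-format readers/writers. Every later
# stage consumes the types defined here: read_pairs (mated FASTQ reads),
# gene_seqs (annotated nucleotide sequences), similarity-hit tables, and
# the file-backed dataset catalog.

#' Construct a set of mated read pairs
#'
#' A \code{read_pairs} object is a column-oriented container: parallel
#' vectors of pair ids, forward/reverse sequences and their Phred+33
#' quality strings. Record \code{i} of the forward file mates record
#' \code{i} of the reverse file.
#'
#' @param id character vector of shared pair identifiers.
#' @param fwd_seq,rev_seq nucleotide strings over \code{A,C,G,T,N}.
#' @param fwd_qual,rev_qual Phred+33 quality strings, same lengths as the
#'   corresponding sequences.
#' @return An object of class \code{read_pairs}.
#' @export
read_pairs <- function(id, fwd_seq, rev_seq, fwd_qual, rev_qual) {
  n <- length(id)
  stopifnot(length(fwd_seq) == n, length(rev_seq) == n,
            length(fwd_qual) == n, length(rev_qual) == n)
  if (any(nchar(fwd_seq) != nchar(fwd_qual)) ||
      any(nchar(rev_seq) != nchar(rev_qual)))
    stop("sequence and quality lengths differ within a read")
  structure(list(id = as.character(id),
                 fwd_seq = toupper(fwd_seq), rev_seq = toupper(rev_seq),
                 fwd_qual = fwd_qual, rev_qual = rev_qual),
            class = "read_pairs")
}

#' @export
length.read_pairs <- function(x) length(x$id)

#' @export
`[.read_pairs` <- function(x, i) {
  structure(lapply(unclass(x), `[`, i), class = "read_pairs")
}

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("read_pairs: %d pairs (read length %s)\n", length(x),
              if (length(x)) paste(range(nchar(x$fwd_seq)), collapse = "-")
              else "NA"))
  invisible(x)
}

# Phred+33 decoding. '!' is Q0, 'I' is Q40; valid scores are 0..93.
qual_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

mean_qual <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

#' Read mated paired-end FASTQ files
#'
#' Reads two Phred+33 FASTQ files in lockstep; record \code{i} of the
#' forward file is paired with record \code{i} of the reverse file. Pair
#' ids are taken from the forward headers with any \code{/1}, \code{/2}
#' or whitespace suffix stripped.
#'
#' @param fwd_path,rev_path paths to the forward and reverse FASTQ files.
#' @return A [read_pairs] object, in file order.
#' @export
read_fastq_pairs <- function(fwd_path, rev_path) {
  fwd <- read_fastq_one(fwd_path)
  rev <- read_fastq_one(rev_path)
  if (length(fwd$id) != length(rev$id))
    stop(sprintf("unequal pair counts: %d records in '%s' vs %d in '%s'",
                 length(fwd$id), fwd_path, length(rev$id), rev_path))
  read_pairs(id = sub("/[12]$", "", fwd$id),
             fwd_seq = fwd$seq, rev_seq = rev$seq,
             fwd_qual = fwd$qual, rev_qual = rev$qual)
}

# Single-file four-line FASTQ parser with record-indexed errors.
# (Biostrings reads FASTQ but drops the ability to report which record
# is malformed; pair-count and per-record diagnostics matter here.)
read_fastq_one <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop(sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4",
                 path, length(lines)))
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seq) != nchar(qual))
  if (length(bad))
    stop(sprintf("malformed FASTQ record %d in '%s'", bad[1L], path))
  qint <- utf8ToInt(paste(qual, collapse = ""))
  if (any(qint < 33L | qint > 126L))
    stop(sprintf("quality characters outside Phred+33 range in '%s'", path))
  list(id = sub("^@", "", sub("\\s.*$", "", hdr)),
       seq = toupper(seq), qual = qual)
}

#' Write mated read pairs as two FASTQ files
#'
#' @param pairs a [read_pairs] object.
#' @param fwd_path,rev_path output FASTQ paths.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pairs <- function(pairs, fwd_path, rev_path) {
  stopifnot(inherits(pairs, "read_pairs"))
  fmt <- function(id, mate, seq, qual)
    paste0("@", id, "/", mate, "\n", seq, "\n+\n", qual)
  writeLines(fmt(pairs$id, 1L, pairs$fwd_seq, pairs$fwd_qual), fwd_path)
  writeLines(fmt(pairs$id, 2L, pairs$rev_seq, pairs$rev_qual), rev_path)
  invisible(c(fwd_path, rev_path))
}

#' Construct a table of annotated gene sequences
#'
#' The central per-sequence container: a data frame with one row per
#' sequence and columns \code{seq_id} (namespaced
#' \code{"<taxon_id>@<id>"} once catalogued), \code{taxon_id},
#' \code{gene_id} (isoform group), \code{sequence}, plus annotation
#' columns \code{orf_frame}, \code{orf_start}, \code{orf_end} (0-based
#' half-open, forward strand), \code{is_rrna}, \code{is_vector} and
#' \code{expression}.
#'
#' @param seq_id,taxon_id,gene_id,sequence character vectors.
#' @param expression optional non-negative expression values.
#' @return A data frame of class \code{gene_seqs}.
#' @export
gene_seqs <- function(seq_id, taxon_id = NA_character_,
                      gene_id = seq_id, sequence,
                      expression = NA_real_) {
  if (any(!nzchar(seq_id))) stop("empty seq_id")
  if (anyDuplicated(seq_id))
    stop("duplicate seq_id: ", seq_id[duplicated(seq_id)][1L])
  df <- data.frame(seq_id = as.character(seq_id),
                   taxon_id = as.character(taxon_id),
                   gene_id = as.character(gene_id),
                   sequence = toupper(chartr("Uu", "Tt", sequence)),
                   orf_frame = NA_integer_, orf_start = NA_integer_,
                   orf_end = NA_integer_,
                   is_rrna = FALSE, is_vector = FALSE,
                   expression = as.numeric(expression),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_seqs", "data.frame")
  df
}

#' Read a FASTA file of gene sequences
#'
#' Sequences are uppercased and RNA \code{U} is mapped to \code{T}. The
#' first whitespace-delimited header token becomes \code{seq_id}; taxon
#' and gene assignment follow a configurable convention because external
#' gene predictions carry no standard metadata in their headers.
#'
#' @param path FASTA file path.
#' @param taxon_id taxon assigned to every record (a catalog-level
#'   property), or \code{NA}.
#' @param gene_id_pattern regular expression applied to \code{seq_id}
#'   whose first capture group yields \code{gene_id}; default keeps the
#'   whole id (every sequence its own gene).
#' @return A [gene_seqs] data frame.
#' @export
read_fasta <- function(path, taxon_id = NA_character_,
                       gene_id_pattern = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate seq_id in '", path, "': ", ids[duplicated(ids)][1L])
  gene <- ids
  if (!is.null(gene_id_pattern)) {
    m <- regmatches(ids, regexec(gene_id_pattern, ids))
    gene <- vapply(seq_along(m), function(i)
      if (length(m[[i]]) >= 2L) m[[i]][2L] else ids[i], character(1))
  }
  gene_seqs(seq_id = ids, taxon_id = taxon_id, gene_id = gene,
            sequence = as.character(set))
}

#' Write sequences to FASTA
#'
#' @param x a [gene_seqs] data frame, or a named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (inherits(x, "gene_seqs") || is.data.frame(x))
    x <- setNames(x$sequence, x$seq_id)
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

hit_cols <- c("query_id", "subject_id", "percent_identity", "align_len",
              "mismatches", "gap_opens", "q_start", "q_end",
              "s_start", "s_end", "evalue", "bitscore")

#' Read a 12-column tabular similarity-hit file
#'
#' The classic all-by-all search output dialect: query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end (1-based inclusive), e-value, bit score.
#'
#' @param path tab-separated hit file.
#' @return A data frame with columns named after the 12 fields; zero rows
#'   for an empty file.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    df <- as.data.frame(setNames(
      c(list(character(), character()), rep(list(numeric()), 10L)), hit_cols))
    return(df)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop(sprintf("expected 12 tab-separated columns, found %d at line %d of '%s'",
                 nf[nf != 12L][1L], which(nf != 12L)[1L], path))
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  df <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                   stringsAsFactors = FALSE)
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop(sprintf("non-numeric value in column %d at line %d of '%s'",
                   j, which(is.na(v))[1L], path))
    df[[hit_cols[j]]] <- v
  }
  ints <- c("align_len", "mismatches", "gap_opens",
            "q_start", "q_end", "s_start", "s_end")
  for (j in ints) df[[j]] <- as.integer(df[[j]])
  if (any(df$evalue < 0)) stop("negative e-value in '", path, "'")
  if (any(df$align_len < 1L)) stop("alignment length < 1 in '", path, "'")
  df
}

#' @rdname read_hit_table
#' @param hits a hit data frame as returned by [read_hit_table].
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(all(hit_cols %in% names(hits)))
  h <- hits[, hit_cols]
  h$evalue <- formatC(h$evalue, format = "g", digits = 6)
  write.table(h, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- dataset catalog ----------------------------------------------------

#' Open (or create) a dataset catalog
#'
#' The catalog is an embedded file-backed key-value store: one JSON file,
#' one entry per dataset, addressed by \code{catalog_id}. Cataloguing is
#' the first step of every analysis; it records sample metadata and the
#' paths to the data files.
#'
#' @param path path of the catalog JSON file; created if absent.
#' @return A catalog handle (class \code{mfx_catalog}).
#' @export
catalog_open <- function(path) {
  store <- new.env(parent = emptyenv())
  if (file.exists(path) && file.size(path) > 0) {
    entries <- jsonlite::read_json(path, simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE)
    for (id in names(entries)) assign(id, entries[[id]], envir = store)
  }
  structure(list(path = path, store = store), class = "mfx_catalog")
}

#' Create a catalog entry
#'
#' @param catalog_id unique dataset identifier.
#' @param species species binomial (free text).
#' @param taxon_id short taxon label used to namespace sequence ids;
#'   must not contain \code{"@"}.
#' @param data_paths character vector of existing data file paths.
#' @param data_kind \code{"raw_reads"} or \code{"assembled_genes"}.
#' @param metadata free-form named list.
#' @return A list of class \code{catalog_entry}.
#' @export
catalog_entry <- function(catalog_id, species, taxon_id, data_paths,
                          data_kind = c("raw_reads", "assembled_genes"),
                          metadata = list()) {
  data_kind <- match.arg(data_kind)
  if (!nzchar(catalog_id)) stop("catalog_id must be non-empty")
  if (grepl("@", taxon_id, fixed = TRUE))
    stop("'@' is reserved and may not appear in taxon_id")
  if (length(data_paths) == 0L) stop("data_paths must be non-empty")
  missing <- data_paths[!file.exists(data_paths)]
  if (length(missing)) stop("missing data path: ", missing[1L])
  structure(list(catalog_id = catalog_id, species = species,
                 taxon_id = taxon_id,
                 data_paths = as.character(data_paths),
                 data_kind = data_kind, metadata = metadata),
            class = "catalog_entry")
}

#' Add, fetch and list catalog entries
#'
#' \code{catalog_add} persists an entry immediately; re-adding an
#' existing \code{catalog_id} requires \code{force = TRUE}.
#'
#' @param catalog a handle from [catalog_open].
#' @param entry a [catalog_entry].
#' @param force overwrite an existing entry with the same id.
#' @return \code{catalog_add} returns the \code{catalog_id};
#'   \code{catalog_get} the stored entry; \code{catalog_ids} all ids.
#' @export
catalog_add <- function(catalog, entry, force = FALSE) {
  stopifnot(inherits(catalog, "mfx_catalog"), inherits(entry, "catalog_entry"))
  id <- entry$catalog_id
  if (exists(id, envir = catalog$store, inherits = FALSE) && !force)
    stop("catalog_id '", id, "' already exists (use force = TRUE to replace)")
  assign(id, unclass(entry), envir = catalog$store)
  catalog_flush(catalog)
  id
}

#' @rdname catalog_add
#' @param catalog_id id to fetch.
#' @export
catalog_get <- function(catalog, catalog_id) {
  if (!exists(catalog_id, envir = catalog$store, inherits = FALSE))
    stop("no catalog entry '", catalog_id, "'")
  e <- get(catalog_id, envir = catalog$store)
  class(e) <- "catalog_entry"
  e
}

#' @rdname catalog_add
#' @export
catalog_ids <- function(catalog) sort(ls(envir = catalog$store))

catalog_flush <- function(catalog) {
  ids <- ls(envir = catalog$store)
  entries <- setNames(lapply(ids, get, envir = catalog$store), ids)
  jsonlite::write_json(entries, catalog$path, auto_unbox = TRUE, digits = NA)
  invisible(catalog)
}
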