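# Supermatrix assembly: concatenate per-ortholog alignments into one
# matrix with a RAxML-style partitions table, occupancy diagnostics,
# and FASTA / relaxed-PHYLIP / partitions writers with a reader for
# round-trips.

#' Concatenate gene alignments into a supermatrix
#'
#' Each alignment contributes one column block (a partition). Rows are
#' keyed by taxon: alignment row names may be bare taxon ids or
#' namespaced \code{"taxon@seq"} ids (the taxon prefix is used). A taxon
#' absent from a gene gets \code{'?'} across that partition —
#' distinguishing missing genes from alignment gaps \code{'-'}. Gene
#' order defaults to lexicographic by name, for reproducibility.
#'
#' @param alignments named list of alignments (named character vectors
#'   of equal row length); names are gene names.
#' @param taxa optional explicit taxon order; default is the sorted
#'   union of observed taxa.
#' @param datatype \code{"DNA"} or \code{"PROT"} (recorded per
#'   partition).
#' @param sort_genes concatenate in lexicographic gene order (default
#'   TRUE); \code{FALSE} keeps list order.
#' @return A list of class \code{supermatrix}: \code{taxa},
#'   \code{matrix} (named character vector of rows) and
#'   \code{partitions} (data frame \code{gene_name}, \code{start},
#'   \code{end} 1-based inclusive, \code{datatype}).
#' @export
concatenate <- function(alignments, taxa = NULL,
                        datatype = c("DNA", "PROT"), sort_genes = TRUE) {
  datatype <- match.arg(datatype)
  if (length(alignments) == 0L) stop("no alignments to concatenate")
  if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
    stop("alignments must be named by gene")
  if (sort_genes)
    alignments <- alignments[order(names(alignments))]
  per_gene <- lapply(names(alignments), function(g) {
    aln <- check_alignment(alignments[[g]])
    tx <- ifelse(grepl("@", names(aln), fixed = TRUE),
                 taxon_of(names(aln)), names(aln))
    dup <- tx[duplicated(tx)]
    if (length(dup))
      stop(sprintf("gene '%s' has more than one row for taxon '%s'",
                   g, dup[1L]))
    setNames(unname(aln), tx)
  })
  names(per_gene) <- names(alignments)
  if (is.null(taxa))
    taxa <- sort(unique(unlist(lapply(per_gene, names))))
  widths <- vapply(per_gene, function(a) nchar(a[1L]), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  rows <- vapply(taxa, function(tx) {
    paste(vapply(seq_along(per_gene), function(i) {
      a <- per_gene[[i]]
      if (tx %in% names(a)) a[[tx]] else strrep("?", widths[i])
    }, character(1)), collapse = "")
  }, character(1))
  structure(list(taxa = taxa, matrix = rows,
                 partitions = data.frame(gene_name = names(per_gene),
                                         start = starts, end = ends,
                                         datatype = datatype,
                                         row.names = NULL)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  occ <- occupancy(x)
  cat(sprintf("supermatrix: %d taxa x %d columns, %d partitions, occupancy %.1f%%\n",
              length(x$taxa), nchar(x$matrix[1L]),
              nrow(x$partitions), 100 * occ$overall))
  invisible(x)
}

#' Supermatrix occupancy
#'
#' Fraction of characters that are neither missing (\code{?}) nor gaps
#' (\code{-}), per taxon and overall (mean over all cells).
#'
#' @param sm a \code{supermatrix}.
#' @return List with \code{per_taxon} (named numeric) and
#'   \code{overall}.
#' @export
occupancy <- function(sm) {
  filled <- vapply(sm$matrix, function(row)
    nchar(gsub("[?-]", "", row)) / nchar(row), numeric(1))
  names(filled) <- sm$taxa
  list(per_taxon = filled, overall = mean(filled))
}

#' Extract one partition's columns
#'
#' @param sm a \code{supermatrix}.
#' @param gene_name partition to extract.
#' @return Named character vector: that gene's column block per taxon.
#' @export
extract_partition <- function(sm, gene_name) {
  p <- sm$partitions[sm$partitions$gene_name == gene_name, , drop = FALSE]
  if (nrow(p) != 1L) stop("no partition '", gene_name, "'")
  vapply(sm$matrix, substr, "", p$start, p$end)
}

#' Write a supermatrix to FASTA, relaxed PHYLIP and a partitions file
#'
#' The partitions file uses the RAxML-style format
#' \code{"<DATATYPE>, <gene_name> = <start>-<end>"} (1-based inclusive).
#' For protein matrices a model token (e.g. \code{WAG}) can replace the
#' datatype token.
#'
#' @param sm a \code{supermatrix}.
#' @param fasta_path,phylip_path,partitions_path output paths; any may
#'   be \code{NULL} to skip.
#' @param model optional model token overriding the datatype token in
#'   the partitions file (e.g. \code{"WAG"}).
#' @return Invisibly, the written paths.
#' @export
write_supermatrix <- function(sm, fasta_path = NULL, phylip_path = NULL,
                              partitions_path = NULL, model = NULL) {
  written <- character()
  if (!is.null(fasta_path)) {
    write_fasta(setNames(sm$matrix, sm$taxa), fasta_path)
    written <- c(written, fasta_path)
  }
  if (!is.null(phylip_path)) {
    lines <- c(sprintf(" %d %d", length(sm$taxa), nchar(sm$matrix[1L])),
               sprintf("%s  %s", sm$taxa, sm$matrix))
    writeLines(lines, phylip_path)
    written <- c(written, phylip_path)
  }
  if (!is.null(partitions_path)) {
    tok <- model %||% sm$partitions$datatype
    writeLines(sprintf("%s, %s = %d-%d", tok, sm$partitions$gene_name,
                       sm$partitions$start, sm$partitions$end),
               partitions_path)
    written <- c(written, partitions_path)
  }
  invisible(written)
}

#' Read a supermatrix back from FASTA + partitions file
#'
#' Inverse of [write_supermatrix] for the FASTA/partitions pair;
#' \code{read(write(sm)) == sm}.
#'
#' @param fasta_path supermatrix FASTA.
#' @param partitions_path partitions file.
#' @return A \code{supermatrix}.
#' @export
read_supermatrix <- function(fasta_path, partitions_path) {
  rows <- read_alignment_fasta(fasta_path)
  lines <- readLines(partitions_path)
  m <- regmatches(lines,
                  regexec("^\\s*(\\S+),\\s*(\\S+)\\s*=\\s*(\\d+)-(\\d+)\\s*$",
                          lines))
  if (any(lengths(m) != 5L))
    stop("malformed partitions line: ", lines[which(lengths(m) != 5L)[1L]])
  parts <- data.frame(
    gene_name = vapply(m, `[`, "", 3L),
    start = as.integer(vapply(m, `[`, "", 4L)),
    end = as.integer(vapply(m, `[`, "", 5L)),
    datatype = ifelse(vapply(m, `[`, "", 2L) == "PROT" |
                        vapply(m, `[`, "", 2L) %in%
                        c("WAG", "LG", "JTT"), "PROT", "DNA"),
    row.names = NULL)
  structure(list(taxa = names(rows), matrix = rows, partitions = parts),
            class = "supermatrix")
}
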