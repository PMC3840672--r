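# Internal helpers shared across stages.

#' @importFrom methods as is
#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.table write.table head tail
NULL

# Run an expression with a temporary RNG state seeded from `seed`,
# restoring the caller's state afterwards. All stochastic operations in
# the package route through this so results are pure functions of
# (input, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# "<taxon_id>@<seq_id>" namespacing. "@" is reserved: user-supplied ids
# must not contain it, so leaf labels in gene trees are unambiguous.
namespace_id <- function(taxon_id, seq_id) {
  if (any(grepl("@", taxon_id, fixed = TRUE)) ||
      any(grepl("@", seq_id, fixed = TRUE)))
    stop("'@' is reserved for internal id namespacing and may not appear ",
         "in user-supplied taxon or sequence ids")
  paste0(taxon_id, "@", seq_id)
}

#' Split a namespaced sequence id into taxon and local id
#'
#' Internal leaf labels have the form \code{"<taxon_id>@<seq_id>"}; the
#' taxon part is everything before the first \code{"@"}.
#'
#' @param ids character vector of namespaced ids.
#' @return For \code{taxon_of}, the taxon part; for \code{local_id_of},
#'   the sequence part.
#' @export
taxon_of <- function(ids) sub("@.*$", "", ids)

#' @rdname taxon_of
#' @export
local_id_of <- function(ids) sub("^[^@]*@", "", ids)

# Reverse complement on plain character vectors (ACGTN alphabet).
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s)
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
           character(1), USE.NAMES = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
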