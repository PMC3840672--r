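# Homology evaluation: build a weighted graph from all-by-all similarity
# hits passing a stringent threshold, then break it into clusters of
# putative homologs with a from-scratch Markov Clustering (MCL)
# implementation. Plain connected components are available as an
# alternative clustering mode and as an upper bound on cluster extent.

#' Build the homology graph from similarity hits
#'
#' An edge \code{{a, b}} exists iff \code{a != b} and at least one
#' directional hit between them passes both thresholds; the edge weight
#' is the maximum bit score over passing hits in either direction (bit
#' scores, unlike e-values, are database-size independent).
#'
#' @param hits a hit data frame ([read_hit_table]).
#' @param evalue_max maximum e-value for a hit to count (default 1e-20;
#'   the "stringent threshold" of the homology search).
#' @param min_align_len minimum alignment length (default 50).
#' @param nodes optional character vector of all catalogued sequence
#'   ids, so sequences without passing hits appear as isolated nodes.
#' @return A list of class \code{homology_graph} with \code{nodes}
#'   (character) and \code{edges} (data frame \code{from}, \code{to},
#'   \code{weight}; \code{from < to} lexicographically).
#' @export
build_homology_graph <- function(hits, evalue_max = 1e-20,
                                 min_align_len = 50L, nodes = NULL) {
  pass <- hits$evalue <= evalue_max & hits$align_len >= min_align_len &
    hits$query_id != hits$subject_id
  h <- hits[pass, , drop = FALSE]
  if (nrow(h)) {
    a <- pmin(h$query_id, h$subject_id)
    b <- pmax(h$query_id, h$subject_id)
    key <- paste0(a, "\r", b)
    w <- tapply(h$bitscore, key, max)
    ab <- strsplit(names(w), "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(ab, `[`, "", 1L),
                        to = vapply(ab, `[`, "", 2L),
                        weight = as.numeric(w),
                        stringsAsFactors = FALSE, row.names = NULL)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  all_nodes <- sort(unique(c(edges$from, edges$to, nodes)))
  structure(list(nodes = all_nodes, edges = edges),
            class = "homology_graph")
}

#' @export
print.homology_graph <- function(x, ...) {
  cat(sprintf("homology_graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(graph$nodes), name = graph$nodes)
  if (nrow(graph$edges))
    g <- igraph::add_edges(g, rbind(graph$edges$from, graph$edges$to),
                           weight = graph$edges$weight)
  g
}

#' Connected components of a homology graph
#'
#' @param graph a \code{homology_graph}.
#' @return List of character vectors (sorted ids), sorted by their first
#'   member; empty list for an empty graph.
#' @export
connected_components <- function(graph) {
  if (length(graph$nodes) == 0L) return(list())
  comp <- igraph::components(as_igraph(graph))
  out <- split(graph$nodes, comp$membership)
  out <- lapply(out, function(x) sort(unname(x)))
  out <- out[order(vapply(out, `[`, "", 1L))]
  names(out) <- NULL
  out
}

#' MCL parameters
#'
#' @param inflation inflation exponent (> 1; default 2.0). Higher
#'   inflation gives finer clusters.
#' @param expansion expansion power (integer >= 2; default 2).
#' @param prune_below entries below this are zeroed each iteration
#'   (default 1e-5).
#' @param max_iterations iteration cap (default 100).
#' @param convergence_tol maximum column change declaring convergence
#'   (default 1e-6).
#' @return A list of class \code{mcl_params}.
#' @export
mcl_params <- function(inflation = 2.0, expansion = 2L,
                       prune_below = 1e-5, max_iterations = 100L,
                       convergence_tol = 1e-6) {
  stopifnot(inflation > 1, expansion >= 2L)
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 prune_below = prune_below,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol),
            class = "mcl_params")
}

#' Markov Clustering of the homology graph
#'
#' Standard MCL on the weighted adjacency matrix with self-loops (loop
#' weight = maximum incident edge weight; 1 for isolated nodes):
#' column-normalize, then iterate expansion (matrix power) and inflation
#' (elementwise power + renormalization), pruning entries below
#' \code{prune_below}, until the maximum column change falls below
#' \code{convergence_tol}. Clusters are read off the limit matrix as
#' weakly connected groups of its nonzero entries, so every node lands
#' in exactly one cluster. Each connected component of the input graph
#' is iterated independently (the result is identical; components never
#' mix).
#'
#' @param graph a \code{homology_graph}.
#' @param params an [mcl_params].
#' @return List of clusters (character vectors, each sorted), sorted by
#'   first member, with attribute \code{converged} (logical: FALSE if
#'   any component hit \code{max_iterations}, with a warning).
#' @export
mcl_cluster <- function(graph, params = mcl_params()) {
  comps <- connected_components(graph)
  converged <- TRUE
  clusters <- list()
  for (comp in comps) {
    if (length(comp) == 1L) {
      clusters[[length(clusters) + 1L]] <- comp
      next
    }
    sub <- graph$edges[graph$edges$from %in% comp, , drop = FALSE]
    A <- matrix(0, length(comp), length(comp),
                dimnames = list(comp, comp))
    A[cbind(sub$from, sub$to)] <- sub$weight
    A[cbind(sub$to, sub$from)] <- sub$weight
    res <- mcl_iterate(A, params)
    if (!res$converged) converged <- FALSE
    clusters <- c(clusters, read_mcl_clusters(res$M, comp))
  }
  if (!converged)
    warning("MCL did not converge within max_iterations; ",
            "returning current clustering")
  clusters <- lapply(clusters, sort)
  clusters <- clusters[order(vapply(clusters, `[`, "", 1L))]
  structure(clusters, converged = converged)
}

# Core dense MCL iteration on one adjacency matrix. Self-loops are set
# to the maximum incident weight (1 for isolated nodes) before column
# normalization; this regularization keeps attractors stable.
mcl_iterate <- function(A, params) {
  diag(A) <- 0
  loop <- apply(A, 2L, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(params$max_iterations)) {
    Mexp <- matpow(M, params$expansion)
    Minf <- Mexp^params$inflation
    Minf[Minf < params$prune_below] <- 0
    cs <- colSums(Minf)
    dead <- cs == 0           # fully pruned column: restart on itself
    if (any(dead)) {
      Minf[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    Mnew <- sweep(Minf, 2L, cs, "/")
    delta <- max(abs(Mnew - M))
    M <- Mnew
    if (delta < params$convergence_tol) { converged <- TRUE; break }
  }
  list(M = M, converged = converged)
}

matpow <- function(M, p) {
  R <- M
  for (i in seq_len(p - 1L)) R <- R %*% M
  R
}

# Interpret a converged MCL matrix: nodes i, j belong to one cluster
# when they are weakly connected through nonzero entries of M.
read_mcl_clusters <- function(M, ids, eps = 1e-9) {
  n <- length(ids)
  adj <- (M > eps) | (t(M) > eps)
  seen <- rep(FALSE, n)
  out <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    members <- i
    frontier <- i
    seen[i] <- TRUE
    while (length(frontier)) {
      nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nxt] <- TRUE
      members <- c(members, nxt)
      frontier <- nxt
    }
    out[[length(out) + 1L]] <- ids[sort(members)]
  }
  out
}

#' Write cluster membership as a two-column TSV
#'
#' @param clusters list of character vectors.
#' @param path output path; lines are \code{cluster_id<TAB>seq_id} with
#'   cluster ids \code{"c1"}, \code{"c2"}, ... in list order.
#' @return Invisibly, \code{path}.
#' @export
write_clusters <- function(clusters, path) {
  df <- data.frame(
    cluster_id = rep(paste0("c", seq_along(clusters)), lengths(clusters)),
    seq_id = unlist(clusters) %||% character())
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read cluster membership TSV
#'
#' @param path a two-column \code{cluster_id<TAB>seq_id} file.
#' @return Named list of character vectors.
#' @export
read_clusters <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("cluster_id", "seq_id"),
                   colClasses = "character")
  split(df$seq_id, df$cluster_id)
}
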