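# Independent oracle implementations and small fixture builders shared
# across the suite. Each oracle re-derives the expected answer by a
# different mechanism than the implementation it checks.

## Six-frame longest-ORF oracle: walks codons index by index, tracking
## the current stop-free stretch explicitly (the implementation uses an
## rle over stop masks instead).
orf_oracle <- function(sequence) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  rc <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", sequence), "",
                           fixed = TRUE)[[1]]), collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    s <- if (fr > 0) sequence else rc
    off <- abs(fr) - 1L
    run_start <- off
    pos <- off
    flush <- function(run_start, pos) {
      if (pos <= run_start) return()
      if (fr > 0) { fs <- run_start; fe <- pos }
      else { fs <- L - pos; fe <- L - run_start }
      len <- pos - run_start
      frame_rank <- match(fr, c(1L, 2L, 3L, -1L, -2L, -3L))
      cand <- list(frame = fr, start = fs, end = fe, length = len,
                   rank = frame_rank)
      if (is.null(best) || len > best$length ||
          (len == best$length && (frame_rank < best$rank ||
            (frame_rank == best$rank && fs < best$start))))
        best <<- cand
    }
    while (pos + 3L <= L) {
      codon <- substr(s, pos + 1L, pos + 3L)
      if (codon %in% stops) {
        flush(run_start, pos)
        run_start <- pos + 3L
      }
      pos <- pos + 3L
    }
    flush(run_start, pos)
  }
  best[c("frame", "start", "end", "length")]
}

## Whole-graph dense MCL oracle: no per-component decomposition, matrix
## built through igraph, clusters read through igraph components.
mcl_oracle <- function(graph, params = mcl_params()) {
  if (length(graph$nodes) == 0L) return(list())
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(graph$nodes), name = graph$nodes)
  if (nrow(graph$edges))
    g <- igraph::add_edges(g, rbind(graph$edges$from, graph$edges$to),
                           weight = graph$edges$weight)
  A <- as.matrix(igraph::as_adjacency_matrix(g, attr = if (nrow(graph$edges))
    "weight" else NULL, sparse = TRUE))
  diag(A) <- 0
  loop <- apply(A, 2, max); loop[loop == 0] <- 1
  diag(A) <- loop
  M <- A %*% diag(1 / colSums(A))
  dimnames(M) <- dimnames(A)
  for (it in seq_len(params$max_iterations)) {
    E <- M
    for (p in seq_len(params$expansion - 1L)) E <- E %*% M
    I <- E^params$inflation
    I[I < params$prune_below] <- 0
    cs <- colSums(I)
    zero <- cs == 0
    if (any(zero)) { I[cbind(which(zero), which(zero))] <- 1; cs[zero] <- 1 }
    Mn <- I %*% diag(1 / cs)
    dimnames(Mn) <- dimnames(A)
    d <- max(abs(Mn - M)); M <- Mn
    if (d < params$convergence_tol) break
  }
  keep <- ((M > 1e-9) | (t(M) > 1e-9)) * 1
  gl <- igraph::graph_from_adjacency_matrix(keep, mode = "undirected",
                                            diag = TRUE)
  comp <- igraph::components(gl)
  out <- lapply(split(graph$nodes, comp$membership), function(x)
    sort(unname(x)))
  out <- unname(out[order(vapply(out, `[`, "", 1L))])
  out
}

## Branch-induced candidate leaf sets of a tree, via igraph edge
## deletion (the implementation derives them from clade tip sets).
candidate_sets_oracle <- function(tree) {
  labels <- if (is.character(tree)) tree else tree$tip.label
  sets <- list(sort(labels))
  if (!is.character(tree) && length(labels) >= 2L) {
    n_node <- length(labels) + tree$Nnode
    g <- igraph::make_empty_graph(n = n_node, directed = FALSE)
    g <- igraph::add_edges(g, t(tree$edge))
    for (e in seq_len(nrow(tree$edge))) {
      gd <- igraph::delete_edges(g, e)
      comp <- igraph::components(gd)$membership
      for (side in unique(comp)) {
        tips <- which(comp == side & seq_len(n_node) <= length(labels))
        if (length(tips))
          sets[[length(sets) + 1L]] <- sort(labels[tips])
      }
    }
  }
  unique(sets)
}

max_taxon_unique_size <- function(tree) {
  sets <- candidate_sets_oracle(tree)
  ok <- sets[vapply(sets, function(s)
    !anyDuplicated(sub("@.*$", "", s)), logical(1))]
  max(lengths(ok))
}

## Random gene-tree generator: random topology, tips labeled over a
## bounded taxon set so duplicates (paralogs) occur.
random_labeled_tree <- function(n_leaves, n_taxa, seed) {
  set.seed(seed)
  taxa <- sample(sprintf("t%d", seq_len(n_taxa)), n_leaves, replace = TRUE)
  labels <- paste0(taxa, "@s", seq_len(n_leaves))
  if (n_leaves == 1L) return(labels)
  ape::rtree(n_leaves, tip.label = sample(labels))
}

## Quick read-pair builder with uniform quality.
make_pairs <- function(fwd, rev = fwd, q = 35L) {
  n <- length(fwd)
  qs <- function(seqs) vapply(nchar(seqs), function(k)
    strrep(intToUtf8(33L + q), k), character(1))
  read_pairs(sprintf("p%03d", seq_len(n)), fwd, rev, qs(fwd), qs(rev))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# clustering as a bare list, attributes dropped, for oracle comparison
plain_list <- function(x) { attributes(x) <- NULL; x }

empty_hits <- function() {
  f <- tempfile(); file.create(f)
  read_hit_table(f)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
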