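# End-to-end matrix construction: homology graph -> MCL clusters ->
# sampling/length filters and end trimming -> per-cluster alignment ->
# gene trees -> support filter -> ortholog decomposition -> supermatrix.
# Stage counts are recorded along the way so the sequence-count funnel
# can be reported afterwards.

#' Run the matrix-construction pipeline
#'
#' Chains the phylogenetic-analysis stages on catalogued sequences and
#' an all-by-all hit table. Gene trees are either supplied per cluster
#' (inferred externally) or, by default, built internally by
#' neighbor-joining on pairwise distances of the cluster alignment —
#' adequate for synthetic/desk-scale runs; real analyses should supply
#' maximum-likelihood trees. Internally built trees carry no bootstrap
#' supports and are therefore only subjected to the support filter when
#' \code{min_mean_support > 0} and supplied trees carry supports.
#'
#' @param seqs a [gene_seqs] data frame of all catalogued sequences
#'   (namespaced ids).
#' @param hits hit data frame from an all-by-all search (or
#'   [simulate_hit_table]).
#' @param evalue_max,min_align_len homology-graph thresholds.
#' @param mcl an [mcl_params].
#' @param min_taxa,min_seq_len,max_seqs cluster filters (applied to the
#'   homolog clusters and again to the ortholog sets).
#' @param aligner function mapping a named character vector of
#'   sequences to an alignment; default [pad_align] (see its caveats),
#'   use [align_mafft] or an external round-trip for real data.
#' @param gene_trees optional named list of \code{phylo} gene trees
#'   keyed by cluster id; clusters without a tree get an internal NJ
#'   tree.
#' @param min_mean_support gene-tree support filter threshold (default
#'   0 = off).
#' @param clean_max_gap_fraction,clean_min_block_len alignment cleaning
#'   knobs ([clean_alignment]).
#' @param store,run_id optional [run_store] handle and run id for stage
#'   recording.
#' @return List with \code{graph}, \code{homolog_clusters},
#'   \code{refined_clusters}, \code{trees}, \code{ortholog_clusters},
#'   \code{alignments}, \code{supermatrix} and \code{stage_counts}
#'   (named integer vector).
#' @export
run_matrix_pipeline <- function(seqs, hits,
                                evalue_max = 1e-20, min_align_len = 50L,
                                mcl = mcl_params(),
                                min_taxa = 4L, min_seq_len = 60L,
                                max_seqs = 100L,
                                aligner = pad_align,
                                gene_trees = NULL,
                                min_mean_support = 0,
                                clean_max_gap_fraction = 0.5,
                                clean_min_block_len = 10L,
                                store = NULL, run_id = NULL) {
  counts <- integer()
  note <- function(stage, n, reason = NA_character_) {
    counts[[stage]] <<- as.integer(n)
    if (!is.null(store))
      record_stage(store, run_id, stage, n, reason)
  }
  note("catalog", nrow(seqs))

  graph <- build_homology_graph(hits, evalue_max, min_align_len,
                                nodes = seqs$seq_id)
  deg <- table(c(graph$edges$from, graph$edges$to))
  note("homologize", sum(seqs$seq_id %in% names(deg)),
       "sequences with no similarity edge dropped")
  homolog_clusters <- mcl_cluster(graph, mcl)
  homolog_clusters <- Filter(function(x) length(x) >= 2L, homolog_clusters)
  names(homolog_clusters) <- paste0("c", seq_along(homolog_clusters))

  filt <- filter_clusters(homolog_clusters, seqs, min_taxa,
                          min_seq_len, max_seqs)
  refined <- list()
  for (cid in names(filt$clusters)) {
    members <- seqs[match(filt$clusters[[cid]], seqs$seq_id), , drop = FALSE]
    members <- trim_ends(members, hits)
    if (nrow(members) >= 2L) refined[[cid]] <- members
  }
  note("multalign", sum(vapply(refined, nrow, integer(1))),
       "clusters failing taxon sampling / size criteria dropped")

  alignments <- lapply(refined, function(m) {
    aln <- aligner(setNames(m$sequence, m$seq_id))
    clean_alignment(aln, clean_max_gap_fraction, clean_min_block_len)
  })
  alignments <- Filter(function(a) nchar(a[1L]) > 0L, alignments)

  trees <- list()
  for (cid in names(alignments)) {
    tr <- gene_trees[[cid]]
    if (is.null(tr)) tr <- nj_gene_tree(alignments[[cid]])
    if (!is.null(tr)) trees[[cid]] <- tr
  }
  if (min_mean_support > 0)
    trees <- filter_trees_by_support(trees, min_mean_support)
  note("genetree", sum(vapply(trees, function(t)
    length(t$tip.label), integer(1))),
    "gene trees below mean-support threshold dropped")

  ortho_sets <- list()
  for (cid in names(trees)) {
    sets <- prune_orthologs(trees[[cid]])
    for (s in sets)
      ortho_sets[[length(ortho_sets) + 1L]] <- s$labels
  }
  names(ortho_sets) <- paste0("o", seq_along(ortho_sets))
  ofilt <- filter_clusters(ortho_sets, seqs, min_taxa,
                           min_seq_len = 0L, max_seqs = max_seqs)
  ortholog_clusters <- ofilt$clusters
  note("treeprune", sum(lengths(ortholog_clusters)),
       "ortholog sets failing taxon sampling dropped")

  gene_alns <- list()
  for (oid in names(ortholog_clusters)) {
    members <- ortholog_clusters[[oid]]
    src <- NULL
    for (cid in names(alignments)) {
      if (all(members %in% names(alignments[[cid]]))) { src <- cid; break }
    }
    if (is.null(src)) next
    gene_alns[[oid]] <- alignments[[src]][members]
  }
  sm <- if (length(gene_alns)) concatenate(gene_alns) else NULL
  note("supermatrix", if (is.null(sm)) 0L else
    sum(vapply(gene_alns, length, integer(1))),
    "sequences placed in the supermatrix")

  list(graph = graph, homolog_clusters = homolog_clusters,
       refined_clusters = refined, trees = trees,
       ortholog_clusters = ortholog_clusters,
       alignments = gene_alns, supermatrix = sm,
       stage_counts = counts)
}

# Neighbor-joining gene tree from a (gap-free or lightly gapped)
# nucleotide alignment; NULL for alignments too small to resolve.
nj_gene_tree <- function(aln) {
  if (length(aln) < 4L) return(NULL)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(aln), "",
                                                fixed = TRUE)))
  d <- ape::dist.dna(bin, model = "JC69", pairwise.deletion = TRUE)
  if (any(!is.finite(d))) d[!is.finite(d)] <- max(d[is.finite(d)], 1) * 2
  ape::nj(d)
}

#' Run the bundled end-to-end fixture analysis
#'
#' Simulates gene families and a hit table at the default scale, runs
#' the full matrix-construction pipeline, and reports the stage-count
#' funnel — the self-contained check that all pipeline stages work
#' together (and the regression harness used by the test suite).
#'
#' @param seed integer seed for the simulation.
#' @param out_dir optional directory: when given, cluster TSVs, the
#'   supermatrix (FASTA, PHYLIP, partitions) and the stage-count CSV
#'   are written there.
#' @param cfg a [sim_config]; default uses \code{seed}.
#' @return The [run_matrix_pipeline] result, plus \code{sim} (the
#'   simulation truth) and \code{report} (stage-count data frame).
#' @export
run_fixture_pipeline <- function(seed = 42L, out_dir = NULL,
                                 cfg = sim_config(seed = seed)) {
  sim <- simulate_gene_families(cfg)
  hits <- simulate_hit_table(sim$seqs)
  store <- NULL; run_id <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    store <- run_store(file.path(out_dir, "runs"))
    run_id <- new_run(store, "mfx test",
                      parameters = list(seed = seed))
  }
  res <- run_matrix_pipeline(sim$seqs, hits, store = store, run_id = run_id)
  report <- data.frame(stage_name = names(res$stage_counts),
                       n_sequences = unname(res$stage_counts))
  if (!is.null(out_dir)) {
    write_clusters(res$ortholog_clusters,
                   file.path(out_dir, "ortholog_clusters.tsv"))
    if (!is.null(res$supermatrix))
      write_supermatrix(res$supermatrix,
                        file.path(out_dir, "supermatrix.fa"),
                        file.path(out_dir, "supermatrix.phy"),
                        file.path(out_dir, "partitions.txt"))
    report <- stage_report(store, run_id,
                           csv_path = file.path(out_dir, "stage_counts.csv"))
    finish_run(store, run_id)
  }
  c(res, list(sim = sim, report = report))
}
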