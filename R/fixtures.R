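# Seeded synthetic-data generator: gene families with known orthology
# evolved along a random species tree, defect-injected paired reads, and
# directly constructed gene trees. Every stage of the pipeline — and the
# pipeline end to end — is testable from these fixtures with no
# downloads and no external search/assembly/inference tools. All
# outputs are pure functions of the configuration seed.

#' Simulation configuration
#'
#' Defaults mirror the scale of a small bundled transcriptome test set:
#' five ingroup taxa with tens of gene families each, and 25,000 100-bp
#' read pairs per library.
#'
#' @param n_taxa number of taxa (>= 2; default 5).
#' @param n_single_copy single-copy gene families (default 50).
#' @param n_duplicated families carrying one planted duplication, i.e.
#'   two paralogous copies in a taxon subset (default 10).
#' @param seq_len_range family sequence length range in nt (default
#'   300-900, rounded to codons).
#' @param substitution_rate per-site substitution probability per branch
#'   (default 0.02; substitutions are i.i.d. uniform over the three
#'   alternative bases, no indels).
#' @param read_len read length in bp (default 100).
#' @param n_read_pairs pairs per simulated library (default 25000).
#' @param insert_mean,insert_sd insert-size distribution in bp (defaults
#'   266 and 40; inserts are truncated at \code{read_len}).
#' @param frac_rrna,frac_adapter,frac_skewed,frac_lowq fractions of read
#'   pairs carrying each injected defect class (defaults 0).
#' @param seed integer seed (default 42).
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_taxa = 5L, n_single_copy = 50L, n_duplicated = 10L,
                       seq_len_range = c(300L, 900L),
                       substitution_rate = 0.02,
                       read_len = 100L, n_read_pairs = 25000L,
                       insert_mean = 266, insert_sd = 40,
                       frac_rrna = 0, frac_adapter = 0,
                       frac_skewed = 0, frac_lowq = 0,
                       seed = 42L) {
  stopifnot(n_taxa >= 2L,
            frac_rrna + frac_adapter + frac_skewed + frac_lowq <= 1,
            insert_mean >= read_len)
  structure(as.list(environment()), class = "sim_config")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Mutate each site with probability `rate`, uniformly to one of the
# three alternative bases.
mutate_seq <- function(seq, rate) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  paste(bases, collapse = "")
}

# Evolve a root sequence down a phylo tree; returns tip sequences (named
# by tip label) and, optionally, the sequence at a given internal node.
evolve_along_tree <- function(tree, root_seq, rate) {
  tree <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root]] <- root_seq
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    seqs[[child]] <- mutate_seq(seqs[[p]], rate)
  }
  list(tips = setNames(unlist(seqs[seq_len(n_tip)]), tree$tip.label),
       nodes = seqs)
}

#' Simulate gene families with known orthology
#'
#' Draws one random species tree, then evolves each family's root
#' sequence along it by i.i.d. substitutions. Single-copy families
#' yield exactly one sequence per taxon. Duplicated families plant one
#' duplication on a random internal branch: taxa below it carry two
#' independently evolving paralog copies (\code{a} and \code{b}).
#' Every sequence gets a lognormal expression value. The truth table
#' maps each sequence to its (family, copy).
#'
#' @param cfg a [sim_config].
#' @return List with \code{seqs} (a [gene_seqs] data frame with
#'   namespaced ids), \code{truth} (data frame \code{seq_id},
#'   \code{taxon_id}, \code{family}, \code{copy}), and \code{tree}
#'   (the species tree, a \code{phylo}).
#' @export
simulate_gene_families <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    taxa <- sprintf("t%d", seq_len(cfg$n_taxa))
    sp_tree <- ape::rtree(cfg$n_taxa, tip.label = taxa)
    fam_ids <- sprintf("g%03d", seq_len(cfg$n_single_copy + cfg$n_duplicated))
    rows <- list(); truth <- list()
    add_seq <- function(taxon, gene, seq, family, copy) {
      id <- namespace_id(taxon, gene)
      rows[[length(rows) + 1L]] <<- data.frame(
        seq_id = id, taxon_id = taxon, gene_id = gene, sequence = seq,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <<- data.frame(
        seq_id = id, taxon_id = taxon, family = family, copy = copy,
        stringsAsFactors = FALSE)
    }
    for (f in seq_along(fam_ids)) {
      fam <- fam_ids[f]
      len <- 3L * (sample(cfg$seq_len_range[1L]:cfg$seq_len_range[2L],
                          1L) %/% 3L)
      root_seq <- random_dna(len)
      ev <- evolve_along_tree(sp_tree, root_seq, cfg$substitution_rate)
      if (f <= cfg$n_single_copy) {
        for (tx in taxa) add_seq(tx, fam, ev$tips[[tx]], fam, "a")
      } else {
        # plant a duplication: an internal node's clade gets a second,
        # independently evolved copy seeded from that node's sequence
        internal <- (cfg$n_taxa + 2L):(cfg$n_taxa + sp_tree$Nnode)
        dup_node <- if (length(internal)) sample(internal, 1L)
        else cfg$n_taxa + 1L
        sub <- ape::extract.clade(sp_tree, dup_node)
        dup_taxa <- sub$tip.label
        ev_b <- evolve_along_tree(sub, ev$nodes[[dup_node]],
                                  cfg$substitution_rate)
        for (tx in taxa) {
          if (tx %in% dup_taxa) {
            add_seq(tx, paste0(fam, "a"), ev$tips[[tx]], fam, "a")
            add_seq(tx, paste0(fam, "b"), ev_b$tips[[tx]], fam, "b")
          } else {
            add_seq(tx, paste0(fam, "a"), ev$tips[[tx]], fam, "a")
          }
        }
      }
    }
    seqs <- do.call(rbind, rows)
    out <- gene_seqs(seq_id = seqs$seq_id, taxon_id = seqs$taxon_id,
                     gene_id = seqs$gene_id, sequence = seqs$sequence,
                     expression = round(stats::rlnorm(nrow(seqs), 3, 1), 2))
    list(seqs = out, truth = do.call(rbind, truth), tree = sp_tree)
  })
}

#' Generate a similarity hit table from true pairwise identity
#'
#' Stands in for an external all-by-all search: a (bidirectional) hit is
#' emitted for every sequence pair whose identity over the length of the
#' shorter sequence reaches \code{min_identity}. Passing hits get a
#' fixed small e-value and a bit score of twice the match count, so the
#' default homology-graph thresholds accept them.
#'
#' @param seqs a [gene_seqs] data frame.
#' @param min_identity identity fraction required to emit a hit
#'   (default 0.7).
#' @return A hit data frame in the 12-column dialect.
#' @export
simulate_hit_table <- function(seqs, min_identity = 0.7) {
  n <- nrow(seqs)
  ints <- lapply(seqs$sequence, utf8ToInt)
  lens <- lengths(ints)
  hits <- vector("list", 1000L); nh <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      L <- min(lens[i], lens[j])
      matches <- sum(ints[[i]][seq_len(L)] == ints[[j]][seq_len(L)])
      if (matches / L >= min_identity) {
        nh <- nh + 1L
        if (nh > length(hits)) hits <- c(hits, vector("list", length(hits)))
        hits[[nh]] <- data.frame(
          query_id = seqs$seq_id[i], subject_id = seqs$seq_id[j],
          percent_identity = round(100 * matches / L, 2),
          align_len = L, mismatches = L - matches, gap_opens = 0L,
          q_start = 1L, q_end = L, s_start = 1L, s_end = L,
          evalue = 1e-30, bitscore = 2 * matches,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (nh == 0L) return(read_hit_table(tempfile_empty()))
  h <- do.call(rbind, hits[seq_len(nh)])
  rev <- h
  rev[, c("query_id", "subject_id")] <- h[, c("subject_id", "query_id")]
  rbind(h, rev)
}

tempfile_empty <- function() { f <- tempfile(); file.create(f); f }

#' Simulate paired reads with injected defects
#'
#' Fragments are drawn from the transcripts with normally distributed
#' insert lengths (truncated at the read length and the transcript
#' length); mates are the fragment ends, the reverse mate
#' reverse-complemented. Defect pairs are injected at the configured
#' fractions, each constructed to be unambiguously detectable by exactly
#' one filter: \code{adapter} pairs carry a full adapter verbatim in the
#' forward mate, \code{composition} pairs replace the forward mate with
#' a homopolymer, \code{quality} pairs get uniformly low quality scores,
#' and \code{rrna} pairs are drawn from the rRNA reference instead of
#' the transcripts. Clean fragments are redrawn if they would trip the
#' composition or adapter filter by chance, so the manifest partition is
#' exact.
#'
#' @param transcripts a [gene_seqs] data frame (fragment source).
#' @param cfg a [sim_config].
#' @param rrna_ref optional [gene_seqs]/named vector of rRNA reference
#'   sequences; defaults to the bundled synthetic rRNA set when
#'   \code{frac_rrna > 0}.
#' @param adapters adapter set used for the injected class and the
#'   clean-read rejection check (default [default_adapters]).
#' @return List with \code{pairs} (a [read_pairs] object) and
#'   \code{manifest} (data frame \code{id}, \code{class}).
#' @export
simulate_reads <- function(transcripts, cfg = sim_config(),
                           rrna_ref = NULL, adapters = default_adapters()) {
  if (cfg$insert_mean < cfg$read_len)
    stop("insert_mean must be at least read_len")
  stopifnot(nrow(transcripts) >= 1L)
  n <- cfg$n_read_pairs
  counts <- c(adapter = round(cfg$frac_adapter * n),
              composition = round(cfg$frac_skewed * n),
              quality = round(cfg$frac_lowq * n),
              rrna = round(cfg$frac_rrna * n))
  if (sum(counts) > n) stop("defect fractions exceed 1")
  if (counts[["rrna"]] > 0L && is.null(rrna_ref))
    rrna_ref <- read_fasta(system.file("extdata", "rrna_synthetic.fa",
                                       package = "mfx", mustWork = TRUE))
  with_seed(cfg$seed, {
    classes <- sample(rep(c(names(counts), "clean"),
                          c(counts, n - sum(counts))))
    src_main <- transcripts$sequence[nchar(transcripts$sequence) >=
                                       cfg$read_len]
    if (length(src_main) == 0L) stop("no transcript as long as a read")
    src_rrna <- if (!is.null(rrna_ref)) {
      s <- if (is.data.frame(rrna_ref)) rrna_ref$sequence else
        as.character(rrna_ref)
      s[nchar(s) >= cfg$read_len]
    }
    qual_clean <- function(k) vapply(seq_len(k), function(i)
      intToUtf8(33L + sample(33:40, cfg$read_len, replace = TRUE)),
      character(1))
    draw_frags <- function(k, pool) {
      vapply(sample.int(length(pool), k, replace = TRUE), function(ti) {
        tlen <- nchar(pool[ti])
        ins <- min(max(round(rnorm(1, cfg$insert_mean, cfg$insert_sd)),
                       cfg$read_len), tlen)
        start <- sample.int(tlen - ins + 1L, 1L)
        substr(pool[ti], start, start + ins - 1L)
      }, character(1))
    }
    frag_reads <- function(frags) {
      list(fwd = substr(frags, 1L, cfg$read_len),
           rev = revcomp(substring(frags, nchar(frags) - cfg$read_len + 1L)))
    }
    fwd <- rev_ <- fq <- rq <- character(n)
    for (cls in unique(classes)) {
      idx <- which(classes == cls)
      k <- length(idx)
      if (k == 0L) next
      pool <- if (cls == "rrna") src_rrna else src_main
      reads <- frag_reads(draw_frags(k, pool))
      # redraw any fragment that would trip the composition or adapter
      # filter by chance, BEFORE defect injection: every class must be
      # detectable by exactly one filter for the manifest to be exact
      for (attempt in 1:20) {
        bad <- base_composition_skewed(reads$fwd) |
          base_composition_skewed(reads$rev) |
          has_adapter(reads$fwd, adapters) |
          has_adapter(reads$rev, adapters)
        if (!any(bad)) break
        redo <- frag_reads(draw_frags(sum(bad), pool))
        reads$fwd[bad] <- redo$fwd
        reads$rev[bad] <- redo$rev
      }
      q_f <- qual_clean(k); q_r <- qual_clean(k)
      if (cls == "adapter") {
        ad <- sample(unname(adapters), k, replace = TRUE)
        reads$fwd <- paste0(substr(reads$fwd, 1L, cfg$read_len - nchar(ad)),
                            ad)
      } else if (cls == "composition") {
        reads$fwd <- strrep("A", cfg$read_len)
      } else if (cls == "quality") {
        q_f <- rep(strrep(intToUtf8(33L + 10L), cfg$read_len), k)  # Q10
        q_r <- rep(strrep(intToUtf8(33L + 10L), cfg$read_len), k)
      }
      fwd[idx] <- reads$fwd; rev_[idx] <- reads$rev
      fq[idx] <- q_f; rq[idx] <- q_r
    }
    ids <- sprintf("p%06d", seq_len(n))
    list(pairs = read_pairs(ids, fwd, rev_, fq, rq),
         manifest = data.frame(id = ids, class = classes,
                               stringsAsFactors = FALSE))
  })
}

#' Construct a synthetic gene tree with a planted duplication
#'
#' Builds a gene tree directly (no inference): copy \code{a} is a random
#' topology over all taxa, copy \code{b} over the duplicated taxon
#' subset; the two copies are sister. Internal nodes get support values
#' drawn from \code{support_range}. Useful for exercising the ortholog
#' decomposition against a known answer.
#'
#' @param taxa character vector of taxon ids.
#' @param dup_taxa subset of \code{taxa} carrying a second copy (may be
#'   empty for a single-copy tree).
#' @param gene gene label used in leaf names (\code{taxon@gene[a|b]}).
#' @param support_range range for random support values (default
#'   60-100).
#' @param seed integer seed.
#' @return A \code{phylo} gene tree.
#' @export
sim_gene_tree <- function(taxa, dup_taxa = character(), gene = "g1",
                          support_range = c(60L, 100L), seed = 1L) {
  with_seed(seed, {
    leaf <- function(tx, copy) namespace_id(tx, paste0(gene, copy))
    subtree_nwk <- function(tx, copy) {
      if (length(tx) == 1L) return(paste0(leaf(tx, copy), ":1"))
      t <- ape::rtree(length(tx), tip.label = leaf(sample(tx), copy))
      sub(";$", "", ape::write.tree(t))
    }
    nwk <- if (length(dup_taxa) >= 1L)
      paste0("(", subtree_nwk(taxa, "a"), ":1,",
             subtree_nwk(dup_taxa, "b"), ":1);")
    else paste0(subtree_nwk(taxa, "a"), ";")
    tree <- ape::read.tree(text = nwk)
    tree$node.label <- as.character(sample(support_range[1L]:support_range[2L],
                                           tree$Nnode, replace = TRUE))
    tree
  })
}
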