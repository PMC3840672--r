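test_that("gene-family simulation is seed-deterministic with consistent truth", {
  cfg <- sim_config(n_taxa = 5L, n_single_copy = 8L, n_duplicated = 2L,
                    seq_len_range = c(120L, 300L), seed = 7L)
  s1 <- simulate_gene_families(cfg)
  s2 <- simulate_gene_families(cfg)
  expect_identical(s1$seqs$sequence, s2$seqs$sequence)   # byte-identical
  expect_identical(s1$truth, s2$truth)
  # every emitted sequence appears in exactly one truth row
  expect_identical(sort(s1$seqs$seq_id), sort(s1$truth$seq_id))
  # single-copy families: exactly one sequence per taxon
  sc <- s1$truth[s1$truth$family %in% sprintf("g%03d", 1:8), ]
  tab <- table(sc$family, sc$taxon_id)
  expect_true(all(tab == 1L))
  # duplicated families have both copies somewhere
  dup <- s1$truth[s1$truth$family %in% sprintf("g%03d", 9:10), ]
  expect_true(all(tapply(dup$copy, dup$family,
                         function(x) all(c("a", "b") %in% x))))
  # ids are namespaced and '@'-unique
  expect_true(all(grepl("^t[0-9]+@", s1$seqs$seq_id)))
})

test_that("zero substitution rate gives identical family members", {
  cfg <- sim_config(n_taxa = 4L, n_single_copy = 3L, n_duplicated = 0L,
                    substitution_rate = 0, seq_len_range = c(90L, 90L),
                    seed = 3L)
  sim <- simulate_gene_families(cfg)
  for (fam in unique(sim$truth$family)) {
    members <- sim$seqs$sequence[sim$truth$family == fam]
    expect_identical(length(unique(members)), 1L)
  }
})

test_that("synthetic hit tables connect families and never cross them", {
  cfg <- sim_config(n_taxa = 4L, n_single_copy = 5L, n_duplicated = 0L,
                    seq_len_range = c(150L, 300L), seed = 11L)
  sim <- simulate_gene_families(cfg)
  hits <- simulate_hit_table(sim$seqs)
  fam <- setNames(sim$truth$family, sim$truth$seq_id)
  expect_true(all(fam[hits$query_id] == fam[hits$subject_id]))
  # within-family: all pairs hit (low divergence), both directions present
  f1 <- sim$truth$seq_id[sim$truth$family == "g001"]
  h1 <- hits[hits$query_id %in% f1 & hits$subject_id %in% f1, ]
  expect_identical(nrow(h1), length(f1) * (length(f1) - 1L))
  # the emitted rows satisfy the 12-column contract after a round-trip
  f <- tempfile()
  write_hit_table(hits, f)
  back <- read_hit_table(f)
  expect_identical(nrow(back), nrow(hits))
  expect_true(all(back$evalue >= 0))
})

test_that("read simulation hits the requested counts and mates are fragment ends", {
  cfg <- sim_config(n_taxa = 2L, n_single_copy = 3L, n_duplicated = 0L,
                    seq_len_range = c(400L, 600L), n_read_pairs = 500L,
                    frac_adapter = 0.1, frac_lowq = 0.05, seed = 19L)
  sim <- simulate_gene_families(cfg)
  rd <- simulate_reads(sim$seqs, cfg)
  expect_length(rd$pairs, 500L)
  expect_identical(sum(rd$manifest$class == "adapter"), 50L)
  expect_identical(sum(rd$manifest$class == "quality"), 25L)
  expect_identical(unique(nchar(rd$pairs$fwd_seq)), 100L)
  expect_identical(unique(nchar(rd$pairs$rev_seq)), 100L)
  # determinism
  rd2 <- simulate_reads(sim$seqs, cfg)
  expect_identical(rd$pairs$fwd_seq, rd2$pairs$fwd_seq)
  # a clean forward mate maps verbatim into some transcript; its reverse
  # mate's reverse complement does too
  clean <- which(rd$manifest$class == "clean")[1:20]
  tx <- paste(sim$seqs$sequence, collapse = "|")
  for (i in clean) {
    expect_true(grepl(rd$pairs$fwd_seq[i], tx, fixed = TRUE))
    rcrev <- mfx:::revcomp(rd$pairs$rev_seq[i])
    expect_true(grepl(rcrev, tx, fixed = TRUE))
  }
  expect_error(simulate_reads(sim$seqs,
                              sim_config(insert_mean = 50, read_len = 100)),
               "insert_mean")
})

test_that("rRNA-class pairs are drawn from the bundled reference and detected by the screen", {
  cfg <- sim_config(n_taxa = 2L, n_single_copy = 4L, n_duplicated = 0L,
                    seq_len_range = c(400L, 600L), n_read_pairs = 400L,
                    frac_rrna = 0.2, seed = 23L)
  sim <- simulate_gene_families(cfg)
  rd <- simulate_reads(sim$seqs, cfg)
  matcher <- kmer_matcher(system.file("extdata", "rrna_synthetic.fa",
                                      package = "mfx"))
  res <- remove_rrna_reads(rd$pairs, matcher)
  expect_setequal(res$removed$id,
                  rd$manifest$id[rd$manifest$class == "rrna"])
  expect_equal(res$rrna_fraction, 0.2, tolerance = 0.01)
})
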