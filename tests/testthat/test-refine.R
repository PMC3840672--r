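mk_seqs <- function(ids, lens, taxa = NULL) {
  if (is.null(taxa)) taxa <- sub("@.*", "", ids)
  gene_seqs(seq_id = ids, taxon_id = taxa,
            sequence = vapply(seq_along(ids), function(i)
              random_seq(lens[i], seed = 7000 + i), character(1)))
}

test_that("cluster filters remove short members first, then apply taxa/size rules", {
  seqs <- mk_seqs(c("t1@a", "t2@b", "t3@c", "t4@d", "t5@e", "t1@f"),
                  c(500, 500, 500, 45, 500, 500))
  cl <- list(c1 = c("t1@a", "t2@b", "t3@c", "t4@d", "t5@e"),  # t4 member short
             c2 = c("t1@a", "t2@b", "t3@c"),                   # 3 taxa
             c3 = c("t1@a", "t2@b", "t3@c", "t5@e", "t1@f"))
  res <- filter_clusters(cl, seqs, min_taxa = 4L, min_seq_len = 60L)
  # c1: short member removed -> 4 taxa remain -> kept without t4@d
  expect_identical(res$clusters$c1, c("t1@a", "t2@b", "t3@c", "t5@e"))
  expect_false("c2" %in% names(res$clusters))
  expect_identical(res$log$reason[res$log$cluster_id == "c2"], "taxa")
  expect_identical(res$clusters$c3, cl$c3)
  res2 <- filter_clusters(cl["c3"], seqs, min_taxa = 2L, max_seqs = 4L)
  expect_identical(res2$log$reason, "size")
})

test_that("end trimming cuts to the hit-span envelope and removes unsupported members", {
  seqs <- mk_seqs(c("t1@a", "t2@b", "t3@c"), c(500, 400, 450))
  hit <- function(q, s, qs, qe) data.frame(
    query_id = q, subject_id = s, percent_identity = 95,
    align_len = qe - qs + 1L, mismatches = 0L, gap_opens = 0L,
    q_start = qs, q_end = qe, s_start = 1L, s_end = qe - qs + 1L,
    evalue = 1e-40, bitscore = 100, stringsAsFactors = FALSE)
  hits <- rbind(hit("t1@a", "t2@b", 51L, 400L),
                hit("t2@b", "t1@a", 20L, 100L),
                hit("t2@b", "t3@c", 80L, 300L))
  # t3@c has no query-side hits at all -> removed (possible chimera)
  orig <- seqs
  out <- trim_ends(seqs, hits)
  expect_identical(out$seq_id, c("t1@a", "t2@b"))
  # a: envelope 51..400 -> 350 nt, the stated substring
  expect_identical(nchar(out$sequence[1]), 350L)
  expect_identical(out$sequence[1], substr(orig$sequence[1], 51, 400))
  # b: spans [20,100] and [80,300] union to [20,300]
  expect_identical(out$sequence[2], substr(orig$sequence[2], 20, 300))
  # never lengthens; trimmed result is a contiguous substring
  expect_true(all(nchar(out$sequence) <= nchar(orig$sequence[1:2])))
  expect_true(grepl(out$sequence[2], orig$sequence[2], fixed = TRUE))
})

test_that("end trimming shifts ORF coordinates into the trimmed frame", {
  seqs <- mk_seqs(c("t1@a", "t2@b"), c(300, 300))
  seqs$orf_frame <- c(1L, 1L)
  seqs$orf_start <- c(90L, 0L)
  seqs$orf_end <- c(240L, 60L)
  hit <- data.frame(query_id = c("t1@a", "t2@b"),
                    subject_id = c("t2@b", "t1@a"),
                    percent_identity = 95, align_len = 101L,
                    mismatches = 0L, gap_opens = 0L,
                    q_start = c(101L, 150L), q_end = c(250L, 250L),
                    s_start = 1L, s_end = 101L,
                    evalue = 1e-40, bitscore = 100)
  out <- trim_ends(seqs, hit)
  # a: trimmed to [101,250]; ORF [90,240) -> clamped to [0,140)
  expect_identical(out$orf_start[1], 0L)
  expect_identical(out$orf_end[1], 140L)
  # b: trimmed to [150,250]; ORF [0,60) falls entirely before -> dropped
  expect_true(is.na(out$orf_frame[2]))
})

test_that("alignment cleaning drops gappy columns and short blocks, keeps row order", {
  aln <- c(s1 = "AAAAAAAAAAAA-A", s2 = "CCCC-CCCCCCC-C",
           s3 = "GGGG-GGGGGGG-G", s4 = "TTTT-TTTTTTT-T",
           s5 = "AAAA-AAAAAAA-A")
  # column 5 has 4/5 gaps, column 13 is 5/5 gaps -> both removed; of the
  # remaining runs (1-4, 6-12, 14) only the 7-column run is long enough
  out <- clean_alignment(aln, max_gap_fraction = 0.5, min_block_len = 5L)
  expect_identical(names(out), names(aln))
  expect_identical(nchar(out[[1]]), 7L)
  expect_identical(attr(out, "kept_columns"), 6:12)
  # gap-free alignment with long blocks is untouched
  clean <- c(a = strrep("ACGT", 5), b = strrep("TGCA", 5))
  expect_identical(unname(clean_alignment(clean)[1]), unname(clean[1]))
  # a column at exactly the gap threshold is kept; above it, removed
  at <- c(a = "A-", b = "AA", c = "AC", d = "A-")   # col2: 2/4 gaps = 0.5
  expect_identical(nchar(clean_alignment(at, min_block_len = 1L)[[1]]), 2L)
  over <- c(a = "A-", b = "AA", c = "A-", d = "A-") # col2: 3/4 > 0.5
  expect_identical(nchar(clean_alignment(over, min_block_len = 1L)[[1]]), 1L)
  expect_warning(gone <- clean_alignment(c(a = "--", b = "--")),
                 "every column")
  expect_identical(unname(gone[1]), "")
})

test_that("translation follows the standard code with gap and stop conventions", {
  expect_identical(unname(translate_alignment(c(x = "ATGGCT"))[1]), "MA")
  expect_identical(unname(translate_alignment(c(x = "---ATG"))[1]), "-M")
  expect_warning(out <- translate_alignment(c(x = "ATGTAAGCT")),
                 "stop codon")
  expect_identical(unname(out[1]), "MXA")
  expect_identical(unname(translate_alignment(c(x = "A--ATG"))[1]), "XM")
  expect_error(translate_alignment(c(x = "ATGG")), "divisible by 3")
  # row-length contract: protein length is nt/3 for every row
  aln <- c(a = "ATGGCTTTA", b = "ATGGCT---")
  expect_identical(unique(nchar(translate_alignment(aln))), 3L)
})

test_that("the built-in pad aligner and mafft both produce rectangular alignments", {
  seqs <- c(s1 = "ACGTACGTAC", s2 = "ACGTACG")
  aln <- pad_align(seqs)
  expect_identical(unique(nchar(aln)), 10L)
  expect_identical(unname(aln["s2"]), "ACGTACG---")
  seqs2 <- c(a = random_seq(60, 1), b = random_seq(60, 2))
  maln <- align_mafft(seqs2)
  expect_identical(sort(names(maln)), c("a", "b"))
  expect_length(unique(nchar(maln)), 1L)
  expect_identical(gsub("-", "", toupper(maln[["a"]])), seqs2[["a"]])
})
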