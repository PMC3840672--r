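test_that("base-composition skew uses strict 5%/60% bounds on non-N bases", {
  expect_false(base_composition_skewed("ACGTACGTACGTACGTACGT"))  # 25% each
  expect_true(base_composition_skewed("AAAAAAAAAA"))             # A = 100%
  # exactly one G in 20 non-N bases: G = 5%, not < 5%; others between
  # 30% and 35% -> not skewed under strict inequality
  s <- paste0("G", strrep("A", 7), strrep("C", 6), strrep("T", 6))
  expect_equal(nchar(s), 20L)
  expect_false(base_composition_skewed(s))
  # one fewer G-equivalent: G at 1/21 < 5% -> skewed
  expect_true(base_composition_skewed(paste0(s, "A")))
  # N excluded from the denominator: NNNN + balanced core stays balanced
  expect_false(base_composition_skewed("NNNNACGTACGTACGTACGTACGT"))
  expect_true(base_composition_skewed("NNNN"))   # all-N is degenerate
})

test_that("pair filtering is either-mate, reasons follow quality > adapter > composition", {
  ad <- default_adapters()[[1]]
  balanced <- strrep("ACGT", 25)
  cfg <- sanitize_config(seed = 7)
  # clean pair
  expect_identical(filter_read_pairs(make_pairs(balanced), cfg), "keep")
  # low mean quality on the forward mate only
  p <- make_pairs(balanced, q = 20L)
  p$rev_qual <- make_pairs(balanced, q = 35L)$rev_qual
  expect_identical(filter_read_pairs(p, cfg), "quality")
  # adapter on the reverse mate only
  p <- make_pairs(balanced)
  p$rev_seq <- paste0(substr(balanced, 1, 100 - nchar(ad)), ad)
  p$rev_qual <- strrep(intToUtf8(33 + 35), nchar(p$rev_seq))
  expect_identical(filter_read_pairs(p, cfg), "adapter")
  # a read that is both low-quality AND adapter-bearing reports quality
  p2 <- p
  p2$fwd_qual <- strrep(intToUtf8(33 + 10), nchar(p2$fwd_seq))
  expect_identical(filter_read_pairs(p2, cfg), "quality")
  # homopolymer mate -> composition
  p <- make_pairs(balanced)
  p$fwd_seq <- strrep("A", 100)
  p$fwd_qual <- strrep(intToUtf8(33 + 35), 100)
  expect_identical(filter_read_pairs(p, cfg), "composition")
})

test_that("sanitize keeps mates together, conserves pairs, and is seed-deterministic", {
  set.seed(11)
  seqs <- vapply(1:50, function(i) random_seq(100), character(1))
  pairs <- make_pairs(seqs, vapply(1:50, function(i) random_seq(100),
                                   character(1)))
  cfg <- sanitize_config(seed = 99)
  r1 <- sanitize_pairs(pairs, cfg)
  r2 <- sanitize_pairs(pairs, cfg)
  expect_identical(r1$kept$id, r2$kept$id)        # determinism
  expect_identical(r1$stats$n_input_pairs,
                   r1$stats$n_kept_pairs + sum(r1$stats$discards))
  # conservation: kept ids are a permutation of the surviving inputs
  reasons <- filter_read_pairs(pairs, cfg)
  expect_setequal(r1$kept$id, pairs$id[reasons == "keep"])
  # pairing: mates at output index i still carry one shared id
  i <- match(r1$kept$id, pairs$id)
  expect_identical(r1$kept$fwd_seq, pairs$fwd_seq[i])
  expect_identical(r1$kept$rev_seq, pairs$rev_seq[i])
  # a different seed permutes differently (overwhelmingly likely at n=50)
  r3 <- sanitize_pairs(pairs, sanitize_config(seed = 100))
  expect_false(identical(r1$kept$id, r3$kept$id))
  # single survivor: identity permutation
  one <- pairs[1]
  expect_identical(sanitize_pairs(one, cfg)$kept$id, one$id)
})

test_that("injected defects are recovered exactly from a synthetic read pool", {
  cfg <- sim_config(n_taxa = 3L, n_single_copy = 6L, n_duplicated = 0L,
                    n_read_pairs = 2000L, frac_adapter = 0.05,
                    frac_skewed = 0.03, frac_lowq = 0.02, seed = 123L)
  sim <- simulate_gene_families(cfg)
  rd <- simulate_reads(sim$seqs, cfg)
  res <- sanitize_pairs(rd$pairs, sanitize_config(seed = 5))
  truth <- table(rd$manifest$class)
  expect_identical(unname(res$stats$discards[["adapter"]]),
                   as.integer(truth[["adapter"]]))
  expect_identical(unname(res$stats$discards[["composition"]]),
                   as.integer(truth[["composition"]]))
  expect_identical(unname(res$stats$discards[["quality"]]),
                   as.integer(truth[["quality"]]))
  expect_identical(res$stats$n_kept_pairs, as.integer(truth[["clean"]]))
  # and the discarded ids are exactly the injected ones, per class
  reasons <- filter_read_pairs(rd$pairs, sanitize_config())
  expect_setequal(rd$pairs$id[reasons == "adapter"],
                  rd$manifest$id[rd$manifest$class == "adapter"])
  expect_setequal(rd$pairs$id[reasons == "quality"],
                  rd$manifest$id[rd$manifest$class == "quality"])
})
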