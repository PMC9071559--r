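test_that("an exact slice of the genome yields a single forward block", {
  g <- organelle_genome(random_seq(80000, seed = 1))
  numt <- substr(g$sequence, 10001, 60000)
  b <- decompose_synteny(numt, g)
  expect_equal(nrow(b), 1L)
  expect_equal(b$numt_start, 0L)
  expect_equal(b$numt_end, 50000L)
  expect_equal(b$org_start, 10000L)
  expect_equal(b$org_end, 60000L)
  expect_equal(b$orientation, "+")
})

test_that("multi-fragment genesis at 0.1% divergence is recovered within k", {
  k <- 31L
  cfg <- sim_config(genome_length = 70000L, large_repeats = integer(0),
                    small_repeats = integer(0), seed = 17,
                    fragment_plan = list(
                      list(start = 2000, end = 18000, strand = "+"),
                      list(start = 25000, end = 40000, strand = "-"),
                      list(start = 45000, end = 60000, strand = "+"),
                      list(start = 65000, end = 72000, strand = "+")),
                    mutation_rate = 0.001)
  g <- simulate_organelle_genome(cfg)
  gen <- simulate_numt_genesis(g, cfg)
  b <- decompose_synteny(gen$numt, g, k = k)
  tb <- gen$truth$source_blocks
  expect_equal(nrow(b), nrow(tb))
  expect_true(all(abs(b$numt_start - tb$numt_start) <= k))
  expect_true(all(abs(b$numt_end - tb$numt_end) <= k))
  expect_true(all(abs(b$org_start - tb$org_start) <= k))
  expect_true(all(abs(b$org_end - tb$org_end) <= k))
  expect_equal(b$orientation, tb$orientation)
  # the wrapping fragment is flagged
  expect_true(b$wrapped[4])
  # blocks tile >= 95% of the numt at this divergence
  expect_gte(sum(b$numt_end - b$numt_start) / nchar(gen$numt), 0.95)
  # block tiling invariant: numt order, non-overlapping
  expect_true(all(diff(b$numt_start) > 0))
  expect_true(all(b$numt_end[-nrow(b)] <= b$numt_start[-1]))
})

test_that("reverse-complementing the numt flips block order and strand", {
  cfg <- sim_config(genome_length = 50000L, large_repeats = integer(0),
                    small_repeats = integer(0), seed = 23,
                    fragment_plan = list(
                      list(start = 1000, end = 15000, strand = "+"),
                      list(start = 20000, end = 35000, strand = "-")),
                    mutation_rate = 0.001)
  g <- simulate_organelle_genome(cfg)
  gen <- simulate_numt_genesis(g, cfg)
  b_fwd <- decompose_synteny(gen$numt, g)
  b_rev <- decompose_synteny(revcomp(gen$numt), g)
  expect_equal(nrow(b_rev), nrow(b_fwd))
  flip <- b_rev[rev(seq_len(nrow(b_rev))), ]
  expect_equal(flip$org_start, b_fwd$org_start)
  expect_equal(flip$org_end, b_fwd$org_end)
  expect_equal(flip$orientation,
               ifelse(b_fwd$orientation == "+", "-", "+"))
})

test_that("no shared anchors gives an empty decomposition with a warning", {
  g <- organelle_genome(random_seq(5000, seed = 2))
  numt <- random_seq(3000, seed = 99)
  expect_warning(b <- decompose_synteny(numt, g), "anchors")
  expect_equal(nrow(b), 0L)
})

test_that("breakpoints classify NHEJ fusions and repeat recombination", {
  # single block: no breakpoints
  g1 <- organelle_genome(random_seq(40000, seed = 3))
  b1 <- decompose_synteny(substr(g1$sequence, 1, 20000), g1)
  expect_equal(nrow(classify_breakpoints(b1, g1)), 0L)

  # NHEJ fusion of two non-adjacent fragments, no repeat at the junction
  cfg <- sim_config(genome_length = 60000L, large_repeats = integer(0),
                    small_repeats = integer(0), seed = 5,
                    fragment_plan = list(
                      list(start = 1000, end = 15000, strand = "+"),
                      list(start = 30000, end = 45000, strand = "+")),
                    mutation_rate = 0.001)
  g <- simulate_organelle_genome(cfg)
  gen <- simulate_numt_genesis(g, cfg)
  b <- decompose_synteny(gen$numt, g)
  bp <- classify_breakpoints(b, g)
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$class, "nhej")
  expect_lte(abs(bp$numt_pos - gen$truth$fusion_points$pos[1]), 31)

  # recombinant conformation through a planted repeat pair
  cfg2 <- sim_config(genome_length = 60000L, large_repeats = c(3000L),
                     small_repeats = integer(0), seed = 5,
                     mutation_rate = 0)
  g2 <- simulate_organelle_genome(cfg2)
  rp <- g2$repeat_pairs[1, ]
  cfg2$fragment_plan <- list(
    list(start = rp$end1 - 6000, end = rp$end1, strand = "+"),
    list(start = rp$end2, end = rp$end2 + 6000, strand = "+"))
  gen2 <- simulate_numt_genesis(g2, cfg2)
  expect_equal(gen2$truth$fusion_points$class, "repeat_conformation")
  b2 <- decompose_synteny(gen2$numt, g2)
  bp2 <- classify_breakpoints(b2, g2)
  expect_equal(nrow(bp2), 1L)
  expect_equal(bp2$class, "repeat_mediated")
  expect_equal(bp2$mediating_repeat, rp$name)

  # overlapping blocks are a structural error
  bb <- b
  bb$numt_start[2] <- bb$numt_end[1] - 100L
  expect_error(classify_breakpoints(bb, g), "overlapping")
})

test_that("repeat conformations: parental, three of four, and all four", {
  cfg <- sim_config(genome_length = 80000L, large_repeats = c(2000L),
                    small_repeats = integer(0), seed = 13,
                    mutation_rate = 0)
  g <- simulate_organelle_genome(cfg)
  rp <- g$repeat_pairs[1, ]
  s1 <- rp$start1; e1 <- rp$end1; s2 <- rp$start2; e2 <- rp$end2

  # an exact copy of the (linearized) genome shows only the parental
  # conformations
  cfg$fragment_plan <- list(list(start = 0, end = 80000, strand = "+"))
  gen <- simulate_numt_genesis(g, cfg)
  cs <- detect_repeat_conformations(decompose_synteny(gen$numt, g),
                                    rp$name, g)
  expect_setequal(cs$present, c("A-B", "A'-B'"))

  # fragments traversing a copy, plus one recombinant junction: 3 of 4
  flank <- 5000
  plan3 <- list(
    list(start = s1 - flank, end = e1 + flank, strand = "+"),  # A-B
    list(start = s2 - flank, end = e2 + flank, strand = "+"),  # A'-B'
    list(start = s1 - flank, end = s1, strand = "+"),          # A ...
    list(start = s2, end = e2 + flank, strand = "+"))          # ... B'
  cfg$fragment_plan <- plan3
  gen3 <- simulate_numt_genesis(g, cfg)
  cs3 <- detect_repeat_conformations(decompose_synteny(gen3$numt, g),
                                     rp$name, g)
  expect_length(cs3$present, 3L)
  expect_setequal(cs3$present, c("A-B", "A'-B'", "A-B'"))

  # all four conformations planted
  cfg$fragment_plan <- c(plan3, list(
    list(start = s2 - flank, end = s2, strand = "+"),          # A' ...
    list(start = s1, end = e1 + flank, strand = "+")))         # ... B
  gen4 <- simulate_numt_genesis(g, cfg)
  cs4 <- detect_repeat_conformations(decompose_synteny(gen4$numt, g),
                                     rp$name, g)
  expect_length(cs4$present, 4L)

  expect_error(detect_repeat_conformations(decompose_synteny(gen$numt, g),
                                           "nosuch", g), "not annotated")
})

test_that("syntenic reference concatenates blocks and round-trips coords", {
  g <- organelle_genome(random_seq(50000, seed = 6))
  blocks <- data.frame(numt_start = c(0L, 12000L), numt_end = c(12000L,
                                                                20000L),
                       org_start = c(30000L, 5000L),
                       org_end = c(42000L, 13000L),
                       orientation = c("+", "-"), anchor_count = c(1L, 1L),
                       identity_estimate = c(1, 1),
                       wrapped = c(FALSE, FALSE))
  ref <- build_syntenic_reference(blocks, g)
  expect_equal(nchar(ref$sequence), 20000L)
  expect_identical(substr(ref$sequence, 1, 12000),
                   substr(g$sequence, 30001, 42000))
  expect_identical(substr(ref$sequence, 12001, 20000),
                   revcomp(substr(g$sequence, 5001, 13000)))
  # offset round trip: the mapped organelle base matches the reference
  # base (complemented on minus-orientation blocks)
  pos <- c(0L, 500L, 11999L, 12000L, 15000L, 19999L)
  org <- syntenic_to_organelle(ref$offsets, pos, g$length)
  rb <- strsplit(ref$sequence, "")[[1]][pos + 1]
  gb <- strsplit(g$sequence, "")[[1]][org + 1]
  minus <- pos >= 12000L
  expect_identical(rb[!minus], gb[!minus])
  expect_identical(rb[minus], chartr("ACGT", "TGCA", gb[minus]))
  # empty block list -> empty sequence
  expect_equal(nchar(build_syntenic_reference(blocks[0, ], g)$sequence), 0L)
})

test_that("maximal exact matches find planted long repeats exactly", {
  # random self-comparison: no non-trivial >= 7 kb match
  a <- random_seq(10000, seed = 40)
  expect_equal(nrow(find_identical_regions(a, a, 7000)), 0L)

  # planted 8-kb duplicate inside one sequence
  core <- random_seq(8000, seed = 41)
  seq1 <- paste0(random_seq(3000, seed = 42), core,
                 random_seq(4000, seed = 43), core,
                 random_seq(2000, seed = 44))
  hits <- find_identical_regions(seq1, seq1, 7000)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$a_start, 3000L)
  expect_equal(hits$a_end, 11000L)
  expect_equal(hits$b_start, 15000L)
  expect_equal(hits$b_end, 23000L)

  # one internal mismatch splits the match into two flanking maximal
  # matches whose lengths sum to 8000 - 1
  core2 <- core
  mid <- substr(core2, 4000, 4000)
  substr(core2, 4000, 4000) <- setdiff(c("A", "C", "G", "T"), mid)[1]
  seq2 <- paste0(random_seq(3000, seed = 42), core2,
                 random_seq(4000, seed = 43), core,
                 random_seq(2000, seed = 44))
  h2 <- find_identical_regions(seq2, seq2, 1000)
  h2 <- h2[h2$orientation == "+", ]
  expect_equal(nrow(h2), 2L)
  expect_true(all(h2$length < 8000))
  expect_equal(sum(h2$length), 7999L)

  # reverse-orientation match between two sequences
  sa <- paste0(random_seq(2000, seed = 45), core, random_seq(1000, seed = 46))
  sb <- paste0(random_seq(1500, seed = 47), revcomp(core),
               random_seq(2500, seed = 48))
  hr <- find_identical_regions(sa, sb, 7000)
  expect_equal(nrow(hr), 1L)
  expect_equal(hr$orientation, "-")
  expect_equal(hr$a_start, 2000L)
  expect_equal(hr$b_start, 1500L)
  expect_equal(hr$length, 8000L)
})
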