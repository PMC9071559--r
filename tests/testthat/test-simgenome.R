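test_that("organelle genome has exact length, planted repeats and target GC", {
  cfg <- sim_config(genome_length = 10000L, large_repeats = integer(0),
                    small_repeats = integer(0), seed = 7)
  g <- simulate_organelle_genome(cfg)
  expect_equal(nchar(g$sequence), 10000L)

  cfg2 <- sim_config(genome_length = 100000L, gc_fraction = 0.45, seed = 3)
  g2 <- simulate_organelle_genome(cfg2)
  # defaults plant the two large pairs (6.0 / 4.2 kb) and small pairs
  expect_setequal(g2$repeat_pairs$length, c(6000L, 4200L, 457L, 206L))
  for (i in seq_len(nrow(g2$repeat_pairs))) {
    rp <- g2$repeat_pairs[i, ]
    expect_identical(substr(g2$sequence, rp$start1 + 1, rp$end1),
                     substr(g2$sequence, rp$start2 + 1, rp$end2))
  }
  # realized GC within 3 binomial standard deviations of the target
  gc <- sum(strsplit(g2$sequence, "")[[1]] %in% c("G", "C")) / 100000
  expect_lt(abs(gc - 0.45), 3 * sqrt(0.45 * 0.55 / 100000))
})

test_that("genome generation is deterministic given the seed", {
  cfg <- sim_config(genome_length = 20000L, seed = 11,
                    large_repeats = c(1000L), small_repeats = c(200L))
  expect_identical(simulate_organelle_genome(cfg),
                   simulate_organelle_genome(cfg))
  cfg2 <- sim_config(genome_length = 20000L, seed = 12,
                     large_repeats = c(1000L), small_repeats = c(200L))
  expect_false(identical(simulate_organelle_genome(cfg)$sequence,
                         simulate_organelle_genome(cfg2)$sequence))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(genome_length = 1000L, large_repeats = c(400L)),
               "genome_length / 4")
  expect_error(sim_config(spectrum_weights = c("GC<>AT" = 0, "AT<>GC" = 0,
                                               "GC<>TA" = 0, "AT<>CG" = 0,
                                               "GC<>CG" = 0, "AT<>TA" = 0)),
               "not all zero")
  expect_error(sim_config(duplication = list(start = 0, end = 10,
                                             time_fraction = 2)))
})

test_that("zero mutation rate reproduces the exact fragment concatenation", {
  cfg <- sim_config(genome_length = 30000L, large_repeats = integer(0),
                    small_repeats = integer(0), seed = 4,
                    fragment_plan = list(
                      list(start = 2000, end = 9000, strand = "+"),
                      list(start = 12000, end = 20000, strand = "-"),
                      list(start = 28000, end = 32000, strand = "+")),
                    mutation_rate = 0)
  g <- simulate_organelle_genome(cfg)
  gen <- simulate_numt_genesis(g, cfg)
  expected <- paste0(
    substr(g$sequence, 2001, 9000),
    revcomp(substr(g$sequence, 12001, 20000)),
    paste0(substr(g$sequence, 28001, 30000), substr(g$sequence, 1, 2000)))
  expect_identical(gen$numt, expected)
  expect_equal(nrow(gen$truth$planted_variants), 0L)
  expect_equal(gen$truth$fusion_points$class, c("nhej", "nhej"))
})

test_that("numt length obeys conservation with duplication and indels", {
  cfg <- sim_config(genome_length = 40000L, large_repeats = integer(0),
                    small_repeats = integer(0), seed = 21,
                    fragment_plan = list(
                      list(start = 1000, end = 16000, strand = "+"),
                      list(start = 20000, end = 35000, strand = "+")),
                    mutation_rate = 5e-4,
                    duplication = list(start = 2000, end = 12000,
                                       time_fraction = 0.5),
                    indel_rate = 2e-4)
  g <- simulate_organelle_genome(cfg)
  gen <- simulate_numt_genesis(g, cfg)
  deltas <- ifelse(gen$truth$indels$type == "del",
                   -gen$truth$indels$length, gen$truth$indels$length)
  expect_equal(nchar(gen$numt), 15000 + 15000 + 10000 + sum(deltas))
  expect_gt(nrow(gen$truth$indels), 0)
})

test_that("pre-duplication variants occur at both homologous positions", {
  cfg <- sim_config(genome_length = 40000L, large_repeats = integer(0),
                    small_repeats = integer(0), seed = 8,
                    fragment_plan = list(list(start = 1000, end = 31000,
                                              strand = "+")),
                    mutation_rate = 2e-3,
                    duplication = list(start = 5000, end = 15000,
                                       time_fraction = 0.5))
  g <- simulate_organelle_genome(cfg)
  gen <- simulate_numt_genesis(g, cfg)
  tv <- gen$truth$planted_variants
  dup <- gen$truth$duplication
  expect_equal(dup$copy1, c(5000, 15000))
  expect_equal(dup$copy2, c(15000, 25000))
  sc <- strsplit(gen$numt, "")[[1]]
  pre_in <- tv[tv$epoch == "pre_duplication" &
               tv$numt_pos >= dup$copy1[1] & tv$numt_pos < dup$copy1[2], ]
  expect_gt(nrow(pre_in), 0)
  partner <- pre_in$numt_pos + 10000
  expect_true(all(sc[pre_in$numt_pos + 1] == pre_in$alt))
  expect_true(all(sc[partner + 1] == pre_in$alt))
  # pre variants inside the duplication are recorded at both positions
  expect_true(all(partner %in% tv$numt_pos[tv$epoch == "pre_duplication"]))
  # post variants are copy-specific: the homologous position is ancestral
  post_in <- tv[tv$epoch == "post_duplication" &
                tv$numt_pos >= dup$copy1[1] & tv$numt_pos < dup$copy1[2], ]
  partner_post <- post_in$numt_pos + 10000
  clean <- !(partner_post %in% tv$numt_pos)
  expect_true(all(sc[partner_post[clean] + 1] == post_in$ref[clean]))
})

test_that("realized spectrum matches configured weights and AT bias", {
  cfg <- sim_config(genome_length = 150000L, large_repeats = integer(0),
                    small_repeats = integer(0), seed = 3,
                    fragment_plan = list(list(start = 0, end = 150000,
                                              strand = "+")),
                    mutation_rate = 0.07)
  g <- simulate_organelle_genome(cfg)
  gen <- simulate_numt_genesis(g, cfg)
  tv <- gen$truth$planted_variants
  expect_gt(nrow(tv), 10000)
  cl <- numtscope:::classify_spectrum_vec(tv$ref, tv$alt)
  tab <- table(factor(cl$category, levels = names(cfg$spectrum_weights)))
  # chi-squared goodness of fit vs configured weights, alpha = 0.001
  p_exp <- cfg$spectrum_weights / sum(cfg$spectrum_weights)
  gof <- suppressWarnings(stats::chisq.test(as.vector(tab), p = p_exp))
  expect_gt(gof$p.value, 0.001)
  # AT-bias ratio within Poisson sampling error of 6.71
  ratio <- tab[["GC<>AT"]] / tab[["AT<>GC"]]
  se <- ratio * sqrt(1 / tab[["GC<>AT"]] + 1 / tab[["AT<>GC"]])
  expect_lt(abs(ratio - 235 / 35), 4 * se)
})

test_that("expected substitution count obeys the Poisson oracle", {
  # per-site Bernoulli(rate) summed over sites: realized count within
  # 4 * sqrt(expected) of the expectation
  sim <- simple_genesis(genome_len = 80000L, frag = c(0L, 80000L),
                        rate = 0.01, seed = 14)
  expected <- 0.01 * 80000
  expect_lt(abs(nrow(sim$truth$planted_variants) - expected),
            4 * sqrt(expected))
})

test_that("gene-conversion tracts homogenize donor and acceptor copies", {
  sim <- three_copy_genesis(seed = 31, time_fraction = 0,
                            conversion_tracts = list(
                              list(donor = 1, acceptor = 2,
                                   start = 2000L, end = 5000L)))
  ev <- sim$truth$conversion_events
  expect_equal(nrow(ev), 1L)
  sc <- strsplit(sim$numt, "")[[1]]
  don <- sc[(sim$truth$duplication$copy1[1] + 2000 + 1):
            (sim$truth$duplication$copy1[1] + 5000)]
  acc <- sc[(ev$start + 1):ev$end]
  expect_identical(don, acc)
})

test_that("simulated reads respect source alleles and methylation states", {
  sim <- simple_genesis(seed = 2, rate = 0.001)
  blocks <- decompose_synteny(sim$numt, sim$genome)
  v <- call_block_variants(sim$numt, sim$genome, blocks)
  sites <- derive_diagnostic_sites(v)
  expect_gt(nrow(sites), 10)

  rc0 <- read_config(n_reads = 60, read_length = 8000, numt_fraction = 1,
                     allele_error = 0, seed = 5)
  rs0 <- simulate_reads(sim$numt, sim$genome, sites, rc0)
  m <- match(rs0$alleles$numt_pos, sites$numt_pos)
  expect_true(all(rs0$alleles$allele == sites$numt_allele[m]))

  # organelle methylation rate 0 -> organelle reads contribute 0 methylation
  rc1 <- read_config(n_reads = 80, read_length = 5000, numt_fraction = 0.5,
                     allele_error = 0, seed = 6)
  rs1 <- simulate_reads(sim$numt, sim$genome, sites, rc1)
  org_ids <- rs1$reads$read_id[rs1$reads$source == "organelle"]
  expect_equal(sum(rs1$meth$methylated[rs1$meth$read_id %in% org_ids]), 0L)

  # per-site allele error within binomial bounds
  rc2 <- read_config(n_reads = 200, read_length = 10000, numt_fraction = 1,
                     allele_error = 0.05, seed = 7)
  rs2 <- simulate_reads(sim$numt, sim$genome, sites, rc2)
  m2 <- match(rs2$alleles$numt_pos, sites$numt_pos)
  flips <- sum(rs2$alleles$allele != sites$numt_allele[m2])
  n_obs <- nrow(rs2$alleles)
  expect_lt(abs(flips - 0.05 * n_obs), 4 * sqrt(n_obs * 0.05 * 0.95) + 1)

  # determinism and the read-length precondition
  expect_identical(simulate_reads(sim$numt, sim$genome, sites, rc2),
                   rs2)
  expect_error(simulate_reads(sim$numt, sim$genome, sites,
                              read_config(read_length = nchar(sim$numt) + 1)),
               "read length")
})
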