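test_that("identical sequences align with zero edits and full score", {
  s <- random_seq(1000, seed = 1)
  al <- align_block(s, s)
  expect_equal(al$score, 1000)
  expect_equal(al$op, "M")
  expect_equal(al$len, 1000L)
  expect_equal(nrow(call_variants(al)), 0L)
})

test_that("banded aligner equals the exhaustive-DP oracle on short pairs", {
  set.seed(101)
  for (i in 1:60) {
    n1 <- sample(5:200, 1)
    n2 <- max(1, n1 + sample(-15:15, 1))
    a <- random_seq(n1)
    b <- random_seq(n2)
    al <- align_block(a, b)
    expect_equal(al$score, nw_oracle_score(a, b),
                 info = sprintf("pair %d (%d x %d)", i, n1, n2))
    # run-length encoding reconstructs the inputs exactly
    s <- alignment_strings(al)
    expect_identical(gsub("-", "", s$numt), a)
    expect_identical(gsub("-", "", s$ref), b)
  }
})

test_that("planted substitutions are recovered at their exact offsets", {
  ref <- random_seq(5000, seed = 33)
  sc <- strsplit(ref, "")[[1]]
  set.seed(34)
  pos <- sort(sample(seq(10, 4990, by = 7), 10))
  for (p in pos) sc[p] <- setdiff(c("A", "C", "G", "T"), sc[p])[1]
  mut <- paste(sc, collapse = "")
  al <- align_block(mut, ref)
  v <- call_variants(al)
  expect_equal(nrow(v), 10L)
  expect_true(all(v$vtype == "snv"))
  expect_false(any(v$excluded))
  expect_equal(v$numt_pos, pos - 1L)
  expect_equal(v$organelle_pos, pos - 1L)
})

test_that("variant exclusion rules: MNVs, indel-adjacent SNVs, N columns", {
  base <- random_seq(600, seed = 55)
  sc <- strsplit(base, "")[[1]]
  flip <- function(x) chartr("ACGT", "GTAC", x)

  # two adjacent mismatches -> one MNV, zero SNVs
  sc2 <- sc; sc2[100:101] <- flip(sc2[100:101])
  v <- call_variants(align_block(paste(sc2, collapse = ""), base))
  expect_equal(v$vtype, "mnv")
  expect_true(v$excluded)
  expect_equal(v$reason, "mnv")
  expect_equal(nchar(v$ref_allele), 2L)

  # SNV within the adjacency window of a deletion -> excluded
  sc3 <- sc[-300]               # 1-bp deletion in the numt
  sc3[302] <- flip(sc3[302])    # 3 columns right of the gap
  sc3[390] <- flip(sc3[390])    # far from the gap
  v3 <- call_variants(align_block(paste(sc3, collapse = ""), base),
                      adjacency_window = 5L)
  snv <- v3[v3$vtype == "snv", ]
  expect_equal(nrow(snv), 2L)
  expect_equal(sort(snv$reason, na.last = TRUE), c("indel_adjacent", NA))
  ind <- v3[v3$vtype == "indel", ]
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$alt_allele, "-")

  # N columns are unalignable: not variants, not eligible
  sc4 <- sc; sc4[200] <- "N"
  v4 <- call_variants(align_block(paste(sc4, collapse = ""), base))
  expect_equal(nrow(v4), 0L)
  expect_equal(attr(v4, "eligible_columns"), 599L)
})

test_that("percent identity follows the exclusion arithmetic", {
  v0 <- structure(data.frame(vtype = character(0), excluded = logical(0)),
                  class = c("variant_records", "data.frame"))
  expect_equal(percent_identity(v0, aligned_length = 1000), 100)
  v5 <- data.frame(vtype = rep("snv", 5), excluded = FALSE)
  expect_equal(percent_identity(v5, aligned_length = 10000), 99.95)
  expect_error(percent_identity(v5, aligned_length = 0), "undefined")
  # adding a non-excluded SNV never increases identity
  v6 <- rbind(v5, data.frame(vtype = "snv", excluded = FALSE))
  expect_lt(percent_identity(v6, 10000), percent_identity(v5, 10000))
})

test_that("the twelve ordered substitutions partition into six categories", {
  bases <- c("A", "C", "G", "T")
  prs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  prs <- prs[prs$ref != prs$alt, ]
  cls <- mapply(function(r, a) classify_spectrum(r, a)$category,
                prs$ref, prs$alt)
  trs <- mapply(function(r, a) classify_spectrum(r, a)$transition,
                prs$ref, prs$alt)
  expect_equal(sum(trs), 4L)
  expect_equal(as.vector(table(cls)), rep(2L, 6))
  expect_true(classify_spectrum("G", "A")$transition)
  expect_equal(classify_spectrum("G", "A")$category, "GC<>AT")
  expect_equal(classify_spectrum("C", "T")$category, "GC<>AT")
  expect_error(classify_spectrum("N", "A"))
})

test_that("spectrum table accounting and the published-count ratio", {
  # empty set
  st0 <- spectrum_table(call_variants(align_block("ACGT", "ACGT")))
  expect_equal(st0$snvs, 0L)
  expect_equal(st0$indels, 0L)

  # a variant set with the published Table-1 category counts
  mk <- function(ref, alt, n) if (n > 0)
    data.frame(numt_pos = seq_len(n), organelle_pos = seq_len(n),
               ref_allele = ref, alt_allele = alt, vtype = "snv",
               excluded = FALSE, reason = NA_character_,
               spectrum_category = classify_spectrum(ref, alt)$category,
               transition = classify_spectrum(ref, alt)$transition)
  v <- rbind(mk("G", "A", 235), mk("A", "G", 35), mk("G", "T", 58),
             mk("A", "C", 30), mk("G", "C", 42), mk("A", "T", 25))
  st <- spectrum_table(v)
  expect_equal(st$snvs, 425L)
  expect_equal(st$transitions, 270L)
  expect_equal(st$transversions, 155L)
  expect_equal(st$transitions + st$transversions, st$snvs)
  expect_equal(sum(st$counts), st$snvs)
  expect_equal(round(st$at_bias_ratio, 1), 6.7)

  # zero AT<>GC transitions -> infinite ratio with flag
  sti <- spectrum_table(mk("G", "A", 3))
  expect_true(is.infinite(sti$at_bias_ratio))
  expect_true(sti$ratio_infinite)
})

test_that("spectrum is invariant under reverse-complementing both sequences", {
  sim <- simple_genesis(genome_len = 40000L, frag = c(2000L, 38000L),
                        rate = 0.003, seed = 61)
  al <- align_block(sim$numt,
                    substr(sim$genome$sequence, 2001, 38000))
  v_f <- call_variants(al)
  al_r <- align_block(revcomp(sim$numt),
                      revcomp(substr(sim$genome$sequence, 2001, 38000)))
  v_r <- call_variants(al_r)
  st_f <- spectrum_table(v_f)
  st_r <- spectrum_table(v_r)
  expect_equal(st_f$counts, st_r$counts)
  expect_equal(st_f$snvs, st_r$snvs)
})

test_that("cytosine context classification and genome-wide fractions", {
  expect_equal(classify_context("ACGT", 1), "CpG")
  expect_equal(classify_context("CAGT", 0), "CHG")
  expect_equal(classify_context("CATT", 0), "CHH")
  # minus strand: G at position 2 of TCGA; upstream is C -> CpG
  expect_equal(classify_context("TCGA", 2, strand = "-"), "CpG")
  expect_warning(ctx <- classify_context("AAAA", 0), "not C")
  expect_true(is.na(ctx))
  expect_equal(classify_context("CANT", 0), "unknown")
  # circular wrap: trailing C with the first base G
  expect_equal(classify_context("GTAC", 3), "CpG")

  expect_equal(unname(context_fractions("CG")), c(1, 0, 0))
  fr <- context_fractions(random_seq(5000, seed = 70))
  expect_equal(sum(fr), 1)
  expect_error(context_fractions("ATTA"), "no cytosines")
})

test_that("chi-squared enrichment matches the z-statistic identity", {
  # exactly at expectation -> zero statistic
  e0 <- context_enrichment(100, 200, 1 / 3)
  expect_equal(e0$chi2, 0)
  # chi2 equals the square of the one-sample proportion z statistic
  for (case in list(c(80, 40, 0.5), c(175, 60, 1 / 3), c(10, 90, 0.2))) {
    en <- context_enrichment(case[1], case[2], case[3])
    n <- case[1] + case[2]
    z <- (case[1] / n - case[3]) / sqrt(case[3] * (1 - case[3]) / n)
    expect_equal(en$chi2, z^2, tolerance = 1e-12)
  }
  en <- context_enrichment(1, 1, 0.01)
  expect_true(en$small_expected)
})

test_that("context multipliers drive detectable CpG/CHG enrichment", {
  runs <- 8
  p_null <- p_alt <- numeric(runs)
  for (r in seq_len(runs)) {
    mk <- function(mult) {
      cfg <- sim_config(genome_length = 30000L,
                        large_repeats = integer(0),
                        small_repeats = integer(0), seed = 200 + r,
                        fragment_plan = list(list(start = 0, end = 30000,
                                                  strand = "+")),
                        mutation_rate = 0.03,
                        context_multipliers = c(CpG = mult, CHG = mult,
                                                CHH = 1))
      g <- simulate_organelle_genome(cfg)
      gen <- simulate_numt_genesis(g, cfg)
      tv <- gen$truth$planted_variants
      ct <- tv[(tv$ref == "C" & tv$alt == "T") |
               (tv$ref == "G" & tv$alt == "A"), ]
      ctx <- numtscope:::contexts_along(g$sequence, circular = TRUE)
      cc <- ifelse(ct$ref == "C", ctx$plus[ct$organelle_pos + 1],
                   ctx$minus[ct$organelle_pos + 1])
      fr <- context_fractions(g)
      context_enrichment(sum(cc %in% c("CpG", "CHG")),
                         sum(cc == "CHH"),
                         unname(fr["CpG"] + fr["CHG"]))$p_value
    }
    p_null[r] <- mk(1)
    p_alt[r] <- mk(6)
  }
  expect_true(all(p_alt < 0.001))
  expect_gte(mean(p_null > 0.05), 0.8)
})
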