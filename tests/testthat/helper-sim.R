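# Shared fixture builders: everything is generated in code under fixed
# seeds; no data files.

random_seq <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# a plain genome + single-fragment genesis at a given divergence
simple_genesis <- function(genome_len = 60000L, frag = c(5000L, 55000L),
                           rate = 0.001, seed = 1L, ...) {
  cfg <- sim_config(genome_length = genome_len, large_repeats = integer(0),
                    small_repeats = integer(0), seed = seed,
                    fragment_plan = list(list(start = frag[1],
                                              end = frag[2],
                                              strand = "+")),
                    mutation_rate = rate, ...)
  g <- simulate_organelle_genome(cfg)
  gen <- simulate_numt_genesis(g, cfg)
  list(config = cfg, genome = g, numt = gen$numt, truth = gen$truth)
}

# genesis with a region present three times: two insertion-time copies and
# one post-insertion (or insertion-time, when time_fraction = 0) tandem
# duplication of the first copy
three_copy_genesis <- function(seed, time_fraction, genome_len = 60000L,
                               copy_len = 10000L, rate = 0.002,
                               conversion_tracts = NULL) {
  cfg <- sim_config(
    genome_length = genome_len, large_repeats = integer(0),
    small_repeats = integer(0), seed = seed,
    fragment_plan = list(
      list(start = 5000L, end = 5000L + copy_len, strand = "+"),
      list(start = 30000L, end = 45000L, strand = "+"),
      list(start = 5000L, end = 5000L + copy_len, strand = "+")),
    mutation_rate = rate,
    duplication = list(start = 0L, end = copy_len,
                       time_fraction = time_fraction),
    conversion_tracts = conversion_tracts)
  g <- simulate_organelle_genome(cfg)
  gen <- simulate_numt_genesis(g, cfg)
  list(config = cfg, genome = g, numt = gen$numt, truth = gen$truth)
}

# align the three copies of a three_copy_genesis result
three_copy_alignment <- function(sim, min_len = 5000L) {
  blocks <- decompose_synteny(sim$numt, sim$genome)
  groups <- extract_repeat_copies(blocks, sim$genome, min_copies = 3L,
                                  min_len = min_len)
  stopifnot(length(groups) >= 1L)
  align_copies(groups[[1L]], sim$numt, sim$genome)
}

# build a copy_alignment directly from equal-length ungapped copy sequences
manual_copy_alignment <- function(copies, organelle, org_start = 0L) {
  W <- nchar(organelle)
  alleles <- do.call(rbind, lapply(copies, function(s)
    strsplit(s, "")[[1]]))
  numt_pos <- matrix(rep(seq_len(W) - 1L, each = length(copies)),
                     nrow = length(copies))
  structure(list(alleles = alleles,
                 organelle = strsplit(organelle, "")[[1]],
                 numt_pos = numt_pos,
                 org_pos = org_start + seq_len(W) - 1L,
                 insertions = data.frame(copy = integer(0),
                                         org_pos = integer(0),
                                         seq = character(0)),
                 copies = data.frame(
                   numt_start = (seq_along(copies) - 1L) * W,
                   numt_end = seq_along(copies) * W,
                   orientation = "+", block = seq_along(copies))),
            class = "copy_alignment")
}

# unbanded global alignment score via Biostrings (the exhaustive-DP oracle)
nw_oracle_score <- function(a, b, match = 1, mismatch = -2,
                            gap_open = 4, gap_extend = 1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(a, b, type = "global",
                                substitutionMatrix = mat,
                                gapOpening = gap_open,
                                gapExtension = gap_extend,
                                scoreOnly = TRUE)
}

write_temp_fasta <- function(seqs, name = "seqs") {
  path <- tempfile(paste0(name, "_"), fileext = ".fasta")
  write_fasta(seqs, path)
  path
}
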