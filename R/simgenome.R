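# Numt-genesis simulator: synthetic organelle genomes, multi-fragment numt
# insertions with known history, and long-read observations with methylation
# states. Every stochastic draw flows from R's global RNG, seeded once per
# top-level operation, so identical configs give byte-identical output.

SPECTRUM_CATEGORIES <- c("GC<>AT", "AT<>GC", "GC<>TA", "AT<>CG", "GC<>CG",
                         "AT<>TA")

#' Simulation configuration for numt genesis
#'
#' Defaults emulate the Arabidopsis chromosome 2 numt system: a ~368-kb
#' circular mitogenome with two large repeat pairs (6.0 and 4.2 kb) and two
#' small pairs (457 and 206 bp), numt divergence of ~0.067% dominated by
#' GC->AT transitions (6.7:1 over AT->GC), elevated C->T rates in CpG and
#' CHG contexts, and a deletion-biased indel process.
#'
#' @param genome_length circular genome length in bases.
#' @param gc_fraction target GC content in `[0,1]`.
#' @param large_repeats,small_repeats integer vectors of repeat lengths; each
#'   entry is planted as a pair of identical copies.
#' @param seed integer seed; all draws derive from it.
#' @param fragment_plan list of `list(start, end, strand)` organelle intervals
#'   (0-based half-open, `end` may exceed the genome length to wrap the
#'   origin) fused in order into the numt.
#' @param mutation_rate expected substitutions per site.
#' @param spectrum_weights named nonnegative vector over the six
#'   strand-collapsed substitution categories; relative rates.
#' @param context_multipliers named vector `c(CpG=, CHG=, CHH=)` multiplying
#'   the C->T (and strand-symmetric G->A) rate by cytosine context.
#' @param duplication optional `list(start, end, time_fraction)`: a tandem
#'   duplication of numt interval `[start,end)` occurring after fraction
#'   `time_fraction` of the divergence time has elapsed.
#' @param conversion_tracts optional list of `list(donor, acceptor, start,
#'   end)` gene-conversion tracts between duplication copies (offsets
#'   relative to the duplicated interval).
#' @param indel_rate expected indels per site; `deletion_bias` is the
#'   fraction of indels that shorten the numt.
#' @param deletion_bias fraction of indels drawn as deletions.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 368000L,
                       gc_fraction = 0.45,
                       large_repeats = c(6000L, 4200L),
                       small_repeats = c(457L, 206L),
                       seed = 1L,
                       fragment_plan = NULL,
                       mutation_rate = 6.7e-4,
                       spectrum_weights = c("GC<>AT" = 235, "AT<>GC" = 35,
                                            "GC<>TA" = 58, "AT<>CG" = 30,
                                            "GC<>CG" = 42, "AT<>TA" = 25),
                       context_multipliers = c(CpG = 6, CHG = 6, CHH = 1),
                       duplication = NULL,
                       conversion_tracts = NULL,
                       indel_rate = 0,
                       deletion_bias = 30 / 44) {
  stopifnot(genome_length > 0, gc_fraction >= 0, gc_fraction <= 1,
            mutation_rate >= 0, indel_rate >= 0,
            deletion_bias >= 0, deletion_bias <= 1)
  if (any(c(large_repeats, small_repeats) <= 0))
    stop("repeat lengths must be positive")
  if (any(c(large_repeats, small_repeats) >= genome_length / 4))
    stop("repeat lengths must be < genome_length / 4")
  if (!all(SPECTRUM_CATEGORIES %in% names(spectrum_weights)))
    stop("spectrum_weights must name all six categories")
  if (any(spectrum_weights < 0) || all(spectrum_weights == 0))
    stop("spectrum_weights must be nonnegative and not all zero")
  if (!all(c("CpG", "CHG", "CHH") %in% names(context_multipliers)))
    stop("context_multipliers must name CpG, CHG and CHH")
  if (!is.null(duplication)) {
    stopifnot(is.list(duplication),
              duplication$time_fraction >= 0, duplication$time_fraction <= 1,
              duplication$end > duplication$start, duplication$start >= 0)
  }
  structure(list(genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction,
                 large_repeats = as.integer(large_repeats),
                 small_repeats = as.integer(small_repeats),
                 seed = as.integer(seed),
                 fragment_plan = fragment_plan,
                 mutation_rate = mutation_rate,
                 spectrum_weights = spectrum_weights[SPECTRUM_CATEGORIES],
                 context_multipliers = context_multipliers,
                 duplication = duplication,
                 conversion_tracts = conversion_tracts,
                 indel_rate = indel_rate,
                 deletion_bias = deletion_bias),
            class = "sim_config")
}

#' Simulate a circular organelle genome with planted repeat pairs
#'
#' Background sequence is i.i.d. with the configured GC fraction; each
#' requested repeat is planted as two identical copies at non-overlapping
#' random positions (no wrap across the origin, so annotated intervals stay
#' simple).
#'
#' @param config a [sim_config()].
#' @return an `organelle_genome`: list with `sequence` (character scalar),
#'   `length`, and `repeat_pairs` (data.frame with columns `name, start1,
#'   end1, start2, end2, length`; 0-based half-open).
#' @export
simulate_organelle_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  seq <- random_dna(L, config$gc_fraction)

  lens <- c(config$large_repeats, config$small_repeats)
  names <- character(0)
  if (length(config$large_repeats))
    names <- paste0("R", seq_along(config$large_repeats))
  if (length(config$small_repeats))
    names <- c(names, c("C", "Q", paste0("S", seq_len(max(0,
                 length(config$small_repeats) - 2))))[
                 seq_along(config$small_repeats)])
  placed <- data.frame(name = character(0), start1 = integer(0),
                       end1 = integer(0), start2 = integer(0),
                       end2 = integer(0), length = integer(0),
                       stringsAsFactors = FALSE)
  occupied <- matrix(numeric(0), ncol = 2)  # rows of (start, end)
  place_one <- function(len, nm) {
    for (try in 1:2000) {
      s <- sample.int(L - len, 1L) - 1L
      e <- s + len
      ok <- !any(apply(occupied, 1L, function(iv)
        iv_overlap(s, e, iv[1], iv[2])))
      if (ok) return(c(s, e))
    }
    stop("cannot place repeat pair '", nm, "' without overlap")
  }
  if (length(lens)) {
    sc <- seq_chars(seq)
    for (i in seq_along(lens)) {
      len <- lens[i]
      p1 <- place_one(len, names[i])
      occupied <- rbind(occupied, p1)
      p2 <- place_one(len, names[i])
      occupied <- rbind(occupied, p2)
      # copy the sequence of copy 1 into copy 2
      sc[(p2[1] + 1L):p2[2]] <- sc[(p1[1] + 1L):p1[2]]
      placed <- rbind(placed, data.frame(
        name = names[i], start1 = p1[1], end1 = p1[2],
        start2 = p2[1], end2 = p2[2], length = len,
        stringsAsFactors = FALSE))
    }
    seq <- paste(sc, collapse = "")
  }
  structure(list(sequence = seq, length = L, repeat_pairs = placed),
            class = "organelle_genome")
}

#' @export
print.organelle_genome <- function(x, ...) {
  cat("organelle_genome: ", x$length, " bp circular, ",
      nrow(x$repeat_pairs), " repeat pair(s)\n", sep = "")
  if (nrow(x$repeat_pairs)) print(x$repeat_pairs)
  invisible(x)
}

# cytosine context (CpG/CHG/CHH) for every position of a sequence, both
# strands; positions that are not C (plus strand) / G (minus strand) get NA.
# circular = TRUE wraps the two downstream bases around the origin.
contexts_along <- function(seq, circular = FALSE) {
  sc <- seq_chars(seq)
  n <- length(sc)
  idx <- function(i) if (circular) ((i - 1L) %% n) + 1L else i
  nxt1 <- c(sc[-1L], if (circular) sc[1L] else NA)
  nxt2 <- c(sc[-(1:2)], if (circular) sc[1:2] else c(NA, NA))
  prv1 <- c(if (circular) sc[n] else NA, sc[-n])
  prv2 <- c(if (circular) sc[(n - 1L):n] else c(NA, NA), sc[seq_len(n - 2L)])
  plus <- ifelse(sc == "C",
                 ifelse(nxt1 == "G", "CpG",
                        ifelse(nxt2 == "G", "CHG", "CHH")), NA)
  # minus strand: G here is a C on the reverse strand; its downstream bases
  # are the forward-strand upstream bases, complemented
  minus <- ifelse(sc == "G",
                  ifelse(prv1 == "C", "CpG",
                         ifelse(prv2 == "C", "CHG", "CHH")), NA)
  list(plus = plus, minus = minus)
}

# per-site substitution machinery ------------------------------------------

# For each site, the three candidate substitutions get relative weights
# spectrum_weights[category]/2; the C->T candidate (ref C, plus strand) and
# the strand-symmetric G->A candidate (ref G) are additionally multiplied by
# the context multiplier at that site.
ALT_TABLE <- list(
  A = c("G", "C", "T"), C = c("T", "A", "G"),
  G = c("A", "T", "C"), T = c("C", "G", "A"))
CAT_TABLE <- list(  # categories for the ALT_TABLE order
  A = c("AT<>GC", "AT<>CG", "AT<>TA"),
  C = c("GC<>AT", "GC<>TA", "GC<>CG"),
  G = c("GC<>AT", "GC<>TA", "GC<>CG"),
  T = c("AT<>GC", "AT<>CG", "AT<>TA"))

site_weights <- function(seq, config) {
  sc <- seq_chars(seq)
  n <- length(sc)
  ctx <- contexts_along(seq, circular = FALSE)
  w <- config$spectrum_weights / 2
  m <- config$context_multipliers
  W <- matrix(0, nrow = n, ncol = 3)
  # weights are target event proportions genome-wide: compensate for base
  # composition (GC<>* categories only occur at G/C sites and vice versa)
  n_gc <- sum(sc %in% c("G", "C")); n_at <- sum(sc %in% c("A", "T"))
  comp <- c(A = n_at, C = n_gc, G = n_gc, T = n_at) / max(1L, n_gc + n_at)
  for (b in DNA_BASES) {
    sel <- sc == b
    if (!any(sel)) next
    W[sel, ] <- matrix(rep(w[CAT_TABLE[[b]]] / max(comp[b], 1e-9), sum(sel)),
                       ncol = 3, byrow = TRUE)
  }
  # context multiplier on the deamination-like candidate (column 1 for C/G),
  # normalized to mean 1 over C/G sites so multipliers redistribute C->T
  # events across contexts without changing the configured category totals
  selC <- sc == "C"
  selG <- sc == "G"
  ccC <- ctx$plus[selC]; ccC[is.na(ccC)] <- "CHH"
  ccG <- ctx$minus[selG]; ccG[is.na(ccG)] <- "CHH"
  mu <- c(m[ccC], m[ccG])
  if (length(mu) && mean(mu) > 0) {
    mu <- mu / mean(mu)
    if (any(selC)) W[selC, 1] <- W[selC, 1] * mu[seq_len(sum(selC))]
    if (any(selG)) W[selG, 1] <- W[selG, 1] * mu[sum(selC) + seq_len(sum(selG))]
  }
  W[sc == "N", ] <- 0
  W
}

# draw substitutions on seq at overall expected per-site rate `rate`;
# returns data.frame(pos0, ref, alt) (0-based positions)
draw_substitutions <- function(seq, config, rate, exclude_pos0 = integer(0)) {
  if (rate <= 0) {
    return(data.frame(pos0 = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  }
  W <- site_weights(seq, config)
  tot <- rowSums(W)
  mean_tot <- mean(tot[tot > 0])
  p_site <- pmin(1, rate * tot / mean_tot)
  if (length(exclude_pos0)) p_site[exclude_pos0 + 1L] <- 0
  hit <- which(runif(length(p_site)) < p_site)
  if (!length(hit)) {
    return(data.frame(pos0 = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  }
  sc <- seq_chars(seq)
  alts <- vapply(hit, function(i) {
    wi <- W[i, ]
    sample(ALT_TABLE[[sc[i]]], 1L, prob = wi)
  }, character(1))
  data.frame(pos0 = hit - 1L, ref = sc[hit], alt = alts,
             stringsAsFactors = FALSE)
}

apply_substitutions <- function(seq, subs) {
  if (!nrow(subs)) return(seq)
  sc <- seq_chars(seq)
  sc[subs$pos0 + 1L] <- subs$alt
  paste(sc, collapse = "")
}

#' Simulate numt genesis from an organelle genome
#'
#' Fuses the configured organelle fragments into a proto-numt, optionally
#' interleaves a tandem duplication with the accumulation of substitutions
#' (variants arising before the duplication are copied into both daughter
#' copies; later variants are copy-specific), applies optional
#' gene-conversion tracts between the duplication copies, and finally a
#' deletion-biased indel process. Ground truth for every event is returned.
#'
#' @param genome an `organelle_genome`.
#' @param config a [sim_config()] with a non-NULL `fragment_plan`.
#' @return list with `numt` (character scalar) and `truth` (class
#'   `numt_truth`): `source_blocks`, `fusion_points`, `planted_variants`
#'   (with `epoch`), `duplication`, `conversion_events`, `indels`.
#' @export
simulate_numt_genesis <- function(genome, config) {
  stopifnot(inherits(genome, "organelle_genome"),
            inherits(config, "sim_config"))
  plan <- config$fragment_plan
  if (is.null(plan) || !length(plan))
    stop("config$fragment_plan is required for numt genesis")
  set.seed(config$seed + 1L)
  L <- genome$length

  # 1. fuse fragments
  frags <- lapply(plan, function(f) {
    stopifnot(f$end > f$start, f$end - f$start <= L)
    s <- circ_subseq(genome$sequence, f$start, f$end)
    if ((f$strand %||% "+") == "-") s <- revcomp(s)
    s
  })
  flens <- vapply(frags, nchar, integer(1))
  numt0 <- paste(unlist(frags), collapse = "")
  ends <- cumsum(flens)
  starts <- c(0L, ends[-length(ends)])
  source_blocks <- data.frame(
    numt_start = starts, numt_end = ends,
    org_start = vapply(plan, function(f) as.integer(f$start), integer(1)),
    org_end = vapply(plan, function(f) as.integer(f$end), integer(1)),
    orientation = vapply(plan, function(f) f$strand %||% "+", character(1)),
    stringsAsFactors = FALSE)

  # 2. fusion points between consecutive fragments, classified against the
  # annotated repeat pairs: a junction that splices one repeat copy's flank
  # onto the other copy's flank is a repeat conformation, otherwise NHEJ
  fusion_points <- data.frame(pos = integer(0), class = character(0),
                              repeat_name = character(0),
                              stringsAsFactors = FALSE)
  if (length(plan) > 1L) {
    for (i in seq_len(length(plan) - 1L)) {
      fl <- plan[[i]]; fr <- plan[[i + 1L]]
      cls <- "nhej"; rname <- NA_character_
      sl <- fl$strand %||% "+"; sr <- fr$strand %||% "+"
      # a seamless continuation is not a structural fusion at all
      if (sl == "+" && sr == "+" && fr$start %% L == fl$end %% L)
        cls <- "collinear"
      if (sl == "-" && sr == "-" && fl$start %% L == fr$end %% L)
        cls <- "collinear"
      if (cls != "collinear" &&
          (fl$strand %||% "+") == "+" && (fr$strand %||% "+") == "+") {
        gl <- fl$end %% L     # genome position just past the left fragment
        gr <- fr$start %% L   # genome position where the right one resumes
        rp <- genome$repeat_pairs
        for (j in seq_len(nrow(rp))) {
          edges1 <- c(rp$start1[j], rp$end1[j])
          edges2 <- c(rp$start2[j], rp$end2[j])
          # copy1-edge -> copy2-edge (either repeat end), both directions
          hit <- (gl == rp$end1[j] && gr == rp$end2[j]) ||
                 (gl == rp$end2[j] && gr == rp$end1[j]) ||
                 (gl == rp$start1[j] && gr == rp$start2[j]) ||
                 (gl == rp$start2[j] && gr == rp$start1[j])
          if (hit) { cls <- "repeat_conformation"; rname <- rp$name[j]; break }
        }
      }
      fusion_points <- rbind(fusion_points, data.frame(
        pos = ends[i], class = cls, repeat_name = rname,
        stringsAsFactors = FALSE))
    }
  }

  # map a position on the fused proto-numt back to an organelle coordinate
  map_to_org <- function(pos0) {
    i <- findInterval(pos0, starts)
    off <- pos0 - starts[i]
    f <- plan[[i]]
    if ((f$strand %||% "+") == "+") (f$start + off) %% L
    else (f$end - 1L - off) %% L
  }

  dup <- config$duplication
  t_frac <- if (is.null(dup)) 0 else dup$time_fraction

  # 3. pre-duplication substitutions on the proto-numt
  pre <- draw_substitutions(numt0, config, config$mutation_rate * t_frac)
  seq1 <- apply_substitutions(numt0, pre)

  variants <- data.frame(numt_pos = integer(0), organelle_pos = integer(0),
                         ref = character(0), alt = character(0),
                         epoch = character(0), stringsAsFactors = FALSE)
  dup_truth <- NULL
  if (!is.null(dup)) {
    a <- as.integer(dup$start); b <- as.integer(dup$end)
    if (b > nchar(seq1))
      stop("duplication interval lies outside the fused numt")
    dlen <- b - a
    seq2 <- paste0(subseq0(seq1, 0L, b), subseq0(seq1, a, b),
                   subseq0(seq1, b, nchar(seq1)))
    # pre-dup coordinate -> final coordinate(s)
    shift <- function(p) ifelse(p < b, p, p + dlen)
    if (nrow(pre)) {
      first <- data.frame(numt_pos = shift(pre$pos0),
                          organelle_pos = vapply(pre$pos0, map_to_org,
                                                 numeric(1)),
                          ref = pre$ref, alt = pre$alt,
                          epoch = "pre_duplication",
                          stringsAsFactors = FALSE)
      in_dup <- pre$pos0 >= a & pre$pos0 < b
      second <- first[in_dup, , drop = FALSE]
      if (nrow(second)) second$numt_pos <- pre$pos0[in_dup] + dlen
      variants <- rbind(first, second)
    }
    dup_truth <- list(src = c(a, b),
                      copy1 = c(a, b), copy2 = c(b, b + dlen),
                      breakpoint = b)
    # organelle mapping for the second copy
    map_final_to_org <- function(p) {
      p0 <- ifelse(p < b, p, ifelse(p < b + dlen, p - dlen + 0L, p - dlen))
      # p in [b, b+dlen) is the new copy of [a, b): p - (b - a)
      p0 <- ifelse(p >= b & p < b + dlen, p - (b - a), p0)
      vapply(p0, map_to_org, numeric(1))
    }
    post <- draw_substitutions(seq2, config,
                               config$mutation_rate * (1 - t_frac),
                               exclude_pos0 = variants$numt_pos)
    if (nrow(post)) {
      variants <- rbind(variants, data.frame(
        numt_pos = post$pos0,
        organelle_pos = map_final_to_org(post$pos0),
        ref = post$ref, alt = post$alt, epoch = "post_duplication",
        stringsAsFactors = FALSE))
    }
    numt <- apply_substitutions(seq2, post)
  } else {
    post <- draw_substitutions(seq1, config,
                               config$mutation_rate * (1 - t_frac),
                               exclude_pos0 = pre$pos0)
    allsub <- rbind(
      if (nrow(pre)) data.frame(pos0 = pre$pos0, ref = pre$ref,
                                alt = pre$alt, epoch = "pre_duplication",
                                stringsAsFactors = FALSE),
      if (nrow(post)) data.frame(pos0 = post$pos0, ref = post$ref,
                                 alt = post$alt, epoch = "post_duplication",
                                 stringsAsFactors = FALSE))
    if (!is.null(allsub) && nrow(allsub)) {
      variants <- data.frame(numt_pos = allsub$pos0,
                             organelle_pos = vapply(allsub$pos0, map_to_org,
                                                    numeric(1)),
                             ref = allsub$ref, alt = allsub$alt,
                             epoch = allsub$epoch, stringsAsFactors = FALSE)
    }
    numt <- apply_substitutions(seq1, post)
  }

  # 4. gene-conversion tracts between the duplication copies
  conversion_events <- NULL
  if (!is.null(config$conversion_tracts)) {
    if (is.null(dup_truth))
      stop("conversion_tracts require a configured duplication")
    conversion_events <- data.frame(donor = integer(0), acceptor = integer(0),
                                    start = integer(0), end = integer(0),
                                    stringsAsFactors = FALSE)
    sc <- seq_chars(numt)
    for (tr in config$conversion_tracts) {
      cpy <- list(dup_truth$copy1, dup_truth$copy2)
      dsrc <- cpy[[tr$donor]]; dacc <- cpy[[tr$acceptor]]
      ds <- dsrc[1] + tr$start; de <- dsrc[1] + tr$end
      as_ <- dacc[1] + tr$start; ae <- dacc[1] + tr$end
      sc[(as_ + 1L):ae] <- sc[(ds + 1L):de]
      # variants in the acceptor tract now carry the donor allele: rewrite
      in_acc <- variants$numt_pos >= as_ & variants$numt_pos < ae
      if (any(in_acc)) {
        variants$alt[in_acc] <- sc[variants$numt_pos[in_acc] + 1L]
        variants <- variants[!(in_acc & variants$alt == variants$ref), ,
                             drop = FALSE]
      }
      # donor variants in the tract are now shared with the acceptor
      in_don <- variants$numt_pos >= ds & variants$numt_pos < de
      if (any(in_don)) {
        copied <- variants[in_don, , drop = FALSE]
        copied$numt_pos <- copied$numt_pos - dsrc[1] + dacc[1]
        copied <- copied[!copied$numt_pos %in% variants$numt_pos, ,
                         drop = FALSE]
        variants <- rbind(variants, copied)
      }
      conversion_events <- rbind(conversion_events, data.frame(
        donor = tr$donor, acceptor = tr$acceptor, start = as_, end = ae,
        stringsAsFactors = FALSE))
    }
    numt <- paste(sc, collapse = "")
  }

  # 5. deletion-biased indels (length geometric, capped at 20 bp)
  indels <- data.frame(pos = integer(0), type = character(0),
                       length = integer(0), stringsAsFactors = FALSE)
  if (config$indel_rate > 0) {
    n <- nchar(numt)
    sites <- which(runif(n) < config$indel_rate)
    if (length(sites)) {
      types <- ifelse(runif(length(sites)) < config$deletion_bias,
                      "del", "ins")
      lens <- pmin(1L + rgeom(length(sites), 0.5), 20L)
      ord <- order(sites, decreasing = TRUE)  # right to left: stable coords
      for (ii in ord) {
        p <- sites[ii]; ln <- lens[ii]
        if (types[ii] == "del") {
          if (p + ln - 1L > nchar(numt)) next
          numt <- paste0(substr(numt, 1L, p - 1L),
                         substr(numt, p + ln, nchar(numt)))
          drop <- variants$numt_pos >= (p - 1L) &
                  variants$numt_pos < (p - 1L + ln)
          variants <- variants[!drop, , drop = FALSE]
          variants$numt_pos <- ifelse(variants$numt_pos >= (p - 1L + ln),
                                      variants$numt_pos - ln,
                                      variants$numt_pos)
          indels <- rbind(indels, data.frame(pos = p - 1L, type = "del",
                                             length = ln,
                                             stringsAsFactors = FALSE))
        } else {
          ins <- random_dna(ln, config$gc_fraction)
          numt <- paste0(substr(numt, 1L, p - 1L), ins,
                         substr(numt, p, nchar(numt)))
          variants$numt_pos <- ifelse(variants$numt_pos >= (p - 1L),
                                      variants$numt_pos + ln,
                                      variants$numt_pos)
          indels <- rbind(indels, data.frame(pos = p - 1L, type = "ins",
                                             length = ln,
                                             stringsAsFactors = FALSE))
        }
      }
    }
  }

  variants <- variants[order(variants$numt_pos), , drop = FALSE]
  rownames(variants) <- NULL
  truth <- structure(list(source_blocks = source_blocks,
                          fusion_points = fusion_points,
                          planted_variants = variants,
                          duplication = dup_truth,
                          conversion_events = conversion_events,
                          indels = indels),
                     class = "numt_truth")
  list(numt = numt, truth = truth)
}

#' Read-set configuration for the read simulator
#'
#' @param n_reads number of reads.
#' @param read_length read length in bases.
#' @param numt_fraction fraction of reads drawn from the numt locus (the
#'   remainder are organelle-derived reads aligning to the homologous numt
#'   region).
#' @param allele_error per-site probability that a read reports the other
#'   source's allele at a diagnostic site.
#' @param meth_numt,meth_organelle named per-context methylation call
#'   probabilities `c(CpG=, CHG=, CHH=)` for numt- and organelle-derived
#'   reads.
#' @param emit_sequence also carry each read's base sequence (needed for
#'   consensus validation).
#' @param seed integer seed.
#' @return a `read_config` list.
#' @export
read_config <- function(n_reads = 200L, read_length = 2000L,
                        numt_fraction = 0.5, allele_error = 0.001,
                        meth_numt = c(CpG = 0.9, CHG = 0.7, CHH = 0.05),
                        meth_organelle = c(CpG = 0, CHG = 0, CHH = 0),
                        emit_sequence = FALSE, seed = 1L) {
  structure(list(n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 numt_fraction = numt_fraction,
                 allele_error = allele_error,
                 meth_numt = meth_numt, meth_organelle = meth_organelle,
                 emit_sequence = isTRUE(emit_sequence),
                 seed = as.integer(seed)),
            class = "read_config")
}

#' Simulate long reads with diagnostic alleles and methylation calls
#'
#' Reads are placed uniformly on the numt; organelle-derived reads align to
#' the homologous numt interval but carry the organelle allele at each
#' covered diagnostic site and are (near-)unmethylated. Numt-derived reads
#' carry numt alleles and per-context methylation rates typical of
#' heterochromatin. Allele observations are flipped to the other source's
#' allele with probability `allele_error`.
#'
#' @param numt numt sequence (character scalar).
#' @param genome an `organelle_genome` (kept for interface symmetry; alleles
#'   come from the diagnostic site table).
#' @param diagnostic_sites data.frame with columns `numt_pos, organelle_pos,
#'   numt_allele, organelle_allele` (see [derive_diagnostic_sites()]).
#' @param config a [read_config()].
#' @return a `simulated_read_set`: list of data.frames `reads` (read_id,
#'   source, start, end, and `seq` if requested), `alleles` (read_id,
#'   numt_pos, allele), `meth` (read_id, pos, context, methylated).
#' @export
simulate_reads <- function(numt, genome, diagnostic_sites, config) {
  stopifnot(inherits(config, "read_config"))
  set.seed(config$seed + 2L)
  L <- nchar(numt)
  if (config$read_length > L)
    stop("read length exceeds source sequence length")
  n <- config$n_reads
  src <- ifelse(runif(n) < config$numt_fraction, "numt", "organelle")
  start <- sample.int(L - config$read_length + 1L, n, replace = TRUE) - 1L
  end <- start + config$read_length
  ids <- sprintf("read%05d", seq_len(n))
  reads <- data.frame(read_id = ids, source = src, start = start, end = end,
                      stringsAsFactors = FALSE)

  # allele observations at covered diagnostic sites
  al <- NULL
  if (!is.null(diagnostic_sites) && nrow(diagnostic_sites)) {
    ds <- diagnostic_sites
    al <- do.call(rbind, lapply(seq_len(n), function(i) {
      cov <- which(ds$numt_pos >= start[i] & ds$numt_pos < end[i])
      if (!length(cov)) return(NULL)
      own <- if (src[i] == "numt") ds$numt_allele[cov] else
        ds$organelle_allele[cov]
      other <- if (src[i] == "numt") ds$organelle_allele[cov] else
        ds$numt_allele[cov]
      flip <- runif(length(cov)) < config$allele_error
      data.frame(read_id = ids[i], numt_pos = ds$numt_pos[cov],
                 allele = ifelse(flip, other, own),
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(al))
    al <- data.frame(read_id = character(0), numt_pos = integer(0),
                     allele = character(0), stringsAsFactors = FALSE)

  # methylation calls at cytosines (both strands) of the covered interval
  ctx <- contexts_along(numt)
  cpos_plus <- which(!is.na(ctx$plus)) - 1L
  cpos_minus <- which(!is.na(ctx$minus)) - 1L
  allpos <- c(cpos_plus, cpos_minus)
  allctx <- c(ctx$plus[cpos_plus + 1L], ctx$minus[cpos_minus + 1L])
  o <- order(allpos)
  allpos <- allpos[o]; allctx <- allctx[o]
  meth <- do.call(rbind, lapply(seq_len(n), function(i) {
    sel <- allpos >= start[i] & allpos < end[i]
    if (!any(sel)) return(NULL)
    rates <- if (src[i] == "numt") config$meth_numt else config$meth_organelle
    p <- rates[allctx[sel]]
    data.frame(read_id = ids[i], pos = allpos[sel], context = allctx[sel],
               methylated = as.integer(runif(sum(sel)) < p),
               stringsAsFactors = FALSE)
  }))
  if (is.null(meth))
    meth <- data.frame(read_id = character(0), pos = integer(0),
                       context = character(0), methylated = integer(0),
                       stringsAsFactors = FALSE)

  if (config$emit_sequence) {
    seqs <- vapply(seq_len(n), function(i) {
      s <- subseq0(numt, start[i], end[i])
      if (src[i] == "organelle" && nrow(al)) {
        # swap in the organelle allele where this read observed it
        mine <- al[al$read_id == ids[i], , drop = FALSE]
        if (nrow(mine)) {
          sc <- seq_chars(s)
          sc[mine$numt_pos - start[i] + 1L] <- mine$allele
          s <- paste(sc, collapse = "")
        }
      } else if (nrow(al)) {
        mine <- al[al$read_id == ids[i], , drop = FALSE]
        if (nrow(mine)) {
          sc <- seq_chars(s)
          sc[mine$numt_pos - start[i] + 1L] <- mine$allele
          s <- paste(sc, collapse = "")
        }
      }
      s
    }, character(1))
    reads$seq <- seqs
  }
  structure(list(reads = reads, alleles = al, meth = meth),
            class = "simulated_read_set")
}
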