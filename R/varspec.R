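# Variant calling and mutation-spectrum analysis for >99%-identity
# numt/organelle comparisons.
#
# Scoring defaults (+1 match, -2 mismatch, -4 gap open, -1 gap extend; a
# length-L gap costs 4 + L) behave like a standard global aligner at high
# identity; they are not tuned to any particular substitution matrix.

#' Banded global alignment of two homologous sequences
#'
#' Optimal global alignment (affine gap penalties) restricted to a diagonal
#' band; the band is widened and the alignment recomputed whenever the
#' optimal path touches the band edge, so the result equals the unbanded
#' optimum.
#'
#' @param numt_sub,ref_sub the two sequences (character scalars).
#' @param band initial band half-width; default adapts to the length
#'   difference.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @param max_band give up (error) beyond this band width.
#' @return object of class `block_alignment`: `score`, run-length encoded
#'   columns (`op` in M/X/I/D, `len`), the two input sequences, and the band
#'   used. `I` columns consume only the numt (insertion in the numt), `D`
#'   only the reference.
#' @export
align_block <- function(numt_sub, ref_sub, band = NULL,
                        match = 1, mismatch = -2,
                        gap_open = -4, gap_extend = -1,
                        max_band = 65536L) {
  ld <- abs(nchar(numt_sub) - nchar(ref_sub))
  if (is.null(band)) band <- max(32L, ld + 32L)
  if (band <= ld) stop("band must exceed the sequence length difference")
  repeat {
    res <- .banded_align_cpp(numt_sub, ref_sub, as.integer(band),
                             match, mismatch, gap_open, gap_extend)
    if (!res$band_hit || band >= max_band) break
    band <- min(max_band, band * 4L)
  }
  if (res$band_hit && band >= max_band)
    stop("alignment band exceeded max_band; retry with a larger max_band")
  structure(list(score = res$score, op = res$op, len = res$len,
                 numt = numt_sub, ref = ref_sub, band = band),
            class = "block_alignment")
}

# expand a block_alignment into per-column vectors
alignment_columns <- function(aln) {
  op <- rep(aln$op, aln$len)
  n_consume <- op %in% c("M", "X", "I")
  r_consume <- op %in% c("M", "X", "D")
  numt_i <- ifelse(n_consume, cumsum(n_consume), NA)      # 1-based
  ref_i <- ifelse(r_consume, cumsum(r_consume), NA)
  list(op = op, numt_i = as.integer(numt_i), ref_i = as.integer(ref_i))
}

#' Reconstruct the two aligned sequences from an alignment (consistency aid)
#' @param aln a `block_alignment`.
#' @return list with `numt` and `ref` gapped strings.
#' @export
alignment_strings <- function(aln) {
  cols <- alignment_columns(aln)
  nsc <- seq_chars(aln$numt); rsc <- seq_chars(aln$ref)
  list(numt = paste(ifelse(is.na(cols$numt_i), "-", nsc[cols$numt_i]),
                    collapse = ""),
       ref = paste(ifelse(is.na(cols$ref_i), "-", rsc[cols$ref_i]),
                   collapse = ""))
}

#' Call variants from a block alignment with high-identity exclusion rules
#'
#' Isolated mismatch columns become SNVs; maximal runs of two or more
#' adjacent mismatches become one excluded MNV; gap runs become indels
#' (excluded from identity); SNVs within `adjacency_window` columns of any
#' gap are excluded as `indel_adjacent`; columns containing N are excluded
#' as `unalignable` and never emitted as variants. Alleles are reported in
#' the organelle -> numt direction (`ref_allele` = reference/organelle).
#'
#' @param aln a `block_alignment` (numt vs organelle-homologous reference).
#' @param adjacency_window columns on each side of a gap within which SNVs
#'   are excluded.
#' @return data.frame of class `variant_records` with columns `numt_pos,
#'   organelle_pos` (0-based, relative to the aligned substrings),
#'   `ref_allele, alt_allele, vtype, excluded, reason, spectrum_category,
#'   transition`. Attribute `eligible_columns` holds the column count used
#'   for identity after all exclusions.
#' @export
call_variants <- function(aln, adjacency_window = 5L) {
  cols <- alignment_columns(aln)
  op <- cols$op
  nsc <- seq_chars(aln$numt); rsc <- seq_chars(aln$ref)
  nbase <- ifelse(is.na(cols$numt_i), NA, nsc[cols$numt_i])
  rbase <- ifelse(is.na(cols$ref_i), NA, rsc[cols$ref_i])
  ncol_ <- length(op)
  has_n <- (!is.na(nbase) & nbase == "N") | (!is.na(rbase) & rbase == "N")

  gapcol <- op %in% c("I", "D")
  # distance to the nearest gap column
  near_gap <- rep(FALSE, ncol_)
  if (any(gapcol) && adjacency_window > 0) {
    gi <- which(gapcol)
    for (d in seq_len(adjacency_window)) {
      lo <- pmax(1L, gi - d); hi <- pmin(ncol_, gi + d)
      near_gap[lo] <- TRUE; near_gap[hi] <- TRUE
    }
    near_gap[gi] <- FALSE
  }

  recs <- list()
  rle_op <- rle(op)
  run_end <- cumsum(rle_op$lengths)
  run_start <- run_end - rle_op$lengths + 1L
  for (r in seq_along(rle_op$values)) {
    v <- rle_op$values[r]
    s <- run_start[r]; e <- run_end[r]
    if (v == "M") next
    if (v == "X") {
      idx <- s:e
      idx <- idx[!has_n[idx]]  # N columns are unalignable, not variants
      if (!length(idx)) next
      # split by N interruptions into sub-runs
      grp <- cumsum(c(1L, diff(idx) != 1L))
      for (g in split(idx, grp)) {
        if (length(g) == 1L) {
          i <- g
          excl <- near_gap[i]
          recs[[length(recs) + 1L]] <- data.frame(
            numt_pos = cols$numt_i[i] - 1L,
            organelle_pos = cols$ref_i[i] - 1L,
            ref_allele = rbase[i], alt_allele = nbase[i], vtype = "snv",
            excluded = excl,
            reason = if (excl) "indel_adjacent" else NA_character_,
            stringsAsFactors = FALSE)
        } else {
          recs[[length(recs) + 1L]] <- data.frame(
            numt_pos = cols$numt_i[g[1]] - 1L,
            organelle_pos = cols$ref_i[g[1]] - 1L,
            ref_allele = paste(rbase[g], collapse = ""),
            alt_allele = paste(nbase[g], collapse = ""),
            vtype = "mnv", excluded = TRUE, reason = "mnv",
            stringsAsFactors = FALSE)
        }
      }
    } else {
      # gap run: one indel record
      idx <- s:e
      if (v == "I") {
        alt <- paste(nbase[idx], collapse = "")
        recs[[length(recs) + 1L]] <- data.frame(
          numt_pos = cols$numt_i[s] - 1L,
          organelle_pos = if (s > 1L && !is.na(cols$ref_i[s - 1L]))
            cols$ref_i[s - 1L] else 0L,
          ref_allele = "-", alt_allele = alt, vtype = "indel",
          excluded = TRUE, reason = "indel", stringsAsFactors = FALSE)
      } else {
        ref <- paste(rbase[idx], collapse = "")
        recs[[length(recs) + 1L]] <- data.frame(
          numt_pos = if (s > 1L && !is.na(cols$numt_i[s - 1L]))
            cols$numt_i[s - 1L] else 0L,
          organelle_pos = cols$ref_i[s] - 1L,
          ref_allele = ref, alt_allele = "-", vtype = "indel",
          excluded = TRUE, reason = "indel", stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(numt_pos = integer(0), organelle_pos = integer(0),
               ref_allele = character(0), alt_allele = character(0),
               vtype = character(0), excluded = logical(0),
               reason = character(0), stringsAsFactors = FALSE)
  # unalignable N-column SNV-like records are dropped entirely; account for
  # them (and other exclusions) in the eligible column count
  sub_col <- op %in% c("M", "X")
  mnv_col <- rep(FALSE, ncol_)
  if (nrow(out)) {
    # recompute mnv columns from runs: columns in X runs of length >= 2
    xr <- rle(op == "X")
    xe <- cumsum(xr$lengths); xs <- xe - xr$lengths + 1L
    for (r in which(xr$values & xr$lengths >= 2L)) mnv_col[xs[r]:xe[r]] <- TRUE
  }
  eligible <- sum(sub_col & !has_n & !near_gap & !mnv_col)
  # spectrum classification for included SNVs
  out$spectrum_category <- rep(NA_character_, nrow(out))
  out$transition <- rep(NA, nrow(out))
  is_snv <- out$vtype == "snv"
  if (any(is_snv)) {
    cl <- classify_spectrum_vec(out$ref_allele[is_snv],
                                out$alt_allele[is_snv])
    out$spectrum_category[is_snv] <- cl$category
    out$transition[is_snv] <- cl$transition
  }
  ord <- order(out$numt_pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "eligible_columns") <- eligible
  attr(out, "adjacency_window") <- adjacency_window
  class(out) <- c("variant_records", "data.frame")
  out
}

#' Percent identity after exclusions
#'
#' Identity over columns eligible after excluding indels, MNVs, unalignable
#' (N) columns and SNVs adjacent to indels:
#' `100 * (1 - snvs / eligible_columns)`.
#'
#' @param variants a `variant_records` data.frame (only non-excluded SNVs
#'   are counted).
#' @param aligned_length the eligible column count (defaults to the
#'   `eligible_columns` attribute of `variants`).
#' @return identity as a percentage (e.g. `99.933`).
#' @export
percent_identity <- function(variants, aligned_length = NULL) {
  if (is.null(aligned_length))
    aligned_length <- attr(variants, "eligible_columns")
  if (is.null(aligned_length) || aligned_length <= 0)
    stop("identity undefined: no eligible aligned columns")
  n_snv <- sum(variants$vtype == "snv" & !variants$excluded)
  100 * (1 - n_snv / aligned_length)
}

# vectorized strand-collapsed spectrum classification (organelle -> numt)
classify_spectrum_vec <- function(ref, alt) {
  key <- paste0(ref, alt)
  map <- c(GA = "GC<>AT", CT = "GC<>AT", AG = "AT<>GC", TC = "AT<>GC",
           GT = "GC<>TA", CA = "GC<>TA", AC = "AT<>CG", TG = "AT<>CG",
           GC = "GC<>CG", CG = "GC<>CG", AT = "AT<>TA", TA = "AT<>TA")
  if (any(!key %in% names(map)))
    stop("non-ACGT or identical alleles in spectrum classification")
  cat <- unname(map[key])
  list(category = cat, transition = cat %in% c("GC<>AT", "AT<>GC"))
}

#' Classify a single substitution into the strand-collapsed spectrum
#'
#' Categories collapse the two strands in the organelle -> numt direction:
#' G->A and C->T are `GC<>AT` (transition); A->G/T->C `AT<>GC` (transition);
#' G->T/C->A `GC<>TA`; A->C/T->G `AT<>CG`; G->C/C->G `GC<>CG`; A->T/T->A
#' `AT<>TA`.
#'
#' @param ref_allele,alt_allele single bases, organelle and numt allele.
#' @return list with `category` and `transition` flag.
#' @export
classify_spectrum <- function(ref_allele, alt_allele) {
  stopifnot(nchar(ref_allele) == 1L, nchar(alt_allele) == 1L,
            ref_allele != alt_allele)
  cl <- classify_spectrum_vec(ref_allele, alt_allele)
  list(category = cl$category, transition = cl$transition)
}

#' Tabulate the mutation spectrum of a variant set
#'
#' @param variants a `variant_records` data.frame; only non-excluded SNVs
#'   enter the SNV counts, all indel records enter the indel counts.
#' @return object of class `spectrum_table`: per-category counts, totals,
#'   indel polarity (`numt_shorter`/`numt_longer`) and `at_bias_ratio`
#'   (GC<>AT transitions over AT<>GC transitions; `Inf` with
#'   `ratio_infinite = TRUE` when the denominator is zero).
#' @export
spectrum_table <- function(variants) {
  snvs <- variants[variants$vtype == "snv" & !variants$excluded, ,
                   drop = FALSE]
  counts <- setNames(integer(length(SPECTRUM_CATEGORIES)),
                     SPECTRUM_CATEGORIES)
  if (nrow(snvs)) {
    tab <- table(factor(snvs$spectrum_category,
                        levels = SPECTRUM_CATEGORIES))
    counts[names(tab)] <- as.integer(tab)
  }
  transitions <- sum(counts[c("GC<>AT", "AT<>GC")])
  transversions <- sum(counts[c("GC<>TA", "AT<>CG", "GC<>CG", "AT<>TA")])
  ind <- variants[variants$vtype == "indel", , drop = FALSE]
  numt_shorter <- sum(ind$alt_allele == "-")
  numt_longer <- sum(ind$ref_allele == "-")
  ratio_inf <- counts["AT<>GC"] == 0 && counts["GC<>AT"] > 0
  ratio <- if (counts["AT<>GC"] == 0) {
    if (counts["GC<>AT"] == 0) NA_real_ else Inf
  } else unname(counts["GC<>AT"] / counts["AT<>GC"])
  structure(list(counts = counts,
                 snvs = transitions + transversions,
                 transitions = transitions,
                 transversions = transversions,
                 indels = nrow(ind),
                 numt_shorter = numt_shorter,
                 numt_longer = numt_longer,
                 at_bias_ratio = ratio,
                 ratio_infinite = isTRUE(unname(ratio_inf))),
            class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat("Sequence variants (organelle <> numt)\n")
  cat(sprintf("  %-28s %6d\n", "Total SNVs", x$snvs))
  cat(sprintf("  %-28s %6d\n", "Total transitions", x$transitions))
  for (cc in c("GC<>AT", "AT<>GC"))
    cat(sprintf("    %-26s %6d\n", cc, x$counts[cc]))
  cat(sprintf("  %-28s %6d\n", "Total transversions", x$transversions))
  for (cc in c("GC<>TA", "AT<>CG", "GC<>CG", "AT<>TA"))
    cat(sprintf("    %-26s %6d\n", cc, x$counts[cc]))
  cat(sprintf("  %-28s %6d\n", "Total indels", x$indels))
  cat(sprintf("    %-26s %6d\n", "numt shorter", x$numt_shorter))
  cat(sprintf("    %-26s %6d\n", "numt longer", x$numt_longer))
  cat(sprintf("  %-28s %6s\n", "AT-bias ratio (ts)",
              ifelse(is.finite(x$at_bias_ratio),
                     sprintf("%.2f", x$at_bias_ratio), "Inf")))
  invisible(x)
}

#' Cytosine context at a position of a (circular) genome
#'
#' @param genome an `organelle_genome` or character scalar.
#' @param pos 0-based position whose base must be C on `strand`.
#' @param strand `"+"` or `"-"`.
#' @param circular wrap the two downstream bases around the origin.
#' @return `"CpG"`, `"CHG"` or `"CHH"`; `NA` (with a warning) when the base
#'   is not C; `"unknown"` when an N falls in the context window.
#' @export
classify_context <- function(genome, pos, strand = "+", circular = TRUE) {
  seq <- if (inherits(genome, "organelle_genome")) genome$sequence else genome
  L <- nchar(seq)
  at <- function(p) {
    p <- if (circular) p %% L else p
    if (p < 0 || p >= L) return(NA_character_)
    substr(seq, p + 1L, p + 1L)
  }
  base <- at(pos)
  if (strand == "-") {
    if (is.na(base) || base != "G") {
      warning("base at position is not C on the minus strand")
      return(NA_character_)
    }
    b1 <- at(pos - 1L); b2 <- at(pos - 2L)  # downstream on minus strand
    b1 <- chartr("ACGT", "TGCA", b1); b2 <- chartr("ACGT", "TGCA", b2)
  } else {
    if (is.na(base) || base != "C") {
      warning("base at position is not C")
      return(NA_character_)
    }
    b1 <- at(pos + 1L); b2 <- at(pos + 2L)
  }
  if (is.na(b1) || is.na(b2) || b1 == "N" || b2 == "N") return("unknown")
  if (b1 == "G") "CpG" else if (b2 == "G") "CHG" else "CHH"
}

#' Context fractions over all cytosines of a genome (both strands)
#'
#' @param genome an `organelle_genome` or character scalar (treated as
#'   circular).
#' @return named numeric vector `c(CpG=, CHG=, CHH=)` summing to 1.
#' @export
context_fractions <- function(genome) {
  seq <- if (inherits(genome, "organelle_genome")) genome$sequence else genome
  ctx <- contexts_along(seq, circular = TRUE)
  all <- c(ctx$plus[!is.na(ctx$plus)], ctx$minus[!is.na(ctx$minus)])
  if (!length(all)) stop("no cytosines in sequence: fractions undefined")
  tab <- table(factor(all, levels = c("CpG", "CHG", "CHH")))
  as.vector(tab) / length(all) -> fr
  setNames(fr, c("CpG", "CHG", "CHH"))
}

#' Chi-squared goodness-of-fit test for context enrichment
#'
#' One-degree-of-freedom goodness-of-fit of an observed (in-context,
#' out-of-context) split against an expected in-context fraction.
#'
#' @param observed_in,observed_out nonnegative counts.
#' @param expected_fraction expected in-context fraction, in (0,1).
#' @return object of class `enrichment_result`: `observed_in, observed_out,
#'   expected_fraction, chi2, p_value`, plus `small_expected` when an
#'   expected cell is below 1.
#' @export
context_enrichment <- function(observed_in, observed_out, expected_fraction) {
  stopifnot(observed_in >= 0, observed_out >= 0,
            observed_in + observed_out > 0,
            expected_fraction > 0, expected_fraction < 1)
  n <- observed_in + observed_out
  e_in <- n * expected_fraction
  e_out <- n - e_in
  chi2 <- (observed_in - e_in)^2 / e_in + (observed_out - e_out)^2 / e_out
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(observed_in = observed_in, observed_out = observed_out,
                 expected_fraction = expected_fraction,
                 chi2 = chi2, p_value = p,
                 small_expected = (e_in < 1 || e_out < 1)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "context enrichment: %d/%d in context (expected fraction %.3f)\n",
    x$observed_in, x$observed_in + x$observed_out, x$expected_fraction))
  cat(sprintf("  chi-squared (1 df) = %.1f, p = %.3g\n", x$chi2, x$p_value))
  if (x$small_expected) cat("  warning: an expected cell is below 1\n")
  invisible(x)
}

#' Annotate SNV records with the cytosine context of the organelle allele
#'
#' The context is evaluated on the organelle genome at the organelle
#' position, on the strand where the organelle allele is C (the ancestral
#' state of a C->T deamination).
#'
#' @param variants a `variant_records` data.frame whose `organelle_pos`
#'   column holds genuine organelle coordinates.
#' @param genome an `organelle_genome` or character scalar.
#' @return `variants` with a `context` column (`NA` for non-C organelle
#'   alleles and non-SNVs).
#' @export
annotate_variant_context <- function(variants, genome) {
  seq <- if (inherits(genome, "organelle_genome")) genome$sequence else genome
  ctx <- contexts_along(seq, circular = TRUE)
  variants$context <- rep(NA_character_, nrow(variants))
  is_snv <- variants$vtype == "snv"
  selC <- is_snv & variants$ref_allele == "C"
  selG <- is_snv & variants$ref_allele == "G"
  variants$context[selC] <- ctx$plus[variants$organelle_pos[selC] + 1L]
  variants$context[selG] <- ctx$minus[variants$organelle_pos[selG] + 1L]
  variants
}

#' Align all synteny blocks and call variants genome-wide
#'
#' Aligns each block's numt substring to its homologous organelle interval
#' and pools the variant records, mapping positions into full numt and
#' organelle coordinates.
#'
#' @param numt numt sequence.
#' @param genome an `organelle_genome` or character scalar.
#' @param blocks a `synteny_blocks` data.frame (from [decompose_synteny()]).
#' @param adjacency_window see [call_variants()].
#' @param band initial alignment band (default adapts per block).
#' @return a `variant_records` data.frame in global coordinates with a
#'   `context` column; attribute `eligible_columns` sums over blocks.
#' @export
call_block_variants <- function(numt, genome, blocks,
                                adjacency_window = 5L, band = NULL) {
  gseq <- if (inherits(genome, "organelle_genome")) genome$sequence else genome
  L <- nchar(gseq)
  all <- list()
  eligible <- 0
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    nsub <- subseq0(numt, b$numt_start, b$numt_end)
    rsub <- circ_subseq(gseq, b$org_start, b$org_end)
    if (b$orientation == "-") rsub <- revcomp(rsub)
    aln <- align_block(nsub, rsub, band = band)
    v <- call_variants(aln, adjacency_window = adjacency_window)
    eligible <- eligible + attr(v, "eligible_columns")
    if (nrow(v)) {
      v$numt_pos <- v$numt_pos + b$numt_start
      if (b$orientation == "+") {
        v$organelle_pos <- (b$org_start + v$organelle_pos) %% L
      } else {
        # position within the reverse-complemented reference substring
        v$organelle_pos <- (b$org_end - 1L - v$organelle_pos) %% L
        # report alleles on the organelle forward strand
        flip <- v$vtype %in% c("snv", "mnv")
        v$ref_allele[flip] <- vapply(v$ref_allele[flip], revcomp, "")
        v$alt_allele[flip] <- vapply(v$alt_allele[flip], revcomp, "")
      }
      v$block <- i
      all[[length(all) + 1L]] <- v
    }
  }
  out <- if (length(all)) do.call(rbind, all) else
    call_variants(align_block("A", "A"))[0, ]
  if (!"block" %in% names(out)) out$block <- integer(0)
  out <- annotate_variant_context(out, genome)
  out <- out[order(out$numt_pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "eligible_columns") <- eligible
  attr(out, "adjacency_window") <- adjacency_window
  class(out) <- c("variant_records", "data.frame")
  out
}
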