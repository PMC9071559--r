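# Duplication-history inference from multi-copy repeat regions of the numt.
#
# Copies are >99% identical to their organelle homolog, so instead of a
# heuristic multiple aligner each copy is aligned pairwise to the homolog
# and projected onto organelle columns; copy-specific insertions are kept
# as side records. Shared derived alleles between exactly two of three (or
# more) copies are the signature of a post-insertion duplication.

#' Group organelle regions covered by multiple numt copies
#'
#' Finds organelle intervals covered by at least `min_copies` synteny
#' blocks of at least `min_len` bases and intersects the contributing
#' blocks to a common core, yielding one group per multi-copy region.
#' Origin-wrapping blocks are split at the origin before grouping.
#'
#' @param blocks a `synteny_blocks` data.frame.
#' @param genome an `organelle_genome` (for the circle length).
#' @param min_copies minimum copy number (default 3, the three-copy
#'   repeats).
#' @param min_len minimum core length in bases.
#' @return list of `repeat_copy_group` objects: `org_start, org_end` (the
#'   common core) and `copies`, a data.frame `numt_start, numt_end,
#'   orientation, block`.
#' @export
extract_repeat_copies <- function(blocks, genome, min_copies = 3L,
                                  min_len = 5000L) {
  L <- if (inherits(genome, "organelle_genome")) genome$length else
    nchar(genome)
  if (!nrow(blocks)) return(list())
  # split wrapped blocks into linear organelle segments
  segs <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    s <- b$org_start %% L; e <- b$org_end
    if (e <= L) {
      segs[[length(segs) + 1L]] <- c(s, e, i)
    } else {
      segs[[length(segs) + 1L]] <- c(s, L, i)
      segs[[length(segs) + 1L]] <- c(0, e - L, i)
    }
  }
  segm <- do.call(rbind, segs)
  ir <- IRanges::IRanges(start = segm[, 1] + 1L, end = segm[, 2])
  cov <- IRanges::coverage(ir, width = L)
  hi <- IRanges::slice(cov, lower = min_copies, rangesOnly = TRUE)
  hi <- hi[IRanges::width(hi) >= min_len]
  groups <- list()
  for (g in seq_along(hi)) {
    rs <- IRanges::start(hi)[g] - 1L; re <- IRanges::end(hi)[g]
    # contributing segments overlapping the region by >= min_len
    ovl <- which(pmin(segm[, 2], re) - pmax(segm[, 1], rs) >= min_len)
    if (length(ovl) < min_copies) next
    core_s <- max(pmax(segm[ovl, 1], rs))
    core_e <- min(pmin(segm[ovl, 2], re))
    core_s <- max(core_s, rs); core_e <- min(core_e, re)
    if (core_e - core_s < min_len) next
    copies <- do.call(rbind, lapply(ovl, function(si) {
      b <- blocks[segm[si, 3], , drop = FALSE]
      if (b$orientation == "+") {
        off_s <- core_s - (b$org_start %% L)
        if (off_s < 0) off_s <- off_s + L  # wrapped second segment
        data.frame(numt_start = b$numt_start + off_s,
                   numt_end = b$numt_start + off_s + (core_e - core_s),
                   orientation = "+", block = segm[si, 3])
      } else {
        off_e <- (b$org_end - core_e) %% L
        data.frame(numt_start = b$numt_start + off_e,
                   numt_end = b$numt_start + off_e + (core_e - core_s),
                   orientation = "-", block = segm[si, 3])
      }
    }))
    copies <- copies[order(copies$numt_start), , drop = FALSE]
    rownames(copies) <- NULL
    groups[[length(groups) + 1L]] <- structure(
      list(org_start = as.integer(core_s), org_end = as.integer(core_e),
           copies = copies),
      class = "repeat_copy_group")
  }
  groups
}

#' Reference-guided alignment of repeat copies onto organelle columns
#'
#' Each copy is aligned pairwise to the organelle homolog
#' ([align_block()]) and projected onto homolog columns; deletions appear
#' as `-`, copy-specific insertions are retained as side records.
#'
#' @param group a `repeat_copy_group`.
#' @param numt numt sequence.
#' @param genome an `organelle_genome` or character scalar.
#' @return object of class `copy_alignment`: `alleles` (copies x columns
#'   character matrix), `organelle` (character vector), `numt_pos` (matrix
#'   of 0-based numt coordinates per copy and column, NA at deletions),
#'   `org_pos` (0-based organelle position per column), `insertions`
#'   (data.frame copy, org_pos, seq), `copies` (the group's copy table).
#' @export
align_copies <- function(group, numt, genome) {
  gseq <- if (inherits(genome, "organelle_genome")) genome$sequence else
    genome
  hom <- circ_subseq(gseq, group$org_start, group$org_end)
  W <- nchar(hom)
  nc <- nrow(group$copies)
  alleles <- matrix(NA_character_, nrow = nc, ncol = W)
  numt_pos <- matrix(NA_integer_, nrow = nc, ncol = W)
  ins <- list()
  for (i in seq_len(nc)) {
    cp <- group$copies[i, ]
    sub <- subseq0(numt, cp$numt_start, cp$numt_end)
    if (cp$orientation == "-") sub <- revcomp(sub)
    aln <- align_block(sub, hom)
    cols <- alignment_columns(aln)
    nsc <- seq_chars(sub)
    keep <- !is.na(cols$ref_i)
    ref_i <- cols$ref_i[keep]
    nmt_i <- cols$numt_i[keep]
    base <- ifelse(is.na(nmt_i), "-", nsc[nmt_i])
    alleles[i, ref_i] <- base
    # numt coordinate of each aligned base (orientation-aware)
    glob <- ifelse(is.na(nmt_i), NA_integer_,
                   if (cp$orientation == "+") cp$numt_start + nmt_i - 1L
                   else cp$numt_end - nmt_i)
    numt_pos[i, ref_i] <- glob
    insc <- which(is.na(cols$ref_i))
    if (length(insc)) {
      grp <- cumsum(c(1L, diff(insc) != 1L))
      for (gi in split(insc, grp)) {
        at <- if (gi[1] > 1L) cols$ref_i[max(which(!is.na(
          cols$ref_i[seq_len(gi[1] - 1L)])))] else 0L
        ins[[length(ins) + 1L]] <- data.frame(
          copy = i, org_pos = group$org_start + at,
          seq = paste(nsc[cols$numt_i[gi]], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(alleles = alleles,
                 organelle = seq_chars(hom),
                 numt_pos = numt_pos,
                 org_pos = group$org_start + seq_len(W) - 1L,
                 insertions = if (length(ins)) do.call(rbind, ins) else
                   data.frame(copy = integer(0), org_pos = integer(0),
                              seq = character(0)),
                 copies = group$copies),
            class = "copy_alignment")
}

#' Pairwise divergence matrix among repeat copies and the organelle homolog
#'
#' Entry (i, j) is the fraction of mismatching columns among columns where
#' both rows carry an ungapped base.
#'
#' @param aln a `copy_alignment`.
#' @return symmetric numeric matrix with rows/cols `copy1..copyN,
#'   organelle`; entries are `NA` when no comparable columns exist.
#' @export
pairwise_divergence <- function(aln) {
  rows <- rbind(aln$alleles, aln$organelle)
  n <- nrow(rows)
  nm <- c(paste0("copy", seq_len(n - 1L)), "organelle")
  D <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(rows[i, ]) & !is.na(rows[j, ]) &
      rows[i, ] != "-" & rows[j, ] != "-"
    D[i, j] <- D[j, i] <- if (!any(ok)) NA_real_ else
      mean(rows[i, ok] != rows[j, ok])
  }
  D
}

#' Classify polymorphic columns into allele-sharing patterns
#'
#' For each SNV column (no gaps, all copies aligned), compares copy alleles
#' to the organelle allele: `singleton` (one copy derived), `shared_pair`
#' (exactly two copies share a derived allele, the rest match the
#' organelle), `all_derived` (every copy carries the same derived allele),
#' `other`.
#'
#' @param aln a `copy_alignment` with at least 3 copies.
#' @return data.frame of class `shared_variant_patterns`: `column`
#'   (0-based alignment column), `org_pos`, `org_allele`, `alleles`
#'   (comma-separated copy alleles), `pattern_class`, `copy_i, copy_j` (the
#'   sharing pair, NA otherwise), `numt_pos_i, numt_pos_j`.
#' @export
detect_shared_variants <- function(aln) {
  nc <- nrow(aln$alleles)
  if (nc < 3L) stop("shared-variant patterns require at least 3 copies")
  W <- ncol(aln$alleles)
  out <- list()
  org <- aln$organelle
  ok_col <- colSums(is.na(aln$alleles) | aln$alleles == "-") == 0 &
    org != "N"
  poly <- which(ok_col & colSums(aln$alleles != rep(org, each = nc)) > 0)
  for (cix in poly) {
    al <- aln$alleles[, cix]
    derived <- al != org[cix]
    nd <- sum(derived)
    cls <- "other"; ci <- NA_integer_; cj <- NA_integer_
    if (nd == 1L) cls <- "singleton"
    else if (nd == nc && length(unique(al)) == 1L) cls <- "all_derived"
    else if (nd == 2L) {
      w <- which(derived)
      if (al[w[1]] == al[w[2]]) {
        cls <- "shared_pair"; ci <- w[1]; cj <- w[2]
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      column = cix - 1L, org_pos = aln$org_pos[cix],
      org_allele = org[cix],
      alleles = paste(al, collapse = ","),
      pattern_class = cls, copy_i = ci, copy_j = cj,
      numt_pos_i = if (!is.na(ci)) aln$numt_pos[ci, cix] else NA_integer_,
      numt_pos_j = if (!is.na(cj)) aln$numt_pos[cj, cix] else NA_integer_,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(column = integer(0), org_pos = integer(0),
               org_allele = character(0), alleles = character(0),
               pattern_class = character(0), copy_i = integer(0),
               copy_j = integer(0), numt_pos_i = integer(0),
               numt_pos_j = integer(0), stringsAsFactors = FALSE)
  attr(res, "n_columns") <- sum(ok_col)
  attr(res, "n_copies") <- nc
  class(res) <- c("shared_variant_patterns", "data.frame")
  res
}

#' Monte-Carlo test of the star-phylogeny null for shared derived variants
#'
#' Under the null, all copies diverge independently from the insertion-time
#' ancestor (approximated by the organelle homolog) at their observed
#' per-copy rates; shared pairs then arise only by homoplasy: two copies
#' mutating the same column to the same base (probability 1/3 given both
#' hit). The Monte-Carlo distribution of shared-pair counts under this null
#' gives the p-value for the observed count.
#'
#' @param patterns a `shared_variant_patterns` data.frame.
#' @param divergence the matrix from [pairwise_divergence()].
#' @param n_columns number of comparable columns (defaults to the
#'   `n_columns` attribute of `patterns`).
#' @param n_sim Monte-Carlo replicates (default 10000; below 100 a
#'   precision warning is issued).
#' @param seed integer seed (required: the test is replayable).
#' @return list of class `star_test`: `observed`, `expected_homoplasy`,
#'   `p_value` (conservative, `(1 + #{sim >= obs})/(n_sim + 1)`),
#'   `p_value_smoothed` (randomized tie-broken, uniform under the null),
#'   `verdict` (`post_insertion_duplication` when `p_value < 0.001`, else
#'   `star_phylogeny`).
#' @export
test_star_phylogeny <- function(patterns, divergence, n_columns = NULL,
                                n_sim = 10000L, seed) {
  if (missing(seed)) stop("seed is required")
  if (n_sim < 100L) warning("n_sim < 100: p-value has low precision")
  n_columns <- n_columns %||% attr(patterns, "n_columns")
  if (is.null(n_columns)) stop("n_columns is required")
  set.seed(seed)
  obs <- sum(patterns$pattern_class == "shared_pair")
  nc <- attr(patterns, "n_copies") %||% (nrow(divergence) - 1L)
  rates <- divergence[seq_len(nc), "organelle"]
  rates[is.na(rates)] <- 0
  sims <- integer(n_sim)
  pairs <- utils::combn(nc, 2)
  for (s in seq_len(n_sim)) {
    pos <- lapply(rates, function(r)
      sample.int(n_columns, rbinom(1L, n_columns, min(1, r))))
    cnt <- 0L
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      common <- intersect(pos[[i]], pos[[j]])
      # exclude columns hit by a third copy (those are not clean pairs)
      if (length(common) && nc > 2L) {
        others <- unlist(pos[-c(i, j)])
        common <- setdiff(common, others)
      }
      if (length(common))
        cnt <- cnt + rbinom(1L, length(common), 1 / 3)
    }
    sims[s] <- cnt
  }
  p_cons <- (1 + sum(sims >= obs)) / (n_sim + 1)
  p_smooth <- (sum(sims > obs) + runif(1) * (1 + sum(sims == obs))) /
    (n_sim + 1)
  structure(list(observed = obs,
                 expected_homoplasy = mean(sims),
                 p_value = p_cons,
                 p_value_smoothed = p_smooth,
                 verdict = if (p_cons < 0.001) "post_insertion_duplication"
                           else "star_phylogeny",
                 n_sim = n_sim, n_columns = n_columns),
            class = "star_test")
}

#' @export
print.star_test <- function(x, ...) {
  cat(sprintf(
    "star-phylogeny test: observed %d shared pairs over %d columns\n",
    x$observed, x$n_columns))
  cat(sprintf("  expected homoplasies %.3g; p = %.4g (%d simulations)\n",
              x$expected_homoplasy, x$p_value, x$n_sim))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Infer a single tandem duplication from shared-variant patterns
#'
#' Finds the copy pairing supported by the most shared-pair patterns; when
#' that support is strong, spread along the alignment (a localized cluster
#' suggests gene conversion, not duplication) and dominant over conflicting
#' pairings, the two paired copies are declared daughters of one tandem
#' duplication. The duplicated interval is the tandem span of the two
#' daughter copies on the numt and the central breakpoint their junction.
#'
#' @param patterns a `shared_variant_patterns` data.frame.
#' @param aln the `copy_alignment` the patterns came from (provides copy
#'   intervals in numt coordinates).
#' @param min_support minimum consistent shared-pair patterns.
#' @param min_spread minimum fraction of the alignment spanned by the
#'   consistent patterns.
#' @return list of class `duplication_model`: `interval` (c(start, end) on
#'   the numt or NULL), `breakpoint`, `daughter_copies`,
#'   `supporting_pattern_count`, `conflicting_pattern_count`, `verdict`.
#' @export
infer_tandem_duplication <- function(patterns, aln, min_support = 3L,
                                     min_spread = 0.5) {
  sp <- patterns[patterns$pattern_class == "shared_pair", , drop = FALSE]
  mk <- function(interval, breakpoint, daughters, supp, conf, verdict)
    structure(list(interval = interval, breakpoint = breakpoint,
                   daughter_copies = daughters,
                   supporting_pattern_count = supp,
                   conflicting_pattern_count = conf,
                   verdict = verdict),
              class = "duplication_model")
  if (!nrow(sp))
    return(mk(NULL, NA, NULL, 0L, 0L, "inconclusive"))
  key <- paste(pmin(sp$copy_i, sp$copy_j), pmax(sp$copy_i, sp$copy_j))
  tab <- sort(table(key), decreasing = TRUE)
  dom <- names(tab)[1L]
  dom_ij <- as.integer(strsplit(dom, " ")[[1L]])
  consistent <- sp[key == dom, , drop = FALSE]
  conflicting <- nrow(sp) - nrow(consistent)
  W <- ncol(aln$alleles)
  spread <- (max(consistent$column) - min(consistent$column) + 1L) / W
  cp <- aln$copies[dom_ij, , drop = FALSE]
  cp <- cp[order(cp$numt_start), , drop = FALSE]
  interval <- c(cp$numt_start[1L], cp$numt_end[2L])
  breakpoint <- as.integer(round((cp$numt_end[1L] + cp$numt_start[2L]) / 2))
  if (nrow(consistent) < min_support || spread < min_spread) {
    # localized or weakly supported sharing: report everything as
    # conflicting evidence rather than forcing a duplication verdict
    return(mk(NULL, NA, dom_ij, 0L, nrow(sp), "inconclusive"))
  }
  if (nrow(consistent) <= 2L * conflicting)
    return(mk(interval, breakpoint, dom_ij, nrow(consistent),
              conflicting, "inconclusive"))
  mk(interval, breakpoint, dom_ij, nrow(consistent), conflicting,
     "post_insertion_duplication")
}

#' @export
print.duplication_model <- function(x, ...) {
  cat("duplication model:", x$verdict, "\n")
  if (!is.null(x$interval))
    cat(sprintf("  tandem span [%d, %d), central breakpoint %d\n",
                x$interval[1], x$interval[2], x$breakpoint))
  cat(sprintf("  supporting %d, conflicting %d shared-pair pattern(s)\n",
              x$supporting_pattern_count, x$conflicting_pattern_count))
  invisible(x)
}
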