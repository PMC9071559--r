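# Synteny-block decomposition of a numt against a circular organelle genome.
#
# Anchors are k-mers that occur exactly once in the organelle genome
# (counting both strands). Large repeats are therefore anchorless and block
# boundaries at repeats are resolved by flank connectivity: collinear chains
# are merged across anchor gaps when the numt and organelle gaps agree.

kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

# reverse complement a character vector of fixed-width k-mers
revcomp_vec <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Decompose a numt into syntenic blocks against a circular organelle genome
#'
#' k-mers unique in the organelle genome (both strands) are matched against
#' the numt and chained into collinear blocks; chains are merged across
#' anchorless gaps (repeat interiors, diverged patches) when the numt-side
#' and organelle-side gaps agree within the drift tolerance.
#'
#' @param numt numt sequence (character scalar).
#' @param genome an `organelle_genome`, or a plain character scalar treated
#'   as a circular sequence without repeat annotation.
#' @param k anchor k-mer length (>= 15; default 31).
#' @param min_block minimum block span on the numt, bases.
#' @param drift_tol maximum diagonal drift between consecutive anchors.
#' @param max_merge_gap largest anchorless gap bridged when merging
#'   collinear chains.
#' @return data.frame of class `synteny_blocks`: `numt_start, numt_end,
#'   org_start, org_end, orientation, anchor_count, identity_estimate,
#'   wrapped` (0-based half-open; `org_end` may exceed the genome length for
#'   origin-wrapping blocks, flagged by `wrapped`). Ordered by numt
#'   coordinate.
#' @export
decompose_synteny <- function(numt, genome, k = 31L, min_block = 500L,
                              drift_tol = 50L, max_merge_gap = 10000L) {
  stopifnot(k >= 15L, nchar(numt) > 0)
  gseq <- if (inherits(genome, "organelle_genome")) genome$sequence else genome
  L <- nchar(gseq)
  stopifnot(L > 0)
  empty <- data.frame(numt_start = integer(0), numt_end = integer(0),
                      org_start = integer(0), org_end = integer(0),
                      orientation = character(0), anchor_count = integer(0),
                      identity_estimate = numeric(0), wrapped = logical(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("synteny_blocks", "data.frame")

  # genome k-mers, wrapping the origin
  gext <- paste0(gseq, substr(gseq, 1L, k - 1L))
  gk <- substring(gext, 1:L, k:(L + k - 1L))
  u <- unique(gk)
  cnt <- tabulate(match(gk, u), nbins = length(u))
  rc_u <- revcomp_vec(u)
  unique_ok <- cnt == 1L & is.na(match(rc_u, u))
  anchors_fwd <- u[unique_ok]
  anchor_gpos <- match(anchors_fwd, gk) - 1L
  anchors_rc <- rc_u[unique_ok]

  nk <- kmers_of(numt, k)
  m_f <- match(nk, anchors_fwd)
  m_r <- match(nk, anchors_rc)
  hit_f <- which(!is.na(m_f))
  hit_r <- which(!is.na(m_r))
  if (!length(hit_f) && !length(hit_r)) {
    warning("no unique anchors shared between numt and organelle genome")
    return(empty)
  }
  an <- data.frame(
    npos = c(hit_f, hit_r) - 1L,
    gpos = c(anchor_gpos[m_f[hit_f]], anchor_gpos[m_r[hit_r]]),
    strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))))
  an <- an[order(an$npos), , drop = FALSE]

  # chain anchors into collinear runs (circular-aware unwrapping)
  n_an <- nrow(an)
  chain_id <- integer(n_an)
  gunw <- numeric(n_an)  # unwrapped genome coordinate along each chain
  cid <- 1L
  chain_id[1L] <- cid
  gunw[1L] <- an$gpos[1L]
  if (n_an > 1L) {
    for (i in 2:n_an) {
      step <- an$npos[i] - an$npos[i - 1L]
      same <- an$strand[i] == an$strand[i - 1L]
      ok <- FALSE
      if (same && step <= max_merge_gap) {
        expect <- if (an$strand[i] == "+") gunw[i - 1L] + step
                  else gunw[i - 1L] - step
        cand <- an$gpos[i] + L * round((expect - an$gpos[i]) / L)
        if (abs(cand - expect) <= drift_tol + step * 0.005) {
          gunw[i] <- cand
          ok <- TRUE
        }
      }
      if (!ok) {
        cid <- cid + 1L
        gunw[i] <- an$gpos[i]
      }
      chain_id[i] <- cid
    }
  }

  blocks <- do.call(rbind, lapply(split(seq_len(n_an), chain_id),
                                  function(ix) {
    npos <- an$npos[ix]; g <- gunw[ix]; strand <- an$strand[ix[1L]]
    ns <- min(npos); ne <- max(npos) + k
    gs <- min(g); ge <- max(g) + k
    span <- ne - ns
    cov <- length(ix) / max(1L, span - k + 1L)
    div <- if (cov >= 1) 0 else -log(max(cov, 1e-6)) / k
    data.frame(numt_start = ns, numt_end = ne,
               org_start_unw = gs, org_end_unw = ge,
               orientation = strand, anchor_count = length(ix),
               identity_estimate = max(0, min(1, 1 - div)),
               stringsAsFactors = FALSE)
  }))
  blocks <- blocks[order(blocks$numt_start), , drop = FALSE]

  # merge consecutive collinear chains across anchorless gaps (repeat
  # interiors, locally diverged patches): numt-side and organelle-side gaps
  # must agree within the drift tolerance
  merged <- blocks[0, ]
  cur <- blocks[1, ]
  for (i in seq_len(nrow(blocks))[-1]) {
    nxt <- blocks[i, ]
    ngap <- nxt$numt_start - cur$numt_end
    # organelle gap between the chains, on the genome circle, taken as the
    # representative closest to the numt gap
    if (cur$orientation == "+") {
      raw <- (nxt$org_start_unw %% L) - (cur$org_end_unw %% L)
    } else {
      raw <- (cur$org_start_unw %% L) - (nxt$org_end_unw %% L)
    }
    ogap <- raw + L * round((ngap - raw) / L)
    nxt_span <- nxt$org_end_unw - nxt$org_start_unw
    if (nxt$orientation == cur$orientation && ngap >= -k &&
        ngap <= max_merge_gap && abs(ogap - ngap) <= drift_tol) {
      cur$numt_end <- nxt$numt_end
      if (cur$orientation == "+") {
        cur$org_end_unw <- cur$org_end_unw + ogap + nxt_span
      } else {
        cur$org_start_unw <- cur$org_start_unw - ogap - nxt_span
      }
      cur$anchor_count <- cur$anchor_count + nxt$anchor_count
      cur$identity_estimate <- min(cur$identity_estimate,
                                   nxt$identity_estimate)
    } else {
      merged <- rbind(merged, cur)
      cur <- nxt
    }
  }
  merged <- rbind(merged, cur)

  merged <- merged[merged$numt_end - merged$numt_start >= min_block, ,
                   drop = FALSE]
  if (!nrow(merged)) {
    warning("no blocks of at least min_block bases")
    return(empty)
  }
  span <- merged$org_end_unw - merged$org_start_unw
  org_start <- ((merged$org_start_unw %% L) + L) %% L
  out <- data.frame(numt_start = as.integer(merged$numt_start),
                    numt_end = as.integer(merged$numt_end),
                    org_start = as.integer(org_start),
                    org_end = as.integer(org_start + span),
                    orientation = merged$orientation,
                    anchor_count = as.integer(merged$anchor_count),
                    identity_estimate = merged$identity_estimate,
                    wrapped = org_start + span > L,
                    stringsAsFactors = FALSE)
  out <- out[order(out$numt_start), , drop = FALSE]
  # junction k-mers can extend a chain a base or two past the true boundary
  # by chance; trim any small overlap so blocks strictly tile the numt
  if (nrow(out) > 1L) {
    for (i in seq_len(nrow(out))[-1L]) {
      o <- out$numt_end[i - 1L] - out$numt_start[i]
      if (o > 0L) {
        out$numt_start[i] <- out$numt_start[i] + o
        if (out$orientation[i] == "+") out$org_start[i] <- out$org_start[i] + o
        else out$org_end[i] <- out$org_end[i] - o
      }
    }
    out <- out[out$numt_end > out$numt_start, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("synteny_blocks", "data.frame")
  out
}

# strand-aware genome coordinate of the numt-forward END of a block
block_exit_g <- function(b, L) {
  if (b$orientation == "+") b$org_end %% L else b$org_start %% L
}
# strand-aware genome coordinate of the numt-forward START of a block
block_entry_g <- function(b, L) {
  if (b$orientation == "+") b$org_start %% L else b$org_end %% L
}

near_circ <- function(a, b, tol, L) {
  d <- abs(a - b) %% L
  min(d, L - d) <= tol
}

#' Classify junctions between adjacent synteny blocks
#'
#' A junction is `repeat_mediated` when the left block ends at one copy of
#' an annotated repeat pair and the right block resumes at the other copy
#' (within `tolerance`), the signature of recombination between the two
#' copies; otherwise `nhej` when the flanking organelle intervals are
#' disjoint, and `unknown` when they overlap or the evidence is ambiguous.
#'
#' @param blocks a `synteny_blocks` data.frame, sorted by numt coordinate.
#' @param genome an `organelle_genome` with repeat annotation.
#' @param tolerance distance in bases allowed between a block edge and a
#'   repeat-copy edge.
#' @return data.frame of class `breakpoints`: `numt_pos, left_block,
#'   right_block, class, mediating_repeat`.
#' @export
classify_breakpoints <- function(blocks, genome, tolerance = 50L) {
  stopifnot(inherits(genome, "organelle_genome"))
  L <- genome$length
  rp <- genome$repeat_pairs
  if (nrow(blocks) > 1L) {
    for (i in seq_len(nrow(blocks) - 1L)) {
      if (blocks$numt_end[i] > blocks$numt_start[i + 1L])
        stop("overlapping blocks on the numt: rows ", i, " and ", i + 1L)
    }
  }
  out <- data.frame(numt_pos = integer(0), left_block = integer(0),
                    right_block = integer(0), class = character(0),
                    mediating_repeat = character(0), stringsAsFactors = FALSE)
  if (nrow(blocks) < 2L) {
    class(out) <- c("breakpoints", "data.frame")
    return(out)
  }
  for (i in seq_len(nrow(blocks) - 1L)) {
    bl <- blocks[i, ]; br <- blocks[i + 1L, ]
    gl <- block_exit_g(bl, L)
    gr <- block_entry_g(br, L)
    cls <- NA_character_; rname <- NA_character_
    if (nrow(rp)) {
      for (j in seq_len(nrow(rp))) {
        s1 <- rp$start1[j]; e1 <- rp$end1[j]
        s2 <- rp$start2[j]; e2 <- rp$end2[j]
        cross <- (near_circ(gl, s1, tolerance, L) &&
                  (near_circ(gr, e2, tolerance, L) ||
                   near_circ(gr, s2, tolerance, L))) ||
                 (near_circ(gl, s2, tolerance, L) &&
                  (near_circ(gr, e1, tolerance, L) ||
                   near_circ(gr, s1, tolerance, L))) ||
                 (near_circ(gl, e1, tolerance, L) &&
                  near_circ(gr, e2, tolerance, L)) ||
                 (near_circ(gl, e2, tolerance, L) &&
                  near_circ(gr, e1, tolerance, L))
        if (cross) { cls <- "repeat_mediated"; rname <- rp$name[j]; break }
      }
    }
    if (is.na(cls)) {
      # disjoint organelle intervals (circularly) -> NHEJ-like fusion
      ls <- bl$org_start %% L; le <- bl$org_end
      rs <- br$org_start %% L; re <- br$org_end
      ov <- circ_intervals_overlap(ls, le, rs, re, L)
      cls <- if (ov) "unknown" else "nhej"
    }
    out <- rbind(out, data.frame(
      numt_pos = as.integer(bl$numt_end), left_block = i,
      right_block = i + 1L, class = cls, mediating_repeat = rname,
      stringsAsFactors = FALSE))
  }
  class(out) <- c("breakpoints", "data.frame")
  out
}

# overlap of two circular 0-based half-open intervals (end may exceed L)
circ_intervals_overlap <- function(s1, e1, s2, e2, L) {
  seg <- function(s, e) {
    s <- s %% L
    w <- e - s
    if (s + w <= L) list(c(s, s + w)) else list(c(s, L), c(0, s + w - L))
  }
  for (a in seg(s1, e1)) for (b in seg(s2, e2)) {
    if (a[1] < b[2] && b[1] < a[2]) return(TRUE)
  }
  FALSE
}

#' Detect which flanking-sequence conformations of a repeat pair are present
#'
#' Recombination between the two copies of a repeat pair yields four
#' possible combinations of flanking sequences. Copy 1's upstream/downstream
#' flanks are labelled `A`/`B` and copy 2's `A'`/`B'`; the four combinations
#' are `A-B`, `A'-B'` (parental) and `A-B'`, `A'-B` (recombinant). A block
#' spanning a copy evidences its parental conformation; a junction whose
#' flanks enter through one copy and exit through the other evidences a
#' recombinant one.
#'
#' @param blocks a `synteny_blocks` data.frame.
#' @param repeat_name name of the pair in `genome$repeat_pairs`.
#' @param genome an `organelle_genome`.
#' @param tolerance edge tolerance in bases.
#' @return list of class `conformation_set` with `repeat_name` and
#'   `present`, a character subset of `c("A-B","A-B'","A'-B","A'-B'")`.
#' @export
detect_repeat_conformations <- function(blocks, repeat_name, genome,
                                        tolerance = 50L) {
  rp <- genome$repeat_pairs
  row <- rp[rp$name == repeat_name, , drop = FALSE]
  if (!nrow(row)) stop("repeat pair '", repeat_name, "' not annotated")
  L <- genome$length
  s <- c(row$start1, row$start2); e <- c(row$end1, row$end2)
  lab_up <- c("A", "A'"); lab_dn <- c("B", "B'")
  present <- character(0)

  # blocks spanning a full copy (with flanking margin) -> parental
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    for (cpy in 1:2) {
      if (spans_circ(b$org_start, b$org_end, s[cpy] - tolerance,
                     e[cpy] + tolerance, L))
        present <- c(present, paste0(lab_up[cpy], "-", lab_dn[cpy]))
    }
  }
  # junctions entering via one copy, exiting via the other
  if (nrow(blocks) > 1L) {
    for (i in seq_len(nrow(blocks) - 1L)) {
      bl <- blocks[i, ]; br <- blocks[i + 1L, ]
      gl <- block_exit_g(bl, L); gr <- block_entry_g(br, L)
      up <- NA_integer_; dn <- NA_integer_
      for (cpy in 1:2) {
        # left block stops at a copy's upstream edge: traversed flank A_cpy
        if (bl$orientation == "+" && near_circ(gl, s[cpy], tolerance, L))
          up <- cpy
        if (bl$orientation == "-" && near_circ(gl, e[cpy], tolerance, L))
          dn <- cpy
        # right block resumes at a copy's downstream edge: flank B_cpy
        if (br$orientation == "+" && near_circ(gr, e[cpy], tolerance, L))
          dn <- if (is.na(dn)) cpy else dn
        if (br$orientation == "-" && near_circ(gr, s[cpy], tolerance, L))
          up <- if (is.na(up)) cpy else up
      }
      if (!is.na(up) && !is.na(dn))
        present <- c(present, paste0(lab_up[up], "-", lab_dn[dn]))
    }
  }
  structure(list(repeat_name = repeat_name,
                 present = sort(unique(present))),
            class = "conformation_set")
}

# does circular interval [s,e) contain [cs,ce)?
spans_circ <- function(s, e, cs, ce, L) {
  s0 <- s %% L; w <- e - s
  cs0 <- ((cs %% L) + L) %% L
  # unwrap the candidate start relative to the block start
  off <- (cs0 - s0) %% L
  off + (ce - cs) <= w
}

#' Build the synteny-matched concatenated organelle reference
#'
#' Concatenates the homologous organelle interval of each block (reverse
#' complemented for minus-orientation blocks) in numt order, so the result
#' can be globally aligned to the numt. The offset table maps every output
#' interval back to organelle coordinates.
#'
#' @param blocks a `synteny_blocks` data.frame.
#' @param genome an `organelle_genome` or character scalar.
#' @return list with `sequence` and `offsets` (data.frame `out_start,
#'   out_end, org_start, org_end, orientation, block`).
#' @export
build_syntenic_reference <- function(blocks, genome) {
  gseq <- if (inherits(genome, "organelle_genome")) genome$sequence else genome
  if (!nrow(blocks)) {
    return(list(sequence = "",
                offsets = data.frame(out_start = integer(0),
                                     out_end = integer(0),
                                     org_start = integer(0),
                                     org_end = integer(0),
                                     orientation = character(0),
                                     block = integer(0))))
  }
  pieces <- character(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    p <- circ_subseq(gseq, b$org_start, b$org_end)
    if (b$orientation == "-") p <- revcomp(p)
    pieces[i] <- p
  }
  lens <- nchar(pieces)
  ends <- cumsum(lens)
  starts <- c(0L, ends[-length(ends)])
  list(sequence = paste(pieces, collapse = ""),
       offsets = data.frame(out_start = as.integer(starts),
                            out_end = as.integer(ends),
                            org_start = blocks$org_start,
                            org_end = blocks$org_end,
                            orientation = blocks$orientation,
                            block = seq_len(nrow(blocks))))
}

#' Map positions on a syntenic reference back to organelle coordinates
#'
#' @param offsets the offset table from [build_syntenic_reference()].
#' @param pos 0-based positions on the concatenated reference.
#' @param genome_length organelle genome length (for origin wrapping).
#' @return integer vector of 0-based organelle positions.
#' @export
syntenic_to_organelle <- function(offsets, pos, genome_length) {
  vapply(pos, function(p) {
    i <- findInterval(p, offsets$out_start)
    off <- p - offsets$out_start[i]
    g <- if (offsets$orientation[i] == "+") offsets$org_start[i] + off
         else offsets$org_end[i] - 1L - off
    as.integer(g %% genome_length)
  }, integer(1))
}

#' Find maximal exact matches of at least a minimum length
#'
#' Reports maximal exact matches between two sequences (or within one
#' sequence when `seq_b` is identical to `seq_a`, excluding the trivial
#' full-length self match), in both orientations. Used to locate long
#' (e.g. >7 kb) 100%-identity regions that are candidates for assembly
#' overwriting.
#'
#' @param seq_a,seq_b character scalars.
#' @param min_len minimum match length in bases.
#' @return data.frame `a_start, a_end, b_start, b_end, length, orientation`
#'   (0-based half-open; `b_*` always on the forward strand of `seq_b`).
#' @export
find_identical_regions <- function(seq_a, seq_b, min_len) {
  stopifnot(min_len >= 1)
  self <- identical(seq_a, seq_b)
  res <- list()
  for (orient in c("+", "-")) {
    b_use <- if (orient == "+") seq_b else revcomp(seq_b)
    hits <- mem_scan(seq_a, b_use, min_len)
    if (nrow(hits)) {
      if (orient == "-") {
        nb <- nchar(seq_b)
        bs <- nb - hits$b_end; be <- nb - hits$b_start
        hits$b_start <- bs; hits$b_end <- be
      }
      hits$orientation <- orient
      res[[orient]] <- hits
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(a_start = integer(0), a_end = integer(0),
               b_start = integer(0), b_end = integer(0),
               length = integer(0), orientation = character(0))
  if (self && nrow(out)) {
    drop <- out$orientation == "+" & out$a_start == out$b_start
    out <- out[!drop, , drop = FALSE]
    # keep one record per unordered pair of self-match locations
    keep <- !(out$orientation == "+" & out$a_start > out$b_start)
    out <- out[keep, , drop = FALSE]
  }
  out <- unique(out)
  rownames(out) <- NULL
  out
}

# seed-and-extend maximal exact match scan (forward orientation only)
mem_scan <- function(a, b, min_len) {
  na <- nchar(a); nb <- nchar(b)
  empty <- data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      length = integer(0), stringsAsFactors = FALSE)
  k <- min(64L, as.integer(min_len))
  if (na < k || nb < k) return(empty)
  stride <- max(1L, as.integer(min_len) - k + 1L)
  apos <- seq(1L, na - k + 1L, by = stride)
  akmers <- substring(a, apos, apos + k - 1L)
  bkmers <- substring(b, 1:(nb - k + 1L), k:nb)
  hit_map <- split(apos, akmers)
  bm <- match(bkmers, names(hit_map))
  bhit <- which(!is.na(bm))
  if (!length(bhit)) return(empty)
  seen <- new.env(hash = TRUE)
  rows <- list()
  for (bi in bhit) {
    for (ai in hit_map[[bm[bi]]]) {
      # extend seed (ai, bi) [1-based starts] to a maximal match
      lext <- match_extend_left(a, b, ai - 1L, bi - 1L)
      rext <- match_extend_right(a, b, ai + k - 1L, bi + k - 1L)
      as0 <- ai - 1L - lext
      bs0 <- bi - 1L - lext
      len <- lext + k + rext
      if (len < min_len) next
      key <- paste(as0, bs0, len)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        a_start = as0, a_end = as0 + len, b_start = bs0, b_end = bs0 + len,
        length = len, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  unique(do.call(rbind, rows))
}

# number of matching bases immediately left of 0-based positions (ai, bi)
match_extend_left <- function(a, b, ai, bi) {
  ext <- 0L
  chunk <- 1024L
  repeat {
    w <- min(chunk, ai - ext, bi - ext)
    if (w <= 0L) return(ext)
    sa <- substr(a, ai - ext - w + 1L, ai - ext)
    sb <- substr(b, bi - ext - w + 1L, bi - ext)
    if (sa == sb) { ext <- ext + w; next }
    # scan the failing chunk for the longest matched suffix
    lo <- 0L
    while (lo + 1L <= w &&
           substr(sa, w - lo, w - lo) == substr(sb, w - lo, w - lo))
      lo <- lo + 1L
    return(ext + lo)
  }
}

match_extend_right <- function(a, b, ai, bi) {
  # ai, bi: 0-based positions just past the seed
  na <- nchar(a); nb <- nchar(b)
  ext <- 0L
  chunk <- 1024L
  repeat {
    w <- min(chunk, na - ai - ext, nb - bi - ext)
    if (w <= 0L) return(ext)
    sa <- substr(a, ai + ext + 1L, ai + ext + w)
    sb <- substr(b, bi + ext + 1L, bi + ext + w)
    if (sa == sb) { ext <- ext + w; next }
    lo <- 0L
    while (lo + 1L <= w &&
           substr(sa, lo + 1L, lo + 1L) == substr(sb, lo + 1L, lo + 1L))
      lo <- lo + 1L
    return(ext + lo)
  }
}
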