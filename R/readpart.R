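# Diagnostic-SNV read partitioning and windowed methylation profiles.
#
# A diagnostic site is a reliable (non-excluded) SNV whose allele
# distinguishes numt-derived from organelle-derived reads. Reads carrying
# only numt alleles at enough covered sites are assigned to the numt;
# organelle reads are removed before methylation profiling, which raises
# numt methylation estimates because the organelle itself is unmethylated.

#' Derive diagnostic sites from a variant set
#'
#' @param variants a `variant_records` data.frame.
#' @return data.frame of class `diagnostic_sites`: `numt_pos,
#'   organelle_pos, numt_allele, organelle_allele`, sorted by numt
#'   position, one row per position.
#' @export
derive_diagnostic_sites <- function(variants) {
  keep <- variants$vtype == "snv" & !variants$excluded
  v <- variants[keep, , drop = FALSE]
  if (!nrow(v)) warning("no non-excluded SNVs: empty diagnostic site set")
  out <- data.frame(numt_pos = v$numt_pos,
                    organelle_pos = v$organelle_pos,
                    numt_allele = v$alt_allele,
                    organelle_allele = v$ref_allele,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$numt_pos), , drop = FALSE]
  out <- out[order(out$numt_pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("diagnostic_sites", "data.frame")
  out
}

#' Classify one read as numt- or organelle-derived
#'
#' `numt_support` and `organelle_support` count covered diagnostic sites
#' carrying each source's allele. Origin is `numt` when `numt_support >=
#' min_sites` and no organelle allele is seen (symmetric for `organelle`),
#' `ambiguous` when both alleles are seen, `uninformative` when fewer than
#' `min_sites` informative sites are covered.
#'
#' @param obs data.frame with columns `numt_pos, allele`: the read's
#'   observed alleles at covered diagnostic sites.
#' @param sites a `diagnostic_sites` data.frame.
#' @param min_sites minimum informative sites (default 2; the strictness of
#'   the duplicate-ID rule is a tunable, not a hidden constant).
#' @return list of class `read_classification`: `numt_support,
#'   organelle_support, origin`.
#' @export
classify_read <- function(obs, sites, min_sites = 2L) {
  stopifnot(min_sites >= 1L)
  m <- match(obs$numt_pos, sites$numt_pos)
  if (any(is.na(m)))
    stop("observed allele at a position that is not a diagnostic site")
  ns <- sum(obs$allele == sites$numt_allele[m])
  os <- sum(obs$allele == sites$organelle_allele[m])
  origin <- if (ns + os < min_sites) "uninformative"
    else if (ns >= 1L && os >= 1L) "ambiguous"
    else if (ns >= min_sites && os == 0L) "numt"
    else if (os >= min_sites && ns == 0L) "organelle"
    else "uninformative"
  structure(list(numt_support = ns, organelle_support = os,
                 origin = origin),
            class = "read_classification")
}

#' Partition reads by inferred origin
#'
#' @param observations data.frame `read_id, numt_pos, allele` pooling all
#'   reads' allele observations (one row per read and covered site).
#' @param sites a `diagnostic_sites` data.frame.
#' @param min_sites see [classify_read()].
#' @return list of class `read_partition` with disjoint, exhaustive
#'   character vectors `numt, organelle, ambiguous, uninformative`, and a
#'   `table` data.frame of per-read support counts.
#' @export
partition_reads <- function(observations, sites, min_sites = 2L) {
  key <- paste(observations$read_id, observations$numt_pos)
  if (anyDuplicated(key)) {
    n_alleles <- tapply(observations$allele, key,
                        function(a) length(unique(a)))
    if (any(n_alleles > 1L))
      stop("duplicate read_id with conflicting observations")
    observations <- observations[!duplicated(key), , drop = FALSE]
  }
  ids <- unique(observations$read_id)
  res <- lapply(split(observations, observations$read_id), classify_read,
                sites = sites, min_sites = min_sites)
  tab <- data.frame(
    read_id = names(res),
    numt_support = vapply(res, `[[`, 0L, "numt_support"),
    organelle_support = vapply(res, `[[`, 0L, "organelle_support"),
    origin = vapply(res, `[[`, "", "origin"),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  part <- lapply(c(numt = "numt", organelle = "organelle",
                   ambiguous = "ambiguous",
                   uninformative = "uninformative"),
                 function(o) tab$read_id[tab$origin == o])
  structure(c(part, list(table = tab, ids = ids)),
            class = "read_partition")
}

#' Windowed methylation profile
#'
#' Pools methylation calls into tiling windows (the last window may be
#' short) per cytosine context. Percentages are calls-weighted (total
#' methylated calls over total calls in the window), not read-averaged;
#' windows with no calls are flagged `no_calls` rather than zero-filled.
#'
#' @param calls data.frame `read_id, pos, context, methylated` (0/1).
#' @param region_length length of the profiled region in bases.
#' @param window window size in bases.
#' @param contexts contexts to profile.
#' @param exclude_reads optional read ids to drop (e.g. organelle-derived
#'   reads) before profiling.
#' @return data.frame of class `window_profile`: `window_start, window_end,
#'   context, methylated_calls, total_calls, percent, no_calls`.
#' @export
methylation_profile <- function(calls, region_length, window = 50000L,
                                contexts = c("CpG", "CHG", "CHH"),
                                exclude_reads = NULL) {
  stopifnot(window > 0)
  if (!is.null(exclude_reads))
    calls <- calls[!calls$read_id %in% exclude_reads, , drop = FALSE]
  if (nrow(calls) && (any(calls$pos < 0) || any(calls$pos >= region_length)))
    stop("methylation call position outside the profiled region")
  starts <- seq(0L, region_length - 1L, by = window)
  ends <- pmin(starts + window, region_length)
  out <- do.call(rbind, lapply(contexts, function(cc) {
    sub <- calls[calls$context == cc, , drop = FALSE]
    wi <- findInterval(sub$pos, starts)
    meth <- tapply(sub$methylated, factor(wi, levels = seq_along(starts)),
                   sum)
    tot <- tapply(rep(1L, nrow(sub)),
                  factor(wi, levels = seq_along(starts)), sum)
    meth[is.na(meth)] <- 0L; tot[is.na(tot)] <- 0L
    data.frame(window_start = starts, window_end = ends, context = cc,
               methylated_calls = as.integer(meth),
               total_calls = as.integer(tot),
               percent = ifelse(tot > 0, 100 * meth / tot, NA_real_),
               no_calls = tot == 0L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("window_profile", "data.frame")
  out
}

#' Anchored spanning-read consensus over an interval
#'
#' Validates the assembly across a long identical region: reads that span
#' the interval and carry the numt allele at flanking diagnostic sites on
#' both sides are anchored to the numt; their per-column majority consensus
#' is compared with the assembly substring.
#'
#' @param reads data.frame `read_id, start, end, seq` with each read's base
#'   sequence over its numt interval.
#' @param assembly the numt sequence.
#' @param interval `c(start, end)` 0-based half-open interval to validate.
#' @param sites a `diagnostic_sites` data.frame; at least one site must
#'   flank the interval on each side within each read.
#' @param min_span_reads minimum anchored spanning reads.
#' @return list of class `anchored_consensus`: `consensus`,
#'   `matches_assembly`, `n_reads`, `mismatch_positions` (0-based, on the
#'   numt).
#' @export
anchored_consensus <- function(reads, assembly, interval, sites,
                               min_span_reads = 3L) {
  a <- interval[1]; b <- interval[2]
  span <- reads[reads$start <= a & reads$end >= b, , drop = FALSE]
  anchored <- logical(nrow(span))
  for (i in seq_len(nrow(span))) {
    r <- span[i, ]
    sc <- seq_chars(r$seq)
    in_read <- sites$numt_pos >= r$start & sites$numt_pos < r$end
    left <- sites[in_read & sites$numt_pos < a, , drop = FALSE]
    right <- sites[in_read & sites$numt_pos >= b, , drop = FALSE]
    ok_l <- nrow(left) > 0 &&
      any(sc[left$numt_pos - r$start + 1L] == left$numt_allele)
    ok_r <- nrow(right) > 0 &&
      any(sc[right$numt_pos - r$start + 1L] == right$numt_allele)
    anchored[i] <- ok_l && ok_r
  }
  span <- span[anchored, , drop = FALSE]
  if (nrow(span) < min_span_reads)
    stop("insufficient coverage: only ", nrow(span),
         " anchored spanning read(s), need ", min_span_reads)
  mat <- do.call(rbind, lapply(seq_len(nrow(span)), function(i) {
    r <- span[i, ]
    seq_chars(subseq0(r$seq, a - r$start, b - r$start))
  }))
  cons <- apply(mat, 2L, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    names(tb)[1L]
  })
  consensus <- paste(cons, collapse = "")
  target <- subseq0(assembly, a, b)
  mism <- which(cons != seq_chars(target)) - 1L + a
  structure(list(consensus = consensus,
                 matches_assembly = consensus == target,
                 n_reads = nrow(span),
                 mismatch_positions = as.integer(mism)),
            class = "anchored_consensus")
}
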