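# Internal sequence and interval helpers.
#
# Sequences are plain upper-case character scalars (alphabet A,C,G,T,N);
# Biostrings is used at the I/O boundary. All intervals are 0-based
# half-open internally; human-readable reports are 1-based inclusive.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A,C,G,T,N.
#' @return character scalar, the reverse complement.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
}

# 0-based half-open substring
subseq0 <- function(x, start, end) {
  substr(x, start + 1L, end)
}

# 0-based half-open substring on a circular sequence of length L.
# start in [0, L); end may exceed L (wraps past the origin).
circ_subseq <- function(x, start, end) {
  L <- nchar(x)
  stopifnot(start >= 0, end > start, end - start <= L)
  w <- end - start
  start <- start %% L
  e <- start + w
  if (e <= L) {
    subseq0(x, start, e)
  } else {
    paste0(subseq0(x, start, L), subseq0(x, 0L, e - L))
  }
}

# random i.i.d. DNA with a target GC fraction (draws from the current RNG)
random_dna <- function(n, gc_fraction) {
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# do two 0-based half-open intervals overlap?
iv_overlap <- function(s1, e1, s2, e2) {
  s1 < e2 && s2 < e1
}

# GC fraction of a sequence
gc_fraction_of <- function(x) {
  tab <- table(strsplit(x, "", fixed = TRUE)[[1L]])
  gc <- sum(tab[names(tab) %in% c("G", "C")])
  gc / sum(tab[names(tab) %in% DNA_BASES])
}

# split a character scalar into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a single sequence from a FASTA file
#'
#' @param path FASTA file with at least one record; only the first is used.
#' @return upper-case character scalar.
#' @export
read_fasta_seq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 1L) stop("no sequences in ", path)
  toupper(as.character(ss[[1L]]))
}

#' Write named sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
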