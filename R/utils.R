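#' @keywords internal
#' @noRd
DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# complement of a character vector of single bases
comp_bases <- function(v) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[v]
}

#' Phred string/integer conversions (Sanger, offset 33)
#'
#' @param q integer vector of Phred scores, or a character scalar of
#'   Phred+33 encoded qualities.
#' @return `phred_encode()` returns a single character string;
#'   `phred_decode()` an integer vector.
#' @export
phred_encode <- function(q) {
  intToUtf8(as.integer(q) + 33L)
}

#' @rdname phred_encode
#' @export
phred_decode <- function(q) {
  utf8ToInt(q) - 33L
}

# character matrix of the first (from = "start") or last (from = "end")
# `w` characters of each string; NA beyond the string length
char_matrix <- function(x, w, from = c("start", "end")) {
  from <- match.arg(from)
  n <- length(x)
  len <- nchar(x)
  m <- matrix(NA_character_, nrow = n, ncol = w)
  for (j in seq_len(w)) {
    pos <- if (from == "start") rep.int(j, n) else len - j + 1L
    ok <- len >= j & pos >= 1L
    if (any(ok)) m[ok, j] <- substring(x[ok], pos[ok], pos[ok])
  }
  m
}

#' Weighted delete-one block jackknife
#'
#' Standard weighted block-jackknife variance estimate used for
#' f-statistics: blocks of unequal size contribute leave-one-out
#' estimates weighted by their size.
#'
#' @param theta_hat full-data estimate.
#' @param theta_loo numeric vector of leave-one-block-out estimates.
#' @param weights block sizes (e.g. SNV counts per block).
#' @return list with `est` (jackknife-corrected estimate) and `se`.
#' @export
weighted_jackknife <- function(theta_hat, theta_loo, weights) {
  stopifnot(length(theta_loo) == length(weights), all(weights > 0))
  g <- length(theta_loo)
  if (g < 2) stop("weighted_jackknife: need at least 2 blocks")
  n <- sum(weights)
  h <- n / weights
  est <- g * theta_hat - sum((1 - weights / n) * theta_loo)
  tau <- h * theta_hat - (h - 1) * theta_loo
  v <- sum((tau - est)^2 / (h - 1)) / g
  list(est = est, se = sqrt(v))
}

# draw a child seed (< 2^31) deterministically from the current RNG stream
child_seed <- function() {
  sample.int(.Machine$integer.max, 1L)
}

# set seed if non-NULL (NULL = use the ambient RNG stream)
with_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

#' Read and write FASTQ via Biostrings
#'
#' @param path file path.
#' @return `read_fastq()` returns a data.frame with columns `id`, `seq`
#'   and `qual` (Phred+33 strings).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @rdname read_fastq
#' @param id,seq character vectors of read names and sequences.
#' @param qual character vector of Phred+33 quality strings.
#' @export
write_fastq <- function(id, seq, qual, path) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual),
            all(nchar(seq) == nchar(qual)))
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Read and write FASTA via Biostrings
#'
#' @param path file path.
#' @param x a named character vector or `DNAStringSet`.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
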