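#' Construct an aligned read
#'
#' `read` and `ref` are equal-length strings in the read's sequenced
#' orientation (position 1 is the sequenced 5' base); for reverse-strand
#' alignments `ref` is therefore the reverse complement of the
#' reference slice. This orientation is what damage profiling needs:
#' terminal deamination always appears at position 1 of `read`.
#'
#' @param id query name.
#' @param contig reference contig name.
#' @param start 0-based reference start of the alignment.
#' @param strand `"+"` or `"-"`.
#' @param mapq mapping quality in \[0, 60\].
#' @param read,ref aligned read/reference strings (sequenced orientation).
#' @return an object of class `aligned_read`.
#' @export
aligned_read <- function(id, contig, start, strand, mapq, read, ref) {
  stopifnot(nchar(read) == nchar(ref), start >= 0,
            strand %in% c("+", "-"), mapq >= 0, mapq <= 60)
  structure(list(id = id, contig = contig, start = as.integer(start),
                 strand = strand, mapq = as.integer(mapq),
                 read = read, ref = ref, length = nchar(read)),
            class = "aligned_read")
}

#' Trim bases from both ends
#'
#' Removes the first and last `n` bases (the paper-motivated use is
#' `n = 1`, stripping putative terminal deamination before downstream
#' analyses). Alignment reference coordinates are advanced/retracted
#' accordingly.
#'
#' @param x a `merged_read`, `aligned_read`, list of either, or a
#'   character vector.
#' @param n bases to remove from each end; object length must exceed `2n`.
#' @return the trimmed object (same class).
#' @export
trim_ends <- function(x, n = 1L) UseMethod("trim_ends")

#' @export
trim_ends.character <- function(x, n = 1L) {
  if (any(nchar(x) <= 2 * n)) stop("sequence length must exceed 2*n")
  substring(x, n + 1L, nchar(x) - n)
}

#' @export
trim_ends.merged_read <- function(x, n = 1L) {
  L <- nchar(x$seq)
  if (L <= 2 * n) stop("read length must exceed 2*n")
  x$seq <- substring(x$seq, n + 1L, L - n)
  x$qual <- x$qual[(n + 1L):(L - n)]
  x
}

#' @export
trim_ends.aligned_read <- function(x, n = 1L) {
  L <- x$length
  if (L <= 2 * n) stop("alignment length must exceed 2*n")
  x$read <- substring(x$read, n + 1L, L - n)
  x$ref <- substring(x$ref, n + 1L, L - n)
  # both ends shrink by n, so the reference window advances by n
  # regardless of strand
  x$start <- x$start + as.integer(n)
  x$length <- L - 2L * as.integer(n)
  x
}

#' @export
trim_ends.list <- function(x, n = 1L) lapply(x, trim_ends, n = n)

#' Filter alignments by mapping quality
#'
#' Retains alignments with mapping quality strictly greater than
#' `min_mapq` (the study keeps reads of mapping quality > 30).
#'
#' @param alignments list of `aligned_read` objects.
#' @param min_mapq threshold; equality is dropped.
#' @return filtered list.
#' @export
filter_mapq <- function(alignments, min_mapq = 30L) {
  alignments[vapply(alignments, `[[`, integer(1), "mapq") > min_mapq]
}

#' Naive exact-seed fixture aligner
#'
#' Seed-and-extend placement against an in-memory reference: exact
#' 16-mer seeds taken every `k` bases along the read (both strands),
#' extension scored by Hamming distance. The unique best placement gets
#' mapping quality 60; tied best placements get 0. This is test
#' plumbing, not a production aligner — reads shorter than `k` or with
#' no exact seed go unaligned.
#'
#' @param reads named character vector of read sequences (names become
#'   query ids).
#' @param reference named character vector of contig sequences.
#' @param k seed length.
#' @return list of `aligned_read` objects; unaligned read ids are kept
#'   in attribute `unaligned`.
#' @export
naive_align <- function(reads, reference, k = 16L) {
  if (is.null(names(reads))) names(reads) <- sprintf("read%d", seq_along(reads))
  index <- kmer_index(reference, k)
  out <- list()
  unaligned <- character(0)
  for (i in seq_along(reads)) {
    hit <- place_read(reads[[i]], reference, index, k)
    if (is.null(hit)) {
      unaligned <- c(unaligned, names(reads)[i])
    } else {
      out[[length(out) + 1L]] <- aligned_read(
        id = names(reads)[i], contig = hit$contig, start = hit$start,
        strand = hit$strand, mapq = hit$mapq,
        read = reads[[i]], ref = hit$ref
      )
    }
  }
  attr(out, "unaligned") <- unaligned
  out
}

kmer_index <- function(reference, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (ctg in names(reference)) {
    s <- reference[[ctg]]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    sp <- split(starts, kmers)
    for (km in names(sp)) {
      prev <- if (exists(km, envir = env, inherits = FALSE))
        get(km, envir = env) else NULL
      assign(km, rbind(prev, cbind(match(ctg, names(reference)), sp[[km]])),
             envir = env)
    }
  }
  env
}

place_read <- function(read, reference, index, k) {
  L <- nchar(read)
  if (L < k) return(NULL)
  best <- NULL; best_mm <- Inf; ties <- 0L
  for (strand in c("+", "-")) {
    oriented <- if (strand == "+") read else revcomp(read)
    offs <- unique(c(seq(1L, L - k + 1L, by = k), L - k + 1L))
    cand <- unique(do.call(rbind, lapply(offs, function(o) {
      km <- substring(oriented, o, o + k - 1L)
      hits <- if (exists(km, envir = index, inherits = FALSE))
        get(km, envir = index) else NULL
      if (is.null(hits)) return(NULL)
      cbind(hits[, 1], hits[, 2] - o + 1L)   # contig idx, 1-based ref start
    })))
    if (is.null(cand)) next
    for (r in seq_len(nrow(cand))) {
      ci <- cand[r, 1]; st <- cand[r, 2]
      if (st < 1L || st + L - 1L > nchar(reference[[ci]])) next
      refseq <- substring(reference[[ci]], st, st + L - 1L)
      mm <- sum(strsplit(oriented, "", fixed = TRUE)[[1]] !=
                  strsplit(refseq, "", fixed = TRUE)[[1]])
      if (mm < best_mm) {
        best_mm <- mm; ties <- 1L
        best <- list(contig = names(reference)[ci], start = st - 1L,
                     strand = strand,
                     ref = if (strand == "+") refseq else revcomp(refseq))
      } else if (mm == best_mm) {
        ties <- ties + 1L
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$mapq <- if (ties == 1L) 60L else 0L
  best
}

#' Total-bases coverage of a reference
#'
#' @param alignments list of `aligned_read` objects.
#' @param reference_length reference length in bp.
#' @return total aligned bases divided by reference length.
#' @export
coverage <- function(alignments, reference_length) {
  stopifnot(reference_length > 0)
  sum(vapply(alignments, `[[`, integer(1), "length")) / reference_length
}
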