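#' Construct a read pair
#'
#' @param id read name.
#' @param seq1,seq2 mate sequences (R1, R2 as sequenced).
#' @param qual1,qual2 integer Phred vectors (or Phred+33 strings)
#'   matching the sequence lengths; values in \[0, 60\].
#' @return an object of class `read_pair`.
#' @export
read_pair <- function(id, seq1, qual1, seq2, qual2) {
  if (is.character(qual1) && length(qual1) == 1) qual1 <- phred_decode(qual1)
  if (is.character(qual2) && length(qual2) == 1) qual2 <- phred_decode(qual2)
  stopifnot(nchar(seq1) > 0, nchar(seq2) > 0,
            nchar(seq1) == length(qual1), nchar(seq2) == length(qual2),
            all(qual1 >= 0 & qual1 <= 60), all(qual2 >= 0 & qual2 <= 60))
  structure(list(id = id, seq1 = seq1, qual1 = as.integer(qual1),
                 seq2 = seq2, qual2 = as.integer(qual2)),
            class = "read_pair")
}

#' Merge a read pair into a consensus single-end read
#'
#' R2 is reverse-complemented (qualities reversed) and slid along R1:
#' candidate placements put the reoriented R2 at offset `s >= 0` from
#' the R1 start (R1 always begins at the fragment 5' end), covering both
#' geometries — a fragment longer than one read (R1-tail/R2-head
#' overlap) and a fragment short enough that one read contains the
#' other. A candidate with overlap >= `min_overlap` is valid when its
#' high-quality mismatches (both base qualities >= `hq_threshold`) do
#' not exceed `max_hq_mismatch` and its low-quality mismatches do not
#' exceed `max_lq_mismatch`. Among valid candidates the one with fewest
#' total mismatches wins, ties go to the longest overlap, and remaining
#' ties are rejected as ambiguous.
#'
#' Consensus arithmetic: at matching positions the base quality is the
#' maximum of the two base qualities; at mismatching positions the base
#' call of higher quality is retained and its quality is the difference
#' of the two; an equal-quality mismatch keeps the R1 base with
#' quality 0.
#'
#' @param pair a [read_pair()].
#' @param min_overlap minimum overlap length (bp).
#' @param hq_threshold base quality at or above which a mismatch counts
#'   as high-quality (classification uses the minimum of the two
#'   qualities at the position).
#' @param max_hq_mismatch,max_lq_mismatch mismatch budgets, applied
#'   simultaneously.
#' @return an object of class `merged_read` (fields `id`, `seq`, `qual`,
#'   `overlap_len`, `mismatches_high`, `mismatches_low`, `offset`) or of
#'   class `merge_rejection` (field `reason`, `"no_overlap"` or
#'   `"ambiguous"`).
#' @export
merge_pair <- function(pair, min_overlap = 15L, hq_threshold = 20L,
                       max_hq_mismatch = 1L, max_lq_mismatch = 3L) {
  stopifnot(inherits(pair, "read_pair"))
  if (min_overlap < 1) stop("min_overlap must be positive")
  c1 <- strsplit(pair$seq1, "", fixed = TRUE)[[1]]
  q1 <- pair$qual1
  c2 <- rev(comp_bases(strsplit(pair$seq2, "", fixed = TRUE)[[1]]))
  q2 <- rev(pair$qual2)
  len1 <- length(c1); len2 <- length(c2)

  if (len1 < min_overlap || len2 < min_overlap)
    return(structure(list(id = pair$id, reason = "no_overlap"),
                     class = "merge_rejection"))
  cand <- list()
  for (s in 0:(len1 - min_overlap)) {
    L <- min(len1, s + len2) - s
    if (L < min_overlap || L > len2) next
    i1 <- (s + 1L):(s + L)
    i2 <- seq_len(L)
    mm <- c1[i1] != c2[i2]
    qmin <- pmin(q1[i1], q2[i2])
    hq <- sum(mm & qmin >= hq_threshold)
    lq <- sum(mm & qmin < hq_threshold)
    if (hq <= max_hq_mismatch && lq <= max_lq_mismatch) {
      cand[[length(cand) + 1L]] <- list(s = s, L = L, hq = hq, lq = lq,
                                        total = hq + lq)
    }
  }
  if (length(cand) == 0)
    return(structure(list(id = pair$id, reason = "no_overlap"),
                     class = "merge_rejection"))
  tot <- vapply(cand, `[[`, numeric(1), "total")
  cand <- cand[tot == min(tot)]
  ov <- vapply(cand, `[[`, numeric(1), "L")
  cand <- cand[ov == max(ov)]
  if (length(cand) > 1)
    return(structure(list(id = pair$id, reason = "ambiguous"),
                     class = "merge_rejection"))
  ch <- cand[[1]]
  s <- ch$s; L <- ch$L
  i1 <- (s + 1L):(s + L)
  i2 <- seq_len(L)

  cons <- c1[i1]
  qcons <- pmax(q1[i1], q2[i2])
  mm <- which(c1[i1] != c2[i2])
  for (k in mm) {
    a <- q1[i1[k]]; b <- q2[i2[k]]
    if (a > b) {
      cons[k] <- c1[i1[k]]; qcons[k] <- a - b
    } else if (b > a) {
      cons[k] <- c2[i2[k]]; qcons[k] <- b - a
    } else {
      cons[k] <- c1[i1[k]]; qcons[k] <- 0L
    }
  }
  pre_s <- if (s > 0) c1[seq_len(s)] else character(0)
  pre_q <- if (s > 0) q1[seq_len(s)] else integer(0)
  if (s + len2 > len1) {
    suf_s <- c2[(L + 1L):len2]; suf_q <- q2[(L + 1L):len2]
  } else if (s + L < len1) {
    suf_s <- c1[(s + L + 1L):len1]; suf_q <- q1[(s + L + 1L):len1]
  } else {
    suf_s <- character(0); suf_q <- integer(0)
  }
  structure(list(id = pair$id,
                 seq = paste(c(pre_s, cons, suf_s), collapse = ""),
                 qual = as.integer(c(pre_q, qcons, suf_q)),
                 overlap_len = L, mismatches_high = ch$hq,
                 mismatches_low = ch$lq, offset = s),
            class = "merged_read")
}

#' Merge many pairs and report rejections
#'
#' @param pairs either a list of [read_pair()] objects or a data.frame
#'   with columns `id`, `seq1`, `qual1`, `seq2`, `qual2` (qualities as
#'   Phred+33 strings, e.g. from [simulate_read_pairs()]).
#' @inheritParams merge_pair
#' @return list with `merged` (list of `merged_read`) and `report`
#'   (data.frame `id`, `status`, `reason`).
#' @export
merge_pairs <- function(pairs, min_overlap = 15L, hq_threshold = 20L,
                        max_hq_mismatch = 1L, max_lq_mismatch = 3L) {
  if (is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) {
      read_pair(pairs$id[i], pairs$seq1[i], pairs$qual1[i],
                pairs$seq2[i], pairs$qual2[i])
    })
  }
  res <- lapply(pairs, merge_pair, min_overlap = min_overlap,
                hq_threshold = hq_threshold,
                max_hq_mismatch = max_hq_mismatch,
                max_lq_mismatch = max_lq_mismatch)
  ok <- vapply(res, inherits, logical(1), "merged_read")
  report <- data.frame(
    id = vapply(res, `[[`, character(1), "id"),
    status = ifelse(ok, "merged", "rejected"),
    reason = vapply(res, function(r)
      if (inherits(r, "merge_rejection")) r$reason else "", character(1)),
    stringsAsFactors = FALSE
  )
  list(merged = res[ok], report = report)
}

#' Write merged reads as single-end FASTQ
#'
#' @param merged list of `merged_read` objects.
#' @param path output FASTQ path.
#' @export
write_merged_fastq <- function(merged, path) {
  write_fastq(
    id = vapply(merged, `[[`, character(1), "id"),
    seq = vapply(merged, `[[`, character(1), "seq"),
    qual = vapply(merged, function(m) phred_encode(m$qual), character(1)),
    path = path
  )
}
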