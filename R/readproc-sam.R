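#' Write alignments to a SAM file
#'
#' Emits single-end records with an `M`-only CIGAR and an MD tag
#' computed from the stored read/reference strings, so the reference
#' bases can be reconstructed on read-back without the reference FASTA.
#' Internal coordinates are 0-based half-open; SAM output is 1-based.
#'
#' @param alignments list of `aligned_read` objects.
#' @param path output path.
#' @param reference_lengths named integer vector of contig lengths for
#'   the `@SQ` header lines.
#' @export
write_sam <- function(alignments, path, reference_lengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (ctg in names(reference_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ctg, reference_lengths[[ctg]]), con)
  }
  for (a in alignments) {
    fwd_read <- if (a$strand == "+") a$read else revcomp(a$read)
    fwd_ref <- if (a$strand == "+") a$ref else revcomp(a$ref)
    flag <- if (a$strand == "+") 0L else 16L
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tMD:Z:%s",
                       a$id, flag, a$contig, a$start + 1L, a$mapq,
                       a$length, fwd_read, strrep("I", a$length),
                       md_tag(fwd_read, fwd_ref)), con)
  }
  invisible(path)
}

# MD tag for an ungapped alignment, forward-strand orientation
md_tag <- function(read, ref) {
  rc <- strsplit(read, "", fixed = TRUE)[[1]]
  fc <- strsplit(ref, "", fixed = TRUE)[[1]]
  out <- character(0)
  run <- 0L
  for (i in seq_along(rc)) {
    if (rc[i] == fc[i]) {
      run <- run + 1L
    } else {
      out <- c(out, as.character(run), fc[i])
      run <- 0L
    }
  }
  paste(c(out, as.character(run)), collapse = "")
}

# expand an MD tag against the read to recover reference bases
# (ungapped alignments only; deletions are out of scope)
md_expand <- function(read, md) {
  if (grepl("^\\^", md) || grepl("[0-9]\\^", md))
    stop("MD tags with deletions are not supported")
  toks <- regmatches(md, gregexpr("[0-9]+|[A-Z]", md))[[1]]
  rc <- strsplit(read, "", fixed = TRUE)[[1]]
  fc <- rc
  pos <- 0L
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) {
      pos <- pos + as.integer(t)
    } else {
      pos <- pos + 1L
      fc[pos] <- t
    }
  }
  if (pos != length(rc)) stop("MD tag does not span the read")
  paste(fc, collapse = "")
}

#' Read alignments from a SAM file
#'
#' Uses Rsamtools for parsing (the SAM is converted to BAM internally).
#' Reference bases are reconstructed from the MD tag, or from a
#' supplied reference when MD tags are absent. Only ungapped (`M`-only
#' CIGAR) primary alignments are supported; reverse-strand records are
#' reoriented so position 1 is the sequenced 5' base.
#'
#' @param path SAM file path.
#' @param reference optional named character vector of contig sequences
#'   (required when records lack MD tags).
#' @return list of `aligned_read` objects.
#' @export
read_sam <- function(path, reference = NULL) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "seq", "cigar"),
    tag = "MD"
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (!grepl("^[0-9]+M$", x$cigar[i]))
      stop("read_sam supports ungapped (M-only) alignments")
    fwd_read <- as.character(x$seq[i])
    md <- x$tag$MD[i]
    if (!is.null(md) && !is.na(md)) {
      fwd_ref <- md_expand(fwd_read, md)
    } else if (!is.null(reference)) {
      ctg <- as.character(x$rname[i])
      fwd_ref <- substring(reference[[ctg]], x$pos[i],
                           x$pos[i] + nchar(fwd_read) - 1L)
    } else {
      stop("records lack MD tags and no reference was supplied")
    }
    rev <- bitwAnd(x$flag[i], 16L) != 0L
    out[[i]] <- aligned_read(
      id = x$qname[i], contig = as.character(x$rname[i]),
      start = x$pos[i] - 1L, strand = if (rev) "-" else "+",
      mapq = x$mapq[i],
      read = if (rev) revcomp(fwd_read) else fwd_read,
      ref = if (rev) revcomp(fwd_ref) else fwd_ref
    )
  }
  out
}
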