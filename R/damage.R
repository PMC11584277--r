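#' Substitution type labels (ordered base pairs X>Y, X != Y)
#' @keywords internal
#' @noRd
SUB_TYPES <- {
  g <- expand.grid(from = c("A", "C", "G", "T"), to = c("A", "C", "G", "T"),
                   stringsAsFactors = FALSE)
  g <- g[g$from != g$to, ]
  g <- g[order(g$from, g$to), ]
  paste0(g$from, ">", g$to)
}

#' Build a per-position misincorporation profile
#'
#' Counts, for each position from the 5' end and (independently) from
#' the 3' end, every substitution type X>Y against the number of reads
#' offering the opportunity (reference base X at that position).
#' Alignments must be in sequenced orientation ([aligned_read()] stores
#' them that way), so reverse-strand reads need no special handling
#' here. Rates are `NA` where a position has zero opportunities.
#'
#' @param alignments list of `aligned_read` objects (one read group).
#' @param window number of positions profiled from each end.
#' @return an object of class `damage_profile`: list with `window`,
#'   `five_prime` and `three_prime` (each a list of `rate` and `count`
#'   `window x 12` matrices plus an `opportunity` `window x 4` matrix),
#'   `n_reads` and `lengths`.
#' @export
build_profile <- function(alignments, window = 25L) {
  window <- as.integer(window)
  n <- length(alignments)
  if (n == 0) {
    empty <- end_profile(matrix(character(0), 0, window),
                         matrix(character(0), 0, window), window)
    return(structure(list(window = window, five_prime = empty,
                          three_prime = empty, n_reads = 0L,
                          lengths = integer(0)),
                     class = "damage_profile"))
  }
  reads <- vapply(alignments, `[[`, character(1), "read")
  refs <- vapply(alignments, `[[`, character(1), "ref")
  lens <- vapply(alignments, `[[`, integer(1), "length")
  five <- end_profile(char_matrix(reads, window, "start"),
                      char_matrix(refs, window, "start"), window)
  three <- end_profile(char_matrix(reads, window, "end"),
                       char_matrix(refs, window, "end"), window)
  structure(list(window = window, five_prime = five, three_prime = three,
                 n_reads = n, lengths = lens),
            class = "damage_profile")
}

end_profile <- function(readm, refm, window) {
  count <- matrix(0L, window, length(SUB_TYPES),
                  dimnames = list(NULL, SUB_TYPES))
  opp <- matrix(0L, window, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (j in seq_len(window)) {
    ok <- !is.na(refm[, j]) & !is.na(readm[, j])
    if (!any(ok)) next
    rf <- factor(refm[ok, j], levels = c("A", "C", "G", "T"))
    opp[j, ] <- tabulate(rf, nbins = 4)
    mism <- ok & refm[, j] != readm[, j]
    if (any(mism)) {
      sub <- factor(paste0(refm[mism, j], ">", readm[mism, j]),
                    levels = SUB_TYPES)
      count[j, ] <- tabulate(sub, nbins = length(SUB_TYPES))
    }
  }
  denom <- opp[, substring(SUB_TYPES, 1, 1), drop = FALSE]
  rate <- count / denom
  rate[denom == 0] <- NA_real_
  colnames(rate) <- SUB_TYPES
  list(rate = rate, count = count, opportunity = opp)
}

#' Three-criterion ancient/modern classification of a read group
#'
#' Scores a misincorporation profile against the damage-authentication
#' criteria for UDG-half libraries, each required at *both* ends
#' (C>T at the 5' end, G>A at the 3' end):
#'
#' 1. the terminal (position 1) damage rate is the strict maximum of
#'    that substitution's rates over positions 1–10;
#' 2. the terminal damage rate exceeds the mean + 2 SD of the other 11
#'    substitution types' rates at position 1;
#' 3. away from the terminus the damage substitution stays within the
#'    background band: its rate aggregated over positions 2–11 is below
#'    the mean + 2 SD of the other substitution types' per-position
#'    rates pooled over those positions.
#'
#' Criterion 3 aggregates the ten interior positions into a single test
#' per end: a per-position two-sigma test would reject a clean group at
#' each of twenty positions with a few percent probability each, making
#' the criterion fail most authentic groups on count noise alone, while
#' the aggregate keeps full power against interior (contamination-like)
#' elevation. SDs are sample SDs (n-1). Undefined rates (zero
#' opportunities) make the affected criterion false, with a diagnostic.
#'
#' @param profile a [build_profile()] result covering at least 11
#'   positions per end.
#' @param min_reads groups with fewer reads are flagged low-confidence.
#' @return an object of class `ancient_score`: list with `criteria`
#'   (named logical of length 3), `score` (0–3), `diagnostics`
#'   (per-criterion observed value and threshold, per end),
#'   `low_confidence` and `n_reads`.
#' @export
classify_group <- function(profile, min_reads = 100L) {
  stopifnot(inherits(profile, "damage_profile"))
  if (profile$window < 11)
    stop("classification needs a profile window of at least 11 positions")
  e5 <- end_criteria(profile$five_prime, "C>T")
  e3 <- end_criteria(profile$three_prime, "G>A")
  criteria <- c(
    terminal_max = isTRUE(e5$c1) && isTRUE(e3$c1),
    terminal_elevated = isTRUE(e5$c2) && isTRUE(e3$c2),
    interior_background = isTRUE(e5$c3) && isTRUE(e3$c3)
  )
  structure(list(
    criteria = criteria,
    score = sum(criteria),
    diagnostics = list(five_prime = e5$diag, three_prime = e3$diag),
    low_confidence = profile$n_reads < min_reads,
    n_reads = profile$n_reads
  ), class = "ancient_score")
}

end_criteria <- function(end, focal) {
  rate <- end$rate
  others <- setdiff(SUB_TYPES, focal)
  r1 <- rate[1, focal]
  thr2 <- NA_real_
  thr3 <- NA_real_
  # criterion 1: strict maximum over positions 1..10
  c1 <- if (anyNA(rate[1:10, focal])) NA else all(r1 > rate[2:10, focal])
  # criterion 2: above the cross-substitution band at position 1
  o1 <- rate[1, others]
  c2 <- if (is.na(r1) || sum(!is.na(o1)) < 2) NA else {
    thr2 <- mean(o1, na.rm = TRUE) + 2 * sd(o1, na.rm = TRUE)
    r1 > thr2
  }
  # criterion 3: interior positions 2..11 within the pooled background band
  fb <- substring(focal, 1, 1)
  icount <- sum(end$count[2:11, focal])
  iopp <- sum(end$opportunity[2:11, fb])
  band <- as.vector(rate[2:11, others])
  c3 <- if (iopp == 0 || sum(!is.na(band)) < 2) NA else {
    thr3 <- mean(band, na.rm = TRUE) + 2 * sd(band, na.rm = TRUE)
    (icount / iopp) < thr3
  }
  list(c1 = c1, c2 = c2, c3 = c3,
       diag = data.frame(
         criterion = 1:3,
         observed = c(r1, r1, if (iopp > 0) icount / iopp else NA_real_),
         threshold = c(if (anyNA(rate[1:10, focal])) NA_real_
                       else max(rate[2:10, focal]),
                       thr2, thr3),
         defined = !is.na(c(c1, c2, c3))
       ))
}

#' Read-length summary of a profile
#'
#' @param profile a [build_profile()] result with at least one read.
#' @param binwidth histogram bin width (bp).
#' @return list with `median`, `iqr` and `histogram` (data.frame of bin
#'   `mid` and `count`; counts sum to `n_reads`).
#' @export
length_summary <- function(profile, binwidth = 5L) {
  stopifnot(inherits(profile, "damage_profile"), profile$n_reads >= 1)
  x <- profile$lengths
  breaks <- seq(floor(min(x) / binwidth) * binwidth,
                ceiling((max(x) + 1) / binwidth) * binwidth, by = binwidth)
  h <- hist(x, breaks = breaks, plot = FALSE, right = FALSE)
  list(median = median(x), iqr = unname(diff(quantile(x, c(0.25, 0.75)))),
       histogram = data.frame(mid = h$mids, count = h$counts))
}

#' Export / import a misincorporation profile as TSV
#'
#' The table layout (end, position, substitution, count, opportunity,
#' rate) follows the spirit of mapDamage misincorporation files; read
#' lengths are stored alongside with `end = "length"`.
#'
#' @param profile a `damage_profile`.
#' @param path TSV path.
#' @export
export_profile <- function(profile, path) {
  rows <- function(end, label) {
    do.call(rbind, lapply(seq_len(profile$window), function(p) {
      data.frame(end = label, pos = p, sub = SUB_TYPES,
                 count = end$count[p, ],
                 opportunity = end$opportunity[p, substring(SUB_TYPES, 1, 1)],
                 rate = end$rate[p, ], stringsAsFactors = FALSE)
    }))
  }
  tab <- rbind(rows(profile$five_prime, "5p"), rows(profile$three_prime, "3p"))
  lens <- data.frame(end = "length", pos = profile$lengths, sub = "",
                     count = NA_integer_, opportunity = NA_integer_,
                     rate = NA_real_)
  write.table(rbind(tab, lens), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname export_profile
#' @return `import_profile()` returns the reconstructed `damage_profile`
#'   (counts, opportunities, rates, lengths, `n_reads`).
#' @export
import_profile <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  lens <- tab$pos[tab$end == "length"]
  tab <- tab[tab$end != "length", ]
  window <- max(tab$pos)
  rebuild <- function(label) {
    sub <- tab[tab$end == label, ]
    count <- matrix(0L, window, length(SUB_TYPES),
                    dimnames = list(NULL, SUB_TYPES))
    opp <- matrix(0L, window, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    count[cbind(sub$pos, match(sub$sub, SUB_TYPES))] <- sub$count
    first <- substring(sub$sub, 1, 1)
    opp[cbind(sub$pos, match(first, c("A", "C", "G", "T")))] <- sub$opportunity
    denom <- opp[, substring(SUB_TYPES, 1, 1), drop = FALSE]
    rate <- count / denom
    rate[denom == 0] <- NA_real_
    colnames(rate) <- SUB_TYPES
    list(rate = rate, count = count, opportunity = opp)
  }
  structure(list(window = window, five_prime = rebuild("5p"),
                 three_prime = rebuild("3p"), n_reads = length(lens),
                 lengths = as.integer(lens)),
            class = "damage_profile")
}
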