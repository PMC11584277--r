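# Independent brute-force oracles used to pin down expected values.
# These are deliberately literal, position-by-position implementations
# kept free of the package's vectorised code paths.

# Exhaustive-offset merge oracle: applies the overlap/consensus rules
# one position at a time for every candidate offset.
oracle_merge <- function(seq1, qual1, seq2, qual2,
                         min_overlap = 15L, hq_threshold = 20L,
                         max_hq = 1L, max_lq = 3L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  c1 <- strsplit(seq1, "")[[1]]
  c2raw <- strsplit(seq2, "")[[1]]
  c2 <- rev(unname(comp[c2raw]))
  q2 <- rev(qual2)
  q1 <- qual1
  len1 <- length(c1); len2 <- length(c2)
  valid <- list()
  if (len1 >= min_overlap && len2 >= min_overlap) {
    for (s in 0:(len1 - min_overlap)) {
      L <- min(len1, s + len2) - s
      if (L < min_overlap) next
      hq <- 0L; lq <- 0L
      for (k in seq_len(L)) {
        b1 <- c1[s + k]; b2 <- c2[k]
        if (b1 != b2) {
          if (min(q1[s + k], q2[k]) >= hq_threshold) hq <- hq + 1L
          else lq <- lq + 1L
        }
      }
      if (hq <= max_hq && lq <= max_lq)
        valid[[length(valid) + 1L]] <- c(s = s, L = L, total = hq + lq)
    }
  }
  if (length(valid) == 0) return(list(status = "no_overlap"))
  tot <- vapply(valid, `[[`, numeric(1), "total")
  valid <- valid[tot == min(tot)]
  Ls <- vapply(valid, `[[`, numeric(1), "L")
  valid <- valid[Ls == max(Ls)]
  if (length(valid) > 1) return(list(status = "ambiguous"))
  s <- valid[[1]][["s"]]; L <- valid[[1]][["L"]]
  out_s <- character(0); out_q <- integer(0)
  for (k in seq_len(s)) {
    out_s <- c(out_s, c1[k]); out_q <- c(out_q, q1[k])
  }
  for (k in seq_len(L)) {
    b1 <- c1[s + k]; b2 <- c2[k]; a <- q1[s + k]; b <- q2[k]
    if (b1 == b2) {
      out_s <- c(out_s, b1); out_q <- c(out_q, max(a, b))
    } else if (a > b) {
      out_s <- c(out_s, b1); out_q <- c(out_q, a - b)
    } else if (b > a) {
      out_s <- c(out_s, b2); out_q <- c(out_q, b - a)
    } else {
      out_s <- c(out_s, b1); out_q <- c(out_q, 0L)
    }
  }
  if (s + len2 > len1) {
    for (k in (L + 1L):len2) {
      out_s <- c(out_s, c2[k]); out_q <- c(out_q, q2[k])
    }
  } else if (s + L < len1) {
    for (k in (s + L + 1L):len1) {
      out_s <- c(out_s, c1[k]); out_q <- c(out_q, q1[k])
    }
  }
  list(status = "merged", offset = s,
       seq = paste(out_s, collapse = ""), qual = out_q)
}

# Random read pairs with mixed geometries and injected mismatches of
# both quality classes; returns a data.frame consumable by merge_pairs.
random_merge_pairs <- function(n, read_len = 101L, seed = 1) {
  set.seed(seed)
  ref <- coralaDNA::simulate_reference(1, 5000, 0.5)
  flen <- coralaDNA::fragment_length_dist("lognormal", mean = 80, sdlog = 0.5,
                                          min_len = 20, max_len = 180)
  frags <- coralaDNA::simulate_fragments(ref, n, flen)
  pairs <- coralaDNA::simulate_read_pairs(frags$seq, read_len,
                                          qual_mean = 30, qual_sd = 8)
  inject <- function(seq, qual) {
    ch <- strsplit(seq, "")[[1]]
    qv <- coralaDNA::phred_decode(qual)
    k <- sample(0:3, 1)
    if (k > 0) {
      pos <- sample(length(ch), min(k, length(ch)))
      for (p in pos) {
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
        # mix of confident and doubtful miscalls around the q20 class cut
        qv[p] <- sample(c(5, 15, 19, 20, 25, 35), 1)
      }
    }
    list(seq = paste(ch, collapse = ""), qual = coralaDNA::phred_encode(qv))
  }
  for (i in seq_len(n)) {
    a <- inject(pairs$seq1[i], pairs$qual1[i])
    b <- inject(pairs$seq2[i], pairs$qual2[i])
    pairs$seq1[i] <- a$seq; pairs$qual1[i] <- a$qual
    pairs$seq2[i] <- b$seq; pairs$qual2[i] <- b$qual
  }
  pairs
}

# checks one pair against the oracle; returns TRUE on full agreement
merge_agrees <- function(row, ...) {
  res <- coralaDNA::merge_pair(coralaDNA::read_pair(
    row$id, row$seq1, row$qual1, row$seq2, row$qual2), ...)
  orc <- oracle_merge(row$seq1, coralaDNA::phred_decode(row$qual1),
                      row$seq2, coralaDNA::phred_decode(row$qual2), ...)
  if (inherits(res, "merge_rejection")) {
    return(identical(res$reason, orc$status))
  }
  orc$status == "merged" &&
    res$offset == orc$offset &&
    identical(res$seq, orc$seq) &&
    identical(as.integer(res$qual), as.integer(orc$qual))
}

# Exhaustive hypergeometric enumeration of the two-sided Fisher p-value
# for a 2x2 table, using exact binomial coefficients.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  tot <- choose(r1 + r2, k)
  prob_a <- function(x) choose(r1, x) * choose(r2, k - x) / tot
  support <- max(0, k - r2):min(r1, k)
  probs <- vapply(support, prob_a, numeric(1))
  p_obs <- prob_a(a)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# fraction of the ten 5'-interior positions etc. -- small shared helpers
pooled_rate <- function(end, type, positions) {
  fb <- substr(type, 1, 1)
  sum(end$count[positions, type]) / sum(end$opportunity[positions, fb])
}

# ancient / modern / contaminated read-group factories (study conditions)
sim_group_profile <- function(kind = c("ancient", "modern", "uniform"),
                              n_reads = 5000, d_max = 0.10,
                              background = 0.002, reference) {
  kind <- match.arg(kind)
  flen <- coralaDNA::fragment_length_dist("lognormal", mean = 45,
                                          sdlog = 0.35, min_len = 20,
                                          max_len = 150)
  if (kind == "uniform") {
    # contamination-like construction: damage-type substitutions at a
    # uniform rate across ALL positions, both ends
    frags <- coralaDNA::simulate_fragments(reference, n_reads, flen)
    alns <- uniform_damage_alignments(frags, rate = d_max,
                                      background = background)
    return(coralaDNA::build_profile(alns))
  }
  model <- coralaDNA::damage_model(
    d_max = if (kind == "ancient") d_max else 0,
    decay = 3, udg_half_cutoff = 2L, background_error = background)
  g <- coralaDNA::simulate_read_group(reference, n_reads, flen, model)
  coralaDNA::build_profile(g)
}

uniform_damage_alignments <- function(frags, rate, background) {
  n <- nrow(frags)
  alns <- vector("list", n)
  for (i in seq_len(n)) {
    ch <- strsplit(frags$seq[i], "")[[1]]
    damaged <- ch
    u <- runif(length(ch))
    damaged[ch == "C" & u < rate] <- "T"
    damaged[ch == "G" & u < rate] <- "A"
    e <- runif(length(ch)) < background & damaged == ch
    if (any(e)) {
      for (p in which(e))
        damaged[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    alns[[i]] <- coralaDNA::aligned_read(
      id = paste0("u", i), contig = frags$contig[i], start = frags$start[i],
      strand = frags$strand[i], mapq = 60L,
      read = paste(damaged, collapse = ""), ref = frags$seq[i])
  }
  alns
}

# nearest-population-centroid lookup in PC space
nearest_centroid <- function(fit, coords) {
  pops <- sub("_s[0-9]+$", "", fit$sample_id)
  cent <- vapply(unique(pops), function(p)
    colMeans(fit$scores[pops == p, , drop = FALSE]), numeric(ncol(fit$scores)))
  dists <- colSums((cent - coords)^2)
  names(which.min(dists))
}
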