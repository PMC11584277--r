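#' Ancient-DNA damage model (UDG-half)
#'
#' Parametrises terminal cytosine deamination as observed in
#' partial-UDG ("UDG-half") treated libraries: C-to-T substitutions at
#' the 5' end and the mirrored G-to-A substitutions at the 3' end, at a
#' rate that decays geometrically into the read and is cut off beyond a
#' fixed position (interior uracils are enzymatically repaired).
#'
#' The deamination probability at position `i` (1-based, counted from
#' the relevant end) is `d_max * exp(-decay * (i - 1))` for
#' `i <= udg_half_cutoff` and 0 beyond the cutoff. An independent
#' uniform sequencing-error probability applies everywhere.
#'
#' @param d_max deamination probability at position 1, in \[0, 1\].
#' @param decay per-position exponential decay constant (>= 0).
#' @param udg_half_cutoff integer position beyond which deamination is
#'   forced to zero (0 disables deamination entirely).
#' @param background_error per-base probability of a uniform sequencing
#'   error (substitution to one of the three alternative bases).
#' @return an object of class `damage_model`.
#' @export
damage_model <- function(d_max = 0.10, decay = 3, udg_half_cutoff = 2L,
                         background_error = 0.001) {
  stopifnot(d_max >= 0, d_max <= 1, decay >= 0, udg_half_cutoff >= 0,
            background_error >= 0, background_error <= 1)
  structure(list(d_max = d_max, decay = decay,
                 udg_half_cutoff = as.integer(udg_half_cutoff),
                 background_error = background_error),
            class = "damage_model")
}

#' Deamination probability by position
#'
#' @param model a [damage_model()].
#' @param pos integer vector of positions (1-based, from the relevant end).
#' @return numeric vector of deamination probabilities (excludes the
#'   background error).
#' @export
deamination_prob <- function(model, pos) {
  p <- model$d_max * exp(-model$decay * (pos - 1))
  p[pos > model$udg_half_cutoff] <- 0
  p
}

#' Fragment length distribution
#'
#' @param family `"lognormal"` or `"geometric"` (shifted geometric,
#'   support starting at `min_len`).
#' @param mean target mean fragment length (bp).
#' @param sdlog log-scale SD for the lognormal family.
#' @param min_len,max_len inclusive length bounds; sampling is by
#'   rejection so all lengths fall inside the bounds.
#' @return an object of class `fragment_length_dist`.
#' @export
fragment_length_dist <- function(family = c("lognormal", "geometric"),
                                 mean = 45, sdlog = 0.35,
                                 min_len = 20L, max_len = 150L) {
  family <- match.arg(family)
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (min_len < 20L) stop("min_len must be >= 20")
  if (max_len < min_len) stop("max_len must be >= min_len")
  if (mean <= min_len && family == "geometric")
    stop("mean must exceed min_len for the shifted geometric family")
  structure(list(family = family, mean = mean, sdlog = sdlog,
                 min_len = min_len, max_len = max_len),
            class = "fragment_length_dist")
}

#' Sample fragment lengths
#'
#' @param flen a [fragment_length_dist()].
#' @param n number of lengths.
#' @param seed optional RNG seed.
#' @return integer vector of lengths within `[min_len, max_len]`.
#' @export
sample_fragment_lengths <- function(flen, n, seed = NULL) {
  with_seed(seed)
  draw <- function(m) {
    if (flen$family == "lognormal") {
      # meanlog chosen so the arithmetic mean of the untruncated law is flen$mean
      meanlog <- log(flen$mean) - flen$sdlog^2 / 2
      as.integer(round(rlnorm(m, meanlog, flen$sdlog)))
    } else {
      p <- 1 / (flen$mean - flen$min_len + 1)
      flen$min_len + rgeom(m, p)
    }
  }
  out <- integer(0)
  while (length(out) < n) {
    x <- draw(max(n, 1000L))
    out <- c(out, x[x >= flen$min_len & x <= flen$max_len])
  }
  out[seq_len(n)]
}

#' Simulate a reference sequence set
#'
#' @param n_contigs number of contigs.
#' @param contig_lengths integer vector (recycled to `n_contigs`) of
#'   contig lengths, each >= 100.
#' @param gc target GC fraction in (0, 1).
#' @param seed optional RNG seed.
#' @return named character vector of contig sequences (FASTA-writable
#'   with [write_fasta()]).
#' @export
simulate_reference <- function(n_contigs = 1L, contig_lengths = 10000L,
                               gc = 0.41, seed = NULL) {
  if (n_contigs < 1) stop("n_contigs must be positive")
  contig_lengths <- rep_len(as.integer(contig_lengths), n_contigs)
  if (any(contig_lengths < 100)) stop("contig lengths must be >= 100")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  with_seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(contig_lengths, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  setNames(seqs, sprintf("contig%d", seq_len(n_contigs)))
}

#' Simulate fragments from a reference
#'
#' Fragment start positions are uniform within each contig, contigs are
#' chosen proportional to length, and the strand is uniform. A
#' reverse-strand fragment's sequence is the reverse complement of the
#' reference slice.
#'
#' @param reference named character vector of contig sequences.
#' @param n number of fragments (> 0).
#' @param flen a [fragment_length_dist()]; `max_len` must not exceed the
#'   shortest contig.
#' @param seed optional RNG seed.
#' @return data.frame with columns `contig`, `start` (0-based), `length`,
#'   `strand` and `seq`.
#' @export
simulate_fragments <- function(reference, n, flen, seed = NULL) {
  if (n <= 0) stop("n must be positive")
  clen <- nchar(reference)
  if (flen$max_len > min(clen)) stop("max_len exceeds the shortest contig")
  with_seed(seed)
  lens <- sample_fragment_lengths(flen, n)
  ci <- sample.int(length(reference), n, replace = TRUE, prob = clen)
  start <- floor(runif(n) * (clen[ci] - lens + 1))    # 0-based
  strand <- sample(c("+", "-"), n, replace = TRUE)
  fwd <- substring(reference[ci], start + 1L, start + lens)
  seq <- ifelse(strand == "+", fwd, revcomp(fwd))
  data.frame(contig = names(reference)[ci], start = as.integer(start),
             length = lens, strand = strand, seq = unname(seq),
             stringsAsFactors = FALSE)
}

#' Apply UDG-half deamination damage to fragment sequences
#'
#' C bases near the 5' end flip to T with probability
#' `d_max * exp(-decay * (i - 1))` for positions `i` up to the UDG-half
#' cutoff; G bases near the 3' end flip to A under the mirrored rule.
#' Every position not deaminated is additionally subject to a uniform
#' sequencing error (`background_error`, split evenly over the three
#' alternative bases).
#'
#' @param seqs character vector of fragment sequences over A/C/G/T.
#' @param model a [damage_model()].
#' @param seed optional RNG seed.
#' @return list with `seq` (damaged sequences) and `truth`, a data.frame
#'   of every alteration (`fragment`, `pos` from the 5' end, `type` one
#'   of `"CT5"`, `"GA3"`, `"error"`, `orig`, `new`).
#' @export
apply_damage <- function(seqs, model, seed = NULL) {
  stopifnot(inherits(model, "damage_model"))
  with_seed(seed)
  n <- length(seqs)
  lens <- nchar(seqs)
  if (n == 0) return(list(seq = seqs, truth = empty_truth()))
  v <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  frag <- rep.int(seq_len(n), lens)
  pos5 <- sequence(lens)
  pos3 <- rep.int(lens, lens) - pos5 + 1L

  u <- runif(length(v))
  flip5 <- v == "C" & u < deamination_prob(model, pos5)
  flip3 <- v == "G" & u < deamination_prob(model, pos3) & !flip5
  err <- runif(length(v)) < model$background_error & !flip5 & !flip3

  newv <- v
  newv[flip5] <- "T"
  newv[flip3] <- "A"
  if (any(err)) {
    # uniform choice among the three alternative bases
    alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                  nrow = 4, byrow = TRUE,
                  dimnames = list(DNA_BASES, NULL))
    k <- sample.int(3L, sum(err), replace = TRUE)
    newv[err] <- alt[cbind(match(v[err], DNA_BASES), k)]
  }

  changed <- which(newv != v)
  truth <- if (length(changed)) {
    type <- character(length(changed))
    type[flip5[changed]] <- "CT5"
    type[flip3[changed]] <- "GA3"
    type[err[changed]] <- "error"
    data.frame(fragment = frag[changed], pos = pos5[changed], type = type,
               orig = v[changed], new = newv[changed],
               stringsAsFactors = FALSE)
  } else empty_truth()

  out <- seqs
  for (i in seq_along(changed)) {
    j <- changed[i]
    substr(out[frag[j]], pos5[j], pos5[j]) <- truth$new[i]
  }
  list(seq = out, truth = truth)
}

empty_truth <- function() {
  data.frame(fragment = integer(0), pos = integer(0), type = character(0),
             orig = character(0), new = character(0), stringsAsFactors = FALSE)
}

#' Simulate paired-end reads from fragments
#'
#' Adapter-free geometry: R1 reads the first `read_len` bases of the
#' fragment (5' to 3'), R2 the reverse complement of the last `read_len`
#' bases. A fragment shorter than `read_len` yields a fully overlapping
#' pair. Base qualities are drawn from a normal distribution, rounded
#' and clamped to \[2, 41\]; no sequencing errors are injected beyond
#' whatever damage the fragments already carry.
#'
#' @param seqs character vector of (damaged) fragment sequences.
#' @param read_len read length in bp (>= 20); the study layout is
#'   2 x 101 bp.
#' @param qual_mean,qual_sd normal parameters of the per-base Phred
#'   quality scores.
#' @param seed optional RNG seed.
#' @return data.frame with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`
#'   (qualities as Phred+33 strings).
#' @export
simulate_read_pairs <- function(seqs, read_len = 101L, qual_mean = 37,
                                qual_sd = 3, seed = NULL) {
  if (read_len < 20) stop("read_len must be >= 20")
  with_seed(seed)
  n <- length(seqs)
  lens <- nchar(seqs)
  l1 <- pmin(lens, read_len)
  seq1 <- substring(seqs, 1L, l1)
  seq2 <- revcomp(substring(seqs, lens - l1 + 1L, lens))
  rq <- function(m) {
    paste(phred_chars()[pmin(pmax(round(rnorm(m, qual_mean, qual_sd)), 2), 41) + 1L],
          collapse = "")
  }
  qual1 <- vapply(l1, rq, character(1))
  qual2 <- vapply(l1, rq, character(1))
  data.frame(id = sprintf("frag%d", seq_len(n)), seq1 = seq1, qual1 = qual1,
             seq2 = seq2, qual2 = qual2, stringsAsFactors = FALSE)
}

phred_chars <- function() strsplit(intToUtf8(33:33 + 0:93), "")[[1]]

#' Simulate a damaged, aligned read group
#'
#' Convenience composition of [simulate_fragments()] and
#' [apply_damage()] that returns alignments ready for
#' [build_profile()]: the read is the damaged fragment in sequenced
#' orientation and the reference string is the pre-damage fragment, so
#' every mismatch is a simulated misincorporation.
#'
#' @inheritParams simulate_fragments
#' @param model a [damage_model()].
#' @return list of `aligned_read` objects (see [naive_align()]).
#' @export
simulate_read_group <- function(reference, n, flen, model, seed = NULL) {
  with_seed(seed)
  frags <- simulate_fragments(reference, n, flen)
  dmg <- apply_damage(frags$seq, model)
  alns <- vector("list", n)
  for (i in seq_len(n)) {
    alns[[i]] <- aligned_read(
      id = sprintf("read%d", i), contig = frags$contig[i],
      start = frags$start[i], strand = frags$strand[i], mapq = 60L,
      read = dmg$seq[i], ref = frags$seq[i]
    )
  }
  attr(alns, "truth") <- dmg$truth
  alns
}

#' Population-simulation configuration
#'
#' Frequencies drift independently around a shared ancestral frequency:
#' `p_pop = p0 + Normal(0, sqrt(drift * p0 * (1 - p0)))`, truncated to
#' \[0, 1\]. An optional hybrid population has frequency
#' `alpha * p_C + (1 - alpha) * p_D` where C and D are the last two
#' regular populations. SNVs are assigned round-robin to `n_blocks`
#' chromosome blocks (default 16, mirroring 14 chromosome-level
#' scaffolds plus two pseudo-chromosomes).
#'
#' @param n_pops number of regular populations.
#' @param drift per-population drift parameter (variance scale, Fst-like).
#' @param n_snvs number of biallelic SNVs.
#' @param n_blocks number of chromosome blocks.
#' @param samples_per_pop diploid samples per population.
#' @param admixture_alpha mixing fraction for the optional hybrid
#'   population (`NA` = no hybrid).
#' @param ancient_missing_rate default missingness for ancient-like
#'   pseudohaploid samples derived from this simulation.
#' @param seed RNG seed.
#' @return an object of class `pop_sim_config`.
#' @export
pop_sim_config <- function(n_pops = 4L, drift = 0.02, n_snvs = 20000L,
                           n_blocks = 16L, samples_per_pop = 10L,
                           admixture_alpha = NA_real_,
                           ancient_missing_rate = 0.9, seed = NULL) {
  stopifnot(n_pops >= 1, drift >= 0, n_snvs >= 1, n_blocks >= 1,
            samples_per_pop >= 1,
            is.na(admixture_alpha) ||
              (admixture_alpha >= 0 && admixture_alpha <= 1),
            ancient_missing_rate >= 0, ancient_missing_rate < 1)
  if (!is.na(admixture_alpha) && n_pops < 2)
    stop("a hybrid population needs at least two regular populations")
  structure(list(n_pops = as.integer(n_pops), drift = drift,
                 n_snvs = as.integer(n_snvs), n_blocks = as.integer(n_blocks),
                 samples_per_pop = as.integer(samples_per_pop),
                 admixture_alpha = admixture_alpha,
                 ancient_missing_rate = ancient_missing_rate, seed = seed),
            class = "pop_sim_config")
}

#' Simulate a multi-population genotype matrix
#'
#' @param cfg a [pop_sim_config()].
#' @return a [genotype_matrix()] with attribute `truth`: list of `p0`
#'   (ancestral frequencies), `pop_freqs` (populations x SNVs) and
#'   `alpha`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "pop_sim_config"))
  with_seed(cfg$seed)
  pops <- sprintf("P%d", seq_len(cfg$n_pops))
  hybrid <- !is.na(cfg$admixture_alpha)
  all_pops <- if (hybrid) c(pops, "H") else pops
  n_pop_total <- length(all_pops)
  n_samp <- n_pop_total * cfg$samples_per_pop

  keep_p0 <- numeric(0)
  keep_freq <- matrix(numeric(0), nrow = n_pop_total, ncol = 0)
  keep_dos <- matrix(integer(0), nrow = n_samp, ncol = 0)
  while (ncol(keep_dos) < cfg$n_snvs) {
    m <- max(cfg$n_snvs - ncol(keep_dos) + 50L, 200L)
    p0 <- runif(m, 0.05, 0.95)
    freq <- matrix(NA_real_, n_pop_total, m)
    for (k in seq_len(cfg$n_pops)) {
      freq[k, ] <- pmin(pmax(p0 + rnorm(m, 0, sqrt(cfg$drift * p0 * (1 - p0))), 0), 1)
    }
    if (hybrid) {
      a <- cfg$admixture_alpha
      freq[n_pop_total, ] <- a * freq[cfg$n_pops - 1L, ] + (1 - a) * freq[cfg$n_pops, ]
    }
    dos <- matrix(rbinom(n_samp * m, 2L,
                         rep(freq[rep(seq_len(n_pop_total),
                                      each = cfg$samples_per_pop), ],
                             1)),
                  nrow = n_samp)
    # biallelic in the pooled (modern) samples: polymorphic dosage column
    tot <- colSums(dos)
    ok <- tot > 0L & tot < 2L * n_samp
    keep_p0 <- c(keep_p0, p0[ok])
    keep_freq <- cbind(keep_freq, freq[, ok, drop = FALSE])
    keep_dos <- cbind(keep_dos, dos[, ok, drop = FALSE])
  }
  idx <- seq_len(cfg$n_snvs)
  p0 <- keep_p0[idx]
  freq <- keep_freq[, idx, drop = FALSE]
  dos <- keep_dos[, idx, drop = FALSE]

  block <- ((idx - 1L) %% cfg$n_blocks) + 1L
  ra <- matrix(DNA_BASES[ceiling(4 * runif(2 * cfg$n_snvs))], ncol = 2)
  same <- ra[, 1] == ra[, 2]
  ra[same, 2] <- DNA_BASES[(match(ra[same, 1], DNA_BASES)) %% 4 + 1]
  snvs <- data.frame(
    block = sprintf("chr%d", block),
    pos = as.integer(stats::ave(idx, block, FUN = seq_along) * 100L),
    ref = ra[, 1], alt = ra[, 2], stringsAsFactors = FALSE
  )
  samples <- data.frame(
    id = sprintf("%s_s%d", rep(all_pops, each = cfg$samples_per_pop),
                 rep(seq_len(cfg$samples_per_pop), n_pop_total)),
    population = rep(all_pops, each = cfg$samples_per_pop),
    era = "modern", stringsAsFactors = FALSE
  )
  rownames(dos) <- samples$id
  gm <- genotype_matrix(snvs, samples, dos)
  attr(gm, "truth") <- list(p0 = p0, pop_freqs = freq,
                            alpha = cfg$admixture_alpha)
  gm
}

#' Degrade a diploid sample into an ancient-like pseudohaploid sample
#'
#' Each retained SNV carries a single allele sampled from the diploid
#' genotype (dosage 0 or 2; heterozygotes resolve by a fair coin); a
#' fraction `missing_rate` of SNVs is set missing.
#'
#' @param dosages integer vector of diploid dosages (0/1/2, `NA` allowed).
#' @param missing_rate fraction of SNVs to drop, in \[0, 1).
#' @param seed optional RNG seed.
#' @return integer vector over \{0, 2, `NA`\}.
#' @export
make_ancient_like <- function(dosages, missing_rate = 0.9, seed = NULL) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  with_seed(seed)
  out <- dosages
  het <- !is.na(out) & out == 1L
  out[het] <- 2L * rbinom(sum(het), 1L, 0.5)
  drop <- runif(length(out)) < missing_rate
  out[drop] <- NA_integer_
  as.integer(out)
}

#' Simulate microbial read counts over a genome panel
#'
#' Counts are zero where a genome is absent from a sample and
#' negative-binomial where present.
#'
#' @param n_genomes,n_samples panel dimensions.
#' @param presence_prob probability a genome is present in a sample;
#'   scalar or `n_genomes x n_samples` matrix.
#' @param mu,size negative-binomial mean and dispersion of counts where
#'   present.
#' @param seed optional RNG seed.
#' @return list with `counts` (genome x sample integer matrix) and
#'   `presence` (logical truth matrix).
#' @export
simulate_microbe_counts <- function(n_genomes, n_samples, presence_prob = 0.5,
                                    mu = 50, size = 2, seed = NULL) {
  with_seed(seed)
  pp <- matrix(presence_prob, n_genomes, n_samples)
  if (any(pp < 0 | pp > 1)) stop("presence_prob entries must be in [0, 1]")
  pres <- matrix(rbinom(n_genomes * n_samples, 1L, pp) == 1L,
                 n_genomes, n_samples)
  cnt <- matrix(0L, n_genomes, n_samples)
  cnt[pres] <- rnbinom(sum(pres), mu = mu, size = size)
  dimnames(cnt) <- dimnames(pres) <-
    list(sprintf("MAG%d", seq_len(n_genomes)), sprintf("S%d", seq_len(n_samples)))
  list(counts = cnt, presence = pres)
}
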