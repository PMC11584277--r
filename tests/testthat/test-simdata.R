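test_that("simulated references have the requested length, GC and determinism", {
  ref <- simulate_reference(1, 1000, gc = 0.5, seed = 1)
  expect_equal(nchar(ref[[1]]), 1000)

  ref2 <- simulate_reference(1, 10000, gc = 0.39, seed = 7)
  gc_obs <- mean(strsplit(ref2[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.39), 3 * sqrt(0.39 * 0.61 / 10000))

  expect_identical(simulate_reference(2, c(500, 600), 0.4, seed = 3),
                   simulate_reference(2, c(500, 600), 0.4, seed = 3))
  expect_error(simulate_reference(1, 50), "100")
  expect_error(simulate_reference(0, 1000), "positive")
})

test_that("FASTA and FASTQ round-trip identically", {
  ref <- simulate_reference(2, c(500, 500), 0.5, seed = 11)
  fa <- tempfile(fileext = ".fasta")
  write_fasta(ref, fa)
  expect_identical(read_fasta(fa), ref)

  fq <- tempfile(fileext = ".fastq")
  write_fastq(c("r1", "r2"), c("ACGT", "GGCC"), c("IIII", "!!~~"), fq)
  back <- read_fastq(fq)
  expect_identical(back$seq, c("ACGT", "GGCC"))
  expect_identical(back$qual, c("IIII", "!!~~"))
})

test_that("fragment sampling respects bounds, mean and determinism", {
  ref <- simulate_reference(1, 2000, 0.5, seed = 2)
  flen <- fragment_length_dist("geometric", mean = 45, min_len = 20,
                               max_len = 100)
  fr <- simulate_fragments(ref, 1000, flen, seed = 5)
  expect_true(all(fr$length >= 20 & fr$length <= 100))
  expect_identical(fr, simulate_fragments(ref, 1000, flen, seed = 5))

  # reverse-strand sequence is the reverse complement of the slice
  i <- which(fr$strand == "-")[1]
  slice <- substring(ref[[fr$contig[i]]], fr$start[i] + 1,
                     fr$start[i] + fr$length[i])
  expect_identical(fr$seq[i], revcomp(slice))
  i <- which(fr$strand == "+")[1]
  expect_identical(fr$seq[i],
                   substring(ref[[fr$contig[i]]], fr$start[i] + 1,
                             fr$start[i] + fr$length[i]))

  # Monte-Carlo check of the configured mean (rejection-truncated)
  set.seed(9)
  big <- sample_fragment_lengths(flen, 10000)
  ideal <- 20 + rgeom(200000, 1 / (45 - 20 + 1))
  ideal <- ideal[ideal <= 100]
  expect_lt(abs(mean(big) - mean(ideal)), 3 * sd(ideal) / sqrt(10000))
  expect_error(simulate_fragments(ref, 0, flen), "positive")
})

test_that("deamination damage follows the UDG-half position rule", {
  model0 <- damage_model(0, 0, 2, 0)
  out <- apply_damage(c("ACGTACGT", "CCCCGGGG"), model0, seed = 1)
  expect_identical(out$seq, c("ACGTACGT", "CCCCGGGG"))
  expect_equal(nrow(out$truth), 0)

  # forced terminal flip only: d_max=1, cutoff=1
  m1 <- damage_model(1, 0, 1, 0)
  out1 <- apply_damage("CCCC", m1, seed = 1)
  expect_identical(out1$seq, "TCCC")

  # mirrored 3' rule: G at the last position flips to A
  out2 <- apply_damage("GGGG", m1, seed = 1)
  expect_identical(out2$seq, "GGGA")

  # probability model honored at scale: position-1 C->T near d_max
  m <- damage_model(0.15, 0.3, 2, 0)
  set.seed(42)
  seqs <- rep(strrep("C", 30), 20000)
  out3 <- apply_damage(seqs, m)
  r1 <- sum(out3$truth$pos == 1 & out3$truth$type == "CT5") / 20000
  r2 <- sum(out3$truth$pos == 2 & out3$truth$type == "CT5") / 20000
  r4 <- sum(out3$truth$pos == 4) / 20000
  expect_lt(abs(r1 - 0.15), 3 * sqrt(0.15 * 0.85 / 20000))
  expect_lt(abs(r2 - 0.15 * exp(-0.3)), 3 * sqrt(0.12 * 0.88 / 20000))
  expect_equal(r4, 0)   # beyond the cutoff, zero deamination
})

test_that("5' C->T and 3' G->A rates mirror each other", {
  m <- damage_model(0.12, 0.5, 2, 0)
  set.seed(7)
  seqs <- replicate(20000, paste(sample(c("A", "C", "G", "T"), 40,
                                        replace = TRUE), collapse = ""))
  out <- apply_damage(seqs, m)
  ct <- sum(out$truth$type == "CT5" & out$truth$pos == 1)
  ga <- sum(out$truth$type == "GA3" & out$truth$pos == 40)
  # both ends have ~5000 eligible bases at rate 0.12
  expect_lt(abs(ct - ga) / 5000, 3 * sqrt(2 * 0.12 * 0.88 / 5000))
})

test_that("simulated pairs have the forced geometry and merge back to the fragment", {
  frag <- paste(rep("ACGT", 10), collapse = "")   # length 40
  p <- simulate_read_pairs(frag, read_len = 101, seed = 1)
  expect_equal(nchar(p$seq1), 40)
  expect_equal(nchar(p$seq2), 40)
  expect_identical(p$seq2, revcomp(p$seq1))

  # fragment longer than the read: overlap = 2*read_len - fragment
  ref <- simulate_reference(1, 3000, 0.5, seed = 3)
  frag150 <- substring(ref[[1]], 101, 250)
  p2 <- simulate_read_pairs(frag150, read_len = 101, seed = 2)
  m <- merge_pair(read_pair("x", p2$seq1, p2$qual1, p2$seq2, p2$qual2))
  expect_s3_class(m, "merged_read")
  expect_equal(m$overlap_len, 101 + 101 - 150)
  expect_identical(m$seq, frag150)

  # error-free round trip through damage + pairing + merging
  flen <- fragment_length_dist("lognormal", 45, 0.35, 20, 150)
  frags <- simulate_fragments(ref, 50, flen, seed = 4)
  dmg <- apply_damage(frags$seq, damage_model(0.2, 0.5, 2, 0), seed = 5)
  pr <- simulate_read_pairs(dmg$seq, 101, seed = 6)
  res <- merge_pairs(pr)
  expect_equal(length(res$merged), 50)
  expect_identical(vapply(res$merged, `[[`, character(1), "seq"), dmg$seq)
})

test_that("genotype simulation recovers its own truth", {
  # drift 0: all populations share the ancestral frequency
  cfg0 <- pop_sim_config(n_pops = 3, drift = 0, n_snvs = 500,
                         samples_per_pop = 5, seed = 1)
  gm0 <- simulate_genotypes(cfg0)
  tr <- attr(gm0, "truth")
  expect_equal(tr$pop_freqs[1, ], tr$pop_freqs[2, ])
  expect_equal(tr$pop_freqs[1, ], tr$p0)

  # alpha = 1: hybrid frequencies identical to population C (second-last)
  cfg1 <- pop_sim_config(n_pops = 3, drift = 0.05, n_snvs = 300,
                         samples_per_pop = 4, admixture_alpha = 1, seed = 2)
  gm1 <- simulate_genotypes(cfg1)
  tr1 <- attr(gm1, "truth")
  expect_equal(tr1$pop_freqs[4, ], tr1$pop_freqs[2, ])

  # every SNV biallelic in the pooled samples; blocks balanced round-robin
  dos <- gm1$dosages
  expect_true(all(colSums(dos) > 0 & colSums(dos) < 2 * nrow(dos)))
  blk <- table(gm1$snvs$block)
  expect_lte(max(blk) - min(blk), 1)   # round-robin balance

  # sample frequencies converge to configured population frequencies
  cfgN <- pop_sim_config(n_pops = 2, drift = 0.02, n_snvs = 200,
                         samples_per_pop = 200, seed = 3)
  gmN <- simulate_genotypes(cfgN)
  trN <- attr(gmN, "truth")
  f1 <- allele_freqs(gmN, "P1")
  se <- sqrt(trN$pop_freqs[1, ] * (1 - trN$pop_freqs[1, ]) / (2 * 200))
  expect_gt(mean(abs(f1 - trN$pop_freqs[1, ]) <= 3 * pmax(se, 1e-6)), 0.95)
})

test_that("ancient-like degradation is pseudohaploid with the right missingness", {
  hom <- rep(c(0L, 2L), 50)
  expect_identical(make_ancient_like(hom, 0, seed = 1), hom)

  set.seed(2)
  het <- rep(1L, 10000)
  calls <- make_ancient_like(het, 0)
  expect_true(all(calls %in% c(0L, 2L)))
  expect_lt(abs(mean(calls == 2L) - 0.5), 3 * sqrt(0.25 / 10000))

  set.seed(3)
  sparse <- make_ancient_like(rep(2L, 20000), 0.9)
  expect_lt(abs(sum(!is.na(sparse)) - 2000), 3 * sqrt(20000 * 0.9 * 0.1))
  expect_error(make_ancient_like(hom, 1), "missing_rate")
})

test_that("microbial count simulation matches its presence truth", {
  all_on <- simulate_microbe_counts(10, 10, 1, mu = 1000, size = 50, seed = 1)
  expect_true(all(all_on$presence))
  expect_true(all(all_on$counts > 0))
  expect_true(all(presence_absence(all_on$counts, 1, warn_below = 0)))

  all_off <- simulate_microbe_counts(10, 10, 0, seed = 2)
  expect_true(all(all_off$counts == 0))

  cal <- simulate_microbe_counts(100, 100, 0.3, seed = 3)
  expect_lt(abs(mean(cal$presence) - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})
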