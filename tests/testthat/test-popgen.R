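sim_gm <- function(n_pops = 2, drift = 0.05, n_snvs = 1000,
                   samples_per_pop = 10, seed = 1, ...) {
  simulate_genotypes(pop_sim_config(n_pops = n_pops, drift = drift,
                                    n_snvs = n_snvs,
                                    samples_per_pop = samples_per_pop,
                                    seed = seed, ...))
}

with_ancient <- function(gm, source_pop = "P1", missing_rate = 0.9,
                         id = "anc1", seed = 2) {
  set.seed(seed)
  truth <- attr(gm, "truth")
  k <- match(source_pop, sprintf("P%d", seq_len(nrow(truth$pop_freqs))))
  dip <- rbinom(ncol(gm$dosages), 2, truth$pop_freqs[k, ])
  append_sample(gm, id, source_pop, "ancient",
                make_ancient_like(dip, missing_rate))
}

test_that("genotype matrices enforce the pseudohaploid constraint", {
  gm <- sim_gm(n_snvs = 50, samples_per_pop = 3)
  expect_error(append_sample(gm, "bad", "P1", "ancient",
                             rep(1L, ncol(gm$dosages))),
               "pseudohaploid")
  gm2 <- with_ancient(gm, missing_rate = 0.5)
  expect_true(all(gm2$dosages["anc1", ] %in% c(0L, 2L, NA)))
})

test_that("SNV selection keeps modern-biallelic, ancient-covered sites", {
  snvs <- data.frame(block = rep("chr1", 5), pos = 1:5,
                     ref = rep("A", 5), alt = rep("G", 5))
  samples <- data.frame(id = c("m1", "m2", "a1"),
                        population = c("P1", "P1", "anc"),
                        era = c("modern", "modern", "ancient"))
  dos <- rbind(c(0L, 1L, 2L, 0L, 0L),
               c(1L, 1L, 2L, 0L, 2L),
               c(2L, NA, 0L, NA, NA))
  gm <- genotype_matrix(snvs, samples, dos)
  # SNV3 monomorphic (all 2), SNV4 monomorphic (all 0) among moderns;
  # SNVs 2, 4, 5 uncovered or monomorphic -> only 1 survives with both rules
  sel <- select_snvs(gm)
  expect_equal(sel$snvs$pos, 1L)
  sel2 <- select_snvs(gm, require_ancient = FALSE)
  expect_equal(sel2$snvs$pos, c(1L, 2L, 5L))

  # all-missing ancient rows empty the matrix under the restriction
  dos[3, ] <- NA_integer_
  gm3 <- genotype_matrix(snvs, samples, dos)
  expect_error(select_snvs(gm3), "no SNVs")

  # random matrices agree with a brute-force row scan
  gm4 <- with_ancient(sim_gm(n_snvs = 300, samples_per_pop = 4, seed = 9),
                      missing_rate = 0.8)
  sel4 <- select_snvs(gm4)
  modern <- gm4$samples$era == "modern"
  expected <- which(vapply(seq_len(ncol(gm4$dosages)), function(j) {
    m <- gm4$dosages[modern, j]
    a <- gm4$dosages[!modern, j]
    poly <- sum(m, na.rm = TRUE) > 0 &&
      sum(m, na.rm = TRUE) < 2 * sum(!is.na(m))
    poly && any(!is.na(a))
  }, logical(1)))
  expect_equal(ncol(sel4$dosages), length(expected))
  expect_equal(unname(sel4$dosages), unname(gm4$dosages[, expected]))
  expect_equal(sel4$snvs$pos, gm4$snvs$pos[expected])
  expect_equal(sel4$snvs$block, gm4$snvs$block[expected])
})

test_that("pseudohaploid calls sample one usable observation", {
  expect_equal(pseudohaploid_call("A", "A", "G"), 0L)
  expect_equal(pseudohaploid_call(character(0), "A", "G"), NA_integer_)
  expect_equal(pseudohaploid_call(c("T", "T"), "A", "G"), NA_integer_)
  set.seed(3)
  draws <- replicate(10000, pseudohaploid_call(c("A", "G"), "A", "G"))
  expect_lt(abs(mean(draws == 2L) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("PCA on two drifted populations separates them on PC1", {
  gm <- sim_gm(n_pops = 2, drift = 0.05, n_snvs = 2000, seed = 11)
  fit <- fit_pca(gm, K = 2)
  pops <- gm$samples$population
  pc1 <- fit$scores[, 1]
  # silhouette of the two-population labelling on PC1
  sil <- vapply(seq_along(pc1), function(i) {
    own <- mean(abs(pc1[i] - pc1[setdiff(which(pops == pops[i]), i)]))
    oth <- mean(abs(pc1[i] - pc1[pops != pops[i]]))
    (oth - own) / max(oth, own)
  }, numeric(1))
  expect_gt(mean(sil), 0.8)
  # loadings orthonormal; eigenvalues non-increasing
  expect_equal(crossprod(fit$loadings), diag(2), tolerance = 1e-8)
  expect_true(all(diff(fit$evals) <= 1e-8))
})

test_that("duplicating every sample leaves the loadings unchanged up to sign", {
  gm <- sim_gm(n_pops = 2, drift = 0.05, n_snvs = 400,
               samples_per_pop = 6, seed = 12)
  fit1 <- fit_pca(gm, K = 2)
  gm2 <- genotype_matrix(
    gm$snvs,
    rbind(gm$samples,
          transform(gm$samples, id = paste0(id, "_dup"))),
    rbind(gm$dosages, gm$dosages))
  fit2 <- fit_pca(gm2, K = 2)
  expect_equal(fit1$snv_idx, fit2$snv_idx)
  for (k in 1:2) {
    s <- sign(sum(fit1$loadings[, k] * fit2$loadings[, k]))
    expect_equal(fit2$loadings[, k] * s, fit1$loadings[, k],
                 tolerance = 1e-8)
  }
  expect_error(fit_pca(gm, K = 50), "rank|K")
})

test_that("projection reproduces in-fit coordinates and refuses low overlap", {
  gm <- sim_gm(n_pops = 2, drift = 0.05, n_snvs = 600, seed = 13)
  fit <- fit_pca(gm, K = 2)
  pj <- project_sample(fit, gm$dosages[1, ])
  expect_equal(as.vector(pj), as.vector(fit$scores[1, ]), tolerance = 1e-6)

  sparse <- gm$dosages[1, ]
  sparse[-(1:30)] <- NA_integer_
  ref <- project_sample(fit, sparse)
  expect_s3_class(ref, "projection_refusal")
  expect_equal(ref$n_overlap, length(intersect(1:30, fit$snv_idx)))
})

test_that("ancient-like samples project nearest their source population", {
  gm <- with_ancient(sim_gm(n_pops = 3, drift = 0.05, n_snvs = 2000,
                            seed = 14), "P2", 0.9, seed = 15)
  fit <- fit_pca(gm, K = 2)
  pj <- project_sample(fit, gm$dosages["anc1", ])
  expect_false(inherits(pj, "projection_refusal"))
  expect_identical(nearest_centroid(fit, pj), "P2")
})

test_that("the jackknife cloud is bookkept per block and brackets the estimate", {
  gm <- with_ancient(sim_gm(n_pops = 2, drift = 0.05, n_snvs = 1600,
                            seed = 16), "P1", 0.8, seed = 17)
  jk <- jackknife_projection(gm, "anc1")
  expect_s3_class(jk, "projection_result")
  expect_equal(nrow(jk$cloud), 16)
  expect_true(all(jk$se > 0))
  # removing 1 of 16 equal blocks removes exactly 1/16 of the SNVs
  b1 <- gm$snvs$block != gm$snvs$block[1]
  expect_equal(sum(!b1), 1600 / 16)
  # full-data coordinate inside the leave-one-out min/max box
  expect_true(all(jk$coords >= apply(jk$cloud, 2, min) - 1e-9 &
                  jk$coords <= apply(jk$cloud, 2, max) + 1e-9))
})

test_that("allele frequencies are missing-aware and match a per-site loop", {
  snvs <- data.frame(block = "chr1", pos = 1:3, ref = "A", alt = "G")
  samples <- data.frame(id = c("s1", "s2", "s3"), population = "P1",
                        era = "modern")
  dos <- rbind(c(2L, 0L, NA), c(NA, 1L, NA), c(NA, 2L, NA))
  gm <- genotype_matrix(snvs, samples, dos)
  f <- allele_freqs(gm, "P1")
  expect_equal(unname(f), c(1, 0.5, NA_real_))

  gm2 <- sim_gm(n_pops = 2, n_snvs = 200, samples_per_pop = 5, seed = 18)
  f2 <- allele_freqs(gm2, "P2")
  rows <- gm2$samples$population == "P2"
  loop <- vapply(seq_len(200), function(j) {
    x <- gm2$dosages[rows, j]
    sum(x, na.rm = TRUE) / (2 * sum(!is.na(x)))
  }, numeric(1))
  expect_equal(unname(f2), loop)
})

test_that("f4 obeys exact zero, antisymmetry and linearity identities", {
  gm <- sim_gm(n_pops = 4, drift = 0.02, n_snvs = 2000, seed = 19)
  # C = D: zero estimate and zero Z, exactly
  r0 <- f4(gm, "P1", "P2", "P3", "P3")
  expect_identical(r0$f4, 0)
  expect_identical(r0$z, 0)
  expect_false(r0$significant)

  r1 <- f4(gm, "P1", "P2", "P3", "P4")
  r2 <- f4(gm, "P1", "P2", "P4", "P3")
  expect_equal(r1$f4, -r2$f4)
  expect_equal(abs(r1$z), abs(r2$z))

  # one population duplicated under four labels: every f4 identically zero
  dup <- gm$dosages[gm$samples$population == "P1", ][rep(1:10, 4), ]
  samp4 <- data.frame(id = paste0("s", 1:40),
                      population = rep(c("A", "B", "C", "D"), each = 10),
                      era = "modern")
  gm4 <- genotype_matrix(gm$snvs, samp4, dup)
  rz <- f4(gm4, "A", "B", "C", "D")
  expect_identical(rz$f4, 0)
  expect_identical(rz$z, 0)

  # linearity: concatenation = SNV-weighted average of the two halves
  half <- 1:1000
  gma <- genotype_matrix(gm$snvs[half, ], gm$samples,
                         gm$dosages[, half])
  gmb <- genotype_matrix(gm$snvs[-half, ], gm$samples,
                         gm$dosages[, -half])
  fa <- f4(gma, "P1", "P2", "P3", "P4")$f4
  fb <- f4(gmb, "P1", "P2", "P3", "P4")$f4
  expect_equal(r1$f4, (1000 * fa + 1000 * fb) / 2000)
})

test_that("f4 permutation tables cover the expected quadruples once", {
  gm <- sim_gm(n_pops = 5, drift = 0.02, n_snvs = 800,
               samples_per_pop = 5, seed = 20)
  tab <- f4_permutations(gm, "P1", "P2", c("P3", "P4", "P5"))
  # B = focal: choose(3,2) pairs; B in others: 3 * choose(2,2)
  expect_equal(nrow(tab), 3 + 3)
  expect_true(all(c("z", "significant") %in% names(tab)))
  expect_equal(anyDuplicated(tab[, c("B", "C", "D")]), 0)
  # canonical orientation: C before D in input order
  others <- c("P3", "P4", "P5")
  expect_true(all(match(tab$C, others) < match(tab$D, others)))
})

test_that("genotype TSV round-trip preserves the matrix", {
  gm <- with_ancient(sim_gm(n_pops = 2, n_snvs = 100, samples_per_pop = 3,
                            seed = 21), "P1", 0.5)
  pre <- file.path(tempdir(), "gt_test")
  write_genotypes(gm, pre)
  back <- read_genotypes(pre)
  expect_equal(back$snvs$block, gm$snvs$block)
  expect_equal(unname(back$dosages), unname(gm$dosages))
  expect_equal(back$samples$era, gm$samples$era)
})
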