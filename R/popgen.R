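#' Genotype matrix of biallelic SNVs
#'
#' @param snvs data.frame with columns `block` (chromosome/block id),
#'   `pos`, `ref`, `alt`; one row per SNV.
#' @param samples data.frame with columns `id`, `population`, `era`
#'   (`"modern"` or `"ancient"`).
#' @param dosages samples x SNVs integer matrix over \{0, 1, 2, `NA`\};
#'   ancient rows are pseudohaploid and may not contain dosage 1.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(snvs, samples, dosages) {
  stopifnot(is.data.frame(snvs), is.data.frame(samples),
            all(c("block", "pos", "ref", "alt") %in% names(snvs)),
            all(c("id", "population", "era") %in% names(samples)),
            nrow(dosages) == nrow(samples), ncol(dosages) == nrow(snvs),
            all(samples$era %in% c("modern", "ancient")))
  bad <- dosages[!is.na(dosages)]
  if (!all(bad %in% 0:2)) stop("dosages must be 0, 1, 2 or NA")
  anc <- samples$era == "ancient"
  if (any(anc)) {
    a <- dosages[anc, , drop = FALSE]
    if (any(a == 1L, na.rm = TRUE))
      stop("ancient samples must be pseudohaploid (no dosage 1)")
  }
  rownames(dosages) <- samples$id
  structure(list(snvs = snvs, samples = samples,
                 dosages = dosages),
            class = "genotype_matrix")
}

#' Append one sample to a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param id,population,era sample metadata.
#' @param dosages dosage vector over the matrix's SNVs.
#' @return the extended `genotype_matrix`.
#' @export
append_sample <- function(gm, id, population, era, dosages) {
  stopifnot(inherits(gm, "genotype_matrix"), length(dosages) == nrow(gm$snvs))
  genotype_matrix(
    gm$snvs,
    rbind(gm$samples, data.frame(id = id, population = population, era = era,
                                 stringsAsFactors = FALSE)),
    rbind(gm$dosages, matrix(as.integer(dosages), nrow = 1))
  )
}

#' Select SNVs for ancient/modern comparison
#'
#' Retains SNVs that are biallelic (polymorphic) among the pooled
#' modern samples and, when `require_ancient` is on, covered by at
#' least one ancient sample.
#'
#' @param gm a [genotype_matrix()].
#' @param require_ancient require >= 1 non-missing ancient call per SNV.
#' @return the filtered `genotype_matrix`.
#' @export
select_snvs <- function(gm, require_ancient = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  modern <- gm$samples$era == "modern"
  dm <- gm$dosages[modern, , drop = FALSE]
  nn <- colSums(!is.na(dm))
  tot <- colSums(dm, na.rm = TRUE)
  keep <- nn > 0 & tot > 0 & tot < 2 * nn
  if (require_ancient) {
    anc <- gm$samples$era == "ancient"
    cov <- if (any(anc)) colSums(!is.na(gm$dosages[anc, , drop = FALSE])) > 0
           else rep(FALSE, ncol(gm$dosages))
    keep <- keep & cov
  }
  if (!any(keep)) stop("no SNVs survive selection")
  genotype_matrix(gm$snvs[keep, , drop = FALSE], gm$samples,
                  gm$dosages[, keep, drop = FALSE])
}

#' Pseudohaplotype call from a pileup of base observations
#'
#' One observation is sampled uniformly at random among those matching
#' the site's two alleles; the call is dosage 0 (reference) or 2
#' (alternate). No usable observations gives a missing call.
#'
#' @param bases character vector of observed bases at the site.
#' @param ref,alt the site's alleles.
#' @param seed optional RNG seed.
#' @return integer 0, 2, or `NA`.
#' @export
pseudohaploid_call <- function(bases, ref, alt, seed = NULL) {
  with_seed(seed)
  usable <- bases[bases %in% c(ref, alt)]
  if (length(usable) == 0) return(NA_integer_)
  pick <- usable[[sample.int(length(usable), 1L)]]
  if (pick == alt) 2L else 0L
}

#' Fit a PCA model on modern samples
#'
#' Sites are mean-imputed (model fitting only), centred by the mean
#' dosage `m` and, optionally, scaled by `sqrt((m/2) * (1 - m/2))` (the
#' smartpca convention); sites monomorphic after imputation are
#' dropped. Loadings come from the SVD of the standardized matrix.
#'
#' @param gm a [genotype_matrix()]; only modern samples are used.
#' @param K number of components (at most the matrix rank).
#' @param scale logical; apply the frequency-based scaling.
#' @return an object of class `pca_model`: list with `snv_idx`
#'   (columns of `gm` used), `center`, `scale`, `loadings`
#'   (SNVs x K, orthonormal), `evals` (non-increasing), `scores`
#'   (modern in-fit coordinates) and `sample_id`.
#' @export
fit_pca <- function(gm, K = 2L, scale = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  modern <- gm$samples$era == "modern"
  if (sum(modern) < K + 1) stop("need at least K+1 modern samples")
  core <- fit_pca_core(gm$dosages[modern, , drop = FALSE], K, scale)
  core$sample_id <- gm$samples$id[modern]
  core
}

# workhorse behind fit_pca and the block jackknife: X is the modern
# dosage matrix (samples x SNVs), columns indexed relative to X
fit_pca_core <- function(X, K, scale) {
  m <- colMeans(X, na.rm = TRUE)
  nas <- which(colSums(is.na(X)) > 0)
  for (j in nas) X[is.na(X[, j]), j] <- m[j]
  v <- colMeans(X * X) - m * m          # population variance per site
  sc <- if (scale) sqrt((m / 2) * (1 - m / 2)) else rep(1, length(m))
  keep <- which(!is.na(m) & m > 0 & m < 2 & sc > 0 & v > 1e-12)
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, m[keep]), 2, sc[keep], "/")
  sv <- svd(Z, nu = min(dim(Z)), nv = min(dim(Z)))
  pos <- sum(sv$d > sv$d[1] * 1e-10)
  if (K > pos) stop("K exceeds the rank of the standardized matrix")
  structure(list(snv_idx = keep, center = m[keep], scale = sc[keep],
                 loadings = sv$v[, seq_len(K), drop = FALSE],
                 evals = (sv$d^2 / (nrow(Z) - 1))[seq_len(K)],
                 scores = sweep(sv$u[, seq_len(K), drop = FALSE], 2,
                                sv$d[seq_len(K)], "*"),
                 K = K),
            class = "pca_model")
}

#' Project a (possibly sparse) sample into a fitted PCA space
#'
#' Least-squares projection over the sample's observed sites only: the
#' coordinates minimize the squared reconstruction error of the
#' standardized observed dosages against the loading subvectors. No
#' imputation is applied to the projected sample. Samples overlapping
#' the model at fewer than `min_overlap` sites are refused — the
#' behaviour for unplaceably low-coverage samples.
#'
#' @param model a [fit_pca()] result.
#' @param dosages dosage vector over the genotype matrix's SNVs
#'   (`NA` = missing).
#' @param min_overlap minimum non-missing overlapping site count.
#' @return numeric vector of K coordinates with attribute `n_overlap`,
#'   or an object of class `projection_refusal`.
#' @export
project_sample <- function(model, dosages, min_overlap = 50L) {
  stopifnot(inherits(model, "pca_model"))
  d <- dosages[model$snv_idx]
  obs <- which(!is.na(d))
  if (length(obs) < min_overlap) {
    return(structure(list(n_overlap = length(obs), min_overlap = min_overlap,
                          reason = "insufficient overlapping sites"),
                     class = "projection_refusal"))
  }
  z <- (d[obs] - model$center[obs]) / model$scale[obs]
  B <- model$loadings[obs, , drop = FALSE]
  coords <- as.vector(qr.solve(crossprod(B), crossprod(B, z)))
  attr(coords, "n_overlap") <- length(obs)
  coords
}

#' Chromosome-block jackknife of a PCA projection
#'
#' Refits the PCA with each block's SNVs removed, sign-aligns the
#' leave-one-out loadings to the full-data loadings (PCA sign
#' indeterminacy would otherwise corrupt the cloud), re-projects the
#' sample, and reports the leave-one-out coordinate cloud and a
#' weighted delete-one jackknife SE per component (weights = block SNV
#' counts). Blocks whose refit or projection fails are flagged and
#' excluded from the SE.
#'
#' @param gm a [genotype_matrix()].
#' @param sample_id the sample to project.
#' @param K,scale passed to [fit_pca()].
#' @param min_overlap passed to [project_sample()].
#' @return an object of class `projection_result`: list with
#'   `sample_id`, `coords` (full-data), `se` (per PC), `cloud`
#'   (blocks x K matrix), `blocks_used`, `failed_blocks`, `n_overlap`.
#' @export
jackknife_projection <- function(gm, sample_id, K = 2L, scale = TRUE,
                                 min_overlap = 50L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  blocks <- unique(gm$snvs$block)
  if (length(blocks) < 3) stop("need at least 3 blocks")
  i <- match(sample_id, gm$samples$id)
  if (is.na(i)) stop("unknown sample: ", sample_id)
  d <- gm$dosages[i, ]

  full <- fit_pca(gm, K = K, scale = scale)
  coords <- project_sample(full, d, min_overlap = min_overlap)
  if (inherits(coords, "projection_refusal")) return(coords)

  cloud <- matrix(NA_real_, length(blocks), K,
                  dimnames = list(blocks, NULL))
  wts <- numeric(length(blocks))
  modern <- gm$samples$era == "modern"
  Xm <- gm$dosages[modern, , drop = FALSE]
  for (b in seq_along(blocks)) {
    cols <- which(gm$snvs$block != blocks[b])
    fit_b <- tryCatch(fit_pca_core(Xm[, cols, drop = FALSE], K, scale),
                      error = function(e) NULL)
    if (is.null(fit_b)) next
    fit_b$snv_idx <- cols[fit_b$snv_idx]   # absolute SNV indices
    # sign-align to the full-data loadings over shared SNVs
    shared_full <- match(fit_b$snv_idx, full$snv_idx)
    ok <- !is.na(shared_full)
    for (k in seq_len(K)) {
      s <- sum(fit_b$loadings[ok, k] * full$loadings[shared_full[ok], k])
      if (s < 0) fit_b$loadings[, k] <- -fit_b$loadings[, k]
    }
    cb <- project_sample(fit_b, d, min_overlap = min_overlap)
    if (inherits(cb, "projection_refusal")) next
    cloud[b, ] <- cb
    wts[b] <- length(fit_b$snv_idx)
  }
  used <- which(!is.na(cloud[, 1]))
  if (length(used) < 2) stop("fewer than 2 usable jackknife blocks")
  se <- vapply(seq_len(K), function(k) {
    weighted_jackknife(coords[k], cloud[used, k], wts[used])$se
  }, numeric(1))
  structure(list(sample_id = sample_id, coords = as.vector(coords), se = se,
                 cloud = cloud[used, , drop = FALSE],
                 blocks_used = blocks[used],
                 failed_blocks = blocks[setdiff(seq_along(blocks), used)],
                 n_overlap = attr(coords, "n_overlap")),
            class = "projection_result")
}

#' Missing-aware population allele frequencies
#'
#' @param gm a [genotype_matrix()].
#' @param population population label.
#' @return per-SNV alternate-allele frequency (sum of dosages over
#'   twice the non-missing sample count); `NA` where no sample is
#'   called.
#' @export
allele_freqs <- function(gm, population) {
  stopifnot(inherits(gm, "genotype_matrix"))
  rows <- gm$samples$population == population
  if (!any(rows)) stop("population not found: ", population)
  d <- gm$dosages[rows, , drop = FALSE]
  nn <- colSums(!is.na(d))
  f <- colSums(d, na.rm = TRUE) / (2 * nn)
  f[nn == 0] <- NA_real_
  f
}

#' f4 statistic with weighted block-jackknife Z score
#'
#' `f4(A, B; C, D)` is the mean over SNVs of `(a - b) * (c - d)` for
#' the four populations' allele frequencies. The standard error comes
#' from a weighted delete-one block jackknife over SNV blocks (weights
#' = block SNV counts); `Z = f4 / SE`, significant when `|Z| >= 3`.
#' SNVs with any of the four frequencies missing are excluded.
#'
#' @param gm a [genotype_matrix()].
#' @param A,B,C,D population labels.
#' @param z_threshold significance threshold on `|Z|`.
#' @return an object of class `f4_result`: list with `quad`, `f4`,
#'   `se`, `z`, `significant`, `n_snvs`, `n_blocks`.
#' @export
f4 <- function(gm, A, B, C, D, z_threshold = 3) {
  stopifnot(inherits(gm, "genotype_matrix"))
  fa <- allele_freqs(gm, A); fb <- allele_freqs(gm, B)
  fc <- allele_freqs(gm, C); fd <- allele_freqs(gm, D)
  use <- !(is.na(fa) | is.na(fb) | is.na(fc) | is.na(fd))
  v <- (fa - fb) * (fc - fd)
  v <- v[use]
  blk <- gm$snvs$block[use]
  if (length(v) == 0) stop("no SNVs usable for f4")
  bs <- tapply(v, blk, sum)
  bn <- tapply(v, blk, length)
  if (length(bs) < 2) stop("f4 jackknife needs at least 2 non-empty blocks")
  n <- length(v)
  est <- sum(bs) / n
  loo <- (sum(bs) - bs) / (n - bn)
  jk <- weighted_jackknife(est, as.vector(loo), as.vector(bn))
  z <- if (jk$se == 0) 0 else est / jk$se
  structure(list(quad = c(A = A, B = B, C = C, D = D), f4 = est,
                 se = jk$se, z = z,
                 significant = abs(z) >= z_threshold,
                 n_snvs = n, n_blocks = length(bs)),
            class = "f4_result")
}

#' All f4 permutations around an outgroup and a focal population
#'
#' Mirrors the published permutation scheme: with outgroup A fixed,
#' tests `f4(A, B; C, D)` where B runs over the focal population and
#' every other population, and (C, D) over the unordered pairs of the
#' remaining populations (canonical orientation: C before D in input
#' order; the antisymmetric partner is derivable, not stored).
#'
#' @param gm a [genotype_matrix()].
#' @param outgroup outgroup population label (A).
#' @param focal focal population label (e.g. the ancient group).
#' @param others character vector of comparison population labels.
#' @param z_threshold significance threshold on `|Z|`.
#' @return data.frame with one row per tested quadruple: `A`, `B`, `C`,
#'   `D`, `f4`, `se`, `z`, `significant`, `n_snvs`, `n_blocks`.
#' @export
f4_permutations <- function(gm, outgroup, focal, others, z_threshold = 3) {
  if (length(others) < 2) stop("need at least 2 other populations")
  rows <- list()
  for (B in c(focal, others)) {
    pool <- setdiff(others, B)
    if (length(pool) < 2) next
    pairs <- utils::combn(pool, 2)
    for (j in seq_len(ncol(pairs))) {
      r <- f4(gm, outgroup, B, pairs[1, j], pairs[2, j],
              z_threshold = z_threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        A = outgroup, B = B, C = pairs[1, j], D = pairs[2, j],
        f4 = r$f4, se = r$se, z = r$z, significant = r$significant,
        n_snvs = r$n_snvs, n_blocks = r$n_blocks, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Genotype matrix TSV round-trip
#'
#' Writes `<prefix>_genotypes.tsv` (SNV metadata columns then one
#' column per sample, dosages 0/1/2/NA) and `<prefix>_samples.tsv`
#' (id, population, era).
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output path prefix.
#' @export
write_genotypes <- function(gm, prefix) {
  g <- cbind(gm$snvs, as.data.frame(t(gm$dosages)))
  write.table(g, paste0(prefix, "_genotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(gm$samples, paste0(prefix, "_samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(prefix) {
  g <- read.delim(paste0(prefix, "_genotypes.tsv"), stringsAsFactors = FALSE,
                  check.names = FALSE)
  samples <- read.delim(paste0(prefix, "_samples.tsv"),
                        stringsAsFactors = FALSE)
  meta <- c("block", "pos", "ref", "alt")
  dos <- t(as.matrix(g[, setdiff(names(g), meta), drop = FALSE]))
  storage.mode(dos) <- "integer"
  genotype_matrix(g[, meta], samples, dos[samples$id, , drop = FALSE])
}

#' Read a genotype matrix from VCF
#'
#' Maps diploid genotypes to dosages (count of alternate alleles);
#' multi-allelic records are dropped. Requires the `vcfR` package.
#'
#' @param path VCF path.
#' @param samples data.frame with `id`, `population`, `era` covering the
#'   VCF sample columns.
#' @return a [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path, samples) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_genotypes_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1 &
    nchar(fix[, "ALT"]) == 1
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c(".", "./.", ".|."), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", x), "/"), function(a)
             sum(a == "1"), integer(1)))
  }
  dos <- t(apply(gt, 1, count_alt))
  snvs <- data.frame(block = fix[biallelic, "CHROM"],
                     pos = as.integer(fix[biallelic, "POS"]),
                     ref = fix[biallelic, "REF"],
                     alt = fix[biallelic, "ALT"], stringsAsFactors = FALSE)
  ord <- match(samples$id, colnames(gt))
  if (anyNA(ord)) stop("samples missing from VCF: ",
                       paste(samples$id[is.na(ord)], collapse = ", "))
  genotype_matrix(snvs, samples, t(dos[, ord, drop = FALSE]))
}
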