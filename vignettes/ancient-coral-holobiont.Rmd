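---
title: "Authenticating and analysing ancient coral holobiont DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authenticating and analysing ancient coral holobiont DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralaDNA)
```

## The problem

DNA recovered from fossil coral skeletons is short, scarce and
chemically damaged. Before any biological conclusion can be drawn from
such material, three questions have to be answered in order: are the
recovered molecules authentically ancient (and not modern
contamination)? where do the ancient host genotypes fall relative to
modern populations? and which members of the associated microbial
community (the holobiont) are represented in the ancient material?

`coralaDNA` implements a complete desk-scale treatment of this
workflow: a simulator that generates every input with known truth, the
read-merging and filtering arithmetic used for paired-end ancient
libraries, a misincorporation-profile classifier for read groups, a
projection-PCA and f4 framework for placing sparse pseudohaploid
samples among modern populations, and presence/absence comparison of
microbial genomes. Everything downstream of the simulator works the
same on real data supplied in the standard formats (FASTQ, SAM,
genotype tables, count tables).

## The damage model

Post-mortem cytosine deamination converts C to U at single-stranded
fragment ends, read as C→T at the 5' end and, on the complementary
strand, G→A at the 3' end. Partial uracil-DNA-glycosylase ("UDG-half")
library treatment excises interior uracils but leaves the terminal
ones, so an authentic UDG-half library shows elevated damage only at
the outermost base or two.

`damage_model()` parametrises this as

* `d_max` — deamination probability at position 1 (dimensionless,
  default 0.10, a typical terminal rate for Holocene material),
* `decay` — exponential decay per position (default 3, confining
  damage essentially to the terminal base, as UDG-half chemistry
  produces; use smaller values, e.g. 0.3, to emulate untreated
  libraries truncated by `udg_half_cutoff`),
* `udg_half_cutoff` — position beyond which deamination is zero
  (default 2),
* `background_error` — uniform per-base sequencing error (default
  0.001, split evenly over the three alternative bases).

The deamination probability at position $i$ from the relevant end is
$d_{\max} e^{-\lambda (i-1)}$ for $i \le$ cutoff and 0 beyond it.
Damage is applied to the fragment *before* reads are extracted, so R2
observes the 3' G→A pattern at its own 5' end after reverse
complementation, matching real library chemistry.

## Read merging

Paired 2×101 bp reads from short fragments overlap; merging
reconstructs the fragment and filters long templates. The rules are:

* minimum overlap 15 bp;
* at most one mismatch where both base qualities are ≥ 20, and at most
  three at lower quality (both budgets simultaneously);
* at matches the consensus quality is the maximum of the two
  qualities; at mismatches the higher-quality base is kept with
  quality equal to the difference; an exact tie keeps the R1 base at
  quality 0.

Candidate placements put the reverse-complemented R2 at offsets
`s ≥ 0` from the R1 start — R1 always begins at the fragment's 5'
end, so negative offsets cannot arise physically and admitting them
would only create spurious matches. Among valid candidates the fewest
total mismatches wins, ties go to the longest overlap, and remaining
ties are rejected as ambiguous rather than guessed. The mismatch
quality class uses the *minimum* of the two base qualities: a
disagreement is only confidently real when both calls are confident.
Unmerged pairs are dropped from downstream analysis. Adapters are not
simulated; the full-overlap geometry of short fragments exercises the
same merging logic without an adapter-matching stage, which keeps the
merge arithmetic itself the tested unit.

```{r merge-example}
frag <- simulate_reference(1, 150, gc = 0.4, seed = 1)[[1]]
pair <- simulate_read_pairs(frag, read_len = 101, seed = 2)
m <- merge_pair(read_pair("ex", pair$seq1, pair$qual1, pair$seq2, pair$qual2))
c(overlap = m$overlap_len, length = nchar(m$seq))
```

## Damage profiling and the three authentication criteria

`build_profile()` tabulates all twelve substitution types by position
from each read end (window 25), with explicit opportunity counts, from
alignments held in sequenced orientation. `classify_group()` then
scores a read group 0–3:

1. **Terminal maximum** — the position-1 C→T rate (5') and G→A rate
   (3') are each the strict maximum of their substitution's rates over
   positions 1–10.
2. **Terminal elevation** — the position-1 damage rate exceeds the
   mean + 2 SD of the other eleven substitution types' rates at that
   position.
3. **Interior background** — away from the terminus the damage
   substitution stays inside the background band: its rate aggregated
   over positions 2–11 is below the mean + 2 SD of the other types'
   per-position rates pooled over those positions.

Both ends must pass each criterion. The comparison band is always
computed *within* the group, across substitution types — the
colored-curve-versus-grey-band convention of standard
misincorporation plots — so no cross-group pooling is needed.

Criterion 3 deserves a note. Evaluating it position-by-position looks
natural but cannot work at realistic group sizes: with 5,000 reads a
position offers roughly 1,250 opportunities per reference base, so
each per-position rate is a small Poisson count, and a clean group
exceeds a 2 SD band at *some* of the twenty interior position-tests
(ten per end) with high probability — simulation puts the all-pass
probability at 20–45%, which would make the criterion reject most
authentic groups on count noise alone. Aggregating the ten interior
positions into one test per end keeps the false-rejection rate well
below 1% while losing no power against the pattern the criterion
exists to exclude: contamination-like damage spread uniformly along
the read, which inflates the aggregate just as much as any single
position. The SD is the sample SD (n−1); rates with zero
opportunities are undefined and fail the affected criterion
explicitly.

Groups below 100 reads are flagged low-confidence rather than
silently scored.

## Trimming and filtering

One base is trimmed from each read end before all analyses other than
damage profiling itself — exactly the operation that removes terminal
deamination. The package ties the two together: profiles rebuilt from
trimmed reads of a cutoff-1 library show terminal rates at background
and fail criterion 2. Alignments are kept only at mapping quality
strictly above 30.

## Population-genetic placement

Ancient genotypes are pseudohaploid: at each covered site one read's
allele is sampled uniformly, giving dosage 0 or 2 — never 1
(`pseudohaploid_call()`, `make_ancient_like()`). Sites enter the
analysis when they are biallelic among the pooled modern samples and
covered by at least one ancient sample.

**Projection PCA.** `fit_pca()` fits components on modern samples
only: sites are mean-imputed (fitting only), centred, and scaled by
$\sqrt{(m/2)(1-m/2)}$ with $m$ the mean dosage — the smartpca
convention; scaling can be toggled off. `project_sample()` places a
sparse sample by least squares over its observed sites only, never
imputing the projected sample; fitting on moderns and projecting
ancients avoids the shrinkage of low-coverage samples toward the
origin. Samples overlapping the model at fewer than 50 sites are
refused with a diagnostic instead of being placed meaninglessly — the
operational form of "could not be placed due to low coverage".
Uncertainty comes from `jackknife_projection()`: the fit is repeated
with each chromosome block deleted (default 16 blocks, mirroring 14
chromosome-level scaffolds plus two pseudo-chromosomes), each
leave-one-out loading set is sign-aligned to the full-data loadings
before projecting (PCA sign indeterminacy would otherwise corrupt the
cloud), and a weighted delete-one jackknife SE is reported per
component.

**f4 statistics.** `f4()` computes the mean over SNVs of
$(a-b)(c-d)$ with the standard error from a weighted block jackknife
(block weights = SNV counts, the convention for f-statistics), and
declares significance at $|Z| \ge 3$. `f4_permutations()` reproduces
the permutation scheme around a fixed outgroup and focal population,
storing each quadruple once in a canonical orientation since the
antisymmetric partner is derivable. Exact identities — zero when C =
D, antisymmetry under C/D exchange, linearity under SNV-set
concatenation — hold by construction and are enforced in the tests.

## The simulator as the source of study conditions

`simulate_genotypes()` draws an ancestral frequency $p_0 \sim
U(0.05, 0.95)$ per SNV and lets each population drift as $p = p_0 +
N(0, \sqrt{\text{drift} \cdot p_0(1-p_0)})$, truncated to $[0,1]$ —
truncation rather than redrawing introduces a small, documented bias
acceptable at the drift levels used. An optional hybrid population
has frequency $\alpha p_C + (1-\alpha) p_D$, mirroring a natural
F1-like hybrid between two congeners. SNVs are assigned round-robin
to 16 blocks; monomorphic draws are filtered so every SNV is
biallelic in the pooled samples.

The standard simulated panel used throughout the calibration studies
is 20,000 SNVs, 16 blocks and 10 diploid samples per population, with
drift 0.02 for the f4 studies and 0.05 for the projection studies,
ancient-like samples at 90% missingness, and read groups of 5,000
reads (20,000 where rate recovery itself is measured) with fragment
lengths lognormal around 45 bp within [20, 150]. These sizes make
every operating characteristic measurable in minutes on one CPU while
keeping Monte-Carlo error far from each test's threshold.

What the simulator does *not* emulate — and what passing tests
therefore do not establish about real data — includes: linkage within
blocks (SNVs are exchangeable, so block jackknives are conservative
relative to real linkage only through block counts), reference bias
in mapping, contamination mixtures, indel damage, adapter artefacts,
and coalescent tree structure beyond star-shaped drift with one
optional admixture event.

## Microbial presence and overlap

`count_by_genome()` counts reads at mapping quality strictly above 30
per metagenome-assembled genome and sample;
`restrict_to_ancient_present()` keeps genomes seen in at least one
ancient sample (default threshold: a single read — the source
protocol states none, so the choice is exposed and every presence
call resting on fewer than 10 reads warns, since absence claims from
shallow ancient data deserve caution). `relative_abundance()`
normalises per sample over the restricted genome set.
`overlap_fisher()` cross-classifies each genome as present/absent in
two sample groups (group presence = any sample) and applies a
two-sided Fisher exact test whose p-value is computed by direct
hypergeometric summation; the genome-by-group construction is the
only one consistent with comparing overlap of genome sets between
groups, and is stated as an interpretation since the source protocol
does not print its contingency table.

## Numerical and degenerate-input choices

* Phred qualities are Sanger-encoded (offset 33), clamped to [2, 41]
  in simulation; consensus qualities may reach 60.
* Coordinates are 0-based half-open internally; SAM I/O converts
  to/from 1-based. Only ungapped (M-only) alignments are supported —
  indel-aware merging and alignment are out of scope.
* Misincorporation rates with zero opportunities are `NA`, never 0.
* PCA drops sites monomorphic after imputation; `K` above the matrix
  rank is an error.
* f4 with identical C and D yields estimate, SE and Z all exactly
  zero (the 0/0 case is defined as Z = 0); fewer than two non-empty
  blocks is an error.
* The exact test includes tied tables within a relative tolerance of
  1e-7, the conventional guard for floating-point ties.
* All randomness flows through a single seed; pipeline stages derive
  deterministic child seeds so each stage is independently
  reproducible.

## Limitations

The classifier's criteria were designed for UDG-half libraries; fully
untreated libraries (slowly decaying damage) deliberately fail
criterion 3, and criterion thresholds assume groups of at least a few
thousand reads — below that, the low-confidence flag matters. The
projection refuses rather than places very sparse samples, so a
sample can be authentically ancient yet unplaceable. The f4
machinery assumes biallelic, block-assigned SNVs and does not model
genotype likelihoods; analyses that need likelihood-aware PCA or
admixture proportions are outside this package's scope.
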