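---
title: "Weighted single-step GWAS: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted single-step GWAS: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Growth traits in beef cattle (birth weight, yearling weight, daily gain,
18-month weight) are recorded on far more animals than are ever genotyped:
a breeding program may hold phenotypes and complete genealogy for
thousands of animals and SNP-chip genotypes for a few hundred. Classical
GWAS discards the ungenotyped majority and loses power. Single-step GBLUP
keeps everyone: pedigree and marker information are merged in one additive
relationship matrix `H`, the mixed model is solved once for all animals,
and the genomic breeding values of the genotyped subset are then
back-solved into per-SNP effects. The *weighted* variant iterates this
back-solution, letting SNPs that absorb variance earn larger weights in
the genomic relationship matrix, which sharpens QTL-bearing regions over a
small number of rounds.

## Model

The single-trait animal model is

$$y = Wb + Za + e, \qquad a \sim N(0, H\sigma_a^2), \qquad e \sim N(0, I\sigma_e^2),$$

with fixed effects (sex, birth year, use type, farm as factors; age in
days as a covariate where the trait is age-dependent) and one additive
effect per pedigree animal. `H` never needs to be formed; its inverse is

$$H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1} \end{bmatrix},$$

where `A` is the numerator relationship matrix of the whole pedigree
(tabular method; `build_A()`), `A^{-1}` comes from Henderson's rules with
Meuwissen–Luo inbreeding coefficients (`build_A_inverse()`, exact for
inbred pedigrees), `A22` is the pedigree block of the genotyped animals,
and

$$G = \frac{Z D Z'}{\sum_i 2p_i(1-p_i)}$$

is the VanRaden genomic matrix with per-SNP weights on the diagonal of
`D`. `Z` holds dosages column-centred by `2p_i`; missing calls are
mean-imputed to `2p_i` (centred value 0), the convention that leaves `G`
unbiased in expectation. Allele frequencies are the observed frequencies
of the genotyped set unless the user supplies a reference set — the output
records which (`allele_freqs` carries a `source` tag).

### Blending, and why it is not optional

A consequence worth stating explicitly: with *observed* frequencies the
centred dosage columns each sum to zero, so `G` has the vector of ones in
its null space and is **exactly singular** regardless of how many markers
are used. Every inversion of `G` in the pipeline therefore operates on the
blend

$$G_b = \beta G + (1-\beta) A_{22}, \qquad \beta = 0.95 \text{ by default},$$

which restores full rank while barely perturbing the genomic
relationships. `beta = 1` disables blending for algebraic checks with
supplied (non-observed) frequencies, where the identity
`Z u = \hat a_g` holds exactly.

## The weighting loop

With variance components held fixed, `run_wssgwas()` iterates (default 3
rounds, the point at which the scheme is conventionally stopped before
overfitting single markers):

1. `G(t)` from the current weights `D(t)` (`D(1) = I`), blended, inserted
   into `H^{-1}`; the MME are solved for GEBVs.
2. SNP effects by back-solution
   `u(t) = lambda D(t) Z' G(t)^{-1} \hat a_g` with
   `lambda = 1/\sum_i 2p_i(1-p_i)`.
3. New weights `d_i = u_i^2 \, 2p_i(1-p_i)`, rescaled so that
   `tr(D)` equals the marker count — the total genetic variance implied by
   the weights is held constant, and the trace is asserted to 1e-8 at
   every round.

Variance components are estimated once (at unit weights) and held fixed
across iterations: re-estimating inside the loop would let the weights
redefine the variance scale they are normalised against, defeating the
trace constraint's purpose. The back-solve inside the loop uses the same
blended `G` that enters `H^{-1}`, so the chain is self-consistent; the
exact back-solve identity is only available unblended.

## Window decomposition and selection

The association signal is the share of additive variance captured by
windows of 20 consecutive SNPs, step 1, never spanning a chromosome
boundary: for the window starting at SNP `i`, each genotyped animal's
window genetic value is `sum_{j=i}^{i+19} z_j u_j`, and

$$\mathrm{gVar}\% = \frac{\widehat{\mathrm{var}}(\text{window value})}{\sigma_a^2} \times 100$$

with the empirical variance using the `n-1` denominator (the unbiased
default; the choice is visible in the documentation rather than buried).
Chromosomes shorter than the window are skipped with a warning.

Windows above the 1% threshold (strict `>`) are reported nonredundantly:
each contiguous run of overlapping selected windows collapses to the
window with the locally maximal share. Within a reported window the
**top SNP** is the marker maximising the individual contribution
`u_j^2 \, 2p_j(1-p_j)`, ties resolved to the lower bp position. Two
definitions of "top SNP" circulate — the marker contributing most
variance, versus a marker contributing about equally with its window —
and they conflict; the variance-maximiser is implemented because it is
deterministic and matches how reported tables identify the marker that
"explained the largest proportion" of a window.

Selections from several traits are merged by `nonredundant_union()`:
regions identical in (chromosome, start, end) count once; overlapping but
unequal regions stay separate, mirroring how shared exact regions are
counted once across trait tables while near-misses are not.

## REML

`reml_estimate()` is EM-REML on Henderson's mixed-model equations with
optional average-information (AI) acceleration (the default: three EM
warm-up rounds, then AI steps with step-halving back toward the EM update
whenever a step would leave the parameter space — the same safeguard used
by production REML software). The EM updates are

$$\sigma_a^{2\,\mathrm{new}} = \frac{\hat a' H^{-1} \hat a + \sigma_e^2\,\mathrm{tr}(H^{-1} C^{aa})}{q},
\qquad \sigma_e^{2\,\mathrm{new}} = \frac{y'\hat e}{n - \mathrm{rank}(W)}.$$

The trace `tr(H^{-1}C^{aa})` — the expensive quantity — is computed from
the sparse Cholesky factor of the coefficient matrix by the Takahashi
selected-inverse recurrence (a small compiled kernel), which yields the
inverse only on the factor's fill pattern. This makes an AI-REML fit on a
2000-animal pedigree take on the order of a second, and the unit tests
verify the selected-inverse trace against a dense inverse and the full
REML fit against direct maximisation of the dense REML log-likelihood.
Convergence is declared at a relative parameter change below `tol`
(default 1e-8). Standard errors of the components and of `h2` (delta
method) come from the inverse AI matrix; under plain EM they are reported
as not available.

Identifiability of the fixed design uses reference (drop-first) coding
plus pivoted-QR removal of residual rank deficiencies, so confounded farm
x year layouts degrade gracefully.

## Quality control

`apply_genotype_qc()` fixes the filter order: individual call rate, SNP
call rate, MAF, exact HWE, non-autosomal/unmapped — individuals before
markers, with SNP statistics recomputed after individual removal, the
usual PLINK-style practice. MAF removal is strict (`< 0.05` removed,
`0.05` kept). The HWE test is the exact conditional test (summing
configurations no more probable than the observed heterozygote count),
which behaves correctly at the rare-genotype counts where the chi-square
approximation fails; the suite checks it against an independently coded
conditional distribution to 1e-12. One caveat the report makes visible:
call rates are evaluated against the *current* panel, so an individual
sitting exactly at the threshold can pass on the full panel yet fail after
markers are removed — QC is idempotent whenever failures are clear-cut,
which is the realistic regime, but not for adversarial missingness
patterns straddling the threshold. Phenotype screening
(`remove_outliers()`) removes values beyond three SDs of the raw trait in
a single pass; mean and SD are not re-estimated after removal.

## The synthetic-data generator

`sim_config()` + `simulate_pedigree()` + `gene_drop_genotypes()` +
`simulate_phenotypes()` emulate the data-generating situation the method
targets: a multi-generation pedigree with only ~12% of animals genotyped
(the default `genotyped_fraction = 0.1235` reproduces a 744-of-6022
genotyping rate), heritabilities in the 0.2–0.45 range, and phenotypes
assembled as fixed effects + QTL values + polygenic values + residual on a
unit-phenotypic-variance scale. Design choices, made once:

* **Mating**: discrete non-overlapping generations, random pairing, equal
  sex ratio, no selection — the simplest neutral scheme sufficient for
  method testing; real breeding populations are under selection, which
  this deliberately does not model.
* **Recombination**: Haldane's map function (no interference), closed-form
  testable; 1 cM is mapped to 1 Mb of physical coordinate.
* **Founders**: allele frequencies uniform on `founder_maf_range`,
  haplotypes at linkage equilibrium; LD then accrues only from
  co-transmission and drift. The generator is *not* calibrated to any real
  cattle LD decay — no published effective population size was available
  to calibrate against — so tests exercising window behaviour demonstrate
  the machinery, not cattle-specific resolution.
* **QTLs** are drawn from the simulated SNPs so they can be kept on or
  masked from the analysed panel (`qtl_on_panel`), letting tests probe
  tagged and untagged causal variants; QTL and polygenic components are
  rescaled to their exact target variance shares, so the realized
  heritability is unbiased for the configured value (checked over 50
  replicates at n = 2000, tolerance 0.03).
* **Fixed effects** are categorical level shifts (sex, farm, year, use
  type) plus a linear age slope, matching the fixed part of the analysis
  model.

What passing simulation tests do *not* show: behaviour under selection or
assortative mating, X-chromosome handling (autosomes only, by
construction), sequence-level variation, or the LD structure of any
particular breed.

## Numerical choices and degenerate inputs

* MME solves use a sparse Cholesky factorisation with a relative-residual
  check at 1e-10; singular `G` raises an error directing the user to
  blending rather than silently regularising.
* Weight flooring is deliberately absent: with three iterations, zero
  weights (from zero effect estimates) are harmless; a floor would only
  matter for long runs and can be imposed by the caller.
* Monomorphic markers are rejected by `compute_allele_freqs()` (they
  should have been removed by the MAF filter); SNPs with all calls
  missing are a hard error rather than a silent drop.
* Ties: top-SNP ties break to the lower bp position; equidistant genes in
  `nearest_gene()` break to the smaller interval start. Both rules are
  deterministic and tested.
* LD is the squared Pearson correlation of dosages over pairwise-complete
  animals (the composite estimator for unphased data); pairs involving a
  monomorphic SNP are `NA`, and the diagonal is 1 by convention.

## Problem sizes used by the test suite

The suite validates statistical behaviour at sizes chosen to make the
checks sharp yet quick on a single core: heritability recovery uses
2000-animal pedigrees with 50 replicates per generating value (0.23 and
0.42); the QTL-reweighting property uses 1000 animals, 1000 markers and a
QTL carrying 30% of the additive variance over 20 replicates; oracle
equivalences (path-counting A, dense inverses, brute-force window
variances) run at up to 500 animals. The full suite completes in about
three minutes.

## Interface

The package is organised as an analysis workflow rather than a shell
tool: exported functions cover every stage, the numbered scripts under
`analysis/` narrate one full study on simulated data, and
`run_pipeline()` executes the chain (QC, relationships, REML, weighted
GWAS, selection, annotation) from a single YAML or list configuration,
writing plain-text TSV artifacts and a manifest with input checksums and
per-stage counts. PLINK PED/MAP and BED/BIM/FAM filesets are read and
written natively (BED magic bytes checked; dosages count the A1 allele);
annotation comes from local BED/GFF3 files only, keeping every run
network-free and version-pinned.

## Known limitations

Single trait only; no maternal or permanent-environment effects; no
metafounders or unknown-parent groups; no tau/omega scaling of the
`H^{-1}` correction block (the plain form is implemented exactly); no
p-values — inference is by variance-explained thresholds, which is how
the windowed decomposition is conventionally reported; and desk-scale
dense algebra for `G` (hundreds to a few thousand genotyped animals, not
hundreds of thousands).
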