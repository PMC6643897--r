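---
title: "Methods: models, estimators and design choices in orthopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in orthopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthopop)
```

`orthopop` analyses panels of single-copy orthologous genes resequenced in
many accessions of several closely related species. This vignette explains
the statistical models behind each stage, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the design decisions taken where reasonable alternatives existed. It states
no empirical result that the package's tests do not themselves compute.

## Data model

A **gene alignment** is a character matrix over `{A, C, G, T, -, N}`: rows
are accessions, columns are alignment positions. On input, residues are
uppercased, RNA `U` becomes `T`, and everything else — including all IUPAC
ambiguity codes — becomes `N` (missing). Treating ambiguity codes as missing
rather than as heterozygous genotypes is deliberate: the target panels are
essentially inbred and heterozygous calls are too rare to model usefully.
`-` is an alignment gap and is kept distinct from missing data throughout.
Coordinates are 0-based and half-open internally; report files are 1-based.

A **species panel** maps each accession to exactly one species. Cross-gene
**concatenation** keeps a gene only if every species has at least
`min_presence` accessions covering ≥ 50% of its columns with non-missing
calls (`min_presence = 4` by default, encoding the common "present in more
than three accessions per species" ortholog-selection rule); accessions
missing a retained gene are N-padded over its span, and per-gene offsets are
recorded so concatenation is lossless.

## Site statistics

For each species and column we count the four bases among non-gap, non-N
calls. A column is **evaluable** for a species when its within-species
sample size is ≥ 2 and the species has no gap call there; among evaluable
columns, a column **segregates** when ≥ 2 distinct bases occur, and
multiallelic columns count once toward S (the Watterson convention).

Three rules here were open choices:

- *n ≥ 2 evaluability*: a singleton sample cannot segregate, so columns with
  one usable call contribute to neither S nor L. This keeps S ≤ L exact
  under heavy missingness.
- *Gap policy*: any gap in the focal species excludes the column from that
  species' SNP statistics. This is conservative; indels are counted
  separately (a maximal run of gap columns in one sequence is one event,
  deduplicated across accessions sharing identical runs) and never enter S.
- *Marginalization consistency*: restricting an alignment to one species and
  re-profiling reproduces that species' counts exactly; the tests enforce
  this.

## Diversity: Watterson's θ and π

With S segregating sites over L evaluable sites in a sample of n sequences,
Watterson's estimator is θ̂ = S/(aₙ·L), aₙ = Σᵢ₌₁ⁿ⁻¹ 1/i. Nucleotide
diversity π is estimated per column via the unbiased heterozygosity
h = n/(n−1)·(1 − Σₐ pₐ²) with the *column-specific* sample size, and
π̂ = Σ h / L. On complete data this equals the brute-force mean pairwise
Hamming distance per site exactly (an equality the tests assert against an
independent all-pairs oracle); with missing data it degrades gracefully
instead of dropping columns.

For the pooled per-species report, θ̂ uses the species' nominal accession
count for aₙ, mirroring the single "number of individuals" convention of
published diversity tables; since per-column sample sizes vary under missing
data, the mean evaluable-site sample size is available as
`n_policy = "mean_site"`. Reports round θ and π to 4 decimals; in-memory
results are full precision.

## Divergence: Tajima–Nei distance, between-group means, NJ

For two sequences compared at the columns where both carry bases (pairwise
deletion), with mismatch proportion p, averaged base frequencies gᵢ, and
mismatch-type relative frequencies xᵢⱼ:

h = Σᵢ<ⱼ xᵢⱼ²/(2gᵢgⱼ),  b = ½(1 − Σgᵢ² + p²/h),  d = −b·ln(1 − p/b).

This "equal input" distance assumes equal rates among sites and no
transition/transversion asymmetry but corrects for base composition. Under
uniform composition and a uniform mismatch spectrum, b = 3/4 and d collapses
to the Jukes–Cantor formula — the tests verify this algebraic limit to
1e−12. Conventions at the edges: d = 0 when p = 0 (h is then undefined);
when p ≥ b (possible at saturation) the distance is *flagged undefined,
never clamped*. Undefined pairs are excluded from between-group means and
counted; a tree is refused, with the offending pairs named, if any needed
entry is undefined.

Between-species distances average the per-accession-pair distances over all
cross-species pairs **on the concatenated alignment** (the between-group
mean convention of the standard distance software), rather than averaging
per-gene distances — concatenation weighs genes by their comparable length
and is how the reference tables in this literature are produced. Pairwise
deletion, not complete deletion, is the default for the same reason.

The neighbor-joining tree is plumbing, not inference: `nj_tree()` delegates
the Saitou–Nei agglomeration to `ape::nj()` (deterministic for a given label
order) and returns Newick text. It exactly recovers additive 4-taxon
matrices, which the tests check by reconstructing random additive matrices.
Maximum-likelihood trees, model selection and bootstraps are out of scope.

## Trans-specific polymorphism

A column yields a trans-specific locus for an unordered allele pair when two
or more species are each *internally polymorphic for exactly that pair*
(biallelic within the species, n ≥ 2, no gap call in that species).
Decisions worth recording:

- A third allele inside a species disqualifies *that species only*, not the
  column — the defining notion is "same segregating allele pair".
- Singletons are admitted (no frequency threshold), because shared ancestral
  variants surviving at low frequency are precisely the signal.
- Mutation classes fold complements — A/G with T/C (transitions), A/C with
  T/G; A/T and C/G are self-complementary — matching how such classes are
  reported in the field.
- Per species-pair counts expand a locus shared by k species to all
  C(k,2) pairs by default, so the pair-table total exceeds the locus count
  whenever k > 2 (the report footer says so). A `"primary"` attribution
  (each locus counted once, for the lexicographically first pair of its
  sharing set) is available since the literature does not always state its
  convention.

The package makes no attempt to distinguish true shared ancestral
polymorphism from recurrent mutation or alignment error; at the divergence
depths where trans-specific sites are common, recurrent mutation is rare,
and the simulator's infinite-sites mode excludes it by construction.

## The HKA test

For loci i = 1..L between species A and B, the observations are S_Ai, S_Bi
(within-species segregating sites) and D_i (mean pairwise between-species
differences, including the ancestral component — *not* net divergence,
because the neutral expectation E[D] = θᵢ(T + (1+f)/2) already contains the
ancestral (1+f)/2 term). The moment equations

- Σ S_Ai = Σ θᵢ a(n_Ai)
- Σ S_Bi = f Σ θᵢ a(n_Bi)
- Σ D_i = (T + (1+f)/2) Σ θᵢ
- S_Ai + S_Bi + D_i = θᵢ·(a(n_Ai) + f·a(n_Bi) + T + (1+f)/2)

are solved by fixed-point iteration: f initialized from the ratio of summed
polymorphism, then θᵢ, f, T updated in turn until the maximum relative
parameter change is below 1e−10 *and* the aggregate equations hold to 1e−9
in count units (the residual check is needed because parameter stability
alone can leave ~1e−8 residuals). The first aggregate equation is implied by
the rest and serves as a conservation check. X² sums the standardized
squared deviations of all 3L observations with the model variances
Var(S) = E + θ²b(n), Var(D) = E + (θ(1+f)/2)², and is referred to
χ²(2L−2). Sample sizes are per-locus evaluable accession counts, so a(n)
and b(n) are computed per locus. Zero-information loci (both species
monomorphic, D = 0) are dropped and logged.

Per-gene significance uses the locus' summed component X²ᵢ against the
χ²(1) quantile at α — a documented proxy, since the per-locus convention of
the usual desktop implementation is not published.

**Known calibration property.** The model variance of D is the variance for
a *single* cross-species sequence pair, but the observation is the *mean*
over all n_A·n_B pairs, whose true variance is smaller; S and D also share
within-species branches and correlate positively. Both effects make X²
stochastically smaller than its nominal χ² reference, i.e. the test is
conservative — a property already noted by its original authors. Under this
package's null simulations (10 loci, θ = 3/locus, T = 5, n = 10/10) the
dataset-level rejection rate at α = 0.05 is about 0.013 and the X² QQ slope
against χ²(18) about 0.86. Re-running with single-pair divergence moves
rejection to ≈ 0.02, confirming the averaging convention as the cause. The
mean-pairwise convention is retained because it is what the field's tools
compute; consumers should read HKA p-values as conservative.

## The synthetic-data generator

The simulator is a stated world, fixed once: eight species named after the
*Glycine* panel it emulates, accession counts (15, 12, 12, 15, 12, 12, 10,
12), per-species θ from 0.0011 to 0.0040/bp, an ultrametric species tree
whose splits (1.7 to 15 coalescent units, θ_ref = 0.003) give expected
between-species divergences θ_ref(τ+1) of ≈ 0.008–0.048/bp, 52 genes of
500–1500 bp, a 3% missing-gene probability and a 5% probability of an
N-masked segment covering 5–30% of a gene. Time is in units of 2N_ref
generations; species s coalesces at relative rate θ_ref/θ_s, so
E[S] = θ_s·aₙ·L within species while mutations fall at the common rate
θ_ref/2 per site per unit time. θ = 0 everywhere (including ancestors) is
interpreted as zero mutation rate.

Infinite sites is the default because it gives clean truth bookkeeping —
every mutation is a column, and the truth bundle records which mutations are
polymorphic in ≥ 2 species (the detectable trans-specific sites). A
finite-sites Jukes–Cantor mode exists to exercise the distance machinery
under recurrent substitution; it keeps no per-mutation truth.
`ancestral_sharing_mode()` rescales the tree so the shallowest split sits at
0.05 units and triples the ancestral θ, the regime where incomplete lineage
sorting leaves abundant trans-specific variation; at the default depths the
expected count is ≈ 0, and the tests assert both directions.

Randomness derives entirely from one seed: gene lengths and per-gene
sub-seeds are drawn up front, and each gene runs on its own sub-stream, so
gene i's output never depends on whether other genes were generated, and the
same seed yields byte-identical output files.

What the generator does **not** emulate: recombination within genes,
migration and admixture, selection, realistic indel evolution (gaps arise
only through masking, never as evolutionary events), base-composition
heterogeneity along sequences, and alignment error. A green test therefore
establishes estimator correctness under the neutral multispecies coalescent
with missing data — not robustness to misalignment, paralogy or selection,
which real panels must address upstream.

## Numerical and degenerate-input conventions

- Harmonic sums are computed by direct summation (n is at most a few dozen).
- Distances: undefined (p ≥ b or no comparable sites) is a flag, never an
  exception at pair level; it becomes an error only where a downstream
  consumer (NJ) cannot proceed.
- HKA: non-convergence raises a classed error carrying the last iterate;
  < 2 usable loci is an insufficient-data error; all-zero observations a
  degenerate-data error.
- Empty data (no evaluable sites, all genes filtered) raise classed
  empty-data errors rather than returning NaN.
- Report determinism: output headers carry version, seed and a hash of the
  semantic settings only, so byte-identical reruns are testable.

## Limitations

Beyond the generator's non-goals above: the package assumes its inputs are
correctly aligned single-copy orthologs (no paralog screening), computes no
sliding-window statistics or Tajima's D, offers no coalescent-simulation
p-values for HKA (the χ² approximation only), and its NJ tree is a
convenience summary, not a substitute for likelihood-based phylogenetics.
Replicating published tables from a real panel requires that panel's
alignments; the test suite instead anchors every estimator to independent
oracles and coalescent theory on simulated data.
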