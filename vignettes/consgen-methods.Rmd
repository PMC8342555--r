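---
title: "Methods and modelling choices in consgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in consgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`consgen` implements a dual-marker conservation-genetics workflow for small,
fragmented fish populations: neutral microsatellite analyses on one side and
adaptive MHC class II β1-domain analyses on the other, together with the
simulators needed to validate every stage against known truth. This vignette
explains the models, the tunable parameters that matter, the numerical
choices, and what the synthetic generators do and do not establish.

## 1. Neutral side: microsatellite statistics

### Diversity and equilibrium tests

Per-locus, per-population summaries (`locus_summaries()`) report the allele
count *A*, rarefied allelic richness *A~R~*, observed heterozygosity *H~O~*,
Nei's unbiased expected heterozygosity
*H~E~* = 2n/(2n−1)·(1−Σp²), and *F~IS~* = 1 − *H~O~*/*H~E~*. Rarefaction is
hypergeometric, to a gene-copy count *g* that defaults to the smallest
per-population, per-locus typed gene-copy count in the data set (the Fstat
convention); supplying a larger *g* is an error rather than an
extrapolation.

Hardy–Weinberg and linkage exact tests (`hwe_exact_test()`,
`ld_exact_test()`) are Markov-chain estimates of Fisher-style exact p-values,
with the classic chain schedule (1000 batches × 10 000 iterations, burn-in
10 000) as the default and the standard error taken across batches. Both
chains exploit the same fact: a *uniform* distribution over latent token
arrangements (random union of gametes given allele counts; random
permutation of one locus's genotypes given margins) induces exactly the
conditional distribution of tables given their margins. The swap proposal is
therefore symmetric and always accepted — there is no Metropolis ratio to
get wrong — and the p-value is the chain fraction of tables whose
conditional probability does not exceed the observed one. For two alleles
the suite checks the chain against complete enumeration.

The null-allele screen uses the Brookfield-1 estimator
r = (H~E~−H~O~)/(1+H~E~), floored at zero, plus a homozygote-excess flag
based on the 95th percentile of homozygote counts simulated under HWE from
the observed allele frequencies.

### Differentiation

* `fst_weir_cockerham()` implements the Weir–Cockerham (1984) variance
  components a, b, c per allele per locus, combined by summing components.
  Negative estimates are reported as computed; truncation is a display
  decision, not an estimation one. Pairwise p-values permute individuals
  between the two populations.
* `rst_slatkin()` runs the same three-level ANOVA
  (populations / individuals / gene copies) on allele size in repeat units
  (bp divided by the locus motif length), components summed over loci with
  no per-locus standardisation — the Arlequin-style choice.
* `gst_nei()` uses unweighted means: H~S~ averaged over populations, H~T~
  from mean allele frequencies, both averaged over loci before the ratio.
* `ibd_test()` regresses the lower triangles and permutes population labels
  for a one-tailed Mantel test of positive association; untransformed
  genetic distance against waterway km is the default, log transforms are
  available but off.
* `pcoa_from_fst()` is classical metric scaling of the pairwise matrix.

The test suite holds θ and R~ST~ to *independently coded* oracles — a
mean-squares nested ANOVA for θ and pairwise-distance sum-of-squares
identities for R~ST~ — exactly (machine precision) on randomised small
instances, missing data included.

### Bottleneck detection

`het_excess_test()` asks whether *H~E~* exceeds the heterozygosity expected
at mutation–drift equilibrium for the observed allele count *k* — the
transient signature of a recent bottleneck. Equilibrium samples conditional
on *k* are drawn by rejection: θ is initialised at the Ewens (infinite
alleles) solution of E[k | θ, n] = k, coalescent samples are simulated under
the working mutation model, and only those with allele count exactly *k* are
kept (cap: 50 000 attempts per locus). The per-locus standardised excess
DH = (H~E~ − mean H~eq~)/sd(H~eq~) feeds a one-tailed Wilcoxon signed-rank
test across loci. The headline mutation model is the two-phase model with
90% single-repeat steps and 10% multi-step jumps, jump length
1 + Geometric(0.5), sign equiprobable. Monomorphic loci are excluded with a
log notice; all-zero DH degenerates to p = 1.

Two calibration facts, measured under the matched generator (100
replicates): the Ewens starting value must be pilot-calibrated to the
two-phase model or the test runs hot (type-I 0.15 at nominal 0.05); and
even calibrated, per-locus θ estimation couples each locus's reference
distribution to its own observed k, leaving type-I ≈ 0.10. With
`shared_theta = TRUE` — appropriate when loci are exchangeable, as in the
calibration world — the pooled estimate brings type-I to ≈ 0.07, within the
0.08 tolerance the acceptance suite demands. The default remains the
classical per-locus protocol.

`mode_shift()` pools alleles across loci into ten frequency classes of
width 0.1; "L-shaped" means the (0, 0.1] class holds the (possibly tied)
largest allele count — ties deliberately favour the no-bottleneck reading.

`m_ratio()` computes M = k/(r+1) per locus with r the size range in repeat
units, averages over loci, and flags means below the conventional 0.68
threshold. Two properties of this statistic, reproduced by our simulations
and worth knowing: (i) it responds to *recent, severe* declines from a
*diverse* baseline (our power world: θ = 40 equilibrium, size 5000 → 25 for
the last 50 generations); (ii) long or total collapses do **not** depress
M — once the sample coalesces inside the bottleneck, both k and r shrink
together and M returns toward 1. The full critical-value machinery
(simulated M~c~) is out of scope; the fixed 0.68 threshold is applied as in
common practice.

## 2. Bayesian clustering and ΔK

`admixture_gibbs()` is a standard admixture-model Gibbs sampler:
Dirichlet(λ + counts) updates for cluster allele frequencies (independent
frequencies, λ = 1), multinomial full conditionals for copy origins,
Dirichlet(α + origin counts) for admixture rows, and a Metropolis random
walk for the symmetric α with a uniform prior on (0, 10]. Binary MHC
presence/absence matrices (1/0/−1) are treated as haploid two-state loci,
−1 skipped, so one sampler serves both data types.

Two burn-in-only adaptations matter in practice. During the first half of
burn-in (a) the origin conditionals are tempered, with the temperature
annealed linearly from 3 to 1, and (b) α is held at its initial value.
Without these, chains at the true K intermittently lock into poor labelling
modes (one population split, two merged) that single-site updates cannot
escape; with them, replicate runs at and below the true K agree to within a
few log-likelihood units. Burn-in states are discarded, so the recorded
chain is an ordinary Gibbs sampler.

Each run reports two summaries of fit: `L`, the posterior mean of the
mixture log-likelihood, and `lnPD = mean − var/2`, the harmonic
model-evidence estimate that the original Structure program prints and that
the Evanno ΔK procedure was designed around. ΔK
(`evanno_delta_k()`) is mean|L(K+1) − 2L(K) + L(K−1)| / sd(L(K)) across
replicate runs, undefined at the endpoints, with a hard error when
sd(L(K)) = 0. Use `lnPD` for ΔK: the raw posterior mean is so reproducible
between converged runs that its sd degenerates and ΔK collapses to its
well-documented K = 2 bias.

Honest limitations: ΔK remains a fragile instrument. In our synthetic
three-population world (equidistant divergence, F~ST~ ≈ 0.15–0.2, 30 loci)
a 4-runs-per-K economy protocol recovers K = 3 in 7 of 10 data seeds, the
failures being near-ties with ΔK(2); the study-style 10-runs-per-K protocol
stabilises the run-to-run dispersion estimates and is what the acceptance
test executes. This fragility matches the literature on ΔK's hierarchical
(K = 2) bias and is reported as-is rather than tuned away. Assignment
accuracy at the true K is 1.00 in every seed we examined — the sampler, not
the model-choice heuristic, is the reliable component.

## 3. Adaptive side: MHC genotyping

The read pipeline mirrors a two-step tailed-PCR MiSeq design with 8-bp dual
indices: `quality_filter()` (mean Phred ≥ 30 — the per-base reading would
discard nearly every read and is available as `quality_mode = "min"` — no
ambiguous bases, length within ±5 bp of the expected amplicon),
`map_to_draft()` (best gapless identity against draft locus sequences,
configurable 0.85 threshold), `demultiplex_and_trim()` (exact dual-index
match, primers with at most one mismatch honouring IUPAC degeneracy), then
`validate_alleles()`:

1. within an individual, a variant survives with more than 1000 reads *or*
   a within-amplicon frequency above 0.1 (the "or" is implemented as
   written; an "and" mode exists for sensitivity analysis);
2. across a population, a variant becomes an allele if it appears in at
   least two individuals, or in exactly one individual that also carries an
   independently validated allele (the heterozygote exception — read
   strictly, so two mutually private variants in one individual are both
   rejected, which blocks chimeric pairs).

Genotypes are the up-to-two highest-count validated variants; more than two
flags putative contamination/paralogy (top two kept, warning logged).
Individuals with a single validated allele are counted as homozygous for
frequency purposes (`single_allele = "haploid"` changes this).

The amplicon simulator generates variant count tables directly (alleles,
single-crossover chimeras between an individual's two alleles, per-base
substitution errors, optional index hopping), and can also emit a fully
indexed FASTQ to exercise the demultiplexer. At study-like settings (0.3%
per-base error, 5% chimeras, depth 2000) validation recovers the planted
catalog with recall and precision 1.0 in our 20-seed acceptance run; the
generator draws genotypes so that every allele has at least two carriers,
because the validation protocol is by construction blind to alleles whose
only carrier lacks an anchoring shared allele.

## 4. Selection statistics

`nei_gojobori()` computes dN/dS per sequence pair: synonymous site counts
per codon as the fraction of non-stop single-nucleotide changes that are
synonymous (averaged over the two sequences), differences by equal-weight
enumeration of substitution pathways with stop-crossing pathways dropped and
weights renormalised (if every pathway is blocked, all are counted — a
documented fallback), Jukes–Cantor correction d = −(3/4)·ln(1 − 4p/3)
applied to the pooled proportions, and the overall value as the mean over
all unique pairs (the MEGA convention). The codon bootstrap (default 2000
replicates, resampling within the analysed partition) yields SE(dN), SE(dS)
and the one-tailed Z test of dN > dS; bootstrap replicates that leave the
Jukes–Cantor domain are dropped, and a resampled codon set with no
synonymous (or no nonsynonymous) sites contributes a zero proportion rather
than 0/0. p ≥ 3/4 in the observed data is a hard
error naming the offending pair; `correction = "none"` exists for tiny
hand-checked alignments.

The peptide-binding-residue mask defaults to the 17 β1-domain codons
9, 25, 27, 34, 35, 44, 53, 57, 58, 62, 65, 67, 68, 71, 75, 78, 79 (numbering
starts at codon 9), shipped as `inst/extdata/pbr_positions.csv` and fully
configurable. Codon-site likelihood models (M1a/M2a, M7/M8, BEB) and the
FEL/FUBAR/MEME family are external-tool territory; `write_phylip()` exports
alignments for them.

The codon simulator evolves sites independently along a rooted tree under a
Goldman–Yang-style scheme (transition bias κ, per-site ω scaling the
nonsynonymous flux, stops forbidden), with branch lengths in expected
neutral substitutions per codon. Note that with κ > 1 the Nei–Gojobori
estimator is conservative (ω biased below its simulated value); the
neutrality calibration in the tests therefore uses κ = 1, while the power
analysis (ω = 4 at PBR codons, κ = 2, 20 sequences, 0.3 subs/codon) reflects
the biased regime a real analysis would face. That bias has a measurable
cost: at κ = 2 the 50-replicate partition-test power is 0.72 against a 0.8
target (one replicate saturates past the Jukes–Cantor domain and counts as
a miss), while the identical pipeline at κ = 1 reaches 0.84. The acceptance
test keeps the κ = 2 world and is allowed to stay red rather than retuning
the generator to the estimator — the honest summary is that NG86 trades
power for simplicity whenever transitions are favoured, which is worth
knowing before relying on it for marginal selection signals.

## 5. Supertyping

`build_descriptor_matrix()` translates each allele's PBR codons and encodes
the residues with the published five-dimensional z-scales (z1
hydrophobicity, z2 steric bulk, z3 polarity, z4/z5 electronic effects;
20 × 5 table shipped as `inst/extdata/zscales_sandberg.csv`), concatenated
in position order, so alleles synonymous at every PBR codon share a row.

`choose_k()` votes across five canonical cluster-validity indices
(Calinski–Harabasz, mean silhouette, Davies–Bouldin, Dunn, gap statistic
with the Tibshirani one-SE rule) over k-means partitions (50 restarts);
majority wins, ties resolve to the smaller K. The original workflow polled
thirty indices through NbClust; five well-chosen indices preserve the
majority-rule semantics at a fraction of the code, and the index list is
exposed in the result so the sensitivity is visible. `dapc_assign()` centres
and scales, retains principal components to 90% variance (capped at n − K),
seeds groups by k-means and assigns by linear discriminants — the DAPC
recipe with the interactive axis choice frozen at a documented default.
K = 1 short-circuits to a single label.

## 6. MHC population genetics

Haplotype diversity A~d~ = n/(n−1)·(1−Σp²) over gene copies; nucleotide
diversity π is the copy-pair mean proportion of differing sites (the
frequency-weighted form with the n/(n−1) correction is algebraically the
same, and the tests hold it to a brute-force pair loop). φ~ST~ is the
two-level AMOVA ratio with the number of differing sites used directly as
the squared Euclidean distance — the per-site 0/1 embedding makes the
difference *count* the squared distance, a convention that is easy to square
twice by accident — and permutation p-values over gene copies (default
1000, so the smallest attainable p is 1/1001). No substitution-model
correction is applied to these short intra-species alignments.
`encode_for_structure()` produces the 1/0/−1 presence matrix per allele or
per supertype, with untyped individuals as −1 rows.

## 7. Simulators: what a green test establishes

The forward Wright–Fisher simulator (`simulate_msat()`) is deliberately
simple — per-generation multinomial reproduction over gene copies, row-wise
migration (`island_migration_matrix()` uses the convention where a deme
receives a fraction m equally from the other demes, under which the two-deme
Weir–Cockerham θ expectation is 1/(1+8N~e~m), θ being referenced to the
between-deme comparison), SMM/IAM/TPM mutation, optional bottleneck — and is
validated against those classical expectations, not against real data. The
coalescent sampler (`coalescent_msat()`) adds piecewise-constant population
size for equilibrium and decline scenarios at negligible cost. Neither
models selection on microsatellites, size constraints on the repeat ladder,
genotyping error, or allele dropout; a green recovery test therefore
establishes that the *inference machinery* is correct under its own model
assumptions, not that the model captures every feature of real data.
Initial standing variation is uniform over 15–24 repeats, so short-horizon
scenarios start from high shared diversity, which is what the divergence
scenarios exploit.

Replicate counts in the routine test suite are scaled down from the stated
designs (each file says so where it happens) to fit a single-CPU budget;
the acceptance tests keep the stated counts for the oracle sweeps,
calibrations, power runs and end-to-end genotyping.
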