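---
title: "Pedigree-based imputation from sparse GBS panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based imputation from sparse GBS panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedimpute)
```

# The problem

Whole-genome sequencing (WGS) of every member of a pedigreed cohort — a
primate breeding colony, a livestock herd — is expensive. A cost-effective
alternative characterizes the cohort in two tiers: a *sparse* panel of
reliable markers is genotyped in everyone by reduced-representation
sequencing (genotyping-by-sequencing, GBS), and *dense* genome-wide variants
are sequenced in only a few relatives and imputed into the rest through the
pedigree. `pedimpute` implements the full strategy: designing the GBS assay
by in silico restriction digest, building framework and dense marker panels,
inferring inheritance vectors from the framework genotypes, imputing dense
genotypes, choosing which relatives to sequence, and evaluating the result on
simulated data with known truth.

# Model

## Inheritance vectors and descent partitions

For a pedigree with $f$ founders and $n - f$ non-founders there are
$m = 2(n - f)$ meioses. At a locus, the **inheritance vector (IV)**
$S \in \{0,1\}^m$ records, for each meiosis, whether the parent transmitted
the allele on its own paternal ($0$) or maternal ($1$) slot. Given $S$,
every allele slot in the pedigree maps to exactly one of the $2f$ **founder
genes** (the descent partition, `build_descent()`); IBD sharing is fully
determined.

Along a chromosome, each meiosis is modelled as an independent two-state
Markov chain: between loci at genetic distance $d$ the indicator flips with
the Haldane recombination fraction
$\theta = \tfrac12\left(1 - e^{-2d}\right)$ ($d$ in Morgans; no
interference). The joint transition kernel over IVs factorizes,
$P(S \to S') = \theta^{k}(1-\theta)^{m-k}$ with $k$ the Hamming distance.

## Single-locus likelihood

The emission probability of the observed unphased genotypes at one biallelic
marker given a descent partition sums over assignments of founder-gene
alleles (alt frequency $p$, founders in linkage equilibrium):
$$
P(\mathbf{y} \mid S) \;=\; \sum_{a \in \{0,1\}^{2f}}
\prod_g p^{a_g}(1-p)^{1-a_g}
\prod_i \mathbf{1}\{a_{g_1(i)} + a_{g_2(i)} = y_i\}.
$$
`locus_likelihood()` evaluates this sum in closed form rather than by
enumeration: a homozygous individual forces both of its genes, a
heterozygous individual imposes an unequal-allele (XOR) constraint between
its two genes, and the sum factorizes over the connected components of the
resulting constraint graph. Each component contributes either the forced
product of frequencies or the two-term sum over its two parity classes.
This makes one likelihood evaluation $O(\text{observed slots})$ and is what
lets the samplers below run at realistic marker counts. The generic
enumeration (used as the test oracle) reproduces it to $10^{-12}$.

Framework genotypes are treated as error-free by this likelihood, as the
imputation model assumes; Mendelian-inconsistent data is an error, and
`mendelian_errors()` is the documented pre-screen.

## Exact IV posterior and the blocked Gibbs sampler

For pedigrees with $m \le 16$, `exact_iv_posterior()` runs forward–backward
over all $2^m$ states. Because transitions factorize per meiosis, one HMM
step costs $m 2^m$ (a butterfly pass per bit) instead of $4^m$. Joint
realizations are drawn by backward sampling.

Larger pedigrees use `sample_iv_mcmc()`. The sampler was designed around a
mixing failure that is easy to reproduce: with fully observed genotypes, the
IVs consistent at a marker can differ by several bits at once (the phase of
a parent couples all of its children's meioses), so a sampler that updates
one meiosis — or even one individual's two meioses — at a time is reducible
or metastable; it freezes in one phase mode. `pedimpute` therefore uses
**sibship-blocked Gibbs updates**: one update jointly resamples, for one
parent, the entire bit paths of all meioses to that parent's children (both
meioses of each child) from their conditional $2^q$-state HMM along the
chromosome, with sibships chunked so $q \le 8$. In addition,
**founder-phase flips** — swapping a founder's two gene labels by flipping
the corresponding meiosis bit of each of its children at every marker — are
an exact symmetry of both likelihood and path prior and are applied with
probability $1/2$ per founder per sweep; they mix the chain across the
global phase modes. On a randomized battery of small pedigrees the sampled
per-locus marginals agree with the exact posterior to total-variation
distance $< 0.02$ with 20,000 retained samples.

The chain is initialized marker-by-marker with a *conditional gene drop*:
founder slot alleles are drawn consistent with the founder's observed
genotype, and each non-founder's two meiosis bits are drawn uniformly from
the combinations consistent with its own genotype, with bounded restarts.
Unconditioned gene-dropping until a globally consistent configuration
appears is hopeless at hundreds of markers, while per-marker consistency is
sufficient because transitions are strictly positive.

## Dense-site imputation

Dense positions between framework markers inherit their IVs by
interpolation: per meiosis,
$P(b = x \mid b_L, b_R) \propto P(b_L \to x)\,P(x \to b_R)$ with
single-interval Haldane transitions to the flanking framework markers (one
flank outside the framework span). For each retained framework IV
realization, `impute_chromosome()` draws `k_dense` (default 1) dense-position
IVs, builds the descent partition, conditions the founder-gene alleles on
the observed dense genotypes of the sequenced donors (using the same
component/parity machinery; realizations contradicting the observations are
dropped and counted), and averages the per-individual genotype posteriors
$P(RR), P(RA), P(AA)$ and per-slot allele posteriors over realizations.
Genes carried by no observed individual follow the Bernoulli($p$) prior, so
an individual unrelated to every donor receives the Hardy–Weinberg
posterior. A verification mode enumerates all dense IVs exactly on small
pedigrees and matches a full joint-likelihood brute force to $10^{-9}$.

## Genotype calling

Two calling methods are provided, mirroring the two conventions in
pedigree-imputation practice:

* **Most likely** (`call_most_likely()`): the argmax genotype, always two
  alleles; ties break toward the genotype carrying the population-major
  allele, then $RR < RA < AA$.
* **Threshold** (`call_threshold()`): both alleles are called when the
  maximum genotype posterior reaches `t_both`; otherwise a single allele
  $a$ is called when the posterior probability that the genotype *contains*
  at least one copy of $a$ reaches `t_single`; otherwise no call. The
  strict preset is `t_both = 0.98`, `t_single = 0.99`; the relaxed preset
  `0.95 / 0.98`. Lowering thresholds can only add calls.

The single-allele rule deserves a note. An alternative formulation
thresholds the per-slot allele posteriors. For founders, however, the two
slots are posterior-symmetric — founder phase is unobservable — so the slot
rule can never half-call a founder even when the allele content is certain
(for example, when a sequenced child is homozygous). The default
genotype-content rule is phase-invariant, is exactly the event against which
half-call accuracy is later scored (containment in the true allele pair),
and restores the expected behaviour of deep-relative donor sets; the slot
rule remains available via `rule = "slot"`.

# Donor selection

`expected_coverage()` scores a donor set $S$ by the expected fraction of
allele slots in the pedigree whose founder gene is carried by some member of
$S$, at a single unlinked locus — a structure-only metric computed by exact
enumeration over all $2^m$ IVs when $m \le 16$, else by Monte-Carlo gene
dropping. This descent-based coverage counts a slot as covered as soon as
its gene is carried by a donor; it does not integrate over genotype
configurations (a heterozygous carrier resolves its genes only partially),
making it an optimistic but monotone screening criterion.
`gigi_pick_rank()` greedily adds the candidate maximizing the coverage of
the augmented set; `heuristic_founders()` (most prolific founders) and
`heuristic_bottom()` (deepest childless generation) are the two common
heuristics it is compared against.

# The synthetic-data generator

`colony_pedigree()` ships a fixed 16-member, two-generation template
(ids `A`–`P`) emulating a macaque breeding colony. The real cohort's
topology is not published; the template is one instantiation consistent
with everything documented about it: founders include `A`–`E`; `K` is a
child of `D`; `E`'s only relative is the childless non-candidate `N`;
`M`, `P`, `K` are the childless bottom generation; ranked by descendant
count the three most prolific founders are `B`, `C`, `D`; and the pairwise
relationships include parent/offspring, half-sibling, half-avuncular,
half-cousin and grandparent/grandchild — the classes common in colonies
where a few sires breed with several dams. Peripheral founders (`C`, `D`
with few descendants, five founder dams) reflect the described structure in
which the founder-only sequencing strategy under-serves much of the
pedigree.

`simulate_truth()` gene-drops phased founder haplotypes with map-based
Haldane recombination and records the full latent truth (slot alleles,
founder-gene labels, true IVs). Founder alleles are independent across
markers (linkage equilibrium), matching the imputation model's assumption —
so simulation-based accuracy estimates do not probe model misspecification
from background LD, and are expected to be optimistic relative to real
colonies in that one respect.

`simulate_observation()` applies a read-depth model per cell: depth
$\sim$ Poisson($\lambda$), alt-read count $\sim$ Binomial(depth, $\mu$)
with $\mu = \varepsilon, \tfrac12, 1-\varepsilon$ for 0/1/2 true alt
copies, flat-prior maximum-likelihood calling, phred GQ, and the standard
hard filters DP $\ge 10$, GQ $\ge 20$. `apply_gbs_design()` adds
assay-level sparsity: markers outside the design are missing everywhere,
and cells within it are retained with a per-site call rate (default 0.69,
the callability typical of a PstI GBS panel); the default scenario applies
this call rate to the framework matrix, since the sparse assay's
missingness is part of the study conditions being emulated.

The default scenario (`sim_scenario()`) mirrors the canonical test-case
dimensions: one ~55 Mb chromosome at 1 cM/Mb, 833 framework markers
(~65 kb spacing, alt frequencies uniform in 0.25–0.75 so the minor-allele
frequency exceeds 0.25) and 5,010 dense markers (~10 kb spacing) whose alt
frequencies follow a right-skewed Beta(1, 3) truncated to [0.02, 0.98] —
a pragmatic stand-in for the site-frequency spectrum of variants
discovered in a small sequencing panel. Framework and dense markers are
gene-dropped as one linkage chain so they share their recombination
history.

# GBS assay design

`digest_genome()` performs an exact in silico restriction digest: motif
occurrences (IUPAC degeneracy via `Biostrings`; `N` never matches;
non-palindromic motifs scanned on both strands) cut each contig into
fragments tiling it exactly, with terminal fragments retained.
`size_select()` keeps the 200–500 bp library window (bounds inclusive),
`mask_filter()` drops fragments with more than 50% soft-masked (lowercase)
bases — the stand-in for a repeat annotation, since no numeric repeat
criterion is standard — and `rank_enzymes()` orders enzymes by whether
their in-window fragment count falls in the 60,000–100,000 target band
(within the band, more captured bp ranks higher; outside it, distance to
the nearest bound). `synth_genome()` builds test genomes with a known
number of planted sites and recorded repeat blocks.

# Evaluation

Accuracy is allele-level: each called allele is matched against the true
unphased genotype by multiset containment — a two-allele call contributes
two attempts and `2 - |dose_called - dose_true|` correct alleles; a
single-allele call contributes one attempt, correct when the allele occurs
in the true pair. `fraction_imputed()` reports both the marker-level
fraction (markers with at least one called allele) and the allele-level
fraction; the figures in the field are plotted at marker level, and the
most-likely method is always 1 at marker level by construction.
`stratify_by_freq()` bins every true allele copy by its population
frequency (half-open bins `[0, 0.25), ..., [0.75, 1]`), reporting per-bin
imputation rate and accuracy, with singletons — exactly one copy among 30
reference chromosomes — as their own stratum. `genotype_concordance()`
compares two call sets on cells non-missing in both.

Three experiment drivers reproduce the study designs on simulated data:
`run_strategy_comparison()` (greedy coverage ranking vs founders vs bottom
generation, IV inference shared per replicate), `run_wgs_ratio_sweep()`
(donors added consecutively in a ranking) and `run_panel_density_sweep()`
(nested framework panels at per-site callability thresholds).

# Numerical and design choices

* Coordinates: VCF and marker tables are 1-based; fragment intervals are
  0-based half-open; conversions happen only at I/O boundaries.
* The default genetic map is constant 1 cM/Mb (configurable; anchored maps
  interpolate linearly and extrapolate at the boundary rate).
* Threshold presets follow the strict = (0.98 both, 0.99 single) /
  relaxed = (0.95, 0.98) convention; both values are configurable.
* Monte-Carlo donor-selection draws and all simulators take explicit seeds;
  every pipeline stage is bit-reproducible given its seed.
* Degenerate inputs: markers with zero informative observations leave the
  IV posterior at the transition prior; dense sites where every sampled
  realization contradicts the donors' genotypes are flagged and skipped
  with a count rather than failing the run (real call sets contain errors).
* Inbred pedigrees are rejected at construction (loop handling is out of
  scope); half-specified parentage is an error rather than silently padded,
  because padding changes the meiosis count and hence the likelihood.

## Problem sizes used by the shipped verification suite

Exactness checks (HMM vs enumeration, likelihood vs enumeration, dense
posterior vs joint brute force) run on pedigrees with up to 6 meioses and
up to 4 markers, where full enumeration is feasible. Sampler calibration
uses 20,000 retained samples. End-to-end experiments run the full
833 + 5,010 marker chromosome for the headline recovery check, and scaled
chromosomes (120–150 framework, 240–300 dense markers, 300–400 IV samples)
for the replicated strategy and donor-number sweeps; these sizes preserve
the contrasts of interest while keeping replication practical. Because the
blocked sampler's marginals verify against exact posteriors at small size,
shorter burn-ins (a few hundred sweeps) are used for the large simulated
scenarios than the conservative package defaults (1,000 sweeps, thin 5).

# Limitations

* Founder linkage equilibrium and a known, error-free framework panel are
  assumed by the likelihood; background LD, genotyping error inside the
  IV machinery, and map misspecification are not modelled.
* The coverage metric is descent-based and does not integrate over
  genotype configurations; a full-genotype refinement is a documented hook.
* X-chromosome inheritance, indels/CNVs, multi-allelic sites and inbred
  pedigrees are out of scope.
* Simulation results quantify the method's behaviour under its own model
  assumptions; they do not by themselves establish accuracy on real
  colony data. In particular, with complete and error-free donor
  genotypes and framework panels dense enough to pin the inheritance
  vectors, the simulated fraction of markers imputed for well-connected
  recipients is substantially higher than what sparse, noisy real assays
  deliver; accuracy comparisons transfer more readily than completeness
  comparisons.
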