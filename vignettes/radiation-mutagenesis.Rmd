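---
title: "Modelling ionizing-radiation mutagenesis across DNA-repair genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ionizing-radiation mutagenesis across DNA-repair genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsig)
```

# The problem

Mutation-accumulation experiments in *C. elegans* expose clonal lines to a
genotoxin — here ionizing radiation (IR) from a Cs-137 gamma source — and
sequence single F1 descendants, so that every called variant is a germline
mutation acquired in one generation. Comparing wild-type worms with strains
carrying defects in individual DNA-repair pathways (nucleotide excision
repair, homologous recombination, translesion synthesis, base excision
repair, end joining, ...) asks which pathways normally suppress which kinds
of radiation damage. radsig implements the statistical machinery of such a
study end to end: mutation channelization, dose-response rate estimation, a
hierarchical Bayesian signature model with per-genotype fold-changes,
clustered-mutation detection, and cross-genome spectrum adjustment — plus a
synthetic-data generator that reproduces the experimental design so every
stage is testable without sequencing data.

# The 119-channel scheme

Variants are classified into a fixed, ordered set of 119 channels:

* **96 SNV channels** — the six pyrimidine-centred substitution types
  (C>A, C>G, C>T, T>A, T>C, T>G) crossed with the 16 combinations of 5' and
  3' flanking base. Context is always read from the supplied reference
  genome, never from the VCF; substitutions with a purine reference base are
  reverse-complemented (mutated base and both flanks) onto the
  pyrimidine-centred channel, so a variant and its reverse-complement
  representation land in the same channel.
* **1 DNV and 1 MNV channel** — aggregate channels for di- and
  multi-nucleotide substitutions.
* **14 indel channels** — deletions and insertions binned by size
  (1, 2–5, 6–50, 51–400, >400 bp) and deletion-with-insertion events binned
  by deleted length (1–5, 6–50, 51–400, >400 bp). The bin edges below 50 bp
  follow the size ranges conventionally displayed for this assay; the edges
  above 50 bp are a package convention.
* **7 SV channels** — tandem duplication, large deletion, inversion,
  complex, translocation, interchromosomal rearrangement, foldback.

SNVs at the first or last base of a chromosome, or with an `N` in the
context window, have no defined trinucleotide; they are routed to an
`unclassified` bucket that is reported alongside the spectrum, so that
classified + unclassified always equals the number of input records.

Coordinates are 1-based inclusive throughout (VCF convention). Indels are
normalized to unanchored form on reading (left-trimming the shared anchor
base), so classification sees pure event lengths.

# Dose-response rate estimation

Per-sample counts of a mutation class are modelled as
$y_i \sim \mathrm{Poisson}(b + r \, d_i)$ with background $b \ge 0$
(mutations per sample at dose 0) and rate $r \ge 0$ per Gray — an additive,
identity-link Poisson regression with a non-zero intercept, not a log-link
GLM: doses add expected mutations rather than multiplying them. The
likelihood is maximized under the non-negativity constraints
(`stats::optim`, L-BFGS-B, two-stage polish), standard errors come from the
observed Fisher information at the maximum, and boundary solutions get
one-sided standard errors from the corresponding diagonal information
element. Rates are reported per 80 Gy, the top dose of the assay. An
all-zero count vector yields the degenerate fit $(0, 0)$ with a flag.

Genotypes are screened for a dose response before signature fitting: for
each of the three broad classes (substitutions, indels, SVs), the
per-sample class total is correlated with dose (Pearson, two-sided p); a
genotype passes when at least two classes show a positive correlation with
p below the screen threshold (default $\alpha = 0.05$, exposed as a config
knob — the criterion is fixed by the assay design, the $\alpha$ is not).
Zero-variance classes have an undefined correlation and count as
non-significant.

# The hierarchical signature model

Observed counts of sample $s$ in channel $k$ follow

$$Y_{s,k} \sim \mathrm{Poisson}\!\left(G_{g(s),k} +
\frac{d_s}{80}\, \mathrm{IR}_k \, e^{L_{g(s),k}}\right)$$

where $G_{g,k} \ge 0$ is a per-genotype background shared by that
genotype's samples, $\mathrm{IR}_k \ge 0$ is the wild-type radiation
signature in expected counts per 80 Gy (dose is scaled internally by 80 so
the signature is directly in the reporting unit), and $L_{g,k}$ is the log
fold-change of genotype $g$'s radiation signature relative to wild-type.
Fixing $L_{\mathrm{wild\text{-}type},k} \equiv 0$ identifies the model.

## Priors

The model statement above prescribes no priors, so these are the
package's choices:

* $G_{g,k}$ and $\mathrm{IR}_k$ carry independent half-normal priors whose
  scale is set so that the *prior mean equals the average moment estimate*
  of that parameter type — dose-0 sample means for the background,
  wild-type through-origin regression slopes for the signature. The
  magnitude matching matters: with $\mathcal{O}(1)$ counts per channel, a
  prior that is flat over a range much wider than the truth gives every
  channel rate a posterior mean of roughly $(y + 1)/\text{exposure}$ — one
  spurious count per channel — which summed over 119 channels inflates the
  class aggregates severely and forces the fold-changes to compensate
  downward. Anchoring the prior at the per-channel magnitude removes this
  small-count bias while leaving well-measured channels
  likelihood-dominated.
* $L_{g,k} \sim \mathcal{N}(0, 3)$. The prior must be wide on the log
  scale: at the study's sample sizes each channel carries a Fisher
  information of only ~4 on its fold-change, so a $\mathcal{N}(0,1)$ prior
  would shrink a true 2-fold change by ~20% — enough to push the planted
  value outside the 95% interval systematically. With sd 3 the residual
  shrinkage is ~3%, while channels with no information (e.g. an empty SV
  channel in a small experiment) remain regularized enough to keep the
  sampler stable.

## Sampling

Because the likelihood factorizes over channels, the posterior is explored
by an adaptive Metropolis-within-Gibbs sampler whose blocks (per-genotype
background row, signature vector, per-genotype fold-change row) are
proposed for all 119 channels simultaneously with componentwise
acceptance. Rates are sampled on the log scale (with the Jacobian term);
proposal scales adapt per channel toward 44% acceptance during warmup and
are frozen afterwards. Chains start from moment estimates (jittered per
chain): backgrounds from dose-0 means, the signature from a wild-type
through-origin regression, fold-changes from per-genotype slope ratios.
Defaults are 4 chains with 1000 warmup and 1000 retained iterations, fully
determined by the seed.

Diagnostics are computed on the class aggregates that downstream analyses
report: split-chain $\hat R$ (flag above 1.1) and effective sample sizes
(flag below 50). A flagged fit is refused by the comparison and divergence
functions unless explicitly overridden.

## Reported quantities

* **Fold-changes** (`class_fold_change`) are posterior means of the
  class-aggregate rate ratio
  $\sum_k \mathrm{IR}_k e^{L_{g,k}} / \sum_k \mathrm{IR}_k$ — the
  rate-weighted mean of per-channel fold-changes, computed per draw. This
  aggregate is well identified even when single-channel fold-changes are
  noisy. (Averaging per-channel posterior means of $L$ with fixed weights
  would be badly biased: within a draw, $\mathrm{IR}_k$ and $L_{g,k}$ are
  anti-correlated because only their product is constrained by the data.)
* **Genotype comparisons** (`compare_to_wildtype`) use the z statistic
  $(r_g - r_{wt})/\sqrt{SE_g^2 + SE_{wt}^2}$ on the class-aggregate
  posterior means and standard deviations, with two-sided normal p-values
  and Benjamini–Hochberg FDR control across the genotype × class family
  (significant at q < 0.05 by default). The same statistic serves the
  rate-estimate and clustering comparisons.
* **Profile divergence** (`profile_divergence`) is the cosine distance
  between $\mathrm{IR} \cdot e^{L_g}$ and $\mathrm{IR}$, with mean and 95%
  interval over draws. Because "significantly different profile" has no
  printed formula in this assay, the package flags a genotype when any of
  its class-aggregate comparisons reaches BH q < 0.05, and reports the
  distance interval alongside.

# Clustered mutations

Cluster input is the start points of substitutions and indels (SVs are
excluded; DNVs/MNVs count once at their start). Two callers are provided:

* **Window caller** (default): clusters are maximal runs of ≥ 2 positions
  in which every consecutive gap is ≤ 1000 bp. This parameter-free
  formulation reproduces the connected components of any fixed 1000-bp
  sliding-window scan.
* **HMM caller**: a two-state hidden Markov model over the inter-mutation
  gaps of each chromosome, with geometric emissions (clustered mean 100 bp;
  background mean estimated per chromosome as span/gaps unless supplied)
  and the transition probabilities used for cancer-genome analyses
  (0.01 clustered→background, 0.1 background→clustered). The Viterbi path
  is decoded exactly; a maximal run of clustered gaps becomes one cluster
  whose members are the touched positions. Defining states on gaps rather
  than mutations makes a single short gap yield a two-mutation cluster and
  keeps the decode unambiguous; the emission choice is a package
  convention, exposed in `hmm_params()`.

Clusters are called per sample by default — biologically a cluster cannot
span animals — with a pooled per-genotype × generation mode available for
fidelity with analyses that pool clonal lines. Summaries report the
clustered proportion of eligible mutations, the cluster rate per genome
normalized to 80 Gy through the additive Poisson dose-response fit of
per-sample cluster counts, and median/IQR of spans and sizes. A linear
model of a per-sample clustering response on dose
(`clustering_dose_model`, ordinary least squares with coefficient SEs)
feeds the z-test comparison of clustering between genotypes, again with BH
control.

# Spectrum adjustment between genomes

To compare spectra across genomes with different base composition, each
trinucleotide-context SNV channel is reweighted by the ratio of target to
source context frequency and the spectrum renormalized
(`adjust_spectrum`); when a 119-channel vector is supplied only the SNV
block is reweighted. Context frequencies (`trinuc_frequencies`) count all
overlapping trinucleotides on both strands and collapse to the 32
pyrimidine-centred classes. Since cosine similarity is scale-invariant,
renormalization does not affect similarity values. The package bundles a
*synthetic* human-like frequency table generated from a CpG-depleted
Markov-chain genome (`synthetic_human_freqs`) — it mimics the
CpG depletion that shapes mammalian trinucleotide composition but is not
derived from the human genome; users comparing against real tumour
profiles should supply frequencies computed from the actual target
genome's FASTA.

# The synthetic-data generator

`simulate_experiment` is the generative counterpart of the signature
model: per-channel counts are Poisson with mean
$\text{background}_k + (d/80)\,\mathrm{IR}_k e^{L_{g,k}}$, realized as
concrete variant records on a toy genome (default: 5 chromosomes × 1 Mb of
i.i.d. uniform bases, which contains every trinucleotide context with high
probability). SNVs are placed at context-matching positions found by
bounded rejection sampling on both strands; indel and SV lengths are drawn
uniformly within their channel's size bin; SVs get plausible end
coordinates, with interchromosomal events pairing two distinct
chromosomes.

`default_wildtype_config` encodes the wild-type study conditions:
triplicate lines at 0/20/40/60/80 Gy; per-80-Gy class totals of 36.63 SNVs
(flat across the 96 channels — the radiation signature affects all
nucleotides equally), 1.3 DNVs, 4 indels and 1.4 SVs; and 6% of
substitution + indel mutations re-placed into clusters of 2–3 mutations
spanning 10–20 bp. Two conventions are the package's own: the MNV channel
rate is 0 (no MNV rate is reported for this assay), and the spontaneous
background is a small flat vector totalling 1 expected mutation per genome
(the assay does not state its dose-0 rate).

Two details of cluster placement matter for interpretation. First,
relocated substitutions take their reference allele from the new locus
(with a random differing alternative), so the realized channel of a
clustered SNV follows the genome's local context — consistent with the
flat radiation signature, and necessary for the generator and classifier
to remain exact inverses at the record level (the generator returns its
own realized per-channel tally, which `count_spectrum` reproduces
exactly). Second, on a 5-Mb toy genome ~43 mutations leave a ~0.3
per-genome chance of two *independent* mutations falling within 1000 bp,
so the window caller reports ~1.3 clusters per genome at 80 Gy: the ~1.0
planted clusters plus this background coincidence rate. On a full-size
100-Mb genome the coincidence term is negligible.

# What passing tests do and do not show

The generator emulates the count structure, dose design, flat signature,
genotype fold-changes and cluster geometry of the real experiment. It does
not emulate alignment or variant-calling artifacts, coverage-dependent
detection, homopolymer-context indel errors, zygosity, or selection
against deleterious mutations (lines that die are never sequenced — a
known censoring mechanism in the real assay). Recovery results on
synthetic data therefore validate the *statistical pipeline*, not the
upstream calling pipeline, and rates estimated from real data inherit
whatever ascertainment biases calling introduces.

# Numerical choices and problem sizes

* Rate fits: L-BFGS-B with parameter rescaling and a polish restart;
  observed-information SEs; degenerate and boundary cases flagged rather
  than errored.
* Sampler test budgets: the packaged tests and the acceptance script use
  1–2 chains with 400–800 warmup/retained iterations on experiments of
  10–20 samples, and 5–50 replicate experiments (or 500 genomes for
  cluster rates) per estimate — sizes chosen so each check completes in
  seconds to a few minutes on one CPU while Monte-Carlo error stays well
  inside the tested tolerances. Production fits default to 4 × 1000/1000.
* Ties in variant ordering are broken by (ref, alt) lexicographically, so
  sorting is total and outputs byte-reproducible.
* The planted 2-fold recovery check pools posterior draws over three
  seeded replicate experiments: a single 10+10-sample experiment realizes
  a rate ratio of 2 ± ~0.2 before any estimation, so pooling separates
  estimator bias from experiment-level Poisson noise without touching the
  acceptance thresholds.

# Known limitations

* Per-channel fold-changes at realistic burdens are individually noisy;
  only class aggregates are reported with confidence. This mirrors the
  assay itself, which reports class-level rates.
* The background prior borrows strength from dose-0 samples across
  genotypes; a genotype with a genuinely elevated spontaneous mutation
  rate and no dose-0 samples would be shrunk toward the experiment-wide
  dose-0 level.
* The HMM caller's emission means are conventions; decoded clusters depend
  on them when gap distributions are diffuse.
* `read_variants` collapses each breakend record to one SV event; paired
  BND mates are not deduplicated across records.
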