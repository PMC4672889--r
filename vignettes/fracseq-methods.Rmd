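---
title: "Methods: occupancy and motif analysis of polysome-fractionated RNA-seq"
author: "fracseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupancy and motif analysis of polysome-fractionated RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracseq)
```

## The experimental design and the model

In a polysome-fractionation experiment, a cell or tissue lysate is resolved
on a sucrose gradient and RNA is sequenced from three pools per individual:
**total** RNA, the ribosome-free **mRNP** pool (translationally repressed
messenger ribonucleoprotein particles), and the **polysome** pool (mRNAs
engaged by multiple ribosomes, a proxy for active translation). In germ
cells, where large programs of mRNAs are stored translationally silent by
Y-box proteins and released later, the balance between these pools is the
quantity of biological interest.

fracseq works at the gene level from count matrices. Its core statistic is
the **occupancy** of gene $g$ in fraction $F$ for one individual $i$:

$$\mathrm{occ}_F(g, i) = \frac{\mathrm{TPM}_F(g, i)}{\mathrm{TPM}_{\mathrm{total}}(g, i)},$$

the fraction signal normalized by total expression within the same
individual, computed before any averaging across a genotype. Because both
numerator and denominator come from the same animal, occupancy is immune to
between-animal expression differences. The per-individual **polysome:mRNP
ratio** $\mathrm{occ}_{\mathrm{poly}}/\mathrm{occ}_{\mathrm{mRNP}}$ (the
total cancels, so it equals
$\mathrm{TPM}_{\mathrm{poly}}/\mathrm{TPM}_{\mathrm{mRNP}}$) indexes
translational activity: a loss of repression moves transcripts out of the
mRNP pool and into polysomes, raising the ratio without changing total
abundance.

Per gene, genotype differences in occupancy are tested fraction by fraction
with a two-sided two-sample t-test against wildtype, and a gene is called a
**high-confidence derepression target** when it is significant at raw
$p < 0.05$ in *both* the mRNP and the polysome fraction. Requiring
concordance in two semi-independent measurements is the multiplicity
control in this design; BH q-values are reported alongside but are not used
for the call. The direction of change (mutant ratio above wildtype) is
summarized post hoc and never used for inclusion.

### Assumptions

* The three libraries of an individual are a matched triple from one
  animal; the sample sheet encodes this by giving replicate $r$ of each
  fraction the same replicate number.
* Gene-level counts are adequate (no isoform switching within the pools).
* TPM is the right within-library normalization; effective lengths are
  supplied by the quantifier, not computed here.
* The t-test is applied on the raw occupancy scale. With two to four
  replicates no distributional diagnostics are possible, and occupancies
  are mildly right-skewed ratios, so p-values are approximate; the null
  calibration property in the test suite quantifies how approximate.

## Normalization

TPM for gene $g$ in sample $j$ is
$10^6 (c_{gj}/L_g) / \sum_{g'} (c_{g'j}/L_{g'})$ with the sum over
*biological* genes only: spike-in rows are carried through with the same
denominator but excluded from it, so biological TPMs remain comparable when
the spike mass fraction varies between libraries.

Cross-library scaling is anchored on ERCC-style spike-in controls with a
deterministic median-of-ratios estimator: the reference for control $i$ is
the geometric mean of its counts across samples (controls with a zero
anywhere are dropped — a zero would put $-\infty$ into the log mean), the
factor for sample $j$ is the median ratio to the reference, and factors are
rescaled to geometric mean 1 so they carry no overall library-size
information. This is the spike-in analogue of the median-of-ratios size
factors standard in count-based differential expression, chosen over a
factor-analysis correction because it is closed-form, deterministic and
directly testable: with noiseless scaled spikes it recovers the true
factors to machine precision, and the test suite measures its error under
negative-binomial noise. An optional rank-$k$ SVD smoothing of the residual
spike log-count matrix (`ruv_k`) is available for structured unwanted
variation; it is off by default. If fewer than three usable controls
remain, the function refuses and advises total-count normalization rather
than silently degrading.

Note that occupancy itself is invariant to any per-library scaling (TPM
self-normalizes and the ratio is within-individual); the factors matter for
the total-RNA differential stage and for any cross-library comparison of
absolute signal.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` (filter) | 5 TPM | gene kept iff TPM strictly above this in every total replicate of at least one genotype |
| `alpha` | 0.05 | raw per-fraction p threshold for target calling |
| `total_floor` | 1 TPM | minimum total TPM for a defined occupancy (below: NA, never 0) |
| `ratio_floor` | 1e-3 | minimum mRNP occupancy for a defined polysome:mRNP ratio |
| `welch` | FALSE | pooled-variance Student's t by default; Welch behind the flag |
| `ratio_method` | per_individual | ratio per individual then mean; `of_means` takes the ratio of genotype-mean occupancies |
| `eps` (PWM) | 1e-4 | pseudocount so disallowed bases keep finite log-odds |
| `report_threshold_p` | 1e-2 | motif scan emission threshold |
| `q_threshold` | 0.2 | q-value cutoff for calling a UTR motif-positive |
| `n_bins` | 1000 | score-lattice resolution for exact p-values |

The pooled-variance t is the default because at $N = 2$ (the duplicate
design this analysis targets) Welch's degrees-of-freedom estimate is
unstable; pooling gives deterministic $df = n_1 + n_2 - 2$. Degenerate
inputs are handled explicitly rather than left to chance: fewer than two
defined occupancies in a group gives NA with a flag; zero variance in both
groups gives $p = 1$ for equal means and a flagged $p = 0$ sentinel
otherwise. NA always propagates — an undefined occupancy is never silently
treated as zero.

The aggregation of per-individual ratios into a genotype value is genuinely
ambiguous in a duplicate design (mean of ratios vs ratio of means); the
default takes the mean of per-individual ratios, keeping each animal a
self-contained measurement, and the alternative is available behind
`ratio_method`.

## The motif scanner

The Y-box recognition sequence (YRS) is a degenerate 7-mer,
`[UAC][CA]CA[UC]C[ACU]` in RNA alphabet, found in 3'UTRs of translationally
repressed spermatid mRNAs. The scanner is built from first principles so
that its p-values are exact rather than asymptotic:

1. **Consensus → PWM.** Position probabilities share the mass among allowed
   bases with pseudocount $\varepsilon$:
   $P(b) = (\mathbb{1}[b\ \mathrm{allowed}]/n_\mathrm{allowed} +
   \varepsilon)/(1 + 4\varepsilon)$.
2. **Scoring.** Windows are scored by $\log_2$ odds against a 0-order
   background (estimated from the scanned set by default, with a $10^{-6}$
   floor; a uniform option exists for deterministic work). Scanning is
   sense-strand only — the element is an RNA feature, so the reverse
   complement is not meaningful — and windows containing N are skipped.
3. **Exact p-values.** Per-position scores are shifted and floored onto an
   integer lattice of `n_bins` bins; the per-position score distributions
   under the background are convolved by dynamic programming, giving the
   exact tail probability $P_\mathrm{bg}(\mathrm{score} \ge s)$ at every
   lattice point. Rounding *down* to bin edges makes reported p-values
   conservative (never understated). For widths small enough to enumerate,
   the lattice tail agrees with brute-force enumeration of all $4^w$
   k-mers to within $10^{-12}$; the test suite checks this on random PWMs
   and backgrounds. For the YRS under a uniform background the maximal
   score has $p = 36/16384 \approx 2.197\times10^{-3}$ — there are
   $3\cdot2\cdot1\cdot1\cdot2\cdot1\cdot3 = 36$ consensus-compatible
   7-mers.
4. **q-values.** BH step-up over all emitted positions of one scanned set,
   so significance is judged within each dataset being compared, not pooled
   across datasets with different sizes and compositions.

Coordinates are 0-based half-open internally and 1-based inclusive in every
output. `count_canonical()` counts exact (possibly overlapping) consensus
windows, and `compare_utr_sets()` reports, per labelled set, the fraction
of UTRs with at least one $q \le 0.2$ hit and the mean canonical count
among canonical-containing UTRs.

## The synthetic-data generator

`simulate_experiment()` emulates the fractionated count structure so every
stage is testable without external data. Per gene: a baseline abundance
$a_g$ (log-normal), a length $L_g$, and a partition of the transcript pool
into mRNP ($m_g$), polysome ($p_g$) and a free remainder, with fraction
weights $w_\mathrm{total} = 1$, $w_\mathrm{mRNP} = m_g$,
$w_\mathrm{polysome} = p_g$. For sample $j$ the expected fragment share of
gene $g$ is proportional to $a_g\, w_F\, L_g$, and counts are negative
binomial with mean $\mathrm{share}\cdot\mathrm{depth}\cdot s_j$ and
variance $\mu + \phi\mu^2$ ($\phi = 0$ is the Poisson limit). Spike-in rows
get means proportional to their nominal concentrations times
$\mathrm{depth}\cdot\mathrm{smf}\cdot s_j$.

Derepression is planted in the compound heterozygote as
$m \leftarrow m/k$ together with $p \leftarrow \min(pk,\ 1 - m/k)$, leaving
total abundance untouched: repression loss empties the mRNP pool into
polysomes. When the cap binds the truth table flags it (`cap_bound`); for
uncapped genes the true partition ratio increases by exactly $k^2$.

Defaults, chosen once as a realistic testis-like profile and then left
alone: abundance `sdlog = 1.5` (a wide but not extreme dynamic range),
partitions Dirichlet(2, 2, 2) (no pool systematically dominant, mild
concentration away from the simplex corners), gene lengths log-normal
around 1.5 kb, two replicates per genotype (the duplicate design),
library depth $5\times10^6$ expected fragments (a desk-scale stand-in for
a production depth of tens of millions), spike mass fraction 0.05, and a
92-control spike design log-spaced over the nominal ERCC Mix-1
concentration range (0.014–30 000 attomol/µl). All randomness derives from
the single config seed: gene-level parameters are drawn first, then each
library draws its counts from a sub-seed sampled from the same stream, and
the caller's RNG state is saved and restored.

What the generator does **not** emulate: GC- and position-dependent
coverage bias, isoform structure, batch effects beyond a scalar per-library
factor, correlated dispersion across fractions of the same animal, and
contamination between gradient fractions. Passing tests therefore
demonstrate the statistical machinery on an idealized version of the data
structure, not robustness to every artifact of real libraries.

## Problem sizes and what the end-to-end checks show

The packaged end-to-end checks (and `scripts/acceptance.R`) use: 250 genes
at depth $10^6$ and $\phi = 0$ for partition identifiability — about 4 000
fragments per gene, so the large-depth limit the property describes is
actually approached and the measured correlation reflects the estimator
rather than coverage; 5 000 genes, 250 planted targets, $k = 3$, four
replicates, $\phi = 0.05$, depth $5\times10^6$ for recovery and null
calibration; 100 replicate simulations for spike-factor error; and 20
random PWMs for the exact-p-value oracle.

Two structural facts about the recovery setting are worth stating because
the test suite measures them. First, the mRNP and polysome tests of a gene
share the same total-RNA denominator, so their null rejections are
positively correlated: the measured null intersection rate is roughly two
to three times the $0.05^2$ independence value. Consequently the
false-discovery rate among intersection calls sits near 0.1–0.2 when 5% of
genes carry true effects — the intersection rule controls the *rate* of
false calls well (below 1% of null genes) but not the FDR at this effect
prevalence. Second, the polysome-side power of the raw-scale t-test is
limited for genes where the partition cap binds (large baseline polysome
occupancy leaves little headroom), so sensitivity of the two-fraction
intersection at $k = 3$, $N = 4$ sits near 0.6 rather than near the
per-fraction mRNP power of ~0.86. The direction property is clean: among
true positives, the mutant polysome:mRNP ratio exceeds wildtype in 100% of
cases in these runs.

## Known limitations

* The total-RNA differential stage is a deliberately simple surrogate
  (log2 of pseudocounted mean TPM plus a pooled t on log TPM); it flags
  gross abundance changes and is not a replacement for a count-model DE
  analysis.
* Raw $p < 0.05$ target calling follows the duplicate design it mirrors;
  with more replicates a user may prefer the reported q-values.
* The scanner is 0-order-background and sense-strand only; no higher-order
  background models, no motif discovery (guided scanning only).
* Occupancy floors (`total_floor`, `ratio_floor`) are pragmatic guards
  against ratio blow-ups, not model-based shrinkage.
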