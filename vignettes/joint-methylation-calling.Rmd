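---
title: "Joint 5mC/6mA calling from nanopore signal: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint 5mC/6mA calling from nanopore signal: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanojoint)
```

## The problem

Antibody-directed adenine methyltransferase footprinting deposits
N6-methyladenine (6mA) near targeted nucleosomes, while CpG sites carry
endogenous 5-methylcytosine (5mC). Both marks perturb the ionic current
of a nanopore, so a single long read carries evidence for both at once.
nanojoint reads event-aligned signal tables (one row per measured
current event, anchored to a reference k-mer), trains per-k-mer emission
models from labelled control DNA, and classifies each read's CpG sites
and 50-bp windows as methylated/unmethylated and
6mA-containing/non-6mA.

## The signal model

An event $e_i$ measured while k-mer $k$ occupies the pore is modelled as
Gaussian,

$$ e_i \mid k \sim \mathcal N\!\big(a + b\,\mu_k,\ (d\,\sigma_k)^2 \big), $$

where $(\mu_k, \sigma_k)$ come from the pore model and $(a, b, d)$ are
read-specific shift, scale and variance-scale distortions. `fit_read_scaling()`
estimates $(a, b)$ by least squares of event means on model means and
$d$ as the root mean square of standardised residuals. Because a read
may carry methylation shifts at an unknown subset of k-mers, the fit
trims events whose standardised residual exceeds 2.5 robust sds and
refits (twice), then debiases $d$ for the truncation; on clean reads the
trimmed estimator equals the plain one in expectation. $d$ is floored at
0.01 to avoid degenerate zero-variance fits.

The probability of an event sequence given a candidate sequence $S$ is
computed by a hidden Markov model with one state block per k-mer of $S$:
a *match* state with the Gaussian emission above (and a self-transition,
so one k-mer can emit several events), silent *skips* with geometrically
decaying mass, a *bad* state whose sd is broadened 10-fold, and uniform
*softclip* states absorbing unassigned leading/trailing events. The
transition constants (`p_stay` = 0.1, `p_skip` = 0.01, `p_bad` = 0.001,
`p_clip` = 0.001, skip band `max_skip` = 3) are declared defaults in
`hmm_config()`, not measured quantities; every classification property
in the test suite holds for any fixed choice, which the
forward-vs-enumeration oracle tests make explicit.

## The six-letter alphabet and k-bar classes

Sequences are written over `{A, C, G, T, M, Z}` with `M` = 5mC
(CpG context only) and `Z` = 6mA, giving $6^6 = 46{,}656$ candidate
6-mers of which the instrument provides the $4^6 = 4{,}096$ unmodified
ones. K-mers where `M` is followed by anything but `G` are invalid; a
terminal `M` is kept valid because its `G` lies in the next k-mer.

Training DNA carries *partial* adenine methylation, so events can never
be attributed to one specific `Z`-pattern. All k-mers equal up to A/Z
substitution are therefore pooled into a *k-bar* class, written here as
the A-collapsed k-mer with a trailing `+` (`TACACG+`). The class keeps a
multi-component emission: one Gaussian per pooled modification pattern,
fitted as a mixture.

## Training

Each methylated entry is initialised from its unmodified parent with the
same mean and sd + 2 pA. Training then iterates five rounds of: Viterbi
realignment of every read to its condition sequence under the current
model; pooling of shift/scale-transformed events
$e_i' = (e_i - a)/b$ per k-mer class, with per-event variance factors
$v_i = d_i/b_i$; and EM fitting of Gaussian mixtures,

$$ P(e_i') = \sum_j \omega_j\, \mathcal N\!\big(\mu_j, (v_i \sigma_j)^2\big), $$

with the responsibility-weighted updates using residuals rescaled by
$1/v_i$ in the variance update. Each fit is repeated from a fixed
initialisation grid — component means at $\mu_k$ and $\mu_k \pm 5, \pm
10$ pA, sds at $\sigma_k$ and $\sigma_k + 1$, weights $0.95/0.05$,
$0.5/0.3/0.2$ or $0.25 \times 4$ by component count — capped at 1000
iterations. Since the grid lists values but not their combination, the
package anchors one component at $\mu_k$ and draws the remaining
component means from the non-zero offsets (a zero offset would duplicate
the anchor), applying both sd choices to all components.

Assignment is consistency-based: fits whose sorted means agree within
1 pA form a consensus group, and a group covering at least half of the
initialisations elects its highest-likelihood member. For
single-modification k-mers the component farthest from the reference
mean is assigned; for k-bar classes the reference-matching component is
dropped and the rest keep renormalised weights. Components with mixture
weight below 0.1 are ignored during assignment: the training conditions
methylate most molecules, so a trace-weight component is an alignment
artifact rather than the methylated population. Entries without a
consensus keep their sd + 2 initialisation and are flagged untrained;
classification still works for them, just without mean separation.
Component counts are guessed from the pooled patterns
($\min(2^{n_A}, 4)$ for a k-bar class with $n_A$ adenines, 2 for a
single modification) and step down when the pooled events cannot
support the guess (10 events per component minimum). Long reads are
realigned in 120-k-mer chunks keyed by the event anchors, which keeps
the alignment cost linear in read length; chunk-boundary events lose
access to cross-boundary stay transitions, a negligible effect at this
chunk size.

Unmodified k-mers are refit with a closed-form single-Gaussian weighted
fit from their pooled unmodified events, so training on an untreated
dataset reproduces the base model.

## Classification

For every read, CpG substrings (maximal CpG clusters with at least
10 bp CpG-free flanks, merged when separated by fewer than 10 CpG-free
bases) and non-overlapping 50-bp adenine windows (tiled from the read's
reference start, terminal remainder dropped) are tested jointly under
four hypotheses: ref1 unmodified, ref2 all CpGs in the interval
methylated, ref3 all adenines in the interval under their 6mA class,
ref4 both. The log-likelihood ratio sums log maximum likelihoods,

$$ \mathrm{LLR} = \sum_{i \in \text{with mark}} \log \max_\Theta
  \mathcal L(S_i \mid e) - \sum_{j \in \text{without}} \log \max_\Theta
  \mathcal L(S_j \mid e), $$

with $i \in \{\text{ref2}, \text{ref4}\}$ for CpG calls and
$i \in \{\text{ref3}, \text{ref4}\}$ for 6mA calls; duplicate
hypotheses are omitted when the interval lacks one mark, reducing the
ratio to a two-hypothesis contrast. The maximum over $\Theta$ is a hard
per-event selection of the highest-density mixture component
(`best_component()`), with deterministic lowest-index tie-breaks. LLRs
are natural logarithms throughout. Calls use inclusive boundaries:
CpG methylated at LLR $\ge 1.5$, unmethylated at $\le -1.5$, otherwise
no-call; 6mA-containing at LLR $\ge 8$ (low stringency) or $\ge 32$
(high stringency). A window's events are those anchored within the
window plus $k - 1$ flanking bases; a window with no events is a
no-call and never aborts the read.

Two structural points are worth knowing. First, summing log maxima over
two hypotheses per side is a product of likelihoods, not a mixture
marginal; the package implements this form directly. Second, the 6mA
hypothesis asserts `Z` at *every* adenine of the interval while real
labelling is partial, so windows containing a single methylated adenine
near an edge score weakly — window-level classification, not
base-resolution calling, is the designed output.

## Aggregation and allele-specific statistics

Per-site methylation frequencies exclude no-calls, and joint substring
calls propagate to each CpG they cover; frequency bins use the 70% /
30% boundaries. Background correction scales the IgG count by the
coverage ratio, $sf = C_s/C_i$, $R_f = R_s - sf \cdot R_b$, flooring
$R_f$ at zero because a negative corrected count has no meaning in a
count track. Distances between adjacent 6mA-containing windows within a
read are measured midpoint to midpoint.

Allele-specific CpG methylation uses a two-sided Fisher exact test on
the 2x2 haplotype-by-call table, gated at 20 combined informative
calls. Allele-specific 6mA enrichment samples 30 windows (250 bp,
flagged positive when any contained window call is 6mA-positive) with
replacement per allele per replication, 100 replications, and pools the
replication counts into a single 2x2 table for the Fisher test —
reporting the bootstrap distribution alongside. This pooling is exactly
calibrated when both alleles share one realized window set; when the
alleles are small independent samples it pseudo-replicates and is
anticonservative, which is why results carry both the raw p-value gate
(p < 0.01) and the Benjamini-Hochberg q-value gate (q <= 0.10).
Alleles offering fewer than 30 windows are skipped rather than sampled
short.

## What the simulator emulates — and what it does not

`simulate_reference()` draws a CpG-free background (G suppressed after
C) and injects CpGs to a target density; `simulate_reads()` applies
per-read $(a, b, d)$ distortions, geometric stays, Bernoulli skips, and
methylation-dependent mean shifts. The shift of a modified k-mer is
$3\sigma_k$ at the strongest-placed modification, weighted by position
(6mA strongest mid-k-mer, 5mC strongest at the fifth position), with a
deterministic sign per (k-mer, position, mark) so shifts go both
directions and the two marks perturb a k-mer independently.
`simulate_training_conditions()` reproduces the four-control design:
untreated, 96.2% CpG methylation, partial (40%) adenine methylation on
naked DNA, and both. `footprint_regions()` adds the 147 bp
protected / 30 bp linker alternation of chromatin footprints for
reads emulating in-situ footprinting experiments.

The simulator draws events from the same Gaussian family the caller
assumes. Real signal has heavier tails, homopolymer-dependent
segmentation errors, strand asymmetries and basecalling-alignment
artifacts, none of which are modelled — so passing the simulation
benchmark demonstrates correctness of the training and inference
machinery under the stated model, not accuracy on any particular flow
cell chemistry.

## The benchmark and problem sizes

`run_benchmark()` is the package's end-to-end check: a 900-bp reference
at CpG density 0.02, 32 reads per training condition, and the full
5-round training. CpG performance is scored on singleton CpG substrings
of 55 footprinted evaluation reads (50% per-read CpG methylation,
adenine labelling confined to nucleosome linkers — the regime the
method operates in, where most CpG substrings carry no co-occurring
6mA) against the per-read truth. 6mA performance is scored on windows
of 12, 24, 50 and 100 bp from a treated/untreated pair of 28-read
sets: positives are windows of the everywhere-labelled set that truly
contain a methylated adenine, negatives the unlabelled set's windows —
a treated-versus-untreated site benchmark. CpG calling degrades
measurably when every substring carries partial co-occurring 6mA
(reproducing the ordering reported for real data), which is why the
two marks are scored in their respective operating regimes. These
sizes give at least 200 items per class and finish in a few minutes on
one core; they are the package's chosen trade-off between statistical
resolution and a test suite that runs everywhere.

```{r benchmark, eval = FALSE}
bm <- run_benchmark(seed = 1)
bm$auc
```

## Numerical choices and degenerate inputs

* Forward/Viterbi run in log space; log-sum-exp guards `-Inf` blocks.
* EM convergence: max $|\Delta\mu| < 10^{-3}$ pA or a log-likelihood
  step below $10^{-6}$; components collapse (and weights renormalise)
  below sd 0.05 pA or weight 0.01.
* Missing methylated entries are derived on the fly from their parent
  (mean kept, sd + 2) so every valid queried class has a component.
* Ties in component selection break to the lowest index; Viterbi ties
  keep the stay transition.
* Reads with fewer than 30 labelled events have no scaling fit and are
  skipped with a warning; a degenerate design (all model means equal)
  is an error.

## Known limitations

* Base-resolution 6mA calls are out of scope by construction: k-bar
  pooling trades positional identity for trainability under partial
  labelling.
* The bootstrap pooling interpretation above is one of several ways to
  reduce 100 replications to a single test; the bootstrap distribution
  is returned so users can substitute their own summary.
* Minus-strand events are expected to arrive reference-oriented, as
  eventalign-style tables provide them; the package does not
  re-orient raw signal.
* Training quality depends on coverage per k-mer class: classes below
  10 events per component stay at their initialisation and are flagged
  `untrained` in the training summary.
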