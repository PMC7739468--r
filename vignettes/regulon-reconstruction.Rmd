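---
title: "Methods: gene-centered comparative reconstruction of bacterial regulons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-centered comparative reconstruction of bacterial regulons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cregulon)
```

# Overview

`cregulon` reconstructs the regulon of a bacterial transcription factor
(TF) across a set of target species from two kinds of prior knowledge:
aligned collections of experimentally supported binding sites for one or
more *reference* TF instances, and annotated genome sequences for the
*target* species. The unit of reporting is the gene: operons act as logical
units of regulation (genes of an operon share their promoter's posterior),
but all comparative reporting — ortholog groups, the regulon matrix,
ancestral states — is gene-centered, which keeps results interpretable when
operon structure differs between species.

This vignette describes the statistical model, the tunable parameters and
their defaults, the numerical choices, what the synthetic-data generator
does and does not emulate, and known limitations.

# Motif representation and transfer

A site collection (equal-width, gap-free strings over A/C/G/T; at least
two sites) becomes a position-specific weight matrix (PSWM) with a
background-apportioned pseudocount:

$$f_{jb} = \frac{n_{jb} + c \, p_b}{n + c}$$

with total pseudocount $c = 0.5$ by default. This keeps every log-odds
score finite while barely distorting small collections; users with large
collections can set $c$ lower. The PSSM score is
$\log_2(f_{jb} / p_b)$ in bits, with the background $p$ taken from the
**target genome's** mononucleotide frequencies — score thresholds behave
differently across genomes with different oligomer composition, so the
conversion is always per-species.

Binding specificity is transferred to each target species as a mixture of
the reference PSWMs. The TF phylogeny is estimated internally: pairwise
global protein alignments (BLOSUM62, gap open 10, extend 0.5), mismatch
fraction over aligned columns Poisson-corrected as $d = -\ln(1 - p)$,
neighbor joining, negative branches clamped to zero, midpoint rooting (no
outgroup is assumed, and ancestral reconstruction needs a root). Mixture
weights are inversely proportional to the patristic distance from the
target's TF to each reference, floored at $\epsilon = 0.01$
substitutions/site:

$$w_r \propto \frac{1}{d_r + \epsilon}, \qquad \sum_r w_r = 1$$

The classical progressive-alignment literature weights sequences by tree
partitioning; the exact formula used by those tools is not fully specified
for this setting, so we adopt inverse patristic distance, which preserves
the monotone behavior that matters (closer references weigh more), is
reproducible, and lets a target that *is* a reference dominate its own
mixture without silencing the other references (that is what the
$\epsilon$ floor buys). The mixture's effective site count is the
weighted sum of the references' counts. Reference motifs must share a
width; aligning or trimming incompatible motifs is deliberately left to
the user.

# Promoter scoring and the posterior of regulation

Each operon's promoter window spans $[-250, +50]$ bp around the predicted
translation start of its first gene, truncated at the boundary of the
adjacent upstream gene, at the gene's own end, and at contig edges. The
window matches the span within which bacterial TF-binding sites
overwhelmingly occur; both bounds are parameters
(`promoter_upstream`, `promoter_downstream`).

Every window position is scored on both strands and combined as
$\log_2(2^{s^f} + 2^{s^r})$, evaluated stably as
$\max + \log_2(1 + 2^{-|s^f - s^r|})$. Windows containing ambiguous bases
(N, common in drafts) are skipped, not scored.

Two score distributions drive the inference:

* background $B \sim N(\mu_G, \sigma_G^2)$, fitted as the sample mean/SD
  of combined scores over **all promoter windows of the genome** (not
  coding sequence — promoters have their own composition). If a genome
  yields fewer than 100 windows, whole-genome windows are added so the fit
  cannot degenerate.
* motif $M \sim N(\mu_M, \sigma_M^2)$, computed **analytically** from the
  mixture PSWM under column independence
  ($\mu_M = \sum_j \sum_b f_{jb} s_{jb}$; $\sigma_M^2$ the sum of column
  variances), on single-strand scores. A mixture motif has no physical
  site list to rescore, so the analytic route is the consistent choice for
  every species.

A regulated promoter draws each position from the mixture
$\alpha N(\mu_M,\sigma_M^2) + (1-\alpha) N(\mu_G,\sigma_G^2)$. The mixing
parameter $\alpha$ is the prior probability that a given window of a
regulated promoter is a functional site: sites per promoter (default 1)
divided by the average promoter length, which is measured per genome as
the mean intergenic distance between divergently transcribed directon
heads (fallback 250 bp). One site per 250 bp gives $\alpha = 0.004$ — a
regulated promoter still draws from the background 99.6% of the time.

With position independence, the posterior of regulation of an operon given
its score vector $D$ is

$$P(R|D) = \frac{P(D|R)P(R)}{P(D|R)P(R) + P(D|B)P(B)}$$

The prior $P(R)$ is seeded from a known regulon size (regulated promoters
/ operons) when the configuration supplies one, otherwise from the motif's
information content: the expected number of sites in the scanned windows
is $m = n_{\text{windows}} 2^{-IC}$ and $P(R) = \min(m/n_{\text{operons}},
1 - 10^{-6})$. All likelihoods accumulate in log space with log-sum-exp,
so underflow is impossible for any promoter length; the suite checks
agreement with direct-space arithmetic to ten significant digits wherever
direct space does not underflow.

One property worth stating precisely: for promoters drawn from $B$, the
expected likelihood *ratio* is exactly 1, but the posterior is a concave
transform of it, so the mean posterior of background promoters sits
*below* the prior (approximately shrunk by $(1-\alpha)^n$), while promoters
containing a genuine site are driven toward 1. The calibration tests
assert exactly this asymmetry.

# Operon prediction

Directons are maximal runs of adjacent same-strand genes on a contig.
Within a directon, adjacent genes are co-operonic when their intergenic
distance (0-based half-open: $\text{start}_{i+1} - \text{end}_i$; negative
for overlapping genes, which are therefore always joined) is at most the
threshold. The threshold is **adaptive**: the mean intergenic distance
over all within-directon pairs of that genome, tracking each genome's
coding density; a multiplier (default 1) lets users loosen or tighten it,
and a 50 bp fallback covers pathological inputs with no within-directon
pairs. Ties at exactly the threshold keep genes together — the prediction
is deliberately conservative, because a missed split is recoverable and a
spurious split is not.

Recovery works through the site-based split: every gene's upstream window
is scanned, and a non-first operon member whose window holds a site with
single-strand PSSM score at or above the split threshold becomes the first
gene of a new operon. The split threshold is the smallest score $t$ with
$\mathrm{FPR}(t) \le 2^{-IC}$, where the false positive rate is the exact
probability that an i.i.d. background sequence scores at least $t$,
computed by dynamic programming over per-position scores discretised to
0.01-bit bins (discretisation error is far below the score gap between
consecutive k-mers at realistic widths; the suite verifies the DP against
exhaustive k-mer enumeration at widths 4–6). The single-strand convention
matches the FPR definition; scanning considers both orientations of the
window. Splitting is applied at every qualifying gene, is idempotent, and
triggers a rescan of the affected (new first-gene) promoters only — the
background fit is not redone, since operon structure does not change the
genome-wide window population materially. For a zero-information motif the
FPR target is unattainable; the maximum attainable score is returned with
a warning.

# Orthologs and ancestral reconstruction

Ortholog detection is restricted to genes whose operon posterior exceeds
the `posterior_cutoff` (default 0.5) in their own species — regulon
reconstruction does not need genome-wide orthology, and the restriction
keeps the quadratic search small. Candidate pairs are reciprocal best
hits; the bundled search backend scores global BLOSUM62 alignments and
normalises by the query self-score (1 = identity), with significance
cutoffs `min_score_ortholog = 0.3` and `min_score_tf = 0.5` standing in
for the e-value cutoffs used with external search tools. The backend is a
plain function `(query, subjects) -> ranked data.frame`, so an external
tool can be plugged in without touching the pipeline. Ties on score break
lexicographically by gene id, making every edge deterministic.

Ortholog groups are cliques of the RBH graph. A gene can lie in several
maximal cliques; groups are assigned greedily by decreasing clique size
(ties: larger total edge score, then lexicographic member ids), cliques
broken by earlier assignments are skipped, and leftover genes become
singleton groups. The policy is a package choice — clique membership alone
does not determine a partition — and it is pinned down by tests against an
independent brute-force implementation.

For each group, one bootstrap replicate assigns each species the regulated
state `s1` with probability equal to its posterior, `s0` otherwise, and
the absent state `sa` deterministically when the species lacks a member.
Treating absence as a third Markov state (rather than missing data)
follows from absence being informative: gene loss and regulatory loss are
correlated events. Marginal ancestral probabilities are computed exactly
by a pruning (inside) pass and an outside pass under a 3-state equal-rates
continuous-time Markov model with uniform root prior; the per-replicate
rate is fitted by one-dimensional likelihood maximisation (tolerance
1e-4, interval [0.001, 20], fallback 1.0 when the optimum is degenerate
or the leaves are uniform). Replicate marginals are averaged; the seed is
recorded in the report and identical seeds give bit-identical results.
With all branches of length zero and conflicting leaves the likelihood
vanishes; marginals then fall back to the root prior rather than NaN.

# The synthetic-data generator

`generate_fixture()` produces the study system the tests run on: `n`
species (default 4) sharing one-to-one ortholog families (default 60),
genes arranged into operons (sizes 1–4) within directons of 1–2 operons on
alternating strands, within-operon gaps $\sim N(15, 5^2)$ bp and
promoter-bearing gaps $\sim N(150, 40^2)$ bp clamped to $[60, 400]$ —
typical bacterial spacing, with the lower clamp reflecting the minimum
room a promoter with −35/−10 elements plus an operator realistically
occupies. A fraction (default 0.3) of operons is regulated, conserved
across species; each regulated promoter carries one site sampled from the
planting PSWM at a uniform position in $[-250, -10]$. The planting motif
has one consensus base per column at probability 0.9 (~21 bits over 16
bp), the regime of a well-characterised, high-information repressor motif
— the regime in which regulon transfer is actually practised. Proteins
are random sequences diverged per species by point mutations (families 4%
per species step, the TF 5%), back-translated with the bacterial genetic
code, and emitted as minimal GenBank records so the production parser is
exercised, not bypassed. Truth tables record every planted site, operon,
family and gap.

What the generator does **not** emulate: genome rearrangements, horizontal
transfer, paralog families, pseudogenes, codon bias, compositional
heterogeneity along the genome, and motif divergence between species
(sites are drawn from one planting motif everywhere). Passing tests
therefore demonstrate the machinery end to end under a faithful but benign
data-generating process; they do not quantify accuracy on real genomes,
where motif divergence and annotation errors dominate.

# Numerical choices and problem sizes

* Log base 2 throughout (bits), so the information content and the
  $-\log_2 \mathrm{FPR}$ split rule are commensurable.
* Posterior and likelihoods in natural-log space internally; log-sum-exp
  everywhere two exponentials meet.
* FPR dynamic programming bin width: 0.01 bits.
* Tie-breaking is always deterministic: leaf names sorted before tree
  construction, RBH ties by gene id, clique ties by size, score, then
  lexicographic members.
* Test problem sizes were chosen to keep the whole suite around a minute
  on one core while leaving the oracles exhaustive: brute-force posterior
  checks on 1,000 random vectors, k-mer enumeration at widths 4–6, clique
  oracles up to 40 vertices, ancestral enumeration on trees of up to 6
  leaves, operon oracles over 100 random layouts, and one full 4-species /
  60-gene end-to-end recovery run at 100 bootstrap replicates.

# Limitations

* The normal approximation to PSSM scores is coarse for very short or
  near-deterministic motifs; the analytic $\sigma_M$ ignores inter-column
  dependence.
* Position independence across overlapping windows is formally false but
  standard; posteriors are well calibrated in rank, less so in absolute
  value.
* The bundled alignment backend is quadratic in gene count; for
  genome-scale regulated sets an external search tool should be plugged
  into the backend hook.
* Single-species runs produce per-species scans only; comparative stages
  need at least two species with a detectable TF ortholog.
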