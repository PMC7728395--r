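---
title: "Detecting horizontal transposon transfer from dS and codon usage bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal transposon transfer from dS and codon usage bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(httscan)
```

## The inference model

A transposable element (TE) family present in two species can have
reached them in two ways: vertical descent from the common ancestor, or
a horizontal transfer after the species split. Under vertical descent
the family's synonymous divergence (dS) reflects the full divergence
time of the hosts; after a horizontal transfer it reflects only the
(shorter) time since the transfer. The difficulty is that dS is not
clock-like across sequences within a genome: codon usage bias (CUB)
correlates with the synonymous substitution rate, so a slowly diverging
TE might simply be a highly biased one.

`httscan` resolves this with a per-species-pair reference: single-copy
orthologous genes, which are vertically inherited by construction. For a
pair of species the genes define an ordinary least squares regression of
dS on CUB. A TE family contributes one `(CUB, dS)` observation — from
the two representative copies, one per species — and is scored by the
studentized prediction residual

$$t = \frac{dS_{TE} - \hat a - \hat b\,\mathrm{CUB}_{TE}}
{\hat\sigma\sqrt{1 + 1/n + h(\mathrm{CUB}_{TE})}},\qquad
p = P(T_{n-2} \le t),$$

with $h$ the regression leverage at the TE's CUB. The test is
one-tailed: only anomalously *low* dS indicates horizontal transfer.
The decision level is $\alpha = 0.01$ per pairwise comparison, with no
multiple-testing correction by default (an optional Benjamini–Hochberg
flag exists in spirit via the returned p-value table; the per-test
$\alpha$ is the package's operating convention). A family with at
least one significant pair counts as one HTT family; the package
deliberately does not reconstruct a minimal transfer scenario from the
significance network, because no principled algorithm for that exists —
counts are therefore lower bounds at family level.

Assumptions inherited from this construction, and checked by
`check_assumptions()`: approximately Gaussian gene residuals
(Kolmogorov–Smirnov test of the standardized residuals) and a detectable
linear dS–CUB relation (Pearson test). Pairs failing either at
$\alpha_{diag} = 0.05$ are flagged, not dropped.

## The statistics underneath

* **dS** — Nei–Gojobori (1986) counting: fractional synonymous site
  counts per codon averaged over the two sequences; differences at
  multiply substituted codons averaged over all shortest mutational
  pathways, excluding pathways through stop codons (all-blocked pairs
  fall back to all pathways); Jukes–Cantor correction
  $dS = -\tfrac34\log(1 - \tfrac43 p_S)$. Mutations *to* stop codons
  count as nonsynonymous in site counting, which preserves
  $S + N = 3\cdot\text{codons}$. Codon pairs containing a gap, an `N`
  or a stop are skipped pairwise; $p_S \ge 3/4$ flags saturation and
  suppresses the call rather than producing a number.
* **CUB** — Wright's effective number of codons
  $N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$ with
  bias-corrected homozygosities, clipped to $[20, 61]$. Amino acids
  observed fewer than twice and non-positive homozygosities are excluded
  from class means; a missing 3-fold class is imputed as the mean of the
  2- and 4-fold classes, any other missing class as the mean of the
  represented ones. Larger $N_c$ = weaker bias, so the gene cloud has a
  *positive* dS–$N_c$ slope.
* **K2P** — $K = -\tfrac12\log((1-2p-q)\sqrt{1-2q})$ on gap/N-free
  columns; copy-to-consensus K2P profiles proxy intragenomic family age.
* **Dating** — $T = k/2r$, with $k$ the TE dS of the pair and $r$ a
  per-taxon-pair synonymous rate (defaults: 17.567e-3 within
  Anophelinae, 9.205e-3 within Culicinae, 10.006e-3 between the
  subfamilies, substitutions per synonymous site per My). Rates can be
  re-estimated from gene dS as $r = \overline{dS}/2T_{div}$
  (`estimate_rate()`; arithmetic mean by default, median behind a flag).

## Upstream reconstruction rules

Copy recovery from tabular homology hits keeps HSPs with bit score
strictly above 200 and merges same-family, same-contig, same-strand hits
whose genomic gap is at most 1000 nt ("above 200" is read strictly;
merging only same-strand hits avoids chimeric copies from nested
opposite-orientation insertions; merging uses subject proximity only,
not query-coordinate colinearity — both choices are configurable).
Families are built by greedy incremental clustering at 80% global
identity and 80% coverage of the shorter sequence (length-descending
insertion order, lexicographic ties, so clustering is deterministic
under permutation), with a star-alignment majority consensus.
HTT candidates must span at least two species, have all members at least
600 nt, and carry an ORF strictly longer than 300 aa (Class I) or 200 aa
(Class II). ORFs are maximal stop-to-stop or edge-bounded runs over all
six frames with no start-codon requirement, because TE consensuses are
often start-degraded; an unclassified family is an error unless an
explicit threshold is supplied, since the rule is class-specific.
Flank comparison (default 4000 nt, the midpoint of the 3–5 kb window;
minimum 3000 nt before a flank counts) separates transfer from
introgression: a side is "shared" at $\ge$ 0.70 local-alignment identity
over $\ge$ 0.50 of the shorter flank, any shared side yields
`putative_introgression`, and missing flanks yield `indeterminate`
rather than a call. The long-range screen against external genomes
requires merged query coverage strictly above 80%, identity at least
80%, and copy number strictly above 5 — or qualifying matches in a
strict majority of a species' assemblies when several are available.

Pairwise alignment uses fixed deterministic scoring (match +1, mismatch
-1, gap open 2, gap extend 1); identity is matches over alignment
columns excluding terminal gaps. Coordinates are 0-based half-open
internally, converted from 1-based inclusive tabular input on read, and
written as BED without further shifting.

## What the simulator emulates

`simulate_gene()`/`simulate_te()` evolve codon sequences along a
phylogeny with *synonymous substitutions only*: the protein is
invariant, so emitted tip sets are trivially aligned and dS is the only
divergence statistic with signal — precisely the quantity the test
consumes. Each codon accrues Poisson events at rate
$r_s\,t\,s_c$, where $s_c$ is its fractional synonymous site count and

$$r_s = r_{max}(1 - \lambda\,\beta)$$

couples the synonymous rate to the bias strength $\beta \in [0,1]$ of
the unit's codon preference (preferred codon probability
$1/k + \beta(1-1/k)$ per amino acid, one fixed preferred codon table).
Each event moves the codon to a single-nucleotide synonymous neighbour
drawn by the preference, so one event is one substitution. Defaults:
50 genes of 500 codons, TEs of 600 codons, $r_{max} = 0.02$ per
synonymous site per My, $\lambda = 0.5$. The $\lambda$ default gives a
two-fold rate range across the CUB spectrum — strong enough that the
gene regression has unambiguous signal, far from the degenerate
$\lambda \to 1$ corner where biased genes stop evolving. Horizontal TEs
evolve along the donor lineage, are copied into the recipient at the
transfer time, and evolve independently afterwards; vertical TEs evolve
like genes. `simulate_copy_burst()` emits intragenomic copy sets of
known age with a 2:1 transition bias. One root seed drives everything;
per-unit seeds derive from a stable hash of unit ids, so adding units
does not perturb existing ones.

What the simulator does *not* emulate — and what passing tests therefore
do not establish about real data: indels and alignment error (real codon
alignments come from an external aligner and carry frame errors),
nonsynonymous change and selection, rate variation among sites and
lineages, nested/fragmented TE copies, assembly artefacts, and
biological lack-of-fit in the dS–CUB relation beyond sampling noise.

## Numerical behaviour of the null

Two second-order effects are worth knowing. First, TE length: the
pipeline's 600-codon TEs carry less sampling noise than the 500-codon
reference genes, so their prediction-residual p-values are mildly
underdispersed (conservative). Under the exchangeable null — TE
simulated at the gene length — p-values are uniform up to the second
effect. Second, skew: dS is a count statistic (roughly Poisson
differences through a convex log correction), so its noise is slightly
right-skewed and the p-value distribution's centre sits just below 0.5
(median ~0.48 at the default depths) even though the lower tail — the
part that sets the false-positive rate at $\alpha = 0.01$ — is exact to
conservative. `calibration_study()` exposes both regimes via its
`codons_per_te` argument; `power_study()` and `dating_study()` complete
the simulation-based validation. Problem sizes used by the test suite
and `scripts/acceptance.R`: 20 pair replicates x 50 TEs (1000 null
tests), 200 power replicates, 200 dating replicates — sizes at which the
binomial CI on the significant fraction and the stated power/dating
tolerances are sharp.

## Degenerate inputs and tie-breaks

Exact-fit regressions (residual sd ~ 0) short-circuit to p in {0, 0.5,
1} by sign rather than dividing by zero; constant-CUB gene sets and
fewer than `min_genes` usable genes are errors; saturated TE dS
suppresses the call with a reason instead of emitting p = NA silently.
Consensus ties break in fixed A < C < G < T order; ORF ties prefer the
plus strand, then the lower frame, then the leftmost position;
clustering ties prefer the earlier-founded cluster. The flat
`key = value` configuration reader covers the thresholds the pipeline
echoes into its run manifest; reruns on identical inputs are
byte-identical because no analysis stage uses randomness.

## Known limitations

Family-level event counts are lower bounds (one event per family with
any significant pair). The dS estimator is NG86 with JC correction;
at high divergence it inherits JC's mild bias for two-fold degenerate
sites, which is visible as a few-percent offset in deep simulated
comparisons and is irrelevant to the low-dS regime where transfers are
called. The clustering and consensus steps are simple deterministic
stand-ins for heavier external tools (greedy 80/80 clustering, star
alignment): adequate for simulated and well-behaved data, not a
replacement for a production aligner on diverged real families. The
geographic test treats species pairs as independent observations, as in
the underlying method.
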