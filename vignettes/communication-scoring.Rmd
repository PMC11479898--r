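---
title: "Scoring ligand-receptor communication between cell states"
author: "LRlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring ligand-receptor communication between cell states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LRlink)
```

## The problem

A stimulated sentinel cell (the *sender*, e.g. an IL-33-primed mast cell)
can instruct a neighbouring lymphocyte (the *receiver*, e.g. an activated
memory CD4+ T cell) through ligand-receptor (L-R) contacts. Given bulk
RNA-seq mean expression (FPKM) for both cell states, a differential-
expression contrast for the sender (stimulated versus resting), and a
curated L-R database in which either side may be a multichain complex,
LRlink asks: *which pairs are plausibly active, and how do they rank?*

## The scoring model

For a pair $i$ with ligand level $L_i$ (sender) and receptor level $R_i$
(receiver), the communication score is the product

$$S_i = L_i \cdot R_i, \qquad S_i \in [0, 100],$$

and a pair is called **active** iff $S_i > 0$. The levels are built in
four stages:

1. **Ligand selection.** Sender ligand candidates are the genes
   upregulated on stimulation: FDR $< 0.01$ and $\log_2$ fold change
   $> 1$, both strict and signed (downregulated genes never qualify).
2. **Thresholding.** On each side only genes with FPKM $> 1$ (strict)
   survive; this is the "active pair" filter, since any lost subunit
   zeroes its side.
3. **Scaling.** Each side's surviving values are divided by that side's
   own *scale maximum* — the arithmetic mean of the top 10% of its values
   — multiplied by 10, and values above 10 (outliers) are coerced to 10.
   Unclipped values therefore span $(0, 10]$.
4. **Complex aggregation.** A multichain ligand or receptor is summarized
   by the geometric mean of its (clipped) chain values; a single-chain
   molecule is its sole value.

Active pairs are ranked by descending $S_i$, ties broken by pair id
(ascending) so the ranking is deterministic.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `fpkmMin` | 1 | FPKM | strict expression floor per side |
| `fdrMax` | 0.01 | probability | strict FDR cut for ligand selection |
| `log2fcMin` | 1 | log2 units | strict, signed fold-change cut |
| `scaleFactor` | 10 | — | multiplier after division by the scale max |
| `ceiling` | 10 | scaled units | cap for outliers |
| `topFraction` | 0.10 | — | fraction of values averaged into the scale max |
| `topK` | 30 | pairs | chord-diagram size |

All live in a `ScoringConfig` and are echoed into the result's
provenance, so any run can be reproduced from its output alone.

## Design choices that were genuinely open

* **Universe of the scale maximum.** "The mean of the 10% highest values"
  needs a gene set. LRlink uses exactly the values that are subsequently
  scaled: database ligand subunits that passed the DEG cuts and the
  threshold (ligand side), database receptor subunits that passed the
  threshold (receptor side). This is the self-consistent choice — scaled
  values then genuinely range over $(0, 10]$ apart from clipped outliers.
  Computing the maximum over *all* expressed genes instead would shrink
  every scaled value by a constant factor per side and leave rankings
  intact, but break the $[0,10]$ reading of levels.
* **Clip before aggregating.** When a chain of a complex exceeds the
  ceiling, one must choose between clipping chains first or clipping the
  geometric mean. LRlink clips per gene first, keeping every intermediate
  in $[0, 10]$; the two orders differ only when a single chain clips
  while the complex mean would not.
* **Multichain completeness.** A complex missing *any* chain (unmeasured,
  not DEG-selected, or below the threshold) gets level 0: a heteromeric
  receptor cannot signal without all of its chains. The alternative —
  averaging over present chains only — silently converts missing data
  into signal.
* **Small-n top decile.** The number of averaged top values is
  $\lceil 0.1\,n \rceil$, at least 1, so the scale maximum is defined for
  every non-empty side (with 10 values it is the single largest; with
  constant values it is that constant).
* **Both-sides genes.** A gene appearing as both a ligand and a receptor
  is scaled independently on each side with that side's own maximum.
* **Degenerate inputs.** If no ligand or no receptor survives selection
  and thresholding, the result is an explicit zero-active outcome with a
  note in the provenance, not an error: an empty communication network is
  a legitimate finding.

## Numerical behaviour

All arithmetic is double precision; nothing is rounded before output
formatting (the TSV writer rounds to 4 decimals for readability and a
JSON sidecar keeps 17 significant digits). The ranking tie-break makes
output byte-stable across runs.

Two invariance properties deserve care:

* **Scale invariance.** Multiplying every sender FPKM by $c > 0$ leaves
  all $L_i$ — and hence all $S_i$ — unchanged *provided the FPKM > 1
  survivor set does not change*: the scaling is relative to the same
  set's top-decile mean, and clipping commutes because ratios are
  unchanged. The proviso is real: the threshold is absolute (FPKM is a
  normalized unit with physical meaning), so a factor that pushes genes
  across 1 FPKM legitimately changes the analysis. In floating point the
  invariance is additionally exact only for factors that are powers of
  two (exact binary multiplication); for general factors each input picks
  up an independent 1-ulp rounding, and agreement is at the $10^{-15}$
  relative level rather than bitwise.
* **Aggregation/scaling commutation.** Because all chains of one side
  share one scale maximum, the geometric mean of scaled chains equals the
  scaled geometric mean of raw chains whenever no chain clips; the test
  suite asserts this on random unclipped fixtures.

## What the synthetic generator emulates

`generateDataset()` builds a dataset whose correct answer is known by
construction. Background FPKM is drawn log-normal (default meanlog 2,
sdlog 1.5: median ~7 FPKM, heavy right tail), emulating the marginal
shape of bulk RNA-seq FPKM. Each side receives decoy genes that shape its
top-decile scale maximum but can never form an active pair: decoy
ligands pass the DEG cuts yet pair with receptors expressed below the
threshold; decoy receptors pair with ligands that fail the DEG cuts.
Planted pairs are given ligand and receptor levels of
$\sqrt{S_\text{target}}$; the generator inverts the scaling transform by
iterating the raw-FPKM solution to a fixed point (planted values may
themselves enter the top-decile set), verifies the achieved scaled
values to $10^{-9}$, and rescales the background and retries — finally
failing loudly — when no fixed point exists. Multichain planted pairs
use two chains with equal expression, so the geometric mean is the
identity and aggregation correctness is tested independently of the
inversion.

What the generator does **not** emulate: replicate-level variance,
count-based noise, correlated gene modules, alias/synonym mismatches
between database and expression tables, and the composition of any real
curated L-R database. Passing the planted-recovery tests therefore shows
the pipeline's bookkeeping and arithmetic are right, not that any
particular biological dataset will yield a particular number of active
pairs — with real data that count also depends on the database release
used.

The default synthetic conditions are 100 background genes per side, five
planted pairs at scores 80/60/40/20/5 (40% of them multichain), sizes at
which every end-to-end property in the test suite runs in seconds; the
oracle-equivalence checks use 200 random instances of up to 30 genes and
15 pairs.

## Visualization

`renderChord()` draws the top-`topK` active pairs as a circular diagram:
ligand complexes occupy one semicircle, receptor complexes the other,
and each pair is a ribbon whose angular width is proportional to its
score on both sides. Editorial exclusions (e.g. dropping ubiquitous
adhesion pairs such as ICAM/integrin interactions) and display-name
overrides (e.g. showing TNFSF4 as OX40L) are explicit arguments, never
inferred. Every quantitative aspect of the figure is exported to a JSON
geometry sidecar; tests assert on that geometry, never on pixels.

## Worked example

```{r example}
ds <- generateDataset(SyntheticSpec(seed = 1L))
res <- runPipeline(ds$db, ds$deg, ds$sender, ds$receiver)
res
as.data.frame(activePairs(res))
```

## Known limitations

* Scores carry no significance measure; ranking is descriptive, and no
  permutation null is computed.
* Direction is fixed sender-to-receiver; autocrine or reverse signalling
  requires a second run with roles swapped.
* Gene-symbol matching is exact (after case folding); records that
  curated databases and expression tables sometimes disagree on symbols,
  `validateSymbols()` reports — but does not repair — such gaps.
* FPKM thresholds are absolute, so cross-dataset comparability assumes
  comparable normalization.
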