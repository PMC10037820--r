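---
title: "Dating gene-family founder events with genefounder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating gene-family founder events with genefounder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genefounder)
```

## The model

A gene's relative age is the index of the deepest clade of the focal
species' lineage that contains a detectable homolog. `genefounder` takes
that classical phylostratigraphic idea and wraps it in the corrections
that make it trustworthy: reconfirmation of the age through intermediate
levels, collapse of levels without genomic representation, family-level
dating, and an explicit statistical test against homology detection
failure (HDF).

The package consumes only *tabular* evidence — pairwise-alignment hit
tables in the BLAST/DIAMOND `outfmt 6` dialect with subject taxids, and a
local taxonomy — so it is agnostic to which aligner produced the
alignments, and never runs one itself.

### Taxonomic representativeness

For a gene with age level $AP$ (its oldest represented level) and $RP$
represented levels among $2..AP$,

$$L = 100 \times \frac{RP}{AP - 1} \in \left[\frac{100}{AP-1},\, 100\right].$$

The youngest level is excluded from the denominator because presence in
the focal species is self-confirming; by the same argument a gene found
*only* in the focal species gets $L = 100$ by convention (the formula is
undefined at $AP = 1$). $RP$ always counts the oldest level itself, which
necessarily has a hit, giving the lower endpoint $100/(AP-1)$. A gene
present only in the focal species and one distant clade — the signature
of contamination, horizontal transfer, or a false-positive match — sits
at that lower endpoint and is flagged when $L$ falls below the 30%
default (strict `<`). Flagging assumes a ladder-like topology between the
query and the database species, which holds as long as the lineage's
levels are monophyletic; non-monophyletic levels (the classic example is
Eumetazoa) can be removed by name with `exclude_levels`, and only
interior levels may be excluded — the focal species anchors the young end
of the scale and the root the old end.

### Level collapsing

Public databases represent some clades by a handful of sequences rather
than genomes; treating those levels as real absences manufactures
spurious loss events and drags down $L$. A level is therefore retained
only when at least one species diverging there matches **more than** 10%
of the query proteome (strict inequality at the boundary). The
denominator is the full query proteome, not only age-assignable genes —
the fraction is meant to measure how completely a *genome* covers the
query gene set. Dropped levels re-map onto the next retained older level,
and the operation is idempotent.

### Families as single events

Paralog ages are not independent: a family's members descend from one
founder. Families are recovered by Markov clustering of the all-vs-all
self-search graph, with edge weights $\min(-\log_{10} E, 200)$ (the cap
handles underflowed e-values; the best e-value of the two directions is
used, since MCL wants a symmetric matrix). The MCL loop is the textbook
one — self-loops, column normalisation, expansion by squaring, inflation
at 2.0, pruning at $10^{-6}$, attractor-based cluster read-out — with two
conventions worth stating. Self-loops take each column's maximum edge
weight (the convention of the canonical MCL implementation): a small
constant loop would let a strong two-gene edge oscillate under expansion
and shatter tight pairs into singletons. And a vertex attracted to two
attractor systems joins the one with the larger incoming flow, ties going
to the system with the lexicographically smallest attractor, which makes
the partition deterministic; tie detection uses a $10^{-9}$ slack so that
exact symmetric ties are not broken by floating-point noise.

The family founder age is the maximum age over members with status
`assigned`; flagged members carry unreliable ages and are excluded. Each
family contributes exactly one founder event at its founder level.

### The HDF test

Bitscores of true homologs decay roughly exponentially with evolutionary
distance. Per gene, the best-hit bitscores against the species of a
user-supplied distance table (substitutions/site from a published
phylogeny) are fitted to

$$\mu(d) = a e^{-r d},$$

by constrained least squares: $a$ is profiled in closed form given $r$,
$r \ge 0$ is found by 1-D minimisation and the pair is polished by
`nls(algorithm = "port")` with lower bounds — a deterministic procedure
with no random restarts. At least 3 points are required (two parameters
plus a noise scale); all-equal distances are degenerate. The noise scale
$c$ is the RMS of relative residuals, giving the Gaussian detection-failure
probability at distance $d^*$:

$$p = \Phi\!\left(\frac{S_{thr} - \mu(d^*)}{c\,\mu(d^*)}\right),$$

with the deterministic limits $p \in \{0, 1\}$ when $c = 0$. This
relative-noise Gaussian is a concrete, testable model (monotone in $d^*$,
checked against Monte-Carlo sampling in the test suite); it is inspired
by, but not guaranteed bit-compatible with, external bitscore-decay
tools. $S_{thr} = \log_2(mn/E_{thr})$ couples detectability to the same
e-value threshold used for age assignment, with nominal query length $m$
and database size $n$ supplied by the user (or a fixed override).

The tested outgroup is the *single closest* distance-table species
diverging deeper than the gene's level; when no such species is sampled
the gene is `untestable` — the reach of the HDF test is set by the
taxonomic sampling of the phylogeny behind the distance table. A family's
founder event is high confidence only when a member with the founder age
itself passes at $p < 0.05$ (strict): a younger member passing says
nothing about the founder event.

## Defaults and the choices behind them

| parameter | default | why |
|---|---|---|
| e-value threshold | `1e-5`, inclusive | robust middle ground: looser thresholds admit false positives, stricter ones inflate young TRGs and `absent` genes; aligners report "hits at or below" a threshold, hence `<=` |
| representativeness flag | `L < 30` | relaxed enough to tolerate genuine secondary losses and patchy databases, strict enough to catch the `100/(AP-1)` contamination signature |
| level retention | fraction `> 0.10` | excludes taxa represented by stray sequences rather than genomes |
| MCL inflation | 2.0 | the standard default granularity |
| HDF significance | `p < 0.05` | conventional test level; strict comparison |

All of these surface as arguments of `pipeline_config()` and are recorded
in `run_metadata.json`.

## What the simulator emulates — and what it does not

`simulate_dataset()` draws a ladder taxonomy (default 8 levels, 3 species
per divergence ring), families (50, of 1–4 genes) with a family-shared
birth level (uniform by default), per-gene decay parameters
($a \sim \mathrm{lognormal}(\log 150, 0.3)$ bits,
$r \sim \Gamma(2, 0.5)$ per subst/site — typical well-detectable proteins
with realistic decay spread), 5% relative score noise, 5% per-ring gene
loss, and ring distances doubling from 0.05 to 3.2 substitutions/site. A
species carries a hit iff it diverges within the gene's birth clade, no
loss applies, and the realised bitscore clears the detection threshold;
e-values are back-computed from bitscores via the Karlin–Altschul
identity with $m = 400$, $n = 10^{10}$, so the default emission threshold
equals the pipeline's own $S_{thr} \approx 58.5$ bits. Contaminants, when
requested, hit only the focal species plus one ring at level ≥ 5,
reproducing the flagging signature in closed form.

This emulates the *statistical* structure the method assumes — it does
not emulate real sequence evolution. There are no actual sequences, no
rate variation across sites, no correlated loss, no database biases
beyond ring occupancy, and within-family self-hit e-values are uniformly
strong. Passing tests therefore demonstrate that the pipeline's
inferences are correct *under its own generative assumptions* (exact
birth-level recovery in the noiseless regime, founder counts matching
truth, contaminant flagging), not that those assumptions hold for any
particular real proteome.

Simulated problem sizes in the test suite (tens of families, hundreds of
genes, 8 levels) were chosen as the smallest scales at which every
qualitative behaviour of the method is visible; all statistical suites
(500 MCL reference comparisons, 200 decay-fit replicates, $10^5$-draw
Monte-Carlo oracles, 10,000 score patterns) run in seconds at these
sizes.

## Numerical corners

* E-value 0 (aligner underflow) is accepted and maps to the similarity
  cap; malformed hit rows are counted, reported and skipped.
* Subjects not contained under the lineage root are unmappable: the hit
  is discarded and counted (`n_unmappable`), never silently re-mapped.
* Best-distant-hit ties break by bitscore, then e-value, then subject id,
  so outputs are byte-stable across runs and platforms.
* An MCL run that fails to converge within 100 iterations returns the
  current hard clustering with a warning flag rather than failing.
* Collapsing every interior level is legal: the lineage degenerates to
  {species, root} and ages re-map accordingly.
* A decay fit where the flat model is optimal returns the boundary
  $r = 0$; genes with fewer than 3 decay points, or points at a single
  distance, are `untestable`, never force-fitted.

## Known limitations

* The relative-noise Gaussian is one defensible reading of the
  bitscore-decay test; absolute probabilities will differ from tools with
  other noise parameterisations, though the $p < 0.05$ decision is
  insensitive for strongly separated cases (the parameter-recovery suite
  quantifies this).
* Only the single nearest next-level outgroup is tested; a sparse or
  skewed distance table weakens the test accordingly.
* Non-monophyletic lineage levels are handled only by explicit name
  exclusion, not auto-detected.
* Merged or deleted taxids are not resolved; the taxonomy files must
  already be self-consistent.
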