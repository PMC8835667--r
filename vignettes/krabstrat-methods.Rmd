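---
title: "Models and methods behind krabstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind krabstrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(krabstrat)
```

`krabstrat` implements the computational spine of a KRAB-domain
stratification analysis: profile-HMM classification of ancestral (aKRAB)
versus modern (mKRAB) Krüppel-associated box domains, the curation and
scoring conventions around it, sequence-logo and positional-frequency
summaries, an edit-script engine for the aKRAB→mKRAB mutagenesis roadmap,
and α-helix geometry on 3D models. This vignette explains the models, the
defaults, and the design decisions — including the ones where reasonable
alternatives existed.

## The KRAB coordinate frame

All positional reasoning uses per-subdomain, 1-based coordinates: `A1`–`A42`
for KRAB-A and `B1`–`B35` for KRAB-B, with every A position preceding every
B position. Ancestral domains are one residue short in the `A31`–`A34`
region; we keep numbering comparable across classes by treating that
alignment gap as an unoccupied coordinate: an aKRAB `krab_sequence` simply
has no residue mapped at `A32`, rather than carrying a gap character in its
residue string. Internally, string indices are 0-/1-based half-open in the
usual R sense and the boundary to domain coordinates is crossed only inside
the coordinate map, which is validated to be injective and strictly
order-preserving.

## Profile HMMs

`build_profile()` follows the classical match/insert/delete plan without a
multi-hit state. Columns whose residue occupancy is at least the
`occupancy_threshold` (default 0.5, the same "remove mostly-empty columns"
rule the logos use) become match states. Emissions are pseudocounted
background-proportionally, $(c_a + w\,q_a)/(n + w)$ with total weight $w=1$
per column — a deliberate simplification over Dirichlet mixtures that is
adequate at the alignment sizes involved here (tens to hundreds of rows)
and keeps every probability strictly positive. Transitions are tallied from
each row's match/insert/delete usage and Laplace-smoothed; the rare
delete↔insert adjacencies that the 7-transition plan cannot express are
folded into the corresponding exit through a match state. The background is
uniform (1/20) by default because the source analysis never states a null
composition; an alignment-derived background is selectable.

Scoring is **local in sequence, global in model** (the domain-scan
semantics of classic `hmmpfam`): every match column must be visited (as
match or delete), while flanking sequence is free. Flanks are modeled as
background emitters with free transitions, so a flank residue contributes
exactly zero log-odds; entry is possible after any prefix and exit before
any suffix. This makes the score a pure log₂ likelihood ratio over the
aligned region, summed over alignments (forward) or maximized (Viterbi).
Both recursions run in compiled code in log₂ space with log-sum-exp; the
test suite checks them against an independent brute-force enumeration of
every state path on small models, to 10⁻⁹.

One consequence of the free-flank convention is worth stating: paths that
traverse the model entirely through delete states are counted once per
entry point. This is an intrinsic (and harmless) property of
uniform-entry local scoring; it affects only the deep-negative score
regime, far below any decision threshold.

### E-values

The source procedure thresholds on E-values but does not document its null
or database-size convention, so E-value parity with any particular HMMER
version is explicitly *not* a goal; all cross-model conclusions are
rank-based. We calibrate each model by scoring `n_samples` background
sequences (default length: the model length) and fitting a Gumbel law by
maximum likelihood ($\hat\beta$ by the standard one-dimensional root,
$\hat\mu$ in closed form given $\hat\beta$), giving
$E(s) = n_{db}\,(1 - \exp(-\exp(-\lambda(s-\mu))))$. `n_db` defaults to the
size of the catalog being scored, mirroring database-conditional E-values.
Calibration takes an explicit seed and is bit-reproducible; the default
seed used in examples and the pipeline is 1072. A degenerate (zero
variance) score distribution refuses to calibrate rather than returning
nonsense.

## Curation and stratification

The curation pipeline mirrors the published procedure: a permissive filter
removes entries with E ≥ 0.01 against the pooled model (the boundary is
`>=`, so an entry exactly at the threshold is removed), within-species
duplicates collapse to their first occurrence (identical sequences in
different species are kept — they are biology, not gene-model artifacts),
and a strict pass at E ≥ 10⁻¹⁰ removes truncations and spurious hits.
Filtering is idempotent and every removal is logged.

Scores enter all summaries through the clamped −log₁₀ transform: any
E-value at or above the 0.01 floor contributes exactly 2. The clamp is
applied *before* medians and ranges are computed; range minima that sit at
the floor are rendered `"<2"`, matching the display convention of the
published tables (whether the original analysis clamped before or after
computing ranges is not stated; clamping before is our documented choice).
Best-model assignment takes the maximal clamped score with a margin; strict
ties (difference < 10⁻¹²) and all-clamped rows are labelled `unknown`
rather than assigned arbitrarily.

Group comparisons use a two-sided Wilcoxon–Mann–Whitney test implemented in
the package (a spec'd requirement, so that its exact branch can be verified
against enumeration): when both samples have at most 8 values the p-value
is computed by exact enumeration of all $\binom{n_a+n_b}{n_a}$ group
assignments of the pooled values (midranks handle ties; two equal constant
samples give p = 1 by convention); larger samples use the normal
approximation with tie correction and continuity correction. The exact
branch is tested against `stats::wilcox.test(exact = TRUE)` on untied
data, and the approximation against the exact branch at $n = 8+8$, where
they agree within 0.02 everywhere.

## Logos and positional frequencies

Column information content is the relative entropy
$\sum_a p_a \log_2(p_a/q_a)$ over observed residues, with **no
pseudocounts and no small-sample correction** — the groups summarized here
have hundreds of members and the reference logo tool applies none visibly;
a flag exists for composition backgrounds. Letter heights are $ic \cdot
p_a$, so column heights decompose exactly. Ambiguity codes (B, Z, X, U and
friends) are excluded from residue counts but still count as occupied for
occupancy; `drop_sparse_columns()` removes columns with gap fraction above
0.5 and keeps the index map so KRAB coordinates survive the removal. The
manually widened gap display at `A32` in published aKRAB logos is treated
as a rendering concern; the matrices keep the true columns.

`position_counts()` answers "how often does residue X occur at coordinate Y
in subgroup Z", with the denominator being the number of sequences that
occupy the column at all, and counting in B positions proceeding
irrespective of whether a conserved KRAB-B exists in the subgroup — both
conventions taken from the source tables.

## The mutagenesis edit engine

Edits are data, not code: the shipped roster (`mutant_library()`) lives in
a TSV config so that constructs defined only graphically in the source can
be added later without touching the engine. The grammar is
`A27:R>V` for substitutions and `A32-A34:KR>MLE` for block replacements.
Three choices matter:

* **Ranges absorb unmapped coordinates.** The MLE block addresses
  `A32–A34`; on an ancestral sequence `A32` is vacant and the range matches
  the `KR` actually present, so the replacement claims `A32`–`A34` and the
  sequence gains exactly one residue. (The alternative notation `A32-A33`
  parses fine but will refuse application on a frame where KR sits at
  `A33`–`A34` — the context check exists precisely to catch stale
  coordinates.)
* **Insertions beyond the range width stay coordinate-less.** The
  double-proline helix breaker is encoded `A33-A33:L>LPP`; the two prolines
  live in the residue string between `A33` and `A34` without claiming frame
  coordinates, which keeps the non-overlap invariant and makes the edit
  exactly invertible.
* **Scripts are wild-type-relative.** P9Am13 (the MLE back-mutation of
  P9Am10) is stored as its net three substitutions; a test verifies it
  equals P9Am10 followed by the inverse MLE edit.

Every application validates the `from` residues at their coordinates and
refuses with a position report on mismatch; `diff_inventory()` re-applies
the script and tallies substitutions, block replacements and the signed
length delta. Reference sequences for ZNF10/PRDM9/SSX/lcha ship as
**synthetic stand-ins** (`synthetic_reference()`, the generator consensus
at divergence 0) that satisfy every positional residue the scripts address;
they are deliberately not accession sequences, so the package has no fetch
step and never fabricates database content.

## Helix geometry

Helix detection uses CA-only distance windows (i,i+3 ∈ 4.6–5.8 Å and
i,i+4 ∈ 5.6–6.8 Å, P-SEA style), avoiding any hydrogen-bond or DSSP
dependency; thresholds are arguments. Axis fitting proceeds in two steps:
the initial direction is the smallest-eigenvalue eigenvector of the
scatter of second differences of the CA trace (for an ideal helix the
second differences are exactly perpendicular to the axis, so this is exact
at any length ≥ 4 with no turn-count requirement), then the direction is
refined by minimizing the algebraic circle-fit residual of the CAs
projected along the axis. On noise-free generated helices of 6–30 residues
the twist is recovered to well under 0.5°; under 0.2 Å Gaussian coordinate
noise the axis stays within ~1° of truth on average. Rise, twist (signed,
right-handed about the N→C direction) and radius come from the projections
onto and about the fitted axis.

`azimuthal_rotation()` is the measurement that connects sequence to
structure: superpose structure B onto structure A over an anchor stretch
(Kabsch, SVD with determinant correction so mirrored inputs still yield a
proper rotation), fit the helix axis on A's anchor CAs, project both probe
side-chain vectors (CA→CB, with a tetrahedral pseudo-CB built from N/CA/C
when CB is absent — glycine probes work) onto the plane normal to the
axis, and return the signed angle. The anchor/probe convention used by the
original structural comparison is not stated; ours — anchor on the shared
helix-2 N-terminal stretch, CA→CB azimuth, right-handed sign about N→C —
is documented and every piece is an argument. On ideal 100°-per-residue
helices a one-residue insertion upstream of the probe yields 100° ± 2°,
the analytic sibling of the ≈97° reported on relaxed model structures
(real helices are not ideally regular, so a few degrees of difference is
expected, not a discrepancy).

AlphaFold-style pLDDT values in the B-factor column are parsed and
reported, but never used to filter by default.

## The synthetic-data generator

The generator defines the study conditions for every statistical test in
the package. Each of the four subgroups (mKRAB, PRDM9-like, SSX-like,
lcha-like) is a per-position categorical distribution over the 77-column
KRAB frame built from a fixed consensus: the consensus residue carries
$1-d+d/20$ mass at divergence $d$, everything else $d/20$, aKRAB
generators place probability 1 on the gap at `A32` (they never emit
there), and the lcha generator plants `B14/E` at rate 0.4 — emulating the
partial modern-type E at that position in the coelacanth subgroup. The
consensus strings carry the published diagnostic motifs (mKRAB A7–8/DV,
A32–34/MLE, B13–14/LE, B19–20/PW; aKRAB A7–8/DI, A33–34/KR; PRDM9 S9, M20,
R27 and B31/W; lcha B5–10/PKPDFM, A23/W, A34/E) plus a handful of
group-specific scaffold positions so that all four classes are pairwise
distinguishable; the non-motif scaffold is invented, chosen once, and
shared across groups. Default divergence is 0.1, putting ~0.9 of the mass
on consensus — approximating the tall letters of the published logos
without claiming their exact frequencies. Indels are off by default (KRAB
domains have a well-defined size); a per-position `indel_rate` exists.
Species labels are drawn from a 20-species pool and a `duplicate_rate`
fraction of entries is re-emitted verbatim under the same species to
exercise deduplication.

What the generator does **not** emulate: phylogenetic correlation between
species (every sequence is independent), position–position covariation,
length variation beyond the A32 hole, and real subfamily divergence
profiles. Passing the recovery tests therefore demonstrates that the
pipeline's machinery is correct and well-calibrated under motif-structured
data of realistic conservation — not that real catalogs will separate this
cleanly. On real data the published medians depend on HMMER2-era E-value
conventions we deliberately do not replicate, which is why all acceptance
on score tables is rank-based (own-model dominance, group separation)
rather than value-exact.

## Problem sizes and determinism

The shipped tests and the acceptance script use: exhaustive path
enumeration on models with ≤ 3 match states and sequences to length 4 over
a 4-letter alphabet; catalogs of 50 sequences per group (25/25 train/test)
at divergence 0.1 for classifier recovery; 300-sequence calibrations inside
the pipeline and 2000 draws for Gumbel parameter recovery; 20-residue ideal
helices for geometry. These sizes make the whole suite run in well under a
minute while leaving every statistical check comfortably powered. All
stochastic steps take explicit integer seeds and are bit-reproducible; the
pipeline serializes its full configuration into the run report, and
re-running from the report reproduces every output byte-identically.

## Known limitations

* No multi-hit (J-state) scoring, no glocal/uni-hit switching, no DNA
  models, and no acceleration heuristics — single-domain scans only.
* E-values are internally consistent but not comparable to any specific
  HMMER release.
* The exact WMW branch is exponential in the smaller sample; it is capped
  at 8+8 by design.
* Helix detection is CA-geometric; π-helices, tight 3₁₀ stretches, or very
  distorted helices may be split or missed where DSSP would not.
* The curated 666-entry catalog, its alignments, and the relaxed 3D models
  of the original study are not shipped; reproducing the published counts
  (e.g. B14/E at 106/257 in lcha, the 38-column aKRAB-A logo, the ≈97°
  register shift on model PDBs) requires pointing the same functions at
  that supplementary data.
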