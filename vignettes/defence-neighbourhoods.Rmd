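---
title: "Methods: regulator discovery, defence-island association, operator scanning and EMSA quantification"
author: "brxrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: defence neighbourhoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models and
procedures it implements, the parameters that matter, the numerical
choices made where the design was genuinely open, and what the synthetic
validation data does — and does not — establish.

## The analysis in one paragraph

BrxR-family regulators are WYL-domain winged-HTH repressors of phage
defence operons. Given a set of annotated genomes, a regulator query
protein and a panel of defence-system marker proteins, the pipeline (i)
finds regulator homologues by exact local alignment with E-value
statistics, (ii) scans a fixed window on both sides of each homologue for
marker homologues, strand-aware, (iii) collapses marker hits into
defence-system instances and classifies each locus by where its systems
lie, (iv) summarises system classes, class co-occurrence, taxonomy and
replicon type, and (v) searches the sequence immediately upstream of each
homologue for the mismatch-tolerant inverted repeats characteristic of
BrxR operators. A separate module quantifies EMSA titrations into
fractional saturations and fits a binding isotherm to estimate the
dissociation constant.

## Coordinates and distances

All internal coordinates are 0-based half-open; GFF3 and GenBank readers
and writers convert to/from 1-based inclusive, and inverted-repeat TSV
output is again 1-based inclusive. This removes off-by-one ambiguity from
the window arithmetic.

Distances between genes are **edge gaps**: the number of bases between
the nearest feature edges, 0 for overlapping features. The source
analysis does not state whether distances were measured from gene starts,
stops or edges; edge-gap is the most inclusive reading and the package's
documented default. *Downstream* means 3′ of the regulator on **its own
coding strand** (the motivating defence island lies 3′ of the regulator
in its transcription direction); a `direction_mode = "coordinate"` flag
is available for the alternative higher-coordinate reading. Features
that overlap the regulator are inside any window and are returned for
either direction with distance 0. Windows never cross replicon
boundaries, and upstream extraction does not wrap around circular
replicons unless explicitly enabled (`circular_wrap = TRUE`) — wrap-around
changes plasmid results, so it is an explicit flag.

## Homology search

The search is an exact Smith–Waterman/Gotoh local alignment under affine
gaps — full dynamic programming, no heuristic seeding — which is
practical at desk scale and makes the statistic exactly reproducible. A
gap of length *k* costs `gap_open + k · gap_extend` (defaults 11 + k,
BLOSUM62), mirroring a default protein BLAST parameterisation.
Significance uses the Karlin–Altschul form

    E = K · m′ · n′ · exp(−λ S)

with the published gapped constants for BLOSUM62/11/1 (λ = 0.267,
K = 0.041). The tested default is "simple" mode (effective lengths =
raw lengths, ℓ = 0), chosen because it has a closed-form oracle; a
"corrected" mode solves the standard edge-effect length adjustment
iteratively from ℓ = ln(K·m′·n′)/H with H = 0.14. The database length
*n* is the total residue count of all proteins searched. Thresholds are
**strict** (`E < 1e-5`), with `1e-3` as the sensitivity setting.

Determinism choices: traceback prefers diagonal over gap-in-subject over
gap-in-query; among equal-scoring end cells the smallest (subject end,
query end) pair wins; one best hit per (query, CDS) pair (the analysis
counts protein homologues, not HSPs — whether the original analysis
merged multiple HSPs per pair is unknowable from the text, so one-best-hit
is the documented choice). Identity is matches over alignment columns,
gaps included.

## Window association and system grouping

Marker hits on the locus replicon in the requested direction with edge
gap ≤ W (default W = 50,000 bp) are kept; each marker is tested
individually, so a multi-gene system straddling the boundary contributes
only the genes inside the window. Hits sharing a system name whose
features lie within `cluster_gap` of one another (single-linkage on edge
gaps, default 20,000 bp) collapse into one system instance; the same
system name recurring beyond the gap founds a new instance. The source
analysis never states how its marker hits were grouped into systems;
20 kb is our configurable choice, large enough to hold a BREX operon
with interleaved genes and small enough to separate repeated systems. A
marker reachable from two regulator loci counts for both (associations
are per-locus; no global deduplication). Instance subtype is the subtype
of the lowest-E hit in the cluster.

Each locus gets a four-way verdict (`downstream_only`, `upstream_only`,
`both`, `none`); the verdict counts partition the loci. Summary
percentages are `100 · count / total` rounded to two decimals with
round-half-even, matching the two-decimal reporting style of the field.
Co-occurrence tables map each locus's *set* of downstream system classes
to a locus count (the numerical content of an UpSet plot); class
distributions count instances, not loci.

## Inverted-repeat scanning

An inverted repeat is two equal-length arms separated by a spacer, where
the Hamming distance between arm 1 and the reverse complement of arm 2 is
at most `max_mismatch`. The model is substitutions only — no bulges —
matching the classic palindrome-scanner model. Defaults follow the
stated genome-scan settings: minimum repeat length 20, spacer < 8 bp
(`max_gap = 7`), at most 2 mismatches, scanning up to 200 bp upstream.

Whether "minimum repeat length 20" means per arm or the whole footprint
is ambiguous; both semantics are implemented (`length_semantics =
"per_arm"` (default) or `"total"`). The known 11-bp R-BOX arms would be
invisible to a 20-bp per-arm scan, which is why the operator-geometry
tests scan at `min_arm = 11`.

Exact output semantics (oracle-checked): for every inner boundary and
spacer, the scanner reports the *maximal* repeat — the arms cannot be
extended outward (spacer unchanged) within the mismatch budget and the
sequence bounds. Mismatch counts are non-decreasing under outward
extension, so this maximum is unique, and any repeat wholly contained in
a reported repeat with equal spacer is automatically suppressed. `N`
mismatches everything, including `N`; case is ignored. One consequence
worth knowing: a planted repeat with fewer mismatches than the scan
budget can be accompanied by maximal "spacer-eating" variants (longer
arms, shorter spacer) whenever the inner spacer bases happen to pair
within the budget; these are genuine maximal repeats under the stated
rules, not artefacts, and the brute-force enumeration oracle reports
them identically. Tests for planted operators therefore assert exact
recovery of the planted geometry rather than exclusivity, except at the
exact budget where exclusivity holds.

## EMSA quantification

Fractional saturation is `Y = 1 − I_T / I_C` from unbound-band
intensities (test lane vs zero-protein control). Noise can push
`I_T > I_C` (Y < 0) or past the plateau (Y > 1); such points are
**retained**, because clipping asymmetric noise biases Kd upward.

The regression is nonlinear least squares (`stats::nls`, port algorithm)
on `Y(c) = Ymax · cⁿ / (Kdⁿ + cⁿ)` with n fixed at 1 (hyperbolic
default) or free (Hill). The source only says "non-linear regression";
the single-site hyperbola with free Ymax is the default because gels
rarely saturate at exactly 1, and both `fix_ymax` and
`average_replicates` are exposed since neither choice is stated. Kd is
initialised where linear interpolation of the per-concentration mean Y
crosses half of max(Y), bounded in (0, 100 · max conc]; an optimizer
failure or a bound-hitting Kd is reported as non-convergence with a
status string rather than a number. Standard errors come from the
covariance of the fit. Unit invariance (scaling all intensities) holds
exactly because Y is a ratio.

## Synthetic data: what it emulates and what a green test establishes

The generators produce annotated multi-replicon genomes with i.i.d.
background DNA at a configurable GC, planted ORFs (ATG start, no internal
stop, TAA stop) back-translated with uniform synonymous codon choice
(bacterial code) from proteins mutated to a target identity, decoy genes
built by shuffling the residue composition of panel proteins (same
composition, no homology), and flank-guarded upstream inverted repeats of
controlled arm/spacer/mismatch geometry. A single root seed fans out to
per-element child seeds, so the same spec and seed are byte-identical and
editing one element does not perturb the others. Flank-guarding forces
the base pairs immediately outside a planted repeat to mismatch, so a
scan whose budget equals the planted mismatch count recovers the planted
geometry exactly; corpus fixtures plant 2 mismatches to match the
default budget.

The default corpus cycles six archetypes — no systems; downstream at
10 kb; systems at exactly 49.5 kb downstream and exactly 50 kb upstream
of a minus-strand regulator (both inside the window); a system at
50,001 bp (just outside); a plasmid-borne regulator with an upstream
system; and a two-regulator genome — exercising the window boundary from
both sides, both strands, both directions, multi-locus bookkeeping and
replicon typing. Truth verdicts and instances are recomputed from plan
coordinates only (never from the generated sequences), so the comparison
pipeline-vs-truth is a genuine dual route.

What a green corpus test does **not** establish: performance on real
genomes. The background is i.i.d. (no repeats, no skew, no mobile
elements), planted proteins diverge by uniform substitution (no indels,
no domain shuffling, no compositional bias), decoys are
composition-matched but unrelated (no distant paralogs near the E-value
threshold), and annotations are perfect. Sensitivity and specificity on
RefSeq-scale data depend on those realities and on the marker panel, and
are outside what desk-scale validation can show.

## Numerical and degenerate-input choices

* Empty alignment inputs score 0 with empty spans; protein-less genomes
  are a hard error pointing at the translation option.
* Sequences shorter than the minimum repeat footprint yield an empty IR
  result with a log message, not an error.
* CDS with length not divisible by 3 and no supplied protein are kept,
  translated to nothing, with a warning.
* All-zero saturation curves, < 3 distinct concentrations, optimizer
  failures and bound-hitting Kd estimates are reported as
  `converged = FALSE` with a status string.
* Percent formatting uses round-half-even at 2 dp everywhere.
* The run manifest hashes the analysis configuration (window, thresholds,
  IR parameters, input paths, seed — everything except the output
  directory), so identical analyses written to different directories
  compare equal.

## Limitations

No HMM- or profile-based system detection (a marker panel with local
alignment is weaker than PADLOC/DefenseFinder-style models); no gene
prediction (annotations are inputs); no statistical significance for
inverted repeats; no cooperative multi-site or kinetic binding models;
figure rendering (trees, waffle, UpSet) is out of scope — the package
emits the counts tables those figures are drawn from.
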