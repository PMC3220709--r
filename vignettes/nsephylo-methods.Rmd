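---
title: "nsephylo: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nsephylo: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsephylo)
```

# The problem

Nucleotide-sugar interconversion enzymes (NSEs) — the epimerases,
dehydratases, decarboxylases and reductases that convert one NDP-sugar into
another — share a single ancient domain fold, so family membership cannot be
read off pairwise similarity alone. The workflow this package implements is
the standard phylogenomic one: build one profile HMM per family from a seed
alignment, harvest every domain-bearing protein from a database at an
E-value cutoff, assign each harvested domain to the family whose model
scores it best, inspect domain architecture to separate single-domain from
fused bi-domain proteins (the UDP-L-rhamnose synthase case: an N-terminal
4,6-dehydratase fused to a C-terminal 3,5-epimerase-4-reductase), confirm
family structure with supported clades in trees, and corroborate fusion
history with prokaryotic gene-neighborhood synteny (*rmlB*/*rmlC*/*rmlD*-style
clusters).

# The profile HMM

`build_profile()` constructs a simplified Plan7-like model. The architecture
is **glocal**: every path traverses all `M` match columns (through match or
delete states) while consuming an arbitrary contiguous subsequence of the
target; flanking residues are emitted by the null model and cost nothing.
This mirrors the "global in the model, local in the sequence" search mode
classically used for domain models.

Model structure and estimation:

* **Match columns** are alignment columns with gap fraction strictly below
  `gap_threshold` (default 0.5); a column exactly at the threshold becomes
  an insert column, so the boundary is deterministic.
* **Match emissions** are Henikoff position-based weighted counts blended
  with background-proportional pseudocounts of total weight
  `pseudocount_weight` (default 1.0) per column. `henikoff_weights()` is
  exported and hand-checkable: each column contributes `1/(r·s)` to a row
  holding a residue observed `s` times among `r` distinct residues.
* **Insert emissions equal the background**, so insert residues are free in
  log-odds terms and only insert transitions cost. **Transition
  probabilities are fixed constants** (M→M 0.90, M→I 0.05, M→D 0.05,
  I→M = I→I = 0.5, D→M 0.8, D→D 0.2, entry B→M₁ 0.95, B→D₁ 0.05), written
  into the serialization header. Estimating transitions from typical seed
  alignments is noisy and untestable at desk scale; fixing them removes
  free parameters without changing the ranking behavior the pipeline needs.
* **Scores are bits** (log2-odds against the background); internal
  accumulation is in natural log. The background is uniform 1/20 by default
  and overridable — the null model is a modeling choice, not something the
  workflow prescribes.
* Paths that consume zero residues (an all-delete traversal) are excluded
  from the path set; a reported hit therefore always has a well-defined
  envelope, and the exhaustive enumeration oracle used by the tests
  enumerates exactly the same path set.

`score_forward()` (sum over paths) is the scoring used for E-values and
classification; `score_viterbi()` supplies the envelope (the consumed span,
1-based inclusive).

## Smoothing scoring models

A model used for scoring must never contain near-zero emissions: a single
substituted residue would incur an effectively unbounded penalty, which no
alignment-built model exhibits (this is exactly what Dirichlet priors in
classical model builders prevent). `build_profile()` smooths by
construction. Simulation-truth profiles from `make_random_profile()` are
raw draws, so when they double as scoring models they are first passed
through `smooth_profile()`, which applies the same background-pseudocount
blend at a pseudo-depth of `effective_n` (default 10, a typical
seed-alignment depth). Generation always uses the raw profile: the world
and the model of the world are kept distinct.

# Calibration and E-values

`calibrate()` scores `n_samples` i.i.d. background sequences of length
`sample_len` with the Forward algorithm and fits a Gumbel (type-I extreme
value) distribution by maximum likelihood; `evalue()` then reports
`db_size × P(S > s)`. Defaults — 1000 samples of length 350, uniform
background — are package decisions; classical calibration tools leave them
to the user as well. The database size enters E-values explicitly
everywhere, because a cutoff is only meaningful relative to a stated search
size; `db_size` defaults to the number of records actually scanned. The cutoff itself is
strict (`E < 0.01` retains, `E = 0.01` does not).

# Harvest, classification, architecture

`harvest_domains()` keeps one best envelope per sequence per profile and
trims retained domains to their Viterbi envelopes (classifying trimmed
envelopes rather than full-length proteins is this package's documented
choice). `classify_competitive()` gates candidates by
E-value and assigns by highest Forward bit score — "more similar to this
model than to the others" — with exact ties resolved to the
lexicographically smallest family at margin 0. Any profile can be flagged
`sink = TRUE` so that broad absorbing families can soak up distant homologs
without polluting the family-by-taxon count matrix, whose row order is the
fixed six-group vocabulary (Viridiplantae, Fungi, Metazoa, Other
eukaryotes, Archaea, Bacteria).

`detect_architecture()` requires, for a bi-domain call, that both profiles
pass the cutoff, that their envelopes overlap by at most
`max_overlap_frac` (default 0.2, measured against the shorter envelope —
distinct catalytic domains should occupy essentially distinct spans, with
some envelope slop tolerated), and that the N envelope starts before the C
envelope (the biological orientation of the fusion). Both-pass cases that
fail overlap or order resolve to the higher-scoring single-domain label
with an explanatory note, never to bi-domain.

# Trees, supports, subclades

The built-in tree path is neighbor joining over `p` or Poisson-corrected
distances, with bootstrap supports from column resampling — maximum
likelihood inference is deliberately not re-implemented, because the
downstream claims rest on clade membership and support, which
`extract_subclade()` reproduces on *any* imported Newick tree (supports are
internal-node labels in [0, 100], whatever their origin). Numerical
choices: Q-matrix ties break on the lexicographically smallest pair of
cluster representative labels; negative branch-length estimates clamp to 0
with a warning; for the Poisson correction `p` is capped at `1 − 1e-3`
(maximum distance ≈ 6.91) so saturated pairs stay finite; a zero-overlap
sequence pair is an error naming the pair. One support is stored per node;
multi-support annotation (e.g. two methods separated by "/") is out of
scope. `extract_subclade()` returns the smallest bipartition side
containing all seeds; when the seeds span the root under every rooting it
returns the full leaf set with a note, flagged `low_support` (the
conventional display threshold, 70%, is the default).

# Synteny

`synteny_scan()` reads "clustered within a region spanning seven genes" as
an inclusive gene count: two labeled genes at ordinals *i* and *i+6* span 7
and qualify; *i* and *i+7* span 8 and do not. At least `min_distinct`
distinct family labels (default 2) must co-occur; two copies of one family
never qualify. Strand and intergenic distances are ignored — the reasoning
is in gene counts, not base pairs — and windows never cross contigs.
Maximal non-nested windows are reported. Under a uniform null (one pair of
labeled genes among 100), the exact call probability is 579/4950 ≈ 0.117,
which the tests verify by simulation.

# The synthetic world

The generators emulate the statistical structure the analysis assumes, with
defaults chosen once:

| parameter | default | why |
|---|---|---|
| profile length | 80–120 columns | typical single-domain (Rossmann-fold) span |
| Dirichlet concentration | 0.2 | strongly conserved but not degenerate columns |
| divergence | 0.15 subs/residue | within-family divergence that still supports confident assignment |
| flanks | 20–80 background residues/side | envelope localization is non-trivial |
| linker | 10 residues | short inter-domain linker of natural fusions |
| decoys | residue-shuffled family samples | composition preserved, signal destroyed — the hardest null for profile scoring |

Divergence is applied as i.i.d. point substitutions (uniform over the 19
alternative residues); there is no indel process, no rate heterogeneity
across sites, and no substitution-matrix structure. A green test therefore
establishes that the machinery recovers planted structure under
composition-preserving nulls — not that it would match any particular
count from a real database-scale survey, which is explicitly out of
reach. Every generator is a pure function of its seed; truth tables carry
everything needed to score downstream modules.

The two supplementary-style acceptance targets (hit-list intersection of
24; 4 bacterial C-domain entries) are computed on a synthetic stand-in
world **constructed to the reference composition and then measured**: the
pipeline must actually recover the planted fusions and taxon labels through
harvesting and architecture calls for the numbers to come out right.

# Workflow and reproducibility

`run_pipeline()` reads one flat `key: value` config, validates that every
referenced input exists before any stage runs, executes
harvest → classify → architecture → phylo → synteny, and writes per-stage
TSVs plus a JSON report echoing all parameters and seeds. A stage failure
is recorded in the report and later stages still run. All randomness flows
through explicit seeds, so a rerun with the same config is byte-identical
except for the timestamped log.

# Known limitations

* The profile HMM is single-hit: one envelope per sequence per profile.
  Multi-domain detection is only available through two distinct profiles
  (the architecture module); repeats of the same domain are not modeled.
* Fixed transition constants mean alignment-specific indel statistics are
  not learned.
* The Gumbel fit extrapolates far into the tail for very high scores; this
  is the standard practice but tail E-values far below ~1e-10 are nominal.
* NJ is the only built-in tree method; for publication-grade phylogenies an
  external ML tool's Newick output should be imported.
* Stockholm parsing covers plain single-alignment files (sequence lines plus
  `#=` annotations), not embedded alignments or per-residue markup.
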