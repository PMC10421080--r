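---
title: "Isotope-tagged pair screening: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope-tagged pair screening: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopair)
```

## The measurement model

Shotgun derivatization acylates every accessible hydroxyl/phenol in a crude
extract with a 1:1 mixture of light (¹²C₃) and heavy (¹³C₃) propanoic acid.
A compound carrying `n` tags therefore appears in a feature table twice per
isotopologue choice; in practice the two dominant species are the all-light
and all-heavy forms, whose m/z separation at charge `z` is

$$\Delta m = \frac{n \cdot 3\,(m_{^{13}C} - m_{^{12}C})}{z}
           = \frac{n \times 3.010065}{z}\ \mathrm{Da}.$$

Because the two forms are chemically identical, they co-elute and ionize
alike: the pair signature is (i) an exact m/z spacing, (ii) retention-time
coincidence, and (iii) near-1:1 intensity. Each of those three properties
is a tunable filter in `tolerance_policy()`:

| parameter | default | units | rationale |
|---|---|---|---|
| `mz_ppm` | 3 | ppm | Orbitrap-class mass accuracy; evaluated against the *expected* heavy position `mz + n·Δm/z` |
| `rt_window` | 0.05 | min | isotopologues co-elute; only alignment jitter separates them |
| `intensity_max_rel_diff` | 0.33 | fraction | 1:1 tagging; the filter that rejects natural M+3 satellites (~1 % of M+0) |
| `n_tags` | {1} | — | a single +Δm shift; multiply-tagged search is opt-in because each extra multiplicity enlarges the decoy surface |
| `charge` | 1 | — | small-molecule NP ions are overwhelmingly singly charged; multi-charge is a parameter, never the default |

The detector builds the "shifted hypothetical table": every peak is a
candidate light member whose heavy partner must sit at `mz + n·Δm/z`. On
the m/z-sorted table each candidate's tolerance window is located by binary
search, so the join is `O(N log N + hits)` rather than all-pairs; the
all-pairs evaluation survives as `brute_force_pairs()`, the independent
oracle the test suite compares against.

Why the intensity filter carries the decoy burden: the natural M+3
satellite of an untagged compound is dominated by ¹³C₃ substitution, so its
*spacing* is the same 3.010065 Da as the tag delta — exact mass alone
cannot reject it. Its *intensity* can: even for large small molecules the
M+3 abundance stays near 1 % of M+0, a ~99 % relative difference against
the 33 % ceiling. The untagged-control property in the test suite verifies
that envelope-only tables produce essentially no pairs.

## Mass arithmetic

All arithmetic derives from a pinned monoisotopic mass table
(`element_masses()`), shipped to ≥6 decimals so results are bit-stable:
one light propanoylation adds C₃H₄O = 56.026215 Da; cationic adduct shifts
include the electron mass (H⁺ = 1.007276, Na⁺ = 22.989221,
NH₄⁺ = 18.033826), which matters at ppm scale. `tagged_mz()` and
`parent_mz_from_tagged()` are exact inverses (round-trip within 1e-9 Da);
display rounding to 4 decimals is a reporting convention only. Tag and
adduct tables can be replaced wholesale via a YAML file
(`load_tag_config()`), e.g. for a different acyl tag or adduct set.
Molecular-formula prediction from exact mass is deliberately out of scope;
the package computes masses from compositions, never the reverse.

## Pre/post comparison

The cell-affinity assay produces a second feature table from the lysate;
pairs detected there are matched back to the extract's hit table by the
light member's m/z and RT under `match_policy()` (±4 ppm, ±0.5 min). The
looser windows are intentional: the two tables come from separate
injections, so mass calibration and retention drift between runs exceed the
within-run jitter that pair detection faces. ppm is computed against the
mean of the two compared m/z values, which makes the relation symmetric in
its arguments; assignment is one-to-one greedy by increasing ppm difference
(ties by RT difference, then by row order) — deterministic, and adequate
because genuine cross-sample matches are far better separated than the
tolerance radius. The result partitions both tables exactly into matched /
pre-only / post-only, and `enrichment_fraction()` is matched over pre hits
(0 by convention for an empty pre table).

## The synthetic-data generator

`generate_extract_tables()` emulates the parts of the experiment the
analysis sees. Defaults were fixed once, as the package's reference study
conditions:

* **300 tagged compounds, 3000 background features** — a tagged extract in
  the "hundreds of labeled compounds among thousands of features" regime.
* **binder_fraction 0.08** — whole-cell affinity enrichment retains a
  few percent of tagged compounds; the number of binders is
  `round(n · fraction)` so the simulated truth is exact.
* **m/z 150–1200, RT 0.5–45 min** — a small-molecule scan range and a
  ~50-min gradient.
* **mz_jitter 0.5 ppm, rt_jitter 0.005 min, intensity_log_sd 0.1** —
  Orbitrap-class precision; twin-peak intensities differ only by
  ion-statistics noise.
* **envelope decoys on** — every background feature emits M+1/M+2/M+3
  satellites at 20–35 % / 3–8 % / 0.5–1.5 % of M+0, spaced by
  m(¹³C) − m(¹²C); these ranges mimic the qualitative description of
  natural envelopes and are configurable, not measured values.
* **post_attenuation 0.4, 5 metabolite-only pairs** — washing/lysis losses,
  and a handful of cell-metabolized products present only post.

Randomness uses the Mersenne-Twister generator with inversion normals,
explicitly named in `synthetic_spec()` so a seed reproduces tables across
platforms; the generator saves and restores the caller's RNG state.

What the simulation does *not* model: chromatographic peak shapes and
tailing, adduct multiplicity (one ion species per compound), correlated
matrix effects, intensity-dependent mass error, and RT warping between
runs. Passing the recovery properties therefore demonstrates the
correctness of the join and the filters under calibrated noise — not
instrument-grade performance on real exports, where upstream alignment
quality dominates.

## Numerical choices and degenerate inputs

* All tolerances are half-widths ("±") and comparisons are inclusive (`≤`).
* The intensity dissimilarity is `|I_l − I_h| / max(I_l, I_h)`: symmetric,
  bounded in [0, 1], and defined as 0 when both intensities are 0.
* Candidate windows are located with `findInterval` on the sorted m/z
  vector; the exact ppm predicate is then re-evaluated on every candidate,
  so boundary hits never depend on floating-point window edges.
* Hits are sorted by (light id, heavy id, n_tags) before return, which —
  together with id-based tie-breaks — makes the output invariant under
  input row permutation.
* Empty tables, single-peak tables and empty hit tables flow through every
  stage (detection, deduplication, matching, I/O) without special-casing by
  the caller; invalid CSV rows are dropped and counted in a load report
  rather than failing the read, because real exports contain footers and
  blanks.
* `deduplicate_hits(..., "best_ppm")` resolves a light peak matching
  several heavies by minimal |ppm error|, then minimal |RT delta|, then
  smallest heavy m/z; the default keeps all qualifying pairs, since the
  screening procedure treats the hit table as a candidate list for manual
  review.

## Problem sizes in the test suite

The bundled suite validates the oracle equivalence on 200 randomized
tables of 60–500 peaks whose pair offsets deliberately straddle every
tolerance boundary; detection performance on ten simulated extracts of
500 tagged compounds over 5000 background features (pooled recall ≥ 0.99,
precision ≥ 0.95 at the default policy); decoy control on ten
envelope-only tables of 3000 features; and enrichment recovery of a 0.08
binder fraction through the full file-based pipeline. These sizes keep a
full run in the tens of seconds on one core while leaving every code path
exercised at realistic density.

## Known limitations

* Pair detection assumes the light member is the lower-m/z peak and
  imposes no elution-order constraint beyond co-elution.
* A compound tagged at multiple sites produces mixed isotopologues
  (e.g. one light + one heavy tag) that the default single-shift search
  does not model; searching `n_tags = 1:k` finds the all-light/all-heavy
  pair but not the intermediate species.
* Cross-sample matching is presence/absence; quantitative enrichment
  ratios from intensities are out of scope.
* The package consumes aligned feature tables; peak picking, deconvolution
  and cross-run RT alignment belong to the upstream tools that produce
  them.
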