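---
title: "Peptide-map differential analysis of processed allergens with pepshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide-map differential analysis of processed allergens with pepshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepshift)
```

## Scope and model

`pepshift` analyses label-free peptide quantification tables from a
control protein preparation against treated preparations (the motivating
case is pH-shift-treated peanut protein against neutral peanut protein,
NPP). The pipeline has five analytic stages, each exposed as ordinary
functions and orchestrated by `run_pipeline()`:

1. in-silico tryptic digestion (`digest()`, `find_cleavage_sites()`),
2. quant-table validation and the detection-length filter
   (`read_quant_table()`, `apply_detection_filter()`),
3. relative-abundance classification (`compute_ra()`, `classify_ra()`)
   and coverage summaries (`coverage_summary()`),
4. cleavage-site exposure/masking inference (`collect_site_evidence()`,
   `infer_sites()`),
5. linear-epitope intactness and change reporting (`epitope_report()`),

plus an independent competitive-ELISA module (`inhibition_ratio()`,
`fit_4pl()`, `compare_ic50()`).

## Assumptions and parameters

**Digestion.** Trypsin cleaves C-terminal of K/R; cleavage before proline
is suppressed by default (the Keil rule, matching common search-engine
settings), and `X` never matches a cleavage residue so digestion is
deterministic on sequences with unknown residues. Only fully tryptic
peptides are generated or used as site evidence: a ragged terminus says
nothing about trypsin accessibility. Defaults: `max_missed_cleavages = 2`
(a common label-free search setting; the value is configurable and the
site-inference stage does not depend on it), detection window
`[5, 45]` residues, applied inclusively at both ends and after
missed-cleavage enumeration.

**Relative abundance.** `RA = I_treated / I_control` with the control
referenced at level 1. Thresholds default to `> 2.0` (increased) and
`< 0.5` (decreased). Both published rules are strict inequalities, which
leaves the boundary values unassigned; `pepshift` classifies `RA = 0.5`
and `RA = 2.0` as `unchanged` — the conservative reading, and the one
under which swapping control and treated exactly mirrors
increased/decreased (the thresholds are reciprocal). One-sided detections
are first-class categories (`only_in_control`, `only_in_treated`); no
pseudo-count is ever introduced, because an invented denominator would
manufacture arbitrarily extreme ratios. An explicit intensity of 0 is
treated as not detected — label-free exports conflate the two, and one
rule avoids spurious infinite ratios. No cross-run normalisation is
applied by default: ratios are taken on the intensities as provided,
since silently normalising would change results invisibly. Replicate
columns sharing a condition prefix (`NPP_1`, `NPP_2`) are averaged on
read.

**Site inference.** The informal argument "this peptide appeared after
treatment, so its flanking site was exposed" is formalised as a signed
vote per (site, flanking tryptic terminus): +1 for
`increased`/`only_in_treated`, −1 for `decreased`/`only_in_control`, 0
for `unchanged`. The per-site score decides `exposed` (> 0) or `masked`
(< 0); a zero score is `unchanged` when all votes are zero and
`ambiguous` when +1 and −1 votes cancel — a declared tie rule rather than
a narrative judgement. Sites flanked only by peptides outside the
detection window are reported as `no_evidence`, never dropped. Note one
structural artefact this inherits from the data: when a site is masked,
the merged peptide spanning it (if detectable) appears treated-only and
votes at the *neighbouring* sites; single-vote calls at neighbours of a
changed site are therefore expected, which is why downstream recovery
statistics condition on at least two concordant evidence peptides.

**Epitope intactness.** An epitope is intact when the union of detected
peptides covers all of its residues — a coverage map shades epitopes over
multiple peptide tracks, so requiring a single spanning peptide would be
stricter than the visual convention; the strict reading is available via
`require_single_peptide = TRUE`. Change labels: `lost`/`gained` compare
intact flags; `reduced` captures both the abundance route (every covering
peptide decreased or control-only) and the detection route (the treated
covering set a strict subset of the control's); `retained` otherwise when
intact in both. "Reduced" has no single published operational definition;
this rule makes both plausible routes explicit and auditable.

**Packaged epitope registry.** The shipped registry
(`packaged_epitope_registry()`) lists the published linear IgE-binding
epitopes of Ara h 1 (P43238), Ara h 2 (Q6PSU2), Ara h 3 (O82580) and
Ara h 6 (Q647G9) exactly as printed in the source literature. Two entries
are internally inconsistent as printed: the Ara h 3 epitope spans
positions 29–44 (16 positions) but states a 15-residue sequence, and one
Ara h 1 entry contains the non-standard letter `O` (almost certainly a
typesetting artefact). The registry is the source of record, so both are
shipped verbatim with `length_consistent` / `letters_canonical` flags
raised; `load_epitope_registry()` additionally validates entries against
parent sequences when these are supplied, recording a suggested
re-anchoring position on mismatch but never rewriting coordinates.

**ELISA.** The inhibition ratio is
`(1 − (B1 − B0)/(B2 − B0)) × 100`; it is affine- and scale-invariant in
the absorbances, and out-of-range values from noisy wells are flagged but
not clipped (clipping would bias the fit). The dose-response model is the
four-parameter logistic — the standard competitive-ELISA choice;
estimation is Levenberg–Marquardt least squares (`minpack.lm::nlsLM`)
with initialisation `bottom = min(IR)`, `top = max(IR)`, `ic50` at the
geometric mean concentration, `hill = 1`, and positivity bounds on `ic50`
and `hill`. The fit requires at least 4 distinct positive concentrations
spanning the inflection; zero-concentration wells are excluded from the
fit and flat data are rejected rather than fitted. By construction the
fitted curve crosses `(bottom + top)/2` exactly at `IC50`. IC50 is in the
concentration units of the input (µg/mL in the motivating study);
ascending IC50 means descending IgE-binding capacity.

## What the synthetic generator emulates

`sim_config()` / `simulate_dataset()` generate every pipeline input with
recorded ground truth:

* a random protein (default 800 residues, K/R density 0.05 — fragment
  lengths around 20 residues, comfortably inside the 5–45 window, with
  enough long fragments that merging two of them exceeds the window);
* condition-dependent cleavage: each site fires per condition with its
  accessibility probability; planted *masked* sites fire in the control
  but not the treated conditions, planted *exposed* sites the reverse. At
  least one planted site of each direction has a merged fragment longer
  than the window, which converts the accessibility change into a
  detectable coverage loss/gain;
* a hard detection window (probability 1 inside `[5, 45]`, 0 outside)
  matching the stated detection-length rule;
* log-normal intensities: a reproducible per-interval base abundance
  (median 10^6^, log-sd 1) times planted fold changes times multiplicative
  noise — the standard label-free noise assumption, since no empirical
  noise model accompanies the motivating data;
* planted marker RAs of 11.5 and 3.8 (the magnitudes reported for the
  acid- and alkali-shifted conditions in the motivating study) plus a
  clear decrease (0.3) and a null (1.0);
* four planted epitopes engineered to come out `retained`, `reduced`,
  `lost` and `gained`;
* an ELISA plate generated by inverting the inhibition-ratio equation
  from a 4PL with IC50 0.22 µg/mL (the control-condition magnitude in the
  motivating study) over 8 log-spaced concentrations from 0.01 to 100,
  with additive Gaussian noise in percentage points.

Presets: `noiseless` (default; all probabilities 0/1, no noise — planted
effects recover exactly), `noisy` (accessibility 0.9/0.95/0.05, detection
0.9, intensity log-sd 0.3, ELISA sd 3) and `hard` (a stress setting).
Everything is deterministic given the seed.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: search-engine identification error and FDR,
chimeric or semi-tryptic peptides, retention-time effects and
match-between-runs, shared peptides between homologous allergens,
condition-correlated intensity drift, and plate-layout artefacts in the
ELISA. On real tables these enter upstream of `pepshift` and should be
handled in the search/quantification software.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere (the residue notation used
  for epitopes, e.g. 294–303); `subsequence(p, 1, nchar)` is the whole
  sequence.
* Coverage percentages are exact in `peptide_coverage()` and rounded only
  for presentation in `coverage_summary()`, half away from zero (50.5 →
  51), since R's default banker's rounding would be surprising in a
  summary table.
* Duplicate `(accession, start, end)` rows are a hard error, not merged;
  coordinate/sequence mismatches are re-anchored only on a unique exact
  substring hit, otherwise excluded and reported
  (`coerce_to_sequence_match()`).
* Empty inputs produce empty, schema-stable outputs (header-only TSVs).
* `run_pipeline()` output is a deterministic function of its inputs; the
  run log carries wall-clock timestamps and is the one file excluded from
  byte-identity.

## Validation design

The test suite checks each stage against an independent oracle: digestion
against brute-force substring enumeration (site scan written separately
from the package code); coverage against direct set-union arithmetic; the
4PL fit against noiseless self-consistency, random-parameter recovery and
the analytic half-inhibition identity; and the whole pipeline against the
generator's planted truth — 100% recovery of planted site states, RA
categories and epitope changes without noise, and ≥90% site-state
recovery (for sites with ≥2 concordant evidence peptides) pooled over 50
noisy simulations. Problem sizes — proteins up to 60 residues for the
enumeration oracle, 200 random proteins, 800-residue pipeline
simulations, 200 ELISA replicates — were chosen so each property is
exercised at meaningful scale while the whole suite runs in seconds.
`scripts/acceptance.R` recomputes the same recovery metrics from scratch
under a caller-supplied seed.

## Known limitations

* Site inference assumes fully tryptic evidence; semi-tryptic peptides
  are deliberately out of scope.
* Votes weight every evidence peptide equally; a single strong peptide
  and a marginal one count the same, and neighbour-site artefacts of
  merged peptides (see above) can produce single-vote calls that only the
  two-concordant-peptides convention filters out.
* `reduced` epitope calls depend on the declared rule; other operational
  readings are defensible.
* The ELISA module estimates IC50 from a 4PL only; if the underlying
  readout is not sigmoid in log concentration the diagnostics
  (`residual_norm`, `plot()`) should be inspected before comparing IC50s.
* Statistical testing of intensity differences (replicate-based
  inference, imputation) is out of scope; classification is by ratio
  thresholds.
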