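---
title: "Design of the synthetic MSA annotation benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design of the synthetic MSA annotation benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msabench)
```

## The problem

Figures in structural biology papers often *define* named regions of a
protein — a referring expression such as "Binding Site A" together with the
residue range it denotes — by drawing colored bars over a rendered multiple
sequence alignment (MSA). Measuring how well any annotator (an automated
model reading the image, or a human) recovers those name/range pairs
requires a corpus where the truth is known exactly. `msabench` generates
that corpus synthetically, renders it, runs annotators against it, and
scores them. Because the generator and the scorer share one in-memory
representation, ground truth is exact by construction and no manual
annotation is needed.

## The generative model

Each dataset is produced by a deliberately minimal process:

* a **parent** sequence of 180 residues, drawn i.i.d. uniformly from the 20
  standard amino acids (`ARNDCQEGHILKMFPSTWYV`);
* nine **children**, each derived per site independently: with probability
  `p_gap = 0.05` the site becomes a gap (`-`), otherwise with probability
  `p_mut = 0.1` it is substituted by a uniform draw from the 19 *other*
  residues, otherwise copied. Gaps replace residues in place, so every row
  keeps the parent's length and alignment columns coincide with parent
  residue indices (1-based);
* between 2 and 5 **regions** (count uniform on {2,…,5}), each of length
  uniform on [10, 30] columns, placed so consecutive regions are separated
  by at least 4 unannotated columns; each region draws a base name uniformly
  from {Mutation Hotspot, Low Conservation, Binding Site, Structural Motif}
  and gets a suffix letter (A, B, …) assigned per base name in ascending
  start order, so full names are unique within a dataset.

Two conventions deserve a note, because the observable rates depend on
them. Gap emission is evaluated *before* mutation, so the marginal gap rate
is exactly `p_gap`; and a substitution always changes the residue, so among
non-gap sites the mismatch rate is exactly `p_mut`. Both identities are
what the Monte-Carlo tests assert (3σ binomial bands), and both would be
diluted under the alternative orderings.

**Placement algorithm.** Region count and lengths are sampled first; starts
are then drawn independently and uniformly in their admissible ranges and
accepted when the sorted layout satisfies the separation constraint
(rejection sampling, 1000 attempts per length draw, 10 length redraws
before giving up with an error naming the constraint). At the defaults the
worst geometry is 5×30 + 4×4 = 166 ≤ 180 columns, so termination is not a
practical concern; the bounded-retry error path exists for user-supplied
configurations and is tested with a deliberately infeasible one. A
geometrically impossible request (minimum footprint exceeding the width)
fails immediately rather than burning retries.

**Seeding.** A corpus derives one seed per dataset from the master seed via
a seeded integer draw; per-dataset seeds are recorded in the manifest, so
any single dataset can be regenerated bit-for-bit without replaying the
corpus. The pipeline similarly splits its seed into three independent
streams (generation, region colors, simulated annotation) so that, e.g.,
changing the error model cannot perturb the generated truth.

## Rendering

Images are drawn with base-R graphics on the cairo PNG device at exactly
1006 × 867 px: 60 alignment columns per wrapped row panel, residue-number
ticks every 10 columns, region bars colored by an independent uniform draw
from {red, green, blue, orange, purple} (collisions allowed, and recorded
in the sidecar), and the region name above the bar in the same color,
left-aligned at the bar start. A region crossing a wrap boundary is split
across panels with the name over the first segment only — precisely the
visual situation that tempts annotators to invent a name for the orphaned
second segment. Letter glyphs use a fixed Clustal-like residue coloring;
font and letter styling are otherwise the device defaults, since the
benchmark's difficulty lives in the bar/name/tick geometry, not typography.
Rendering is byte-deterministic given the dataset, style and color seed,
which the suite asserts by comparing files.

## Annotator backends

All backends produce the same record shape (name, start, end — unvalidated
integers, since real annotators emit out-of-range and inverted ranges and
the scorer must see them).

**Response parsing.** The parsing pipeline for free-text model responses
strips code fences and stray backticks, locates the *last* occurrence of
the sentinel `parsed_result =` (responses often restate the requested
format before answering; the final assignment is taken as the answer), cuts
out the balanced bracketed literal after it (quote- and escape-aware), and
reads it as a literal list of `[name, start, end]` triples. Nothing is ever
evaluated: a payload containing executable code fails to parse, a property
the suite checks with a canary file that would exist had anything run.
Numeric strings such as `"39"` are coerced to integers, since models
sometimes quote numbers and refusing would manufacture blanks. Failures are
typed: `missing_key` (no sentinel), `syntax` (no balanced literal), and
`schema` (wrong arity or types) — one malformed element fails the whole
parse rather than silently dropping records.

**Retries.** An image is queried up to 3 times *in total* (a failed run of
an image is three unparsable responses in a row), after which a blank
result is returned with every raw response retained for audit. The default
pauses (5 s between images, 3 s before retries) exist for API pacing, are
irrelevant to correctness, and are set to 0 in tests. The transport is a
plain function `(image, prompt) -> text`, so the whole protocol is
exercised offline with mock backends; no network client ships with the
package.

**Simulated annotator.** A parametric error model reproduces the failure
modes seen in practice: per true region a miss (`p_miss`), independent
per-endpoint jitter uniform on `[-j, +j]`, a row-offset shift of both
endpoints by `-row_width` (`p_row_shift`; the bar read one wrapped row too
high), a one-character name typo (`p_name_typo`), a duplicate emission
(`p_duplicate`); plus, per dataset, one fabricated region with an
improvised name from a disjoint pool (`p_spurious`). With all parameters
zero the output equals the truth exactly, which anchors the end-to-end
identity test. The signed-error distribution of this model is analytically
a mixture — MAE = (1−p)·E|J| + p·E|−row_width + J| — and the suite recovers
it, together with the histogram mass near −row_width, from ≥ 10⁴ scored
regions within 3 Monte-Carlo standard errors.

**Human import.** Spreadsheet-entered annotations arrive as a TSV
(`image_id`, `sbre`, `start`, `end`); names are whitespace-trimmed,
boundaries validated as integers with row-level error reporting, and images
absent from the file score as blanks in the pipeline.

## Scoring

Name scoring converts each image's extracted names to a set (after
normalization) and counts exact matches against the truth-name set; counts
are pooled over all images before dividing (micro-averaging), so a blank
image contributes zero extractions but its truth regions still deflate
recall. Precision with zero total extractions is reported as `NA` rather
than 0 — "extracted nothing" and "all wrong" are different outcomes. F1 is
the harmonic mean, 0 when P + R = 0.

Boundary scoring pairs each predicted record with a truth region only when
its normalized name matches exactly one truth name *and* the name is not
duplicated among that image's predictions; everything else is excluded and
counted, never guessed at. Signed errors are estimated − truth, so the
one-row-above misread appears at −60. A name-matched record with reversed
boundaries still pairs; its errors simply reflect the inversion, since the
benchmark imposes no validity filter on predictions.

Matching is case-sensitive exact after whitespace trimming by default; a
case-insensitive matcher is provided (and used in the worked example)
because sentence-case variants of correctly identified names are an
annotator-casing artifact, not a different answer — which of the two
conventions a given study wants is a one-flag choice.

The error histogram uses integer-aligned left-closed bins of configurable
width (default 1 residue) over the pooled start+end errors; counts conserve
the number of error entries.

## What the synthetic corpus does and does not show

The generator emulates fixed-size, stylistically uniform MSA figures: equal
sequence counts, one wrap width, one tick convention, machine-placed bars
and labels. It does not emulate the heterogeneity of published figures —
variable column widths, tick frequencies, indexing conventions,
conservation shading, or hand-drawn annotations — nor realistic evolution
(no substitution matrices or indel length distributions). Results on this
corpus are therefore best read as an upper bound for an annotator's ability
on real figures: passing here is necessary, not sufficient. The region
count is modeled as uniform on {2,…,5}; a published corpus total a couple
of standard deviations above the uniform mean is treated as one stochastic
realization, since the count distribution is not otherwise constrained.

## Problem sizes and determinism

The default study conditions are 100 datasets of 10 × 180 alignments. The
test suite checks structural invariants over 1000 seeded datasets, corpus
totals over 50 master seeds, Monte-Carlo rate convergence over 10⁴ derived
children, and parameter recovery over ≥ 10⁴ scored regions; the brute-force
scoring oracle runs on 60 random small instances (≤ 5 truths, ≤ 6
predictions per image) against an independent reimplementation of the
matching rules. All randomness flows from explicit seeds; two pipeline runs
with the same arguments produce identical reports, manifests and rasters.

## Known limitations

* The renderer's label layout can clip a region name at the right panel
  edge, as real figure layouts sometimes do; the sidecar, not the pixels,
  is the ground truth.
* `parse_literal` accepts only list-of-triples literals; tuple syntax or
  dict-shaped answers fail as `syntax`/`schema` by design, matching the
  strictness of the prompt contract.
* The simulated annotator draws error modes independently per region; it
  does not model within-image correlation (e.g., an annotator who misreads
  one row tends to misread its neighbors).
* Only the `simulated` and `human-import` backends run end-to-end offline;
  live model transports must be supplied by the user as a function and are
  deliberately out of scope here.
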