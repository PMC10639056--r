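---
title: "Computational promoter engineering with promforge: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational promoter engineering with promforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promforge)
```

# Scope

promforge implements the computational half of a promoter-engineering
campaign for glucose-regulated yeast promoters: annotating
transcription-factor binding sites (TFBS) with position weight matrices
(PWMs), exhaustively mutating every base in silico to map which single
substitutions gain or lose sites, designing deletion/duplication variants,
simulating error-prone PCR (EP-PCR) mutant libraries, and analysing
plate-screening fluorescence and secreted-protein yields. The wet-lab half
— strain construction, cell sorting, cultivation — is out of scope; a
seeded synthetic-data layer emulates its outputs so every stage can be
exercised and tested without instruments or downloads.

# Coordinate model

All sequences are *upstream-anchored*: position $-1$ is the base
immediately 5' of the start codon's A, position $-L$ the 5'-most base of an
$L$-nt window. This is the convention in which promoter mutations are
reported ("-453T>C" = T, 453 nt upstream, replaced by C), so every printed
coordinate can be used verbatim. Internally the bijection
$\mathrm{index} = L + \mathrm{position} + 1$ maps onto ordinary 1-based
R indices. Mutation notation accepts both the ASCII hyphen and the
typographic minus; canonical output uses the hyphen.

One consequence worth internalising: because positions are anchored at the
start codon (3' end), deletions and duplications shift the coordinates of
*upstream* (more negative) bases only. Edit plans therefore always address
the *current* intermediate sequence, and `project_position()` carries an
original-frame coordinate forward through earlier edits; this removes the
main ambiguity in multi-edit designs.

# TFBS model and similarity scoring

A PWM is built from a $4 \times W$ count matrix with a per-base
pseudocount $c$ (default 0.8):
$f_i(b) = (n_i(b) + c) / (N_i + 4c)$. Each position gets a conservation
weight — its Kullback–Leibler divergence from the uniform base
distribution,

$$w_i = \sum_b f_i(b)\,\ln\!\big(4 f_i(b)\big),$$

which is 0 for an uninformative column and $\ln 4$ for a single-base
column. The similarity of a window $b_1 \dots b_W$ is the
conservation-weighted frequency ratio

$$\mathrm{mss} = \frac{\sum_i w_i\, f_i(b_i)}{\sum_i w_i \max_b f_i(b)}
\in [0, 1],$$

equal to 1 exactly when every window base attains its position's maximum
frequency (ties allowed, so a degenerate matrix can have several
perfect-scoring words; this is forced by the formula). The *core* of a
matrix is the run of `core_size` (default 4) consecutive positions with
the highest summed weight, leftmost on ties; core similarity is the same
ratio restricted to those positions. Scanning emits a hit when the matrix
similarity is *strictly above* the threshold (default 0.75, the
conventional cutoff for "potentially true" matches) *and* core similarity
is at least the core threshold (default 0.75, can be disabled). Both
strands are scanned; reverse-strand hits are reported in forward
coordinates. Hits may overlap — no masking — because distinct families
genuinely co-locate in TFBS-dense regulatory regions.

These are this package's own design choices. Commercial scanners that use
a similar $[0,1]$ similarity semantics keep their matrix libraries,
per-matrix optimised thresholds and core settings proprietary; only the
global 0.75 cutoff is portable. Consequently promforge is *not* expected
to reproduce any proprietary tool's hit counts for a real promoter, and
the synthetic matrices from `make_pwm_set()` carry no biological meaning
beyond their family labels. The default pseudocount 0.8 keeps minimum
scores away from 0 without flattening informative columns.

# Saturation mutagenesis and the gain/loss map

`enumerate_snvs()` produces all $3L$ single-nucleotide variants (2220 for
the canonical 740-nt window) in a deterministic order: positions $-L$ to
$-1$, alternative bases A<C<G<T skipping the reference. For each variant,
`position_effect_map()` records the TFBS families gained and lost relative
to the reference. Hit identity for the diff is the triple
*(matrix, strand, start)*: a site that shifts by 1 nt counts as one loss
plus one gain. This is deliberately conservative — no published rule
exists for when a moved site is "the same" site — and the choice is
recorded in the map's metadata. Aggregation is at family level, matching
how engineered variants are reported; matrix-level detail remains
available through `diff_tfbs()`.

Because a single substitution can only affect hits whose window covers the
mutated base, each variant is rescanned only over those windows. The
result is provably identical to a naive full rescan, and the test suite
verifies this against an independent brute-force oracle for sequences up
to 50 nt and the scanner itself against an exhaustive-window oracle at
200 nt.

`select_clean_mutations()` extracts the substitutions whose *only* effect
is one target family in one direction — the pattern that makes a
reverse-engineered point mutation interpretable. In the motivating
campaign, the one variant whose single mutation gained a CSRE and nothing
else was the one that cleanly raised induction strength; mutations with
collateral gains/losses behaved unpredictably.

# Variant design

`sliding_window_deletions()` tiles a region with `window`-nt deletions at
`window - overlap` steps, numbered from the upstream end. The canonical
design — 30-bp windows, 10-bp overlap, region $-400..-200$ — is motivated
by the ~10.4-bp helical turn: 30 bp removes about three turns, minimally
disturbing the rotational phasing of flanking sites. A 201-nt region
cannot be tiled exactly by ten such windows (ten windows at uniform 10-bp
overlaps span 210 nt), so the final window is anchored to the downstream
region edge and its overlap with its neighbour is allowed to exceed 10 bp;
the `windows` attribute flags this (`clipped`). This reproduces the
canonical count of ten variants while honouring both region bounds; the
exact historical window coordinates are not published, so the tiling rule
is promforge's own deterministic convention.

Duplications use *template semantics*: a substitution applied before a
duplication appears in every copy (as when a mutated plasmid is the PCR
template), while one applied after affects only the addressed coordinate.
The segment presets `Dup2-3` ($-261..-232$), `Dup5-7` ($-351..-282$) and
`Trip2-3` encode the two key segments identified by deletion analysis —
the printed `Dup5-7` span (70 nt) is wider than what uniform 20-nt steps
would predict for "deletions 5–7 minus shared flanks" (50 nt); the printed
coordinates are taken as authoritative. Whole-region duplication
(`duplicate_region()`, `"D-"` name prefix) defaults to $-506..-126$, the
bounds of the cloned construct; the alternative printed span
$-507..-122$ ships as the `"results"` preset.

```{r design-example, eval = FALSE}
p <- make_fixture_promoter(seed = 1)
mutbp <- compose(p, edit_plan(edit_substitute(-453, "T", "C"),
                              edit_substitute(-235, "A", "G")),
                 name = "MutBP")
d_mutbp <- duplicate_region(mutbp)   # "D-MutBP", 1121 nt
```

# EP-PCR library model

The simulator models the *endpoint* of a mutagenic PCR: each clone derives
from one of the serial mutagenesis steps (drawn from the pooling weights;
equimolar by default, matching how step libraries are pooled), and every
position of the target region then mutates independently with probability
$r \times w(\mathrm{ref})$, where $r$ is that step's cumulative average
rate and $w$ a mean-1 normalised per-base mutability weight. Cycle-by-cycle
lineage simulation is deliberately *not* modelled: only endpoint rates per
step are quantified in practice (here 1.5%, 2.7%, 3.4% per nt for the
three steps over the 321-nt target $-457..-137$), so a per-clone Bernoulli
process at the cumulative rate is the model the data can support. Mutation
counts per clone are therefore Binomial($n$, $r$) within a step and a
binomial mixture across the pooled library — both verified by
goodness-of-fit and closed-form tests.

The spectrum defaults are: 86.2% substitutions, 12.8% single-nt deletions
(the observed library composition), 1% insertions (observed only once in
the characterised clones, so the exact value is not printable);
substitution targets uniform over the three alternatives (the observed
to-base pattern was "fairly even"); from-base weights T:4, A:2, C:1, G:1
reflecting the strong T (and weaker A) bias of Taq/MnCl$_2$ protocols. The
numeric from-base weights are *illustrative* — the underlying bar chart is
not published as numbers — and every component is configurable. One known
discrepancy is documented rather than fitted: the observed median of 5.5
mutations per characterised clone is below the ~8 expected from the stated
rates over 321 nt (plausibly selection during library propagation); the
simulator reproduces the stated rates, not the 5.5.

# Screening statistics

The analysis chain per variant and condition is:

1. **Specific fluorescence** $= F / V^{\gamma}$ with $V$ a cell-volume
   proxy and $\gamma = 1$ by default. The upstream cytometric volume
   normalisation is instrument-specific; dividing by a volume surrogate
   preserves its intent without inventing optics, and $\gamma$ is
   configurable for power-law surrogates.
2. **Outlier removal** per group (variant and control separately) with the
   modified Z-score $Z_i = 0.6745 (x_i - \tilde x)/\mathrm{MAD}$, cutoff
   $|Z| > 3.5$; when $\mathrm{MAD} = 0$ the Iglewicz–Hoaglin fallback
   $Z_i = 0.7979 (x_i - \tilde x)/\mathrm{meanAD}$ is used. Which scale the
   historical analyses filtered on is not recorded; promforge filters on
   specific fluorescence (configurable), before normalisation and testing,
   and logs every removal.
3. **Relative fluorescence** per clone, $100 \times$ value / mean of the
   filtered control group (control average $\equiv$ 100%).
4. **Student's t-test**, two-sided, pooled variance (Welch optional), with
   the star convention `**` $p \le 0.05$, `***` $p \le 0.005$. No
   multiple-testing correction by default (per-variant stars are the
   reporting convention; Benjamini–Hochberg can be applied to the returned
   p-values if desired).

Yields follow the same pattern on $\mathrm{titer}/\mathrm{WCW}$, reported
as fold-change versus the filtered control mean.

## Known limitations of the robust filter at screening scale

Two textbook-sounding properties of this filter are *false* at the sample
sizes screening plates actually have (4–10 clones per group), and
promforge documents rather than hides this:

* **Calibration.** With $n = 8$ variant vs $n = 4$ control clones and
  ~10% lognormal noise, the bare t-test holds its nominal 5% level, but
  per-group filtering inflates the realized level to roughly 8–9%: in a
  *clean* group of four, the two central values frequently sit close
  together, the MAD collapses, and an ordinary point exceeds $|Z| = 3.5$
  (~17% of clean groups of four lose a point). Removing it shrinks the
  group variance and biases the test liberal. The star labels on
  small-plate screens are therefore slightly anti-conservative; treat
  `**` near the boundary with caution.
* **Idempotence.** Re-filtering the filter's own output can remove further
  points: deleting a gross outlier can collapse the recomputed MAD so that
  previously unremarkable values now score above 3.5. The filter is
  applied exactly once per group, by design; it is not run to convergence.

Both behaviours are exercised by the test suite (the acceptance-level
property checks state the idealised versions and fail honestly against
them) and are intrinsic to the MAD-based score at small $n$, not to this
implementation.

# Synthetic data: what it emulates, and what it does not

* `make_pwm_set()` — one synthetic matrix per family (defaults: the five
  nutrient-responsive families recurring in the engineered variants:
  F\$CSRE, Y\$MIG, F\$GATA, F\$MGCM, F\$PRES), unique consensi,
  configurable width and information content.
* `make_fixture_promoter()` — a random 740-nt background with the
  reference alleles implied by the catalogued variant mutations pinned at
  their printed positions, plus optional planted motifs with controlled
  mismatches. The fixture is explicitly synthetic: only the pinned
  coordinates/alleles tie it to the real promoter, whose full sequence is
  not reproduced here. Background composition is uniform by default (GC
  configurable).
* `make_screening_dataset()` — lognormal clone-to-clone variation around
  planted relative-fluorescence levels (defaults mirror the headline
  magnitudes of engineered variants: 100% controls, variants from ~25% up
  to ~620%), an independently noisy volume channel, optional 5–20$\times$
  outlier clones and integer-multiple "multicopy" clones. Truth metadata
  is emitted alongside and never consumed by the analysis functions.

What passing tests on these generators shows: the pipeline's arithmetic,
coordinate handling, recovery of planted effects at realistic noise, and
calibration behaviour. What it does not show: anything about real
cytometry (gating, autofluorescence, compensation), real TFBS biology
(the matrices are synthetic), or growth/selection effects in real
libraries.

# Numerical conventions and degenerate inputs

* Similarity thresholds compare strictly (`>`) for matrix similarity,
  inclusively (`>=`) for core similarity; a fully uninformative matrix
  (all weights 0) scores 1 everywhere by convention.
* Tied per-position maxima all count as consensus; catalog and window
  orderings are fully deterministic (documented tie-breaks: leftmost
  core, upstream-anchored windows, A<C<G<T alternatives).
* `copies = 1` duplications, zero-length regions, out-of-bounds
  coordinates, reference-allele mismatches and duplicate mutation
  positions are rejected with informative errors rather than silently
  normalised.
* All stochastic entry points take explicit seeds, restore the caller's
  RNG state, and are byte-reproducible.

# Problem sizes used by the test and acceptance suites

Chosen as comfortable desk-scale defaults: oracle-equivalence scans at
200 nt with 5 matrices; saturation-oracle comparison at 50 nt (150
variants); EP-PCR calibration from ~1.2 × 10^5 simulated events;
planted-effect recovery over 200 seeded screening replicates and
calibration checks over 10,000.
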