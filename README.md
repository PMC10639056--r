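# promforge

Computational promoter engineering for glucose-regulated yeast promoters.

Strong, tightly regulated promoters are the main lever for recombinant
protein production in hosts such as *Komagataella phaffii*, and improving
one (e.g. the glucose-limitation-induced *GTH1* promoter) combines two
strategies: random diversification (error-prone PCR + cell sorting) and
rational edits (point mutations, segmental deletions and duplications)
guided by transcription-factor binding site (TFBS) maps. promforge
implements the computational workflow behind such a campaign:

* **Sequence model** — upstream-anchored coordinates (−1 = base next to the
  start codon), mutation notation (`-453T>C`, both hyphen and typographic
  minus), FASTA I/O, validated mutation application.
* **PWM scanning** — position weight matrices with per-position
  conservation weights w<sub>i</sub> = Σ<sub>b</sub> f<sub>i</sub>(b) ln(4 f<sub>i</sub>(b)) and the
  similarity score

  mss = Σ w<sub>i</sub> f<sub>i</sub>(b<sub>i</sub>) / Σ w<sub>i</sub> max<sub>b</sub> f<sub>i</sub>(b) ∈ [0, 1],

  scanned on both strands with the conventional 0.75 cutoff plus a
  4-position core filter; JASPAR-PFM and count-table input, TSV/BED6
  output.
* **In silico saturation mutagenesis** — all 3L single-nucleotide variants
  (2220 for a 740-nt promoter) with a per-position map of TFBS families
  gained/lost, and selection of "clean" mutations that affect exactly one
  target family.
* **Variant design** — sliding-window deletions (30 bp / 10 bp overlap →
  10 variants over −400..−200), tandem segment duplications/triplications
  (presets `Dup2-3`, `Dup5-7`, `Trip2-3`), whole-region duplication with
  the `D-` naming convention, and multi-edit plans with template semantics
  (substitutions made before a duplication propagate into all copies).
* **EP-PCR library simulation** — per-clone Bernoulli mutations at the
  per-step endpoint rates (1.5/2.7/3.4% per nt, equimolar pooling) with a
  configurable mutation spectrum (86.2% substitutions / 12.8% deletions /
  1% insertions by default), plus library summary statistics.
* **Screening statistics** — volume-normalised specific fluorescence,
  per-group modified Z-score outlier filtering (|Z| > 3.5,
  Iglewicz–Hoaglin fallback), relative fluorescence in % of the in-plate
  control, pooled-variance Student's t-tests with the `**` (p ≤ 0.05) /
  `***` (p ≤ 0.005) star convention, and titer/WCW yield fold-changes.
* **Synthetic data** — seeded generators for PWM sets, fixture promoters
  (with the catalogued variants' reference alleles pinned and optional
  planted motifs) and planted-effect screening datasets with separate
  truth metadata.

See `vignettes/promoter-engineering.Rmd` for the models, parameter
rationale and known limitations.

## Worked example

Scan a synthetic promoter carrying a near-consensus CSRE (one mismatch),
find the single substitution that cleanly restores it, and screen planted
expression effects:

```r
library(promforge)

pwms <- make_pwm_set(seed = 101, widths = 9, information_levels = 0.95)
prom <- make_fixture_promoter(seed = 202,
  plantings = list(list(pwm = pwms[["F$CSRE"]], position = -330,
                        mismatches = 1, mismatch_offsets = 4)))

map <- position_effect_map(prom, pwms, threshold = 0.9)
select_clean_mutations(map, "F$CSRE", mode = "gain")
#>   position ref alt families_gained families_lost n_hits_gained n_hits_lost
#> 1     -327   C   G          F$CSRE                           1           0
```

The only substitution that gains a CSRE site and nothing else is
`-327C>G` — exactly the planted mismatch position — mirroring how a
reverse-engineered point mutation is chosen so that it alters one binding
site without collateral changes.

```r
ds <- make_screening_dataset(seed = 303,
  effects = list(planted_effect("MutB_like",  150, n_clones = 7),
                 planted_effect("MutBP_like", 250, n_clones = 7),
                 planted_effect("MutS_like",   25, n_clones = 7)))
screen_table(ds$records, control_name = "control")
#>   variant_name condition   mean_rf n_used n_outliers_removed      p_value significance
#> 1    MutB_like  inducing 162.62402      5                  2 1.425527e-08          ***
#> 2   MutBP_like  inducing 250.91755      7                  0 6.681135e-06          ***
#> 3    MutS_like  inducing  26.15781      7                  0 1.181471e-11          ***
```

`mean_rf` is each variant's mean relative fluorescence in percent of the
in-plate control (100% = control level), after volume normalisation and
robust outlier removal; the planted 150%/250%/25% effects are recovered
and all three are significant at the `***` level.

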