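# ramansip

Single-cell Raman stable-isotope-probing (Raman-SIP) analysis for
identifying CO₂-fixing bacteria, with tetranucleotide binning of the
contigs recovered from sorted cells.

## The problem

Carotenoid-containing marine bacteria that fix ¹³C-labeled bicarbonate
incorporate the heavy isotope into their carotenoids, which shifts the
carotenoid resonance Raman bands of a single cell to lower wavenumber
(a red shift). The two diagnostic bands are

- **ν1** — in-phase C=C stretch, 1522 cm⁻¹ in ¹²C cells, moving to
  ~1502 cm⁻¹ at full labeling;
- **ν2** — C–C polyene stretch, 1158 cm⁻¹ moving to ~1145 cm⁻¹.

A cell with ¹³C fraction *f* displaces each band linearly between its
endpoints, `center(f) = center12 − f·(center12 − center13)`, so an
observed center inverts to `f̂ = (center12 − center)/(center12 −
center13)`. Cells are flagged as actively CO₂-fixing — and therefore
worth sorting for single-cell genomics — only when **both** ν1 and ν2
show significant red shifts against the ¹²C control distribution:
per band the threshold is `max(3·σ_control, 4 cm⁻¹)`. The package
implements this pipeline end to end:

1. **synthetic data** — carotenoid spectra (Lorentzian bands +
   fluorescence baseline + noise + cosmic spikes), labeled populations,
   saturating labeling time courses with day-1 heterogeneity, mock
   communities, and multi-genome contig sets with prescribed GC;
2. **preprocessing** — despiking (rolling modified z-score), asymmetric
   least squares baseline removal, Savitzky–Golay smoothing,
   normalization, resampling;
3. **band analysis** — carotenoid detection, Lorentzian band-center
   fits, shifts vs. a ¹²C reference, the ν1 intensity-ratio statistic,
   mean±sd spectra, shift histograms;
4. **classification** — the simultaneous two-band sorting decision;
5. **time course** — per-day summaries, per-cell f̂, steady-state
   detection;
6. **contig binning** — strict >2,000 bp filter, canonical 4-mer
   frequencies (136 features), PCA/t-SNE embedding, density-based
   binning with per-bin GC and purity, and k-mer containment between
   assemblies.

## Worked example

```r
library(ramansip)

# 45 half-labeled cells (f = 0.5, the day-1 condition) and a 12C control
cells <- preprocess_cells(simulate_population(45, labeled_fraction = 1,
                                              f_dist = 0.5, seed = 7))
ctrl  <- preprocess_cells(simulate_population(45, labeled_fraction = 0,
                                              seed = 3))
ref <- build_reference(ctrl)
ref
#> <sip_reference> n = 45 controls | v1: 1522.02 +/- 0.15 | v2: 1157.99 +/- 0.22 cm^-1

summary(sort_run(cells, ref))
#> Sorting run summary
#>   positive: 45  negative: 0  not_carotenoid: 0
#>   positive rate: 1.000
#>   mean shifts among positives: v1 10.01, v2 6.54 cm^-1

summarize_day(analyze_bands(cells, reference = ref), ref, day = 1)
#>   n_cells mean_v1_shift sd_v1_shift mean_v2_shift mean_f_hat
#>        45        10.009       0.121          6.54      0.502
```

The half-labeled population lands at the day-1 positions (ν1 shift ≈ 10,
ν2 shift ≈ 7 cm⁻¹; mean f̂ ≈ 0.5) and every cell passes the two-band
criterion, while the control has zero positives. The full chain —
time-course simulation, steady-state detection and contig binning — runs
with one call:

```r
res <- run_pipeline(pipeline_config(list(seed = 5)))
res$steady_state_hours   # 48
attr(res$bins, "purity") # 1
```

A thin command-line wrapper over the same functions is included at
`inst/cli/ramansip.R` (subcommands `simulate-spectra`,
`simulate-contigs`, `preprocess`, `analyze`, `classify`, `timecourse`,
`bin`, `run`).

## Methods

See `vignettes/raman-sip-workflow.Rmd` for the underlying models, the
parameter choices and their rationale, numerical details, and known
limitations.
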