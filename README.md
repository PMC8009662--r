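# stomapolar

Quantitative tools for studying **asymmetric cell divisions in the
Arabidopsis stomatal lineage** from fluorescence microscopy, and for linking
the division balance to tissue composition.

In the stomatal lineage, a protodermal precursor divides asymmetrically
(ACD) into a meristemoid and a stomatal lineage ground cell (SLGC); the
meristemoid self-renews through amplifying ACDs or differentiates into a
guard mother cell (GMC), whose symmetric division (SCD) makes the guard-cell
pair of a stoma. Polarity proteins such as BRXL2 mark ACDs with a cortical
crescent and SCDs with depolarized signal, so cortical polarity is a readout
of the SCD/ACD balance — which in turn sets the stomatal index
(SI = stomata / all epidermal cells) and the epidermal cell number.

The package provides, end to end:

* **Cortical polarity profiling** — trace cell outlines from label masks,
  sample the cortical intensity in 63 equal arc-length portions, and
  compute the polarity index
  `BPI = #(portions ≥ half of the per-cell maximum) / 63`
  (1 = fully depolarized; 1/63 = maximally polarized), with the standard
  10-brightest-cells selection rule.
* **Crescent peak fitting** — bounded least-squares fit of
  `I(θ) = b + A · wrappedGaussian(θ − μ, σ)`; *peak height* `A` and
  *crescent size* `FWHM/2π = 2σ√(2 ln 2)/2π`.
* **Post-division persistence** — normalized amplitude curves `A(t)/A(0)`
  and the time at which the inherited crescent is first no longer
  detectable, with a reproducible three-part detectability rule and
  censoring at the last frame.
* **Lineage analysis** — validation of lineage-tracing records,
  division-type classification (entry / amplifying / spacing / GMC SCD)
  from parent state and polarity, division fractions, meristemoid
  amplification histograms, stomatal index and cell-count trajectories.
* **A branching simulator** — per-round Bernoulli decisions for
  amplification and spacing, with the analytic oracle
  `SI → 1 / (E[rounds] + 2)` in the spacing-free regime, scenario presets,
  and parameter sweeps.
* **Ground-truthed synthetic data** — two-channel cell images, decaying
  time series and labeled lineage records, so the whole pipeline runs and
  is tested with no external data.

## Worked example

Render a synthetic polarized cell (peak height 90 AU over a 10 AU cortical
baseline, crescent width 0.3 rad, 5 AU noise), trace it, and measure it:

```r
library(stomapolar)

p  <- synth_cell_params(amplitude = 90, baseline = 10, sigma = 0.3,
                        center = pi / 2, noise_sd = 5, seed = 1)
r  <- render_cell_image(p)
ol <- trace_outline(r$mask, 1L)
ol
#> <cell_outline> cell 1 | 152 vertices | perimeter 120.1 px | area 1099.5 px^2

rec <- polarity_record(sample_profile(r$image, ol))
rec
#> <polarity_record> cell 1 t = 0 | BPI 0.095 | crescent 0.111 | peak height 89.29 AU
rec$fit
#> <peak_fit> b = 10.403 | A = 89.29 | mu = 1.574 rad | sigma = 0.296 rad | rmse = 1.5217
```

The cell reads out as strongly polarized: 6 of 63 portions (BPI 0.095) sit
at or above half the maximum, the fitted crescent occupies 11.1% of the
circumference, and the fit recovers the generator's parameters (A = 89.3 vs
90 true, σ = 0.296 vs 0.3, μ = 1.574 vs π/2) from noisy pixels; the
generator's ground truth lists the true above-half-max arc as 9.7% of the
periphery. A depolarized cell (`amplitude = 0`) measures BPI = 1 exactly.

Link the division balance to tissue composition with the simulator:

```r
sweep_simulation(p_amp = c(0, 0.25, 0.5, 0.75), n_founders = 50000L, seed = 1)
#>   p_amp stomatal_index expected_si total_cells
#> 1  0.00         0.5000      0.5000      150000
#> 2  0.25         0.4294      0.4286      166447
#> 3  0.50         0.3372      0.3368      198296
#> 4  0.75         0.2330      0.2332      264554
```

Raising the per-round amplifying-ACD probability lowers the stomatal index
and raises the epidermal cell number — the tissue-level signature of the
ACD/SCD balance — and the simulated SI tracks the analytic
`1/(E[n]+2)` oracle to three decimals.

The full synthetic pipeline (measure → persistence → lineage summary →
simulator comparison, with a seed-and-hash manifest) runs with:

```r
run_pipeline(pipeline_config(out_dir = "demo_run", seed = 1))
```

or from a shell via the thin CLI: `Rscript inst/scripts/stomapolar run
--out demo_run --seed 1`.

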