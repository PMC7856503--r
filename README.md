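# epidqa — EPID-based daily linac quality assurance

`epidqa` turns the portal imager already mounted on a medical linear
accelerator into a daily QA instrument. From two quick portal images — a
10 cm × 10 cm open field and the same field through the 60° wedge, 100 MU
each — it computes the daily TG-142-style parameter set and compares it to a
stored benchmark:

| parameter | definition |
|---|---|
| output constancy | µ = mean signal of a 10 mm × 10 mm ROI at the field centre |
| beam quality | wedge factor W = µ_wedge / µ_open (energy surrogate) |
| flatness | F = (Dmax − Dmin)/Dcenter × 100 % over the central 80 % of the field |
| symmetry | S = max \|D(p) − D(2c − p)\| / Dcenter × 100 % |
| field size / centre | from sub-pixel penumbral inflection points (derivative extrema of the X/Y profiles), centre = midpoints of opposing edges |

It is vendor-independent: readers are included for iViewGT-style 16-bit
TIFF exports (geometry supplied via a machine profile, since TIFF carries
none) and DICOM RT Image exports (self-describing). Flattened and
flattening-filter-free (FFF) beams are both supported; flatness is not
reported for FFF beams, everything else is computed identically. A synthetic
beam generator with exact ground truth (FF, FFF, wedged; logistic penumbra;
seeded noise) makes every stage testable without beam time.

Intended users: clinical medical physicists automating morning checks, and
anyone validating EPID-based QA analysis code.

## Worked example

```r
library(epidqa)

# a daily session: open + wedge acquisitions (synthetic here, with the
# study-condition geometry: 1024x1024 panel, 0.25 mm/px at isocenter)
open_img  <- generate_portal_image(beam_spec(seed = 7))$image
wedge_img <- generate_portal_image(beam_spec(wedge = list(), seed = 8))$image

m <- analyze_acquisition(open_img, wedge_img)
print(m)
#> <field_metrics> beam 6MV
#>   mu_open 1e+04, W 0.5503
#>   flatness  X 0.010 %  Y 0.010 %
#>   symmetry  X 0.000 %  Y 0.000 %
#>   size 100.00 x 100.00 mm, centre (0.000, 0.000) mm
```

µ is the central-ROI mean (10⁴ here: 100 MU × gain 100), W = 0.5503 is the
wedge transmission averaged over the ROI, flatness/symmetry are essentially
zero for the ideal flattened beam, and size/centre land on the 100 mm /
(0, 0) mm ground truth to sub-pixel precision.

Freeze a benchmark, then evaluate a later session (here with a +1.2 % output
drift applied to both images):

```r
bl <- create_baseline(m, "synergy-1", date = as.Date("2026-09-01"))

drift_open  <- open_img;  drift_open$pixels  <- drift_open$pixels  * 1.012
drift_wedge <- wedge_img; drift_wedge$pixels <- drift_wedge$pixels * 1.012
res <- evaluate_daily(analyze_acquisition(drift_open, drift_wedge), bl,
                      run_date = as.Date("2026-09-28"))
print(res)
#> <qa_result> machine synergy-1, run 2026-09-28
#>    parameter     measured baseline deviation unit                 tolerance status
#>  1 output         1.01e+4  10000      1.20   % of baseline - 100        2.5 pass
#>  2 beam_quality   5.50e-1  0.550      0      % of baseline - 100        2   pass
#>  ...
#> => PASS
```

The gain drift shows up only in `output` (+1.20 %, inside the ±2.5 %
tolerance); W, flatness, symmetry, size and centre are invariant to a common
gain, as they should be. `qa_exit_code(res)` gives the 0/1 status used by
the command-line front end (`inst/cli/dqrt.R`: `dqrt baseline`, `dqrt
daily`, `dqrt experiment <kind>`, `dqrt simulate`; exit 0 = pass, 1 = QA
fail, 2 = error) so a shell script can gate the morning treatment start.

Validation experiments (MU linearity, ROI shift sensitivity, adjacent
field-size steps, collimator-pair radiation centre) are available as
`cmd_experiment()` or directly via `generate_linearity_series()`,
`shift_sensitivity()`, `generate_field_size_series()` and
`collimator_pair_center()`. See the methods vignette
(`vignettes/epid-daily-qa.Rmd`) for the model, conventions and numerical
choices.

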