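# structgamma

Structure-based gamma evaluation for patient-specific QA (PSQA) of
radiotherapy dose distributions.

## The problem

Gamma evaluation is the standard way to compare two 3D dose
distributions — for example a treatment planning system (TPS) dose against
an independent Monte Carlo recalculation. At each reference point
**r**<sub>r</sub> it combines the dose difference and the
distance-to-agreement (DTA) into a single index

γ(**r**<sub>r</sub>) = min over **r**<sub>e</sub> of
√( |**r**<sub>e</sub> − **r**<sub>r</sub>|² / δd²
  + (D<sub>e</sub>(**r**<sub>e</sub>) − D<sub>r</sub>(**r**<sub>r</sub>))² / ΔD² ),

with δd the DTA criterion (mm) and ΔD the dose-difference criterion in Gy.
Conventionally ΔD is a percentage of either the **global maximum** dose or
the **local** dose. Both choices have known clinical blind spots: global
normalisation can hide errors that are small relative to the prescription
dose yet large relative to an organ-at-risk (OAR) tolerance; local
normalisation over-penalises harmless discrepancies at low-dose points.

`structgamma` implements a structure-based alternative: each contoured
structure is rasterised onto the dose grid, both dose volumes are masked to
that structure (dose outside set to zero), and the gamma index is computed
per structure with a normalisation dose chosen for that structure:

| mode      | ΔD = δD% × …                                           |
|-----------|--------------------------------------------------------|
| `global`  | maximum of the unmasked reference dose volume          |
| `local`   | the reference dose at each evaluated point             |
| `quantec` | the organ's QUANTEC point-dose (dmax) tolerance        |
| `ro`      | the clinician-specified tolerance for this patient     |

Voxels outside the structure never enter the statistics, so each
structure's pass rate (% of voxels with |γ| ≤ 1 at 2%/2 mm by default)
reflects agreement *in that organ*, judged against *that organ's* dose
tolerance. Gamma values are signed by the local dose difference (positive
where the evaluated dose is hotter, negative where colder), which is what
the red/blue map rendering shows.

The package includes:

* DICOM RT Dose / RT Structure Set readers and writers (plus minimal CT
  slice reading for map backgrounds),
* contour-to-voxel rasterisation (even-odd point-in-polygon on voxel
  centers), structure-name standardisation and planning-structure
  filtering (ring / couch / bolus / artifact),
* the shipped QUANTEC tolerance table (17 organs, conservative values) and
  a plain-text format for clinician (RO) tolerances with the
  PTV-gets-the-prescription-dose rule,
* a C++ gamma engine with an exhaustive-search oracle for verification,
* a synthetic phantom generator with analytically known gamma behaviour,
* tidy results (`tidy()`, `glance()`), aggregate summaries, ggplot2 gamma
  maps, CSV reports, and a `structgamma` command-line tool.

## Worked example

A synthetic pelvis-like case: a Gaussian target dose (peak 50.4 Gy) with a
uniform +1.2 Gy error in the evaluated dose, a "Bladder" sphere sitting on
the dose fall-off and a "Rectum" sphere on the target:

```r
library(structgamma)

spec <- phantom_spec(
  grid_shape = c(20, 14, 10), spacing = 2,
  field = list(type = "gaussian_target", center = c(8, 13, 9),
               width = 6, peak = 50.4, background = 2),
  structures = list(
    list(name = "Bladder", shape = "sphere", center = c(28, 13, 9), radius = 8),
    list(name = "Rectum",  shape = "sphere", center = c(8, 13, 9),  radius = 6)),
  perturbation = list(type = "offset", gy = 1.2), seed = 1)
ph <- make_phantom(spec)

ro <- tolerance_table(tibble::tibble(name = c("BLADDER", "RECTUM"),
                                     dose_gy = c(40, 50)), source = "RO")
sg <- structural_gamma(ph$reference, ph$evaluated, ph$structures,
                       tables = list(quantec_table(), ro))
tidy(sg)
#> # A tibble: 8 × 7
#>   structure canonical mode    norm_dose evaluated_voxels pass_rate skip_reason
#>   <chr>     <chr>     <chr>       <dbl>            <int>     <dbl> <chr>
#> 1 Bladder   BLADDER   global       49.1              268      74.6 <NA>
#> 2 Bladder   BLADDER   local        NA                268      65.7 <NA>
#> 3 Bladder   BLADDER   quantec      65                268     100   <NA>
#> 4 Bladder   BLADDER   ro           40                268      70.1 <NA>
#> 5 Rectum    RECTUM    global       49.1              112     100   <NA>
#> 6 Rectum    RECTUM    local        NA                112     100   <NA>
#> 7 Rectum    RECTUM    quantec      50                112     100   <NA>
#> 8 Rectum    RECTUM    ro           50                112     100   <NA>
```

Reading the bladder rows: against the global maximum (49.1 Gy) a quarter of
the bladder fails; the QUANTEC tolerance (65 Gy, *above* the global
maximum) is more forgiving and the structure passes entirely; the stricter
per-patient RO constraint of 40 Gy pulls the pass rate back down. That
divergence — identical doses, different clinical verdicts per tolerance —
is the point of the method. Aggregate across structures with

```r
summarize_gamma(tidy(sg))
```

which reports, per mode, the mean and population SD of the pass rates and
how many structures score below their own global-gamma baseline. Render a
signed gamma map for one axial slice with

```r
plot_gamma_map(sg$results$result[[1]], slice_index = 5)
```

(white = agreement, red = evaluated hotter, blue = colder, saturating at
|γ| = 2; voxels outside the structure are transparent).

The same workflow runs from the shell against DICOM exports:

```sh
structgamma compare --reference tps_dose.dcm --evaluated mc_dose.dcm \
    --structures rtstruct.dcm --ro-tolerances patient.tol \
    --prescription 50.4 --out report/
structgamma phantom --spec phantom.json --out phantom/
structgamma summarize --in report/structures.csv --out summary/
```

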