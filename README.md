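# crabtherm

Estimation of behavioral thermoregulation parameters for burrowing
intertidal ectotherms — fiddler crabs foraging on hot low-tide sediment —
from three simple field temperatures per animal: body temperature `Tb`,
surface temperature `S` at the capture spot, and the temperature `B` at the
bottom of a nearby reference burrow. It is written for thermal ecologists
who have such records (or want to simulate them) and need the full analysis
as a tested, reproducible pipeline rather than a spreadsheet.

## The model

Putting each crab on the *thermoregulation axes* — cooling capacity
`x = B − S` against thermoregulation capacity `y = Tb − S` — burrow-using
crabs fall on a line

```
y = E_B · x + b
```

* `E_B` — **burrow use efficiency**: 0 = burrow ignored, 1 = body tracks the
  burrow completely.
* `b = T̂e − S` — **no-refuge offset**: how much warmer than the surface the
  body runs when the burrow offers no refuge (`B = S`); expected positive.

A second regression, `Tb − S = m·S + c` (with `m < 0`: the capacity shrinks
as the surface heats), yields the **onset of thermoregulation**: the surface
temperature where the line meets the no-refuge level, `S* = (b − c)/m`, and
the onset body temperature

```
T_reg = S* + b        (upper bound: the x-intercept −c/m)
```

The same line implies the body warms `1 + m` °C per 1 °C of surface warming.

Around these estimators the package re-implements, from first principles,
the supporting statistics — OLS with standard errors, sequential (Type-I)
ANCOVA with the homogeneity-of-slopes interaction test, Kruskal–Wallis with
Dunn/Bonferroni post hoc comparisons, and Euclidean distance-matrix
PERMANOVA with permutation p-values — plus a synthetic field-data generator
whose defaults reproduce the study conditions (441 crabs in four sex-by-size
classes over four months), so every stage is testable offline.

## Worked example

```r
library(crabtherm)

report <- run_pipeline(synthetic_config(seed = 42), seed = 42, n_perm = 199)
print(report)
```

```
Thermoregulation pipeline report
  input: synthetic; 441 records analyzed (377 with burrow readings)
  rows read 441: accepted 441 (flagged 64), rejected 0

Per-group estimates:
        group   n n_axes  e_b e_b_se b_offset b_offset_se     m    c
 small_female  70     58 0.49  0.019     1.87       0.136 -0.32 8.46
 large_female 119    105 0.44  0.022     1.44       0.140 -0.30 7.77
   small_male 127    113 0.33  0.015     0.92       0.099 -0.23 5.86
   large_male 125    101 0.31  0.019     0.82       0.121 -0.20 5.16
 r_squared_s r_squared_axes tb_sensitivity surface_at_onset t_reg t_reg_upper
        0.83           0.92           0.68            20.67 22.54       26.54
        0.72           0.80           0.70            21.42 22.86       26.28
        0.78           0.81           0.77            21.64 22.56       25.67
        0.71           0.73           0.80            21.19 22.02       25.23
 t_reg_se
     0.66
     0.63
     0.54
     0.71
```

Reading the first row: of 70 small females, 58 had a burrow reading; they
harvested about half of the burrow's cooling capacity (`e_b` = 0.49 ± 0.019)
and ran 1.87 °C warmer than the surface when the burrow offered no refuge.
Their capacity declined 0.32 °C per 1 °C of surface warming (so bodies
warmed 0.68 °C/°C), and the fitted line met the no-refuge level at a surface
temperature of 20.67 °C, i.e. an onset body temperature of 22.54 °C
(upper-bound estimate 26.54 °C). Note the onset estimates sit below the
generating onsets (≈24.5 °C): a single line fitted across the full season
absorbs the flat below-onset segment and is attenuated — see the vignette
(`vignettes/thermoregulation-analysis.Rmd`) for why, and for the
above-onset-conditioned recovery analysis in which the estimators recover
the generating parameters.

The report also carries the monthly Kruskal–Wallis/Dunn comparisons, per-sex
ANCOVA and PERMANOVA tables (seeds recorded), and small-vs-large contrasts:

```r
print(report$contrasts$female)
#> Group contrasts (a - b):
#>  quantity difference    se
#>       e_b      0.052 0.029
#>  b_offset      0.435 0.195
#>     t_reg     -0.316 0.909

write_report(report, "out/")   # estimates.tsv, tests.json, report.json, figures/
```

A thin CLI wrapper ships in `inst/exec/crabtherm`:

```sh
Rscript inst/exec/crabtherm simulate --seed 42 --out-dir out
Rscript inst/exec/crabtherm report --config synthetic --seed 42 --out-dir out
Rscript inst/exec/crabtherm report --input field.csv --n-perm 999 --out-dir out
```

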