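# skelchron

Skeletochronological back-calculation and validation for sea turtles.

## The problem

Somatic growth rates of wild sea turtles are usually obtained from
mark–recapture studies that take years to yield data. Skeletochronology
offers a faster route: humerus cross-sections retain annual growth marks
(LAGs, lines of arrested growth), and the diameter of each LAG records how
large the bone — and hence the turtle — was when the mark was deposited.
Before LAG-derived growth histories can be trusted for a population, two
things must be established: that carapace lengths back-calculated from LAG
diameters agree with lengths actually measured on the same animals, and
what time of year LAGs are deposited (which determines the calendar year
each LAG is assigned).

`skelchron` implements that validation workflow for Hawaiian green turtles
(*Chelonia mydas*): turtles measured and tagged in the field, injected with
oxytetracycline (OTC, which leaves a dated fluorescent line in bone), and
later recovered dead, so that every back-calculated length can be checked
against a field measurement.

## The model

Back-calculation uses the body proportional hypothesis (BPH) form

$$L = \frac{L_{op} + b\,(D - D_{op})^{c}}{L_{op} + b\,(D_{final} - D_{op})^{c}} \; L_{final}$$

where $L$ is the estimated straightline carapace length (SCL, cm) at the
time a mark of diameter $D$ (mm) was deposited, $L_{op}$ = 5.1 cm and
$D_{op}$ = 2.6 mm are hatchling SCL and humerus diameter, $b$ = 3.127 and
$c$ = 0.928 are the allometric constants fitted for Hawaiian green turtles,
and $L_{final}$, $D_{final}$ anchor the equation at dead recovery. The
equation is exact at the section edge ($L(D_{final}) = L_{final}$) and
scales each individual's whole trajectory by its personal deviation from
the mean allometry.

Around the equation the package provides calendar-year assignment of LAGs
(spring deposition window, edge-growth rule for the outermost LAG,
double-LAG collapsing), an exact Wilcoxon signed-rank test (zeros dropped,
midranks for ties, $2^N$-enumeration p-values), OTC-based inference of the
seasonal deposition window, and a forward simulator of bone and somatic
growth whose ground truth makes every stage testable.

## Worked example

```r
library(skelchron)
fix <- hawaii_greens()            # bundled ten-turtle validation dataset
fit <- skelchron(fix$turtles, fix$bones)
fit
```

```
Skeletochronological back-calculation validation (10 turtles)

    ID Stranded SCL.strand   Tagged SCL.tag SCL.est Year Diff
  CM-1 08-02-99       58.5 23-04-97    55.1    55.1 1997  0.0
  CM-4 10-12-99       69.6 21-12-98    69.4    69.6 1999 -0.2
  CM-6 09-05-00       56.3 05-10-99    55.9    56.3 2000 -0.4
  CM-8 20-02-01       70.0 24-04-00    70.6    70.0 2000  0.6
  CM-9 23-04-01       44.5 14-04-00    44.7    44.3 2000  0.4
 CM-10 11-12-01       85.5 25-04-00    83.8    84.6 2000 -0.8
 CM-11 28-03-02       57.2 08-07-97    54.8    54.8 1997  0.0
 CM-12 17-10-02       60.2 12-05-98    57.4    57.7 1998 -0.3
 CM-13 19-10-03       69.5 17-06-94    45.5   47.0* 1994 -1.5
 CM-14 14-07-04       53.7 16-05-00    51.0    51.0 2000  0.0
  * SCL back-calculated from the OTC-mark diameter (tagging-era LAG resorbed)

Mean absolute difference: 0.4 cm (0.3 cm excluding OTC-fallback estimates)
Wilcoxon signed-rank test (exact): T = 8.5, N = 7, two-sided p = 0.3906
Measured SCL at tagging:  44.7-83.8 cm (mean +/- SD = 58.8 +/- 12.3)
Estimated SCL at tagging: 44.3-84.6 cm (mean +/- SD = 59.0 +/- 12.3)
```

Each row compares the SCL measured at tagging with the SCL back-calculated
from the LAG deposited closest to the tagging date. The exact Wilcoxon
test finds no significant difference (p = 0.39), the mean absolute
disagreement is 0.4 cm, and the estimates track the measured size range
almost exactly — which is the evidence that LAG-derived growth histories
are reliable for this population. `summary(fit)` additionally prints the
OTC timing table (per-turtle relation of LAG deposition to the dated OTC
mark) and the inferred annual deposition window — after 21 December and by
mid-May, i.e. spring deposition. `residuals(fit)` returns the per-turtle
differences; `fit$growth` holds per-turtle back-calculated growth
histories and annual growth rates.

A command-line wrapper with `backcalc`, `validate`, `timing`, `report`,
`simulate` and `reproduce` subcommands ships at
`inst/cli/skelchron.R`.

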