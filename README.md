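# mrmiso

Positional ¹³C-isotopomer analysis of glutamate and aspartate from
LC-MS/MS multiple-reaction-monitoring (MRM) peak areas.

An n-carbon molecule has 2ⁿ positional ¹³C isotopomers (glutamate 32,
aspartate 16), written as bit strings with C1 leftmost — glutamate `11000`
is labeled at C1 and C2. On a triple quadrupole, each precursor/product
ion pair (M+i, m+j) counts how many labels a molecule carries in total (i)
and inside the retained fragment carbons (j). mrmiso builds the linear map
from isotopomer fractions to ion-pair intensity fractions out of declared
transition families and fragment carbon sets, augments it analytically for
naturally occurring heavy isotopes (²H, ¹³C, ¹⁵N, ¹⁷O, ¹⁸O), and inverts
it by bounded nonnegative least squares — recovering the **complete
positional distribution**, not just mass isotopologues.

The package also quantifies what the ion pairs can and cannot determine
(simulation-based identifiability surveys), computes closed-form TCA-cycle
readouts (two F_C3 estimators, anaplerosis, NMR multiplet aggregation,
pyruvate-carboxylase / fumarate-hydratase / CO₂-recycling diagnostics),
and ships a small TCA labeling-topology simulator for generating
ground-truth test data.

## Worked example

Forward-model a four-component standard (50% unlabeled, 5% `11000`, 15%
`00110`, 30% `11111`) through the natural-abundance-augmented matrix with
2% multiplicative noise, then fit it back:

```r
library(mrmiso)
glu <- glutamate()
A   <- mapping_matrix(glu, na_correct = TRUE)

truth <- setNames(numeric(32), labeling_strings(glu))
truth[c("00000", "11000", "00110", "11111")] <- c(0.50, 0.05, 0.15, 0.30)

set.seed(1)
tab <- simulate_mrm(truth, A, noise = noise_model(rsd = 0.02))
head(tab, 4)
#>   sample_id  Q1 Q3      area
#> 1      sim1 146 41 460760.77
#> 2      sim1 147 41  18133.65
#> 3      sim1 147 42  10284.22
#> 4      sim1 148 41  52455.38

fit <- isotopomer_fit(tab, glu)
summary(fit, min_fraction = 0.01)
#> <isotopomer_fit> glutamate, 1 sample(s), natural-abundance-corrected matrix, solver "hybrid"
#> residual norms:
#>    sim1
#> 0.01543
#>
#> sim1 (fractions >= 0.01):
#>  00000  11111  00110  11000
#> 0.4994 0.2998 0.1495 0.0496
```

All four components come back within half a percentage point despite the
noise. `isotopomer_fit()` returns a classed object with the usual
modelling verbs (`coef`, `fitted`, `residuals`, `predict`, `plot`,
`simulate`); `read_intensity_csv()` / `write_fractions_csv()` handle the
file formats.

TCA readouts on a simulated steady state (80% [1,2-¹³C]acetyl-CoA, 10%
pyruvate-carboxylase inflow):

```r
sim <- run_tca(tca_scenario(accoa = c("11" = 0.8, "00" = 0.2),
                            pc_fraction = 0.1, n_turns = 8))
round(tca_readout(sim$glutamate, sim$aspartate), 4)
#>           fc3_eq1           fc3_eq2     anaplerosis_y          pc_index
#>            0.8000            0.8000           -0.0403            0.1000
#>      fh_asymmetry m1_outer_fraction   glu_pc_contrast
#>            0.0000            0.5000            0.0400
```

Both F_C3 estimators recover the 0.8 input; the PC index reads the 10%
inflow; fumarate scrambling leaves no asymmetry.

Identifiability survey (noiseless forward–invert over random fraction
vectors):

```r
run_survey(glu, n_trials = 500, seed = 20230822)
#> <isotopomer_survey> glutamate: 500 trials, sampler uniform_simplex, constraint none, seed 20230822
#> identifiable: 18 of 32 (max abs error 5.55e-17)
#> under-determined: 14 (95% bound up to 0.0374)
#> ...
```

18 isotopomers recover at machine precision; the remaining 14 carry 95%
error bounds up to ~±4%, which drop below 0.5% under the acetyl-CoA
tracer constraint (`constraint = "acetylcoa"`).

## Command line

A thin CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","mrmiso.R",package="mrmiso"))')
Rscript $CLI matrix --molecule glutamate --na --out matrix.csv
Rscript $CLI simulate --accoa 11=0.8,00=0.2 --turns 10 --out sim
Rscript $CLI deconvolve --in sim_intensities.csv --out fractions.csv
Rscript $CLI metrics --glu fractions.csv --out readouts.csv
Rscript $CLI survey --molecule aspartate --sampler beta_stick --out survey.csv
```

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "mrmiso", load_package = "installed")'
```

`tests/testthat/test-acceptance.R` holds one block per validation
criterion; the remaining files are per-module unit and property tests,
including independent SVD and combinatorial oracles for the matrix and
solver. A methods write-up lives in `vignettes/mrmiso-methods.Rmd`.
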