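# trzsar

Structure–activity analysis of triazolopeptide inhibitors of the
neuropilin-1 (NRP-1) / VEGF<sub>165</sub> interaction.

Branched peptidomimetics of the form *arm–linker–Arg* — e.g.
`Lys(Har)-GlyΨ[Trl]GlyΨ[Trl]Arg`, a lysine whose side chain carries a
homoarginine, joined through two glycyl-1,2,3-triazole units to a C-terminal
arginine — replace proteolysis-prone linker amides with 1,4-disubstituted
1,2,3-triazole rings. This package implements the computational analysis of
a 23-compound panel of such molecules, for medicinal/computational chemists
who want the pipeline reproducible end to end:

* **Notation → structure.** A parser for the compact sequence notation and
  an assembler that builds each compound's heavy-atom molecular graph from
  the junction chemistry of the solid-phase route (diazotransfer + click
  reaction: the azide nitrogen becomes triazole ring N1 and *is* the next
  residue's backbone nitrogen). Elemental formulas are computed by two
  independent routes (residue bookkeeping and graph summation) that must
  agree, and monoisotopic m/z values for [M + zH]<sup>z+</sup> ions are
  validated against the panel's printed characterisation table.
* **Descriptors.** The guanidine-to-guanidine topological distance
  *dis*<sub>N-C</sub> (BFS over the heavy-atom graph; the triazole ring is
  traversed on its nitrogen side by default), its min–max normalisation over
  the panel, and the binary indicators *2Trl*<sub>C-N</sub> (triazole at the
  second backbone linkage from the C side) and *am*<sub>2N</sub> (free
  alpha-amine by the second linkage from the N side).
* **Models.** Classical OLS with normal-equation standard errors:

  *inh* = β₀ + β₁·*dis*<sub>N-C,norm</sub> + β₂·*am*<sub>2N</sub> + β₃·*2Trl*<sub>C-N</sub>,

  reproducing the published single-variable model (R² = 0.54) and
  three-variable model (R² = 0.63, coefficients 8.6/20.9/8.7/8.6), plus an
  exhaustive best-subset search ranked by adjusted R².
* **Bioassay arithmetic.** Competitive-ELISA percent inhibition
  `100 − (S − NS)·100/(Pmax − NS)`, replicate summaries, log-logistic
  IC₅₀ fitting, and exponential stability-decay fits with censoring for
  half-lives beyond the observation window.
* **Synthetic data.** Seeded generators for panels, activities, plate
  signals, dose–response curves and decay series, so every stage runs and is
  testable offline.

## Worked example

```r
library(trzsar)

seq <- parse_sequence("Lys(Har)-GlyΨ[Trl]GlyΨ[Trl]Arg")  # the best compound
g <- assemble_graph(seq)
formula_string(additive_formula(seq))
#> [1] "C25H46N16O4"
monoisotopic_mz(seq, z = 1)$mz_4dp
#> [1] 635.3961
dis_guanidine(g)                       # atoms between the guanidine carbons
#> [1] 30

m <- panel_models()                    # descriptors + both fits, 23 compounds
print(m$model2)
#> OLS fit, n = 23
#>              coef  se
#> (Intercept)   8.6 5.0
#> dis_N_C_norm 20.9 8.6
#> am_2N         8.7 4.5
#> Trl2_CN       8.6 4.6
#> R^2 = 0.63, adjusted R^2 = 0.57

round(ic50_micromolar(-5.076), 2)      # printed logIC50 of the best compound
#> [1] 8.39
```

The formula and m/z match the printed characterisation of the best panel
compound; the model block is the published three-variable equation at
printed precision; the antilog is the published micromolar IC₅₀.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that narrate the whole
study over the package functions and write tables under `results/`:

| script | what it does |
|---|---|
| `01_validate_masses.R` | assembles all 23 compounds, checks formulas and m/z against the printed table |
| `02_descriptors.R` | descriptor matrix under both ring conventions |
| `03_sar_models.R` | both OLS models, predictions, best-subset search |
| `04_bioassay.R` | IC₅₀ conversions; synthetic ELISA/dose–response/decay round trips |
| `05_simulation_checks.R` | generator calibration: R² targeting and SE coverage |

Run them from the repository root, e.g. `Rscript analysis/01_validate_masses.R`.

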