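---
title: "Methods: assembling triazolopeptides and modelling their activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembling triazolopeptides and modelling their activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trzsar)
```

## The problem

Branched peptidomimetic inhibitors of the neuropilin-1 (NRP-1) /
VEGF~165~ interaction follow the pharmacophore *arm–linker–anchor*: a
guanidine-bearing arm (usually homoarginine, Har, acylating the side chain of
an N-terminal lysine), a two-to-three-unit linker, and a C-terminal arginine
anchor. To resist proteolysis, linker amide bonds can be replaced by
1,4-disubstituted 1,2,3-triazole rings — the `GlyΨ[Trl]` unit of the
notation, a glycine whose C-terminal peptide bond has become a triazole.

This package rebuilds the computational side of a 23-compound panel of such
triazolopeptides: structure enumeration and mass validation, topological
descriptors, two ordinary-least-squares activity models, and the assay
arithmetic (competitive ELISA, IC~50~, plasma-stability decay). Raw assay
data were never deposited, so a seeded synthetic-data module generates every
input the analysis consumes.

## From notation to molecule

`parse_sequence()` implements the compact sequence grammar (hyphens between
tokens, `]` as an implicit separator after a triazole unit, `D-` stereo
prefixes, `Fmoc-` caps, one level of parenthesised side-chain branching).
`assemble_graph()` turns a parsed sequence into a heavy-atom graph using the
junction chemistry implied by the solid-phase route: the downstream amine is
converted to an azide on-resin (diazotransfer) and clicked onto an
Fmoc-propargylamine, so the azide nitrogen becomes ring N1, and the alkyne
contributes C4, C5 and the exocyclic CH~2~–NH. Consequences encoded as
assembly rules:

* ring N1 *is* the backbone nitrogen of the following block — a residue
  after a triazole contributes no separate backbone N–H;
* a proline cannot follow a triazole unit (its secondary amine cannot form
  the azide); the package rejects such sequences in both formula routes;
* a triazole unit can neither open a chain (its amide nitrogen must be
  acylated) nor terminate it (no carboxyl terminus).

Every molecule's composition is computed twice — by additive residue
bookkeeping (`additive_formula()`) and by summing the assembled graph
(`formula_from_graph()`) — and the two routes must agree; the test suite
checks this on the panel and on randomly generated panels. Monoisotopic
masses use lightest-isotope masses and a proton mass of 1.007276 Da;
m/z values are reported half-up at 4 decimal places, the table convention.

```{r golden}
v <- validate_panel(triazolopeptide_panel())
attr(v, "summary")
```

All 23 printed formulas reproduce; 22 of 23 printed calculated m/z values
match to 4 decimals. The exception is compound 23, whose printed calculated
value (507.3020) is arithmetically inconsistent with its *own* printed
formula C19H34N14O3: the formula's monoisotopic [M+H]^+^ is 507.3011,
which is exactly the measured value printed beside it. We treat the printed
calculated entry as a typographical error and validate against the formula.

## The distance descriptor and its ring convention

The panel-wide descriptor `dis_N_C` is the topological (bond-path) distance
between the two guanidine carbons — the Har arm's and the C-terminal
arginine's — counted as atoms strictly between the anchors. Two conventions
arise at each triazole ring, which offers a short walk (through C5, two
bonds) and a long walk (through the azide-derived nitrogens N3–N2, three
bonds):

* **backbone** (default): the ring is traversed on its nitrogen side,
  following the full backbone replacement. Implemented as a shortest path on
  the graph with ring C5 atoms removed (which leaves a tree, so paths are
  unique).
* **shortest**: the plain shortest path on the full graph.

The choice matters: compounds differ in triazole count, so the two
conventions are *not* affine-related across the panel and min–max
normalisation does not cancel the difference. Only the backbone convention
reproduces the published statistics (single-variable R² = 0.54; see below);
under the shortest-path convention that model gives R² ≈ 0.48. We therefore
adopt the backbone traversal as the default — it is also the chemically
natural reading of a "backbone elongation" by the isostere — and keep the
shortest-path variant as an explicit option. By contrast, the atoms-between
versus bond-count choice is a panel-wide constant shift, and the normalised
descriptor is provably identical under it (asserted numerically in the
tests).

## The binary indicators

`Trl2_CN` is 1 when the second backbone linkage counted from the C-terminus
is a triazole junction; linkage positions count amide and triazole junctions
alike.

`am_2N` is 1 when a free (uncapped) primary amine sits on the alpha-carbon
adjacent to the acyl (or ring) carbon of the *second* linkage counted from
the amino-terminal end, starting from the branch arm when the first residue
is branched. The verbal definition of this descriptor is ambiguous for the
Fmoc-capped arm variants; the structural rule above resolves it without
per-compound special-casing: in the capped compounds the host lysine's free
alpha-amine flanks the second linkage (value 1, the cap masks a *different*
amine), whereas in the backbone-attached-arm compound the lysine's remaining
free amine is the remote side-chain one, which is not on the alpha-carbon
(value 0). This is also the unique assignment under which the published
three-variable equation reproduces at printed precision; an
`am_2N_override` argument in `build_descriptor_matrix()` exposes the
alternative assignments.

## The two models

```{r models}
m <- panel_models()
print(m$model1)
print(m$model2)
```

Both are classical OLS fits (the original analysis was done in a
spreadsheet): coefficients solve the normal equations, standard errors are
`sqrt(sigma2 * diag((X'X)^-1))` with `sigma2 = RSS/(n - p - 1)`. With the
descriptors above, Model 1 (inhibition on the raw distance) gives R² = 0.54
and Model 2 (normalised distance + the two indicators) gives R² = 0.63 with
coefficients 8.6, 20.9, 8.7, 8.6 and standard errors 5.0, 8.6, 4.5, 4.6 — the
published values at printed precision. `best_subset()` enumerates all
subsets up to a given size and ranks them by adjusted R² (our operational
reading of the verbal "best tradeoff between quality of fit and number of
variables" criterion); raw R² is reported alongside.

## Bioassay arithmetic

Percent inhibition is `100 - (S - NS) * 100 / (Pmax - NS)`. The source
table's footnote uses one symbol for both the percent value and the maximum
binding signal; the implemented reading is the only one under which a
no-inhibition well (`S = Pmax`) gives 0%. Replicates are summarised as mean
± sample SD.

Dose–response curves are fitted as `inh(c) = 100 / (1 + 10^(h (logIC50 -
log10 c)))` by Levenberg–Marquardt nonlinear least squares, with the Hill
slope fitted (initialised at 1) or fixed to 1; the published logIC~50~ ± SE
and R² values are consistent with this standard log-logistic form, which the
source does not spell out. IC~50~ in µM is `10^(logIC50 + 6)`.

Stability series are summarised by a single-exponential fit
`f(t) = 100 exp(-k t)`, `t1/2 = ln 2 / k`. When the fitted decline over the
observation window is below a resolution threshold (default 10 percent
points) the fit is flagged censored and the half-life is reported as a lower
bound at the window end — the appropriate summary for compounds whose
half-life far exceeds the 48 h window, as the best panel members' do.

## Synthetic data: what it emulates and what it does not

The generators produce: panels drawn from the notation grammar
(arm × linker-length × triazole-placement), activities from the
three-variable linear model plus additive Gaussian noise (clipped to
[0, 100] with logging), ELISA plate signals by inverting the
percent-inhibition formula around the competitive-binding expectation,
log-logistic dose–response curves, and exponential decay series — all
bit-reproducible under a seed, every output accepted by the downstream
stage.

The default residual sigma for activity generation is not a free dial: it is
calibrated once as the Model 2 residual SD on the shipped panel
(`calibrated_activity_sigma()`, about 7.9 percent points), so synthetic
panels of the study's size reproduce the published R² on average (checked
over 500 seeds in the tests, together with ≈95% coverage of ±2 SE
intervals).

All noise is additive Gaussian — the study reports only means ± SD, so
nothing richer is inferable. The generators do not emulate plate-layout
effects, outlier structure, measurement drift, or metabolite chemistry;
passing recovery tests on synthetic data therefore demonstrates the
correctness of the fitting arithmetic, not robustness to real-data
pathologies.

## Numerical choices and degenerate inputs

* m/z rounding: half-up at 4 decimals; comparisons use |Δ| ≤ 0.00005 Da.
* Charge states are taken from the compound record (z = 2 only for the two
  Fmoc compounds), never inferred from mass.
* Min–max normalisation over a degenerate panel (max = min) is defined as 0
  and flagged; it cannot occur on the shipped panel.
* OLS refuses n ≤ p + 1 and exactly collinear designs (naming the aliased
  columns); best-subset skips such subsets with a warning.
* Dose–response fitting requires ≥ 4 distinct concentrations; decay fitting
  requires ≥ 3 time points including t = 0.
* Repeated `]` in input notation (a typographical artifact present in one
  printed sequence) is normalised by the tokenizer; an explicit hyphen after
  a triazole unit is tolerated on input, omitted on output.

Problem sizes throughout the package are those of the study itself (23
compounds, 8-point dose curves, 7-point decay series); the simulation checks
use 200–500 seeded replicates, which keeps every stage comfortably fast on a
single core.

## Known limitations

* The original study's descriptor matrix was not deposited; the
  descriptors here are reconstructed from
  their stated definitions, and their validation is indirect — through exact
  reproduction of both models' statistics. The backbone ring convention and
  the `am_2N` rule are the two reconstruction choices that matter, and both
  are documented above.
* Reference compounds outside the panel (the heptapeptide A7R and earlier
  branched pentapeptides) are not modelled; their printed values appear only
  as context.
* Wet-lab quantities (measured m/z, retention times, the measured 58.1%
  inhibition, the ~70% remaining at 48 h) are fixture metadata and are not
  recomputable; the package computes the calculated quantities and the
  statistical summaries that sit on top of measurements.
* No 3D structure, conformers, protonation states or isotope patterns beyond
  the monoisotopic peak.
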