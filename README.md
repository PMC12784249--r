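# gmisr — genetic minimal intervention sets in iMR networks

gmisr enumerates **genetic minimal intervention sets (gMIS)**: minimal
combinations of gene knock-outs (`g-`) and knock-ins (`g+`) that abolish
biomass production in integrated metabolic and signed acyclic regulatory
(iMR) network models. It is aimed at constraint-based modellers and cancer
systems biologists who want to go beyond synthetic lethality (pure
knock-out sets) and systematically recover synthetic **dosage** lethality,
tumor suppressor genes and tumor suppressor gene complexes, and then map
expression data onto the catalogue to call context-specific essential
genes and tumor suppressors.

## Method in brief

For every target reaction *k* the Boolean gene–protein–reaction rule is
extended with up to two levels of signed regulation (activators/repressors
combined as `g = a1 or ... or not r1 or ...` by default), augmented with
knock-out, knock-in and free-input machinery

&nbsp;&nbsp;&nbsp;&nbsp;*g<sub>i</sub> = (ρ<sub>i</sub> ∧ y<sub>i</sub>) ∨ u<sub>i</sub>*,

split into ON/OFF node twins by De Morgan's laws and compiled into an
irreversible artificial reaction network *S<sup>k</sup>*. Closing the
`y`<sub>iON</sub> input exchange knocks gene *i* out; closing
`u`<sub>iOFF</sub> knocks it in. An intervention set blocks the reaction
iff flux through the target output is infeasible, which by Farkas' lemma
is certified by feasibility of the dual system

&nbsp;&nbsp;&nbsp;&nbsp;*S<sup>kT</sup>u + E v − t w ≥ 0*, &nbsp; *α ≤ v ≤ M*, &nbsp; *w ≥ c/r\**.

Minimal cut sets are enumerated by exact implicit enumeration of the
binary side (pairing, mutual exclusion and no-good cuts; smallest support
first) with one strictly convex QP feasibility solve per candidate, and
checked against an independent brute-force Boolean-closure oracle. The
per-reaction sets integrate into the paired sparse matrices **F**
(interventions) and **G** (blocked reactions), from which genome-level
gMISs — minimal sets whose induced deletions drive the biomass maximum to
zero — are enumerated and classified (essential gene / SL / TSG / SDL /
TSGC). Expression data binarised HIGH/LOW then yields per-sample calls
with a Boolean adaptation-mechanism check. Details and all numerical
choices: `vignettes/gmis-methods.Rmd`.

## Worked example

The bundled example iMR model has three metabolites, four reactions and
seven genes; reaction `r3` (`g3 or g4`) is regulated (`g6 ⊣ g4`,
`g7 → g4`, `g7 ⊣ g2`):

```r
library(gmisr)
toy <- toy_imr_model()
fit <- gmis(toy$model, toy$layers)
fit
#> Genetic minimal intervention sets (gMIS)
#>   model: toy_imr (4 reactions, 5 genes, depth 1)
#>   6 gMIS blocking biomass (4 knock-out-only gMCS)
#>    1. {g1-}  [essential-gene]
#>    2. {g2-}  [essential-gene]
#>    3. {g5-}  [essential-gene]
#>    4. {g7+}  [TSG]
#>    5. {g3-, g4-}  [SL]
#>    6. {g3-, g6+, g7-}  [mixed]
```

Six gMISs block biomass; four are knock-out-only gMCSs. The other two only
exist because of regulation: knocking **in** the repressor `g7` silences
`g2` and starves the biomass precursor, and `{g3-, g6+, g7-}` blocks `r3`
by cutting `g3` directly while forcing `g4` off through its regulators.
The per-reaction enumeration of `r3` returns exactly `{g3-, g4-}` and
`{g3-, g6+, g7-}`.

Mapping an expression profile onto the catalogue (values in log2(TPM+1);
HIGH means ≥ 1):

```r
expr <- matrix(c(5, 5, 0.1, 5, 5, 0.2, 0.2), ncol = 1,
               dimnames = list(paste0("g", 1:7), "sampleA"))
predict(fit, expr)
#>    sample gene             role        gmis adaptation
#> 1 sampleA   g1        essential         g1-     passed
#> 2 sampleA   g2        essential         g2-     passed
#> 3 sampleA   g4        essential     g3-;g4-     passed
#> 4 sampleA   g5        essential         g5-     passed
#> 5 sampleA   g6 tumor-suppressor g3-;g6+;g7-     passed
#> 6 sampleA   g7 tumor-suppressor         g7+     passed
```

`g4` is called essential only because its knock-out partner `g3` is lowly
expressed; `g6` is a context-specific tumor suppressor because it is the
unique lowly expressed knock-in of `{g3-, g6+, g7-}` while both knock-out
partners are low. Each call survives the regulatory adaptation check.

A thin CLI over the same functions lives at `inst/cli/gmis.R`
(`run`, `build-gf`, `enumerate-mcs`, `make-fixture` subcommands).

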