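# saponinMS

Annotation of negative-mode tandem mass spectra of sea cucumber
triterpene glycosides (saponins).

Sea cucumbers (Holothuroidea) produce hundreds of triterpene glycosides:
a lanostane-type aglycon — often carrying an 18(20)- or 18(16)-lactone,
acetoxy groups, and a variable side chain — glycosylated at C-3 with a
1–6-unit oligosaccharide built from Xyl, Qui, Glc, MeGlc and MeXyl, with
up to four sulfate groups. Identifying these compounds in crude extracts
by LC-MS/MS is hard: isomers abound, reference spectra are scarce, and
the sulfate chemistry produces unusual multiply-charged adducts. This
package implements the complete in-silico toolchain a natural-products
lab needs to annotate such spectra:

- **Fragment prediction.** Glycosidic-bond cleavage ladders in
  Domon–Costello nomenclature. Y ions are the precursor minus every
  removable (descendant-closed) set of residues across branches; B ions
  follow the anion convention *m/z* = (Σresidues + n·SO₃ − z·H)/z and
  require a retained sulfate; C = B + H₂O and Z = Y − H₂O are gated.
  Aglycon-dependent secondary losses (CO₂ for lactones, AcOH = 60 Da for
  acetoxy groups, AcOH + CO₂ = 104 Da for both together), sulfate
  chemistry (HSO₄⁻ charge reduction, neutral SO₃ loss, the 96.96
  bisulfate and sulfated-monosaccharide diagnostics), side-chain
  signature losses, and a single 0,2-type cross-ring variant (±C₂H₂O₂).
- **Adduct math.** Non-sulfated glycosides ionise as [M−H]⁻; sulfated
  ones are sodium salts losing n Na⁺ to give [M−nNa]ⁿ⁻, one charge per
  sulfate. Two mass modes everywhere: monoisotopic for real data,
  nominal (integer) for the ladders as conventionally printed.
- **Rule-based structure inference.** Sulfation state from precursor
  charge and diagnostic ions; glycan sequence by depth-first walking of
  residue-mass differences (176.0685 / 162.0528 / 146.0579 / 132.0423 Da,
  plus +SO₃ variants for charged losses), with the Qui/MeXyl isobar
  reported as ambiguous, never silently resolved; aglycon feature flags;
  side-chain classification against a 13-class neutral-loss catalogue;
  analog hypotheses from characteristic precursor differences
  (176/162/146/132/58/30/18/16/14/12/2 Da).
- **Dereplication.** MGF (and read-only mzML via mzR) I/O, square-root
  intensity cosine matching, and library search with a retention-time
  gate (default 0.3 min) that separates co-isobaric isomers.
- **Molecular networking.** GNPS-style modified cosine, edge filters
  (score > 0.7, ≥ 7 matched peaks, mutual top-10 rank), and molecular
  family size capping at 100 nodes, all computed locally.
- **Synthetic data.** A grammar-aware structure generator (root xylose,
  methylated units terminal, ≤ 4 sulfates), a spectrum simulator with a
  noise model, and an additive retention-time heuristic — so the whole
  pipeline is testable without any instrument data.

All user-facing functions take and return tibbles and compose with the
pipe; result objects have `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Predict the fragment ladder of psolusoside E, a monosulfated linear
tetraoside (MeGlc–GlcSO₃–Qui–Xyl on an aglycon of 468 Da nominal),
detected as [M−Na]⁻ at *m/z* 1163:

```r
library(saponinMS)
psE <- reference_glycosides()$psolusoside_E
frags <- theoretical_spectrum(psE, mode = "nominal", cross_ring = TRUE)
frags[frags$mz %in% c(96.9601, 241, 417, 475, 563, 695, 987, 1163),
      c("label", "ion_type", "charge", "mz")]
#> # A tibble: 8 × 4
#>   label                      ion_type                       charge     mz
#>   <chr>                      <chr>                           <int>  <dbl>
#> 1 [HSO4]-                    diagnostic_HSO4                     1   97.0
#> 2 [GlcSO3-Na]-               diagnostic_sulfomonosaccharide      1  241
#> 3 [MeGlc+GlcSO3-Na]-         B                                   1  417
#> 4 [MeGlc+GlcSO3+C2H2O2-Na]-  A02                                 1  475
#> 5 [MeGlc+GlcSO3+Qui-Na]-     B                                   1  563
#> 6 [MeGlc+GlcSO3+Qui+Xyl-Na]- B                                   1  695
#> 7 [M-Na-MeGlc]-              Y                                   1  987
#> 8 [M-Na]-                    precursor                           1 1163
```

The B-series 695/563/417, the cross-ring 475, the Y ion 987 and the
diagnostics 241 and 96.96 are the ions reported for this compound.
Going the other way — inferring structure from a spectrum — on a
simulated spectrum of cucumarioside H6 (monosulfated branched
pentaoside, sulfate on the first xylose):

```r
set.seed(2)
sp <- simulate_spectrum(reference_glycosides()$cucumarioside_H6)
ann <- annotate(sp)
ann
#> <saponin_annotation> cucumarioside H6 (precursor 1309.2021, 1-)
#>   sulfates: 1 (diagnostic ions)
#>   glycan ladder: Qui|MeXyl-Xyl-Glc-Qui|MeXyl
#>   side chain: Lefevreoside B
ann$composition
#> # A tibble: 5 × 3
#>   code      sulfated source
#>   <chr>     <lgl>    <chr>
#> 1 Qui|MeXyl FALSE    ladder
#> 2 Xyl       FALSE    ladder
#> 3 Glc       FALSE    ladder
#> 4 Qui|MeXyl FALSE    ladder
#> 5 Xyl       TRUE     diagnostic
```

The ladder recovers the four residues the Y-series can reach (terminal
first; 146-Da steps stay ambiguous between Qui and MeXyl), the sulfated
root xylose is supplied by its 211-Da diagnostic anion — losing it would
strip the only charge, so no Y ion crosses it — and the neutral-loss
series 128/202/228/360/372 identifies the Δ²⁴ side-chain class. A
command-line front end over the same functions is installed at
`inst/cli/saponin-tools.R` (subcommands `fragment`, `annotate`,
`search`, `network`, `simulate`).

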