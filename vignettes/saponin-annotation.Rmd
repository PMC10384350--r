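---
title: "Methods: in-silico fragmentation and annotation of sulfated triterpene glycosides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico fragmentation and annotation of sulfated triterpene glycosides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saponinMS)
```

## The chemistry being modelled

Sea cucumber triterpene glycosides are lanostane-type aglycons
glycosylated at C-3 with a rooted oligosaccharide of one to six units
drawn from xylose (residue 132 Da nominal), quinovose (146), glucose
(162), 3-O-methylglucose (176) and 3-O-methylxylose (146). Quinovose
and 3-O-methylxylose are exactly isobaric (C6H10O4): no mass
measurement can separate them, and every interface in this package
carries the ambiguity explicitly as `"Qui|MeXyl"` rather than picking
one. Natural chains obey a strong grammar — xylose is always the unit
attached to the aglycon, methylated units are always terminal, chains
of five or six units branch at the first or second unit — which the
package can enforce (`grammar = TRUE`) or relax for hypothetical
structures. Up to four hydroxyls may be sulfated.

Under negative-mode electrospray, non-sulfated compounds ionise as
[M−H]⁻. Sulfated compounds are handled as their sodium salts: each
sulfate ester contributes SO₃ and a Na⁺ counter-ion to the neutral
mass, and the observed precursor is [M−nNa]ⁿ⁻ with, for polysulfated
compounds, one charge per sulfate. This single convention reproduces
all the adduct and fragment arithmetic used in the package; the charge
carriers are fixed at 1.007276 Da (proton) and 22.989770 Da (Na⁺), with
the electron mass ignored — its effect (≈ 0.0005 Da) is far below every
matching tolerance used. The one place the electron matters is the
bisulfate diagnostic anion, pinned at its observed m/z 96.9601 in both
mass modes.

Two mass modes run through the whole package. `"mono"` is the working
mode for real spectra. `"nominal"` does all bookkeeping with the
integer residue and loss masses that fragment ladders are
conventionally quoted in (176/162/146/132, SO₃ = 80, HSO₄ = 97,
CO₂ = 44, H₂O = 18, AcOH = 60, AcOH + CO₂ = 104, C₅H₁₀ = 70,
C₂H₂O₂ = 58), so that a predicted ladder can be compared digit-for-digit
with a printed one.

## Fragment generation

`glycosidic_ladder()` enumerates cleavages exhaustively. Y-type ions
(aglycon side retained) correspond to removable unit sets: the
descendant-closed subsets of the glycan tree, i.e. unions of complete
subtrees detached leaves-first across branches. With at most six units
there are at most 2⁶ subsets, so exhaustive enumeration is exact and
cheap; no heuristics are involved. Charge bookkeeping follows the
sulfate-as-charge-site model: a cleaved subtree carrying k charged
sulfates departs as an anion of mass Σresidues + k·SO₃ − k·H and the
fragment charge drops by k; a fragment whose charge would fall below
one is not emitted. This is why, for a monosulfated compound at charge
1, no Y ion crosses the sulfated unit — the annotator compensates with
the sulfated-monosaccharide diagnostics (below).

B-type ions (non-reducing side) use the anion convention
m/z = (Σresidues + n·SO₃ − z·H)/z with z = min(retained sulfates,
precursor charge); subtrees without a sulfate cannot retain charge in
this chemistry and are skipped with an informational message rather
than an error. C ions (B + H₂O) and Z ions (Y − H₂O) are generated only
on request: Z-type series are reported in the source literature but
rarely assigned, so both default to off. Cross-ring chemistry is
restricted to a single 0,2-type variant, ±C₂H₂O₂ (58 Da) on B ions,
also off by default: the worked ladders support exactly this one
cleavage, and the full A/X enumeration is not constrained by available
assignments, so guessing further compositions would be invention, not
modelling.

Secondary losses depend on the aglycon: CO₂ (and CO₂ + H₂O) for any
lactone, acetic acid (60 Da) for acetoxylated aglycons, and the
combined AcOH + CO₂ loss (104 Da) only when an acetoxy group coexists
with an 18(20)-lactone — the 104-Da loss is therefore evidence for
*both* features at once, and the annotator applies that implication in
reverse. Water losses are optional on every fragment. Side-chain
diagnostic losses come from a 13-class catalogue
(`side_chain_classes()`): b1/b2 ions from retro-Diels–Alder cleavage of
the B-ring, f-type ions from C-20–C-22 cleavage combined with D-ring /
lactone losses, and h-type ions from C-22–C-23 cleavage, which exist
only for side chains with a terminal 25-ene. The catalogue is defined
at nominal precision (its monoisotopic compositions are not fully
published), and classification always matches at ±0.5 Da.

Labels mirror the conventional bracket notation (`[M-2Na-MeGlcSO3]-`,
`[MeGlc+GlcSO3+Qui+Xyl-Na]-`), which makes predicted sets directly
comparable to published assignments. Fragments are deduplicated by
(label, charge): two cleavage sets with the same lost-residue multiset
produce the same ion and are reported once.

## Structural inference

The annotator works on singly-charged-equivalent masses: a peak of
charge z maps to z·m/z + (z−1)·1.007276, which re-protonates the extra
charge sites so that the charged loss of a sulfated residue from a
multiply-charged precursor lines up with the neutral residue + SO₃
increment. Simulated spectra carry per-peak charges; for experimental
peak lists without charge assignments, peaks are treated as singly
charged (a documented limitation — multiply-charged fragment ladders in
raw MGF data will only partially participate).

Glycan sequencing is a depth-first search over peak-to-peak differences
matching the four residue masses (and their +SO₃ variants), anchored at
the precursor. Maximal ladders are reported terminal-to-root and ranked
by step count, then summed matched intensity; ties inside the walk are
broken by a fixed residue order (MeGlc < Glc < Qui|MeXyl < Xyl) purely
for determinism. Two design points deserve emphasis:

- **Isobaric collisions are logged, not hidden.** At the default 0.05 Da
  tolerance two systematic coincidences exist: Xyl + CO₂ (176.032) is
  within 0.037 Da of a MeGlc residue, and the pair sums Glc + Qui and
  MeGlc + Xyl agree to 0.0001 Da. When equally long competing ladders
  disagree on the residue multiset, `estimate_composition()` flags the
  result (`attr(x, "ambiguous")`). In the acceptance checks on 100
  noiseless synthetic structures, every recovery failure is such a
  flagged collision.
- **Sulfation evidence is combined, never forced.** Charge ≥ 2 fixes
  the sulfate count (one charge per sulfate); at charge 1 the 96.96
  bisulfate and 255/241/225/211 sulfated-monosaccharide anions indicate
  at least one sulfate. When the count implied by charge exceeds the
  sulfated steps the ladder could reach, the diagnostics supply the
  missing units. Conflicting evidence (say, a doubly-charged precursor
  with no 96.96 ion) is not adjudicated: the report keeps both evidence
  lines and the per-rule hits are inspectable in the `evidence`
  list-columns.

Analog reasoning compares precursors against the characteristic
difference table {176, 162, 146, 132, 58, 30, 18, 16, 14, 12, 2} Da
(monoisotopic equivalents in `"mono"`), in both directions; an exact
precursor match is reported on a separate channel since a zero
difference is identity, not analogy.

## Library search and networking

Spectral similarity is the cosine of square-root-scaled intensity
vectors over greedily paired peaks (best intensity-product pairs first,
each peak used once). Square-root weighting is standard practice; the
vendor "Match Score" behind the bundled dereplication table uses an
unpublished formula, so those score values are deliberately not
reproduced — only ranking behaviour is tested. The greedy pairing is
bounded against an exhaustive optimal-assignment oracle on small
spectra in the test suite and agrees to 1e-9 on those instances.

`library_search()` filters candidates at 0.02 Da precursor tolerance
and scores fragments at 0.05 Da — the tolerances the reference
workflow used for networking — then applies a retention-time gate of
0.3 min, the largest library-vs-extract RT deviation in the bundled
reference table (the source reports no explicit tolerance). Records
failing the gate are retained but ranked strictly below all passers:
the gate exists to separate co-isobaric isomers with near-identical
spectra, and discarding failures would hide the second-best isomer the
user most wants to see.

`build_network()` re-implements the standard molecular-networking
filters locally: modified cosine (fragment pairs may also match when
offset by the precursor difference), edges kept at score > 0.7 with at
least 7 matched peaks ("more than 6" read strictly), mutual top-10
rank, and molecular families capped at 100 nodes by repeated removal of
the globally lowest-scoring edge of any oversized component. Rank ties
break by higher matched-peak count then lower node id, and removal ties
by edge id; node ids are sorted with locale-independent radix order, so
the network is a pure function of the spectrum set, not of input order.

## The synthetic-data generator

The generator exists so that every module is testable without
instrument data; its defaults encode the study conditions rather than
convenient ones. Chain-length frequencies follow the reference
collection (tetraosides the mode, biosides rare: weights 2/3/76/65/45
for 2–6 units), as do sulfate counts (weights 61/55/43/23/9 for 0–4).
When a structure is sulfated the first sulfate goes on the root xylose
— the predominant natural motif — and additional sulfates on random
other units; structures sulfated only on upper units (a real but rarer
pattern) can be built explicitly but are not emitted by default. This
placement choice matters: it guarantees that for multiply-sulfated
structures the Y-ladder can strip every unit down to the charged root,
which is the regime the annotator's ladder + diagnostics recovery logic
is designed for. Intensities are ion-type-based (Y > B > secondary,
reflecting the observed dominance of Y-series) with log-normal jitter;
they carry no physical meaning beyond that ordering. m/z noise is
Gaussian with the same standard-normal draws at every noise level for a
fixed seed, so recovery under increasing noise is evaluated on nested
perturbations of the same spectra — this makes the degradation test a
deterministic monotonicity check instead of a flaky stochastic one.
Spurious peaks are uniform over the mass range at a configurable
fraction.

What the simulator does **not** emulate: isotope envelopes,
chromatographic peak shape, collision-energy response, detector
saturation, and realistic intensity physics. A passing recovery test
therefore shows that the inference rules are internally consistent with
the fragmentation model at realistic m/z accuracy — not that they will
achieve the same rates on instrument data.

The retention-time heuristic is additive with only the coefficient
signs constrained by the observed chromatographic trends (sulfates,
side-chain oxygenation, extra monosaccharides and branching shorten
retention; acetoxy groups, the 18(20)-lactone and side-chain saturation
lengthen it). Magnitudes (intercept 12 min; −0.3 first sulfate, −1.2
per additional; +1.5 per acetoxy; +1.3 lactone; −0.25 per unit beyond
four; −1.8 oxygenated side chain; +0.8 saturated) were chosen once so
that all grammar-valid structures predict inside the observed
4.3–18.9 min elution window without the clip ever binding — which keeps
the sign-monotonicity properties strict. No quantitative RT model is
published for these compounds; this heuristic orders analogs correctly
and nothing more. Tetrasulfated records get `NA` retention times by
default, mirroring the practice of direct-injecting compounds whose
reversed-phase elution is irreproducible.

## Numerical choices and verification scale

- Default tolerances: 0.02 Da precursor, 0.05 Da fragment, 0.5 Da in
  nominal mode and for the (nominal) side-chain signatures; RT gate
  0.3 min.
- The ppm check against the bundled dereplication table allows 0.21 ppm
  per row: the table's m/z values are printed to 4 decimals, which
  alone can shift a recomputed ppm by ±0.16 at m/z 630, plus 0.05 from
  the 1-decimal ppm column. The observed maximum deviation (0.15 ppm)
  sits inside that bound; most rows agree to the printed digit.
- Problem sizes in tests and the acceptance script: 100 synthetic
  structures for noiseless recovery, 40 for the noise-degradation grid
  (σ ∈ {0, 0.005, 0.01, 0.02} Da with 20 % spurious peaks) and the
  self-search/networking rates, 20 spectra for the brute-force network
  comparison, ≤ 4-peak toys for the exhaustive assignment oracles.
  These sizes keep the full suite in a few minutes while leaving every
  oracle exact.
- Degenerate inputs: empty spectra score 0 in all similarity functions;
  an empty MGF yields an empty list; ladder walks on spectra with no
  matching differences return zero candidates rather than errors.

## Known limitations

- Aglycon structure is inferred only as feature flags and a side-chain
  class; de novo aglycon elucidation, stereochemistry and
  quantification are out of scope.
- The worked-example structures ship with bookkeeping aglycon masses
  back-derived from published nominal precursors (the molecular
  formulas are not available), so they are exact in nominal mode and
  placeholders in monoisotopic mode.
- Positive-mode chemistry, vendor raw formats, profile-mode data and
  peak picking are out of scope (use MSConvert/MZmine upstream; mzML is
  read centroided-only).
- Multiply-charged fragments in charge-unannotated peak lists
  participate in ladder walks only as far as their face-value m/z
  allows.
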