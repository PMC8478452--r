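---
title: "Methods: iron-cycling energetics and gene-profile analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iron-cycling energetics and gene-profile analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferroflux)
library(dplyr)
```

`ferroflux` couples two strands of evidence about microbial iron cycling in
deep fracture fluids: a thermodynamic strand (which iron redox reactions are
viable, and how much energy each supplies per kg of fluid) and a functional
strand (which communities and genome bins carry iron-cycling genes). This
vignette documents the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open.

## 1. Thermodynamic model

### Standard-state data

The packaged table (`thermo_table()`) holds ΔG°f and ΔH°f at 298.15 K / 1 bar
for every species in the 48-reaction library, transcribed from standard
compilations (SUPCRT-consistent aqueous species, Robie & Hemingway minerals,
NBS values for acetate and perchlorate); each record carries its source
string. Three points deserve comment:

* **Ferrihydrite.** The library distinguishes three FeOOH polymorphs. On an
  FeOOH basis we use goethite −488.55, lepidocrocite −480.14 and, for
  ferrihydrite, a conventional amorphous-phase value of −474.30 kJ/mol —
  deliberately the *least* stable of the three, which is what makes
  ferrihydrite reduction the most energetic FeOOH reduction and fresh
  ferrihydrite the kinetically expected product of Fe²⁺ oxidation.
* **Siderite** is set self-consistently with the packaged Fe²⁺ and CO₃²⁻
  records through the mineral's solubility product (log Ksp −10.89), rather
  than from an independent compilation, so dissolution equilibria computed
  within the package are internally coherent.
* **Provenance caveat.** Published figures built on other code defaults
  (different database versions, different ferrihydrite conventions) will not
  be reproduced digit-for-digit; the package's contract is the *sign and
  ordering* structure of the results, which is what its tests assert.

### Temperature correction

ΔG°r(T) uses the integrated van't Hoff relation with ΔH°r constant:
ΔG°r(T) = (T/T₀)ΔG°r(T₀) + ΔH°r(1 − T/T₀). Over the site range (10.5–31.6 °C)
heat-capacity terms are second order; a full HKF equation-of-state treatment
(and any pressure correction — all sites are modeled at 1 bar) is out of
scope. `log_k()` is then −ΔG°r(T)/(ln10·RT), and the tests verify the
equivalent van't Hoff form of ln K reproduces it to 1e-12.

### Activities

Measured analytes (mg/liter) convert to molality with fluid density
1.0 kg/liter — a dilute-fluid approximation whose error is far below the
thermodynamic-data uncertainty. Ionic strength is ½Σmz²; single-ion activity
coefficients use the extended Debye–Hückel (B-dot) model with per-ion size
parameters from the data table and temperature-interpolated A, B and Ḃ
coefficients. The Davies equation is available as a fallback
(`geochem_config(activity_model = "davies")`). Special cases:

* a(H⁺) = 10^(−pH) exactly; minerals and water have unit activity.
* Dissolved gases (CH₄, H₂, CO₂, CO) are neutral aqueous species with γ = 1,
  and CO's activity is set equal to its molal concentration outright.
* **Acetate from DOC.** DOC is reported as mg C/liter; acetate molality is
  DOC/(2·12.011·1000) — the only dimensionally coherent reading of
  "acetate approximately equal to measured DOC" for a two-carbon anion.
* **Bicarbonate.** HCO₃⁻ is not among the measured analytes but appears in
  many library reactions. We derive a(HCO₃⁻) = K₁·a(CO₂)/a(H⁺) from the
  first carbonic-acid dissociation, with K₁ computed from the packaged table
  at site temperature (log K₁ ≈ −6.35 at 25 °C). This is a single
  equilibrium, not a carbonate-system solve; full multi-component speciation
  and ion pairing are non-goals.
* **Perchlorate** is estimated at equilibrium with chloride through the
  8-electron ClO₄⁻/Cl⁻ couple at the measured Eh:
  log a(ClO₄⁻) = log a(Cl⁻) + 8pH + 8pe − log K. ORP is taken as Eh vs SHE
  (mV/1000); the reference electrode of the source measurements is not
  stated, so a configurable `electrode_offset_mV` (default 0) is provided.
  At the reducing potentials of these fluids the estimator yields
  astronomically small perchlorate activities (~1e-140), with consequences
  discussed in §3.
* **Nitrite** was not measured in the packaged fixture; reactions requiring
  it use a configurable default of 1e-7 mol/kg (`no2_default_molal`).

### Zeros and floors

Several analytes are true zeros in the fixture (ferrous iron at the two
sulfidic sites, dissolved oxygen at the deepest site). Two different needs
collide: Gibbs energies need finite logarithms, while energy densities must
honor "no substrate, no energy". The resolution: a molality floor of
1e-12 mol/kg (configurable) is applied *only* inside log Q, and the affected
results are flagged `below_floor`/`approximate`; the limiting-reactant
molality always uses the true zero, forcing zero energy density.

## 2. Reaction library

The packaged library encodes 48 reactions: 7 with aqueous Fe²⁺ as donor,
7 generic FeOOH-acceptor rows each instantiated for ferrihydrite, goethite
and lepidocrocite (21 reactions), 7 each for hematite and magnetite, 3 for
pyrite and 3 for siderite. Unqualified FeOOH produced by the Fe²⁺-donor rows
is bound to ferrihydrite, the kinetically expected fresh precipitate — an
interpretation, recorded here. Reactions with aqueous Fe²⁺ or ferrihydrite
are classed planktonic; crystalline-mineral reactions are biofilm
metabolisms.

### Validation and the rebalanced variant

`check_balance()` reports per-element and charge imbalances. Four printed
rows (6, 43, 44, 45) fail mass, charge and/or redox balance; the other 44
balance exactly. Because energy computation requires balanced equations, two
library variants ship:

* `"as-printed"` — verbatim, for validation and electron-count checks;
* `"rebalanced"` (default) — minimal integer corrections preserving the
  named redox couple: row 6 becomes 2Fe²⁺ + NO₃⁻ + 3H₂O = 2FeOOH + NO₂⁻ +
  4H⁺ (couple size 2, as printed); rows 43–45 become 3FeS₂ + 7CO + 17H₂O =
  3Fe²⁺ + 6SO₄²⁻ + 7CH₄ + 6H⁺, 4FeS₂ + 7HCO₃⁻ + 11H₂O = 4Fe²⁺ + 8SO₄²⁻ +
  7CH₄ + H⁺, and FeS₂ + 7NO₃⁻ + H₂O = Fe²⁺ + 2SO₄²⁻ + 7NO₂⁻ + 2H⁺.

For rows 43–45 *no* balanced integer equation over the printed species can
preserve the printed couple size (pyrite oxidation to Fe²⁺ + sulfate
releases 14 e⁻ per FeS₂, forcing e.g. a 3:7 pyrite:CO ratio and 42 rather
than 48 electrons), so the balanced couple size is used and the balance
report documents printed vs corrected counts. Which variant of these rows
was actually evaluated in earlier published work is unknowable from the
printed equations.

### Electron counting

`count_electrons()` assigns fixed per-species oxidation states (disulfide S
−1, sulfate S +6, acetate C 0, …) and counts electrons through the
**non-iron couple**: for each element other than Fe whose per-atom oxidation
state actually differs between participating species, it sums the electron
gain (donor-role reactions) or loss (acceptor-role). Restricting to elements
with *varying* oxidation state is what makes the rule robust on
mass-imbalanced printed rows — spectator O (−2 throughout) and H (+1
throughout) cannot contribute phantom electrons. This single rule reproduces
the printed per-reaction electron column for all 48 rows, including the four
inconsistent ones.

## 3. Energy densities

E = max(0, −ΔGr)·m_lim/ν_lim, in joules per kg of fluid (a `cal_per_kg`
report is available; the choice of unit is ours and documented here). The
limiting reactant is the aqueous reactant minimizing m/ν — minerals never
limit (mineral-consuming reactions are flagged `upper_limit`), and water,
H⁺ and OH⁻ are excluded as ubiquitous medium species. The exclusion of H⁺
is a deliberate interpretation: most reduction reactions as written consume
protons, and a buffered medium resupplies them; treating H⁺ as limiting
would otherwise dominate nearly every scaled density and contradict the
worked convention that, e.g., Fe²⁺ oxidation with O₂ is limited by O₂.

Sanity properties asserted by the tests: doubling every stoichiometric
coefficient (and the electron count) leaves E unchanged; raising the
limiting species' concentration never decreases E; E > 0 implies exergonic;
zero substrate gives E = 0.

On the packaged fixture the qualitative structure is: ferrihydrite reduction
with acetate is the top planktonic energy source at every site; Fe²⁺
oxidation with bicarbonate (methanogenic) is endergonic everywhere; all
Fe²⁺-donor reactions carry zero density at the two sulfidic sites where
ferrous iron is absent.

**The perchlorate anomaly.** Fe²⁺ oxidation with perchlorate is often
described as extremely exergonic per electron. Under the package's own
estimator this cannot hold: putting ClO₄⁻ at equilibrium with Cl⁻ at the
measured Eh pins the ClO₄⁻/Cl⁻ couple's potential to Eh itself, so the
full-reaction ΔG per electron collapses to −F·(Eh − E(Fe²⁺/FeOOH)) — a few
kJ/mol e⁻ at these sites, and slightly positive with the packaged
ferrihydrite data. `energy_ordering_checks()` therefore treats the
perchlorate ordering as a soft check and reports the full Gibbs
decomposition (log K, log Q, ΔG, ΔG/e⁻) instead of asserting it; its
energy-density half (bottom-quartile E, because the estimated perchlorate
supply is ~1e-140 mol/kg) holds regardless.

## 4. Gene-profile analysis

* **Ambiguity rule.** A feature annotated by both emulated pipelines is kept
  only when its pair of calls is exactly FeGenie "iron reduction" +
  METABOLIC "Metal reduction"; all other dual-pipeline combinations are
  reannotated ambiguous and removed before normalization. Keying is per ORF
  by default (both pipelines emit per-ORF calls; it is finer and
  deterministic), with a `key = "contig"` switch for contig-level grouping.
* **Normalization.** Relative abundance = hits / total genes per metagenome,
  exact fractions; metagenomes with no hits are kept as all-zero rows so an
  iron-gene-free control community remains representable.
* **Recategorization.** `default_recategorization()` encodes the documented
  merge rules (oxygen reduction absorbs the two oxidative-phosphorylation
  categories; hydrogen oxidation absorbs "Hydrogenases"; iron reduction
  combines the FeGenie and METABOLIC calls). The full recategorization map
  of the original supplementary material is not public; anything beyond
  these rules is user-configurable, with unmapped categories passed through
  and reported.
* **Clustering.** Bray–Curtis (via vegan) on the iron oxidation/reduction
  gene families only, then UPGMA. The in-package UPGMA is deterministic —
  ties merge the lexicographically smallest cluster pair — and is
  cross-checked against `stats::hclust(method = "average")` on random
  matrices. A pair of all-zero profiles gets dissimilarity 0 with a warning
  (library conventions vary; this keeps the all-zero outgroup clusterable).
  Node heights are half the merge dissimilarity, giving an ultrametric tree
  whose Newick export (via ape) preserves heights. No ordination or
  significance testing is performed on these matrices — none is part of the
  analysis being reimplemented.
* **MAG summaries** are presence-only: bins vary widely in completeness, so
  a missing gene is never evidence of absence. The taxon-by-gene matrix is
  restricted to the energy categories, and bins without any energy-category
  hit are excluded from it. The housekeeping summary tabulates the eight
  presence/absence combinations of acquisition / storage / regulation across
  the bin universe, summing to 100%.

## 5. Synthetic data

The generator's defaults emulate the study conditions rather than being
free dials: six sites on an iron-rich-to-sulfidic gradient (the last site
has zero ferrous iron and elevated sulfide), eight metagenomes including a
service-water-like and a surface-control-like community (the latter with no
FeGenie-detectable iron genes), 3×10⁵ genes per metagenome with iron-energy
gene fractions of order 1e-4 (≈0.045% at the iron-rich end), a dual-pipeline
ambiguous fraction of 0.13% of annotated hits, and 515 genome bins whose
housekeeping-combination counts (255/102/81 of 515, plus a fixed split of
the remainder) reproduce the reported 49.5/19.8/15.7% mix exactly at one
decimal. Category counts are drawn *multinomially* so totals are exact and
relative-abundance recovery is testable against closed-form binomial
99% intervals; ambiguous ORFs are injected as mismatched dual-tool pairs on
top of the planted counts, so reconciliation must remove exactly the planted
number. Every generated byte is a function of the spec and seed.

What the generator does **not** emulate: read-level error, assembly and
binning artifacts, HMM score distributions, taxon-abundance covariance
across sites. Passing recovery tests therefore demonstrates correctness of
the *post-annotation arithmetic*, not robustness to upstream noise.

## 6. Problem sizes and determinism

The test suite and acceptance script run the full 48×6 fixture energetics,
synthetic-annotation recovery at 2×10⁵ genes over six metagenomes, and the
515-bin MAG summary — sizes chosen to exercise every code path at full
fidelity while keeping a complete run in well under a minute. Pipeline
functions (`run_energetics()`, `run_profiles()`) write tab-separated outputs
with a header comment carrying the package version and a configuration
hash; reruns on identical inputs are byte-identical, and the tests assert
it.

## Known limitations

* No multi-component speciation (ion pairing, carbonate-system solving,
  redox disequilibrium beyond the perchlorate estimator).
* Mineral energy densities are upper limits by construction.
* Thermodynamic values are compilation-dependent at the few-kJ level;
  conclusions that hinge on a few kJ (marginally ex-/endergonic reactions)
  should be read accordingly.
* The ORP reference electrode and several averaged analytes of the original
  field campaign are unknown; the packaged fixture uses the printed values
  as-is.
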