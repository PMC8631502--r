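---
title: "Profiling serum N-glycomes by direct-infusion MS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling serum N-glycomes by direct-infusion MS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoMS)
```

glycoMS re-implements, as reusable and tested code, the analysis chain used
to profile serum N-glycomes of five fish species (Atlantic salmon, Arctic
char, Atlantic and shortnose sturgeon, channel catfish) by nanospray
direct-infusion ion-trap mass spectrometry: exact-mass calculus for
permethylated and native glycans, composition assignment of multiply charged
sodiated peaks, total-ion-mapping (TIM) quantification against a
maltotetraose (Dp4) internal standard, MSn B-ion interpretation, in-silico
exoglycosidase sequencing, and species-level structural-feature profiling.
A ground-truthed synthetic-spectra generator stands in for the instrument,
so every stage is testable offline.

## The mass model

All arithmetic rests on six dehydrated monosaccharide residue masses
(`residue_table()`): Hex 162.05282, HexNAc 203.07937, dHex 146.05791,
NeuAc 291.09542, NeuGc 307.09033, KDN 250.06887 Da, with 3/3/2/5/6/6
permethylation sites respectively (each site adds CH2 = 14.01565 Da). A
free-reducing glycan gains an end group of +46.04186 Da permethylated
(+C2H6O) or +18.01056 Da native (+H2O); each O-acetyl group on a sialic
acid adds 42.01057 Da but survives only in native glycans, because
permethylation removes base-labile esters — requesting a permethylated mass
for an O-acetylated composition is an error, not a warning.

Permethylated glycans ionize in positive mode as sodiated species with one
Na+ per charge; native glycans in negative mode as [M − zH]z−. The ion
m/z of the k-th isotopologue is

    positive: (M + k·1.00336 + z·22.98977) / z
    negative: (M + k·1.00336 − z·1.00728) / z

with z = 1..4 and k = 0..6 supported. For glycans of 2.5–5 kDa the
monoisotopic peak is not the most intense one; `most_abundant_ion_mz()`
resolves k from the full isotopic distribution, computed by per-element
convolution of natural abundances (13C 1.07%, 2H 0.0115%, 15N 0.364%,
17O 0.038%, 18O 0.205%), truncated at k = 6 and verified in the test suite
against an independent closed-form binomial/multinomial oracle. The engine
deliberately exposes both conventions (explicit k and most-abundant k):
published peak lists from ion traps mix them, and two of the published
peak values (1251.61/1866.42 for the same molecule at 3+/2+, and
1336.98 at k = 1 where the distribution maximum is k = 2) cannot be
reproduced by any single convention. Displayed m/z values are rounded
half-up to two decimals, matching instrument software.

B-type fragments of permethylated glycans (`b_fragment_mz()`) are sodiated
and gain CH2 + Na relative to the residue sum; every glycosidic cleavage
beyond the one that released the fragment leaves an unmethylated hydroxyl
scar worth −14.01565 Da. A terminal residue lost in MSn departs with the
glycosidic methyl, so the neutral loss is the permethylated residue mass
+ 14.01565 Da (NeuAc: 375.19). These two rules reproduce the whole published
MSn argument chain (1051.5 → 676.3 for the catfish epitope; 894/690 for
the sturgeon epitope series). Y-type and cross-ring ions are not modeled:
no inference in the workflow needs them, and only singly charged fragments
are predicted by default because all interpreted MSn ions are 1+.

## Topologies, motifs and digestion

Topologies are rooted residue trees with per-edge anomericity, written in
an IUPAC-condensed-style linear code, non-reducing end first, branches in
square brackets:

```{r}
t <- parse_glycan("Gal(a-)[Gal(b-)]Gal(b-)GlcNAc")
composition_of(t)
```

Linkage positions are accepted but ignored by matching, since the workflow
determines anomericity (by exoglycosidases), not positions. Hexose
identity (Gal/Man/Glc) lives on topology nodes but is erased in
compositions: MS1 cannot distinguish isomeric hexoses, and keeping the
collapse explicit keeps assignment honest.

The motif library encodes the species signatures: the NeuAc-NeuAc di-SA
cap (salmonids), the Galα(Galβ)Galβ-HexNAc tetrasaccharide (sturgeons),
the NeuAc-branched GalβGalβ-HexNAc cap (catfish), the nonsialylated
GalβGalβ-HexNAc, the NeuAc-Gal cap, and core fucose. Matching requires
pattern leaves to land on topology leaves and the children of every
matched node to correspond one-to-one, so an unsialylated pattern never
matches a sialylated branch — that bijection is what makes the library
pairwise discriminating (property-tested).

Exoglycosidase rules remove one terminal residue kind of fixed
anomericity; a rule may list blocking branches on the parent.
β-galactosidase is blocked by a branching NeuAc (the sialylated catfish
epitope resisted both galactosidases) and by a branching α-Gal (the inner
β-Gals of the sturgeon cap are digestible only after α-galactosidase), so
enzyme order genuinely matters: α-then-β removes 6 hexoses from a
two-antenna sturgeon glycan, β-then-α only 2. Partial digestion of
sterically hindered structures is modeled as a per-site removal
probability (default 1 = complete), a deliberately simple stand-in for a
phenomenon the source measurements note only qualitatively.

## Peak processing and assignment

TIM windows default to the acquisition grid: 600–2000 m/z in 2.8-unit
windows overlapping by 0.8 (700 windows). Isotope clusters are collapsed
by charge-hypothesis search over z = 1..4 (spacing 1.00336/z, tolerance
0.05 m/z, most members then smallest residual then lowest z wins);
cluster intensity is the member sum and the reported m/z is the most
intense member. Charge states of one composition are summed, the 3%
threshold is applied, and retained abundances are normalized to 100%.

Two documented readings deserve mention. First, the 3% threshold is
referenced to the most intense single MS1 peak (the base peak), not to
the largest summed per-glycan response; the published profiles report glycans at
0.38% and 0.12% of the pool, which only a base-peak reference admits.
Second, TIM responses are summed per isotope cluster rather than per
window, so a cluster spanning two overlapping windows is not counted
twice.

Composition search enumerates NeuAc 0–6, NeuGc 0–2, KDN 0–2, Hex 3–14,
HexNAc 2–8, dHex 0–3 (O-acetyl 0–6 in native mode only). NeuGc and KDN
are searched although the sera are expected to lack them — their absence
is then a result, not an assumption. Matching is isotopologue-aware
(k ≤ 3 by default): without the k-search every assignment would be off by
one or two neutrons.

Collision resolution is the package's most consequential design choice.
Composition space is riddled with degeneracies: NeuAc + Hex equals NeuGc
+ dHex *exactly* (NeuGc = NeuAc + O, Hex = dHex + O), and
3 NeuAc + 2 HexNAc sits 0.036 Da from 6 Hex + 2 dHex — within one
isotopologue spacing, so the k-search would happily alias it. Candidates
are therefore ranked the way an annotator resolves them:

1. consistency with canonical serum N-glycan templates (chitobiose core,
   up to tetra-antennary, core fucose only, at most a di-SA pair per
   antenna, antenna hexose extension bounded by the observed three-Gal
   caps, Man9 for high-mannose);
2. plausible sialylation degree;
3. fewest rare sialic acids (NeuGc/KDN);
4. agreement of the matched k with the candidate's own most abundant
   isotopologue (breaks the near-1 Da aliases);
5. mass error compared at the instrument's 0.01 m/z display precision;
6. parsimony (fewest residues), then smallest k.

All collisions within tolerance are returned, never silently dropped.
Because of the exact degeneracies, "≥ 99% top-1 recovery over arbitrary
compositions in bounds" is mathematically unattainable; the recovery
property is instead stated — and enforced in the acceptance tests — over
the canonical NeuAc-family space (416 compositions), where fuzzed
recovery at σ = 0.01 m/z jitter is 100% in practice.

## The synthetic generator

`species_presets()` fixes the five emulated serum conditions. Reported
values are encoded exactly: di-SA on 5% of the Arctic char pool versus 2%
in Atlantic salmon (split as 4.88 + 0.12 and 1.62 + 0.38 between the
biantennary trisialylated carrier and the tetrasialylated glycan); the
triantennary trisialylated glycan abundant in salmon and absent from
char; core fucosylation on 45% ("more than 40%") of the shortnose
sturgeon pool versus 2% in the Atlantic sturgeon; catfish centred on
NeuAc2Hex7HexNAc4 with NeuAc-branched GalβGalβ caps and no
NeuAc3Hex5HexNAc4; O-acetyl ladders spanning 0–3 (salmon), 0–6 (char),
0–1 (sturgeons) and 0–2 (catfish) groups. Abundances without a reported value are fixed plausible ones, flagged `synthetic` in every ground
truth so they are never mistaken for measurements.

`generate_ms1()` emits depth-4 isotope clusters at the charge states the
preset's mixing weights allow inside the scanned range, the Dp4 standard
cluster, and noise: m/z jitter σ = 0.01, intensity CV 10%, 5 spurious
peaks per 100 true ones. These defaults exercise the clustering and
threshold logic while keeping round-trip recovery at the level the
acceptance properties demand; all are configurable, and zeroing them
makes generated peaks equal theory to 1e-6. The internal standard is
spiked so that analyte intensities carry the 5% co-injection factor and
`quantify_vs_standard()` recovers absolute amounts exactly on noise-free
data. What the generator does *not* emulate: profile-mode peak shape,
detector saturation, chemical background correlated in m/z, in-source
fragmentation, and salt adducts other than full sodiation — so passing
round-trip tests validates the pipeline's arithmetic and logic, not its
robustness to every instrument artifact.

The Dp4 standard's theoretical sodiated m/z is 885.43, while the reported
observation is m/z 899.48 — one CH2 apart, unexplained there. The expected
standard m/z is therefore configuration (`standard_mz`), defaulting to
theory; simulations place the standard at the configured position.

## Numerical and degenerate-input choices

Compositions must be non-negative integers; O-acetyl counts are capped at
3 per sialic acid by default (the char maximum of six groups on two NeuAc
fits exactly; whether they sit 3+3 is unknown, so the cap is
configurable). Windowing requires width > overlap. Empty peak lists flow
through every stage and produce empty profiles, not errors. A zero or
missing standard peak makes absolute quantification an error that points
to relative-only mode. Ties in isotopologue argmax go to smaller k; ties
in cluster charge inference to lower z; candidate ranking is a strict
lexicographic order, so assignment is deterministic. Enumeration refuses
bounds spanning more than 1e7 candidates.

Two printed values are excluded from all tests as irreconcilable with
the stated compositions (the published arithmetic appears inconsistent
there): the digestion product at m/z 1457.72 (2+) and the Fig-4-caption
pair 1071 (2+)/1421. The shortnose peaks 1020.16 and 1101.87 (3+) have no
printed compositions; the assigner reports candidates for them but no
test anchors them.

## Problem sizes and verification

The test suite verifies: oracle equivalence of the isotope engine
(150 fuzzed formulas ≤ 30 atoms, tolerance 1e-10), serialization
round-trips on 60 random trees (depth ≤ 6), pairwise motif
discrimination, the full digestion order/resistance matrix, 1,000-peak
fuzzed assignment recovery, zero-noise profile recovery for all five
presets, feature recovery within ±1.5 percentage points over 500 noisy
simulations (100 per preset), and byte-identical pipeline determinism
under fixed seeds. These sizes run the whole suite in about two minutes
on one core while keeping every statistical check comfortably powered.

```{r}
res <- run_pipeline(pipeline_config(seed = 7), species = "arctic_char")
res$features[1:4, ]
```

## Known limitations

Hexose and HexNAc isomers are indistinguishable by construction; antenna
fucosylation is reported as core fucose (flagged in the documentation)
because MS1 cannot separate them; glycopeptides, sulfation,
phosphorylation and non-sodium adducts are out of scope; linkage
positions are never inferred. The canonical-template ranking encodes
vertebrate serum N-glycan biology — applying the assigner to O-glycans
or to invertebrate material would require replacing that tier.
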