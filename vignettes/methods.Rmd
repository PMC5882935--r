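---
title: "Sequencing glucose oligosaccharides from sodiated MSn spectral trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequencing glucose oligosaccharides from sodiated MSn spectral trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoMSn)
```

## The problem

A glucose oligosaccharide of even modest size hides an enormous isomer
space: every glycosidic bond carries a linkage position (1→2, 1→3, 1→4 or
1→6) and an anomeric configuration (α or β), and branches multiply the
possibilities. Conventional single-stage tandem MS cannot separate most of
these isomers, and the classical de novo methods require derivatisation,
which destroys information about the reducing-side residues.

glycoMSn implements a de novo sequencing strategy for *underivatised*
glucose oligosaccharides built on three ingredients:

1. **A mechanism-constrained fragment calculus.** Under low-energy
   resonance-excitation CID of sodium adducts, glycosidic B/C/Y/Z cleavage
   can occur at any bond, but dehydration (−18 u) and retro-aldol
   cross-ring cleavage (−60/−90/−120 u, the ⁰′²A/⁰′³A/⁰′⁴A ions) occur
   essentially only at the reducing ring — the nonreducing-ring channels
   have barrier heights above the desodiation limit. Secondary
   fragmentation within one CID stage is negligible; consecutive losses
   arise only across explicit MS^n stages.
2. **An anomer-resolved disaccharide fingerprint database.** Because
   mutarotation is slower than chromatographic separation, the two
   reducing-end anomers of each disaccharide can be measured separately.
   A fingerprint therefore determines the linkage position *and both*
   anomeric configurations of a disaccharide unit.
3. **A decision procedure over a spectral tree.** The MS2 loss pattern
   constrains the reducing-sugar linkage set; CID of the ring-opened
   (−18/−60/−90) products separates linear from branched topologies and
   produces clean nonreducing-side disaccharides for database matching;
   C-type products inherit the cleaved bond's configuration at their new
   reducing end, which chains interior anomer assignments together; and a
   weighted spectral subtraction deconvolves the isobaric m/z 365 mixture
   to recover the reducing-side disaccharide as a crosscheck.

## The fragment calculus

All ions are singly charged sodium adducts. For `n` hexose residues and a
neutral loss `L`,

$$m/z = n \times 162.0528 + 18.0106 + 22.9892 - L,$$

with `L` drawn from {0, 18.0106, 60.0211, 90.0317, 120.0423}. Matching is
done on nominal (integer) m/z because the method targets unit-resolution
ion traps; monoisotopic values are retained throughout for future
high-resolution use. The familiar ladder follows: 527/509/467 for a
trisaccharide, 689/671/629 for a tetrasaccharide, 365/347/305/275/245 for
the disaccharide region, 203 for a sodiated hexose.

The linkage diagnosis rests on which reducing-ring channels are open:

| reducing linkage | −18 | −60 (⁰′²A) | −90 (⁰′³A) | −120 (⁰′⁴A) |
|---|---|---|---|---|
| 1→2 | (minor) | – | – | – |
| 1→3 | yes | – | yes | – |
| 1→4 | yes | yes | – | – |
| 1→6 | yes | yes | yes | yes |
| (1→6,1→4) | yes | yes | – | – |
| (1→6,1→3) | yes | – | yes | – |
| (1→6,1→2) | – | yes | – | – |
| (1→4,1→3) | yes | – | – | – |
| (1→4,1→2) | – | yes | – | – |
| (1→3,1→2) | – | – | yes | – |

A hypothesis survives only if its expected loss set *equals* the observed
set — absence is evidence too. Three collisions remain and are separated
downstream: linear(1→4) vs branched(1→6,1→4) and linear(1→3) vs
branched(1→6,1→3) are resolved by the presence/absence of
disaccharide-region ions in the CID of the ring-opened products, and
(1→6,1→2) vs (1→4,1→2) by the branch disaccharide matches. A reducing
sugar carrying three substituents is modelled as the union of its pairs —
an assumption (only the pair rules are mechanistically established), which
is why elucidation of such structures stops at topology classification. The 1→1
(trehalose-type) linkage is representable but has no rule support and is
flagged as non-elucidable.

## The synthetic fingerprint database

No public repository holds the measured anomer-resolved spectra, so the
package ships a synthetic database (16 slots: α/β bond × {2,3,4,6} × α/β
reducing end) whose channel ratios are free parameters constrained by the
ordinal rules of the mechanism:

* a cis (α for glucose) reducing end dehydrates strongly, a trans (β) end
  weakly — the α/β ratio at m/z 347 is the reducing-anomer discriminator;
* the glycosidic-bond anomer shifts the partition between the C (m/z 203)
  and B (m/z 185) products and the overall glycosidic share;
* the linkage position selects the cross-ring ladder support;
* 1→2 entries dehydrate only weakly for either anomer (a different
  mechanism operates there, which the package deliberately does not
  model).

The defaults were fixed once, at design time, by a separability
calculation: with dehydration bases 0.35/0.9/1.0/0.45 for positions
2/3/4/6, a trans attenuation of 0.05, and the cross-ring intensities in
`default_channel_params()`, the worst-case cosine between distinct
fingerprints is ≈0.93 (the 1→2 reducing-anomer pair, where dehydration is
the only discriminator), leaving a top-1/top-2 margin above the 0.05
decision threshold for every slot. The 1→6 dehydration base sits at 45%
of the base peak — weaker than 1→4/1→3, where dehydration rivals the base
peak, but strong enough that the reducing anomer stays resolvable by
ratio, which is the database's defining feature. A laboratory can replace
the synthetic entries with measured spectra through the same MSP or JSON
schema; provenance is recorded per entry.

A *mixture* reference — the 50/50 anomer average reconstructed from the
two resolved entries — is used whenever a population retains the original
reducing sugar (Y-type fragments), because the solution anomers coexist.
Matching such populations against resolved entries would let a wrong
linkage slip between the two anomeric variants; `match_bond_spectrum()`
therefore ranks bond-level averaged references instead.

## The simulator

`simulate_tree()` emulates the instrument: each node isolates a nominal
m/z among the parent's product populations — *all* isobaric populations
together, e.g. the C2 and Y2 disaccharides at m/z 365 — and records the
CID spectrum of the ratio-weighted mixture. Channel weights follow the
mechanism (per-bond glycosidic weights scaled by the bond anomer,
reducing-ring channels per the pattern table, C-ion anomer inheritance).
Two deliberate modelling choices:

* **Noise is multiplicative lognormal jitter on open channels only**
  (default sdlog 0.1). Off-ladder "chemical noise" peaks are not
  generated: every simulated peak must be assignable by the fragment
  calculus and peak positions must be seed-invariant, which stray peaks
  would violate. Channels whose relative weight falls below 0.015 are not
  emitted, so jitter cannot move a peak across the 0.01 presence
  threshold except at ≈4σ. Consequently the simulator probes the
  decision logic and ratio rules, not peak-picking robustness — passing
  tests say nothing about contaminated or low signal-to-noise real
  spectra.
* **Branch cleavage is asymmetric by default** (`branch_bias = 0.97`):
  at a branch point the bond at the lowest acceptor position cleaves
  preferentially, so the m/z 365 population from a branched trisaccharide
  is almost purely the (root + high-position branch) disaccharide. This
  reproduces the observed branched-trisaccharide phenomenology, where the
  subtraction residual is near zero and only one branch anomer can be
  determined. A 90/10 split would leave a ~10% residual — clearly above
  the 0.05 near-zero cutoff — and would contradict that outcome, which is
  why the default is more extreme. Setting `branch_bias = 0.5` exercises
  the symmetric case in which both branch anomers become determinable.

## The decision procedure

For a linear chain of `n` residues (numbered 1 = reducing end):

1. MS2 of the sodiated molecular ion → reducing-linkage candidates from
   the loss pattern.
2. CID of a ring-opened product (−60 preferred for n ≥ 4, −18 for
   trisaccharides, −90 when 1→3 closes the −60 channel): presence of the
   (n−1)-mer/disaccharide ions settles linear vs branched.
3. The m/z 365 ion from the opened species is the pure nonreducing
   disaccharide (C2): database match → outermost bond position + anomer,
   and the entry's reducing anomer *is* the next-inner bond's anomer
   (C-ion inheritance).
4. Stripping one nonreducing residue at a time from the opened species
   (−162 steps) yields each interior disaccharide in turn, chaining the
   inheritance inward to bond 1–2.
5. The mixed m/z 365 isolated directly from the precursor contains the
   reducing-side Y2 plus the nonreducing C2; subtracting the identified
   C2 fingerprint — weighted to null an ion unique to its ladder, m/z 275
   for a 1→6 unit against a 1→4 partner — leaves the reducing-side unit as
   an independent crosscheck of bond 1–2.

Anomers decided by more than one route are audited; disagreement
downgrades the assignment to unspecified with a caveat. The reducing-end
anomer itself is always reported unspecified, since both solution anomers
coexist. Partial results are first-class: the report lists what is
undetermined and which precursor path would settle it.

Branched trisaccharides follow the same MS2 pattern logic; the mixed
m/z 365 spectrum is matched at bond level, the dominant component is
subtracted via the mixture reference, and a near-zero residual (< 0.05
before renormalisation) means the minor branch's anomer stays
unspecified. For tetrasaccharides the two presence checks (disaccharide
ions in MS2; trisaccharide ions in the opened-product CID) classify the
topology into the four types — linear (I), branched on the reducing sugar
(II), branched on the nonreducing side (III), two branches on the
reducing sugar (IV) — with the scheme's footnote exceptions attached as
caveats. Types II and III are then worked per branch (for II a
reverse subtraction is used when the identified chain unit has no unique
ladder ion: each candidate second component is nulled instead, and the
residual must reproduce the known unit). These branched-tetrasaccharide
assignments extend beyond any fully worked example and are always flagged
as extrapolated; type IV stops at classification, because the pattern
table constrains linkage pairs, not triples.

## Numerical choices and tunables

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.01 | relative-intensity floor; also the presence cutoff for diagnostic ions |
| `tolerance` | ±0.5 u | nominal binning half-width (unit-resolution trap) |
| `margin` | 0.05 | top-1/top-2 similarity margin for a database decision |
| `near_zero` | 0.05 | pre-renormalisation residual maximum meaning "no second component" |
| `noise` | 0.1 | simulator lognormal sdlog |
| `branch_bias` | 0.97 | preferred-bond share at a branch point |

Similarity is cosine on nominal-binned, base-peak-normalised intensities;
only the ranking, never the absolute score, drives decisions. Subtraction
clips negative residuals to zero before renormalising, and the "no second
component" test is made on the *unrenormalised* residual maximum —
renormalising a near-zero residual would only amplify noise. Ties in
branch serialisation are broken canonically: the lowest acceptor position
continues the main chain, other branches are bracketed in descending
position order.

## Problem sizes used in the checks

The test-suite and the acceptance script run entirely on simulated data:
the full ≤5-residue structure panel for the mass-balance and
complementarity properties, all 36 linear and 12 branched trisaccharides
at zero noise, and four replicates of that 48-structure panel under
default noise with seeded jitter (192 simulations) for the round-trip
recovery rate, which must stay at or above 95%. The four compounds worked
through in full — panose, the β-(1→3)/β-(1→4) trisaccharide, isopanose
and cellotetraose — are asserted as exact string recoveries, including
isopanose's deliberately partial assignment.

## Known limitations

* Glucose only; other hexoses would need their own disaccharide
  databases (the logic generalises, the fingerprints do not).
* One glycan per spectral tree: co-isolated isomers of identical mass are
  out of scope, as for any MS-only method.
* The synthetic fingerprints are ordinal stand-ins; absolute channel
  ratios of real spectra are not modelled, so similarity *scores* (as
  opposed to rankings) carry no physical meaning.
* Branched pentasaccharides and larger are not covered; the 1→1 linkage
  and reducing-sugar triples have no (or assumed) rule support.
* Chromatography, acquisition timing and detection limits are
  instrument-bound and outside the package's scope.
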