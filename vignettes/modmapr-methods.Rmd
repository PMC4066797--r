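---
title: "Mapping tRNA modifications from mass spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping tRNA modifications from mass spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modmapr)
```

## The measurement model

A tRNA is a linear ribonucleotide polymer with a 5′-monophosphate and a
3′-hydroxyl. Every quantity this package computes reduces to elemental
formula arithmetic over that polymer:

* An oligonucleotide of $n$ residues has formula
  $\sum_i \mathrm{nucleoside}_i + (n-1)(\mathrm{HPO_3} - \mathrm{H_2O})$,
  plus one HPO$_3$ per phosphorylated terminus; a 2′,3′-cyclic phosphate is
  the linear 3′-phosphate minus one water.
* Electrospray produces deprotonated ions in negative mode, so
  $m/z = (M - z \cdot 1.007276)/z$. The proton mass, not the hydrogen
  atomic weight, is the correct charge carrier; using it reproduces
  observed fragment ions to the third decimal.
* Two mass scales coexist. Fragment and nucleoside work is *monoisotopic*
  (high-resolution instruments resolve the isotope envelope); intact-mass
  work is *average* (the envelope of a ~23 kDa RNA is unresolved on an ion
  trap, and deconvolution yields the envelope centroid). Monoisotopic
  masses use CODATA/NIST principal-isotope values, average masses IUPAC
  2021 standard atomic weights; both are hard-coded to six decimals.

The nucleoside registry (`default_registry()`) carries, per species, the
free-nucleoside formula and four behaviour flags that drive everything
downstream: RNase T1 cleavability (G and N2-methylguanosine cut; N1-
methylation, N2,N2-dimethylation and the queuosine base swap block the
enzyme), RNase A cleavability (all pyrimidine-ring residues, including
pseudouridine and the 5-substituted uridines; N1-cyanoethylation blocks),
CID base loss (N-glycosides only — pseudouridine's C–C glycosidic bond
cannot break this way), and acrylonitrile derivatizability (pseudouridine
N1 only). All flags are data: a different enzymology is an edited tibble,
not a code change.

## Digestion, matching, localization

`digest()` cuts 3′ of every cleavable residue. Products carry 5′-hydroxyl /
3′-phosphate chemistry; the molecule's own termini are inherited by the
terminal fragments. Two refinements matter in practice:

* **Partial modifications** (e.g. a sub-stoichiometric N2-methylguanosine)
  emit both the modified and unmodified fragment variants, flagged.
* **Missed cleavages** represent cleavage-*blocking* modifications: if a
  guanosine carries N1-methylguanosine the enzyme does not cut, and the
  observed fragment is the union of two reference fragments. The matcher
  therefore enumerates placements on missed-cleavage fragments under a
  consistency constraint — every skipped internal cut site must carry a
  blocking modification, and a fragment's own 3′-terminal cut site must
  remain cleavable. This single constraint is what makes a +CH$_2$ on a
  fragment-terminal guanosine assignable as m2G but never m1G, exactly the
  reasoning used when such digests are interpreted manually.

MS1 matching (`match_peaks()`) uses a 10 ppm tolerance by default
(high-resolution Orbitrap-class data) with an optional absolute fallback
(0.25–0.5 Da) for unit-resolution ion traps. The variable-modification
search is bounded at 3 per fragment in `match_config()` (the largest
co-occurring set in the mitochondrial catalog is 2, plus headroom). The
end-to-end pipeline deepens its own default to 4: a cleavage-blocking
modification merges two digest products, so clusters of co-occurring
modifications land on a single observed fragment more often than the
per-fragment statistics suggest, and a fragment whose enumeration would
exceed the placement bound backs off one level rather than failing the
run.

CID spectra are interpreted against the c/y/w/a−B product-ion series of
nucleic-acid anions. The complementarity identity
$c_i + y_{n-i} = M + \mathrm{H_2O}$ holds exactly at the formula level and
is asserted in the tests. `localize()` scores each candidate placement by
its matched *discriminating* ions — ions whose m/z differs between
candidates by more than the MS2 tolerance (0.3 Da, ion-trap CID) — and
returns a verdict of `unique`, `ambiguous` or `none`. Ties are never
broken by guessing.

## Pseudouridine and the cyanoethylation channel

Pseudouridine is an isomer of uridine: mass-silent, invisible to every
native measurement (the tests assert this as a formula identity).
Acrylonitrile adds C$_3$H$_3$N (+53.0265 Da) to its N1. The workflow
digests a native and a derivatized aliquot with RNase T1, pairs fragments
by span, and counts adducts as
$\Delta = \mathrm{round}((M_{ce} - M_{native})/53.0265)$. The per-span
counts sum to the molecule's pseudouridine count (a conservation law tested
on all fixtures), and placement within a span that has several uridines
comes from CID of the derivatized species. Derivatization is modelled as
complete; a partial-derivatization mode exists but is off, since detection
is qualitative.

## Intact-mass validation

`deconvolve()` re-implements charge-series deconvolution for centroided
peak lists: adjacent peaks of an ESI series are consecutive charge states,
so a grid search over the anchor charge finds the assignment whose implied
neutral masses agree best (minimum RMS), and reports their
intensity-weighted mean. Ties prefer the lower charge; an RMS above
`max_rms` is a rejection, not a result. The default charge range 5–40 suits
tRNA-sized molecules. For the shipped tRNA-Ala record the calculated
average mass is 23180.7 Da; deconvoluted measurements of this molecule run
about 2 Da lighter, a gap the validator reports but does not explain away.

## The synthetic-data generator

Raw spectra for this kind of study are generally not public, so every
pipeline stage is validated by *parameter recovery* on synthetic data whose
ground truth is known:

* `random_trna()` draws a 60–75 nt sequence and modifies each residue with
  probability 0.1 (the catalog's overall density is ~7.5%), drawing
  modifications eligible for the parent base.
* `simulate_trna_run()` emulates the full experimental bundle: a
  positive-mode nucleoside run, native RNase T1 and RNase A MS1 digests at
  charges 1–3, CID spectra of every fragment of ≥2 nt, and a paired
  cyanoethylated T1 channel.
* Noise is mass-proportional (2 ppm SD, typical externally calibrated
  Orbitrap accuracy) for the `orbitrap_like` profile and absolute
  (0.05 Da SD) for `ion_trap_like` and all MS2 spectra; dropout is
  Bernoulli per peak and contaminants Poisson, both 0 by default.
  Intensities are log-normal and deliberately carry no information.
* Every generator is a pure function of its inputs and seed.

What the simulation does *not* model — chromatographic retention, isotope
envelopes, intensity-dependent detection, adducts, incomplete digestion
beyond the configured missed cleavages — bounds what passing tests show:
they validate the interpretive logic (composition census → placement search
→ ion-ladder localization → differential derivatization), not robustness to
every artifact of real chromatography.

## Design choices in the identification pipeline

`identify_modifications()` mirrors the two-stage logic of manual
interpretation: the nucleoside census constrains which modifications may be
placed at all, MS1 matching proposes placements, and only MS2-confirmed
unique placements (or MS1-unique single-residue fragments, which cannot be
fragmented further) become site calls. Pseudouridines are accepted only
from the cyanoethylation channel. Several choices deserve justification:

* **Two nucleases.** Interpretation uses both the RNase T1 and the RNase A
  channel when available. A single digest leaves repeated identical
  fragments (a `CCG` occurring twice leaves a modification assignable to
  either copy); the second enzyme cuts at different residues and usually
  breaks the tie. Sites ambiguous in both digests are left uncalled — with
  random sequences this is the dominant, and irreducible, source of missed
  sites.
* **Positional isomers.** Species sharing a parent base and mass delta
  (3-methyl- vs 5-methylcytidine; the glycosyl-queuosines) are separated on
  instrument only chromatographically, which the peak-list abstraction
  drops. The search space (`default_search_mods()`) therefore carries one
  representative per isomer class; the same limitation applies to the
  census, where 1-methylguanosine and N2-methylguanosine share both
  nucleoside and base-ion masses and are disambiguated only later, by
  cleavage context.
* **Conservatism over coverage.** Any tie, conflict, or missing
  discriminating ion yields no call. On 50 seeded synthetic tRNAs at the
  default conditions the pipeline recovers ≥95% of modified sites with zero
  false positives; the misses are the duplicate-span and
  molecule-terminal-isomer cases above, plus fragments carrying more
  modifications than the placement bound.

Problem sizes used in the shipped tests: 50 records of 60–75 nt for the
end-to-end property, 25 random sequences of ≤15 nt against the brute-force
digestion oracle, 50 Monte-Carlo replicates for noisy deconvolution. These
are the sizes at which the checked statistics stabilize.

## The catalog fixtures

The package ships the complete per-site modification catalog of the 22
bovine mitochondrial tRNAs (125 entries over 118 distinct sites — the
2-thio and 2-methylthio species layer on top of their precursors at the
same site, the counting rule without which the totals do not reconcile),
the 22 anticodons with mature wobble symbols, and a fully annotated
tRNA-Ala record. Of tRNA-Ala's 72 residues, positions 1–10, 34–45 and
54–72 are fixed by the published worked-example fragments and the
anticodon; the remaining stretches are a reconstruction consistent with the
published base composition (U27 C9 A20 G16) and a cloverleaf pairing, and
are marked as such in the FASTA header. All headline statistics and
acceptance quantities depend only on the published segments and the
catalog, never on the reconstruction. Full-length sequences for the other
21 tRNAs are deliberately not shipped (they would have to be reconstructed
wholesale), which is why the genome-wide percent-modified figure is
computed only when the user supplies a total base count.

## Known limitations

* No retention-time modelling: co-eluting isomers are indistinguishable.
* No isotope-envelope simulation or deconvolution; MS1 works on centroided
  monoisotopic peaks, intact masses on average-mass centroids.
* Digestion kinetics are binary (complete, or the configured missed
  cleavages); nonspecific cleavage is out of scope.
* The wobble decoding rules implement the vertebrate mitochondrial code
  only.
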