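---
title: "Collagen fingerprint screening of murine rodents: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collagen fingerprint screening of murine rodents: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoomscreen)
```

This vignette is the package's account of its science: the mass model, the
spectral processing chain, the classification rule, what the synthetic
generator does and does not emulate, and the numerical choices made where
the method leaves them open.

## The mass model

Bone is dominated by collagen type I, whose two alpha chains survive
archaeological timescales. Trypsin cleaves C-terminal to Lys/Arg except
before Pro, and the resulting peptides, measured as singly protonated ions
on a MALDI-TOF instrument, form a peptide mass fingerprint. All masses in
the package are monoisotopic:

$$ m/z_{[M+H]^+} = \sum_i m_\text{residue}(a_i) + m_{H_2O} + m_{H^+}
   + h\,\delta_{OH} + d\,\delta_{deam} $$

with $\delta_{OH} = +15.9949$ Da per hydroxylation (hydroxyproline and
hydroxylysine, near-ubiquitous in collagen) and
$\delta_{deam} = +0.9840$ Da per deamidation of Asn/Gln (common in degraded
collagen). Modification *positions* are deliberately not tracked — mass is
position-independent and MALDI fingerprints cannot localise them — so a
peptide is a sequence plus modification counts. Counts are validated
against the number of modifiable residues.

The marker peptides behind the bundled panel fix their hydroxylation counts
by mass arithmetic: the murine-specific marker GAAGPPGATGFPGAAGR and its
conserved vertebrate homologue GSAGPPGATGFPGAAGR carry two hydroxylations
(1443.70 and 1459.69), GEPGPSGLPGPPGER carries three (1451.68), and the
GFSGLQGPPG(S/P)PGSPGEQGPSGASGPAGPR homologue pair carries three. For that
high-mass pair the table values in circulation (2695.4/2705.4) sit
0.15–0.17 Da above the monoisotopic computation (2695.23/2705.26) — an
offset consistent with observed, externally calibrated values rather than
theory. The panel therefore stores the reported values verbatim and lets
the 0.5 Da matching tolerance absorb the difference; nothing downstream
assumes the panel is theoretical.

Two identities make good unit-level oracles and are worth stating: the
1459.7→1443.7 shift is exactly $m_S - m_A$ (a single Ser→Ala substitution),
and the 2705→2695 shift exactly $m_P - m_S$.

## Spectral processing

**Noise.** The quality rule and peak picking both need a noise level.
Noise is estimated per m/z window (default 100 Da) as
$1.4826 \times \mathrm{MAD}$ of the intensities after subtracting a
running-median baseline (default 151 samples). The MAD is robust to the
peaks themselves as long as peaks occupy a minority of samples per window;
the 1.4826 factor makes it consistent for Gaussian noise. The baseline
window is deliberately much wider than any peak (a peak at FWHM 0.3 Da
spans ~30 samples at the default 0.01–0.05 Da grids) so peaks are treated
as outliers, not baseline.

**Peak picking.** Local maxima of the baseline-subtracted signal qualify
when they exceed `min_snr` (default 3) times the local noise *and* keep at
least `min_width = 3` consecutive samples above half-maximum. The width
criterion exists because a point-wise 3-sigma rule alone admits ~0.1% of
pure-noise samples; those excursions are single-sample spikes with no peak
shape, and requiring a half-maximum region suppresses them by roughly two
orders of magnitude while leaving any adequately sampled real peak
untouched. The assumption to respect is that the profile grid puts at least
three samples across a peak's FWHM. The centroid is the intensity-weighted
mean m/z over the half-maximum region, the reported intensity is the apex
signal, and S/N is apex over local noise. Everything is invariant to
rescaling the trace by a positive constant.

**Calibration.** MALDI plates are calibrated externally: a calibrant spot
containing five standard peptides (bradykinin 1–7, angiotensin II, P14R,
ACTH 18–39, oxidised insulin chain B; reference masses computed from their
sequences, with the two cysteic acids of oxidised chain B as a fixed
+95.97 Da) is measured, each calibrant is matched to its nearest observed
peak within `match_tolerance`, and a least-squares observed→reference model
(linear by default; quadratic optional) is fitted and applied to sample
spectra. Linear is the default because it survives missing calibrants (two
matches suffice) and because TOF drift over this mass range is dominated by
its affine component. Below the minimum number of matches the fit is
refused and spectra pass through unchanged, flagged. The default match
window of 0.5 Da mirrors the fingerprint search tolerance; a plate that has
drifted by more than that at the top of the range needs a wider window
passed explicitly, which the calibration report makes visible.

## The quality gate

A fingerprint is good enough for taxonomic work when **more than 10** peaks
above **m/z 2000** have **S/N above 3** — both inequalities strict, so
exactly ten qualifying peaks fail and a peak at S/N exactly 3 never
qualifies. The rationale for the m/z floor is that the high-mass region is
where collagen's diagnostic peptides live and where degraded samples fail
first. The gate is applied after calibration in the pipeline (the order is
configurable by calling the pieces directly; calibration moves m/z by far
less than the 2000 Da floor's granularity, so the choice is cosmetic in
practice).

## The marker panel and classifier

The reference panel is a taxon × slot table: each of the nine slots is a
homologous peptide position, and each cell a reference m/z. Slot-level
resolution is derived from the column structure — a slot where all taxa
agree is *conserved*, one that separates congeneric species is *species*
(slot 8: 2987.5 in *R. norvegicus* vs 2957.5 in *R. rattus*), the rest are
*genus*. The two *Apodemus* species share every slot and are carried as a
single genus-level row: that irresolvability is a property of the
fingerprint, not a software limit.

Matching is per slot: each taxon's slots are assigned observed peaks within
tolerance by maximum bipartite assignment preferring smaller |Δm/z|, then
higher intensity. This makes a single peak unable to satisfy two slots of
the same taxon, keeps the outcome invariant under peak-list permutation,
and (unlike greedy nearest-first) guarantees that enlarging the tolerance
never loses a match. At the default 0.5 Da tolerance, where adjacent slots
are at least 2 Da apart, it reduces exactly to per-slot nearest-peak
matching, and the per-taxon match counts equal a brute-force all-pairs
check — both are tested.

The assignment rule is an explicit operationalisation of what is otherwise
expert judgement, with every threshold exposed:

* a candidate needs at least `min_markers = 4` matched slots;
* the winner must lead the best taxon of any **other** genus by
  `margin = 1` slot — ties across genera are indeterminate;
* congeneric species tied on count degrade the call to genus;
* a species-level call additionally requires a matched slot whose reference
  value is unique in its column (slot 8 for the rats; slots 1, 5, 7, 8, 9
  for *Mus*).

Orthogonally to the verdict, a spectrum is flagged as a *murine candidate*
when the conserved murine marker (slot 2, 1443.7) matches while the
vertebrate counterpart 1459.7 is absent — the cheap first-pass screen that
makes batch triage fast to audit.

## Batch screening

`screen_batch()` drives manifest rows through
read → pick (if profile) → calibrate (optional) → gate → classify, and
guarantees conservation: every row ends as exactly one of quality-pass,
quality-fail or read-error, and unreadable files never abort the batch.
Positives join to specimen records (accession, morphological ID, westing /
northing / depth-or-stratum) for spatial reporting; the bundled Pin Hole
Cave specimen table exercises that join.

## The synthetic generator

`simulate_spectrum()` emulates a calibrated MALDI fingerprint: the marker
peaks of one panel taxon plus `background_peaks = 40` non-diagnostic
collagen peaks (a partial collagen fingerprint typically presents some
60–80 peptides; 40 background plus 9 markers sits deliberately at the lean
end of that), with

* Gaussian mass error (`mass_error_sd`, default 0.05 Da — representative of
  a well-calibrated TOF and the condition under which the recovery tests
  run);
* an affine calibration drift applied to all true masses;
* per-peak S/N drawn log-uniformly in `snr_range = c(5, 50)` and damped by
  an exponential decay in m/z (e-folding 2700 Da), the bounded analogue of
  the heavy-tailed intensity spread seen in real fingerprints;
* profile rendering as Gaussian peak shapes (FWHM 0.25 Da at m/z 2000,
  scaling linearly with m/z, i.e. constant resolving power) on a uniform
  0.05 Da grid over a constant `baseline_level = 10` plus Gaussian noise.
  The baseline offset matters: a detector-positive trace clipped at zero
  would half-rectify the noise and bias any MAD estimate.

Background masses are drawn uniformly on [800, 3500] Da but excluded from
±2 Da around *every* panel mass (and the 1459.7 counterpart), so
ground-truth labels are unambiguous by construction; `adversarial = TRUE`
lifts the exclusion for stress tests. Everything is deterministic under a
fixed seed.

What the generator does **not** emulate — isotope envelopes, detector
saturation, matrix clusters, mass-dependent resolution loss beyond the
linear FWHM model, correlated (chemical) noise, real collagen peptide mass
distributions — bounds what passing tests show: they demonstrate that the
pipeline's logic is correct under its stated error model, not that the
instrument-facing steps are tuned for any particular spectrometer.

## Problem sizes and numerical choices

The test suite runs the end-to-end recovery at 500 spectra (100 per taxon,
centroid mode, 0.05 Da mass error), which recovers 100% of labels at each
taxon's achievable resolution, and sweeps mass error over
{0.05, 0.2, 0.5, 1.0} Da at 50 spectra per level to confirm accuracy
degrades monotonically. Profile-mode fixtures use narrower m/z ranges to
keep grids small. Duplicate m/z rows merge by intensity sum (deterministic
and conservative); peak lists are kept strictly ascending everywhere;
centroid ties in slot assignment break by |Δm/z| then intensity then peak
order. Degenerate inputs are either rejected loudly (empty files,
non-numeric cells with the line named, unknown residues with the letter
named) or given a sanctioned representation (a zero-peak centroid spectrum
from picking an all-noise trace).

## Known limitations

* The panel asserts column homology; where a printed slot value repeats
  across distant taxa the package encodes the number without claiming the
  underlying peptides are identical.
* Internal (lock-mass) recalibration against conserved collagen peaks is
  not implemented; only external plate calibration is.
* No probabilistic assignment score: the classifier is a transparent
  counting rule, by design.
* mzML support is a minimal MS1 subset (64-bit floats, no compression) —
  enough for MALDI exports, not a general converter.
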