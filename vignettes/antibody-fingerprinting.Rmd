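---
title: "Methods: fingerprinting anti-Abeta antibody specificity"
author: "AbetaFingerprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprinting anti-Abeta antibody specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AbetaFingerprint)
```

# Scope and data model

This package models the computational stages of array-based antibody
fingerprinting for amyloid-beta (Aβ): peptide library design, normalized
binding analysis with core-motif calling, dose-response and 1:1 kinetic
fitting, and theoretical mass/pI annotation of Aβ variant panels. It
starts from probe-level intensity tables; spot-image segmentation and
quantification are upstream of the package, as are structural modelling
and wet-lab chemistry.

Aβ coordinates are integers in −23..51 with **no position 0**, matching
the convention in which Aβ(−3)-x denotes an N-terminally elongated
species and Aβ1 is the canonical N-terminal Asp. The 74-residue displayed
region corresponds bijectively to APP770 residues 649–722
(`abetaToApp770()` / `app770ToAbeta()`). `ModifiedPeptide` carries
per-residue modification tags (phospho on S/T/Y; pyroglutamate on E/Q at
position 1; D-stereo and iso-Asp on D) plus terminal states (free amine
or pyroglutamate-cyclized; free acid or amide), with validity enforced at
construction. The canonical text form uses bracket tags (`S[p]`, `E[pE]`,
`D[d]`, `D[iso]`, `-NH2`); the array shorthand in which `'2'` denotes
phospho-serine is accepted and emitted only in the explicit
`"array-digit"` dialect, because a bare digit is too lossy to serve as
the primary encoding.

# Library design

`tileSequence()` emits all contiguous windows (default width 15, step 1,
i.e. 14-residue overlap between neighbours), giving single-residue
epitope resolution over the displayed region: 74 residues yield 60
windows. `positionalScan()` replaces every position of an unmodified
wildtype with every other proteinogenic letter — cysteine included, since
an 18-mer producing 18 × 19 = 342 variants is only arithmetically
consistent with the full 20-letter alphabet — plus a single wildtype
reference probe. Probe ids encode provenance (scan name, position,
wildtype and substituted letter) so the analysis stage never re-parses
sequences. `ptmPanel()` pairs every modified peptide with an unmodified
control of identical residue string for head-to-head comparison.

# Normalization and core-motif calling

Replicates are aggregated by the arithmetic mean of raw intensities; no
background subtraction is applied unless a `background` column is
provided (then subtracted and floored at zero). Each substitution probe's
mean is divided by the wildtype probe's mean:

$$ r_{i,a} = \frac{\overline{I}(\text{variant } i \to a)}{\overline{I}(\text{wildtype})} $$

Ratios are not clipped above 1 — gains of binding are informative — and
display scaling is left to `heatmapMatrix()`, which min-max scales each
antibody independently to [0, 1]. Min-max (rather than max-only) scaling
was chosen because the arrays' blue-to-red rendering spans 0–1 per
antibody; this is a display decision only and never feeds back into
calls.

Two rules turn the matrix into a motif, both stated as ">50 %" rules and
implemented strictly:

* an exchange is **dominant negative** iff $r < 0.5$ (so $r = 0.49$ is
  flagged and the boundary $r = 0.50$ is not);
* a position is a **core** position iff at least `minCount = 10` of its
  19 exchanges are dominant negative — 10 being the smallest integer
  exceeding half of 19. An alternative reading ("more than 10", i.e. 11)
  exists in the field; we adopt the >50 %-of-exchanges definition and
  expose `minCount` as a configuration knob so the stricter count is one
  argument away.

The motif string shows the wildtype letter at core positions and `X`
elsewhere. Normalization, flags and motifs are invariant to rescaling any
one antibody's raw intensities — the property a per-antibody exposure
change must not break.

Degenerate inputs: a wildtype mean at or below `wtFloorFrac` (default
1 %) of the antibody's maximum probe mean refuses the matrix outright
instead of emitting unstable ratios; an incomplete scan is an error, not
an NA-filled matrix.

`variantImpactReport()` applies the same $r < 0.5$ threshold to classify
point exchanges as binding-reducing or tolerated, with built-in
familial-AD (A2V, A2T, H6R, D7H, D7N, K16Q, L17V) and rodent (R5G, Y10F)
sets; positions outside the scanned span are reported "not covered"
rather than guessed.

# Dose-response and kinetics

`fitTitration()` fits the Boltzmann sigmoid
$y = \text{bottom} + (\text{top} - \text{bottom}) / (1 + e^{(x_{50}-x)/\text{slope}})$
on $x = \log_{10}(\text{concentration})$ by Levenberg–Marquardt least
squares, slope unconstrained. At least 5 points spanning more than one
decade are required; a series whose amplitude is negligible (relative
range below $10^{-6}$) is flagged "no transition" and no EC50 is
reported. EC50 $= 10^{x_{50}}$ in the units of the input concentrations.
Selectivity between two series is the ratio of their EC50s, reported only
when both fits converge.

The kinetic model is the closed-form 1:1 Langmuir system with no
mass-transport, drift or bulk terms — nothing in the underlying assays
justifies more structure:

$$ R_\text{assoc}(t) = R_\text{eq}\,(1 - e^{-(k_\text{on} C + k_\text{off}) t}),
\qquad R_\text{eq} = \frac{R_\text{max} C}{C + K_D}, $$
$$ R_\text{dissoc}(t) = R(t_1)\, e^{-k_\text{off}(t - t_1)}, \qquad K_D = k_\text{off}/k_\text{on}. $$

`globalFit1to1()` shares a single (kon, koff, Rmax) across all traces and
both phases. Initialization is deterministic: koff from a log-linear fit
of the dissociation tail of the highest-concentration trace, kon from the
regression of per-trace observed rates on concentration, Rmax back-solved
from the end-of-association response. Parameters are optimized on the log
scale to keep them positive. Fewer than three distinct concentrations
triggers an "ill-conditioned" warning but still returns the fit, since a
single-trace estimate is sometimes all the data allow. Default phase
spans (1200 s association, 1500 s dissociation, 2 s sampling) mirror
common BLI protocols. `steadyStateKd()` fits
$R_\text{eq}(C) = R_\text{max} C / (K_D + C)$ and refuses flat,
saturated-only (fitted $K_D < \min C/50$) or linear-only
($K_D > 50 \max C$) data as unidentifiable; equilibrium reads are taken
as end-of-association responses, with the read window configurable by the
caller, since fitted-plateau and end-read conventions differ between
instruments.

The bundled `kineticPreset()`s (KD ≈ 4.1 nM, 1.3 µM, 1.4 nM, 8.7 nM)
echo affinity regimes reported for phospho-selective and biosimilar
antibody–peptide pairs; they parameterize the simulator for realistic
examples and are not reference results — raw sensorgrams for those
numbers are not publicly available, so they cannot be reproduced at the
desk and are not treated as targets anywhere in the package.

# Mass and isoelectric-point annotation

`peptideMass()` is additive: residue masses plus one water, plus
modification deltas (phospho +79.966331 Da mono; pyroglutamate
−18.010565 from Glu and −17.026549 from Gln; amide −0.984016; Asp
stereo/iso forms exactly 0), plus one proton for [M+H]+. Peak matching in
`assignPeaks()` uses **average** masses by default, appropriate for
4+ kDa peptides in MALDI reflector practice, with monoisotopic matching
one argument away; the matching tolerance defaults to 1.0 Da and the
centroid threshold to 3× the median intensity, both plain configuration
values since no instrument calibration model is bundled. Each detected
peak is assigned to the nearest panel mass within tolerance (ambiguous if
two qualify), and per-variant intensities are peak-height fractions of
the summed assigned heights — deliberately labelled semi-quantitative.

`isoelectricPoint()` bisects the Henderson–Hasselbalch net charge

$$ Q(\text{pH}) = \sum_{\text{basic } j} \frac{1}{1 + 10^{\,\text{pH} - pK_j}}
 - \sum_{\text{acidic } j} \frac{1}{1 + 10^{\,pK_j - \text{pH}}} $$

on (0, 14) to $|Q| < 10^{-6}$; $Q$ is strictly decreasing, so the pI is
unique whenever the sign changes. The default pKa table is the
Bjellqvist set (N-terminus 7.5, C-terminus 3.55; D 4.05, E 4.45, C 9.0,
Y 10.0, H 5.98, K 10.0, R 12.0), which reproduces the widely quoted
theoretical pI of 5.31 for Aβ1–40; the set is a swappable `PkaSet`
object (an EMBOSS-style alternative is bundled). Phosphate groups are
diprotic (pKa 1.2 and 6.5) and replace the esterified hydroxyl's own
ionization; pyroglutamate removes both the N-terminal amine and the
consumed Glu side-chain carboxyl; amidation removes the C-terminal
charge. Note that *apparent* pI values measured by capillary isoelectric
focusing against pI standards can deviate from these theoretical values
by a few tenths of a pH unit, particularly for N-truncated variants, so
theoretical and instrument pIs should be compared with that caveat in
mind.

# Synthetic data: what it does and does not emulate

The generators are pure functions of (parameters, seed) and write their
ground truth to sidecar JSON, so every stage is testable without raw
images. Defaults define the reference study conditions used throughout
the tests:

* **DMS arrays** (`simulateDmsArray`): an 18-mer Aβ1–18 scan with a
  planted 5-position core (Aβ 3–7), core effect ratio 0.1, wildtype level
  1000, 3 replicates, and multiplicative log-normal noise with σ = 0.2 —
  chemiluminescent readouts are positive and right-skewed, which a
  multiplicative model captures and an additive Gaussian would not.
  Replicate counts on the physical arrays are larger but unspecified
  ("copied in dozens"); 3 is a deliberately conservative default.
* **Titrations**: Boltzmann curves on a log-spaced grid with additive
  Gaussian noise.
* **Sensorgrams**: the closed-form 1:1 model plus additive Gaussian
  noise.
* **Spectra** (`simulateSpectrum`): Gaussian peaks (default FWHM 2 Da) at
  the panel's [M+H]+ masses with weights, constant baseline, optional
  center jitter and additive noise.

What they do *not* emulate: spot-level spatial artefacts, inter-array
batch effects, saturation of the chemiluminescent readout, antibody
cross-reactivity beyond the planted effect structure, mass-spectral
isotope envelopes, adducts and matrix clusters, or sensor drift. Passing
the recovery tests therefore demonstrates correctness of the analysis
chain under the stated noise model, not robustness to every failure mode
of real arrays.

# Numerical choices and problem sizes

All nonlinear fits use Levenberg–Marquardt (minpack.lm) with analytic
model evaluation and deterministic starts as described above; the pI
bisection runs at most 200 iterations (it converges in ~50). The test
suite exercises the pipeline at sizes chosen to probe the statistics
without waste: 100 seeded DMS arrays (343 probes × 3 replicates each) for
core-span recovery, 100 seeded 5-concentration sensorgram sets at 5 %
relative noise for KD recovery, 1000 random small matrices for
brute-force motif-caller equivalence, and 10–20 jittered ten-peak spectra
for assignment accuracy. The end-to-end `runPipeline()` run writes
byte-stable JSON/CSV outputs (no timestamps inside result files) so
identical configs and seeds reproduce identical results.

# Known limitations

* Core-motif calls inherit the thresholded-count rule's discreteness: a
  position with 9 strong and 10 weak knockdowns is not core, however
  close to the boundary. No per-substitution significance testing is
  attempted, since the procedure defines none.
* The 1:1 kinetic model cannot represent avidity or bivalent-analyte
  effects, which matter for IgG binding to multivalently displayed
  peptides; fitted KDs are model-conditional.
* Theoretical pIs assume context-free pKa values; charge-charge
  interactions and measured CIEF positions will differ.
* Peak assignment is height-based and single-charge ([M+H]+) only.
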