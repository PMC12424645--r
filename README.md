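# AbetaFingerprint

Fingerprinting the sequence and modification specificity of
anti-amyloid-beta (Aβ) antibodies.

Aβ peptides accumulate in Alzheimer's disease in a bewildering variety of
forms: N-terminally truncated (Aβ3-x, Aβ4-x, Aβ11-x) or elongated
(Aβ(−3)-x) species, pyroglutamate-cyclized AβpE3-x, Ser8/Ser26
phosphorylation, Asp1 stereo- and iso-forms, and familial-AD point
mutations (H6R, D7N, A2V, ...). Research, diagnostic and therapeutic
antibodies — including biosimilars of Aducanumab, Lecanemab and Donanemab —
differ sharply in which of these forms they recognize. This package
implements the computational side of an array-based fingerprinting
workflow that resolves those differences at single-residue resolution,
for anyone who designs peptide libraries, analyzes antibody binding data,
or needs theoretical mass/pI annotations for Aβ variant panels.

## What it computes

**Library design.** Overlapping tiling libraries (the arrayed APP770
649–722 region, Aβ −23..51, as 60 15-mers overlapping by 14), deep
positional-substitution scans (an 18-mer over the 20 proteinogenic
letters gives 18 × 19 = 342 variants plus the wildtype reference), and
PTM variant panels paired head-to-head with unmodified controls.

**Core-motif calling.** Raw probe intensities are replicate-averaged and
normalized against the wildtype probe,
*r*(i, a) = mean(variant) / mean(wildtype). An exchange is *dominant
negative* when it reduces binding by more than 50% (*r* < 0.5, strictly);
a position joins the *core motif* when more than half of its 19 exchanges
are dominant negative (count ≥ 10). Built-in reports classify
familial-AD (A2V, A2T, H6R, D7H, D7N, K16Q, L17V) and rodent (R5G, Y10F)
exchanges as binding-reducing or tolerated.

**Dose-response and kinetics.** Boltzmann sigmoid fits on
log₁₀(concentration) with EC50 = 10^x50 and selectivity ratios; 1:1
Langmuir sensorgram simulation and global (kon, koff, Rmax) fitting with
KD = koff/kon; steady-state saturation fits Req(C) = Rmax·C/(KD + C).

**Mass and pI annotation.** Monoisotopic/average masses of modified
peptides (phospho +79.96633 Da, pyroglutamate −18.010565 from Glu,
C-terminal amide −0.984016), [M+H]+ species, and theoretical isoelectric
points by bisection on the Henderson–Hasselbalch net-charge function
under the Bjellqvist pKa set. MALDI-style spectra are peak-picked and
assigned to the ten-member synthetic Aβ variant mixture used in IP-MS
experiments.

**Synthetic data.** Seedable generators emulate every input — planted-core
DMS arrays with multiplicative log-normal noise, Boltzmann titrations,
1:1 sensorgrams, Gaussian-peak spectra — each with a ground-truth sidecar,
so the full pipeline is testable without raw array images.

## Worked example

```r
library(AbetaFingerprint)

# Simulate a deep mutational scan of Abeta1-18 with a planted core at 3..7
truth <- dmsGroundTruth(seed = 42)          # effect 0.1, sigma 0.2
sim   <- simulateDmsArray(truth, replicates = 3)
m     <- normalizeToWildtype(sim$table, sim$library, "synthetic")
callCoreMotif(m)
#> CoreMotif: synthetic  XXEFRHDXXXXXXXXXXX  (core: 3,4,5,6,7)

variantImpactReport(m, c("H6R", "R5G", "A2V"))
#>  variant position wildtype substitution      ratio            class
#>      H6R        6        H            R 0.08644462 binding-reducing
#>      R5G        5        R            G 0.10265855 binding-reducing
#>      A2V        2        A            V 0.93101977        tolerated
```

The planted core span (Aβ 3–7, EFRHD) is recovered exactly: every
substitution inside it drops binding below half of wildtype, so all five
positions collect ≥ 10 dominant-negative calls; H6R falls inside the core
and is classified binding-reducing, A2V outside it is tolerated.

```r
panelTable(buildPanel())[, c("name", "mh_avg", "pi")]
#>                   name  mh_avg      pi
#>              Abeta1-40 4330.86 5.31110
#>              Abeta2-40 4215.78 5.77855
#>            AbetapE3-40 4126.68 5.76498
#>  pSer8-Abeta1-40-amide 4409.86 5.27623
#>  ...
```

Aβ1–40 has a theoretical pI of 5.31; removing Asp(1) raises it, and the
phospho-amide variant is slightly more acidic overall.

```r
p <- kineticPreset("phospho-high-affinity")   # KD 4.1 nM
grams <- lapply(c(2, 4, 8, 16, 32) * 1e-9, function(C)
  simulateSensorgram(p, C, noiseSd = 0.01, seed = 7))
globalFit1to1(grams)$params
#> KineticParams: kon = 2.002e+05 /M/s, koff = 0.0008216 /s,
#>                KD = 4.104e-09 M, Rmax = 1 RU
```

A global fit over five noisy 1200 s / 1500 s traces returns the simulator
parameters to a fraction of a percent.

A YAML-configured end-to-end run (`runPipeline("demo.yaml")`) chains the
stages and writes the DMS matrix (CSV), core motif and impact report
(JSON), titration fit (JSON) and peak assignments (CSV) with provenance;
a thin command-line wrapper lives at `inst/scripts/abetafp.R`.

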