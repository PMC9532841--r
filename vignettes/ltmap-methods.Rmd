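---
title: "Rational design and assay reduction for latarcin-derived antimicrobial peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rational design and assay reduction for latarcin-derived antimicrobial peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltmap)
```

## The problem and the peptides

Short cationic, amphipathic α-helical peptides disrupt bacterial membranes
and are a standing template for engineering antimicrobials. `ltmap`
implements the descriptor calculus and design procedure used to derive the
Lt-MAP analog family from latarcin-3a (Ltc-3a), a 20-residue cytolytic
peptide from the venom of the spider *Lachesana tarabaevi*, together with
the downstream reductions of the in vitro assays used to characterize such
analogs (broth microdilution MIC/MBC, crystal-violet biofilm MBIC,
hemolysis, resazurin viability and 4PL EC50 fitting).

The design template is the 13-residue helical core of the parent, residues
5–17 (`MAKKLKEYMEKLK`). Analogs are generated by substituting within a few
residue classes — Met and helix-face Ala to the aliphatics Leu/Ile, acidic
Glu to Lys — while keeping the amino-acid *composition* within roughly 30%
of the parent's and avoiding helix-breaking residues.

```{r}
descriptor_table(latarcin_peptides(include_fragment = TRUE))
```

## Descriptor conventions

Four descriptors summarize a candidate, each with a fixed convention chosen
to match standard practice for helical AMP design:

* **Net charge Z** — side chains only by default: (#K + #R) − (#D + #E),
  His neutral. A variant additionally counts the free N-terminal amine
  (+1), and optionally the free-acid C-terminus (−1); it exists because
  databases differ on whether termini are counted, and the parent's
  commonly quoted +6 corresponds to counting the N-terminal amine.
* **Mean hydrophobicity H** — arithmetic mean of per-residue values on the
  Fauchère–Pliška octanol scale (the HeliQuest default), reported to 3
  decimals. The Eisenberg consensus scale ships as an alternative
  (`hydrophobicity_scale("eisenberg")`) but is not the default: the
  Fauchère–Pliška convention is the one that reproduces the published
  descriptor set for these peptides.
* **Hydrophobic percentage H%** — 100 × #{A, C, F, I, L, M, V, W}/N,
  *truncated* toward zero (7/13 = 53.8 reports as 53; truncation rather
  than rounding is what the published values use).
* **Hydrophobic moment μH** — the Eisenberg vector sum
  μH = (1/N)·|Σₙ hₙ·exp(i·δ·(n−1))| with δ = 100°/residue, the ideal
  α-helix step (3.6 residues/turn). δ is configurable for 3₁₀ or π helices
  but only the 100° convention is validated against published values. The
  moment is invariant to the sign of δ and to reversal-with-negated-δ, and
  is exactly zero for any homopolymer whose length completes whole turns —
  both properties are tested.

The helical wheel (`wheel_projection()`) places residue *n* at angle
(n−1)·δ mod 360 and reports the hydrophobic face as the half-plane
perpendicular to the μH vector; for Lt-MAP3 all four leucines fall on that
face, the geometric signature the design aimed for.

## Mass and fragment calculus

`peptide_mass()` sums standard IUPAC residue masses plus one water
(average and monoisotopic tables; amidation of the C-terminus subtracts
0.98402 Da monoisotopic / 0.98476 Da average). `by_series()` produces only
singly charged, unmodified b and y ions — the ion types annotated in MALDI
LIFT spectra of these peptides — with the complementarity identity
bᵢ + y₍N−i₎ = [M+H]⁺ + proton holding to 1e−6 Da by construction.
`match_peaks()` assigns observed peaks to the nearest theoretical ion
within a tolerance that defaults to 0.5 Da, wide enough for externally
calibrated parental ions which deviate from theory by up to ≈0.3 Da in the
reference spectra. Chemistry note: although these peptides were assembled
on Rink amide resin (which normally yields amidated C-termini), the
published masses match free-acid termini within 0.1 Da, so `c_term`
defaults to `"free-acid"`.

## The design search

`enumerate_analogs()` makes the design procedure explicit and exhaustive:

1. per-position option sets from the substitution rules
   (`ltmap_substitution_rules()` reproduces the Lt-MAP classes), with a
   **helix guard** that refuses to *introduce* Pro or Gly (native ones are
   kept);
2. full enumeration of the option lattice when it contains ≤ 10⁶
   sequences (the Lt-MAP lattice has 600,000), otherwise seeded uniform
   sampling with identical filters;
3. a **composition-divergence** filter: divergence is a multiset distance,
   1 − Σₜ min(countₐ(t), count_b(t))/N, insensitive to rearrangement.
   Positional substitution counts cannot be what a "≤30% difference"
   constraint means here — Lt-MAP3 differs at 7/13 ≈ 54% of positions —
   while composition divergence gives 3–4 units (23–31%) for all three
   analogs, consistent with "approximately three residues modified".
   Strict mode enforces divergence ≤ 0.30 exactly (admits only Lt-MAP1);
   the default tolerant mode allows one extra composition unit,
   floor(0.30·N)+1 = 4 units at N = 13, admitting all three;
4. scoring: w_z·ΔZ + w_μ·ΔμH − w_h·dist(H, band), defaults
   w = (1, 0.5, 1) and band [0, 0.6]. The weights are this package's
   operationalization of "raise charge, reorganize amphipathicity, keep
   hydrophobicity moderate" — the original design reports no explicit
   objective function. Charge-dominant weights rank the published analogs
   Lt-MAP3 > Lt-MAP2 > Lt-MAP1, matching their observed antibacterial
   ranking. Ties break deterministically (higher Z, higher μH, lower
   divergence, sequence order), so identical inputs yield byte-identical
   output.

```{r}
frag <- extract_region(latarcin_peptides()$`Ltc-3a`, 5, 17)
cand <- enumerate_analogs(frag, design_constraints(), limit = 5)
cand
```

Identity between analogs and the parent core uses ungapped position-wise
counting for equal lengths (all the design comparisons are 13 vs 13),
rounded half-up to one decimal: 76.9 and 61.5% for Lt-MAP1/2. Lt-MAP3
recomputes to 46.2% (6/13); the occasionally quoted 46.6% is not
reproducible by position-wise counting and is reported as 46.2 here.
Unequal lengths fall back to a global alignment (match +1, mismatch 0,
linear gap −1, via Biostrings) — a documented general-purpose choice, not
calibrated against any particular alignment server.

## Assay reductions

* **MIC / MBIC** (`call_mic()`, `call_mbic()`): growth fraction per
  concentration is (mean reading − mean blank)/(mean growth control −
  mean blank), clamped to [0, 1]. "No significant growth" is
  operationalized as ≤ 10% of control growth — the assays themselves state
  no numeric rule, so the threshold is an explicit argument. The endpoint
  is the lowest concentration inhibited *with every higher concentration
  also inhibited* (monotone-from-the-top), which makes the call robust to
  isolated noisy wells below the endpoint; endpoints are always members of
  the tested series or censored as `">128"`, never interpolated.
* **MBC** (`call_mbc()`): same rule on zero-colony counts.
* **Hemolysis** (`hemolysis_percent()`): linear scale bracketed by the
  PBS blank (0%) and Triton X-100 (100%), clamped to [0, 100].
* **Viability** (`viability_percent()`): background-corrected single
  metabolic signal relative to untreated control; the dual-wavelength
  resazurin readout is reduced to one background-corrected signal since no
  published reduction formula exists for these data. Death% = 100 −
  viability; the screening flag `activity_flag()` is death ≥ 60%, the
  adapted NCI rule, with the boundary inclusive at exactly 60.
* **EC50** (`fit_dose_response()`): four-parameter logistic
  y = bottom + (top − bottom)/(1 + (x/EC50)^hill), least squares via
  Levenberg–Marquardt with EC50 on the log scale, a small grid of starting
  values (both hill signs unless forced), and optional fixed asymptotes.
  Constant responses are refused as unidentifiable rather than silently
  fitted. EC50 is reported in input units; conversion between μg/ml and μM
  uses the average mass from the mass module.

## What the synthetic generators emulate — and what they do not

The generators (`gen_mic_plate()`, `gen_biofilm_plate()`,
`gen_dose_response()`, `gen_peaklist()`) are seeded and bit-reproducible
given their `generator_spec()`. The plate model is deliberately two-level:
wells at or above the true endpoint draw near the sterile blank
(0.05 A600; biofilm 0.08 A595), wells below draw near the growth control
(0.5 A600; biofilm 0.8 A595), with Gaussian noise (default sd 0.02
absorbance units) truncated at zero, in triplicate over the standard
two-fold 128→4 μg/ml series. Dose–response curves are 4PL with top 100,
bottom 0 and a default hill of 1.5, the steep slopes typical of
membrane-lytic peptides; noise is additive in percentage points.

This exercises the callers — threshold logic, censoring, monotone rules,
fit identifiability — under controlled truth. It does *not* model growth
kinetics, inoculum effects, partial inhibition plateaus, or correlated
plate artifacts (edge effects, drift), so passing recovery tests shows the
reduction logic is correct, not that real plates are this clean. The
recovery experiments used in the tests and analysis scripts are sized to
run on one CPU in seconds-to-minutes: 100 seeded MIC plates at noise sd
0.02 (≥95 must recover the true MIC) and 200 seeded dose–response curves
with EC50 log-uniform in [4, 128] and 3-point noise (median relative error
≤10%), plus a noise-free curve at the 127 μg/ml hemolysis EC50 recovered
to within 1%.

## Numerical choices and known limitations

* H% truncates, identity rounds half-up to 1 decimal, H and μH round to 3
  decimals — each convention validated against the published table.
* A handful of published numbers are not reproducible under any single
  consistent convention and are intentionally *not* targeted: the parent's
  quoted Z = +6 (side chains give +5), the core fragment's μH of 0.699
  (recomputes to 0.669 under the convention that reproduces all four
  full-peptide moments), Lt-MAP3's 46.6% identity (position-wise counting
  gives 46.2%), and Lt-MAP2's calculated mass of 1630.2 Da (average mass
  recomputes to 1630.13, monoisotopic [M+H]⁺ to 1630.10). The package
  reports the recomputed values.
* Charge is pH-independent (no pKa model); secondary structure is assumed,
  not predicted; non-canonical and modified residues, cyclic peptides and
  disulfides are out of scope.
* The design scorer is a transparent linear objective, not an activity
  predictor — wet-lab assays remain the only ground truth for activity.
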