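---
title: "Modeling subsite preferences of chitin deacetylases and reading acetylation patterns back out"
author: "chitosim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling subsite preferences of chitin deacetylases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chitosim)
```

## The scientific problem

Chitosans are linear polysaccharides of N-acetylglucosamine (GlcNAc, written
`A`) and glucosamine (GlcN, written `D`). Their biological activity depends
not only on the fraction of acetylation (F~A~) and degree of polymerization
(DP) but on the *pattern* of acetylation (PA) — the arrangement of A and D
units along the chain. Chitin deacetylases (CDAs) remove (or, driven in
reverse by excess acetate, add) N-acetyl groups at nonrandom positions: the
enzyme binds the substrate across a groove of subsites, numbered relative to
the catalytic subsite 0 (negative toward the substrate's nonreducing end),
and each subsite prefers A or D units. Those preferences decide which
binding frames are populated and therefore where the chain is modified —
ultimately shaping block-wise versus alternating PAs.

`chitosim` implements this mechanistic picture as a simulation, together
with the analytics used to *measure* PAs: in silico chitinosanase
fingerprinting, MS^1^ quantification of partially acetylated
chitooligosaccharide (paCOS) species, MS^2^ B/Y-ion pattern deconvolution,
and the plate-screen analytics of a site-saturation mutagenesis (SSM)
enzyme library. All sequences are written nonreducing → reducing end, and
positions are 1-based from the nonreducing end.

## Sequences, compositions, and masses

A species with n~A~ GlcNAc and n~D~ GlcN units has the singly protonated
monoisotopic mass

$$ m/z = n_A \cdot 203.0794 + n_D \cdot 161.0688 + 18.0106 + 1.0073, $$

with residue masses computed from the monoisotopic atomic masses
(C 12, H 1.0078250319, N 14.0030740, O 15.9949146). The difference between
the residue masses is the acetyl group C~2~H~2~O, 42.0106 Da.

```{r masses}
round(c(A4 = mz_mh("A4"), A3D1 = mz_mh("A3D1"),
        A2D2 = mz_mh("A2D2"), A1D3 = mz_mh("A1D3")), 3)
```

These reproduce the standard MS^2^ target masses for the tetramer series to
the third decimal. Only the [M+H]^+^ adduct is modeled; Na/K adducts,
charge states beyond 1+, and isotope envelopes are out of scope.

## The subsite-preference simulator

A binding frame places the catalytic subsite 0 on a substrate position p;
the frame spans subsites −3…+2, the range implied by the three binding
modes observed on tetramers ([−2,+1], [−1,+2], [−3,0]). Its energy is

$$ E(p) = \sum_{s=-3}^{+2} \varepsilon_s(x_{p+s}), $$

where $\varepsilon_s(A)$ or $\varepsilon_s(D)$ is the preference energy of
the unit bound at subsite s and $\varepsilon_s(\text{empty})$ an occupancy
penalty where the chain does not cover the subsite. Energies are in kT
(β = 1; only ratios matter) and may be `Inf` for hard exclusions. One
catalytic event samples a frame with probability ∝ exp(−E) among the
eligible frames (positions holding A for deacetylation, D for
N-acetylation) and modifies the subsite-0 unit. The model is memoryless:
no processivity, no enzyme concentration, no time axis — trajectory
progress is indexed by F~A~, matching how polymer samples are
characterized. For oligomers, `product_distribution()` enumerates all event
paths exactly; `simulate_polymer()` is the Monte-Carlo path for long chains.

### The bundled presets

No subsite energies have been measured; the presets are qualitative
stand-ins whose contract is to reproduce the *direction* of the observed
product shifts, with magnitudes calibrated against one experimental
anchor (below):

| preset    | ε~A~(−2) | ε~A~(−1) | ε~D~(−1) | uncovered (−3…+2) |
|-----------|---------|---------|---------|--------------------|
| `neutral` | 0       | 0       | 0       | 0                  |
| `nm`      | −2      | −1      | 0       | 0.5, 1, 1, 1, 2, 0.5 |
| `H199K`   | −2      | −1.75   | 0       | same               |
| `H199Y`   | −2      | 0       | −0.75   | same               |

The GlcNAc preference at −2 and −1 makes `nm` deacetylate A4 mostly in
binding mode [−2,+1] (producing AADA) and, in the N-acetylation direction,
lay new A units next to existing ones — blocky PAs. `H199K` strengthens
the −1 preference (larger A-blocks); `H199Y` instead prefers GlcN at −1,
interleaving A and D (more alternating PAs, enriched A1D1 digest
products). The occupancy penalty is largest at +1 — the hydrophobic
pocket — so [−2,+1] beats [−3,0] on tetramers; soft (finite) energies let
N-acetylation of pure polyglucosamine initiate even with D at −2, as
observed (DDAD from D~4~).

Magnitudes were set so that the chitinosanase oligomeric fraction of
simulated chitosans at F~A~ 0.5 falls in the experimentally observed range
(roughly one third to one half of the signal at DP 2–14 for the blocky
enzymes); the first, stronger guesses (−4/−3 kT) produced chains so blocky
that nearly all digest fragments exceeded DP 14, which is outside the
regime the fingerprinting analytics can see.

```{r tetramer}
round(product_distribution("AAAA", profile_preset("nm"), "deacetylate", 1), 3)
```

## Chitinosanase fingerprinting

Chitinosanase cleaves chitosan after every D,A dimer — one unit past each
D→A block transition. Consequently every *interior* product carries exactly
the A- and D-unit counts of the originating A- and D-blocks; `chitosim`
verifies this block theorem against a run-length oracle. Terminal (leading
and trailing) fragments do not satisfy the theorem and are excluded from
the statistics (they are still reported); whether the real chromatograms
include them is not documented, so the exclusion is a package decision,
flagged in output.

From a fragment species table (species keyed by (DP, N(A)) — MS cannot
distinguish sequence isomers), the weight-average block sizes are

$$ block(A)_w = \frac{\sum_i DP_i\, I_i\, N(A)_i}{\sum_i DP_i\, I_i}, \qquad
   block(D)_w = \frac{\sum_i DP_i\, I_i\, N(D)_i}{\sum_i DP_i\, I_i}, $$

evaluated over species with DP 2–14 (the resolvable oligomer window), and
the oligomeric fraction is the share of total DP-weighted intensity inside
that window. Two weightings are exposed: `mass` (I ∝ count·DP, emulating
refractive-index peak areas; default) and `molar` (I ∝ count, MS-like).

A consequence worth knowing: for very blocky chains the fragments outgrow
the DP 2–14 window, so the windowed block(A)~w~ *saturates* — at F~A~ ≥ 0.5
it no longer separates the two blockiest presets (`H199K` vs `nm`), whose
experimental block sizes are close anyway. The package's ordering checks
therefore run at F~A~ 0.3–0.4.

## MS^1^ quantification and relative acetate release

`quantify()` matches centroided peaks to species targets within an absolute
tolerance (default 0.02 Da — appropriate for singly charged species over a
250 Da window) and normalizes matched intensities to relative amounts
(*ra*), assuming equal ionization response across species of equal DP and
including residual substrate in the denominator. The relative acetate
release for a substrate with n~D~ substrate GlcN units is

$$ rar = \sum_{k \ge 1} k \cdot ra_k, \qquad k = n_D(\text{product}) - n_D(\text{substrate}), $$

which specializes to rar~A4~ = ra~A3D1~ + 2·ra~A2D2~ and
rar~A3D1~ = ra~A2D2~ + 2·ra~A1D3~ + 3·ra~D4~ for the two assay substrates.

## MS^2^ pattern deconvolution

For a product of known composition, each candidate PA produces a B/Y
fragment ladder (B: nonreducing oxocarbenium, residues + proton; Y:
reducing-end-retaining, residues + water + proton; the B1 ion of an A unit
is the GlcNAc oxocarbenium at 204.087 Da). Sequence isomers share an m/z
whenever their fragment compositions agree, so the observable is the
(ion type, length, composition) species. `deconvolute()` fits observed
intensity shares onto the candidates' 0/1 incidence profiles by nonnegative
least squares (Lawson–Hanson, with a 10^−9^ ridge for degenerate fits),
drops uninformative ion species (identical across all candidates), and
renormalizes the solution to a distribution; the relative residual norm is
reported as a fit diagnostic.

Equal response per ion is a declared approximation — real cleavage-position
response factors are not modeled — so recovery guarantees are established
on synthetic data only. Exact recovery requires the incidence matrix to
have full column rank; the complete six-isomer A2D2 candidate set is rank
deficient (rank 5), in which case indistinguishable candidate classes are
reported rather than silently resolved.

```{r ms2}
obs <- synth_ms2(c(ADDA = 2/3, AADD = 1/3), noise_cv = 0, seed = 1)
round(deconvolute(obs, c("ADDA", "AADD")), 4)
```

## Plate-screen analytics

The SSM library enumerates all 19 non-wild-type substitutions at each
selected position (27 positions → 513 muteins). The fluorescamine assay
analytics per plate: an ordinary least-squares glucosamine standard curve
(0, 75, 150, 250 µM), conversion of well fluorescence to free-amine
concentration (negative values clamped to 0 and flagged), and division by
the mean of the plate's 4 nonmutated-enzyme control wells, which therefore
average to activity 1. Replicates (4 by default, across plates) are then
combined by `robust_mean()`:

* if the sample SD (n−1 denominator) exceeds 0.2 (on the normalized
  activity scale), the value furthest from the mean is removed — ties
  broken toward the larger value;
* the removal is kept only if it lowers the SD by more than 20%, otherwise
  it is withdrawn;
* at most one value is ever removed, and only when ≥3 replicates exist
  (removing one of two leaves the SD undefined).

The SD flavor and the tie-break are not specified by the assay description;
both choices are deterministic and logged in the output.

## Synthetic data and what passing tests mean

Every input has a seeded generator with emitted ground truth: Bernoulli and
deterministic (alternating/blocky) polymers, MS^1^ peak lists (Gaussian m/z
jitter, multiplicative intensity noise), MS^2^ ion tables (multiplicative
noise on the incidence mixture), and 96-well plates (additive concentration
noise, planted outlier wells, standards on a linear curve). The generators
emulate idealized instruments: no baseline, no co-elution, no adduct or
in-source-decay interference, no plate edge effects, no expression-level
variation between wells. Passing round-trip tests therefore demonstrates
the correctness of the algorithms under their stated assumptions, not
robustness to every artifact of real chromatograms and spectra.

## Numerical choices and problem sizes

* Boltzmann weights are computed after subtracting the minimum finite
  energy (overflow-safe); `Inf` energies give weight 0, and a state with no
  finite-energy frame raises a stalled-reaction error (or flag, for
  polymer trajectories).
* F~A~ along a trajectory is tracked as an integer A-count over DP, so stop
  criteria and checkpoints are exact.
* Exact enumeration (`product_distribution`) refuses state spaces beyond
  ~2×10^5^ and points to the Monte-Carlo path.
* Test and acceptance problem sizes — polymers of DP 400–800, 10–50 seeds,
  1,000-sequence property sweeps — were chosen so each statistical
  assertion has adequate power (orderings ≥3 SE apart) while the whole
  suite runs in minutes; they are the package's own defaults, stated here
  so results are interpreted at the right scale.

## Known limitations

* Subsite energies are not fitted to any binding-free-energy data; only
  directions of product shifts are meaningful, not magnitudes.
* No processivity, no multi-domain (carbohydrate-binding module) effects,
  no kinetics — a trajectory's "time" is its F~A~.
* Chitinosanase digestion is modeled as complete and strictly
  sequence-specific (after every D,A); incomplete digestion and subsite
  tolerance of the real hydrolase are not modeled.
* MS response factors are uniform within an assay; quantification across
  species of different DP is out of scope.
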