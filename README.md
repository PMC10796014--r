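# chitosim

Chitosans — polymers of N-acetylglucosamine (**A**) and glucosamine
(**D**) — owe much of their biology to their *pattern of acetylation*
(PA), not just their acetylation fraction F<sub>A</sub>. Chitin
deacetylases (CDAs) create nonrandom PAs because their binding grooves
prefer A or D units at specific subsites around the catalytic subsite 0.
`chitosim` is for enzyme engineers and glycobiologists who want to (i)
simulate how such subsite preferences shape oligomer products and polymer
PAs, and (ii) run the analytics that measure PAs from experimental
readouts.

The package covers, end to end on synthetic or user data:

* **Sequence/mass core** — A/D sequences (nonreducing → reducing), species
  compositions A<sub>n</sub>D<sub>m</sub>, exact monoisotopic [M+H]⁺
  masses (A3D1 = 789.325, A2D2 = 747.314, A1D3 = 705.304).
* **Subsite-preference simulator** — binding frames over subsites −3…+2
  weighted by per-subsite energies ε<sub>s</sub>(A/D/empty) in kT; one
  catalytic event samples a frame with probability ∝ exp(−E). Exact
  product distributions for oligomers, seeded Monte-Carlo trajectories
  (indexed by F<sub>A</sub>) for polymers; presets `neutral`, `nm`,
  `H199K`, `H199Y`.
* **Chitinosanase fingerprinting** — in silico digestion (cleave after
  every D,A), the block theorem (interior fragments carry the originating
  block sizes), weight-average block sizes
  block(A)<sub>w</sub> = Σ(DP·I·N(A)) / Σ(DP·I) over DP 2–14, and the
  oligomeric fraction.
* **MS¹ quantification** — tolerance-window peak matching to species
  targets, relative amounts, and relative acetate release
  (rar<sub>A4</sub> = ra<sub>A3D1</sub> + 2·ra<sub>A2D2</sub>, …).
* **MS² PA determination** — theoretical B/Y ladders per candidate
  pattern, ion-species incidence matrices, nonnegative-least-squares
  deconvolution of observed intensities into a pattern distribution.
* **SSM plate screen** — 19-substitution library enumeration (27 positions
  → 513 muteins), glucosamine standard regression, per-plate control
  normalization, and the SD > 0.2 outlier-elimination rule (withdrawn
  unless it improves the SD by > 20%).
* **Synthetic data** — seeded generators with emitted ground truth for
  every input above.

See `vignettes/chitosim-methods.Rmd` for the model, its assumptions, and
all numerical choices.

## Worked example

```r
library(chitosim)

parse_sequence("AADA")
#> pa_sequence: AADA (DP = 4, F_A = 0.750)

# Which product does the nonmutated enzyme make from chitin tetramer A4?
round(product_distribution("AAAA", profile_preset("nm"), "deacetylate", 1), 3)
#>  AAAD  AADA  ADAA  DAAA
#> 0.170 0.760 0.062 0.008
```

AADA dominates: with GlcNAc preferred at subsites −2/−1 and the +1 pocket
penalized when empty, binding mode [−2,+1] outcompetes the others.

```r
# MS1 quantification of an A4 assay, then relative acetate release
ra <- quantify(data.frame(mz = c(831.335, 789.325), intensity = c(110, 890)),
               c("A4", "A3D1"))
ra
#> relative amounts:
#>   A4 A3D1
#> 0.11 0.89
relative_acetate_release(unclass(ra)[1:2], "A4")
#> [1] 0.89
```

0.89 released acetates per substrate molecule — near-complete single
deacetylation (A4 → A3D1).

```r
# N-acetylate polyglucosamine to F_A 0.3, fingerprint the product
tr <- simulate_polymer(strrep("D", 1000), profile_preset("nm"),
                       "N-acetylate", target_fa = 0.3, seed = 1)
digest_and_score(tr$final)$stats
#> $blockA_w            2.84
#> $blockD_w            6.3
#> $oligomeric_fraction 0.442

digest_and_score(random_polymer(1000, 0.3, seed = 1))$stats
#> $blockA_w            1.73
#> $blockD_w            6.03
#> $oligomeric_fraction 0.86
```

At the same F<sub>A</sub>, the enzyme's GlcNAc preference at −2/−1 yields
A-blocks (block(A)<sub>w</sub> 2.84) well above the random chemical-control
pattern (1.73), and a smaller oligomeric fraction — the blocky chain's
fragments outgrow the DP 2–14 window.

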