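# sheetscan

Topological recognition of secondary-structure patterns — β-sheets,
α-helices and β-turns — in molecular dynamics trajectories of
multi-peptide systems, designed for coarse-grained (MARTINI-style,
one backbone bead per residue) as well as atomistic (Cα) input, where
hydrogen-bond-based assignment (DSSP/STRIDE) is unavailable.

It is aimed at people studying self-assembling peptides who need to
*track* structure over a trajectory: when β-sheet ladders emerge, in
which orientation and register, how aggregates grow, and how
helix/turn content trades off against sheet formation.

## Method

Each residue is reduced to one representative point. Per frame:

* **Contact maps.** β-contact: distance ≤ *d₀* (default 5.3 Å, the
  cross-β inter-strand spacing); α-contact: intra-molecular distance
  inside [5.1, 6.3] Å at sequence separation ≥ 3.
* **Kernel matching.** For molecules of equal length *RES*, the
  inter-molecular block *B* of the β map is scored against a library
  of 4·*RES* binary shift templates *L(k)* — parallel diagonals and
  antiparallel anti-diagonals at every register shift *s* — by
  normalized cross-correlation,

      NCC(B, K) = Σᵢⱼ Bᵢⱼ Kᵢⱼ / den(B, K),

  with den the printed product-of-sums form or (classification
  default) the geometric mean √(ΣB·ΣK). The argmax over the library
  gives each pair's orientation class (P, AP+, AP−) and shift.
* **Aggregates and domains.** Classified pairs are graph edges;
  clusters are connected components (DFS). Pairs sharing a strand are
  projected through reduced row/column vectors — a nonzero dot product
  confirms a three-strand sheet.
* **Helix/turn.** α-contacts at sequence gap 4–5 are helix contacts
  (their mean gap is the helix *pace*); other gaps are β-turn
  contacts. Contents are % residues covered by contact spans.
* **Time series.** Stability (% frames strictly above the series
  mean), transition entropy (KL divergence, bits, of the normalized
  β-turn series from the α series), mutual information, the
  antiparallel/parallel organizational index, and register-shift
  profiles.

Synthetic generators (`makeHelix`, `makeSheet`, `makeCoil`,
`makeSystem`, `morphTrajectory`) produce ground-truth systems so the
whole pipeline is validated closed-loop. See the vignette
(`vignettes/secondary-structure-patterns.Rmd`) for the full model,
parameter rationale and limitations.

## Worked example

A six-frame synthetic trajectory morphing five random coils into a
three-strand antiparallel ladder (register shift 1) plus two coils:

```r
library(sheetscan)

sheet <- makeSystem(synthSpec(motifs = c(rep("strand", 3), "coil", "coil"),
                              nRes = 8, orientation = "A", shift = 1, seed = 2))
coil  <- makeSystem(synthSpec(motifs = rep("coil", 5), nRes = 8, seed = 52))
writeFramesPDB(morphTrajectory(coil, sheet, nFrames = 6), "demo_system.pdb")

bundle <- analyzeTrajectory(runConfig("demo_system.pdb", outDir = "demo_out"))
bundle$frameMetrics
#>  frame alphaMean betaTurnMean peptidesInBeta orgIndex apToTotal
#>      0      25.0         40.0            0.0       NA         0
#>      1      50.0         67.5            0.0       NA         0
#>      2      57.5         60.0            0.0       NA         0
#>      3      32.5         67.5            0.4       NA         1
#>      4       0.0         35.0            0.4       NA         1
#>      5       0.0         17.5            0.6       NA         1

read.csv("demo_out/edges.csv") |> subset(frame == 5)
#>  frame p q nContacts orientation shift
#>      5 1 2         7         AP+     1
#>      5 2 3         7         AP+     1
```

Reading the output: no peptide is sheet-classified in the early coil
frames; from frame 3 the three strands come into register
(`peptidesInBeta` 3/5 = 0.6 by frame 5), every classified contact is
antiparallel (`apToTotal` = 1, `orgIndex` NA because no parallel
contacts exist to divide by), and both strand pairs are recovered with
the generator's exact orientation and register shift (AP+, shift 1)
with 7 = RES − shift contacts each. The transient α/turn content in
mid-morph frames is the interpolated geometry passing through the
contact bands. `demo_out/` also contains per-molecule tables,
per-frame alignment matrices, cluster memberships and shift profiles;
`plotResults("demo_out", "peptides_in_beta")` renders the series.

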