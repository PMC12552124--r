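# loopflex

Tools for studying the conformational flexibility of protein loops bounded
by two antiparallel β-strands — the structural motif shared by antibody and
T-cell receptor CDR3 loops. The package is aimed at structural
bioinformaticians and antibody engineers who want to (i) mine such loop
motifs from crystal structures, (ii) decide from structural ensembles
whether a loop is *flexible* (adopts several conformations) or *rigid*
(one well-evidenced conformation), and (iii) predict that label from a
single structure with a residue-graph neural classifier.

## What it computes

**Mining.** Secondary structure is assigned with an internal
Kabsch–Sander implementation (backbone H inferred from the preceding
peptide unit; a hydrogen bond is accepted when the electrostatic energy
`E = 0.084 (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) · 332 kcal/mol` falls below
−0.5 kcal/mol). Loops are the residue runs strictly between two
consecutive antiparallel β-strands that bridge to each other. Entries are
kept when solved by X-ray crystallography at resolution < 3.5 Å; loops
when they contain ≤ 3 strand/helix residues and no unresolved residues.
Antibody/TCR CDR3s are taken as IMGT positions 107–116 (insertions
included) from an externally supplied numbering map.

**Labelling.** Structures of the same loop (exact loop-sequence match, or
exact full-Fv match for antibodies/TCRs) are pairwise superposed on their
loop Cα atoms (Kabsch least-squares) and clustered by complete-linkage
agglomeration cut at τ = 1.25 Å, so every cluster ("conformation") has
intra-cluster RMSD ≤ 1.25 Å. A loop is **flexible** with ≥ 2
conformations, **rigid** with a single conformation seen in ≥ 5 distinct
PDB entries, otherwise **unknown**.

**Classification.** A loop plus its structural context (residues with Cα
within 10 Å) becomes a residue graph: 22-dimensional node features (20
amino acids + unknown + loop flag), Cα coordinates, distance-threshold
edges (10 Å) with 9-dimensional features (covalent flag + 8 Gaussian RBFs
over 0–10 Å). Three equivariant graph convolutional layers pass messages
over squared Cα distances — predictions are therefore invariant to all
E(3) transformations (rotations, translations, reflections) — followed by
pooling and a sigmoid readout. Training uses Adam, binary cross-entropy,
random edge dropout (p = 0.2), early stopping on validation PR AUC and
selection of the best of several restarts. Logistic baselines on loop
length and solvent exposure (residue count within 10 Å of the loop),
identity-aware 70–15–15 splitting (80 % aligned-identity cap between
splits for length-matched loops), and PR/ROC AUC metrics round out the
toolkit. A synthetic β-hairpin generator makes the entire pipeline
runnable and testable without any download.

## Worked example

Generate six crystal "entries" of one loop planted in two conformations
3 Å apart, mine the loops back out, and label the group:

```r
library(loopflex)

pg <- generate_loop_group(n_entries = 6, n_conformations = 2,
                          rmsd_target = 3, jitter = 0.1, seed = 42)
motifs <- unlist(lapply(pg$fixtures, function(f)
  mine_loops(f$structure, ann = f$ss)), recursive = FALSE)
motifs[[1]]
#> LoopMotif SG01 chain A [WTPEDCFV] length 8 (pdb_mined)

groups <- group_motifs(motifs)
groups[[1]]
#> LoopGroup [WTPEDCFV]: 6 member(s), 6 distinct entries

D <- rmsd_matrix(groups[[1]])
round(D, 2)
#>      [,1] [,2] [,3] [,4] [,5] [,6]
#> [1,] 0.00 2.58 0.24 2.54 0.19 2.54
#> [2,] 2.58 0.00 2.63 0.20 2.58 0.14
#> [3,] 0.24 2.63 0.00 2.58 0.22 2.59
#> [4,] 2.54 0.20 2.58 0.00 2.53 0.17
#> [5,] 0.19 2.58 0.22 2.53 0.00 2.54
#> [6,] 2.54 0.14 2.59 0.17 2.54 0.00

cluster_conformations(D, tau = 1.25)$assignment
#> [1] 1 2 1 2 1 2

label_groups(groups)
#>   group_key    origin loop_length n_members n_distinct_entries n_conformations
#> 1  WTPEDCFV pdb_mined           8         6                  6               2
#>      label
#> 1 flexible
```

The RMSD matrix shows the two planted conformations (within-state RMSD
≈ 0.2 Å from coordinate jitter, between-state ≈ 2.6 Å); complete-linkage
clustering at 1.25 Å separates them, and the group is labelled flexible.

To train the classifier on labelled graphs, use `loopflex()` (a standard
R modelling object with `print`, `summary`, `coef`, `predict`, `plot`,
`residuals` and `simulate` methods):

```r
pd  <- generate_planted_dataset(800, seed = 1)
fit <- loopflex(pd$graphs[1:600], val_graphs = pd$graphs[601:800],
                control = loopflex_control(hidden_dim = 16, n_restarts = 3,
                                           learning_rate = 5e-3,
                                           weight_decay = 3e-4,
                                           max_epochs = 80, patience = 12))
predict(fit, pd$graphs[1:5])           # flexibility scores in (0, 1)
```

A thin command-line front end over the same functions lives in
`inst/scripts/loopflex.R` (`simulate`, `mine`, `label`, `evaluate`
subcommands).

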