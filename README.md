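# complexqa

Interface quality assessment for models of biomolecular complexes.

`complexqa` compares a *model* of a complex — protein chains, nucleic-acid
chains, and/or small-molecule ligands — against a *reference* structure
(typically an experimental one) and scores the similarity of every
inter-chain interface. It is aimed at people benchmarking docking and
structure-prediction methods who need a single, continuous per-interface
quality number plus a whole-complex summary.

## The score

For each protein–protein or protein–nucleic interface in the reference,
three classic CAPRI-style measures are combined into one number in [0, 1]:

```
DockQ = 1/3 * ( fnat + 1/(1 + (iRMSD/a)^2) + 1/(1 + (LRMSD/b)^2) )
```

with scaling constants a = 1.5 Å and b = 8.5 Å, where

* **fnat** — fraction of the reference (native) residue–residue contacts
  (heavy atoms within 5 Å, 4 Å for peptides) reproduced by the model;
* **iRMSD** — backbone RMSD of the interface residues (any heavy-atom pair
  within 10 Å, Cβ–Cβ within 8 Å for peptides) after superposing on those
  same atoms;
* **LRMSD** — backbone RMSD of the smaller chain (ligand) after superposing
  on the larger chain (receptor).

Scores map onto the CAPRI classes: Incorrect < 0.23 ≤ Acceptable < 0.49 ≤
Medium < 0.80 ≤ High. The per-interface scores are averaged over all
reference interfaces into a **GlobalDockQ**; for complexes with symmetric
subunits the model-to-reference chain assignment is found by exhaustive
permutation within groups of sequence-identical chains, maximizing
GlobalDockQ. Small-molecule ligands are scored by **pocket-aligned LRMSD**
only (all-heavy-atom RMSD after superposing on the binding-pocket
backbone), minimized over symmetry-equivalent atom correspondences found
by element-labeled graph matching. Inter-chain clashes (heavy atoms closer
than 2 Å) are counted and reported.

## Worked example

Score a slightly perturbed homodimer model against its reference (both
written by the built-in fixture generator):

```r
library(complexqa)
fx <- make_complex(fixture_spec("A2", noise = c(B = 0.3), seed = 42))
write_fixture(fx$model, "model.pdb")
write_fixture(fx$reference, "reference.pdb")
rep <- run_complexqa("model.pdb", "reference.pdb", n_workers = 1)
print(rep)
```

```
model:     model.pdb
reference: reference.pdb
chain mapping: A->B B->A
mappings evaluated: 2

interface  model    fnat fnonnat  iRMSD  LRMSD  DockQ class      clashes
A:B        BA      1.000   0.000   0.51   0.50  0.964 High             0

GlobalDockQ: 0.964
```

Reading the output: every native contact of the A:B interface is present in
the model (`fnat` 1.000) with no spurious extras (`fnonnat` 0.000); the
0.3 Å coordinate noise on one chain shows up as a 0.51 Å interface RMSD and
0.50 Å ligand RMSD, giving DockQ 0.964 — a High-quality interface — and,
with a single interface, the same GlobalDockQ. Both chain mappings of the
homodimer were evaluated; for this two-fold-symmetric assembly the swapped
assignment `A->B B->A` ties with the identity and either is correct.

The same run is available from the shell:

```sh
exec/complexqa model.pdb reference.pdb --n-workers 1 --json report.json
```

with options `--mapping SPEC` (fix or constrain the chain mapping, e.g.
`AB:BA`, `A*:A*`, or `:AB` to restrict the reference chains), `--no-align`
(pair residues by author numbering instead of sequence alignment),
`--clash-cutoff`, `--peptide-max-len`.

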