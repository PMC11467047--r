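---
title: "Interface scoring: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface scoring: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexqa)
```

## The measure

`complexqa` assesses a model of a biomolecular complex by the similarity of
its inter-chain interfaces to those of a reference structure. For one
chain-pair interface the score is

$$\mathrm{DockQ} \;=\; \frac{1}{3}\left(\,f_\mathrm{nat}
  + \frac{1}{1+(\mathrm{iRMSD}/a)^2}
  + \frac{1}{1+(\mathrm{LRMSD}/b)^2}\right),
  \qquad a = 1.5\,\text{Å},\; b = 8.5\,\text{Å}.$$

The two scaling constants were calibrated (in the original formulation of
this measure) so that the continuous score tracks the four CAPRI quality
classes; they are part of the definition and are exposed in
`scoring_constants()` but not meant to be changed. Each term lies in
$[0,1]$, so the score does too: 1 only for a perfect interface (every
native contact reproduced, zero interface and ligand RMSD), approaching 0
for a fully dissociated or misdocked pair.

All distance computations are over **heavy atoms**. Hydrogens (and
deuteriums) are dropped at parse time; waters are removed; of alternate
locations only the highest-occupancy conformer is kept (ties resolve to the
blank altloc, then `A`, then file order, so parses are deterministic); only
the first model of a multi-model file is read.

## Definitions and tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `contact_cutoff` | 5.0 Å | two residues in different chains are in contact when any heavy-atom pair is within this distance |
| `contact_cutoff_peptide` | 4.0 Å | contact cutoff when either chain is a peptide |
| `interface_cutoff` | 10.0 Å | heavy-atom distance defining interface residues for the iRMSD |
| `interface_cutoff_peptide_cb` | 8.0 Å | Cβ–Cβ distance (Cα for glycine) defining interface residues when either chain is a peptide |
| `clash_cutoff` | 2.0 Å | inter-chain heavy-atom pairs closer than this are counted as clashes |
| `peptide_max_len` | 20 | amino-acid chains of at most this many residues are peptides |
| `identity_threshold` | 0.90 | sequence identity above which two chains are copies of the same subunit |
| `covalent_tolerance` | 0.4 Å | slack on covalent-radius sums for ligand bond perception |
| `match_cap` | 10000 | maximum ligand-graph isomorphisms enumerated before requiring a user mapping |

**fnat** is the fraction of *native* contacts reproduced: a reference
contact counts when the model residues paired to its two reference residues
are in contact in the model. The prose of the source method description can
also be read with the model-contact denominator; we follow the definition
sentence and the CAPRI convention (native denominator) and report the
model-denominator information separately as `fnonnat`, the fraction of
model contacts with no native counterpart, so either convention is
recoverable. Model contacts involving unmapped residues are non-native by
definition. A reference chain pair with *no* native contact is not an
interface; scoring it is an error rather than a silent zero.

Because a model that collapses all atoms onto each other would reach
fnat = 1, the number of inter-chain clashes is always counted and reported.
The 2.0 Å default is about the shortest covalent bond length: non-bonded
atoms can never be that close in a physically meaningful model.

**iRMSD** selects interface residues on the *reference*, maps them into the
model through the residue correspondence, gathers the backbone atoms
present in both structures (N, CA, C, O for amino acids; P, OP1, OP2,
O2′–O5′, C1′–C5′ for nucleotides — the primed sugar/phosphate atoms, since
unprimed O2/C5 are base atoms), superposes model on reference over exactly
those atoms (SVD-based least squares, proper rotation enforced), and
reports the RMSD. Superposition set and evaluation set coincide, per the
original convention. Missing atoms are handled by intersection semantics —
whatever is present in both paired residues contributes — with the skipped
count reported and a warning raised.

**LRMSD** declares the larger reference chain (by residue count) the
receptor, ties going to the first chain of the pair in reference order,
superposes the model on the reference over all mapped receptor backbone
atoms and reports the ligand-chain backbone RMSD under that transform.

**CAPRI classes** use half-open boundaries
Incorrect $< 0.23 \le$ Acceptable $< 0.49 \le$ Medium $< 0.80 \le$ High,
stored in the constants object rather than hard-coded.

## Residue correspondence

Model and reference residues are paired per chain pair either by **sequence
alignment** (default) or by **author numbering** (number + insertion code).
Alignment is global with free end gaps, identity scoring (match 1,
mismatch 0) and affine gap penalties (open 10, extend 0.5), via
`Biostrings::pairwiseAlignment`; because model and reference are
near-identical sequences, an identity scheme suffices and is deterministic.
Mismatched residues at aligned columns stay paired — models may carry point
mutations — and the mismatch count is reported. Unpaired residues are
excluded from every downstream computation. Test code verifies alignment
score optimality against exhaustive enumeration of all alignment paths on
short strings.

## Small-molecule ligands

Ligand atoms carry no canonical order, so a model/reference atom
correspondence cannot rely on names. Each ligand becomes an element-labeled
graph whose edges join atoms within the sum of their single-bond covalent
radii (Cordero et al. 2008 consensus values, bundled as data) plus 0.4 Å of
slack; bond orders are ignored, geometry resolves the rest. All
element- and adjacency-preserving bijections are enumerated with igraph's
VF2 matcher, and the reported **pocket-aligned LRMSD** is the minimum, over
those bijections, of the all-heavy-atom RMSD after superposing the model on
the reference over the backbone of the binding pocket — the reference
receptor residues with any heavy atom within 10 Å of the ligand (the
interface cutoff, reused for consistency; the source description names the
"receptor interface" without a cutoff, and backbone superposition was
chosen over all-atom as the convention consistent with the polymer
measures). Symmetric molecules are thereby scored on their best equivalent
atom assignment; non-isomorphic ligands fail loudly rather than scoring
silently; a molecule with more than `match_cap` self-matches requires an
explicit user mapping. Only the LRMSD is reported for small molecules —
fnat, iRMSD and DockQ are undefined for them.

## Multiple interfaces and chain mapping

Every reference chain pair with at least one native contact is an
interface. **GlobalDockQ** is the arithmetic mean of DockQ over all
reference *polymer* interfaces; an interface whose chain is missing from
the model contributes 0, so incomplete models are penalized. Ligand
interfaces are reported with their LRMSD only and excluded from the mean.
Interfaces present only in the model are not scored — the reference defines
what should exist.

For complexes with several copies of the same subunit the chain assignment
matters. Chains are grouped into equivalence classes (sequence identity
≥ 90% over the aligned region; identical component code for ligands — the
threshold is a package choice, as the source method names none), and all
injective assignments within matched groups are enumerated exhaustively —
$k!$ for a homomer of $k$ copies. Each candidate's objective is the mean
over reference interfaces of the interface DockQ, with ligand interfaces
entering through the surrogate $1/(1+(\mathrm{LRMSD}/b)^2)$ so that
equivalent ligand copies are also assigned optimally; the surrogate is
never reported as a DockQ. Since an interface score depends only on the
(model pair, reference pair) quadruple and not on the rest of the mapping,
scores are memoized and each quadruple is computed at most once; the
candidate scan then only combines cached numbers. Cache filling can run on
several forked workers (default 8, matching the tool this design follows);
results are identical for any worker count, and ties between
equal-scoring mappings break to the first candidate in the deterministic
enumeration order. The search is exhaustive by design — no greedy
shortcuts — so its cost grows factorially; in this pure-R implementation a
homotetramer search is interactive-fast while a full A8 scan (40320
candidates) takes minutes, which is why the tests exercise enumeration at
A2–A4 and check the A7/A8 counts analytically.

## The synthetic-data generator

`make_complex()` builds reference complexes from idealized geometry: rigid
per-residue templates (N, CA, C, O, Cβ) on an α-helical Cα trace for
proteins, a simplified sugar–phosphate template on a wider helix for
single-stranded DNA, and hand-placed toy ligands (linear O=C=O, branched
urea, a symmetric four-carbon ring) at standard bond lengths. Chains are
arranged on a ring whose radius is solved by bisection so adjacent chains
sit at a 3.5 Å minimum heavy-atom separation — inside both contact cutoffs,
well outside the clash cutoff — guaranteeing every generated dimer is a
scoreable, clash-free interface by construction. Models derive from the
reference by per-chain rigid transforms, Gaussian coordinate noise and/or
chain relabeling, with the ground-truth mapping returned; the same spec and
seed give byte-identical files.

What a green test on these fixtures establishes: the geometry of the
definitions (cutoffs, superpositions, set arithmetic, combinatorics) is
implemented correctly, with exact ground truth. What it does not establish:
behavior on real structures with missing residues and atoms, alternate
conformations, modified residues beyond the common table, or physically
packed side chains — real side-chain geometry is *not* emulated, and ring
placement is not a docking pose. The parser-level features (altlocs,
waters, multi-model files, ligand/polymer chain sharing) are therefore
tested on small hand-written files instead.

## Numerical choices and degenerate inputs

* Superposition uses the SVD formulation with the determinant correction,
  so reflections are never returned; fewer than 3 paired points is an
  error. The test suite checks it against an independent quaternion
  (closed-form eigenvalue) implementation to 1e-6.
* Contact and interface detection are computed from one vectorized
  cross-distance matrix, chunked to bound memory; results are required to
  equal brute-force all-pairs enumeration exactly, and the tests enforce
  that on every fixture.
* A homomer whose assembly is symmetric has several score-equal chain
  mappings (a C2 homodimer's swap is a symmetry operation); the tool
  returns the first optimum in enumeration order and the tie is genuine,
  not an error.
* An empty residue correspondence, an empty reference interface set, an
  empty ligand pocket, a non-isomorphic ligand pair and a mixed
  polymer-type chain all raise errors naming the chains involved; nothing
  degrades to a partial score.
* Modified residues from a small common table (MSE, SEP, TPO, …) map to
  their parent one-letter code; other polymeric unknowns become `X`
  (protein) or `N` (nucleic) and still align.

## Known limitations

* Ligands are matched on connectivity and element only; stereochemistry
  that connectivity cannot see is resolved by the RMSD minimization, not by
  chemistry. Multi-residue non-polymer entities (glycans) are out of scope.
* Residue-numbering mode requires exact author numbering agreement;
  insertion-code conventions differing between files will unpair residues.
* The exhaustive mapping search is factorial by design; very high copy
  numbers need `--mapping` constraints.
* GlobalDockQ is undefined (reported `NA`) for a reference whose only
  interfaces involve small molecules, since ligands carry no DockQ.
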