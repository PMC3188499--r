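---
title: "Methods: structure-based Cxxx binding-specificity prediction"
author: "caaxbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based Cxxx binding-specificity prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caaxbind)
```

## The problem

Protein farnesyltransferase (FTase) attaches a 15-carbon isoprenoid to a
cysteine thiol near the C-terminus of substrate proteins. Recognition is
dominated by the last four residues — the Ca~1~a~2~X (here: Cxxx) motif —
but the sequence rules are broader than the classical
"cysteine + two aliphatics + S/M/Q/A" description. Because the peptide
binding pocket is structurally well characterised, binding specificity can
be estimated by physical modeling instead of sequence statistics: thread a
candidate tetrapeptide onto the backbone of a peptide seen in a solved
receptor complex, rebuild and optimise its side chains, relax the pose
under restraints that conserve the invariant binding geometry, and read
the resulting energy as a binding score. `caaxbind` implements that
protocol end to end, together with the machinery needed to evaluate it
(ROC/AUC on labeled peptide sets), scan sequence space and proteomes, and
generate a fully synthetic test system.

## The pipeline

`scoreSequence()` runs four stages, all deterministic given the seed:

1. **Threading** (`threadSequence`). The template peptide backbone
   (N, CA, C, O and the C-terminal OXT) is copied bitwise; residue types
   are replaced by the requested Cxxx sequence; side chains are built from
   ideal internal coordinates (NeRF construction; Engh–Huber-style bond
   lengths and angles, CB improper +122.55° for L-chirality) at the first
   rotamer of the library.
2. **Packing** (`packSidechains`). Peptide side chains are optimised over
   a coarse, backbone-independent rotamer library (gauche+/gauche−/trans
   sp³ combinations plus standard aromatic and sp² terminal values,
   shipped as a plain-text table users can replace). `extraChi = TRUE`
   adds ±10° sub-rotamers on χ1 and χ2. When the combination count is at
   most `limit` (default 10⁵) all combinations are enumerated through
   precomputed self/pair energy tables, which makes the search exactly
   equal to brute force; above the limit a seeded simulated annealing
   (geometric cooling, position-wise Metropolis sweeps) takes over. The
   current side chains always compete, so packing can never raise the
   objective; ties resolve to the lowest candidate index. The receptor
   stays fixed at this stage.
3. **Minimization** (`minimizePose`). A Davidon–Fletcher–Powell
   quasi-Newton minimizer (implemented in `dfpMinimize`, Armijo
   backtracking line search, absolute objective tolerance 10⁻⁴ by
   default) relaxes the pose in torsion space over exactly this set of
   degrees of freedom: all peptide φ/ψ/ω and χ angles, the peptide's
   rigid-body placement (6 DOF), the χ angles of receptor interface side
   chains (Cβ within 8 Å of any peptide atom; Cα proxy for glycine), and
   the ligand's rotatable dihedrals. The receptor backbone and
   non-interface side chains never move. ω angles are minimized freely;
   starting from the planar template they stay near 180° in practice.
   Gradients are central finite differences of the full
   torsion-to-Cartesian map, evaluated in compiled code.
4. **Scoring** (`scorePose` + `peptideScore`). The reported score is the
   summed energy contribution of the four peptide residues (pair terms
   attributed half/half to their two residues), optionally minus a
   per-amino-acid reference constant. The shipped reference table is all
   zeros — reference energies are a design-calibration device and no
   published values exist for this energy model; `calibrateThresholds`
   plays the equivalent role at the classification step.

Classification compares the peptide score with two thresholds
(`ClassifierConfig`): at or below the stringent threshold →
`strong_binder`; at or below the loose threshold → `binder`; otherwise
`non_binder`. Scores exactly at a threshold take the more favorable class
— the tie rule is part of the contract and mirrored by
`ratesAtThreshold`.

## Constraints: conserving the invariant binding geometry

Three structural features of the complex are invariant across solved
structures: a hydrogen bond from the peptide's C-terminal carboxylate to
a glutamine-amide partner on the receptor's α-side, a hydrogen bond from
the a₂ backbone carbonyl oxygen to an arginine-guanidinium partner on the
β-side, and the coordination of the cysteine Sγ at the catalytic-metal
site. The metal itself is not modeled; instead `deriveConstraints`
measures, in the template, the five distances — carboxylate-O↔Gln anchor,
a₂-O↔Arg anchor, and Sγ to each of the three coordination-site side-chain
atoms — and turns them into pure harmonic restraints
$\sum_k ((d_k - d_{0,k})/\sigma)^2$ with σ = 0.1 Å by default (0.25 Å is
a documented softer setting). The restraint sum enters the minimization
objective with weight 1.0 (configurable via the energy function's
`constraint` weight). The three Sγ-coordination pairs are excluded from
the nonbonded energy, exactly as a bonded pair would be: they model a
coordination bond, and leaving Lennard-Jones active at 2.3 Å would bury
the signal under repulsion that the constraint is meant to replace. The
two hydrogen-bond anchor pairs keep their nonbonded terms (they are at
ordinary hydrogen-bond distance).

Which carboxylate oxygen, and which anchor side-chain atom, defines each
hydrogen bond is not uniquely determined by structure alone; anchors are
therefore configuration (`chain:resno:atom` addresses in the YAML
`template` block), and the carboxylate oxygen defaults to whichever of
O/OXT lies nearer the Gln anchor in the template.

## The energy model

The paper-scale protocol this package re-implements was originally scored
with a large molecular-modeling suite's energy function. That function is
not reproducible bit-wise, so `caaxbind` defines its own small,
self-contained, decomposable model (all quantities in dimensionless
energy units):

* **Lennard-Jones** 6–12 with pair minimum at $r_{min,i}+r_{min,j}$,
  split Rosetta-style into attractive and repulsive buckets, with the
  repulsion continued *linearly* below 0.6 σ so that clashed starting
  structures still have finite, smoothly decreasing energy.
* **Hydrogen bonds**: a Gaussian distance well centred at 2.9 Å (width
  0.35 Å) between donor and acceptor heavy atoms, modulated by the
  squared cosine half-angle of the base–donor–acceptor geometry. Crystal
  structures carry no hydrogens, so donor directionality is inferred from
  the donor's bonded heavy-atom base at scoring time.
* **Implicit solvation**: a Gaussian-exclusion (Lazaridis–Karplus-style)
  pair term. Polar and charged atoms carry negative solvation free
  energies — burying them costs energy — while carbon carries a small
  positive one, rewarding hydrophobic contact.
* **Electrostatics**: Coulomb with distance-dependent dielectric
  ε(r) = 4r.
* All pair terms share an 8 Å cutoff with a smooth switching function
  from 5.5 Å, so energies and gradients are continuous at the cutoff.
  Pairs within three bonds (1-2, 1-3, 1-4) are excluded.

Default term weights (`lj_attr` 1.0, `lj_rep` 0.55, `hbond` 1.5, `solv`
1.0, `elec` 0.15, `constraint` 1.0) and the per-type parameter table
(`inst/extdata/atom_params.tsv`) were chosen once so that typical
tetrapeptide scores fall in the same few-energy-unit range as the
published protocol. **Absolute scores are not transferable** between this
model and any external force field: the conventional −0.4 / −1.1
classification thresholds are retained only as interface-compatible
defaults, and `calibrateThresholds` re-derives operating points from a
labeled score set — by maximizing Youden's J, or against an explicit
false-positive-rate bound.

## Evaluation conventions

Scores are energies, so **lower means binder** everywhere: ROC curves
call a peptide positive when its score is at or below the moving
threshold. Most ROC libraries assume the opposite orientation — when
cross-checking with such a library, flip the direction. `rocCurve`
computes the AUC by the trapezoid rule and verifies it internally against
the concordant-pair (Mann–Whitney) formulation with ties counted ½; the
two must agree to 10⁻⁹ or the function aborts.

## The synthetic test system

`makeToyTemplate()` builds a deterministic, fully synthetic
receptor–peptide complex so that every stage of the pipeline can run and
be tested without any external structure:

* an extended CNIQ tetrapeptide (φ −120°, ψ +130°) with its C-terminal
  carboxylate;
* a Gln side chain whose amide nitrogen sits exactly `hbondDistance`
  (2.8 Å) from the carboxylate oxygen, and an Arg guanidinium nitrogen
  2.8 Å from the a₂ carbonyl oxygen, approaching tilted away from the
  X-reading pocket;
* a Cys/Ser/Thr triad whose terminal side-chain atoms sit
  `thiolDistance` (2.3 Å) from the peptide Sγ on a 45° cone — terminal
  atoms are used so no ring or branch atom protrudes past the
  coordination contact;
* a ring of hydrophobic walls (Leu/Ile/Phe/Leu) around the a₂ side chain,
  an eight-carbon hydrophobic probe ligand filling the remaining a₂
  sector, a small X-reading pocket (Ser/Leu/Val), an open solvent-facing
  a₁ side, and an alanine outer shell up to `pocketSize` residues;
* placement is clash-checked: each residue's free roll angle is chosen
  (from 24 deterministic candidates) to maximise clearance, shell
  residues back off radially until clear, and a deterministic relief
  loop translates any remaining non-anchor residue away from its
  tightest contact. The five anchor residues never move, so the
  constraint geometry is exact by construction.

`makeLabeledPeptides()` draws positives from binder-biased position
distributions (aliphatic-leaning a₂, small/polar X) and negatives from an
anti-biased distribution concentrated on charged and polar residues at
the buried a₂ and X positions. These biases are the generator's
*synthetic ground truth*, not a fitted biological model. Two deliberate
differences from real data follow:

* The toy pocket penalises buried charge (solvation + electrostatics) but
  cannot sterically exclude bulky aromatics: its walls are rigid but the
  pocket is open enough that a tryptophan finds favorable hydrophobic
  contacts. Real non-substrates include sterically excluded sequences;
  the synthetic negative class therefore encodes charge/polarity
  mismatch only.
* Real reactivity data distinguish multiple- from single-turnover
  substrates; the generator emits only a binary binder/non-binder truth.

Passing the synthetic benchmark therefore demonstrates that the pipeline
machinery — threading, packing, constrained minimization, scoring,
calibration — extracts a designed physical signal at realistic problem
sizes. It does not certify accuracy on experimental FTase data, which
would require the published peptide tables and a template derived from a
solved structure.

## Numerical choices and degenerate inputs

* Packing tie-breaks: equal-energy rotamer assignments resolve to the
  lowest candidate index; the exhaustive path is seed-free (verified by
  running with different seeds).
* Minimization: accepted line-search steps never increase the objective;
  convergence is declared when the absolute objective change drops below
  the tolerance; non-convergence at `maxIter` is reported in the result,
  not an error. A non-finite starting energy aborts with advice to
  repack first (with the linearized repulsion this effectively never
  triggers).
* Torsions whose axis lies in a ring (proline χ, aromatic ring bonds) are
  not rotatable and are dropped from the DOF set; the N-terminal φ has no
  reference quadruple and is treated as a displacement DOF.
* `rebuildCoordinates` drives named torsions to absolute target angles by
  rotation, which preserves all bond lengths and angles exactly; atoms
  outside every moving set keep their coordinates bitwise.
* PDB input: first MODEL only; altLoc resolved to the highest-occupancy
  conformer (ties to the alphabetically first code); hydrogens dropped;
  insertion codes kept in the residue key; unknown residues retained as
  hetero units. A missing C-terminal OXT is rebuilt at ideal sp²
  carboxylate geometry (C–OXT 1.25 Å, anti to O); no other repair is
  attempted.
* Proteins shorter than four residues, or with non-standard letters
  (X, U, B, Z) in the C-terminal window, are skipped by the proteome scan
  with a warning.

## Problem sizes

The shipped tests and the acceptance script run the complete pipeline on
a 25 + 25 peptide benchmark against the ~20-residue toy pocket (about
180 atoms, ~50 torsional degrees of freedom, ~2 s per sequence on one
core); these sizes give stable AUC estimates for a designed effect of
this magnitude while keeping a full run in the minutes range. The
8000-sequence enumeration is exercised combinatorially; scoring all 8000
against a template is supported (`scoreSequences(tpl, enumerateCxxx())`)
and takes a few hours on one core.

## Known limitations

* The energy model is deliberately small: no explicit water, no
  polarizability, no aromatic π-interactions, isotropic hydrogen-bond
  geometry. Scores are comparative, not physical binding free energies.
* Backbone conformational search is out of scope: the protocol relies on
  the template backbone being essentially correct, which the three
  conserved constraints enforce. Sequences whose binding requires
  backbone rearrangement (e.g. bulky C-terminal residues in the real
  enzyme) are systematically under-scored by a minimization-only
  protocol.
* The coarse rotamer library can miss narrow side-chain wells; the ±10°
  sub-rotamers and the subsequent continuous χ minimization recover most
  of the gap.
* Proline side chains are built with an approximate (unclosed) ring and
  its χ angles are held rigid during minimization.
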