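# caaxbind

Structure-based prediction of farnesyltransferase (FTase) Cxxx substrate
specificity in R.

Proteins ending in a Ca₁a₂X ("Cxxx") motif — a cysteine followed by three
variable residues at the extreme C-terminus — can be farnesylated: FTase
attaches a 15-carbon isoprenoid to the cysteine thiol. Whether a given
tetrapeptide binds the enzyme is largely decided by how well it fits the
peptide-binding pocket. `caaxbind` estimates that fit physically instead of
statistically: a candidate sequence is **threaded** onto the backbone of a
template peptide taken from a receptor–peptide complex, its side chains are
**packed** over a rotamer library, the pose is **minimized** in torsion
space (Davidon–Fletcher–Powell quasi-Newton) under three harmonic distance
restraints that conserve the invariant binding geometry — the two anchor
hydrogen bonds (C-terminal carboxylate ↔ Gln-amide; a₂ carbonyl ↔
Arg-guanidinium) and the cysteine-Sγ coordination site — and the pose is
**scored** with a decomposable energy model. The reported *peptide score*

    score(s) = Σ_{i ∈ 4 peptide residues} E_i  −  Σ_i E_ref(aa_i)

(lower = better binder; the shipped reference table is zero) is compared
with a loose and a stringent threshold to call `binder` /
`strong_binder` / `non_binder`. ROC/AUC machinery with the
lower-score-is-positive orientation, threshold calibration, full Cxxx
sequence-space enumeration, FASTA proteome scanning and position frequency
matrices round out the toolkit. A deterministic synthetic
receptor–peptide complex (`makeToyTemplate()`) makes the entire pipeline
runnable and testable offline.

The package is for structural bioinformaticians who want a transparent,
self-contained reimplementation of minimization-based peptide
specificity profiling — for prenylation motifs or, with a different
template and anchors, for other peptide-recognition systems.

## Worked example

```r
library(caaxbind)

tpl <- makeToyTemplate()          # deterministic synthetic pocket (CNIQ template)
deriveConstraints(tpl)            # the five harmonic restraints, d0 measured
#>              atom_a     atom_b  d0  sd
#> 1 pep_carboxylate_O    q_alpha 2.8 0.1
#> 2          pep_a2_O     r_beta 2.8 0.1
#> 3        pep_cys_SG zn_triad_1 2.3 0.1
#> 4        pep_cys_SG zn_triad_2 2.3 0.1
#> 5        pep_cys_SG zn_triad_3 2.3 0.1

scoreSequence(tpl, "CVIM", seed = 1)   # the KRas-2B motif
#> ScoreRecord CVIM: peptide_noref = -3.814 -> strong_binder

scoreSequence(tpl, "CDKD", seed = 1)   # charged residues in the pocket
#> ScoreRecord CDKD: peptide_noref = 3.043 -> non_binder
```

`CVIM` (aliphatic a₂, compact X) packs against the hydrophobic a₂ wall
and the probe ligand and satisfies all five restraints, ending several
energy units below zero; `CDKD` buries charged side chains in an apolar
pocket and pays solvation and electrostatic penalties. With the default
thresholds (−0.4 loose, −1.1 stringent, both in model energy units) the
first is called a strong binder, the second a non-binder.

Batch scoring, scanning and evaluation:

```r
scoreSequences(tpl, c("CVIM", "CVLS", "CSVQ"), seed = 1)  # data.frame
hits <- scanProteome(system.file("extdata", "sample_proteome.fa",
                                 package = "caaxbind"))
hits$motif
#> [1] "CVLS" "CIIM" "CYLE"
positionFrequencyMatrix(hits$motif)    # 20 x 4 column-normalized matrix

set <- makeLabeledPeptides(syntheticConfig(seed = 1), 25, 25)
sc  <- scoreSequences(tpl, records(set)$sequence, seed = 1)
roc <- rocCurve(sc$score, records(set)$label, positiveLabels = "MTO")
auc(roc)
#> [1] 0.9264
calibrateThresholds(sc$score, records(set)$label, looseFpr = 0.1,
                    positiveLabels = "MTO")
#> ClassifierConfig: binder <= -1.33, strong binder <= -2.36
```

A thin command-line front end ships in `inst/exec/caaxbind.R`
(`score`, `batch`, `enumerate`, `scan`, `pfm`, `roc`, `fixtures`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","caaxbind.R",package="caaxbind"))')" \
    scan --fasta proteome.fa --unique
```

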