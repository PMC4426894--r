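# fragsite

Template-based prediction of NAD- and FAD-binding residues in protein
structures, for structural bioinformaticians who have a query structure
(PDB format) and want residue-level cofactor-binding calls plus a
predicted ligand location — using only structure and sequence identity,
no evolutionary profiles.

## Method in brief

Binding templates are harvested from cofactor-bound structures: the
ligand is split into its three moieties (nicotinamide/flavin, adenosine,
phosphate), and the residues contacting each moiety (≤ 3.5 Å, optionally
intersected with a BioLiP-style annotation) form one template per
(chain, ligand, moiety) when at least two of them have complete N–Cα–C
backbones, together with the moiety's geometric center L<sub>ω</sub>.

A query of m backbone triplets σ<sub>i</sub> is aligned to a template of
n triplets τ<sub>j</sub> by computing all m×n rigid transforms
M<sub>ij</sub>σ<sub>i</sub> ≈ τ<sub>j</sub> (3-point Kabsch) and
single-linkage clustering mutually consistent pairs (symmetrized 3-atom
RMSD below D₀ = 2 Å, distinct residues on both sides). Each surviving
cluster μ (Cα RMSD < 3 Å) scores

C<sub>μ</sub> = ε<sub>μ</sub> · 1/(1+RMSD) ·
BLOSUM(S<sub>μ</sub>,T<sub>μ</sub>)/(BLOSUM(T<sub>μ</sub>,T<sub>μ</sub>)+1) ·
DSSP(S<sub>μ</sub>,T<sub>μ</sub>)/(DSSP(T<sub>μ</sub>,T<sub>μ</sub>)+1)

and a residue's score C<sub>i</sub> is the maximum over all clusters
containing it, across the whole database. The winning cluster
back-projects the moiety center, Θ<sub>i</sub> = (M<sup>μ</sup>)⁻¹L<sub>ω</sub>;
residues whose predicted centers lie 3–9 Å apart with different moiety
labels reinforce each other (their pre-boost scores are added). Scores
are z-normalized per protein and thresholded at a pooled 5% false
positive rate or at maximum MCC; evaluation is leave-one-out (templates
from the query's own PDB entry excluded).

## Worked example

Everything needed for a full run can be simulated — each toy protein
carries a noisy planted copy of a shared three-moiety binding site and a
pseudo-ligand whose atom names match the real NAD partition table:

```r
library(fragsite)
toy <- make_toy_dataset(6, seed = 42)            # 6 proteins + template DB
dataset <- lapply(toy$entries, function(e)
  list(model = e$model, annotations = e$annotations))
res <- leave_one_out(dataset, toy$db)            # pooled LOO evaluation
```

prints (via the summary code in `cmd_evaluate()`, or directly):

```
templates: 18
5% FPR point: threshold z = 0.862, accuracy 98.0%, sensitivity 81.7%, specificity 100.0%, MCC 0.89
max-MCC point: threshold z = 0.862, accuracy 98.0%, sensitivity 81.7%, specificity 100.0%, MCC 0.89
```

Accuracy/sensitivity/specificity are percentages of residues over the
pooled dataset at the chosen z-threshold; MCC is the Matthews
correlation in [−1, 1]. Per-residue output for one protein:

```
 seq_key res_name    moiety score_boosted        z
       8      ILE adenosine      4.743149 1.190314
       9      TYR adenosine      4.743149 1.190314
      13      THR phosphate     17.216414 5.096179
```

`moiety` names which part of the cofactor the residue is predicted to
contact, `score_boosted` is the composite score after cross-moiety
reinforcement, and `z` its per-protein normalization; a call means
z ≥ the pooled threshold.

The same pipeline runs from the command line on PDB files:

```sh
Rscript inst/cli/fragsite.R simulate --n 6 --seed 42 --out toydir
Rscript inst/cli/fragsite.R build-db toydir/*.pdb \
    --annotations toydir/annotations.txt --out db.jsonl
Rscript inst/cli/fragsite.R predict toydir/s001.pdb --db db.jsonl --out pred.tsv
Rscript inst/cli/fragsite.R evaluate --manifest toydir/manifest.txt \
    --annotations toydir/annotations.txt --out report
```

To build a real template database, collect cofactor-bound PDB entries
(redundancy-filtered externally, e.g. CD-HIT at 40% identity) and a
BioLiP-style annotation table (`pdb chain ligand G12 R15 ...`), then run
`build-db` / `predict` exactly as above; DSSP files can be supplied with
`--dssp` (otherwise a built-in dihedral fallback labels helix/strand).

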