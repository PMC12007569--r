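# gatescape

Conformational-landscape and ligand-interaction analysis for two-protomer
membrane transporters that work by an alternating-access **rocker-switch**
mechanism, built around the mitochondrial pyruvate carrier (MPC). The
package is aimed at structural bioinformaticians who have a large ensemble
of predicted transporter models (multi-model PDB) plus per-model quality
scores, and want to turn it into a small set of interpretable
conformational states and ligand-binding summaries.

## What it computes

**Gate coordination numbers.** Closure of each side of the transporter is
measured by a smooth count of close non-hydrogen atom pairs between two
residue groups flanking the gate. A pair at distance *r* contributes

    s(r) = [1 − (r/R)⁶] / [1 − (r/R)¹²] = 1 / (1 + (r/R)⁶),   R = 4.5 Å

and the gate metric is C = Σᵢ Σⱼ s(rᵢⱼ) over all cross-pairs; a value near
100 means ~100 atom pairs in contact — a closed gate. Defaults carry the
carrier's published N- and C-gate residue groups
(`mpc_gate_metrics()`).

**Landscape analysis.** Models with quality score strictly above 0.4 are
retained, clustered in (C_N, C_C) space by seeded PAM k-medoids (k = 9,
distance-matrix cap 5000 with subsampled medoid search), each cluster is
depicted by its most central model, and clusters are labelled
outward-open / occluded / inward-open / intermediate against endpoint
reference structures.

**Motions.** Fixed-selection rigid-body rotation of the H2–H3 helix bundle
between two states (angle from the rotation-matrix trace, axis, screw
component), plus a per-residue displacement table with a hinge-candidate
window.

**Interactions.** Geometric protein–ligand typing (hydrogen bond, ionic,
parallel/perpendicular π-stacking, hydrophobic), canonical interaction
fingerprints, docking-pose convergence (fraction of poses sharing the
modal fingerprint), and average-linkage pose clustering with the number of
clusters at the minimum of the Kelley penalty.

**Synthetic ground truth.** A fully deterministic rocker-switch ensemble
generator (`generate_ensemble()`) and docking-pose generator
(`generate_pose_set()`) with published ground truth, on which every stage
of the pipeline is validated.

## Worked example

```r
library(gatescape)

# synthetic ensemble standing in for a large predicted-model set
ens <- generate_ensemble(n_models = 500, noise_sigma = 0.15, seed = 42)
gm  <- mpc_gate_metrics("MPC1L")
lnd <- compute_landscape(ens$models, gm)

scores   <- setNames(ens$truth$pseudo_score, ens$truth$model_id)
retained <- filter_by_quality(lnd, scores)
#> quality filter (> 0.4): retained 500 of 500 models

res <- kmedoids(retained[, c("model_id", "C_N", "C_C")], k = 9, seed = 1)
#> k-medoids: 500 models -> 9 clusters (medoid search on 500, 6 iteration(s), cost 5823)

mean(representative_tightness(res, ens$models)$mean_rmsd)
#> [1] 0.38    # members sit ~0.4 A from their state representative
```

Classifying the nine cluster representatives against the two endpoint
structures, ordered by the generator's ground-truth progress coordinate
`t` (0 = outward-open, 1 = inward-open):

```
            rep    t   C_N   C_C        state
 synthetic#0089 0.09  14.0 458.3 outward_open
 synthetic#0468 0.19  24.6 432.6 outward_open
 synthetic#0276 0.34  48.6 373.1 intermediate
 ...
 synthetic#0435 0.93 163.6  70.4  inward_open
```

C_N rises and C_C falls monotonically along the transition: the N-gate
closes as the C-gate opens, and the endpoint clusters are recognized as
the two open states.

The bundle rotation between the most outward and most inward model of the
same noisy ensemble, aligned on the static helices:

```r
bundle_rotation(out_model, in_model,
                fixed  = list(group_spec("A", 20:40), group_spec("B", 30:50)),
                mobile = list(group_spec("B", c(58:72, 79:99))))
#> rotation_analysis: 18.772 deg about (-0.006, -1.000, 0.010), screw 0.015 A
#>   rmsd: fixed 0.3679 A, mobile after fit 0.3627 A
```

close to the 19° applied by the generator for that protomer (exact at zero
noise). Docking-pose convergence on an 80-pose synthetic set built with a
70% modal fraction:

```r
ps   <- generate_pose_set(n = 80, modal_fraction = 0.70, seed = 1)
conv <- pose_convergence(ps$poses, ps$ligand, ps$site)
#> modal fingerprint: hbond:B:100, hbond:B:49, ionic:B:49
#> convergence: 70% of 80 poses
```

A thin command-line wrapper over the same functions lives at
`inst/cli/gatescape.R` (subcommands `simulate`, `landscape`, `cluster`,
`motions`, `poses`).

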