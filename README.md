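# facialdti

Diffusion tensor imaging (DTI) group analysis of thin curved nerve tracts,
built around the intratemporal facial nerve, with a fully synthetic phantom
cohort generator so that every stage of the analysis can be validated
against known ground truth.

## The problem

Bell's palsy — acute idiopathic peripheral facial paralysis — is thought to
arise from injury to the facial nerve inside the bony facial canal of the
temporal bone. DTI separates two injury modes through the eigenvalues
λ₁ ≥ λ₂ ≥ λ₃ (mm²/s) of the per-voxel diffusion tensor **D**:

* **AD** (axial diffusivity) = λ₁ — increases with axonal injury;
* **RD** (radial diffusivity) = (λ₂ + λ₃)/2 — increases with myelin injury;
* **MD** = (λ₁ + λ₂ + λ₃)/3; **FA** = √(3/2) · √Σ(λᵢ − MD)² / √Σλᵢ² —
  overall integrity.

A demyelinating lesion therefore shows **FA↓, MD↑, RD↑ with AD unchanged**
on the affected side. Testing that signature on a nerve ~1 mm across
requires a full pipeline: tensor estimation from the diffusion-weighted
signal S = S₀·exp(−b·gᵀ**D**g), deterministic FACT tractography seeded from
5 mm spheres (track while FA > 0.15, stop at turning angles above 60°,
discard fibers shorter than 2 mm), fusion of per-subject tract maps into a
group **maximum probability map** (MPM) by strict majority voting across
subjects, MPM-based extraction of per-subject scalar indexes, and
paired/pooled-variance unpaired two-tailed t-tests across sides and groups.

Because the matching clinical scans are not publicly available, the package
ships a first-class **phantom module**: bilateral mirror-symmetric curved
tube tracts on a 0.4 mm isotropic grid (optionally a 1.2 × 1.2 × 3.0 mm
native grid plus trilinear resampling), a 1 b0 + 20-direction b = 1000 s/mm²
scheme, cylindrically symmetric tube tensors with log-normal
between-subject variation, Rician noise at SNR 30, and patient cohorts
carrying a unilateral RD increase (×1.128 by default) with AD unchanged.

## Worked example

```r
library(facialdti)

cfg <- pipeline_config(seed = 42L,
                       phantom = list(n_healthy = 6L, n_patient = 6L,
                                      grid_shape = c(44L, 44L, 44L)))
res <- run_pipeline(cfg)
print(res$mpms$all)
df <- format_tables(res$tables$table2)
df[df$mpm == "patient", c("index", "value_x", "value_y", "p_t")]
```

```
MPM over 12 subjects: 456 left + 448 right voxels
 index                 value_x                 value_y                p_t
    FA           0.287 ± 0.025           0.231 ± 0.042  0.030 (t = 2.991)
    MD      0.93082 ± 0.044466      0.97336 ± 0.041385 0.009 (t = -4.190)
    AD  0.0012413 ± 3.1921e-05  0.0012316 ± 7.3881e-05  0.711 (t = 0.392)
    RD 0.00077557 ± 5.1051e-05 0.00084422 ± 4.4252e-05 0.005 (t = -4.694)
```

`value_x` is the patients' healthy side, `value_y` the affected side
(mean ± SD over subjects; MD displayed in 10⁻³ mm²/s, AD/RD in mm²/s; t is
oriented healthy-side minus affected). Even with only six simulated
patients, the demyelination signature is recovered: FA is significantly
lower and MD/RD significantly higher on the affected side, while AD shows
no significant difference — the affected/healthy contrast the analysis is
designed to detect. `run_pipeline(cfg, out_dir = "out")` additionally
writes `measurements.csv`, `table1.csv`–`table3.csv`, the three MPM label
and support volumes as NIfTI, and a YAML run manifest.

Individual stages are exported (`generate_cohort()`, `fit_tensor()`,
`eigendecompose()`, `scalar_maps()`, `make_seeds()`, `track_all()`,
`voxelize_streamlines()`, `build_mpm()`, `extract_indices()`,
`build_tables()`), along with NIfTI, FSL bval/bvec and TrackVis `.trk`
readers/writers. A thin command-line wrapper lives at
`inst/cli/facialdti.R` (`simulate`, `fit`, `run` subcommands).

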