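# mstconnect

Minimum-spanning-tree analysis of wavelet-coherence functional connectomes,
with a synthetic cohort generator and group-level inference — an end-to-end,
tested re-implementation of the resting-state MST pipeline used to compare
psychosis-spectrum groups.

## The problem

Group comparisons of functional brain-network topology are confounded by
overall connectivity strength: densifying or weakening all connections
changes most graph metrics even when the architecture is identical.  The
minimum spanning tree sidesteps this by reducing each subject's weighted
connectivity matrix to the unique backbone of strongest edges — its
*topology* depends only on the rank order of weights, so strength and
topology can be studied separately.  This package implements the full
pipeline for region×time BOLD panels:

1. **Motion QC** — exclude subjects with mean relative RMS displacement
   > 0.2 mm or ≥ 20 frames > 0.25 mm.
2. **Connectivity** — MODWT scale-4 coefficients (0.05–0.10 Hz at a 0.609 s
   sampling interval; LA8 filter) and Welch magnitude-squared coherence
   `|Sxy|²/(Sxx·Syy)` for all region pairs → a symmetric N×N matrix in
   [0, 1].
3. **MST metrics** — maximum-weight spanning tree (Kruskal, deterministic
   tie-break); global metrics: strength (mean edge weight), diameter
   (edges, and normalised by N−1), degree divergence
   κ = ⟨k²⟩/⟨k⟩, leaf fraction; nodal metrics: degree and exact
   normalised tree betweenness; tree overlap between subjects.
4. **Inference** — ANCOVA (age, sex, education covariates) with
   Benjamini–Hochberg FDR over the measure family, LSD post-hoc contrasts,
   medication-stratum contrasts, and max-statistic permutation tests with
   family-wise error control for nodal metrics.
5. **Synthetic cohorts** — band-limited multivariate Gaussian signals with
   controllable coherence strength (global deficit) and hub topology
   (flattening), plus motion traces and demographics, for calibration and
   parameter-recovery testing.

## Worked example

```r
library(mstconnect)

cfg <- cohort_config(group_sizes = c(HC = 10, SCZ = 10, BD = 10),
                     n_nodes = 30, seed = 1)
cohort <- generate_cohort(cfg)

panel <- cohort$panels[["sub-HC001"]]
cm <- build_connectivity_matrix(panel)
cm
#> connectivity_matrix: 30 nodes, wavelet scale 4 (la8), band 0.051-0.103 Hz
#>   mean off-diagonal coherence 0.400 (range 0.116-0.792)

tree <- maximum_spanning_tree(cm)
mst_global_metrics(tree)
#>    strength diameter_edges diameter_norm    kappa leaf_fraction
#> 1 0.6289978              8     0.2758621 2.965517     0.5333333
```

The mean coherence (~0.40) mixes strong hub-incident edges with weaker
peripheral ones; the MST keeps the strongest 29 of 435 edges, so its mean
edge weight (0.63) is much higher.  κ ≈ 3.0 and leaf fraction ≈ 0.53 say
the backbone is clearly hub-dominated (a 30-node path would give κ ≈ 1.97,
leaf fraction 0.07; a star κ = 15, leaf fraction 0.97).

Running the demo inference over all 30 subjects
(`analysis/01…05`, output abridged):

```
Group effects on global MST measures (BH-FDR at q = 0.05):
       measure df_effect df_error     F      p partial_eta_sq fdr_significant
      strength         2       16 5.599 0.0143         0.4117           FALSE
 diameter_norm         2       16 1.846 0.1900         0.1875           FALSE
         kappa         2       16 1.035 0.3778         0.1146           FALSE
 leaf_fraction         2       16 0.804 0.4649         0.0913           FALSE
```

The planted 15% coherence deficit in the SCZ-like group surfaces as a
group effect on strength (raw p = 0.014, partial η² = 0.41) and nothing
else — though at demo scale (22 subjects after QC) it does not survive the
four-measure FDR correction; the full recovery design
(`analysis/06_signature_recovery.R`, 30 subjects/group at 60 nodes) is the
properly powered version.

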