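# homonet

Weighted motor-network analysis of block-design task fMRI, centred on
interhemispheric (homotopic) organisation.

During unilateral movement, most motor regions activate as mirror-symmetric
pairs across the hemispheres. `homonet` quantifies how strongly a
task-state functional network is organised around those pairs. It
implements the full chain from time series to statistics:

* **Design**: block paradigms and canonical double-gamma HRF regressors
  sampled at the TR.
* **Signal**: spherical-ROI extraction from 4D NIfTI volumes, zero-phase
  Butterworth bandpass (0.008–0.09 Hz), nuisance regression (6 motion
  parameters, WM/CSF and their temporal derivatives).
* **Connectivity**: condition-weighted Pearson correlation
  r(x, y; w) with the HRF-convolved block regressor as per-scan weights,
  Fisher transform z = atanh(r), per-edge one-sample t tests across
  subjects, Benjamini–Hochberg FDR, and the thresholded weighted network
  W with distances D = 1 − W.
* **Graph**: strength, shortest paths, betweenness, global efficiency,
  weighted clustering, assortativity, Louvain modularity Q (restarts +
  deterministic refinement, Q re-verified by direct formula), small-world
  indices against degree-preserving nulls.
* **Homotopy**: for every region the strongest incident link; the
  *anchoring count* (paired regions whose strongest link is their
  contralateral homolog, out of 24), within-module homotopic pairing,
  per-module symmetry ratios k_m/n_m — with permutation nulls and exact
  closed-form small-n null distributions.
* **Synthetic data**: an 18-subject block-design BOLD generator with
  planted homotopic / intrahemispheric / background coupling, drift,
  motion-coupled noise and confound tables, plus a volume renderer for
  round-trip testing of ROI extraction.

## Worked example

```r
library(homonet)

nodes    <- default_nodeset()      # 28 regions, 12 homotopic pairs
paradigm <- default_paradigm()     # 10 x 16 s blocks, TR 2 s, 194 scans
model    <- coupling_model(r_homotopic = 0.6, r_intra = 0.3, r_other = 0.1)

res <- run_pipeline(pipeline_config(seed = 7, n_subjects = 18,
                                    model = model, fdr_q = 0.05,
                                    n_perm = 999))
res$homotopy
```

```
homotopy report
  anchoring: 24 of 24 paired regions (p = 0.001)
  pairs co-located in a module: 0 of 12 (p = 1)
  symmetry ratio total: 0/28
  per module: 0/16, 0/12
```

All 24 paired regions anchor to their homolog — with homotopic coupling
planted above every other coupling, each region's strongest surviving link
is its mirror twin, and the permutation p (999 draws) is at its attainable
minimum. The module lines illustrate a structural point discussed in the
vignette: with *uniform* intrahemispheric coupling the modularity optimum
is the hemispheric split (here 16 + 12 regions), which co-locates no pair;
bilateral modules in real data come from spatially clustered connectivity
that a three-level coupling model does not express.

The same steps run individually (see `analysis/01_simulate.R` …
`analysis/05_controls.R` for the scripted workflow):

```r
w    <- condition_regressor(paradigm, "right")$weights
subs <- lapply(simulate_study(nodes, model, paradigm, 18, seed = 7),
               function(ts) subject_connectivity(denoise_subject(ts), w,
                                                 subject_id = ts$subject_id))
net  <- build_group_network(subs, q = 0.05)   # 284 of 378 edges pass FDR
part <- louvain_partition(net$W, seed = 7)    # Q = 0.19, 2 modules
homotopy_report(net, part, nodes, n_perm = 999, seed = 7)
```

A reverse-planted control (`r_intra = 0.6`, `r_homotopic = 0.1`) drives
anchoring to 0 of 24 across replicates, showing the statistic
discriminates rather than saturates; under homogeneous coupling the
permutation p-values are super-uniform (empirical type-I ≈ 0.01–0.03 at
nominal 0.05). `analysis/05_controls.R` reproduces both.

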