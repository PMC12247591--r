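# connectopath

Graph-theoretic analysis of anatomical brain networks in chronic PTSD.

Deterministic diffusion tractography summarises each subject's white matter
as a square ROI-by-ROI matrix of tract counts. `connectopath` treats each
matrix as a weighted graph with edge length equal to the *reciprocal* tract
count ("strong = close"), computes the global network measures used in
structural-connectome studies of trauma, and runs the full statistical
battery such a study reports — group contrasts, ordered trend tests,
covariate-adjusted symptom correlations with FDR control, ROC discrimination
and outlier sensitivity. Because clinical imaging archives are typically
access-restricted, the package ships a synthetic cohort generator that
reproduces the statistical structure of such a study (three ordered groups,
MDD comorbidity, symptom-eligibility bounds, right-skewed path lengths,
configurable group effects), so the entire chain is testable end to end.

## The measures

For tract counts $w_{uv}$, edge length is $d_{uv} = 1/w_{uv}$ and the path
length between nodes $i, j$ is the minimum of $\sum_{(u,v) \in g_{i
\leftrightarrow j}} d_{uv}$ over paths $g_{i \leftrightarrow j}$ (all-pairs
Dijkstra). The package reports, per subject:

- **wCPL** — weighted characteristic path length: the mean shortest path
  length over unordered node pairs (disconnected pairs excluded and
  counted);
- **GE** — global efficiency: mean inverse shortest path length;
- **CC** — weighted clustering coefficient (geometric-mean triangle form,
  max-weight normalisation);
- **SWN** — small-worldness CC/wCPL, plus a variant normalised against
  degree-preserving rewired null networks, and its natural log.

## Worked example

```r
library(connectopath)

cfg <- cohort_config(seed = 1)          # 9 / 53 / 47 subjects, 62 ROIs
run <- run_pipeline(cfg, out_dir = "results/run")
report_run(run)
```

which prints (abridged; your numbers are identical for the same seed):

```
## Group summaries (wCPL)
- control: mean 45.44 (SD 14.18), n = 9
- exposed_noptsd: mean 56.96 (SD 24.23), n = 53
- ptsd: mean 70.48 (SD 28.28), n = 47

## Group contrasts
- wCPL ptsd_vs_exposed_noptsd: d = 0.52, p = 0.012, adjusted p = 0.007
- wCPL ptsd_vs_all_nonptsd: d = 0.59, p = 0.004
...
## ROC discrimination
- ptsd_no_mdd / wcpl: AUC = 0.66, 95% CI [0.54-0.78]
- ptsd_no_mdd / combined: AUC = 0.82, 95% CI [0.73-0.92]
```

Read: PTSD subjects have longer characteristic path lengths than exposed
responders without PTSD (a medium standardized difference that survives
adjustment for age, sex, education and body mass), and wCPL combined with a
second imaging covariate plus demographics separates PTSD-without-MDD cases
from non-cases with high apparent accuracy.

The same stages can be run one at a time as a narrated workflow:

```sh
Rscript analysis/01_simulate.R            # writes results/cohort/
Rscript analysis/02_network_metrics.R     # results/metrics.csv
Rscript analysis/03_group_contrasts.R     # results/contrasts.csv
Rscript analysis/04_symptom_correlations.R
Rscript analysis/05_roc.R
Rscript analysis/06_outlier_sensitivity.R
```

See `vignettes/connectome-path-length.Rmd` for the model, the generator's
assumptions, and every numerical choice.

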