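# fedbids

Federated learning for BIDS-organised brain-MRI regression in R.

`fedbids` is for neuroimaging groups who want to train a regression network
(brain age from T1-weighted MRI, or a cognitive score such as the SDMT in
multiple sclerosis) across several centres **without moving any images**.
Each centre keeps its data in a local [BIDS](https://bids.neuroimaging.io/)
dataset; only model weights travel. The package provides the whole stack:

* **Synthetic BIDS phantoms** (`phantom_config()`, `generate_bids_dataset()`)
  — small 3D "brains" whose ventricle radius encodes the regression target,
  so every component is testable end-to-end on a laptop.
* **BIDS discovery and leak-free splitting** (`discover_subjects()`,
  `subject_split()`, `bootstrap_splits()`) — subject-level 80/20 train/test
  splits (all images of a subject stay on one side), then five fresh 75/25
  train/validation partitions of the training pool per federation round,
  giving a 60/20/20 accounting.
* **Deterministic preprocessing** (`preprocess_pipeline()`) — RAS
  reorientation, isotropic resampling at 1.4 mm, centre crop/zero-pad to a
  130×130×130 window, intensity normalisation; skull-stripping, N4 bias
  correction and affine template registration plug in as external command
  hooks.
* **The 3D DenseNet regression network** (`build_densenet()`) — a fully
  specified DenseNet-121 in three dimensions (bias-free convolutions, batch
  norm, adaptive final pooling, a 1,024→1 head) with **11,243,649**
  trainable parameters, implemented natively (im2col + BLAS, with small C++
  gather kernels) including training by minibatch Adam on the L1 objective.
  Transfer-learning freeze policies: *shallow* (head only, 1,025 parameters)
  and *deep* (everything).
* **The federation** (`run_federation()`, `run_client()`,
  `simulate_federation()`) — a file-based two-message protocol (payload then
  zero-byte `.done` marker; receivers never read unmarked payloads), per
  round: broadcast → bootstrapped local training → collection → sampled,
  sample-size-weighted FedAvg → early stopping on the server-side average
  validation MAE, with the final model taken from the best round.
* **The centralised benchmark** (`run_centralized()`) — the same
  hyperparameters and merged bootstrap splits in a single process, for
  federated-versus-centralised comparisons.
* **Evaluation** (`mae()`, `overall_mae()`, `pearson()`,
  `bad_diagnostics()`, `emit_report()`) — per-client test MAE, the
  sample-size-weighted overall MAE
  `MAE_overall = Σᵢ MAEᵢ·nᵢ / N`, Pearson correlations, and the
  brain-age-difference (BAD = predicted − calendar age) bias diagnostic.

## Worked example

```r
library(fedbids)

# the full-size network used on real T1w images
model <- build_densenet(densenet_spec())
model
#> <fedbids 3D DenseNet: blocks 6/12/24/16, growth 32, init features 64>
#>   parameters: 11,243,649 (11,243,649 trainable)
count_trainable(apply_freeze_policy(model, "shallow"))
#> [1] 1025

# a desk-scale federation on three synthetic phantom clients (the third has
# its target distribution shifted by +25: a non-IID client)
plan <- fl_plan(n_rounds_max = 5, clients_per_round = 2,
                learning_rate = 0.1, seed = 42)
sim <- simulate_federation(plan, n_subjects = c(20, 30, 40),
                           shifted_client = 3, target_shift = 25)
sim$result$history$rounds
#>   round avg_val_mae         sampled
#> 1     1    54.67538 client1,client3
#> 2     2    39.34882 client1,client2
#> 3     3    40.33113 client2,client3
#> 4     4    25.66028 client2,client3
#> 5     5    13.81231 client1,client3
round(sim$overall_mae, 2)
#> [1] 20.24
```

The history shows the federation learning (average validation MAE across the
sampled clients falls from 54.7 to 13.8 in five rounds) and the non-IID
zigzag: rounds whose aggregation sample includes the shifted `client3` sit
higher than rounds that exclude it. `sim$report_dir` holds the metrics
table, JSON summary, per-round loss-curve data and per-client scatter data;
`plot_history()` / `plot_predictions()` render them with ggplot2.

A command-line front-end for deployments lives at `inst/cli/fedbids.R`
(`server`, `client`, `simulate`, `centralized` subcommands).

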