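---
title: "Methods: federated brain-MRI regression with fedbids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: federated brain-MRI regression with fedbids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

`fedbids` trains a scalar-output 3D convolutional network on T1-weighted
brain MRI distributed across centres that cannot share images. The targets
are continuous: chronological age (the "brain age" task) or a cognitive
score such as the Symbol Digit Modalities Test (SDMT) in multiple sclerosis.
Training is federated: a server repeatedly broadcasts global weights,
clients train locally on their own BIDS datasets, and the server aggregates
a sampled subset of the returned models by sample-size-weighted federated
averaging (FedAvg),

$$ w \leftarrow \sum_{i \in S} \frac{n_i}{\sum_{j \in S} n_j}\, w_i , $$

where $n_i$ is the number of training images at client $i$ and $S$ the
sampled subset of that round.

The network is DenseNet-121 in three dimensions: a 7³ stem convolution
(stride 2, no bias), batch norm, ReLU and 3³ max-pool (stride 2, pad 1);
four dense blocks of 6/12/24/16 layers, each layer a BN–ReLU–1³ bottleneck
(to 4×growth = 128 channels)–BN–ReLU–3³ convolution (to growth = 32
channels) concatenated onto the block's feature stack; transitions (BN + 1³
convolution halving channels + 2³ average-pool) between blocks; and a final
BN–ReLU–adaptive average-pool–fully connected 1,024→1 head. All
convolutions are bias-free. This is the unique standard DenseNet
configuration whose 3D parameter count is 11,243,649 with a 1,025-parameter
head, and the package asserts that accounting layer-by-layer
(`parameter_ledger()`), not just in total. Transfer learning uses two
freeze policies: *shallow* (only the head trains, 1,025 parameters) and
*deep* (everything trains).

Because adaptive pooling absorbs any input size, the same architecture runs
on 130³ real images and 32³ test phantoms; the parameter count is
independent of input size.

## Local training protocol

Each client computes, once per federation, a subject-level 80/20
train/test split: every image of a subject falls on one side, which is the
leak-freedom rule for multi-session data. Each round, the training pool is
repartitioned five times into 75% training / 25% validation (fresh random
partitions without replacement — the 60/20/20 accounting only works if
train and validation are disjoint subsets of the 80% pool, so
"bootstrapping" here means resampled splits, not with-replacement
resampling). For each partition the client loads the global weights into a
fresh model copy, applies the freeze mode, trains `epochs_per_round` epochs
of minibatch Adam (batch size 10) on the **L1 objective** — every reported
metric is an MAE, and using it as the loss keeps training and validation
curves commensurable — and records the validation MAE. The update sent to
the server carries the weights of the partition with the lowest validation
MAE. Which of the five models should be transmitted is genuinely open;
averaging the five weight sets is a second defensible choice, so the
selector is a plan switch (`selector = "best"` default, `"average"`
alternative).

Split sizes use R's round-half-to-even with a floor of one subject per
side, making small-$n$ behaviour explicit. All randomness (splits,
sampling, shuffling, initialisation) derives from the plan seed through
`derive_seed()`, so a federation is exactly reproducible, and a one-client
federation is bit-identical to the standalone training loop with the same
seeds — a property the test suite asserts.

## Server orchestration

The server samples `clients_per_round` clients uniformly without
replacement (deterministically per round under the plan seed), aggregates
only the sampled updates, and logs the mean of the sampled clients'
validation MAEs. Early stopping counts consecutive rounds without
improvement of the running minimum of that average; when `patience` is
reached, training stops, and the **final model is the aggregate of the
minimum-MAE round**, not the last round — min-tracking is deliberately
distinct from the stop point. Patience has no canonical value and ships as
a plan field (default 20).

A client that stays silent past the receive timeout aborts the federation
with an error naming it. Dropping it instead would silently change the
sample-size weighting, which is worse than failing loudly.

FedAvg is computed in double precision as the first update plus weighted
deviations from it, $w_1 + \sum_{i>1} c_i (w_i - w_1)$. This is
algebraically the weighted mean but, unlike the naive weighted sum, returns
a bit-identical copy when all updates coincide — floating-point
distributivity failures otherwise break that conservation.

The centralised benchmark (`run_centralized()`) syncs every
hyperparameter, merges the clients' bootstrap-$b$ partitions by index into
one training process, and applies the same selection and stopping rules, so
federated-versus-centralised differences reflect the paradigm rather than
the tuning.

## The transmission protocol

Every message is two files: the payload, copied into the receiver's inbox
under the deterministic name `<kind>_round<r>_<sender>.<ext>`, then a
zero-byte `<stem>.done` marker, strictly in that order. Receivers poll for
the marker and never open a payload without one, so partially transferred
files are invisible; deterministic naming makes re-sends idempotent.
Markers are deliberately content-free — content-bearing markers invite
protocol drift. Two transports implement the copy: a shared-filesystem
`local_transport()` (simulation, CI, single-machine runs) and
`remote_copy_transport()`, an scp-shaped command-template contract tested
against a loopback `cp` endpoint; real networks supply their own
authenticated command. Defaults are a 5 s poll and 24 h timeout — local
epochs on weak hardware are slow, and polling is cheap.

## Preprocessing

The implementable tail of the standard brain-age preparation, in order:
reorientation to RAS (pure axis permutation/flips with a consistently
updated affine; idempotent), optional external hooks (skull-strip, N4 bias
correction, 12-dof affine registration to MNI — third-party tools the
pipeline calls, not reimplements, as `{in}`/`{out}` command templates on
temporary NIfTI files), RAS again, trilinear resampling to 1.4 mm
isotropic, centre crop/zero-pad to 130³, and intensity normalisation.
Numerical choices that must be pinned for bit-exact tests: resampled shape
is `round(extent_mm / spacing)` per axis (so 140³ at 1.0 mm becomes
exactly 100³ at 1.4 mm); the extra voxel of an odd crop/pad difference goes
to the trailing side; voxel centres map through
`old = (new + 0.5)·f − 0.5` with edge clamping, which is exactly the
identity at native spacing. Whether the upstream published chain normalises
intensities is not stated anywhere we could verify, so normalisation is an
explicit config choice defaulting to per-volume min-max to [0, 1] —
scale-free inputs keep training stable across scanners, and the choice is
surfaced rather than hidden. Results are cached on disk keyed by
(input-file hash, configuration hash); the image set is fixed across
rounds, so each image is preprocessed once per federation.

## Batch normalisation without running statistics

The network's batch-norm layers carry only their affine parameters
(gain/shift); they hold no running mean/variance buffers. Training
normalises by minibatch statistics as usual; inference normalises by the
statistics of the evaluation batch (near-equal consecutive batches of at
most `batch_size` images, so no batch degenerates to a single sample at the
deepest 1³ feature maps). The weight set exchanged by the federation is
therefore exactly the trainable parameters, which keeps two contracts that
drifting buffers would break: a zero-learning-rate round returns weights
bit-identical to the broadcast, and shallow transfer learning changes
*only* the head. The cost is transductive evaluation — a test image's
prediction depends mildly on its evaluation batch — which is documented
behaviour, deterministic under the fixed batching rule.

## The phantom generator

Synthetic clients are cubic volumes (default 32³ at 1.0 mm) holding an
outer "brain" sphere at intensity 1.0 and an inner "ventricle" sphere at
intensity 0.2 whose radius varies linearly with the target
(0.12 voxels/unit around the target-range midpoint, targets uniform on
[20, 80], Gaussian intensity noise of SD 0.1 inside the brain only). The
geometry mimics the one real, monotone anatomical correlate the network
must find (ventricle size grows with age), and ordinary least squares of
inner-sphere voxel count on the target recovers it with R² > 0.9 at n = 60
— the generator's recoverability contract. A per-client `target_shift`
adds a constant to every drawn target *without changing the
radius↔target mapping*: a pure distribution shift, which is exactly the
non-IID structure (different SDMT distributions per centre) the federation
tests need. Sex alternates m/f and is carried but unused, matching the
image-only feature set.

What phantoms do **not** emulate: real anatomy, scanner/contrast
differences, registration failures, or label noise. Passing tests
demonstrate that the machinery (splits, protocol, training, aggregation,
stopping, evaluation) is correct and that the network can extract a
geometric signal; they say nothing about real-data MAEs, which require the
full-size network, the external preprocessing tools and GPU-scale compute.

## Desk-scale choices

Simulations and tests use the `small` preset (blocks 2/2/2/2, growth 8, 16
stem features) on 32³ phantoms — chosen so a 3-client, 10-round federation
with five bootstraps per round runs in minutes on one CPU core — with
Adam at `lr = 0.1` and one epoch per round. The learning rate follows from
step-size arithmetic rather than tuning: Adam moves each coordinate by
about one learning rate per step, a 10-round desk federation accumulates
only a few dozen aggregated steps, and the head must travel tens of target
units, so `lr ≈ 0.1` is the scale at which a desk run can move its
predictions into the target range at all. The package default
(`learning_rate = 1e-3`) is the field-standard Adam rate appropriate to
full-scale runs of thousands of steps. `epochs_per_round` and the
learning rate are exactly the hyperparameters a deployment sets in its FL
plan.

## Known limitations

* Training is CPU-bound R/BLAS; the full 11.2M-parameter network on 130³
  volumes is intended for architecture verification and weight exchange,
  not large-scale training, which remains GPU territory.
* No brain-age bias *correction* is applied; `bad_diagnostics()` only
  reports the BAD–age correlation that diagnoses regression-to-the-mean.
* No secure aggregation, differential privacy, or client-dropout
  tolerance; alternative aggregation rules (q-FedAvg and relatives) are out
  of scope.
* The 80/20 split is unstratified; whether stratification by target is
  preferable is left to the analyst.
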