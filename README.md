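# spikegha

Multi-channel extracellular spike sorting for streaming, resource-constrained
settings: nonlinear-energy-operator (NEO) detection with peak alignment,
feature extraction by a streaming principal-component rule (the generalized
Hebbian algorithm, GHA), fuzzy c-means clustering, and a behavioural +
closed-form model of the shared-core datapath that makes the approach viable
for many channels on one computation core.

**Who it is for.** Researchers studying online spike-sorting pipelines —
particularly the hardware-oriented design space (fixed-point arithmetic,
per-spike latency, channel capacity) — who need a fully testable software
model with ground-truthed synthetic data.

## The method

For samples `s_k` of one channel, a spike is detected where the discrete
energy operator crosses a threshold,

```
psi_k = s_k^2 - s_{k-1} s_{k+1} > gamma ,   gamma = c * mean(psi)
```

and the surrounding `m = 64` samples are aligned at the peak. Aligned spikes
`x` train `p` synaptic weight vectors by Sanger's rule,

```
w_j <- w_j + eta * y_j * (x - sum_{k<=j} y_k w_k),   y_j = <w_j, x>,
```

which converge to the leading eigenvectors of the spike covariance without
ever forming the covariance matrix. The feature vector `y` feeds fuzzy
c-means; the classification success rate (CSR) is scored against ground
truth under the best cluster-to-unit assignment. A 17-bit fixed-point
backend (`Q1.16`, round-to-nearest-even, saturating, guard-bit accumulator)
emulates an ASIC datapath next to the double-precision reference.

With one core shared round-robin across `M` channels (sampling rate `r_s`,
clock `r_c`, per-spike latency `P = 2 p (m/L) + 8` cycles for segment length
`L`), no detected spike is ever overwritten before service iff

```
Mmax = floor((Q/P) * (rc/rs))   if Q < P,   else   floor(rc/rs)
```

where `Q` is the minimum inter-peak gap in samples. `capacity_table()`
computes the bound; `stream_schedule()` is a cycle-level event simulation
that confirms it is tight.

## Worked example

```r
library(spikegha)

cfg <- gen_config(n_neurons = 2, snr_db = 8, duration_s = 10, seed = 42)
gen <- generate_recording(cfg)                     # recording + ground truth
det <- detect_all(gen$recording, detector_config())
fit <- gha(det, p = 2, backend = "fixed17", seed = 42)
summary(fit)

feats  <- predict(fit)
labels <- match_spikes_to_truth(det, gen$truth)    # NA = false alarm
m      <- !is.na(labels)
cl     <- fcm(feats[m, ], k = 2, seed = 42)
csr(cl$hard_labels, labels[m])
```

Output:

```
Detected spikes: 202 event(s) on 1 channel(s), window m = 64 (peak offset 16)
GHA fit (fixed17 backend): 2 components, 8080 updates
  PC1: |w| = 1.005, var captured = 0.4440 (39.7% of total)
  PC2: |w| = 1.012, var captured = 0.2231 (19.9% of total)
  mean squared reconstruction residual: 0.00759
  max |w_i . w_j| (i != j): 0.0498
Classification success rate: 100.00% of 117 spikes
    predicted
true  1  2
   1  0 56
   2 61  0
```

The two weight vectors have converged to (near-)unit norm and capture ~60%
of the waveform variance; the 117 detections that match a ground-truth peak
(±3 samples) are classified perfectly once cluster labels are optimally
assigned — the 85 unmatched detections are background false alarms, reported
separately because the CSR scores classification, not detection.

The capacity side:

```r
capacity_table(Q_list = c(16, 32), L_list = c(4, 8, 32), rc_list = c(0.5e6, 1e6, 2e6))
#>   Q  L  P Mmax @ rc=5e+05 Mmax @ rc=1e+06 Mmax @ rc=2e+06
#>  16  4 72               4               9              18
#>  16  8 40               8              16              33
#>  16 32 16              20              41              83
#>  32  4 72               9              18              37
#>  32  8 40              16              33              66
#>  32 32 16              20              41              83
```

A shell front end wrapping the same functions is at
`inst/cli/spikesort.R` (subcommands `generate`, `sort`, `capacity`,
`evaluate`, with a YAML `--config`).

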