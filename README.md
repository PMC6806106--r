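# adlrec — unsupervised detection and recognition of daily-living activities

`adlrec` turns the output of a person tracker — a stream of planar
positions per subject — into a segmented, labelled timeline of Activities
of Daily Living (ADL), with no training labels. It is aimed at long-term
behavioural monitoring (hospital rooms, smart homes) where annotating
recordings is impractical, and at anyone who needs an online,
trajectory-driven alternative to sliding-window action detection.

## The method in brief

**Scene model.** Scene regions are Gaussian zones `SR_i ~ (μ_i, σ_i)`
learned from trajectory density by two-stage k-means (per-subject
candidates, then a merge), with the coarse region count selected by the
spherical k-means BIC. Three topologies — k, 2k, 3k regions — describe the
scene at high/mid/low abstraction.

**Primitive events and discovery.** Consecutive point pairs become
`Stay(P)` or `Change(P→Q)` primitive events; maximal Stay runs and single
Change transitions at the *coarse* level clip the recording into
discovered activities (DAs), each carrying the finer-level events that
temporally overlap it. The encoding is causal, so detection is online.

**Hierarchical Activity Models.** Per discovered class, a tree groups
same-type events per level and fits Gaussian attributes — duration
`(μ_d, σ_d²)`, plus mixture and timelapse over child types. Per scene
region, a bag-of-words codebook over local descriptors lets histogram
matching separate activities that share a zone.

**Recognition.** A test DA is scored against every compatible model by a
recursive log-likelihood: type indicators, bounded duration terms
`exp(−|d − μ_d|/σ_d)`, and a Bhattacharyya/Hellinger descriptor-distance
vote at the root, plus the log prior — a MAP decision.

**Evaluation.** Recognized labels are mapped one-to-one onto ground-truth
labels through the frame co-occurrence (correspondence) matrix; then
interval detection metrics (true positive = overlap strictly above 80% of
the ground-truth interval) and frame-wise FA1 / F-score / IoU are
computed.

A synthetic smart-room generator (`simulate_scenario()`,
`scenario_fixtures()`) produces zones, schedules, noisy trajectories,
skeletons, class-conditional descriptors and ground truth, so the whole
pipeline is testable end to end.

## Worked example

```r
library(adlrec)

cfg   <- scenario_fixtures("easy3", n_sequences = 7, n_activities = 6, seed = 7)
truth <- simulate_scenario(cfg)
seqs  <- lapply(truth, `[[`, "sequence")
descs <- lapply(truth, `[[`, "segments")

model <- adl_train(seqs[1:5], descs[1:5], adl_config(seed = 7))
summary(model)
#> <adl_model> scene k = 3/6/9; 3 codebook(s); 9 activity model(s)
#> activity models:
#>   Activity 1 in Zone 0         prior 0.200  instances 11  nodes 26
#>   Activity 1 in Zone 1         prior 0.164  instances 9  nodes 16
#>   Activity 1 in Zone 2         prior 0.182  instances 10  nodes 19
#>   Change 0 to 1                prior 0.091  instances 5  nodes 3
#>   ...

det    <- adl_detect(model, seqs[6:7], descs[6:7])
report <- adl_evaluate(lapply(det, `[[`, "track"),
                       lapply(truth[6:7], `[[`, "annotations"))
print(report)
#> <metrics_report>
#> label mapping:
#>   Activity 1 in Zone 0         -> PrepareDrink
#>   Activity 1 in Zone 1         -> ReadBook
#>   Activity 1 in Zone 2         -> EatMeal
#>   ...
#> detection (> 80% overlap): macro P 1.000, R 1.000, F 1.000
#> frame-wise: FA1 0.979, mean F 0.990, mean IoU 0.980 (7649 frames)
```

Reading the output: the scene model found the three planted zones (scene
`k = 3/6/9`); unsupervised discovery produced one activity class per zone
plus one class per directed transition; the correspondence mapping
identified each internal label with the ground-truth activity it
co-occurs with; on the two held-out sequences every activity interval was
detected at the 80% overlap rule, and 97.9% of frames carry the correct
mapped label.

The `"twin_zone"` fixture places two activity classes in the *same* zone
with different descriptor distributions — geometry cannot separate them;
codebook matching does.

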