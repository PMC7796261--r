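# ecgid

Subject identification from single-lead ECG acquired under motion, with
**adaptive threshold filter normalization**.

## The problem

A Lead-I electrocardiogram is a usable biometric: the voltages and timings
of the P wave, QRS complex and T wave differ reproducibly between people.
But ECG captured in a vehicle or on a wearable is contaminated by motion
artifacts, and beats that are mostly artifact drag down identification
accuracy. Conventional normalization (time cross-correlation, optimized
bandpass, phase-trajectory mapping) transforms *every* beat — including
corrupted ones — and can distort the very morphology that identifies the
subject.

`ecgid` instead **selects** beats. Each subject's resting beats are
compared with an interpolated *ideal cycle*; the closest beat becomes the
subject's *sample cycle* $z$. Probe beats $x_i$ are scored by Euclidean
distance $S_i = \lVert x_i - z \rVert_2$, and with $k = \min_i S_i$ an
integer threshold $Th$ keeps exactly the beats satisfying

$$S_i < k + Th,$$

so artifact-dominated beats never reach the classifier. Identification is
1:N over the enrolled cohort, by a nearest-template classifier or a
built-in LSTM sequence classifier (RMSprop, learning rate 0.001, 10
epochs, dropout 0.5), scored as
$\mathrm{Accuracy} = (TP+TN)/(TP+FN+FP+TN)$.

The package is aimed at researchers in ECG biometrics and biosignal
quality screening who need a complete, reproducible reference pipeline —
including a seeded multi-subject synthetic ECG generator with
condition-dependent noise (sitting, slide touch, post-exercise, driving),
so everything is testable without access to a private dataset.

## Worked example

```r
library(ecgid)

templates <- make_cohort(4, seed = 42)
records <- synthesize_cohort_records(templates, condition = "driving",
                                     reg_duration = 30, rec_duration = 30,
                                     fs = 360, seed = 42)
cfg <- pipeline_config(fs = 360, classifier = "nearest")
report <- run_pipeline(cfg, records, normalize = "adaptive", n_cycles = 2)
report
#> <pipeline_report> 4 subject(s), normalization: adaptive, classifier: nearest
#>   decisions: 73 (groups of 2 beat(s))
#>   mean similarity: 39.70% before, 47.38% after filtering
#>   accuracy: 0.9863 (TP=71 TN=217 FP=2 FN=2)

report$stages
#>      subject_id reg_beats rec_beats kept_beats Th sample_distance
#> S001       S001        37        45         37  9       0.9192444
#> S002       S002        31        36         29  9       1.0263205
#> S003       S003        40        44         37  3       1.4093364
#> S004       S004        42        49         40  8       1.2628933
```

Each subject enrolls with ~30–40 resting beats; of the driving-state probe
beats, the adaptive threshold (chosen per subject as the smallest `Th`
keeping ≥ 80% of beats) rejects the artifact-corrupted ones, raising the
mean similarity of the scored beats from 39.7% to 47.4%. Decisions are
made from groups of 2 beats by averaged class scores; accuracy is the
one-vs-rest tally over 73 decisions. The same run without normalization:

```r
run_pipeline(cfg, records, normalize = "none", n_cycles = 2)$accuracy
#> [1] 0.9375
```

A command-line interface wrapping the same functions (subcommands
`synth`, `preprocess`, `segment`, `normalize`, `evaluate`) is installed at
`inst/cli/ecgid.R`; pipeline settings load from YAML via
`read_pipeline_config()`.

See the vignette
(`vignettes/adaptive-threshold-normalization.Rmd`) for the model, the
design decisions and what the synthetic generator does and does not
emulate.

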