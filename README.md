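# ieegmap

Scalp-to-intracranial EEG translation with a conditional GAN, and
interictal epileptiform discharge (IED) detection from the translated
signal.

## The problem

Interictal spikes — the transient discharges that guide epilepsy diagnosis
between seizures — are generated by deep brain sources. Intracranial EEG
(iEEG, here from foramen-ovale electrodes) records them cleanly; scalp EEG
(sEEG) is attenuated by the skull, mixed across the montage, and
contaminated by artifacts, so that historically only ~9–22% of
intracranially visible IEDs are discernible at the scalp. `ieegmap`
implements a learning system that maps a scalp segment to an estimate of
the concurrent intracranial segment, and then detects IEDs from the
estimate, so that scalp-invisible discharges become recoverable from a
non-invasive recording.

## The model

Let X ∈ ℝ⁶⁴ˣ¹² be a peak-centred scalp segment (64 samples at 200 Hz, 12
temporal/frontal channels) and Y ∈ ℝ⁶⁴ˣ¹² the concurrent foramen-ovale
segment. A generator G (a 1-D U-net over the time axis) produces
Ỹ = G(X); a discriminator D scores the channel-wise concatenation (X, Y)
versus (X, Ỹ). Training alternates on

- adversarial objective:
  `L_GAN(G, D) = E[log D(X, Y)] + E[log(1 − D(X, G(X)))]`,
  ascended by D, descended by G;
- generator loss:
  `L_G = L_GAN + λ · E‖Y − G(X)‖₂`, with λ = 100 by default (the
  Euclidean norm itself, not its square).

The IED/non-IED classifier is a compact EEGNet-style CNN with two
modifications: all batch-normalization stages removed, and max pooling at
every pooling stage. The whole GAN (generator + discriminator) has 204,157
trainable parameters — under the 0.25 × 10⁶ budget and more than 12× below
the 3.12 × 10⁶ of the autoencoder-based comparator family.

Both networks are implemented natively (vectorized R with hand-written,
finite-difference-verified backpropagation); no deep-learning framework is
required.

Because paired clinical scalp/FO recordings are not publicly available,
the package ships a seeded forward simulator of paired cohorts
(spike-plus-slow-wave sources, focal intracranial projection, attenuated
and blurred scalp projection, 1/f background, 10 Hz rhythm, eye-blink
artifacts, controlled scalp-visibility fraction), so every stage is
testable end to end.

## Worked example

```r
library(ieegmap)

# simulate one subject: 200 annotated IEDs, 15% scalp-visible
scfg   <- synthesis_config(n_subjects = 1, n_ieds_per_subject = 200,
                           visibility_fraction = 0.15, seed = 11)
paired <- preprocess_paired(simulate_subject(scfg, 1))  # 1-70 Hz, notch, CAR

# intra-subject protocol: 70/10/20 split, GAN translator, EEGNet detector
res <- run_intra_subject(paired,
                         translator_config(n_epochs = 25, seed = 2),
                         detector_config(n_epochs = 20, seed = 3),
                         seed = 5, scalp_baseline = TRUE)
res$metrics
#>   subject_id tp tn fp fn acc sen spc
#> 1         S1 36 36  4  4 0.9 0.9 0.9
res$metrics_scalp$acc        # same detector trained on raw scalp segments
#> [1] 0.7
c(res$corr_translated, res$corr_baseline)
#> [1] 0.12702834 0.04525112
```

Read: from the translated segments the detector labels the held-out test
segments with 90% accuracy versus 70% from the raw scalp segments, and the
translated waveforms correlate with the true intracranial ones roughly
three times as well as the channel-matched scalp input does — the
translation recovers intracranial structure the scalp alone misses.

A command-line interface wraps the same pipeline:

```sh
exec/ieegmap simulate --out cohort/ --seed 5
exec/ieegmap run --mode intra --cohort cohort/ --out run/
exec/ieegmap report --run run/
```

## Package layout

- `R/synthesis.R` — seeded paired-cohort simulator and IED templates
- `R/preprocessing.R` — filtering, re-referencing, channel selection,
  peak-centred segmentation
- `R/nn.R` — neural-net primitives with manual backprop
- `R/translator.R` — U-net generator, discriminator, GAN losses, training
- `R/detector.R` — modified-EEGNet classifier
- `R/evaluation.R` — metrics, intra-subject and leave-one-subject-out
  protocols, average voting
- `R/io.R`, `R/config.R`, `R/cli.R`, `exec/ieegmap` — EDF/CSV/JSON I/O,
  YAML run configuration, command-line interface
- `vignettes/translation-methods.Rmd` — model, assumptions, and design
  choices in detail
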