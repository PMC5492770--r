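# semgforce

Continuous hand-force estimation from multichannel surface EMG (sEMG), for
myoelectric prosthesis control research. The package covers the full
pipeline:

1. **Synthetic session simulator** — synchronized sEMG + force recordings
   emulating a realistic acquisition chain (8 electrode sites, 10–500 Hz
   band, 10-bit ADC over 0–3 V with a 1.5 V level shift, 1 kHz/channel),
   with grip bursts (1–2 s, < 30 N) or signed 3D push–pull episodes
   (~1 s, < 20 N).
2. **Time-domain features** — per-channel sliding-window mean absolute
   value (MAV), mean square (VAR), zero crossings (ZC) and Willison
   amplitude (WA).
3. **GRNN regression** — a Generalized Regression Neural Network
   (Gaussian-kernel instance-based regression): one pattern unit per
   training window,
   ŷ(x) = Σᵢ yᵢ·Pᵢ / Σᵢ Pᵢ with Pᵢ = exp(−‖x − xᵢ‖² / 2σ²),
   mapping the feature vector to grip force or the 3-vector of push–pull
   force. No iterative training; σ is selected by cross-validation.
4. **Evaluation** — k-fold (default 2-fold) cross-validated MAVE
   (mean absolute error, N), RMS error (N, with N−1 denominator) and
   Pearson ρ per output dimension.
5. **Feature comparison statistics** — one-way ANOVA (grip) or
   main-effects two-way ANOVA (3D: direction + feature), followed by Tukey
   HSD homogeneous subsets at α = 0.05, in the conventional full-table
   layouts.

A six-subject benchmark table of per-subject estimation accuracies ships
with the package (`reference_accuracy()`), so the comparison statistics
have a worked, reproducible target.

## Worked example

```r
library(semgforce)

# simulate a grip session: 4 EMG channels, 8 grasp bursts, seeded
cfg     <- sim_config("grip", seed = 42)
session <- simulate_session(cfg, n_episodes = 8)

# MAV features on 200-sample windows, hop 50; force sampled at window ends
fm <- sliding_features(session$emg, feature_config(feature = "MAV"))
ts <- assemble_training(fm, session$force)

# 2-fold cross-validated GRNN accuracy
cross_validate(ts, sigma = 0.3, k = 2, seed = 42)
#> <evaluation_report> 2-fold CV on 417 windows (sigma = 0.3)
#>  dimension MAVE (N) RMS (N) rho (%)
#>       grip    1.461   2.221   95.77
```

Held-out estimates correlate with the true grip force at ρ ≈ 96 %, with a
mean absolute error of ≈ 1.5 N against bursts peaking near 28 N.

Comparing the four features on the shipped benchmark table:

```r
res <- compare_features(reference_accuracy("grip"))
res$mave$anova
#> <anova_table> design = oneway
#>          source sum_sq df mean_sq      F        p
#>  Between groups  3.646  3   1.215 70.554 8.17e-11
#>   Within groups  0.345 20   0.017     NA       NA
#>           Total  3.990 23      NA     NA       NA
res$mave$tukey
#> <tukey_result> 4 groups, n = 6, alpha = 0.05
#>  group N subset_1 subset_2 subset_3
#>    MAV 6   0.6100
#>     WA 6            0.9233
#>    VAR 6            1.0483
#>     ZC 6                     1.6817
#>   Sig.      1.000    0.375    1.000
```

The features differ strongly (F(3, 20) = 70.6), and the Tukey subsets show
MAV is the most accurate (lowest error, alone in the best subset), WA and
VAR are statistically indistinguishable, and ZC is the worst.

## Command line

A thin wrapper over the same functions is installed at `exec/semgforce`:

```sh
semgforce simulate --task grip --episodes 6 --seed 1 --out session.csv
semgforce train    --session session.csv --feature MAV --sigma auto --out model.json
semgforce estimate --model model.json --session session.csv --out pred.csv
semgforce evaluate --session session.csv --feature MAV --k 2 --seed 1
semgforce compare  --table accuracy.csv --out stats
```

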