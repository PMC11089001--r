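# phasesig

Beta-oscillation phase signatures and decoding of behavioral transitions in
hypothalamic electrophysiology.

During innate behaviors (feeding **F**, social contact **S**, new-object
exploration **E**), the lateral hypothalamic local field potential (LFP)
shows discrete beta-band (15–30 Hz) oscillation episodes, and the spikes
different neurons fire at different oscillation phases carry information
about the *upcoming* behavior — a phase-resolved population code that is
strongest in the 2 s before behavior onset ("transition epochs").
`phasesig` implements that analysis as a tested, reusable pipeline for
electrophysiologists and computational neuroscientists:

1. **Episode detection** — band-pass, envelope (analytic-signal magnitude),
   smooth; events above `mean + 2 s.d.` for ≥ 80 ms, boundaries at the
   `mean + 1 s.d.` crossings (`detect_episodes()`).
2. **Spike phases** — Hilbert phase of the band-passed LFP, assigned only to
   in-episode spikes; 0° = oscillation peak (`assign_spike_phases()`),
   smoothed 20-bin circular histograms (`phase_histogram()`).
3. **Match scores** — each unit × behavior firing rate as a mid-rank
   percentile *m* ∈ [0, 1] of 2–4-min time-shift surrogates
   (`match_score_table()`); multimodal, burst/tonic and putative-dopamine
   classification (`classify_multimodal()`, `classify_isi()`).
4. **Phase signatures** — per phase bin, among the upper-quartile "highly
   active" cells, the odds that a cell is behavior-activated:

   φ = c / (N − c),  c = #{m > 0.5} of N highly active cells,

   with bootstrap replicates and the peak:trough preference
   (`phase_signature()`, `peak_trough_preference()`).
5. **Decoding** — balanced SVM datasets from signature replicates,
   stratified repeated 10-fold cross-validation, label-permutation
   significance, a train-on-best-bin / test-on-other-bins protocol, and a
   phase-shuffling null that destroys phase structure while preserving
   rates (`crossval_accuracy()`, `permutation_test()`,
   `train_best_bin_test_others()`, `phase_shuffle()`).
6. **Synthetic sessions** — a fully seeded generator (1/f LFP with injected
   beta bursts, Markov-chain ethograms, inhomogeneous-Poisson spike trains
   with von Mises phase coupling and "transition cells" that shift from
   trough to peak before behavior onsets) so the whole chain can be
   validated against known ground truth (`simulate_session()`).

Everything is tibble-in / tibble-out and pipe-friendly, with
`tidy()`/`glance()` methods for fitted objects and `autoplot()` for
signatures and permutation tests. See the methods vignette
(`vignettes/phasesig-methods.Rmd`) for the models, parameter meanings and
design decisions.

## Worked example

```r
library(phasesig)

session <- simulate_session(generator_config(seed = 1))
session
#> <phasesig_session>
#>   duration: 600 s at 1250 Hz
#>   units: 120  spikes: 804985
#>   behavior bouts: 45  ground-truth bursts: 568

episodes <- detect_episodes(session$lfp)
head(episodes, 3)
#> # A tibble: 3 × 5
#>   band    start_s end_s peak_envelope envelope_argmax_s
#>   <chr>     <dbl> <dbl>         <dbl>             <dbl>
#> 1 15-30Hz    11.8  12.1          6.76              12.0
#> 2 15-30Hz    20.4  20.6          9.87              20.5
#> 3 15-30Hz    22.5  22.8          7.33              22.7

phases <- assign_spike_phases(session$spikes, lfp_phase(session$lfp), episodes)
rayleigh_test(phases$phase_deg)
#> # A tibble: 1 × 4
#>       n r_bar     z p_value
#>   <int> <dbl> <dbl>   <dbl>
#> 1 38449 0.437 7347.       0
```

Detected episodes last ≈ 200 ms and the pooled in-episode spike phases are
strongly non-uniform (mean resultant length 0.44): the generator's
entrained cells lock to the oscillation as designed. `run_pipeline()`
chains all stages — detection, phases, match scores, transition/control
epochs, signatures, decoding with permutation and phase-shuffle controls —
writes every stage output plus a provenance manifest to a directory, and is
byte-reproducible for a given seed:

```r
run <- run_pipeline(session, "out", seed = 1)
glance(run)   # accuracy, p-values, peak:trough ratios, episode counts
```

On default synthetic sessions the transition-vs-control decoder reaches
≈ 95–99 % accuracy (permutation p ≈ 0.01), the cross-bin decoder ≈ 85–93 %,
phase-shuffled data fall to ≈ 50–65 %, and the transition-epoch phase
signature is strongly peak-concentrated (peak:trough ≫ 1) while control
epochs are not (≤ 1).

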