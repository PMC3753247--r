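# pupilrps

Can you beat someone at rock-paper-scissors by watching their pupil?
When the three words are read aloud at 4-s intervals and the opponent
silently picks one as it is spoken, the pupil transiently dilates after the
chosen word, so the **time of maximum pupil dilation** decodes the concealed
choice. `pupilrps` implements that analysis end to end as a simulation
pipeline:

* a calibrated **synthetic trace generator** (120 Hz diameter traces,
  decision-locked gamma transient, distractor transients, noise) with
  *exact* control over marker validity via rejection sampling;
* the **peak-timing decoder**: the interval containing the global diameter
  maximum is the decoded choice, `validity()` the fraction of games it gets
  right;
* **player strategies** against the decoded signal — a follower with
  probability *f* wins at rate *f·v + (1 − f)/3* for marker validity *v*;
* the **statistics**: exact one-sided binomial tests of k wins in n games at
  chance 1/3, `p = Σ_{k≤i≤n} C(n,i) (1/3)^i (2/3)^(n−i)`, Bonferroni
  correction across players, per-n sequential significance boundaries for
  learning curves, and group t-tests against 33%;
* a five-condition **study replication** (`replicate_study()`), including
  the 100%-validity subset construction (first 10 decoder-valid games per
  interval, replayed in 4 randomised blocks).

## Worked example

```r
library(pupilrps)

fixture <- reference_fixture()        # deterministic 75-game opponent set
validity(fixture)
#> # A tibble: 1 × 3
#>   n_valid n_total fraction
#>     <int>   <int>    <dbl>
#> 1      45      75      0.6

summarize_traces(fixture)
#> # A tibble: 1 × 3
#>   mean_diameter_mm mean_range_mm sd_range_mm
#>              <dbl>         <dbl>       <dbl>
#> 1             4.63          3.84        1.05

s <- play_session(fixture, strategy_always_follow(), seed = 1)
sum(s$win)
#> [1] 45

binomial_tail(75, 37)[, c("n", "k", "p_value", "significant")]
#> # A tibble: 1 × 4
#>       n     k p_value significant
#>   <dbl> <int>   <dbl> <lgl>
#> 1    75    37 0.00299 TRUE
```

The fixture decodes to exactly 45/75 valid games (60% marker validity), so
a player who always counters the decoded choice wins exactly those 45
games — well above the 25/75 expected by chance. A player with 37/75 wins
is individually significant (p = 0.003 < 0.005, the Bonferroni-corrected
level for 10 players). `learning_curve()`, `autoplot()` and
`plot_learning_curves()` visualise cumulative wins against the per-n exact
binomial significance boundary; `run_condition()` and `replicate_study()`
simulate whole player groups, with `tidy()`/`glance()` summaries.

See `vignettes/pupil-decoding.Rmd` for the trace model, the calibration,
the decoder's window/tie policy and the statistical conventions.

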