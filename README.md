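# phosvpl

Tools for longitudinal studies of visual perceptual learning under
simulated prosthetic (phosphene) vision. The package is aimed at
psychophysicists and prosthesis-simulation researchers who need to (i)
render gaze-contingent phosphene views of images and video, (ii) turn
MNREAD-style reading trials into equivalent acuities, and (iii) separate
how much of a longitudinal acuity gain came from an *active* task (reading
tests) versus a *passive* task (video watching) when both are interleaved
in the same subjects.

## The model at the core

Subjects attend 23 sessions: 21 daily video sessions with reading tests
interleaved at 6 of 8 possible positions per subject. The *syncopated*
placement of tests creates spans between consecutive acuity measurements
containing either three videos (RvvvR) or six (RvvvvvvR). Under an
additive model — each reading session changes acuity by a constant
β<sub>R</sub> (logMAR/session) and each video session by β<sub>V</sub>,
with the span-closing test measuring but not yet influencing its own span
— the mean acuity changes over short and long spans are

    y1 = 3 βV + βR        (RvvvR)
    y2 = 6 βV + βR        (RvvvvvvR)

a linear system whose solution decodes the per-session learning rates:

    βV = (y2 − y1) / 3
    βR = 2 y1 − y2

Equivalent acuity itself comes from a reading test: word-level correctness
versus font size (logMAR 0.9–1.4) is fit by a logistic psychometric
function with asymptotes fixed at 0/100%, and the 50% crossing is the
acuity. The renderer implements *veridical encoding*: a center-weighted
field of 1000 phosphenes is translated to the current gaze point; each
phosphene samples the mean image luminance under its footprint and is
redrawn as a 2D Gaussian at that luminance.

A synthetic-cohort generator produces word-level reading responses, gaze
traces and toy video frames with exactly the statistical structure this
analysis assumes, so the whole pipeline is testable without human data.

## Worked example

Decode the per-session rates from mean span improvements, then attribute
the overall gain to each task (5 influencing reading sessions vs 21
videos):

```r
library(phosvpl)

decode_rates(-0.025, -0.035)
#> <learning_rates> beta_R = -0.015, beta_V = -0.003 logMAR/session
#>   from y1 = -0.025 (n=NA short spans), y2 = -0.035 (n=NA long spans)

attribute_gains(decode_rates(-0.025, -0.035))
#> # A tibble: 2 × 5
#>   task        rate n_sessions gain_logmar pct_of_total
#>   <chr>      <dbl>      <dbl>       <dbl>        <dbl>
#> 1 reading -0.015            5     -0.075          51.7
#> 2 video   -0.00333         21     -0.07           48.3
```

Reading sessions drive roughly twice the per-session improvement of video
sessions (−0.015 vs −0.003 logMAR/session) despite being about half as
long, and the two tasks split the overall gain roughly evenly once the 21
video sessions are accounted for.

The same decoder runs end-to-end on a synthetic cohort:

```r
sch     <- build_schedule(8, seed = 1)           # 23-session syncopated design
sim     <- gen_cohort(cohort_config(), sch, seed = 1)
acuities <- fit_cohort_acuities(sim)             # logistic fit per reading test
spans   <- extract_spans(acuities, sch)          # y1/y2 span improvements
decode_rates(spans, per_subject = TRUE)
#> <learning_rates> beta_R = -0.026, beta_V = -0.001 logMAR/session
#>   from y1 = -0.030 (n=24 short spans), y2 = -0.034 (n=16 long spans)
#>   per-subject decodes attached (8 subjects)
```

A single simulated cohort is noisy (the generating rates here were −0.015
and −0.00333); `recovery_experiment()` repeats this over many replicates
and shows the decoder is unbiased. `autoplot()` methods exist for fields,
psychometric fits, span improvements and recovery reports, and
`tidy()`/`glance()` for the fitted objects.

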