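# speechmarker

Quantifies clinician-rated speech and language change in mild cognitive
impairment (MCI) and Alzheimer's dementia (AD) from timed
picture-description recordings — the Cookie Theft task of the Boston
Diagnostic Aphasia Examination is the canonical stimulus. It is written
for researchers building or validating automated speech biomarkers who
need the full chain from raw transcript/audio to interpretable constructs.

The pipeline:

1. **Feature extraction** from timed, POS-tagged transcripts and optional
   waveforms: pauses and speech rate; framewise zero-crossing and MFCC /
   log-energy statistics (mean, variance, skewness, kurtosis of each
   channel and its ±2-frame regression deltas); word length, frequency and
   psycholinguistic norm scores (AoA, valence, arousal, dominance);
   lexical diversity (TTR, MATTR, Brunet's W, Honoré's R); constituency
   production rates; utterance repetitiveness and picture similarity by
   cosine distance; word-adjacency graph topology. Every emitted feature
   is listed in `feature_manifest()`.
2. **Consensus ratings**: per item the modal rating of an ordinal 0–3
   multi-rater panel, with discrepancy flagging (range ≥ 2) and
   second-round re-rating; inter-rater reliability as the two-way
   random-effects intraclass correlation,
   `ICC(2,1) = (MS_R − MS_E) / (MS_R + (k−1)MS_E + k(MS_C − MS_E)/n)`,
   reported together with ICC(2,k).
3. **Screening**: Spearman's ρ of each feature against the consensus
   rating, two-sided p from `t = ρ√((n−2)/(1−ρ²))`, selection at
   unadjusted p < 0.05.
4. **Odds ratios** of impairment (consensus ≥ 1) between diagnostic
   groups, Haldane–Anscombe corrected with Woolf 95% intervals.
5. **Exploratory factor analysis** of the selected variables: Horn's
   parallel analysis (95th percentile of 100 random-data eigenvalue
   draws) for the factor count, iterated principal-axis extraction,
   direct-oblimin (quartimin) rotation by gradient projection, and a
   conservative |loading| ≥ 0.6 assignment rule.

A synthetic cohort generator (10 HC / 10 MCI / 10 AD, ~1-minute
transcripts, severity-linked pause/duration/word-choice/repetition maps,
noise-burst waveforms, simulated 5-rater panels) makes the whole pipeline
runnable and testable without access-controlled clinical data.

## Worked example

```r
library(speechmarker)

cohort <- simulate_cohort(cohort_config(), seed = 7)
panel  <- simulate_rating_panel(cohort$true_severities, n_raters = 5,
                                rater_sd = 0.35, seed = 8)

icc(panel, "word_finding")
#> ICC(2,1) = 0.786, ICC(2,5) = 0.948 [good], F(29,116) = 19.10, p = 7.22e-32

cons  <- consensus_rating(panel, "word_finding")
feats <- extract_feature_matrix(cohort$transcripts, norms = synthetic_norms(),
                                emb = synthetic_embeddings(),
                                lexicon = read_content_lexicon())
screen <- spearman_screen(feats, setNames(cons$consensus, cons$item))
head(screen[, c("feature", "rho", "p_value", "selected")], 5)
#>                          feature    rho  p_value selected
#>        acoustic.rate.speech_rate -0.912 2.36e-12     TRUE
#>  acoustic.rate.avg_word_duration  0.905 6.93e-12     TRUE
#>    acoustic.pause.total_long_dur  0.866 6.20e-10     TRUE
#>        acoustic.pause.long_count  0.851 2.49e-09     TRUE
#>          acoustic.pause.mean_dur  0.810 5.76e-08     TRUE

group_odds_ratio(cons, cohort$labels, "AD", "HC")
#> OR(AD vs HC) = 21.00, 95% CI 0.97-453.94 (Haldane-Anscombe corrected)

efa <- run_efa(feats[, screen$feature[screen$selected]], seed = 7)
efa
#> <efa_result: 2 factor(s), 12 variables, n = 30>
#> variance explained (%): 53.1, 22.8
#> 12 variable(s) assigned at cutoff
```

Reading the numbers: raters agree well on word-finding difficulty
(ICC(2,1) = 0.79, "good" band); the features most correlated with the
consensus are slower speech (ρ = −0.91) and longer words and pauses
(ρ > 0.8), exactly the signs the generator builds in; the odds of any
word-finding impairment are 21 times higher in AD than in controls (the
interval is wide — n = 10 per group); and the twelve selected variables
collapse onto two oblique factors.

`run_pipeline(run_config(out_dir = "out", seed = 1))` runs all stages —
including waveform synthesis and spectral features — and writes per-stage
CSVs, a feature manifest, `summary.json` and a run log. A thin CLI over
the same functions lives at `inst/cli/speechmarker.R`
(`run | simulate | extract | consensus | icc | screen | odds | efa`).

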