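---
title: "Quantifying clinician-rated speech change from picture descriptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying clinician-rated speech change from picture descriptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechmarker)
```

## The problem

Clinicians describe the speech of people with mild cognitive impairment
(MCI) and Alzheimer's dementia (AD) with constructs such as *word-finding
difficulty*, *incoherence*, *perseveration* and *errors in speech*. Those
constructs are subjective; automatic speech analysis produces hundreds of
objective variables. `speechmarker` implements the bridge between the two
for timed picture-description recordings (the Cookie Theft stimulus of the
Boston Diagnostic Aphasia Examination is the canonical elicitation):

1. extract named lexical, syntactic, semantic and acoustic variables from
   a timed, POS-tagged transcript and (optionally) the waveform;
2. build a modal consensus rating per construct from a multi-rater ordinal
   panel, with inter-rater reliability (ICC);
3. screen variables against the consensus rating with Spearman correlation;
4. compare the odds of impairment between diagnostic groups;
5. summarise the selected variables with exploratory factor analysis (EFA).

Because real clinical corpora of this kind are access-controlled, the
package ships a synthetic cohort generator with the same statistical
structure, so every stage is exercised end to end by code alone.

## Feature extraction

### Pauses and timing

Pauses are computed from the word-level alignment, not from waveform
energy: a pause is a gap between consecutive non-filler token intervals,
pooled across utterances. Two thresholds matter and neither is
standardised in the clinical literature, so both are arguments with
documented defaults: a gap of at least `unfilled_min = 0.25` s counts as
an unfilled (silent) pause, and unfilled pauses of `long_min = 1.0` s or
more are "long", the rest "short". A gap containing a filler token
(um/uh) is a *filled* pause and is excluded from the unfilled counts.
Speech rate is non-filler words per minute of *elapsed* time, so pause
time stays in the denominator — this is what makes rate fall as pausing
rises, which is the behaviour the construct needs.

### Framewise spectral statistics

Zero-crossing counts and mel-frequency cepstral coefficients (MFCCs) are
computed on 25 ms frames advanced by 10 ms (`floor((N - win)/hop) + 1`
frames). The MFCC configuration is not uniquely determined by common
practice, so every element is an argument with these defaults: 0.97
pre-emphasis, Hamming window, power spectrum `|FFT|^2 / nfft`, 26
triangular mel filters (HTK mel scale) spanning 0 to Nyquist, orthonormal
DCT-II, coefficients c1..c13. Indexing is 1-based — "the 4th MFCC" is c4
— and c0 is dropped in favour of a separate per-frame log-energy channel
(natural log of the pre-emphasized frame energy). First and second
derivatives of every channel use ±2-frame regression deltas with
replicated edges. Each channel is summarised by Pearson moment statistics:
mean, population variance, skewness `m3/m2^1.5` and *non-excess* kurtosis
`m4/m2^2`; a zero-variance channel reports missing skewness/kurtosis
rather than a 0/0 artefact. Zero crossings count strict sign changes with
zeros treated as positive, which makes every ZCR statistic exactly
invariant to amplitude scaling.

### Lexical, syntactic, semantic and graph variables

Fillers are excluded from every lexical, semantic and graph count; they
exist only for pause logic. Psycholinguistic norm means (Zipf frequency,
age of acquisition, valence/arousal/dominance) are taken over covered
tokens only, with the coverage fraction reported alongside — a missing
norm is never imputed as 0, because a zero AoA or valence would bias the
mean, which is the statistic being screened. "Use of X" variables are
normalised per 100 words; the clinical literature rarely states its
normalisation, so the manifest (`feature_manifest()`) records ours.

Syntactic variables are counted by pattern matching on bracketed
constituency parses: `NP -> DT NN` productions, `VP -> VBD NP`, VP with
VBZ and PP children, VP dominating SBAR, coordinate phrases (a CC child
flanked by same-category siblings), ADJP nodes, VP with a CC child, and
clauses (S/SBAR), plus coordinate phrases per clause.

Utterance repetitiveness represents each utterance as a bag of lemmas
(surface-level bags would conflate inflection with novelty) and reports
the mean/min/max cosine distance over all unordered pairs: identical
utterances give 0, disjoint vocabularies 1, and *low* mean distance means
repetitive speech. All-pairs rather than consecutive-only distances are
the default because perseverative returns to a topic need not be
adjacent. Picture similarity embeds each utterance as the mean embedding
of its covered lemmas, takes per utterance the minimum cosine distance to
the picture key words, and reports the maximum over utterances — an
utterance far from every key word is the signal. The shipped Cookie Theft
lexicon (subjects boy/girl/mother with synonym lists, objects, places,
actions) is a plain TSV and fully user-replaceable.

The speech graph has lemma types as nodes and consecutive within-utterance
token pairs as directed multigraph edges; reported metrics are node/edge
counts, repeated edges, self-loops, the largest weakly connected
component, and density over distinct non-loop edges.

## Consensus ratings and reliability

Ratings are ordinal 0–3 per sample x characteristic x rater. The
consensus is the modal rating; a multimodal tie goes to the value nearest
the item mean and a remaining tie to the *lower* severity (ties are rare
in practice; the rule just needs to be deterministic and conservative).
Items where raters span 2 or more points are flagged, mirroring the
clinical workflow in which such items are re-rated: a second-round panel
replaces the flagged items and the modes are recomputed.

Reliability is the two-way random-effects absolute-agreement intraclass
correlation. Because reports in this literature often omit which ICC form
they used, the package always computes both the single-rater form

$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + k(MS_C - MS_E)/n}$$

and the average-rater form ICC(2,k), with ICC(2,1) as the headline, and
interprets it on the conventional bands (<0.5 poor, 0.5–0.75 moderate,
0.75–0.9 good, ≥0.9 excellent; boundary values go up). The implementation
is validated to 1e-6 against an independent reference implementation on
20 seeded 30x5 panels.

## Screening and odds ratios

Each feature is screened against the consensus rating with Spearman's
rho (average ranks on ties) and the two-sided t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom. Selection
is at an *unadjusted* 0.05 — deliberately liberal, as the screen feeds an
exploratory factor analysis rather than a confirmatory claim; a
Benjamini–Hochberg flag is available but off by default. Two calibration
facts, both established by the test suite: at the study scale (n = 30,
ordinal consensus) the null selection fraction is 0.05 within ±0.006 over
10,000 features; and at small n the t approximation tracks the
permutation null within 0.02 *for untied data*. With a heavily tied
4-level target and n ≤ 15 the permutation null is lumpy and the t
approximation can deviate by substantially more — a known limitation of
the approximation that matters below roughly n = 20.

Odds ratios dichotomise the consensus at ≥ 1 ("any impairment present";
the threshold is an argument) and form the 2x2 group-by-impairment table.
When a cell is zero the Haldane–Anscombe correction adds 0.5 to all four
cells; the 95% CI is Woolf's log-scale interval. This estimator is an
explicit stand-in: published ORs in this literature rarely state their
estimation method, and with n = 10 per group the intervals are wide
whatever the method.

## Exploratory factor analysis

The number of factors comes from Horn's parallel analysis on the *full*
Pearson correlation matrix (Horn's original formulation; the reduced-matrix
variant is a switch): the observed eigenvalues are compared
position-by-position against the 95th percentile of eigenvalues from 100
correlation matrices of iid standard-normal data of the same shape, and k
is the length of the initial run of exceedances. The percentile uses the
type-6 quantile estimator deliberately: for m iterations it is the
order-statistic estimator whose exceedance probability is exactly the
nominal level, whereas the interpolating default is measurably liberal
(about 7% instead of 5% retention of a null first eigenvalue at m = 100).
Even so, a rule that retains null eigenvalues at exactly 5% sits on its
own boundary: across 100 replicate null datasets the expected number of
spurious retentions is 5.

Extraction is iterated principal-axis factoring: squared multiple
correlations initialise the communalities (`1 - 1/diag(R^-1)`; when R is
singular — e.g. more selected variables than samples, which this design
hits routinely — the Moore–Penrose pseudoinverse is used, with a
max-|off-diagonal| fallback), then the reduced correlation matrix is
eigendecomposed and communalities updated until they move by less than
1e-4 (at most 200 sweeps), clamped at 0.995 to contain Heywood cases.

Rotation is direct oblimin with γ = 0 (quartimin) by the oblique
gradient-projection algorithm, restarted from 30 seeded random rotation
matrices with the lowest criterion kept; factors are sign-flipped so each
factor's largest loading is positive and ordered by explained variance.
Variables are assigned to the factor with their largest absolute pattern
loading *among factors reaching the 0.6 cutoff* (conservative for n = 30),
so each variable lands in at most one factor column; ties go to the lower
factor index. The variance proportion of factor j is its pattern sum of
squares over p, in percent — with oblique factors these proportions need
not sum to the total common variance, and every report carries that
caveat.

## The synthetic cohort

`simulate_cohort()` emulates a 30-sample study: 10 HC / 10 MCI / 10 AD,
each sample with a latent severity per characteristic drawn from its
group's distribution on the 0–3 rating scale (defaults: word-finding
means 0.3/1.5/2.3, incoherence 0.3/1.3/2.0, perseveration 0.2/0.6/1.4,
speech errors 0.2/0.6/1.2 — the last two mostly low and AD-driven, which
is how those constructs present), clipped to [0, 3]. Transcripts of
roughly 60–110 words over a closed Cookie-Theft vocabulary are built from
parse-templated utterances; every generator map is monotone in its
severity:

* word-finding severity raises the probability (0.06 + 0.09 s) and
  lognormal duration of inter-word pauses, lengthens word durations, and
  tilts word sampling toward frequent (high-Zipf, hence shorter) words —
  so pause counts rise, speech rate falls and mean word length falls;
* incoherence severity tilts word sampling toward late-acquired and
  lower-valence words and raises past-tense template use;
* perseveration severity raises the utterance-repetition probability
  (0.05 + 0.10 s) and shrinks the content vocabulary, lowering cosine
  distances and lexical diversity;
* speech-errors severity raises the weight of subordinate-clause
  templates (VP dominating SBAR).

Rater panels draw `clip(round(severity + bias_r + N(0, 0.35)), 0, 3)` per
rater; 5 raters at SD 0.35 put ICC(2,1) in the high-agreement range for
the strongly separated constructs and lower for perseveration/speech
errors, as in real panels. Waveforms are smoothed noise bursts under the
word intervals with exact silence in gaps — sufficient for ZCR, energy
and pause acoustics, and for exercising the MFCC code paths, but *not
speech*: MFCC values from them carry no phonetic meaning and are
validated against an independent reference implementation rather than
against real-speech expectations. The generator does not emulate
disfluent word fragments, prosody, speaker overlap, or ASR/alignment
error; passing tests therefore demonstrate the statistical machinery, not
robustness to transcription noise.

All generators are pure functions of (configuration, seed), so full
pipeline runs are byte-reproducible.

## Problem sizes and numerical checks

The test suite runs the study design at its native scale (30 samples, 5
raters, ~220 features) plus: 20 reference ICC panels; a 10,000-feature
null screen at n = 30; 50 permutation-agreement cases at n = 12 with
20,000 permutations each; 100 replicate factor-recovery datasets (p = 12,
n = 500, loadings 0.8, factor correlation 0.3) and 100 null
parallel-analysis datasets (n = 300, p = 10); and 100 random toy parses
against a brute-force tree-pattern oracle. Tucker congruence ≥ 0.95 after
permutation/sign alignment is the factor-recovery bar.

## Known limitations

* Pause thresholds, MFCC framing and the oblimin criterion are defensible
  defaults, not community standards; all are arguments.
* The odds-ratio estimator is a stand-in (see above).
* The t-approximation p-value degrades under heavy ties at n ≤ 15.
* With more variables than samples the correlation matrix is singular;
  the pseudoinverse SMC path is exercised but factor loadings from p > n
  data should be read qualitatively.
* The synthetic cohort's 60–110-word transcripts and noise-burst audio
  are a model of the data's statistical structure, not of speech.
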