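---
title: "Methods: speech phenotyping from diarized interview transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speech phenotyping from diarized interview transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechmarkers)
```

This vignette is the package's own account of its methods: the data
model, the definition of each speech characteristic, the statistical
models, the synthetic-data generator, and the design decisions taken
where several defensible conventions existed.

## Transcript data model

The unit of input is a diarized, word-timestamped transcript: an ordered
list of word tokens, each with `text`, `start` and `end` times in
seconds, and an opaque diarization label (`spk_0`, `spk_1`, ...). Two
dialects are parsed: a flat word-record format (one JSON object per
line, with an optional `_meta` header holding the interview id and the
recording duration) and a cloud-transcription-style document with an
`items` array in which punctuation entries carry no timing. Automatic
transcribers emit punctuation as separate items; we attach punctuation
to the preceding word and never count it as a word, so "you" + "?"
yields the single token `you?` with clean form `you`. This is a
convention — transcriber output formats differ — and it only affects the
raw text retained for display, not timing or word counts.

All internal computation stays in seconds; minutes appear only in the
emitted feature values. Tokens are sorted by start time on ingestion, so
parsing is insensitive to input record order. A recording duration
missing from the input is derived as the last token's end time and
flagged, because the derived value underestimates the true file length
and hence inflates `speaker_percentage`.

## Speaker identification

Structured symptom interviews follow a script, so the clinician's side
of the conversation is predictable. Each raw speaker's turn texts are
compared against a bundled prompt list; the speaker that best matches
the prompts is labeled clinician, the other participant.

The default text backend is deliberately not a neural embedding: it is a
deterministic tf-idf vectorizer over the union vocabulary of the prompts
and turns at hand (lowercased, punctuation stripped, smoothed idf), with
cosine similarity. A deterministic backend makes tests hermetic and
results reproducible; the vectorizer argument is a plain functional
contract (`character vector -> numeric matrix`), so a sentence
transformer can be dropped in where semantic rather than lexical
similarity is wanted.

Pooling is *mean over prompts of the per-prompt maximum over turns*.
Among the alternatives (mean-of-means, max-of-max), this choice rewards
a speaker who covers many distinct prompts over one who happens to echo
a single prompt — the participant often repeats fragments of the
question just asked, and max-of-max is vulnerable to exactly that. The
margin between the two speakers' scores is reported, with a
`low_confidence` flag below 0.05 (an arbitrary but fixed convention; an
exact tie breaks to the lexicographically smaller label and is always
flagged). The bundled prompts are generic paraphrases of structured
psychiatric-interview questions, not the verbatim text of any
proprietary instrument; the method only requires that the prompt list be
known and distinctive.

## The twelve speech characteristics

A **turn** is a maximal run of consecutive same-speaker tokens in
start-time order; boundaries occur exactly at speaker changes. Features
are computed over the participant's turns.

* **Speaking time is turn span** (last word end − first word start), so
  short within-turn pauses count as speaking. The alternative — summing
  word durations — was rejected because transcriber word boundaries
  systematically truncate, biasing every span-derived feature downward.
* **Rates are pooled**: `words_per_minute` is total words over total
  speaking time (equivalently a duration-weighted mean of per-turn
  rates). An unweighted per-turn mean is noisy when many turns are a
  single word ("yes" in 0.2 s is 300 wpm); the pooled definition is
  stable. The unweighted variant remains available via
  `rate_definition = "per_turn"`.
* **Syllables** are estimated by a standard heuristic: count maximal
  vowel groups (a, e, i, o, u, y), discount a final silent "e" (but not
  "-le"), floor at one. It is wrong on loanwords and some morphology,
  but it is deterministic, fast, and consistent between the extractor
  and the generator, which is what a *relative* rate measure needs.
* **Word pauses** are gaps between consecutive words within a turn.
  Small negative gaps occur in real transcriber output (boundary
  jitter) and are clamped to zero. The variability feature is the
  sample standard deviation and requires at least two gaps; with fewer
  it is emitted as missing — never fabricated as zero, which would be
  indistinguishable from genuinely fluent speech.
* **Pre-turn pause** is the latency from the end of a clinician turn to
  the start of the participant turn that immediately follows it. A
  negative latency means the participant began before the clinician
  finished — an interruption. Interruption latencies are excluded from
  the average (a −0.3 s "pause" is not a short pause; it is a different
  behavior) and counted in `qc$n_interruptions_excluded`. Overlap is
  detected and flagged, but text is never reassigned between speakers
  and the amount of overlapping speech is not quantified.
* **Sentiment** is, by default, the fraction of participant words
  matching bundled positive/negative valence word lists, aggregated
  across turns weighted by turn word count. The scorer is a pluggable
  contract (`words -> c(positive, negative)`) so a model-based valence
  predictor can replace the lexicon.
* **Interview-length adjustment.** Rates, percentages and means are
  intrinsically normalized for interview length, so no further
  adjustment is applied by default; an optional residualization of each
  feature on recording duration is available
  (`adjust_interview_length = TRUE`) for analyses where residual length
  confounding is a concern. The two total-amount features
  (`speech_length_minutes`, `speech_length_words`) are length-related
  by definition and are interpreted as such.

## Statistical layer

**Distributions.** Mean, sample SD and excess kurtosis (bias-uncorrected
fourth standardized moment minus 3) per feature; kurtosis near the
normal range supports parametric testing downstream.

**Demographic screens** use the screening visit only, avoiding repeated
measures: Pearson correlation with age (r, R², p), and Welch two-sample
t-tests for sex (female vs male) and race (black vs white; other
categories are excluded from that contrast). Groups with fewer than
three subjects skip the test with a note rather than reporting an
unstable p-value.

**Mixed-effects associations.** Each feature is modeled against each
subscale score with fixed effects for the feature, age, sex and race,
and *crossed random intercepts* for subject and visit, fit by REML
through `lme4`/`lmerTest`. Random intercepts (no slopes) are the
minimal structure matching the two grouping factors: subjects differ in
baseline severity, and visits shift the whole cohort (interview length
and symptom levels both drift over a trial). The feature coefficient is
tested with Satterthwaite degrees of freedom. When the residual
variance collapses (degenerate inputs), Satterthwaite degrees of
freedom are undefined and the classical residual df is substituted.

**Partial eta-squared** for a mixed model has no single agreed
definition; we use `t² / (t² + df)` with the Satterthwaite denominator
df, which reduces to the classical fixed-model formula when the random
variances vanish and is monotone in the evidence for the coefficient.

**Multiplicity.** Benjamini–Hochberg FDR is applied within each 12-test
family (one per subscale) by default. Whether the two subscales should
form one pooled 24-test family is a judgment call — the subscales are
distinct hypotheses about distinct symptom domains — so per-scale is the
default and `fdr_scope = "pooled"` is a switch. A direction (`+`/`−`)
is only asserted for associations with FDR-adjusted p < 0.05; others
are labeled `ns`.

**Baseline-averaged OLS.** As a sensitivity analysis free of repeated
measures, features and scores are averaged over the screening and
baseline visits per subject (symptoms are assumed stable before
intervention; subjects with only one of the two visits contribute that
single value and are counted) and each feature is fit by OLS with the
same covariates and per-scale FDR.

Missing data are handled complete-case per model, with dropped-row
counts always reported.

## Synthetic cohort generator

The generator exists so that every stage — parsing, identification,
extraction, modeling — can be exercised end-to-end with known ground
truth. It emulates the *statistical structure* the analysis assumes, not
the content of psychotic speech.

Latent positive and negative severity are linear-Gaussian: per-subject
random intercepts (SD 4 score points around a mean of 20), fixed
per-visit shifts declining over the five visits (a treatment-like
trajectory), and visit-level noise (SD 1.5). Reported subscale scores
are the rounded latents clipped to the valid 7–49 range, with clip
events counted. Feature targets are `alpha + lambda_P (P − P0) +
lambda_N (N − N0) + noise`, truncated to each feature's plausible range.
The default loading signs encode the expected clinical direction
structure: amount and rate of speech load positively on positive and
negatively on negative severity; the three pause features the reverse;
positive sentiment loads negatively on positive severity; negative
sentiment positively on both. Two bookkeeping choices matter here:

* The two duration features that are arithmetically determined by
  others (`speech_length_minutes` = words / wpm;
  `turn_length_minutes_mean` ≈ turn words / wpm) are harmonized to the
  driver targets after the linear draw, so recorded targets are
  consistent with what any transcript realizing the drivers must
  produce. Their default loadings are the implied derivatives of that
  relation, keeping the sign structure intact.
* Ground truth (targets, latents, the clinician's raw label) is always
  serialized next to the data; recovery tests read it from there rather
  than re-deriving it from generator internals.

Transcript realization inverts the feature definitions: word counts and
turn structure from the amount targets; total speaking time from the
pooled rate definition; within-turn gaps drawn log-normal (positive,
right-skewed, as empirical pause distributions are) and then
moment-matched so the realized sample mean and SD equal the targets;
response latencies log-normal with a fixed 25% coefficient of
variation, re-centered on the target after interruptions are injected;
per-word durations proportional to syllable count; vocabulary drawn
from bundled neutral word pools (split by syllable count, to hit the
syllables-per-word ratio implied by the two rate targets) mixed with
positive/negative valence words at the sentiment target rates. The
recording duration is set so the speaker-percentage target holds
exactly, with the remaining time distributed as silences before
clinician turns. Interruptions are injected with configurable
probability (default 5%) and kept smaller than the clinician's final
word so token order still reflects turn order. Infeasible target
combinations (pauses that exceed the implied speaking time, or a
speaker percentage leaving no room for the clinician) raise an error
before any tokens are generated.

Default interview scale — a participant speaking ~240 words across ~20
turns at ~140 wpm, ~30% of a ~6-minute file — was chosen once as a
compact but realistic mock structured interview; it keeps cohort-scale
simulation fast while leaving every feature well-supported (≈220 word
gaps and ≈20 latencies per interview). Cohort-scale checks in the test
suite run at 150 subjects × 5 visits, with 20 replicate seeds for
Monte-Carlo properties.

**What the generator does not emulate** — and therefore what passing
tests do *not* establish about real data: transcription and diarization
errors (word substitutions, speaker confusion, dropped segments),
within-turn clinician back-channels, naturalistic language (content is
drawn from word pools), symptom dynamics beyond a fixed visit shift,
rater behavior, and any acoustic property of voice. Identification
accuracy of 100% on synthetic interviews reflects clean diarization and
verbatim-to-dropout prompt coverage; real transcripts will be noisier.

## Numerical conventions and degenerate inputs

* Ties in token start times sort stably by end time; identical
  transcripts always produce identical output.
* An exact identification tie breaks deterministically (smaller label
  is clinician) and is flagged low-confidence.
* Zero-variance features refuse to fit, naming the feature, rather than
  returning a singular model.
* p-values are clamped to the open interval (0, 1] before FDR; the BH
  step-up itself is delegated to `stats::p.adjust`.
* Kurtosis is undefined for constant samples and requires at least four
  finite values; both cases error rather than returning `NaN`.
* All generator randomness flows from one integer seed; per-interview
  seeds are derived arithmetically, so datasets are reproducible
  file-by-file.

## Known limitations

The lexical speaker-identification backend assumes the clinician's
prompts share vocabulary with the bundled list; heavily paraphrased or
non-English interviews need a substituted prompt set or embedding
backend. The syllable heuristic is English-specific. The sentiment
lexicons are small valence lists suited to synthetic and smoke-test use;
substantive sentiment analyses should plug in a validated scorer. The
mixed model treats visit as an unstructured random intercept; modeling
within-subject temporal trends (random slopes, autocorrelation) is out
of scope, as are prediction of symptom scores and any analysis of audio
itself.
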