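---
title: "Connected-speech markers of dementia: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connected-speech markers of dementia: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechmarkers)
```

This vignette documents the scientific model behind `speechmarkers`, the
parameters that matter, the numerical conventions adopted where several
defensible choices existed, and what the synthetic-cohort validation does
and does not establish about real clinical data.

## The measurement model

The pipeline treats a routine-description monologue as a stream of tokens
and derives eight per-participant features in four families.

**Token model.** Transcripts are segmented into words, punctuation, and
three disfluency kinds: fillers (a closed configurable list, default
Spanish "eh", "em", "mmm", "este"), interrupted-word fragments (a trailing
"…" marker, e.g. *hospi…*), and unintelligible spans (default marker
`[inaudible]`). Only `word` tokens enter analysis; everything else is
removed and logged. A token counts as a word when it contains a letter or a
digit — digit-written numerals and dates are stop words and stay in the
denominator, because the word-class ratios are defined against the *total*
word count including stop words. Sentence boundaries (full stops, question
and exclamation marks) delimit the agreement scope for person
disambiguation.

**Tagging model.** Word class (NOUN, VERB, ADJ, ADV, PRON, DET, ADP, CONJ,
INTJ, NUM, OTHER) and grammatical person (first/second/third/none) are
assigned by a pluggable backend; the bundled reference tagger is a
deterministic lexicon + suffix-rule system. The tagger contract is
deliberately thin — surfaces in, one tagged token per input token out — so
a full statistical tagger can be substituted without touching any
downstream stage. A production trigram-HMM tagger is intentionally *not*
re-implemented: the scientific contribution under test is the feature set,
and the bundled tagger is exact on the synthetic corpora (full lexical
coverage) and on the worked examples. Spanish person morphology is encoded
as ordered suffix rules (`-o` first person present, `-as`/`-es` second,
`-a`/`-e` third, `-é`/`-aré` first; imperfect `-aba`/`-ía` ambiguous
between first and third). Ambiguous inflections are resolved by (i) the
nearest preceding subject pronoun in the sentence, (ii) the nearest
preceding person-marked verb in the sentence, (iii) the nearest person
marker in the previous sentence, and otherwise (iv) default to third
person — the unmarked narrative baseline; the fallback order mirrors how a
human annotator uses person-verb agreement and discourse reference.
Possessive determiners (*mi*, *su*) carry person; the clitic *se* is tagged
PRON/third.

**Person counting.** Spanish is pro-drop: a verb's desinence identifies its
subject without a pronoun, yet speakers often insert the pronoun anyway. A
pronoun-verb tandem (*yo salgo*) therefore contributes **two** first-person
markers; this is the single most consequential counting convention, and it
applies symmetrically to first and third person. Second-person markers
(rare in monologue) are discarded before the ratio; a configuration flag
can instead retain them in the denominator.

**Word properties.** The four content-word features are token-level means
(repetitions included) of log10 frequency per million, phonological
neighborhood size and phoneme length from a lexical-property table, plus
semantic variability: reduce the text to content words in order, drop
repetitions, embed each word, take cosine distances between adjacent
vectors, and return the variance of that distance series.

## Numerical conventions and degenerate inputs

Where the procedure is under-specified, the package fixes one convention
and exposes the alternative behind a flag:

* *Repetition removal* for semantic variability is **global** (first
  occurrence kept, order preserved); adjacent-only collapsing via
  `dedup = "adjacent"`.
* *Distance* is cosine (`1 - cos`), the convention of the embedding family
  involved; Euclidean via `metric = "euclidean"`. Cosine makes the
  statistic invariant to global rescaling of the embedding table (tested).
* *Variance* is the sample variance (n−1 over the distance series);
  population variance via `variance = "population"`. Fewer than three
  distinct embeddable content words yield `NA` with a warning, never an
  error — short transcripts are expected clinically and are imputed (by
  training-fold median) only inside the classifier.
* *Person-ratio denominator* is first + third counts; with no such markers
  both ratios are `NA` with a warning.
* The mixed ANOVA guards the exactly degenerate stratum that
  complementary ratios produce (first + third = 1 makes every subject mean
  0.5, so the between-subject effect and error SS both vanish): it reports
  F = 0, p = 1, partial η² = 0 rather than 0/0.
* Outlier screening flags |value − mean| **strictly** greater than 3 sample
  SDs; an all-equal sample warns and flags nothing.
* Dunnett p-values come from the equicorrelated multivariate-t
  (`mvtnorm::pmvt` under a fixed local RNG seed, absolute tolerance 1e-5);
  with one treatment group the test reduces exactly to the pooled
  two-sample t.
* Tukey HSD on the 2×2 mixed design uses a single pooled error MS on the
  between-subject error df — the convention used when a single `MSE`/`df`
  pair is reported for all six cell contrasts; both are overridable
  arguments, and Cohen's d for post hocs is mean difference / √MSE.
* One-tailed t directions default to the accessible-vocabulary hypothesis:
  patients *greater* than controls for frequency and neighborhood,
  *less* for length and semantic variability; directions are arguments.
* FDR (Benjamini–Hochberg) is applied within each analysis block — word
  class, person, word properties, correlations — matching how such result
  families are conventionally reported, not globally across the study.
* Classifier: linear kernel with C = 1 (no tuning), min-max scaler fit on
  training folds only (fitting on all data leaks; the tests assert that
  scaled test values can fall outside [0, 1]), AUC computed on the pooled
  out-of-fold decision scores of each iteration (the stable choice at
  n = 42), mean/SD then taken across iterations. UAR is macro recall;
  positive class is the patient group.

## The synthetic-cohort generator

The generator is the package's stand-in for non-distributable patient
recordings. It emulates the study conditions: a main sample of 21 AD, 21
bvFTD and 21 control participants plus an 11/11/11 hold-out; transcript
lengths drawn from truncated normals (means 238.6 / 253.9 / 304.1 words,
SD 80, minimum 80) matching the reported group means; and group effects
planted on three interpretable parameters:

* `p_nounslot` — probability that a clause's object slot is realized as a
  noun phrase rather than a pro-form (*eso*, *algo*). Lowering it models
  noun-retrieval failure with circumlocution, which keeps clause length
  stable instead of mechanically inflating the verb ratio.
* `p_first` — probability of a first- versus third-person clause.
* `temp` — frequency temperature: content words are sampled from per-class
  Zipf ranks with weight `rank^-temp`, so higher values shift the
  vocabulary toward frequent words.

Each participant draws individual traits around the group parameters
(logit-normal for probabilities, normal for temperature), with a shared
latent severity factor (loading 0.6, signed so that low noun retrieval, low
self-reference and frequent vocabulary go together). The factor leaves the
marginal effect sizes untouched but gives the feature channels the
correlation structure real deficits have; without it the multivariate
classifier separates groups far more easily than any single-channel effect
size would suggest.

Group offsets were calibrated once, by bisection of `calibrate_effect()`
against Monte-Carlo realized Cohen's d (common random numbers across
evaluations), to the published targets — AD noun-ratio deficit d = 1.145
and frequency excess d = 1.13; bvFTD first-person deficit d = 0.91
(equivalently third-person excess, since the ratios are complementary) and
frequency excess d = 0.98 — and frozen as `cohort_config()` defaults
(logit offsets −0.50 and −0.539; temperature offsets +0.176 and +0.155).
Validation across independent cohort seeds at n ≥ 800 per group reproduces
the targets within ±0.1. The calibration routine itself remains exported
and tested for self-consistency.

The generator emits raw text (with configurable filler/fragment/
unintelligible rates) *and* parallel gold tags, so the tagger is testable
by round trip (agreement ≥ 99% on the closed vocabulary) while features
remain testable independently of tagger behavior. Cognitive scores (MoCA,
IFS) are drawn from group-typical distributions *independently* of the
linguistic traits, giving the correlation stage a true null. Verb
inflections in the lexicon use exactly the suffixes the tagger's fallback
rules expect; imperfect (ambiguous) forms are only emitted next to an
explicit subject pronoun, so gold person is always recoverable from
context.

Zipf ranks are assigned per word class (each class carries ranks 1..n)
rather than splitting one global rank sequence: Zipfian sampling weight
concentrates on a handful of top ranks, and a random split made the
frequency-temperature response vary substantially between lexicon
realizations, destabilizing calibration.

## What the validation shows — and what it does not

The test suite validates, among others: exact agreement of the mixed ANOVA
with an independent projection/RSS oracle (1e-10 over random balanced and
unbalanced tables); FDR against exhaustive step-up enumeration; the
demographic worked examples recomputable from published summary statistics
(Yates χ² = 0.384; Dunnett 1.76 — the corresponding AD age contrast
recomputes to 1.51 from the printed means and SDs); uniformity of the
interaction p-value over 2,000 no-effect cohorts plus chance-level CV AUC
under the null; CV AUC within ±0.10 of the closed-form binormal value
Φ(d/√2) for a single planted channel; recovery of planted interactions in
≥ 70% of 200 seeded cohorts; and, on default cohorts, cohort-averaged CV
AUC inside [0.60, 0.85] with word frequency and noun ratio as the top AD
drivers and both person markers in the bvFTD top four.

Quantities that are stochastic at the study's sample size (a 21-vs-21 CV
AUC has a seed-to-seed SD near 0.07; importance rankings flip under
resampling) are asserted on means over several independently seeded
cohorts; single-cohort assertions at these bands would test the seed, not
the method. Problem sizes used by the suites — 2,000 null simulations, 200
power seeds, 8–20 cohorts for classification aggregates, n = 800 per group
for realized effect sizes — were chosen to keep Monte-Carlo error well
inside each asserted tolerance.

Passing these suites shows the *pipeline* is correct and that the planted
effects are recovered faithfully; it does not show that real AD or bvFTD
speech satisfies the generator's assumptions. The generator produces
template clauses over a synthetic vocabulary: it models no discourse
coherence, no topic drift, no acoustic disfluency structure, and no tagger
noise (an optional uniform tag-corruption rate is the only concession). One
visible consequence: with the published effect sizes planted cleanly on
correlated channels, cross-validated AUCs land around 0.75–0.85, somewhat
above the published 0.71 — real features carry additional noise
(imperfect tags, transcription variance, clinical heterogeneity) that the
simulation deliberately omits. Conclusions about real cohorts require real
recordings through `load_corpus()` with a real lexical database and real
embeddings.

## Interfaces

The pipeline's orchestration is plain R: `simulate_cohort()` writes a
complete corpus directory (manifests, transcripts, lexicons, embeddings,
truth record) and `run_pipeline()` consumes either an in-memory cohort or
the same file formats a real study would provide, writing `features.csv`,
`stats.json`, `classification.json`, ROC coordinates and a seeded,
config-hashed `run_info.json`. These two functions, with the exported
module functions they compose, are the package's command surface.
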