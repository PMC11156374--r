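# speechmarkers

Automated connected-speech analysis for dementia phenotyping in R.

Alzheimer's disease (AD) and behavioral-variant frontotemporal dementia
(bvFTD) disturb spontaneous speech in dissociable ways: AD compromises the
retrieval of entities (nouns), while bvFTD shifts narration toward a
depersonalized, exocentric perspective (more third-person, fewer
first-person references), and both syndromes push speakers toward more
frequent, more accessible vocabulary. `speechmarkers` implements a complete,
tested pipeline that quantifies these markers in routine-description
monologues ("describe a typical day") and evaluates them at the group level
(inferential statistics) and the subject level (machine learning), for
researchers in clinical NLP and neuropsychology who need interpretable,
fully automated speech biomarkers.

## What it computes

From each transcript the pipeline derives eight features:

* **Word-class ratios** — `noun_ratio = #NOUN / N` and
  `verb_ratio = #VERB / N`, where `N` is the total word count *including*
  stop words (punctuation and disfluencies are excluded upstream).
* **Grammatical-person ratios** — every person-carrying token (subject
  pronoun, possessive determiner, inflected verb) counts individually, so a
  pronoun-verb tandem like *yo salgo* contributes two first-person markers
  (Spanish is pro-drop: verb desinences carry person on their own).
  Second-person markers are discarded;
  `first_person_ratio = n1 / (n1 + n3)`, `third_person_ratio = n3 / (n1 + n3)`.
* **Word properties** over content words (nouns, verbs, adjectives,
  adverbs): mean log10 frequency per million, mean phonological
  neighborhood size, mean length in phonemes (from a lexical-database TSV),
  and **semantic variability** — map the deduplicated content-word sequence
  to embedding vectors `e_1..e_k`, take adjacent cosine distances
  `d_i = 1 - cos(e_i, e_{i+1})`, and return `Var(d)`.

Group-level inference uses 2×2 mixed ANOVAs (group × tag ratio) with
partial η², Tukey HSD post hocs, one-tailed pooled t-tests for word
properties, Benjamini–Hochberg FDR within each analysis block, 3-SD outlier
screening, Dunnett many-to-one and Yates-corrected χ² demographic tests,
and feature–cognition correlations (Spearman or Pearson). Subject-level
classification uses a linear SVM (C = 1) under repeated stratified 5-fold
cross-validation with fold-wise min–max scaling, pooled out-of-fold AUC,
coefficient-based feature importance, and a train-on-main / test-on-holdout
generalizability protocol.

Because clinical recordings cannot be redistributed, the package ships a
first-class synthetic-cohort generator (`generate_cohort()`): a clause-level
simulator of Spanish-like routine narration with a fully covered lexicon,
gold word-class/person tags, and group effects calibrated to planted
standardized differences (AD noun-ratio deficit d ≈ 1.145, bvFTD
first/third-person shift d ≈ 0.91, word-frequency excess d ≈ 1.13 / 0.98),
so every stage of the pipeline is testable end to end.

## Worked example

```r
library(speechmarkers)

cohort <- generate_cohort(cohort_config(seed = 7))   # 21/21/21 + 11/11/11
feats  <- gold_features(cohort, split = "main")
head(feats[, c("participant_id", "group", "word_count", "noun_ratio",
               "first_person_ratio", "mean_log_freq")], 4)
#>   participant_id group word_count noun_ratio first_person_ratio mean_log_freq
#> 1     main-AD-01    AD        105      0.190              0.629          2.38
#> 2     main-AD-02    AD        337      0.157              0.841          2.33
#> 3     main-AD-03    AD        233      0.167              0.805          2.30
#> 4     main-AD-04    AD        162      0.167              0.613          2.46
```

The AD-vs-HC word-class ANOVA recovers the planted noun-specific deficit as
a group × word-class interaction:

```r
sub  <- feats[feats$group != "bvFTD", ]
long <- data.frame(
  participant_id = rep(sub$participant_id, 2),
  group  = rep(ifelse(sub$group == "HC", "HC", "patient"), 2),
  within = rep(c("noun", "verb"), each = nrow(sub)),
  value  = c(sub$noun_ratio, sub$verb_ratio))
mixed_anova_2x2(long)
#>        effect df1 df2      F        p   pes
#> 1       group   1  40   1.36 2.50e-01 0.033
#> 2      within   1  40 223.37 5.78e-18 0.848
#> 3 interaction   1  40   7.89 7.65e-03 0.165
```

`F(1, 40) = 7.89` with partial η² = 0.165: AD participants lose nouns
specifically, not words in general. Subject-level discrimination:

```r
task <- build_task(feats, "AD")
run_repeated_cv(task$x, task$y, iterations = 200, seed = 1)
#> <svm_cv_report> 200 iterations x 5 folds (positive = patient)
#>   auc       0.686 ± 0.033
#>   accuracy  0.619 ± 0.036
#>   ...
#>   top features: mean_log_freq, verb_ratio, noun_ratio, mean_length
```

A single AD patient is separated from controls with AUC ≈ 0.69, driven by
word frequency and the noun channel. `run_pipeline(cohort, out_dir = "out")`
executes the whole chain — tokenization, tagging, feature extraction,
statistics, classification, hold-out generalizability — and writes
`features.csv`, `stats.json`, `classification.json` and ROC coordinate
files. Real corpora enter through the same front door: a JSON manifest plus
plain-text transcripts, a tag-lexicon TSV, a property-lexicon TSV and an
embedding TSV (see `?load_corpus`, `?run_pipeline`).

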