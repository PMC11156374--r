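#' Group-level statistical analysis of a feature table
#'
#' Runs the full inferential block structure on a per-participant feature
#' table: a 2x2 mixed ANOVA (group x word class) and one (group x person)
#' for each patient group against HC, Tukey HSD post hocs on the cell
#' means, one-tailed t-tests on the four word properties, 3-SD outlier
#' screening, and feature-cognition correlations. FDR correction is applied
#' within each analysis block (word class, person, properties,
#' correlations), matching how such results are conventionally reported.
#'
#' Default t-test directions encode the "more accessible vocabulary"
#' hypothesis: patients greater than HC for frequency and neighborhood,
#' patients less than HC for length and semantic variability.
#'
#' @param features feature `data.frame` (one row per participant, `group`
#'   column with levels AD/bvFTD/HC; optional `moca`/`ifs` columns enable
#'   the correlation block).
#' @param t_directions named directions for the four word properties.
#' @param cor_method correlation method for the cognition block.
#' @return a nested list of class `speech_stats_report`.
#' @export
analyze_features <- function(features,
                             t_directions = c(mean_log_freq = "greater",
                                              mean_phon_neighbors = "greater",
                                              mean_length = "less",
                                              semantic_variability = "less"),
                             cor_method = c("spearman", "pearson")) {
  cor_method <- match.arg(cor_method)
  patient_groups <- intersect(c("AD", "bvFTD"), unique(features$group))
  out <- list()

  long_block <- function(cols, label) {
    block <- list()
    pvals <- c()
    for (pg in patient_groups) {
      sub <- features[features$group %in% c(pg, "HC"), , drop = FALSE]
      long <- data.frame(
        participant_id = rep(sub$participant_id, times = 2L),
        group = rep(ifelse(sub$group == "HC", "HC", "patient"), times = 2L),
        within = rep(names(cols), each = nrow(sub)),
        value = c(sub[[cols[1L]]], sub[[cols[2L]]]),
        stringsAsFactors = FALSE
      )
      long <- long[stats::complete.cases(long$value), , drop = FALSE]
      fit <- mixed_anova_2x2(long)
      block[[pg]] <- list(anova = fit, tukey = tukey_hsd(fit))
      pvals <- c(pvals, stats::setNames(fit$p, paste(pg, fit$effect)))
    }
    adj <- fdr_bh(pvals)
    k <- 0L
    for (pg in patient_groups) {
      block[[pg]]$anova$p_fdr <- adj[k + 1:3]
      k <- k + 3L
    }
    block
  }

  out$word_class <- long_block(c(noun = "noun_ratio", verb = "verb_ratio"),
                               "word_class")
  out$person <- long_block(c(first = "first_person_ratio",
                             third = "third_person_ratio"), "person")

  props <- names(t_directions)
  prop_res <- list()
  pvals <- c()
  for (pg in patient_groups) {
    for (pr in props) {
      x <- features[[pr]][features$group == pg]
      y <- features[[pr]][features$group == "HC"]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      tt <- one_tailed_t(x, y, direction = t_directions[[pr]])
      prop_res[[paste(pg, pr, sep = ".")]] <- tt
      pvals <- c(pvals, tt$p)
    }
  }
  adj <- fdr_bh(pvals)
  for (i in seq_along(prop_res)) prop_res[[i]]$p_fdr <- adj[i]
  out$properties <- prop_res

  out$outliers <- lapply(
    stats::setNames(FEATURE_COLS, FEATURE_COLS),
    function(col) {
      v <- features[[col]]
      flags <- rep(FALSE, length(v))
      ok <- !is.na(v)
      if (sum(ok) >= 3L) flags[ok] <- outlier_screen(v[ok])
      features$participant_id[flags]
    }
  )

  if (all(c("moca", "ifs") %in% names(features))) {
    out$correlations <- list()
    for (pg in patient_groups) {
      pooled <- features[features$group %in% c(pg, "HC"), , drop = FALSE]
      patients <- features[features$group == pg, , drop = FALSE]
      out$correlations[[pg]] <- list(
        pooled = suppressWarnings(
          correlate_features(pooled, FEATURE_COLS, c("moca", "ifs"),
                             method = cor_method)),
        patients_only = suppressWarnings(
          correlate_features(patients, FEATURE_COLS, c("moca", "ifs"),
                             method = cor_method))
      )
    }
  }
  class(out) <- "speech_stats_report"
  out
}

#' Subject-level classification of a feature table
#'
#' Runs the repeated stratified-CV linear SVM for each patient group
#' against HC and, when a hold-out split is present, the train-on-main /
#' test-on-holdout generalizability protocol.
#'
#' @param features feature `data.frame` with `group` and optionally `split`
#'   columns.
#' @param iterations,k,cost,seed passed to [run_repeated_cv()].
#' @return list with one entry per task (`AD`, `bvFTD`), each holding `cv`
#'   and (if applicable) `holdout` reports.
#' @export
classify_features <- function(features, iterations = 1000L, k = 5L,
                              cost = 1, seed = NULL) {
  has_split <- "split" %in% names(features)
  main <- if (has_split) features[features$split == "main", , drop = FALSE]
          else features
  out <- list()
  for (pg in intersect(c("AD", "bvFTD"), unique(main$group))) {
    task <- build_task(main, pg)
    res <- list(cv = run_repeated_cv(task$x, task$y, k = k,
                                     iterations = iterations, cost = cost,
                                     seed = seed))
    if (has_split && any(features$split == "holdout")) {
      ho <- build_task(features[features$split == "holdout", , drop = FALSE],
                       pg)
      res$holdout <- generalizability_eval(
        task$x, task$y, ho$x, ho$y,
        train_ids = task$ids, test_ids = ho$ids, cost = cost
      )
    }
    out[[pg]] <- res
  }
  out
}

#' Run the full connected-speech analysis pipeline
#'
#' End-to-end orchestration: load the corpus (or accept an in-memory
#' cohort), extract the eight features per participant, run the group-level
#' statistics, the repeated-CV classification and — when a hold-out
#' manifest/split exists — the generalizability evaluation, writing every
#' artifact to `out_dir`: `features.csv`, `stats.json`,
#' `classification.json`, `roc_<task>.csv`, and `run_info.json` (config
#' hash and seed). Identical inputs and seed give identical artifacts.
#'
#' @param manifest path to the main-split corpus manifest JSON, or a
#'   `synthetic_cohort` object (then lexicons are taken from the cohort).
#' @param tag_lexicon_path,rules_path,properties_path,embeddings_path input
#'   resource paths (ignored for a `synthetic_cohort`).
#' @param holdout_manifest optional hold-out manifest path.
#' @param out_dir output directory.
#' @param iterations,k,cost classifier parameters.
#' @param seed RNG seed for the classification stage.
#' @param ... feature options passed to [extract_features()].
#' @return invisibly, a list with `features`, `stats`, `classification`.
#' @export
run_pipeline <- function(manifest, tag_lexicon_path = NULL,
                         rules_path = NULL, properties_path = NULL,
                         embeddings_path = NULL, holdout_manifest = NULL,
                         out_dir = "speechmarkers_out", iterations = 1000L,
                         k = 5L, cost = 1, seed = 1L, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(manifest, "synthetic_cohort")) {
    cohort <- manifest
    lex <- cohort$lexicon
    feats <- NULL
    for (split in unique(cohort$participants$split)) {
      parts <- cohort$participants[cohort$participants$split == split, ]
      rows <- lapply(seq_len(nrow(parts)), function(i) {
        id <- parts$participant_id[i]
        tok <- tokenize(cohort$transcripts[[id]]$text)
        words <- clean_word_stream(tok)
        tagged <- tag_stream(words, lex$tags)
        extract_features(list(participant_id = id, group = parts$group[i]),
                         properties = lex$properties,
                         embeddings = lex$embeddings, tagged = tagged, ...)
      })
      block <- do.call(rbind, rows)
      block$split <- split
      block$moca <- parts$moca
      block$ifs <- parts$ifs
      feats <- rbind(feats, block)
    }
    config_repr <- cohort$config
  } else {
    tags <- read_tag_lexicon(tag_lexicon_path, rules_path)
    props <- read_property_lexicon(properties_path)
    emb <- read_embeddings(embeddings_path)
    corpora <- list(main = load_corpus(manifest))
    if (!is.null(holdout_manifest)) {
      corpora$holdout <- load_corpus(holdout_manifest)
    }
    feats <- NULL
    for (split in names(corpora)) {
      block <- extract_corpus_features(corpora[[split]], tag_lex = tags,
                                       properties = props, embeddings = emb,
                                       ...)
      block$split <- split
      sc <- t(vapply(corpora[[split]], function(tr) {
        c(moca = unname(tr$scores["MoCA"] %||% NA_real_),
          ifs = unname(tr$scores["IFS"] %||% NA_real_))
      }, numeric(2)))
      block$moca <- sc[, 1L]
      block$ifs <- sc[, 2L]
      feats <- rbind(feats, block)
    }
    config_repr <- list(manifest = manifest, holdout = holdout_manifest,
                        iterations = iterations, k = k, cost = cost,
                        seed = seed)
  }
  rownames(feats) <- NULL
  utils::write.csv(feats, file.path(out_dir, "features.csv"),
                   row.names = FALSE)

  stats_rep <- analyze_features(feats[feats$split == "main", , drop = FALSE])
  jsonlite::write_json(stats_report_to_list(stats_rep),
                       file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  cls <- classify_features(feats, iterations = iterations, k = k,
                           cost = cost, seed = seed)
  jsonlite::write_json(classification_to_list(cls),
                       file.path(out_dir, "classification.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  for (pg in names(cls)) {
    task <- build_task(feats[feats$split == "main", , drop = FALSE], pg)
    roc <- roc_points(task, cls[[pg]]$cv, seed = seed)
    utils::write.csv(roc, file.path(out_dir, paste0("roc_", pg, ".csv")),
                     row.names = FALSE)
  }

  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config_repr, cfg_file, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  jsonlite::write_json(
    list(config_hash = unname(tools::md5sum(cfg_file)), seed = seed,
         n_participants = nrow(feats)),
    file.path(out_dir, "run_info.json"), auto_unbox = TRUE, digits = NA
  )
  unlink(cfg_file)
  invisible(list(features = feats, stats = stats_rep, classification = cls))
}

# ROC coordinates from one representative CV pass (for plotting)
roc_points <- function(task, report, seed = 1L) {
  set.seed(seed)
  fold <- stratified_folds(task$y, report$k)
  scores <- numeric(length(task$y))
  for (f in seq_len(report$k)) {
    tr <- fold != f
    imp <- impute_median(task$x[tr, , drop = FALSE],
                         task$x[!tr, , drop = FALSE])
    scaler <- fit_minmax(imp$train)
    model <- e1071::svm(apply_minmax(imp$train, scaler), factor(task$y[tr]),
                        kernel = "linear", cost = 1, scale = FALSE)
    scores[!tr] <- decision_scores(model, apply_minmax(imp$test, scaler),
                                   report$positive)$score
  }
  thr <- sort(unique(c(-Inf, scores, Inf)))
  pos <- task$y == report$positive
  data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t0) mean(scores[pos] >= t0), numeric(1)),
    fpr = vapply(thr, function(t0) mean(scores[!pos] >= t0), numeric(1))
  )
}

stats_report_to_list <- function(rep) {
  strip <- function(x) {
    if (is.data.frame(x)) {
      attributes(x)[setdiff(names(attributes(x)),
                            c("names", "row.names", "class"))] <- NULL
      class(x) <- "data.frame"
    }
    x
  }
  rapply(unclass(rep), strip, how = "replace")
}

classification_to_list <- function(cls) {
  lapply(cls, function(task) {
    lapply(task, function(rep) {
      list(metrics = rep$metrics, importance = rep$importance,
           iterations = rep$iterations, k = rep$k, seed = rep$seed)
    })
  })
}

#' Generate a synthetic cohort and write it to disk
#'
#' Thin wrapper coupling [generate_cohort()] and [write_cohort()]; the
#' resulting directory is directly consumable by [run_pipeline()] through
#' its manifest/lexicon file arguments.
#'
#' @param config a [cohort_config()].
#' @param dir output directory.
#' @return the cohort object, invisibly.
#' @export
simulate_cohort <- function(config = cohort_config(), dir) {
  cohort <- generate_cohort(config)
  write_cohort(cohort, dir)
  invisible(cohort)
}
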