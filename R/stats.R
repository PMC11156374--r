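#' Two-by-two mixed-design ANOVA
#'
#' Fits the classic mixed design with one between-subjects factor (two
#' groups) and one within-subjects factor (two levels, both observed on
#' every participant), returning the F tests for the group main effect
#' (against the between-subject error), the within main effect and the
#' group-by-within interaction (both against the within-subject error),
#' with partial eta squared `SS_effect / (SS_effect + SS_error)` for each.
#'
#' The decomposition is computed in closed form from subject means and
#' within-subject differences, which makes the routine fast enough for
#' large simulation studies; it agrees with `aov(value ~ group * within +
#' Error(id/within))` to machine precision, including unbalanced group
#' sizes.
#'
#' @param data long-format `data.frame`.
#' @param id,group,within,value column names.
#' @return a `data.frame` with rows `group`, `within`, `interaction` and
#'   columns `effect`, `df1`, `df2`, `F`, `p`, `pes`; attributes
#'   `ms_error_between`, `ms_error_within`, `cell_means`, `cell_n` support
#'   post hoc tests.
#' @export
mixed_anova_2x2 <- function(data, id = "participant_id", group = "group",
                            within = "within", value = "value") {
  ids <- as.character(data[[id]])
  grp <- as.character(data[[group]])
  wth <- as.character(data[[within]])
  y <- as.numeric(data[[value]])
  wlev <- sort(unique(wth))
  glev <- sort(unique(grp))
  if (length(wlev) != 2L || length(glev) != 2L) {
    stop("design must have exactly two groups and two within levels",
         call. = FALSE)
  }
  tab <- table(ids, wth)
  bad <- rownames(tab)[rowSums(tab) != 2L | apply(tab, 1L, max) > 1L]
  if (length(bad)) {
    stop("participant(s) missing a within level: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ord <- order(ids, wth)
  ids <- ids[ord]; grp <- grp[ord]; wth <- wth[ord]; y <- y[ord]
  i1 <- seq(1L, length(y), by = 2L)
  subj_mean <- (y[i1] + y[i1 + 1L]) / 2
  subj_diff <- y[i1] - y[i1 + 1L]          # within level 1 minus level 2
  subj_grp <- grp[i1]
  n_g <- table(subj_grp)[glev]
  N <- length(subj_mean)
  if (N < 3L) stop("need at least 3 participants", call. = FALSE)

  grand <- mean(subj_mean)
  m_g <- tapply(subj_mean, subj_grp, mean)[glev]
  ss_group <- 2 * sum(n_g * (m_g - grand)^2)
  ss_err_b <- 2 * sum((subj_mean - m_g[subj_grp])^2)

  d_bar <- mean(subj_diff)
  d_g <- tapply(subj_diff, subj_grp, mean)[glev]
  ss_within <- N * d_bar^2 / 2
  ss_inter <- sum(n_g * (d_g - d_bar)^2) / 2
  ss_err_w <- sum((subj_diff - d_g[subj_grp])^2) / 2

  df2 <- N - 2L
  ms_eb <- ss_err_b / df2
  ms_ew <- ss_err_w / df2
  eff <- c("group", "within", "interaction")
  ss <- c(ss_group, ss_within, ss_inter)
  ss_err <- c(ss_err_b, ss_err_w, ss_err_w)
  # degenerate stratum (e.g. complementary ratios: every subject mean is
  # constant, so both effect and error SS vanish): report a null effect
  Fv <- ifelse(ss == 0, 0, ss / c(ms_eb, ms_ew, ms_ew))
  out <- data.frame(
    effect = eff, df1 = 1L, df2 = df2, F = Fv,
    p = stats::pf(Fv, 1L, df2, lower.tail = FALSE),
    pes = ifelse(ss == 0, 0, ss / (ss + ss_err)),
    stringsAsFactors = FALSE
  )
  cell <- tapply(y, list(grp, wth), mean)
  attr(out, "ms_error_between") <- ms_eb
  attr(out, "ms_error_within") <- ms_ew
  attr(out, "cell_means") <- cell
  attr(out, "cell_n") <- n_g
  class(out) <- c("mixed_anova", class(out))
  out
}

#' Tukey HSD post hoc tests on the 2x2 mixed-design cell means
#'
#' Compares all six pairs of the four group-by-level cell means with the
#' studentized-range distribution. By convention the error term is a single
#' pooled mean square on the between-subject error degrees of freedom; both
#' can be supplied explicitly (e.g. to reuse a published MSE). Cohen's d for
#' each pair is the mean difference divided by the square root of the MSE.
#'
#' @param data long-format `data.frame` as in [mixed_anova_2x2()], or a
#'   fitted `mixed_anova` object.
#' @param mse pooled error mean square; default pools the between- and
#'   within-subject error sums of squares over their combined df.
#' @param df error degrees of freedom for the studentized range (default
#'   `N - 2`).
#' @param ... column names passed on to [mixed_anova_2x2()].
#' @return a `data.frame` with one row per cell pair: `diff`, `q`, `p`, `d`.
#' @export
tukey_hsd <- function(data, mse = NULL, df = NULL, ...) {
  fit <- if (inherits(data, "mixed_anova")) data
         else mixed_anova_2x2(data, ...)
  cell <- attr(fit, "cell_means")
  n_g <- attr(fit, "cell_n")
  df2 <- fit$df2[1L]
  if (is.null(mse)) {
    mse <- (attr(fit, "ms_error_between") + attr(fit, "ms_error_within")) / 2
  }
  if (is.null(df)) df <- df2
  if (!is.finite(mse) || mse <= 0) {
    stop("non-positive error mean square", call. = FALSE)
  }
  labs <- as.vector(outer(rownames(cell), colnames(cell), paste, sep = ":"))
  means <- as.vector(cell)
  ns <- unname(rep(n_g[rownames(cell)], times = ncol(cell)))
  pairs <- utils::combn(seq_along(means), 2L)
  res <- apply(pairs, 2L, function(ix) {
    i <- ix[1L]; j <- ix[2L]
    diff <- means[i] - means[j]
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(diff) / se
    c(diff = diff, q = q,
      p = stats::ptukey(q, nmeans = length(means), df = df,
                        lower.tail = FALSE),
      d = diff / sqrt(mse))
  })
  out <- data.frame(
    pair = paste(labs[pairs[1L, ]], labs[pairs[2L, ]], sep = " vs "),
    t(res), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' One-tailed independent-samples t-test with Cohen's d
#'
#' Pooled-variance two-sample t-test with a directional alternative, the
#' standard way single word properties are compared between a patient group
#' and controls. Cohen's d uses the pooled standard deviation.
#'
#' @param x,y numeric samples (n >= 2 each).
#' @param direction alternative hypothesis for `x` relative to `y`:
#'   `"greater"` or `"less"`.
#' @return a list with `statistic`, `df`, `p`, `d`, `direction`.
#' @export
one_tailed_t <- function(x, y, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  ht <- stats::t.test(x, y, var.equal = TRUE, alternative = direction)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, d = (mean(x) - mean(y)) / sqrt(sp2),
       direction = direction)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment; order-preserving, monotone in rank and never
#' below the raw p-value.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
fdr_bh <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Screen a sample for extreme values
#'
#' Flags values lying strictly more than `k` sample standard deviations from
#' the sample mean (n-1 denominator). A value at exactly the threshold is
#' not flagged.
#'
#' @param values numeric vector (n >= 3).
#' @param k threshold in standard deviations (default 3).
#' @return logical vector of flags.
#' @export
outlier_screen <- function(values, k = 3) {
  stopifnot(length(values) >= 3L)
  s <- stats::sd(values)
  if (s == 0) {
    warning("zero standard deviation; no outliers flagged", call. = FALSE)
    return(rep(FALSE, length(values)))
  }
  abs(values - mean(values)) > k * s
}

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Dunnett many-to-one comparisons from summary statistics
#'
#' Compares each treatment group with a designated control using the
#' variance pooled across *all* groups (df-weighted), the convention of
#' demographic comparisons in clinical group tables. Two-sided p-values come
#' from the Dunnett multivariate-t distribution with the usual correlation
#' structure `rho_ij = sqrt(lambda_i * lambda_j)`,
#' `lambda_i = n_i / (n_i + n_0)`; with a single treatment group the test
#' reduces exactly to the two-sample pooled t-test.
#'
#' @param means,sds,ns numeric vectors of per-group summary statistics; the
#'   first element is taken as the control unless `control` says otherwise.
#' @param control index of the control group.
#' @return a `data.frame` with one row per treatment contrast: `statistic`
#'   (absolute standardized difference), `df`, `p`.
#' @export
dunnett_t <- function(means, sds, ns, control = 1L) {
  k <- length(means)
  stopifnot(length(sds) == k, length(ns) == k, k >= 2L)
  if (any(ns < 2L)) stop("each group needs n >= 2", call. = FALSE)
  msw <- sum((ns - 1) * sds^2) / sum(ns - 1)
  df <- sum(ns - 1)
  trt <- setdiff(seq_len(k), control)
  stat <- abs(means[trt] - means[control]) /
    sqrt(msw * (1 / ns[trt] + 1 / ns[control]))
  lam <- sqrt(ns[trt] / (ns[trt] + ns[control]))
  R <- outer(lam, lam)
  diag(R) <- 1
  p <- vapply(stat, function(t0) {
    if (length(trt) == 1L) {
      2 * stats::pt(-t0, df)
    } else {
      with_local_seed(1L, {
        1 - mvtnorm::pmvt(lower = rep(-t0, length(trt)),
                          upper = rep(t0, length(trt)),
                          df = df, corr = R, sigma = NULL,
                          algorithm = mvtnorm::GenzBretz(abseps = 1e-5))[1L]
      })
    }
  }, numeric(1))
  data.frame(contrast = paste0("group", trt, " vs control"),
             statistic = stat, df = df, p = p,
             stringsAsFactors = FALSE)
}

#' Chi-squared test of a 2x2 count table
#'
#' Pearson chi-squared on one degree of freedom, with optional Yates
#' continuity correction (the default, as customary for 2x2 demographic
#' tables).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param yates apply the continuity correction (default `TRUE`).
#' @return a list with `statistic`, `df`, `p`.
#' @export
chi2_2x2 <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin in contingency table", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = yates))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Correlate speech features with cognitive scores
#'
#' Computes the full feature-by-test correlation grid with pairwise-complete
#' observations and a single FDR family across the grid. Constant inputs
#' yield `NA` with a warning rather than an error.
#'
#' @param data per-participant `data.frame`.
#' @param feature_cols,score_cols column names to correlate.
#' @param method `"spearman"` or `"pearson"`.
#' @return a `data.frame` with columns `feature`, `score`, `n`, `r`, `p`,
#'   `p_fdr`.
#' @export
correlate_features <- function(data, feature_cols, score_cols,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  grid <- expand.grid(feature = feature_cols, score = score_cols,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- data[[grid$feature[i]]]
    y <- data[[grid$score[i]]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("constant or too-short input for ", grid$feature[i], " vs ",
              grid$score[i], "; correlation undefined", call. = FALSE)
      return(c(n = length(x), r = NA_real_, p = NA_real_))
    }
    ht <- suppressWarnings(stats::cor.test(x, y, method = method))
    c(n = length(x), r = unname(ht$estimate), p = ht$p.value)
  })
  out <- cbind(grid, do.call(rbind, res))
  out$p_fdr <- NA_real_
  ok <- !is.na(out$p)
  out$p_fdr[ok] <- fdr_bh(out$p[ok])
  out
}
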