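# Benchmarking E-scores against affinity/elution references and external
# predictor tables: affinity transform, binder labels, tie-aware ROC-AUC,
# step-interpolated PR-AUC, bootstrap confidence intervals, recall by
# affinity bin.

#' Log-transform an IC50 affinity to the 0-1 training scale
#'
#' `1 - log(ic50) / log(50000)`: 1 at 1 nM, 0 at 50,000 nM, and 0.426
#' (3 dp) at the conventional 500 nM binder threshold. Monotone decreasing
#' in IC50; values below 1 nM map above 1.
#'
#' @param ic50_nm IC50 in nanomolar; must be positive.
#' @return Transformed affinity.
#' @export
#' @examples
#' transform_affinity(c(1, 500, 50000))
transform_affinity <- function(ic50_nm) {
  if (any(!is.na(ic50_nm) & ic50_nm <= 0)) {
    abort("IC50 must be positive (nM)")
  }
  1 - log10(ic50_nm) / log10(50000)
}

#' Inverse of [transform_affinity()]
#'
#' @param transformed Transformed affinity value(s).
#' @return IC50 in nM.
#' @export
inverse_transform_affinity <- function(transformed) {
  50000^(1 - transformed)
}

#' Binary binder labels from a reference table
#'
#' IC50-based labels are positive strictly below `ic50_threshold` (500 nM
#' by convention; 500 itself is negative). Rows without an IC50 fall back
#' to the elution flag. Rows with neither label are an error.
#'
#' @param reference Data frame with `ic50_nm` and/or `eluted` columns.
#' @param ic50_threshold Positivity cutoff in nM.
#' @return The reference with an added logical `label` column.
#' @export
label_binders <- function(reference, ic50_threshold = 500) {
  reference <- as_tibble(reference)
  has_ic50 <- "ic50_nm" %in% names(reference)
  has_el <- "eluted" %in% names(reference)
  if (!has_ic50 && !has_el) abort("reference needs `ic50_nm` and/or `eluted`")
  ic50 <- if (has_ic50) reference$ic50_nm else rep(NA_real_, nrow(reference))
  el <- if (has_el) reference$eluted else rep(NA, nrow(reference))
  label <- if_else(!is.na(ic50), ic50 < ic50_threshold, as.logical(el))
  if (any(is.na(label))) {
    abort(sprintf("%d reference row(s) carry no usable label",
                  sum(is.na(label))))
  }
  mutate(reference, label = label)
}

#' Tie-aware ROC-AUC (Mann-Whitney concordance)
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted half. Equals the normalised Mann-Whitney U statistic.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or 0/1) class labels.
#' @return AUC in \[0, 1\]; NA with a warning if only one class present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    warn("single-class input: ROC-AUC undefined")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(scores, labels) {
  # fpr/tpr staircase over distinct thresholds, ties grouped
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tibble(
    threshold = s[last],
    tpr = tp[last] / sum(y),
    fpr = fp[last] / sum(!y)
  )
}

#' Step-interpolated precision-recall AUC
#'
#' Area under the precision-recall staircase using step (not trapezoidal)
#' interpolation, which avoids the optimistic bias of linearly
#' interpolating precision. Tied scores are processed as one threshold
#' group.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in \[0, 1\]; NA with a warning if no positives.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  if (sum(labels) == 0 || sum(!labels) == 0) {
    warn("single-class input: PR-AUC undefined")
    return(NA_real_)
  }
  pr <- pr_points(scores, labels)
  sum(diff(c(0, pr$recall)) * pr$precision)
}

pr_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  n_seen <- seq_along(y)
  last <- !duplicated(grp, fromLast = TRUE)
  tibble(
    threshold = s[last],
    recall = tp[last] / sum(y),
    precision = tp[last] / n_seen[last]
  )
}

#' Percentile bootstrap confidence interval for a statistic
#'
#' `B` (default 1000) resamples of the rows of `data` with replacement;
#' the interval is the `level` percentile range of the resampled
#' statistics. Resamples where the statistic is undefined (NA; e.g. a
#' single-class ROC resample) are skipped and counted.
#'
#' @param data A data frame.
#' @param stat Function `data -> single number`.
#' @param B Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Optional integer seed (reproducible intervals).
#' @param min_n Minimum rows required.
#' @return A list: `point`, `low`, `high`, `B_effective`, `n_skipped`.
#' @export
bootstrap_ci <- function(data, stat, B = 1000, level = 0.95, seed = NULL,
                         min_n = 20) {
  data <- as_tibble(data)
  n <- nrow(data)
  if (n < min_n) {
    abort(sprintf("bootstrap needs >= %d rows (got %d)", min_n, n))
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  point <- stat(data)
  vals <- vapply(seq_len(B), function(i) {
    suppressWarnings(stat(data[sample.int(n, n, replace = TRUE), ]))
  }, numeric(1))
  keep <- !is.na(vals)
  alpha <- (1 - level) / 2
  ci <- quantile(vals[keep], c(alpha, 1 - alpha), names = FALSE)
  list(point = point, low = ci[1], high = ci[2],
       B_effective = sum(keep), n_skipped = sum(!keep))
}

metric_row <- function(scores, ref, B, level, seed) {
  dat <- tibble(score = scores, label = ref$label,
                affinity = ref$transformed)
  has_aff <- any(!is.na(dat$affinity))
  pt <- function(d) {
    c(
      pearson_r = if (has_aff) suppressWarnings(
        cor(d$score, d$affinity, use = "complete.obs")) else NA_real_,
      spearman_r = if (has_aff) suppressWarnings(
        cor(d$score, d$affinity, method = "spearman",
            use = "complete.obs")) else NA_real_,
      roc_auc = suppressWarnings(roc_auc(d$score, d$label)),
      pr_auc = suppressWarnings(pr_auc(d$score, d$label))
    )
  }
  point <- pt(dat)
  cis <- purrr::map(names(point), function(m) {
    if (is.na(point[[m]]) || nrow(dat) < 20) {
      return(list(low = NA_real_, high = NA_real_))
    }
    bootstrap_ci(dat, function(d) pt(d)[[m]], B = B, level = level,
                 seed = seed)
  })
  tibble(
    metric = names(point),
    value = as.numeric(point),
    ci_low = purrr::map_dbl(cis, "low"),
    ci_high = purrr::map_dbl(cis, "high"),
    n = nrow(dat),
    n_positive = sum(dat$label)
  )
}

#' Benchmark a score table against an affinity/elution reference
#'
#' Joins scores with the reference on (peptide, allele), derives labels
#' ([label_binders()]) and the transformed affinity when IC50s are
#' present, and computes Pearson r, Spearman r, ROC-AUC and PR-AUC --
#' separately per allele (the primary view) and pooled -- each with a
#' percentile-bootstrap 95% interval.
#'
#' @param scores Data frame (`peptide`, `allele`, plus a score column).
#' @param reference Data frame keyed on (`peptide`, `allele`) with
#'   `ic50_nm` and/or `eluted`.
#' @param score_col Score column name (auto-detected as in
#'   [call_binders()]).
#' @param B,level,seed Bootstrap settings (see [bootstrap_ci()]).
#' @return An object of class `escape_benchmark`; `tidy()` gives the
#'   per-allele metric table, `glance()` the pooled row, `autoplot()` the
#'   ROC curves.
#' @export
escape_benchmark <- function(scores, reference, score_col = NULL,
                             B = 1000, level = 0.95, seed = NULL) {
  scores <- as_tibble(scores)
  if (is.null(score_col)) {
    score_col <- intersect(c("mean_escore", "aligned_escore", "raw_escore",
                             "score"), names(scores))[1]
    if (is.na(score_col)) abort("no score column found")
  }
  ref <- label_binders(reference)
  ref$transformed <- if ("ic50_nm" %in% names(ref)) {
    transform_affinity(ref$ic50_nm)
  } else {
    NA_real_
  }
  joined <- inner_join(
    select(scores, "peptide", "allele", score = dplyr::all_of(score_col)),
    select(ref, "peptide", "allele", "label", "transformed"),
    by = c("peptide", "allele")
  )
  if (nrow(joined) == 0) abort("scores and reference share no (peptide, allele)")
  per_allele <- joined |>
    group_by(.data$allele) |>
    dplyr::group_modify(function(d, key) {
      metric_row(d$score, d, B = B, level = level, seed = seed)
    }) |>
    ungroup()
  pooled <- metric_row(joined$score, joined, B = B, level = level,
                       seed = seed)
  curves <- joined |>
    group_by(.data$allele) |>
    dplyr::group_modify(function(d, key) {
      if (sum(d$label) == 0 || sum(!d$label) == 0) return(tibble())
      bind_rows(
        mutate(roc_points(d$score, d$label), curve = "roc",
               x = .data$fpr, y = .data$tpr),
        mutate(pr_points(d$score, d$label), curve = "pr",
               x = .data$recall, y = .data$precision)
      ) |> select("curve", "threshold", "x", "y")
    }) |>
    ungroup()
  structure(
    list(per_allele = per_allele, pooled = pooled, curves = curves,
         n = nrow(joined), score_col = score_col),
    class = "escape_benchmark"
  )
}

#' @export
print.escape_benchmark <- function(x, ...) {
  cat(sprintf("Benchmark of `%s` on %d (peptide, allele) pairs\n",
              x$score_col, x$n))
  cat("Pooled metrics:\n")
  print(as.data.frame(x$pooled), row.names = FALSE)
  invisible(x)
}

#' @rdname escape_benchmark
#' @param x An `escape_benchmark` object.
#' @param ... Unused.
#' @export
tidy.escape_benchmark <- function(x, ...) {
  x$per_allele
}

#' @rdname escape_benchmark
#' @export
glance.escape_benchmark <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    select(x$pooled, "metric", "value"),
    names_from = "metric", values_from = "value"
  )
  mutate(wide, n = x$n, n_positive = x$pooled$n_positive[1])
}

#' Recall per reference affinity bin
#'
#' Among reference positives, the fraction called positive by the screen,
#' split by an ordinal affinity bin (e.g. IC50 strata). Empty bins give
#' NA.
#'
#' @param calls Binder calls (`peptide`, `allele`, `binder`).
#' @param reference Labelled reference with an `affinity_bin` column (a
#'   factor whose level order is respected) and labels per
#'   [label_binders()].
#' @return A tibble (`affinity_bin`, `n_positive`, `n_recalled`,
#'   `recall`).
#' @export
recall_by_bin <- function(calls, reference) {
  ref <- label_binders(reference)
  if (!"affinity_bin" %in% names(ref)) abort("reference needs `affinity_bin`")
  ref |>
    filter(.data$label) |>
    left_join(select(as_tibble(calls), "peptide", "allele", "binder"),
              by = c("peptide", "allele")) |>
    group_by(.data$affinity_bin, .drop = FALSE) |>
    summarise(
      n_positive = n(),
      n_recalled = sum(.data$binder %in% TRUE),
      .groups = "drop"
    ) |>
    mutate(recall = if_else(.data$n_positive > 0,
                            .data$n_recalled / .data$n_positive, NA_real_))
}

#' Read an external predictor score table
#'
#' Harmonizes a TSV of predictions keyed on (peptide, allele) with a
#' `score` column and a `mode` tag (e.g. binding-affinity vs eluted-ligand
#' output of a neural predictor). When the mode indicates percentile ranks
#' (`%rank`, lower = better), calls are made at the usual 0.5% (strong)
#' and 2% (weak) cutoffs. Pairs absent from the table are missing, not
#' negative.
#'
#' @param path TSV path with columns `peptide`, `allele`, `score`, `mode`.
#' @param rank_strong,rank_weak Rank cutoffs (percent).
#' @return A tibble with an added `call` column (`strong`/`weak`/`non`
#'   for rank modes, NA otherwise).
#' @export
read_predictor_table <- function(path, rank_strong = 0.5, rank_weak = 2.0) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("peptide", "allele", "score", "mode")
  if (!all(need %in% names(tab))) {
    abort(sprintf("predictor table needs columns: %s",
                  paste(need, collapse = ", ")))
  }
  mutate(tab, call = if_else(
    grepl("rank", .data$mode, ignore.case = TRUE),
    case_when(
      .data$score <= rank_strong ~ "strong",
      .data$score <= rank_weak ~ "weak",
      TRUE ~ "non"
    ),
    NA_character_
  ))
}
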