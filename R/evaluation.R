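as_label_sets <- function(x) {
  # Accepts: classification_result (mono-label), boolean predictions tibble
  # (list-column), annotations tibble, or a named list of character vectors.
  if (inherits(x, "classification_result")) {
    a <- x$assignments
    sets <- lapply(seq_len(nrow(a)), function(i) {
      if (a$label[i] == NOISE_LABEL) character(0) else a$label[i]
    })
    names(sets) <- a$post_id
    return(sets)
  }
  if (is.data.frame(x)) {
    idcol <- if ("post_id" %in% names(x)) "post_id" else "id"
    sets <- lapply(x$categories, function(v) setdiff(as.character(v), NOISE_LABEL))
    names(sets) <- x[[idcol]]
    return(sets)
  }
  lapply(x, function(v) setdiff(as.character(v), NOISE_LABEL))
}

#' Per-category confusion counts
#'
#' For a category: TP — post correctly classified into it; FP — post
#' assigned to it that does not belong there; FN — post that belongs to it
#' but was not classified into it. A `NOISE` (empty) prediction can only
#' contribute false negatives. Gold and predictions must cover the same
#' posts.
#'
#' @param gold gold annotations (tibble with `post_id`/`categories`, or
#'   named list of category sets; empty set = noise).
#' @param predicted predictions in any form accepted (see `gold`), including
#'   a `classification_result` or [boolean_classify()] output.
#' @param category category id.
#' @return list with integer `tp`, `fp`, `fn`.
#' @export
confusion_counts <- function(gold, predicted, category) {
  g <- as_label_sets(gold)
  p <- as_label_sets(predicted)
  ids <- names(g)
  if (!setequal(ids, names(p))) stop("gold and predictions cover different post ids")
  in_g <- vapply(g[ids], function(s) category %in% s, logical(1))
  in_p <- vapply(p[ids], function(s) category %in% s, logical(1))
  list(tp = sum(in_g & in_p), fp = sum(!in_g & in_p), fn = sum(in_g & !in_p))
}

#' Confusion counts for every category
#'
#' @inheritParams confusion_counts
#' @param categories character vector of category ids.
#' @return tibble: `category`, `tp`, `fp`, `fn`.
#' @export
confusion_table <- function(gold, predicted, categories) {
  unknown <- setdiff(unlist(as_label_sets(gold)), categories)
  if (length(unknown)) stop("gold references unknown category: ", unknown[1])
  rows <- lapply(categories, function(cat) {
    cc <- confusion_counts(gold, predicted, cat)
    tibble::tibble(category = cat, tp = cc$tp, fp = cc$fp, fn = cc$fn)
  })
  dplyr::bind_rows(rows)
}

#' F1 score (harmonic mean of precision and recall)
#'
#' Scale-invariant: works identically on proportions or percentages.
#' Defined as 0 when `precision + recall == 0`.
#'
#' @param precision,recall numeric vectors.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2PR / (P + R)`. A degenerate denominator yields 0 with a
#' defined-flag set to `FALSE` — applied identically to every method so
#' comparisons stay fair.
#'
#' @param counts tibble from [confusion_table()] (or a single-count list).
#' @return tibble with `precision`, `recall`, `f1` (proportions in \[0, 1\])
#'   and `precision_defined`, `recall_defined` flags.
#' @export
compute_metrics <- function(counts) {
  if (!is.data.frame(counts)) counts <- tibble::as_tibble(counts)
  p_def <- counts$tp + counts$fp > 0
  r_def <- counts$tp + counts$fn > 0
  precision <- ifelse(p_def, counts$tp / (counts$tp + counts$fp), 0)
  recall <- ifelse(r_def, counts$tp / (counts$tp + counts$fn), 0)
  dplyr::bind_cols(counts, tibble::tibble(
    precision = precision, recall = recall,
    f1 = f1_score(precision, recall),
    precision_defined = p_def, recall_defined = r_def
  ))
}

#' Macro-average of per-category metric rows
#'
#' Unweighted arithmetic mean of precision, recall and F1 across categories
#' (degenerate rows enter as 0), mirroring "an overall average of the
#' scores across all categories".
#'
#' @param rows tibble from [compute_metrics()].
#' @return one-row tibble: `precision`, `recall`, `f1`, `n_categories`.
#' @export
macro_average <- function(rows) {
  if (nrow(rows) == 0) stop("macro_average needs at least one category")
  tibble::tibble(
    precision = mean(rows$precision),
    recall = mean(rows$recall),
    f1 = mean(rows$f1),
    n_categories = nrow(rows)
  )
}

#' Evaluate predictions against gold annotations
#'
#' Convenience wrapper: confusion counts, per-category metrics, and the
#' macro average in one call.
#'
#' @inheritParams confusion_table
#' @return list with `per_category` (metrics tibble) and `macro` (one row).
#' @export
evaluate_predictions <- function(gold, predicted, categories) {
  per_cat <- compute_metrics(confusion_table(gold, predicted, categories))
  list(per_category = per_cat, macro = macro_average(per_cat))
}

#' Paired Hotelling T-squared comparison of two methods
#'
#' Omnibus test of whether two categorization methods differ on the
#' combined (precision, recall) performance vector, paired by category:
#' with per-category differences `d_c`, `T2 = n * dbar' S^-1 dbar` where
#' `S` is the sample covariance of the differences, and
#' `F = ((n - p) / (p (n - 1))) * T2 ~ F(p, n - p)` under the null. F1 is
#' excluded from the multivariate vector because it is a deterministic
#' function of precision and recall (covariance singularity).
#'
#' @param method_a,method_b numeric matrices (categories x variables), same
#'   dimensions, rows paired by category. Typically 2 columns:
#'   precision, recall.
#' @return list of class `hotelling_result`: `t2`, `f`, `df1`, `df2`,
#'   `p_value`, `n`, `p`.
#' @export
hotelling_t2_paired <- function(method_a, method_b) {
  A <- as.matrix(method_a)
  B <- as.matrix(method_b)
  if (!all(dim(A) == dim(B))) stop("methods must have identical dimensions")
  n <- nrow(A)
  p <- ncol(A)
  if (n <= p) stop(sprintf("need more categories (n = %d) than variables (p = %d)", n, p))
  d <- A - B
  dbar <- colMeans(d)
  if (max(abs(d)) == 0) {
    res <- list(t2 = 0, f = 0, df1 = p, df2 = n - p, p_value = 1, n = n, p = p)
    class(res) <- "hotelling_result"
    return(res)
  }
  S <- stats::cov(d)
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv) || !all(is.finite(Sinv))) {
    stop("singular covariance of paired differences; jitter the inputs or drop a variable")
  }
  t2 <- as.numeric(n * t(dbar) %*% Sinv %*% dbar)
  f <- (n - p) / (p * (n - 1)) * t2
  res <- list(t2 = t2, f = f, df1 = p, df2 = n - p,
              p_value = stats::pf(f, p, n - p, lower.tail = FALSE),
              n = n, p = p)
  class(res) <- "hotelling_result"
  res
}

#' @export
print.hotelling_result <- function(x, ...) {
  cat(sprintf("Paired Hotelling T2 = %.4f, F(%d, %d) = %.4f, p = %.4g (n = %d)\n",
              x$t2, x$df1, x$df2, x$f, x$p_value, x$n))
  invisible(x)
}

#' Reproducible annotation-quality sample
#'
#' Uniform sample of post ids without replacement, size
#' `round(fraction * N)` — the double-annotation sampling used to check
#' annotation quality (e.g. a 15% second-reviewer sample per language).
#'
#' @param post_ids character vector (or posts tibble with `id`).
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed making the sample reproducible.
#' @export
annotation_sample <- function(post_ids, fraction = 0.15, seed = 1L) {
  if (is.data.frame(post_ids)) post_ids <- post_ids$id
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  size <- round(fraction * length(post_ids))
  withr::with_seed(as.integer(seed), sample(post_ids, size))
}

#' Percentage share helper for reported proportions
#'
#' @param numerator,denominator counts.
#' @param digits rounding digits (default 2).
#' @export
share_percent <- function(numerator, denominator, digits = 2) {
  round(100 * numerator / denominator, digits)
}

#' Method-comparison metrics table (one row per language x method)
#'
#' Layout mirroring the standard benchmark table: language, method, and
#' macro precision/recall/F1 as percentages.
#'
#' @param results named list: `results[[language]][[method]]` is a macro
#'   metrics row from [macro_average()].
#' @param digits rounding digits.
#' @return tibble: `language`, `method`, `precision_pct`, `recall_pct`,
#'   `f1_pct`.
#' @export
metrics_report <- function(results, digits = 2) {
  rows <- list()
  for (lang in names(results)) {
    for (method in names(results[[lang]])) {
      m <- results[[lang]][[method]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        language = lang, method = method,
        precision_pct = round(100 * m$precision, digits),
        recall_pct = round(100 * m$recall, digits),
        f1_pct = round(100 * m$f1, digits)
      )
    }
  }
  dplyr::bind_rows(rows)
}
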