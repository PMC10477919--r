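#' Boolean-query baseline classifier
#'
#' The comparator fed exactly the same keywords as the semisupervised
#' algorithm: each category is an OR-query over its keyword phrases, and a
#' post is assigned every category with at least one phrase match. No
#' graph, no propagation — so a post containing "test" lands in a Testing
#' category even when the context is symptoms, the characteristic
#' false-positive pattern that graph context can disambiguate.
#'
#' Assignments are definitionally consistent with [match_keywords()]:
#' category `c` is assigned iff its hit count is >= 1. Unlike the mono-label
#' algorithm path, the baseline is multi-assignment; the evaluation module's
#' per-category confusion accounting handles both uniformly.
#'
#' @param tokenized tibble from [tokenize_posts()].
#' @param tax a `taxonomy`.
#' @param language keyword language.
#' @return tibble: `post_id`, list-column `categories` (possibly empty
#'   character vector per post).
#' @export
boolean_classify <- function(tokenized, tax, language = "en") {
  hits <- match_keywords_corpus(tokenized, tax, language)
  tibble::tibble(
    post_id = tokenized$post_id,
    categories = lapply(tokenized$post_id, function(pid) {
      h <- hits[[pid]]
      if (is.null(h) || length(h) == 0) character(0) else sort(names(h))
    })
  )
}

#' Export Boolean predictions as CSV (semicolon-joined label sets)
#' @param predictions tibble from [boolean_classify()].
#' @param path destination CSV.
#' @export
write_boolean_predictions <- function(predictions, path) {
  out <- tibble::tibble(
    post_id = predictions$post_id,
    labels = vapply(predictions$categories, paste, character(1), collapse = ";"),
    categorized = lengths(predictions$categories) > 0
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
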