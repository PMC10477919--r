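#' @importFrom rlang .data
NULL

#' Label used for posts the classifier relates to no taxonomy category
#' @export
NOISE_LABEL <- "NOISE"

#' Recognized post source platforms
#' @export
POST_SOURCES <- c("twitter", "facebook", "web")

post_columns <- c("id", "text", "timestamp", "country", "language",
                  "source", "author_name", "author_bio")

# Parse ISO-8601 timestamps; naive (offset-free) strings yield NA because
# weekly aggregation depends on unambiguous time.
parse_post_timestamp <- function(x) {
  x <- as.character(x)
  has_offset <- !is.na(x) & grepl("(Z|[+-][0-9]{2}:?[0-9]{2})$", x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  if (any(has_offset)) {
    parsed <- suppressWarnings(
      lubridate::ymd_hms(x[has_offset], tz = "UTC", quiet = TRUE)
    )
    out[has_offset] <- parsed
  }
  out
}

format_post_timestamp <- function(ts) {
  format(lubridate::with_tz(ts, "UTC"), "%Y-%m-%dT%H:%M:%S+00:00")
}

validate_post_record <- function(rec) {
  required <- c("id", "text", "timestamp", "country", "language", "source")
  for (f in required) {
    v <- rec[[f]]
    if (is.null(v) || length(v) != 1 || is.na(v)) return(sprintf("missing field '%s'", f))
  }
  if (!nzchar(trimws(rec$text))) return("empty text")
  if (!rec$source %in% POST_SOURCES) return(sprintf("unknown source '%s'", rec$source))
  ts <- parse_post_timestamp(rec$timestamp)
  if (is.na(ts)) return("unparseable or naive timestamp")
  NULL
}

record_to_row <- function(rec) {
  tibble::tibble(
    id = as.character(rec$id),
    text = as.character(rec$text),
    timestamp = parse_post_timestamp(rec$timestamp),
    country = as.character(rec$country),
    language = as.character(rec$language),
    source = as.character(rec$source),
    author_name = if (is.null(rec$author_name) || length(rec$author_name) != 1 ||
                      is.na(rec$author_name)) NA_character_ else as.character(rec$author_name),
    author_bio = if (is.null(rec$author_bio) || length(rec$author_bio) != 1 ||
                     is.na(rec$author_bio)) NA_character_ else as.character(rec$author_bio)
  )
}

#' Read a corpus of social posts
#'
#' Reads posts from JSON-lines (one object per line, UTF-8; the canonical
#' dialect) or CSV. Malformed records — missing required fields, empty text,
#' unknown source, or a timestamp without an explicit UTC offset — are
#' skipped with a warning; the skip count is attached as attribute
#' `n_skipped`.
#'
#' @param path file to read.
#' @param format `"jsonl"` or `"csv"`.
#' @param drop_duplicate_text if `TRUE`, keep only the first post for each
#'   exact text string (retweet-like duplicates; off by default).
#' @return tibble of posts in file order with columns `id`, `text`,
#'   `timestamp` (POSIXct, UTC), `country`, `language`, `source`,
#'   `author_name`, `author_bio`.
#' @export
read_posts <- function(path, format = c("jsonl", "csv"),
                       drop_duplicate_text = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read posts: file not found: ", path)
  records <- if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l, simplifyVector = TRUE),
               error = function(e) NULL)
    })
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  rows <- vector("list", length(records))
  n_skipped <- 0L
  for (i in seq_along(records)) {
    rec <- records[[i]]
    problem <- if (is.null(rec)) "unparseable record" else validate_post_record(rec)
    if (is.null(problem)) {
      rows[[i]] <- record_to_row(rec)
    } else {
      n_skipped <- n_skipped + 1L
    }
  }
  posts <- dplyr::bind_rows(rows)
  if (nrow(posts) == 0) {
    posts <- tibble::tibble(
      id = character(), text = character(),
      timestamp = as.POSIXct(character(), tz = "UTC"),
      country = character(), language = character(), source = character(),
      author_name = character(), author_bio = character()
    )
  }
  if (anyDuplicated(posts$id)) {
    stop("duplicate post ids in corpus: ",
         paste(utils::head(unique(posts$id[duplicated(posts$id)]), 3), collapse = ", "))
  }
  if (drop_duplicate_text) posts <- posts[!duplicated(posts$text), ]
  if (n_skipped > 0) {
    warning(sprintf("skipped %d malformed record(s) while reading %s", n_skipped, path))
  }
  attr(posts, "n_skipped") <- n_skipped
  posts
}

#' Write a corpus of social posts
#'
#' Timestamps are serialized as ISO-8601 with an explicit `+00:00` offset so
#' that `read_posts()` round-trips them exactly.
#'
#' @param posts tibble as returned by [read_posts()] or [generate_corpus()].
#' @param path destination file.
#' @param format `"jsonl"` or `"csv"`.
#' @return (invisibly) the number of records written.
#' @export
write_posts <- function(posts, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  out <- posts[, post_columns]
  out$timestamp <- format_post_timestamp(out$timestamp)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(out)), function(i) {
      jsonlite::toJSON(as.list(out[i, , drop = FALSE]), auto_unbox = TRUE,
                       null = "null", na = "null")
    }, character(1))
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (length(lines)) writeLines(lines, con, useBytes = TRUE)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(nrow(out))
}

#' Read gold annotations
#'
#' JSON-lines records `{post_id, categories: [..]}`; an empty category list
#' marks a noise post.
#'
#' @param path file to read.
#' @return tibble with columns `post_id` and list-column `categories`.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  tibble::tibble(
    post_id = vapply(recs, function(r) as.character(r$post_id), character(1)),
    categories = lapply(recs, function(r) as.character(r$categories))
  )
}

#' Write gold annotations as JSON-lines
#'
#' @param annotations tibble with columns `post_id`, `categories`.
#' @param path destination file.
#' @return (invisibly) number of records written.
#' @export
write_annotations <- function(annotations, path) {
  lines <- vapply(seq_len(nrow(annotations)), function(i) {
    jsonlite::toJSON(
      list(post_id = annotations$post_id[[i]],
           categories = as.character(annotations$categories[[i]])),
      auto_unbox = TRUE
    )
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = TRUE)
  invisible(nrow(annotations))
}
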