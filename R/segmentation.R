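#' Load segmentation lexicons
#'
#' Plain-text, one term per line: organization cue terms and per-gender
#' given-name lists. Defaults to the lexicons shipped with the package
#' (small multilingual starter lists; drop-in replacements welcome).
#'
#' @param org_path,men_path,women_path lexicon files.
#' @return list with lowercase character vectors `org`, `men`, `women`.
#' @export
load_lexicons <- function(
    org_path = system.file("extdata", "lexicon_org_cues.txt", package = "soclisten"),
    men_path = system.file("extdata", "lexicon_names_men.txt", package = "soclisten"),
    women_path = system.file("extdata", "lexicon_names_women.txt", package = "soclisten")) {
  read_lex <- function(p) {
    x <- readLines(p, encoding = "UTF-8", warn = FALSE)
    x <- tolower(trimws(x))
    unique(x[nzchar(x) & !startsWith(x, "#")])
  }
  list(org = read_lex(org_path), men = read_lex(men_path),
       women = read_lex(women_path))
}

author_words <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  tolower(regmatches(x, gregexpr("[\\p{L}']+", x, perl = TRUE))[[1]])
}

#' Classify an author as man, woman, organization or unknown
#'
#' Transparent rule-based default for the poster-type/gender segmentation
#' contract (the production system uses a learned model; any drop-in with
#' the same signature can replace this). Deterministic and
#' case-insensitive: an organization cue term in the name or bio wins over
#' any name match; otherwise the first token of the display name is looked
#' up in the gendered given-name lexicons; otherwise `unknown`.
#'
#' @param author_name,author_bio strings (may be `NA`).
#' @param lexicons from [load_lexicons()].
#' @return one of `"man"`, `"woman"`, `"organization"`, `"unknown"`.
#' @export
classify_author <- function(author_name, author_bio = NA_character_,
                            lexicons = load_lexicons()) {
  name_words <- author_words(author_name)
  bio_words <- author_words(author_bio)
  if (any(c(name_words, bio_words) %in% lexicons$org)) return("organization")
  first <- if (length(name_words)) name_words[[1]] else NULL
  if (!is.null(first)) {
    if (first %in% lexicons$men) return("man")
    if (first %in% lexicons$women) return("woman")
  }
  "unknown"
}

#' Segment every author in a corpus
#'
#' @param posts posts tibble (uses `author_name`, `author_bio`).
#' @param lexicons from [load_lexicons()].
#' @param classifier optional drop-in replacement with the signature of
#'   [classify_author()].
#' @return tibble: `post_id`, `segment`.
#' @export
classify_authors <- function(posts, lexicons = load_lexicons(),
                             classifier = classify_author) {
  tibble::tibble(
    post_id = posts$id,
    segment = vapply(seq_len(nrow(posts)), function(i) {
      classifier(posts$author_name[[i]], posts$author_bio[[i]], lexicons)
    }, character(1))
  )
}

strip_quoted_spans <- function(x) {
  x <- gsub('"[^"]*"', " ", x)
  x <- gsub("“[^”]*”", " ", x)
  x <- gsub("‘[^’]*’", " ", x)
  # straight single quotes only when they delimit a span (not apostrophes)
  gsub("(^|\\s)'[^']*'(?=\\s|[[:punct:]]|$)", " ", x, perl = TRUE)
}

#' Detect whether a post carries a question
#'
#' Default rule-based detector for the question-intent contract: `TRUE` iff
#' the text contains a `?` that is not inside a URL and not inside a quoted
#' span, and the text matches none of the advertisement/headline patterns.
#' Rhetorical and already-answered questions are not modeled (the
#' production detector is a learned multilingual model; pass `detector` to
#' plug one in).
#'
#' @param text character vector of post texts.
#' @param ad_patterns character vector of regexes flagging
#'   advertisement/headline posts (matched case-insensitively).
#' @param detector optional drop-in `function(text) -> logical`.
#' @return logical vector.
#' @export
detect_question <- function(text, ad_patterns = character(0), detector = NULL) {
  if (!is.null(detector)) return(detector(text))
  vapply(text, function(x) {
    if (is.na(x)) return(FALSE)
    if (length(ad_patterns) &&
        any(vapply(ad_patterns, function(p) grepl(p, x, ignore.case = TRUE),
                   logical(1)))) {
      return(FALSE)
    }
    x <- gsub("(https?://|www\\.)\\S+", " ", x, ignore.case = TRUE)
    x <- strip_quoted_spans(x)
    grepl("?", x, fixed = TRUE)
  }, logical(1), USE.NAMES = FALSE)
}

#' Gender shares among gender-resolved individual posters
#'
#' Shares over man + woman posts only (organizations and unknowns
#' excluded), as percentages that sum to exactly 100.
#'
#' @param segments character vector of segments, or tibble from
#'   [classify_authors()].
#' @return tibble: `men_share`, `women_share`, `n_resolved`.
#' @export
segment_proportions <- function(segments) {
  if (is.data.frame(segments)) segments <- segments$segment
  n_men <- sum(segments == "man")
  n_women <- sum(segments == "woman")
  n <- n_men + n_women
  if (n == 0) stop("no gender-resolved posts")
  men <- 100 * n_men / n
  tibble::tibble(men_share = men, women_share = 100 - men, n_resolved = n)
}
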