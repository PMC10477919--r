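#' The five main taxonomy topics
#'
#' Main conversation topics of the public-health social-listening taxonomy:
#' the cause of the virus, illness, treatment, interventions (including
#' prevention), and information/misinformation.
#' @export
TAXONOMY_TOPICS <- c("cause", "illness", "treatment", "interventions", "information")

normalize_keyword <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

#' Construct a taxonomy object
#'
#' A taxonomy maps topics to categories and categories to per-language seed
#' keyword phrase lists (each phrase one or more tokens). Keywords are the
#' only supervision the semisupervised classifier receives.
#'
#' @param categories list of category descriptors, each a list with `id`,
#'   `name`, `topic` and `keywords` (named list: language code ->
#'   character vector of phrases).
#' @param version version tag string.
#' @return object of class `taxonomy`.
#' @export
taxonomy <- function(categories, version = "0") {
  ids <- vapply(categories, function(c) as.character(c$id), character(1))
  if (anyDuplicated(ids)) stop("duplicate category ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  categories <- lapply(categories, function(cat) {
    cat$id <- as.character(cat$id)
    cat$name <- as.character(cat$name %||% cat$id)
    cat$topic <- as.character(cat$topic)
    if (!cat$topic %in% TAXONOMY_TOPICS) {
      stop(sprintf("category '%s' has unknown topic '%s'", cat$id, cat$topic))
    }
    kw <- cat$keywords
    if (is.character(kw)) kw <- list(en = kw)
    if (is.null(kw) || length(kw) == 0) {
      stop(sprintf("category '%s' has no keywords", cat$id))
    }
    cat$keywords <- lapply(kw, function(phrases) {
      phrases <- normalize_keyword(as.character(phrases))
      phrases <- phrases[nzchar(phrases)]
      unique(phrases)
    })
    for (lang in names(cat$keywords)) {
      if (length(cat$keywords[[lang]]) == 0) {
        stop(sprintf("category '%s' has an empty keyword list for language '%s'",
                     cat$id, lang))
      }
    }
    cat
  })
  names(categories) <- ids
  # cross-category duplicate keywords are allowed but create ambiguity that
  # the propagation step must resolve; surface them.
  for (lang in unique(unlist(lapply(categories, function(c) names(c$keywords))))) {
    all_kw <- unlist(lapply(categories, function(c) c$keywords[[lang]]))
    dup <- unique(all_kw[duplicated(all_kw)])
    if (length(dup)) {
      message(sprintf("taxonomy: keyword(s) shared across categories [%s]: %s",
                      lang, paste(utils::head(dup, 5), collapse = ", ")))
    }
  }
  structure(
    list(version = as.character(version), topics = TAXONOMY_TOPICS,
         categories = categories),
    class = "taxonomy"
  )
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy v%s: %d categories over %d topics>\n",
              x$version, length(x$categories), length(x$topics)))
  invisible(x)
}

#' Category ids of a taxonomy, in lexicographic order
#' @param tax a `taxonomy`.
#' @export
category_ids <- function(tax) {
  sort(names(tax$categories))
}

#' Per-category keyword lists for one language
#'
#' Keywords are stored per language (they were authored in English and then
#' translated/adapted per language); a corpus is classified with the set
#' matching its language code, falling back to `"en"`.
#'
#' @param tax a `taxonomy`.
#' @param language ISO 639-1 code.
#' @param fallback language used when `language` has no keywords.
#' @return named list: category id -> character vector of phrases.
#' @export
keywords_for <- function(tax, language = "en", fallback = "en") {
  out <- lapply(tax$categories, function(cat) {
    cat$keywords[[language]] %||% cat$keywords[[fallback]] %||% character(0)
  })
  out[order(names(out))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate a taxonomy configuration
#'
#' Accepts YAML or JSON of the shape
#' `{version, categories: [{id, name, topic, keywords: {en: [...], ...}}]}`.
#' Duplicate phrases within a category are collapsed; a category with an
#' empty keyword list or an unknown topic is a fatal validation error.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return a `taxonomy`.
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$categories) || length(cfg$categories) == 0) {
    stop("taxonomy config has no categories")
  }
  taxonomy(cfg$categories, version = cfg$version %||% "0")
}

#' Write a taxonomy configuration
#'
#' Emits YAML that [load_taxonomy()] reads back to an equal object.
#'
#' @param tax a `taxonomy`.
#' @param path destination `.yaml` file.
#' @export
write_taxonomy <- function(tax, path) {
  cfg <- list(
    version = tax$version,
    topics = as.list(tax$topics),
    categories = unname(lapply(tax$categories, function(cat) {
      list(id = cat$id, name = cat$name, topic = cat$topic,
           keywords = lapply(cat$keywords, as.list))
    }))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Path to the shipped placeholder taxonomy
#'
#' A synthetic stand-in for the production taxonomy: category names are the
#' ones recoverable from published summary tables, but each keyword list is
#' a documented placeholder (the full production keyword appendices are not
#' public). Useful as a shape reference for user taxonomies.
#' @export
default_taxonomy_path <- function() {
  system.file("extdata", "taxonomy_placeholder_synthetic.yaml",
              package = "soclisten", mustWork = TRUE)
}
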