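#' Specification of a synthetic social-post corpus
#'
#' Defines the planted structure every pipeline stage is tested against:
#' category-specific core vocabularies whose co-occurrence makes posts of a
#' category similar (the statistical structure the graph classifier
#' assumes), a shared ambient vocabulary, ambient-only noise posts, weekly
#' volume schedules with multiplicative spikes, and known author-type /
#' gender / question proportions.
#'
#' @param n_categories number of planted categories.
#' @param core_vocab_per_category distinct core words per category.
#' @param shared_ambient_vocab distinct ambient words shared by all posts.
#' @param keywords_per_category core words exposed to the taxonomy as seed
#'   keywords (the last one is emitted as a two-word phrase to exercise
#'   phrase matching).
#' @param post_length mean token count per post (Poisson, floored at 3).
#' @param core_mix probability that a planted post's token is drawn from
#'   its category core rather than the ambient vocabulary.
#' @param noise_fraction fraction of the corpus that is ambient-only noise.
#' @param weeks number of ISO weeks covered.
#' @param base_posts_per_week planted posts per category per week.
#' @param spikes list of `list(category, week, multiplier)` volume spikes
#'   (multiplier > 1).
#' @param men_share share of men among gendered individual posters.
#' @param org_share share of organization posters.
#' @param question_rate share of posts carrying a question.
#' @param bigram_rate share of planted posts carrying the category's
#'   two-word keyword phrase.
#' @param language,country codes stamped on every post.
#' @param start_date Monday starting the first ISO week.
#' @param overlap_words keywords shared between the first two categories'
#'   keyword sets (see [ambiguity_injection()]).
#' @param seed integer seed; generation is fully reproducible.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_categories = 3,
                           core_vocab_per_category = 50,
                           shared_ambient_vocab = 200,
                           keywords_per_category = 5,
                           post_length = 12,
                           core_mix = 0.5,
                           noise_fraction = 0.2,
                           weeks = 12,
                           base_posts_per_week = 25,
                           spikes = list(list(category = 1, week = 9, multiplier = 3)),
                           men_share = 0.6,
                           org_share = 0.2,
                           question_rate = 0.2,
                           bigram_rate = 0.25,
                           language = "en",
                           country = "GB",
                           start_date = as.Date("2021-01-04"),
                           overlap_words = 0,
                           seed = 1L) {
  spec <- list(
    n_categories = n_categories,
    core_vocab_per_category = core_vocab_per_category,
    shared_ambient_vocab = shared_ambient_vocab,
    keywords_per_category = keywords_per_category,
    post_length = post_length, core_mix = core_mix,
    noise_fraction = noise_fraction, weeks = weeks,
    base_posts_per_week = base_posts_per_week, spikes = spikes,
    men_share = men_share, org_share = org_share,
    question_rate = question_rate, bigram_rate = bigram_rate,
    language = language, country = country,
    start_date = as.Date(start_date),
    overlap_words = overlap_words, seed = as.integer(seed)
  )
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(spec) {
  probs <- c(spec$core_mix, spec$noise_fraction, spec$men_share,
             spec$org_share, spec$question_rate, spec$bigram_rate)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  if (spec$n_categories < 1) stop("need at least one category")
  if (spec$keywords_per_category + 1 > spec$core_vocab_per_category) {
    stop("keywords (plus the phrase pair) exceed the core vocabulary")
  }
  if (spec$overlap_words > spec$core_vocab_per_category -
        spec$keywords_per_category - 1) {
    stop("overlap_words exceed the non-keyword core vocabulary")
  }
  if (spec$overlap_words > 0 && spec$n_categories < 2) {
    stop("keyword overlap needs at least two categories")
  }
  for (sp in spec$spikes) {
    if (sp$multiplier <= 1) stop("spike multiplier must be > 1")
    if (sp$week < 1 || sp$week > spec$weeks) stop("spike week out of range")
    if (sp$category < 1 || sp$category > spec$n_categories) {
      stop("spike category out of range")
    }
  }
  if (lubridate::wday(spec$start_date, week_start = 1) != 1) {
    stop("start_date must be a Monday (ISO week start)")
  }
  invisible(spec)
}

#' Plant keyword ambiguity between two categories
#'
#' Designates `overlap_words` non-keyword core words of each of the first
#' two categories as seed keywords of the *other* category. Posts of one
#' category then legitimately contain the other's keywords, so Boolean
#' OR-queries must produce false positives, while the graph classifier can
#' still disambiguate from co-occurring context — the failure mode that
#' separates the two methods.
#'
#' @param spec a `synthetic_spec`.
#' @param overlap_words number of shared keywords (0 leaves the spec
#'   unchanged).
#' @return the modified `synthetic_spec`.
#' @export
ambiguity_injection <- function(spec, overlap_words) {
  spec$overlap_words <- overlap_words
  validate_synthetic_spec(spec)
  spec
}

synthetic_category_ids <- function(spec) sprintf("cat%02d", seq_len(spec$n_categories))

core_word <- function(k, i) sprintf("c%02dw%02d", k, i)

synthetic_keywords <- function(spec, k) {
  kw_n <- spec$keywords_per_category
  kws <- if (kw_n == 1) {
    core_word(k, 1)
  } else {
    c(core_word(k, seq_len(kw_n - 1)),
      paste(core_word(k, kw_n), core_word(k, kw_n + 1)))
  }
  if (spec$overlap_words > 0 && k %in% c(1, 2)) {
    other <- if (k == 1) 2 else 1
    start <- spec$keywords_per_category + 2
    kws <- c(kws, core_word(other, seq(start, start + spec$overlap_words - 1)))
  }
  kws
}

synthetic_taxonomy <- function(spec) {
  ids <- synthetic_category_ids(spec)
  cats <- lapply(seq_along(ids), function(k) {
    list(id = ids[k], name = paste("Synthetic category", k),
         topic = TAXONOMY_TOPICS[(k - 1) %% length(TAXONOMY_TOPICS) + 1],
         keywords = stats::setNames(list(synthetic_keywords(spec, k)),
                                    spec$language))
  })
  suppressMessages(taxonomy(cats, version = "synthetic"))
}

#' Generate a synthetic corpus with known ground truth
#'
#' Produces posts, gold annotations, gold author segments, the matching
#' taxonomy (whose keywords are the designated subset of each category's
#' core vocabulary), the true per-category weekly volume table, and a spike
#' ledger listing exactly which (category, week) pairs must exceed the
#' velocity threshold by construction. Post text is a space-joined bag of
#' sampled tokens; questions get a trailing `?`. Fully reproducible under
#' the spec seed.
#'
#' @param spec a `synthetic_spec`.
#' @return list: `posts`, `gold`, `segments`, `taxonomy`, `weekly_counts`,
#'   `ledger`, `spec`.
#' @export
generate_corpus <- function(spec) {
  validate_synthetic_spec(spec)
  withr::with_seed(spec$seed, generate_corpus_impl(spec))
}

generate_corpus_impl <- function(spec) {
  K <- spec$n_categories
  cat_ids <- synthetic_category_ids(spec)
  ambient <- sprintf("amb%03d", seq_len(spec$shared_ambient_vocab))
  cores <- lapply(seq_len(K), function(k) {
    core_word(k, seq_len(spec$core_vocab_per_category))
  })
  lex <- load_lexicons()
  surnames <- c("walker", "smith", "garcía", "lópez", "jones", "brown",
                "pérez", "taylor", "moreno", "khan")
  org_stems <- c("ministry", "agency", "institute", "news", "university",
                 "council", "foundation", "department")
  title_case <- function(x) {
    paste0(toupper(substring(x, 1, 1)), substring(x, 2))
  }

  # deterministic planted volume schedule
  volume <- matrix(spec$base_posts_per_week, nrow = K, ncol = spec$weeks,
                   dimnames = list(cat_ids, NULL))
  for (sp in spec$spikes) {
    volume[sp$category, sp$week] <- round(spec$base_posts_per_week * sp$multiplier)
  }
  n_planted <- sum(volume)
  n_noise <- round(spec$noise_fraction / (1 - spec$noise_fraction) * n_planted)
  noise_per_week <- diff(round(seq(0, n_noise, length.out = spec$weeks + 1)))

  rows <- list()
  make_tokens <- function(k) {
    len <- max(3L, stats::rpois(1, spec$post_length))
    if (is.na(k)) {
      toks <- sample(ambient, len, replace = TRUE)
    } else {
      from_core <- stats::runif(len) < spec$core_mix
      toks <- character(len)
      toks[from_core] <- sample(cores[[k]], sum(from_core), replace = TRUE)
      toks[!from_core] <- sample(ambient, sum(!from_core), replace = TRUE)
      if (spec$keywords_per_category > 1 &&
          stats::runif(1) < spec$bigram_rate) {
        pos <- sample.int(len + 1, 1) - 1L
        toks <- append(toks, core_word(k, spec$keywords_per_category + c(0, 1)),
                       after = pos)
      }
    }
    toks
  }
  make_author <- function() {
    if (stats::runif(1) < spec$org_share) {
      stem <- sample(org_stems, 1)
      list(segment = "organization",
           name = paste(title_case(stem), "Updates"),
           bio = "Official information account")
    } else if (stats::runif(1) < spec$men_share) {
      list(segment = "man",
           name = paste(title_case(sample(lex$men, 1)),
                        title_case(sample(surnames, 1))),
           bio = "views my own")
    } else {
      list(segment = "woman",
           name = paste(title_case(sample(lex$women, 1)),
                        title_case(sample(surnames, 1))),
           bio = "views my own")
    }
  }
  add_post <- function(k, week) {
    toks <- make_tokens(k)
    text <- paste(toks, collapse = " ")
    is_q <- stats::runif(1) < spec$question_rate
    if (is_q) text <- paste0(text, "?")
    author <- make_author()
    ts <- as.POSIXct(spec$start_date, tz = "UTC") +
      (week - 1) * 7 * 86400 + floor(stats::runif(1, 0, 7 * 86400 - 1))
    rows[[length(rows) + 1]] <<- list(
      text = text, timestamp = ts,
      category = if (is.na(k)) NA_character_ else cat_ids[k],
      week = week, segment = author$segment, author_name = author$name,
      author_bio = author$bio, is_question = is_q,
      source = sample(POST_SOURCES, 1, prob = c(0.933, 0.007, 0.06))
    )
  }
  for (w in seq_len(spec$weeks)) {
    for (k in seq_len(K)) {
      for (r in seq_len(volume[k, w])) add_post(k, w)
    }
    for (r in seq_len(noise_per_week[w])) add_post(NA_integer_, w)
  }

  ord <- order(vapply(rows, function(r) as.numeric(r$timestamp), numeric(1)))
  rows <- rows[ord]
  ids <- sprintf("p%05d", seq_along(rows))
  posts <- tibble::tibble(
    id = ids,
    text = vapply(rows, `[[`, character(1), "text"),
    timestamp = as.POSIXct(vapply(rows, function(r) as.numeric(r$timestamp),
                                  numeric(1)),
                           origin = "1970-01-01", tz = "UTC"),
    country = spec$country,
    language = spec$language,
    source = vapply(rows, `[[`, character(1), "source"),
    author_name = vapply(rows, `[[`, character(1), "author_name"),
    author_bio = vapply(rows, `[[`, character(1), "author_bio")
  )
  gold <- tibble::tibble(
    post_id = ids,
    categories = lapply(rows, function(r) {
      if (is.na(r$category)) character(0) else r$category
    })
  )
  segments <- tibble::tibble(
    post_id = ids,
    segment = vapply(rows, `[[`, character(1), "segment"),
    is_question = vapply(rows, `[[`, logical(1), "is_question")
  )
  weekly_counts <- tibble::tibble(
    category = rep(cat_ids, spec$weeks),
    week_index = rep(seq_len(spec$weeks), each = K),
    week = spec$start_date + (rep(seq_len(spec$weeks), each = K) - 1) * 7,
    volume = as.integer(volume[cbind(rep(seq_len(K), spec$weeks),
                                     rep(seq_len(spec$weeks), each = K))])
  ) |> dplyr::arrange(.data$category, .data$week_index)

  # ledger: spikes guaranteed to clear the velocity threshold (week > 4 so
  # a 4-week trailing baseline exists and is spike-free by construction)
  ledger_rows <- list()
  for (sp in spec$spikes) {
    if (sp$week > 4) {
      base <- spec$base_posts_per_week
      vol <- round(base * sp$multiplier)
      ledger_rows[[length(ledger_rows) + 1]] <- tibble::tibble(
        category = cat_ids[sp$category], week_index = sp$week,
        week = spec$start_date + (sp$week - 1) * 7,
        multiplier = sp$multiplier, volume = vol, baseline_mean = base,
        expected_velocity = (vol - base) / base
      )
    }
  }
  ledger <- if (length(ledger_rows)) dplyr::bind_rows(ledger_rows) else
    tibble::tibble(category = character(0), week_index = integer(0),
                   week = as.Date(character(0)), multiplier = numeric(0),
                   volume = integer(0), baseline_mean = numeric(0),
                   expected_velocity = numeric(0))

  list(posts = posts, gold = gold, segments = segments,
       taxonomy = synthetic_taxonomy(spec), weekly_counts = weekly_counts,
       ledger = ledger, spec = spec)
}

#' Write a synthetic bundle to disk
#'
#' Emits `corpus.jsonl`, `gold.jsonl`, `segments.csv`, `taxonomy.yaml`,
#' `weekly_counts.csv` and `spike_ledger.csv` in the formats the other
#' modules consume.
#'
#' @param bundle list from [generate_corpus()].
#' @param dir output directory (created if missing).
#' @return (invisibly) the directory.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_posts(bundle$posts, file.path(dir, "corpus.jsonl"), "jsonl")
  write_annotations(bundle$gold, file.path(dir, "gold.jsonl"))
  readr::write_csv(bundle$segments, file.path(dir, "segments.csv"), progress = FALSE)
  write_taxonomy(bundle$taxonomy, file.path(dir, "taxonomy.yaml"))
  readr::write_csv(bundle$weekly_counts, file.path(dir, "weekly_counts.csv"),
                   progress = FALSE)
  readr::write_csv(bundle$ledger, file.path(dir, "spike_ledger.csv"),
                   progress = FALSE)
  invisible(dir)
}
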