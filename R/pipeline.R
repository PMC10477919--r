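#' Default run configuration
#'
#' Full parameter defaults for the pipeline commands; all values can be
#' overridden via the `config` argument of [run_pipeline()] or a YAML/JSON
#' config file.
#'
#' @return nested named list of defaults.
#' @export
default_config <- function() {
  list(
    language = "en",
    graph = list(k_neighbors = 10, min_df = 2, max_df_ratio = 0.5,
                 edge_floor = 0.05),
    propagation = list(mu = 1.0, nu = 2.0, self_weight = 1.0,
                       max_iter = 200, tol = 1e-4, epsilon_noise = 0.01),
    velocity = list(window = 4, threshold = 0.15, min_volume = 10),
    synthetic = list(),        # synthetic_spec() overrides for `simulate`
    boolean = TRUE,            # also emit Boolean-baseline predictions
    seed = 1L
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

config_hash <- function(config) {
  # stable content digest without external digest packages
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251 + 1)) %%
            .Machine$integer.max)
}

write_run_info <- function(output_dir, command, config) {
  info <- list(command = command, seed = config$seed,
               config_hash = config_hash(config), config = config,
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S+00:00", tz = "UTC"))
  jsonlite::write_json(info, file.path(output_dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
}

#' Run one pipeline stage
#'
#' Ties the stages into the platform's processing pathway (collect /
#' simulate, categorize, segment, analyze):
#' \describe{
#'   \item{simulate}{write a synthetic bundle (corpus, gold, taxonomy,
#'     segments, spike ledger) under `output_dir`.}
#'   \item{classify}{classify `corpus` with `taxonomy`; writes
#'     `classification.csv` (and `boolean.csv` unless disabled).}
#'   \item{evaluate}{score classification and Boolean predictions against
#'     `gold`; writes `metrics.csv`, `metrics_macro.csv` and
#'     `hotelling.json`.}
#'   \item{velocity}{weekly aggregation and alerts from classified posts
#'     (plus author segments and question flags); writes `weekly.csv`,
#'     `alerts.csv` and `alert_counts.csv`.}
#'   \item{report}{summary tables: method metrics, gender proportions, and
#'     alert counts by category/gender/question.}
#' }
#' Every run writes `run_info.json` carrying the seed and a config hash.
#'
#' @param command one of `"simulate"`, `"classify"`, `"evaluate"`,
#'   `"velocity"`, `"report"`.
#' @param corpus path to a posts JSONL (all commands but `simulate`).
#' @param taxonomy_path path to a taxonomy config (defaults to the
#'   simulate bundle's taxonomy when present, else the shipped placeholder).
#' @param gold path to gold annotations JSONL (`evaluate`).
#' @param output_dir artifact directory (created).
#' @param config named list overriding [default_config()].
#' @return (invisibly) a list of the in-memory artifacts.
#' @export
run_pipeline <- function(command = c("simulate", "classify", "evaluate",
                                     "velocity", "report"),
                         corpus = NULL, taxonomy_path = NULL, gold = NULL,
                         output_dir = ".", config = list()) {
  command <- match.arg(command)
  cfg <- merge_config(default_config(), config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  if (command == "simulate") {
    spec <- do.call(synthetic_spec, c(cfg$synthetic, list(seed = cfg$seed)))
    bundle <- generate_corpus(spec)
    write_synthetic_bundle(bundle, output_dir)
    write_run_info(output_dir, command, cfg)
    return(invisible(bundle))
  }

  if (is.null(corpus)) stop(command, " needs a corpus path")
  posts <- read_posts(corpus, "jsonl")
  if (is.null(taxonomy_path)) {
    candidate <- file.path(dirname(corpus), "taxonomy.yaml")
    taxonomy_path <- if (file.exists(candidate)) candidate else default_taxonomy_path()
  }
  tax <- load_taxonomy(taxonomy_path)

  result <- classify_corpus(posts, tax, language = cfg$language,
                            graph_params = cfg$graph,
                            mu = cfg$propagation$mu, nu = cfg$propagation$nu,
                            self_weight = cfg$propagation$self_weight,
                            max_iter = cfg$propagation$max_iter,
                            tol = cfg$propagation$tol,
                            epsilon_noise = cfg$propagation$epsilon_noise)
  tokenized <- tokenize_posts(posts, cfg$language)
  boolean <- if (isTRUE(cfg$boolean)) {
    boolean_classify(tokenized, tax, cfg$language)
  } else NULL

  if (command == "classify") {
    write_classification(result, file.path(output_dir, "classification.csv"))
    if (!is.null(boolean)) {
      write_boolean_predictions(boolean, file.path(output_dir, "boolean.csv"))
    }
    write_run_info(output_dir, command, cfg)
    return(invisible(list(classification = result, boolean = boolean)))
  }

  if (command == "evaluate") {
    if (is.null(gold)) stop("evaluate needs a gold annotations path")
    gold_df <- read_annotations(gold)
    cats <- category_ids(tax)
    ev_alg <- evaluate_predictions(gold_df, result, cats)
    out <- dplyr::bind_cols(tibble::tibble(method = "algorithm"),
                            ev_alg$per_category)
    macro <- list(algorithm = ev_alg$macro)
    hot <- NULL
    if (!is.null(boolean)) {
      ev_bool <- evaluate_predictions(gold_df, boolean, cats)
      out <- dplyr::bind_rows(out, dplyr::bind_cols(
        tibble::tibble(method = "boolean"), ev_bool$per_category))
      macro$boolean <- ev_bool$macro
      hot <- tryCatch(
        hotelling_t2_paired(
          as.matrix(ev_alg$per_category[, c("precision", "recall")]),
          as.matrix(ev_bool$per_category[, c("precision", "recall")])),
        error = function(e) list(error = conditionMessage(e)))
      jsonlite::write_json(unclass(hot), file.path(output_dir, "hotelling.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    readr::write_csv(out, file.path(output_dir, "metrics.csv"), progress = FALSE)
    readr::write_csv(metrics_report(list(en = macro)),
                     file.path(output_dir, "metrics_macro.csv"), progress = FALSE)
    write_run_info(output_dir, command, cfg)
    return(invisible(list(per_method = macro, hotelling = hot)))
  }

  # velocity / report: join labels + segments + question flags
  labeled <- dplyr::inner_join(
    posts, result$assignments, by = c(id = "post_id")) |>
    dplyr::rename(category = "label")
  segs <- classify_authors(posts)
  labeled <- dplyr::left_join(labeled, segs, by = c(id = "post_id"))
  labeled$is_question <- detect_question(labeled$text)
  labeled$post_id <- labeled$id

  weekly <- aggregate_weekly(labeled, by = c("country", "category", "segment",
                                             "is_question"))
  alerts <- velocity_alerts(weekly,
                            window = cfg$velocity$window,
                            threshold = cfg$velocity$threshold,
                            min_volume = cfg$velocity$min_volume)
  counts <- count_alerts(alerts, by = c("country", "category", "segment",
                                        "is_question"))
  readr::write_csv(weekly, file.path(output_dir, "weekly.csv"), progress = FALSE)
  write_alerts(alerts, file.path(output_dir, "alerts.csv"))
  readr::write_csv(counts, file.path(output_dir, "alert_counts.csv"),
                   progress = FALSE)
  if (command == "report") {
    gender <- segment_proportions(segs)
    readr::write_csv(gender, file.path(output_dir, "gender_proportions.csv"),
                     progress = FALSE)
    # per-category totals use the unsplit series (cross-filtered series can
    # each fall below the alert volume floor even when the category spikes)
    by_cat <- count_alerts(
      velocity_alerts(aggregate_weekly(labeled, by = c("country", "category")),
                      window = cfg$velocity$window,
                      threshold = cfg$velocity$threshold,
                      min_volume = cfg$velocity$min_volume),
      by = c("country", "category"))
    readr::write_csv(by_cat, file.path(output_dir, "alerts_by_category.csv"),
                     progress = FALSE)
  }
  write_run_info(output_dir, command, cfg)
  invisible(list(weekly = weekly, alerts = alerts, counts = counts))
}
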