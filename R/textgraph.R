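#' Tokenize a post text
#'
#' Lowercased unicode word tokens. URLs and `@mentions` are removed;
#' hashtags are kept as their bare word (leading `#` stripped) because they
#' carry topical signal inside sentences. `content_flag` is `TRUE` only if
#' at least one alphabetic token remains that did not come from a hashtag —
#' posts containing only hashtags or user mentions are noise-prefiltered.
#'
#' @param text a single character string.
#' @param language ISO 639-1 code (reserved for per-language rules).
#' @return list with `tokens` (character vector) and `content_flag`.
#' @export
tokenize <- function(text, language = "en") {
  if (length(text) != 1) stop("tokenize() expects a single string; see tokenize_posts()")
  if (is.na(text) || !nzchar(trimws(text))) {
    return(list(tokens = character(0), content_flag = FALSE))
  }
  chunks <- strsplit(trimws(text), "\\s+", perl = TRUE)[[1]]
  is_url <- grepl("^(https?://|www\\.)", chunks, ignore.case = TRUE)
  is_mention <- grepl("^@", chunks)
  is_hashtag <- grepl("^#", chunks)
  tokens <- character(0)
  content_flag <- FALSE
  for (i in seq_along(chunks)) {
    if (is_url[i] || is_mention[i]) next
    raw <- chunks[i]
    if (is_hashtag[i]) raw <- sub("^#+", "", raw)
    words <- regmatches(raw, gregexpr("[\\p{L}\\p{N}']+", raw, perl = TRUE))[[1]]
    words <- tolower(words)
    words <- words[nzchar(gsub("'", "", words))]
    if (!length(words)) next
    tokens <- c(tokens, words)
    if (!is_hashtag[i] && any(grepl("\\p{L}", words, perl = TRUE))) {
      content_flag <- TRUE
    }
  }
  list(tokens = tokens, content_flag = content_flag)
}

#' Tokenize every post in a corpus
#'
#' @param posts posts tibble (needs `id`, `text`; `language` optional).
#' @param language language code applied to all posts (defaults to each
#'   post's own `language` column when present).
#' @return tibble with columns `post_id`, `tokens` (list-column) and
#'   `content_flag`.
#' @export
tokenize_posts <- function(posts, language = NULL) {
  langs <- if (!is.null(language)) rep(language, nrow(posts))
           else if ("language" %in% names(posts)) posts$language
           else rep("en", nrow(posts))
  tk <- lapply(seq_len(nrow(posts)), function(i) tokenize(posts$text[[i]], langs[[i]]))
  tibble::tibble(
    post_id = posts$id,
    tokens = lapply(tk, `[[`, "tokens"),
    content_flag = vapply(tk, `[[`, logical(1), "content_flag")
  )
}

count_phrase_occurrences <- function(tokens, phrase_tokens) {
  m <- length(phrase_tokens)
  n <- length(tokens)
  if (m == 0L || n < m) return(0L)
  if (m == 1L) return(sum(tokens == phrase_tokens))
  count <- 0L
  i <- 1L
  while (i <= n - m + 1L) {
    if (all(tokens[i:(i + m - 1L)] == phrase_tokens)) {
      count <- count + 1L   # non-overlapping: jump past the match
      i <- i + m
    } else {
      i <- i + 1L
    }
  }
  count
}

#' Count keyword hits per category for one tokenized post
#'
#' Multiword phrases ("patient zero") are matched as contiguous normalized
#' token subsequences; counts are total non-overlapping occurrences summed
#' over a category's phrases. Categories with zero hits are omitted.
#'
#' @param tokens character vector of normalized tokens.
#' @param tax a `taxonomy`.
#' @param language keyword language (falls back to English).
#' @return named integer vector, category id -> hit count (hits > 0 only).
#' @export
match_keywords <- function(tokens, tax, language = "en") {
  kw <- keywords_for(tax, language)
  hits <- vapply(kw, function(phrases) {
    sum(vapply(phrases, function(ph) {
      count_phrase_occurrences(tokens, strsplit(ph, " ", fixed = TRUE)[[1]])
    }, integer(1)))
  }, integer(1))
  hits[hits > 0L]
}

match_keywords_corpus <- function(tokenized, tax, language = "en") {
  out <- lapply(tokenized$tokens, match_keywords, tax = tax, language = language)
  names(out) <- tokenized$post_id
  out
}

#' Build the post-similarity graph
#'
#' Posts are nodes; edge weights are cosine similarities between tf-idf
#' unigram vectors, the standard instantiation of similarity "computed from
#' the co-occurrences of words". The vocabulary is document-frequency
#' filtered, each node keeps its `k_neighbors` strongest edges, the edge set
#' is symmetrized by union (max weight), and edges below `edge_floor` are
#' dropped. Only `content_flag = TRUE` posts enter the graph.
#'
#' The idf is smoothed (`log((1 + N) / (1 + df)) + 1`) so that duplicated
#' texts still get weight-1 edges when every term is corpus-wide.
#'
#' @param tokenized tibble from [tokenize_posts()].
#' @param k_neighbors neighbors kept per node (default 10).
#' @param min_df minimum document frequency for a term (default 2).
#' @param max_df_ratio maximum document-frequency share (default 0.5).
#' @param edge_floor minimum retained edge weight (default 0.05).
#' @param stopwords optional character vector removed from the vocabulary
#'   (affects graph topology only).
#' @return object of class `similarity_graph`: `node_ids`, sparse symmetric
#'   weight matrix `W` (zero diagonal, weights in \[0, 1\]), `params`.
#' @export
build_graph <- function(tokenized, k_neighbors = 10, min_df = 2,
                        max_df_ratio = 0.5, edge_floor = 0.05,
                        stopwords = NULL) {
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  keep <- tokenized$content_flag
  ids <- tokenized$post_id[keep]
  docs <- tokenized$tokens[keep]
  n <- length(ids)
  if (n < 2) stop("need at least 2 content posts to build a graph")
  if (!is.null(stopwords)) docs <- lapply(docs, function(t) t[!t %in% stopwords])

  counts <- lapply(docs, function(t) table(t))
  vocab_df <- table(unlist(lapply(counts, names)))
  # the high-df cutoff never drops below min_df, so tiny corpora (where
  # every shared term necessarily has high document frequency) keep a vocabulary
  max_df_count <- max(ceiling(max_df_ratio * n), min_df)
  keep_term <- vocab_df >= min_df & vocab_df <= max_df_count
  vocab <- names(vocab_df)[keep_term]

  W <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(n, n))
  if (length(vocab) > 0) {
    idf <- log((1 + n) / (1 + as.numeric(vocab_df[vocab]))) + 1
    names(idf) <- vocab
    trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
    for (d in seq_len(n)) {
      tc <- counts[[d]]
      tc <- tc[names(tc) %in% vocab]
      if (!length(tc)) next
      j <- match(names(tc), vocab)
      trip_i <- c(trip_i, rep(d, length(j)))
      trip_j <- c(trip_j, j)
      trip_x <- c(trip_x, as.numeric(tc) * idf[names(tc)])
    }
    X <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                              dims = c(n, length(vocab)))
    norms <- sqrt(Matrix::rowSums(X^2))
    norms[norms == 0] <- 1
    X <- X / norms
    S <- as.matrix(Matrix::tcrossprod(X))
    diag(S) <- 0
    S[S < 0] <- 0          # numerical guard
    S[S > 1] <- 1
    # k-nearest-neighbor sparsification, union-symmetrized
    keep_mask <- matrix(FALSE, n, n)
    k <- min(k_neighbors, n - 1)
    for (d in seq_len(n)) {
      ord <- order(S[d, ], decreasing = TRUE)[seq_len(k)]
      ord <- ord[S[d, ord] > 0]
      keep_mask[d, ord] <- TRUE
    }
    keep_mask <- keep_mask | t(keep_mask)
    S[!keep_mask] <- 0
    S[S < edge_floor] <- 0
    W <- methods::as(Matrix::Matrix(S, sparse = TRUE), "generalMatrix")
  }
  structure(
    list(node_ids = ids, W = W,
         params = list(k_neighbors = k_neighbors, min_df = min_df,
                       max_df_ratio = max_df_ratio, edge_floor = edge_floor)),
    class = "similarity_graph"
  )
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph: %d nodes, %d edges>\n",
              length(x$node_ids), Matrix::nnzero(x$W) / 2))
  invisible(x)
}

#' Build a similarity graph directly from an edge list
#'
#' Mainly for inspection, fixtures and tests; the same container
#' [build_graph()] produces.
#'
#' @param node_ids character vector of node ids.
#' @param edges data frame with columns `node_i`, `node_j`, `weight`
#'   (undirected; each pair listed once).
#' @export
graph_from_edges <- function(node_ids, edges) {
  n <- length(node_ids)
  i <- match(edges$node_i, node_ids)
  j <- match(edges$node_j, node_ids)
  if (anyNA(i) || anyNA(j)) stop("edge references unknown node id")
  if (any(edges$weight < 0)) stop("edge weights must be nonnegative")
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = rep(as.numeric(edges$weight), 2),
                            dims = c(n, n), use.last.ij = TRUE)
  Matrix::diag(W) <- 0
  structure(list(node_ids = node_ids, W = W, params = list()),
            class = "similarity_graph")
}

#' Export a similarity graph as an edge-list CSV
#' @param graph a `similarity_graph`.
#' @param path destination CSV (`node_i, node_j, weight`).
#' @export
write_graph_edges <- function(graph, path) {
  tw <- Matrix::summary(Matrix::triu(graph$W))
  edges <- tibble::tibble(
    node_i = graph$node_ids[tw$i],
    node_j = graph$node_ids[tw$j],
    weight = tw$x
  )
  readr::write_csv(edges, path, progress = FALSE)
  invisible(path)
}

#' Import a similarity graph from an edge-list CSV
#' @param path CSV written by [write_graph_edges()].
#' @param node_ids optional full node id set (to keep isolated nodes).
#' @export
read_graph_edges <- function(path, node_ids = NULL) {
  edges <- readr::read_csv(path, col_types = "ccd", progress = FALSE)
  if (is.null(node_ids)) node_ids <- sort(unique(c(edges$node_i, edges$node_j)))
  graph_from_edges(node_ids, edges)
}
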