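#' Seed measures from keyword hits
#'
#' Each post with at least one keyword hit receives a seed distribution
#' proportional to its per-category hit counts: `r_i(c) = hits_i(c) /
#' sum_c hits_i(c)`. A post mentioning three fruit keywords therefore
#' carries full seed mass for the fruit category. Posts with no hits are
#' absent (unlabeled).
#'
#' @param hits named list: post_id -> named numeric vector of hit counts.
#' @param categories character vector of all category ids (column order).
#' @return matrix (seeded posts x categories), rows summing to 1.
#' @export
seed_measures <- function(hits, categories) {
  seeded <- names(hits)[vapply(hits, function(h) sum(h) > 0, logical(1))]
  R <- matrix(0, nrow = length(seeded), ncol = length(categories),
              dimnames = list(seeded, categories))
  for (pid in seeded) {
    h <- hits[[pid]]
    if (any(h < 0)) stop("negative hit count for post ", pid)
    unknown <- setdiff(names(h), categories)
    if (length(unknown)) stop("hit for unknown category: ", unknown[1])
    R[pid, names(h)] <- h / sum(h)
  }
  R
}

measure_objective <- function(W, deg, p, q, R, seeded_idx, mu, nu) {
  K <- ncol(p)
  eps <- 1e-300
  logq <- log(pmax(q, eps))
  # seed term: sum_{i in S} KL(r_i || q_i)
  kl_seed <- 0
  if (length(seeded_idx)) {
    Rs <- R[seeded_idx, , drop = FALSE]
    Qs <- q[seeded_idx, , drop = FALSE]
    term <- Rs * (log(pmax(Rs, eps)) - log(pmax(Qs, eps)))
    term[Rs == 0] <- 0
    kl_seed <- sum(term)
  }
  # smoothness: sum_ij w'_ij KL(p_i || q_j)
  plogp <- rowSums(p * log(pmax(p, eps)))
  cross <- sum(p * as.matrix(W %*% logq))
  kl_smooth <- sum(deg * plogp) - cross
  # entropy regularizer: sum_i KL(p_i || u)
  kl_unif <- sum(plogp) + nrow(p) * log(K)
  kl_seed + mu * kl_smooth + nu * kl_unif
}

#' Measure propagation over a similarity graph
#'
#' Diffuses probability distributions over categories from keyword-seeded
#' nodes to the whole graph by alternating closed-form minimization of
#'
#' \deqn{C(p, q) = \sum_{i \in S} KL(r_i \| q_i)
#'   + \mu \sum_{i,j} w'_{ij} KL(p_i \| q_j)
#'   + \nu \sum_i KL(p_i \| u)}
#'
#' with \eqn{w'_{ij} = w_{ij} + self\_weight \cdot [i = j]} and `u` uniform.
#' The q-update is a weighted arithmetic mean of neighbor measures (plus the
#' seed for seeded nodes); the p-update is a weighted geometric mean of
#' neighbor q's and the uniform prior. Both are exact minimizers, so the
#' objective is non-increasing at every half-step. Iteration stops when the
#' maximum per-node total-variation change falls below `tol`.
#'
#' @param graph a `similarity_graph`.
#' @param seeds seed matrix from [seed_measures()] (rows: seeded post ids
#'   that must be graph nodes).
#' @param mu graph-smoothness weight (> 0).
#' @param nu uniform-prior (entropy) weight (>= 0).
#' @param self_weight weight added to each node's self-loop.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on max total-variation change.
#' @return object of class `node_measure`: `p` (nodes x categories),
#'   `node_ids`, `categories`, `iterations`, `objective` (trace, one value
#'   per half-step), `converged`.
#' @export
propagate <- function(graph, seeds, mu = 1.0, nu = 2.0, self_weight = 1.0,
                      max_iter = 200, tol = 1e-4) {
  if (mu <= 0) stop("mu must be > 0")
  if (nu < 0) stop("nu must be >= 0")
  node_ids <- graph$node_ids
  n <- length(node_ids)
  categories <- colnames(seeds)
  if (is.null(categories) || length(categories) == 0) {
    stop("seeds must have category column names")
  }
  K <- length(categories)
  seeded_ids <- rownames(seeds)[rowSums(seeds) > 0]
  if (!all(seeded_ids %in% node_ids)) {
    stop("seed nodes missing from graph: ",
         paste(utils::head(setdiff(seeded_ids, node_ids), 3), collapse = ", "))
  }
  if (length(seeded_ids) == 0) {
    warning("empty seed set: all measures uniform")
    p <- matrix(1 / K, n, K, dimnames = list(node_ids, categories))
    return(structure(list(p = p, node_ids = node_ids, categories = categories,
                          iterations = 0L, objective = numeric(0),
                          converged = TRUE),
                     class = "node_measure"))
  }
  W <- graph$W + Matrix::Diagonal(n, self_weight)
  deg <- as.numeric(Matrix::rowSums(W))
  s <- as.numeric(node_ids %in% seeded_ids)
  R <- matrix(0, n, K, dimnames = list(node_ids, categories))
  R[seeded_ids, ] <- seeds[seeded_ids, colnames(R), drop = FALSE]
  seeded_idx <- which(s == 1)

  p <- matrix(1 / K, n, K)
  q <- p
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  log_u <- log(1 / K)
  eps <- 1e-300
  while (iter < max_iter) {
    iter <- iter + 1L
    # q-update (W symmetric: column sums over w'_ij p_i equal W %*% p)
    q <- (s * R + mu * as.matrix(W %*% p)) / (s + mu * deg)
    objective <- c(objective,
                   measure_objective(W, deg, p, q, R, seeded_idx, mu, nu))
    # p-update
    A <- (nu * log_u + mu * as.matrix(W %*% log(pmax(q, eps)))) / (nu + mu * deg)
    A <- A - apply(A, 1, max)
    p_new <- exp(A)
    p_new <- p_new / rowSums(p_new)
    objective <- c(objective,
                   measure_objective(W, deg, p_new, q, R, seeded_idx, mu, nu))
    delta <- max(0.5 * rowSums(abs(p_new - p)))
    p <- p_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning(sprintf("propagation did not converge in %d iterations", max_iter))
  dimnames(p) <- list(node_ids, categories)
  structure(list(p = p, node_ids = node_ids, categories = categories,
                 iterations = iter, objective = objective,
                 converged = converged),
            class = "node_measure")
}

#' @export
print.node_measure <- function(x, ...) {
  cat(sprintf("<node_measure: %d nodes x %d categories, %d iterations%s>\n",
              length(x$node_ids), length(x$categories), x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

tv_to_uniform <- function(p) {
  0.5 * rowSums(abs(p - 1 / ncol(p)))
}

#' Assign mono-labels (or NOISE) from node measures
#'
#' A post is labeled `NOISE` when its content flag is off (hashtag/mention
#' -only posts) or when its distribution is indistinguishable from
#' uninformative — total-variation distance to uniform at most
#' `epsilon_noise`, i.e. no category signal reached the node. Otherwise the
#' max-posterior category wins, with a deterministic lexicographic tie-break
#' on category id.
#'
#' @param p matrix of per-post distributions (rows named by post id).
#' @param content_flag named logical vector (same posts).
#' @param epsilon_noise noise threshold on TV distance to uniform.
#' @return tibble: `post_id`, `label`, `max_posterior`, `categorized`.
#' @export
assign_labels <- function(p, content_flag, epsilon_noise = 0.01) {
  categories <- colnames(p)
  ord <- order(categories)   # lexicographic preference for ties
  tv <- tv_to_uniform(p)
  labels <- character(nrow(p))
  maxp <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    flag <- content_flag[[rownames(p)[i]]]
    maxp[i] <- max(p[i, ])
    if (isFALSE(flag) || tv[i] <= epsilon_noise) {
      labels[i] <- NOISE_LABEL
    } else {
      best <- categories[ord][which(p[i, ord] == maxp[i])[1]]
      labels[i] <- best
    }
  }
  tibble::tibble(post_id = rownames(p), label = labels, max_posterior = maxp,
                 categorized = labels != NOISE_LABEL)
}

#' Classify a corpus into the taxonomy
#'
#' End-to-end semisupervised categorization: tokenize, match seed keywords,
#' build the tf-idf co-occurrence similarity graph, run measure propagation,
#' and assign one category (or `NOISE`) per post. Posts failing the content
#' prefilter, or left with an uninformative distribution, are noise and
#' excluded from downstream analytics. The share of non-noise posts is
#' reported as `categorized_fraction`.
#'
#' @param posts posts tibble.
#' @param tax a `taxonomy`.
#' @param language keyword/tokenizer language (default `"en"`).
#' @param graph_params list overriding [build_graph()] defaults.
#' @param mu,nu,self_weight,max_iter,tol see [propagate()].
#' @param epsilon_noise see [assign_labels()].
#' @return object of class `classification_result`: `assignments` tibble
#'   (`post_id`, `label`, `max_posterior`, `categorized`), `p`,
#'   `categorized_fraction`, `measure` (the full `node_measure`).
#' @export
classify_corpus <- function(posts, tax, language = "en",
                            graph_params = list(),
                            mu = 1.0, nu = 2.0, self_weight = 1.0,
                            max_iter = 200, tol = 1e-4,
                            epsilon_noise = 0.01) {
  categories <- category_ids(tax)
  tokenized <- tokenize_posts(posts, language)
  flags <- stats::setNames(tokenized$content_flag, tokenized$post_id)
  n_content <- sum(tokenized$content_flag)

  K <- length(categories)
  assignments <- tibble::tibble(
    post_id = tokenized$post_id,
    label = NOISE_LABEL,
    max_posterior = 1 / K,
    categorized = FALSE
  )
  measure <- NULL
  p_full <- matrix(1 / K, nrow(posts), K,
                   dimnames = list(tokenized$post_id, categories))
  if (n_content >= 2) {
    graph <- do.call(build_graph, c(list(tokenized = tokenized), graph_params))
    hits <- match_keywords_corpus(tokenized[tokenized$content_flag, ], tax, language)
    seeds <- seed_measures(hits, categories)
    measure <- propagate(graph, seeds, mu = mu, nu = nu,
                         self_weight = self_weight, max_iter = max_iter,
                         tol = tol)
    labs <- assign_labels(measure$p, flags, epsilon_noise)
    idx <- match(labs$post_id, assignments$post_id)
    assignments$label[idx] <- labs$label
    assignments$max_posterior[idx] <- labs$max_posterior
    assignments$categorized[idx] <- labs$categorized
    p_full[labs$post_id, ] <- measure$p[labs$post_id, ]
  }
  structure(
    list(assignments = assignments, p = p_full,
         categorized_fraction = mean(assignments$categorized),
         measure = measure, categories = categories),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result: %d posts, %.1f%% categorized>\n",
              nrow(x$assignments), 100 * x$categorized_fraction))
  invisible(x)
}

#' Export classification assignments as CSV
#' @param result a `classification_result`.
#' @param path destination CSV.
#' @export
write_classification <- function(result, path) {
  readr::write_csv(result$assignments, path, progress = FALSE)
  invisible(path)
}
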