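# Shared fixtures: tiny corpora built in code, an independent clamped
# label-propagation oracle, and random two-cluster graph instances.

make_posts <- function(texts, start = as.POSIXct("2021-02-01 12:00:00", tz = "UTC"),
                       country = "GB", language = "en",
                       author_name = NA_character_) {
  n <- length(texts)
  tibble::tibble(
    id = sprintf("t%03d", seq_len(n)),
    text = texts,
    timestamp = start + (seq_len(n) - 1) * 3600,
    country = country, language = language, source = "twitter",
    author_name = rep_len(author_name, n), author_bio = NA_character_
  )
}

fruit_taxonomy <- function() {
  taxonomy(list(
    list(id = "fruit", name = "Fruit", topic = "information",
         keywords = list(en = c("apple", "banana", "grapes")))
  ))
}

two_topic_taxonomy <- function() {
  taxonomy(list(
    list(id = "symptoms", name = "Other Discussed Symptoms", topic = "illness",
         keywords = list(en = c("sore throat", "ear ache", "cough"))),
    list(id = "testing", name = "Testing", topic = "interventions",
         keywords = list(en = c("test", "pcr", "swab")))
  ))
}

# Independent oracle: iterative neighbor averaging with seed rows clamped.
# Deliberately a different algorithm family from measure propagation.
clamped_label_propagation <- function(graph, seeds, max_iter = 1000, tol = 1e-12) {
  W <- as.matrix(graph$W)
  n <- nrow(W)
  K <- ncol(seeds)
  P <- matrix(1 / K, n, K, dimnames = list(graph$node_ids, colnames(seeds)))
  seeded <- match(rownames(seeds), graph$node_ids)
  P[seeded, ] <- seeds
  deg <- rowSums(W)
  isolated <- deg == 0
  denom <- ifelse(isolated, 1, deg)
  for (it in seq_len(max_iter)) {
    Pn <- (W %*% P) / denom
    Pn[isolated, ] <- 1 / K
    Pn[seeded, ] <- seeds
    if (max(abs(Pn - P)) < tol) {
      P <- Pn
      break
    }
    P <- Pn
  }
  dimnames(P) <- list(graph$node_ids, colnames(seeds))
  P
}

# Random two-cluster weighted graph with point-mass seeds per cluster.
two_cluster_instance <- function(n = 40, p_in = 0.3, p_out = 0.03,
                                 n_seeds = 2) {
  stopifnot(n %% 2 == 0)
  ids <- sprintf("n%03d", seq_len(n))
  half <- n / 2
  cluster <- rep(c(1, 2), each = half)
  edges_i <- c(); edges_j <- c(); edges_w <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      same <- cluster[i] == cluster[j]
      if (stats::runif(1) < (if (same) p_in else p_out)) {
        edges_i <- c(edges_i, ids[i]); edges_j <- c(edges_j, ids[j])
        edges_w <- c(edges_w, if (same) stats::runif(1, 0.6, 1.0)
                     else stats::runif(1, 0.02, 0.1))
      }
    }
  }
  # spanning chain inside each cluster so clusters are connected
  for (cl in 1:2) {
    members <- which(cluster == cl)
    for (m in seq_len(length(members) - 1)) {
      edges_i <- c(edges_i, ids[members[m]])
      edges_j <- c(edges_j, ids[members[m + 1]])
      edges_w <- c(edges_w, stats::runif(1, 0.6, 1.0))
    }
  }
  graph <- graph_from_edges(ids, data.frame(node_i = edges_i, node_j = edges_j,
                                            weight = edges_w))
  seed_ids <- c(sample(ids[cluster == 1], n_seeds),
                sample(ids[cluster == 2], n_seeds))
  seeds <- matrix(0, length(seed_ids), 2,
                  dimnames = list(seed_ids, c("c1", "c2")))
  seeds[seq_len(n_seeds), "c1"] <- 1
  seeds[seq(n_seeds + 1, 2 * n_seeds), "c2"] <- 1
  list(graph = graph, seeds = seeds, truth = stats::setNames(cluster, ids))
}
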