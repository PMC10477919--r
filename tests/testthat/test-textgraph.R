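test_that("tokenizer strips urls and mentions, keeps hashtag words, sets the content flag", {
  # hashtag/mention-only posts keep the bare hashtag word but carry no content
  tk <- tokenize("#COVID @user")
  expect_equal(tk$tokens, "covid")
  expect_false(tk$content_flag)

  expect_equal(tokenize(""), list(tokens = character(0), content_flag = FALSE))

  tk <- tokenize("Patient zero was identified in Wuhan https://t.co/x")
  expect_equal(tk$tokens, c("patient", "zero", "was", "identified", "in", "wuhan"))
  expect_true(tk$content_flag)

  # hashtag inside a sentence does not spoil the flag; punctuation split
  tk <- tokenize("Vaccines work! #vaccine @who www.who.int")
  expect_equal(tk$tokens, c("vaccines", "work", "vaccine"))
  expect_true(tk$content_flag)
})

test_that("keyword matching counts contiguous phrase occurrences per category", {
  tax <- fruit_taxonomy()
  tk <- tokenize("apple and banana smoothie")
  expect_equal(match_keywords(tk$tokens, tax), c(fruit = 2L))

  tax2 <- taxonomy(list(list(id = "origin", name = "Origin", topic = "cause",
                             keywords = list(en = "patient zero"))))
  expect_equal(match_keywords(tokenize("patient zero identified")$tokens, tax2),
               c(origin = 1L))
  # broken phrase does not match; non-overlapping repeats count separately
  expect_equal(length(match_keywords(tokenize("patient was zero")$tokens, tax2)), 0)
  expect_equal(match_keywords(tokenize("patient zero patient zero")$tokens, tax2),
               c(origin = 2L))
  expect_equal(length(match_keywords(tokenize("kiwi pear melon")$tokens,
                                     fruit_taxonomy())), 0)
})

test_that("identical texts get a weight-1 edge; disjoint vocabularies get none", {
  tok <- tokenize_posts(make_posts(c("vaccine works well", "vaccine works well")))
  g <- build_graph(tok, k_neighbors = 5, edge_floor = 0)
  expect_equal(as.numeric(g$W[1, 2]), 1.0, tolerance = 1e-12)
  expect_equal(as.numeric(g$W[1, 1]), 0)

  tok2 <- tokenize_posts(make_posts(c("alpha beta alpha beta", "gamma delta gamma delta")))
  g2 <- build_graph(tok2, min_df = 1, edge_floor = 0)
  expect_equal(Matrix::nnzero(g2$W), 0)
})

test_that("edge weights equal a hand-computed dense tf-idf cosine oracle", {
  texts <- c("apple banana apple", "banana cherry", "apple cherry cherry",
             "banana banana apple")
  tok <- tokenize_posts(make_posts(texts))
  g <- build_graph(tok, k_neighbors = 3, min_df = 1, max_df_ratio = 1,
                   edge_floor = 0)
  # independent dense computation with explicit loops
  vocab <- c("apple", "banana", "cherry")
  tf <- rbind(c(2, 1, 0), c(0, 1, 1), c(1, 0, 2), c(1, 2, 0))
  df <- c(3, 3, 2)
  idf <- log((1 + 4) / (1 + df)) + 1
  X <- tf * rep(idf, each = 4)
  cos <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    cos[i, j] <- sum(X[i, ] * X[j, ]) /
      (sqrt(sum(X[i, ]^2)) * sqrt(sum(X[j, ]^2)))
  }
  diag(cos) <- 0
  expect_equal(as.matrix(g$W), cos, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("graphs are symmetric, nonnegative, zero-diagonal, in [0,1], and sparsified weights are a subset of dense ones", {
  set.seed(7)
  vocab <- c(sprintf("w%02d", 1:12))
  texts <- vapply(1:15, function(i) paste(sample(vocab, 8, TRUE), collapse = " "),
                  character(1))
  tok <- tokenize_posts(make_posts(texts))
  dense <- build_graph(tok, k_neighbors = 14, min_df = 1, max_df_ratio = 1,
                       edge_floor = 0)
  sparse <- build_graph(tok, k_neighbors = 3, min_df = 1, max_df_ratio = 1,
                        edge_floor = 0.05)
  W <- as.matrix(sparse$W)
  expect_equal(W, t(W))
  expect_true(all(W >= 0 & W <= 1))
  expect_true(all(diag(W) == 0))
  D <- as.matrix(dense$W)
  retained <- W > 0
  expect_equal(W[retained], D[retained], tolerance = 1e-12)
  expect_true(all(W[retained] >= 0.05))
})

test_that("permuting post order yields an isomorphic graph with identical weights", {
  set.seed(11)
  texts <- c("apple banana apple", "banana cherry plum", "apple cherry cherry",
             "banana banana apple plum", "plum cherry apple")
  posts <- make_posts(texts)
  tok1 <- tokenize_posts(posts)
  perm <- c(4, 2, 5, 1, 3)
  tok2 <- tokenize_posts(posts[perm, ])
  g1 <- build_graph(tok1, k_neighbors = 2, min_df = 1, edge_floor = 0)
  g2 <- build_graph(tok2, k_neighbors = 2, min_df = 1, edge_floor = 0)
  W1 <- as.matrix(g1$W); dimnames(W1) <- list(g1$node_ids, g1$node_ids)
  W2 <- as.matrix(g2$W); dimnames(W2) <- list(g2$node_ids, g2$node_ids)
  ids <- sort(g1$node_ids)
  expect_equal(W1[ids, ids], W2[ids, ids], tolerance = 1e-12)
})

test_that("graphs survive an edge-list CSV round-trip and invalid params error", {
  tok <- tokenize_posts(make_posts(c("apple banana", "banana cherry", "apple cherry")))
  g <- build_graph(tok, min_df = 1, edge_floor = 0)
  f <- withr::local_tempfile(fileext = ".csv")
  write_graph_edges(g, f)
  g2 <- read_graph_edges(f, node_ids = g$node_ids)
  expect_equal(as.matrix(g2$W), as.matrix(g$W), tolerance = 1e-12)
  expect_error(build_graph(tok, k_neighbors = 0), "k_neighbors")
  expect_error(build_graph(tokenize_posts(make_posts("#only @tags"))),
               "at least 2 content posts")
})
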