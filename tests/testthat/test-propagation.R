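test_that("seed measures normalize hit counts into distributions", {
  cats <- c("fruit", "veg")
  R <- seed_measures(list(p1 = c(fruit = 3)), cats)
  expect_equal(R["p1", ], c(fruit = 1, veg = 0))
  R2 <- seed_measures(list(p1 = c(fruit = 1, veg = 1), p2 = numeric(0)), cats)
  expect_equal(R2["p1", ], c(fruit = 0.5, veg = 0.5))
  expect_false("p2" %in% rownames(R2))     # zero hits -> unlabeled
  expect_error(seed_measures(list(p1 = c(meat = 1)), cats), "unknown category")
})

test_that("a single seed dominates its neighbor on a 2-node graph", {
  g <- graph_from_edges(c("A", "B"),
                        data.frame(node_i = "A", node_j = "B", weight = 1))
  seeds <- matrix(c(1, 0), 1, 2, dimnames = list("A", c("c1", "c2")))
  m <- propagate(g, seeds)
  expect_equal(unname(which.max(m$p["B", ])), 1)
  expect_true(m$converged)
})

test_that("a node equidistant from two opposite seeds stays balanced", {
  g <- graph_from_edges(c("A", "B", "C"),
                        data.frame(node_i = c("A", "B"), node_j = c("B", "C"),
                                   weight = c(1, 1)))
  seeds <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
                  dimnames = list(c("A", "C"), c("c1", "c2")))
  m <- propagate(g, seeds, tol = 1e-8)
  expect_equal(m$p["B", "c1"], m$p["B", "c2"], tolerance = 1e-6)
})

test_that("the objective is non-increasing at every alternating half-step and measures stay normalized", {
  set.seed(101)
  for (rep in 1:5) {
    inst <- two_cluster_instance(n = 24)
    m <- propagate(inst$graph, inst$seeds, tol = 1e-6)
    expect_true(all(diff(m$objective) <= 1e-8))
    expect_true(all(is.finite(m$p)) && all(m$p >= 0))
    expect_equal(unname(rowSums(m$p)), rep(1, nrow(m$p)), tolerance = 1e-9)
  }
})

test_that("propagation is deterministic for identical inputs", {
  set.seed(5)
  inst <- two_cluster_instance(n = 20)
  m1 <- propagate(inst$graph, inst$seeds)
  m2 <- propagate(inst$graph, inst$seeds)
  expect_identical(m1$p, m2$p)
  expect_identical(m1$iterations, m2$iterations)
})

test_that("a point-mass seed keeps its own category with nu = 0 and large mu", {
  set.seed(9)
  inst <- two_cluster_instance(n = 20)
  m <- propagate(inst$graph, inst$seeds, mu = 50, nu = 0)
  for (sid in rownames(inst$seeds)) {
    expect_equal(unname(which.max(m$p[sid, ])),
                 unname(which.max(inst$seeds[sid, ])))
  }
})

test_that("argmax labels match the clamped label-propagation oracle on two-cluster graphs", {
  set.seed(2024)
  for (rep in 1:10) {
    inst <- two_cluster_instance(n = 30)
    m <- propagate(inst$graph, inst$seeds, tol = 1e-7)
    oracle <- clamped_label_propagation(inst$graph, inst$seeds)
    got <- apply(m$p, 1, which.max)
    want <- apply(oracle, 1, which.max)
    expect_equal(got, want)
  }
})

test_that("empty seeds yield uniform measures with a warning; missing seed nodes error", {
  g <- graph_from_edges(c("A", "B"),
                        data.frame(node_i = "A", node_j = "B", weight = 1))
  empty <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("c1", "c2")))
  expect_warning(m <- propagate(g, empty), "empty seed set")
  expect_true(all(m$p == 0.5))
  bad <- matrix(1, 1, 2, dimnames = list("Z", c("c1", "c2")))
  expect_error(suppressWarnings(propagate(g, bad)), "missing from graph")
})

test_that("label assignment applies the noise rule, argmax, and lexicographic ties", {
  p <- rbind(a = c(x = 0.6, y = 0.4),
             b = c(x = 1 / 2, y = 1 / 2),
             c = c(x = 0.9, y = 0.1),
             d = c(x = 0.5, y = 0.5))
  flags <- c(a = TRUE, b = TRUE, c = FALSE, d = TRUE)
  out <- assign_labels(p, flags, epsilon_noise = 0.01)
  expect_equal(out$label, c("x", NOISE_LABEL, NOISE_LABEL, NOISE_LABEL))
  # exact tie above the noise floor breaks to the lexicographically first id
  p2 <- rbind(e = c(y = 0.4, b = 0.4, a = 0.2))
  out2 <- assign_labels(p2, c(e = TRUE), epsilon_noise = 0.01)
  expect_equal(out2$label, "b")
})

test_that("a fully separable corpus is classified perfectly; hashtag-only corpora are all noise", {
  texts <- c(rep("apple banana grapes apple", 3), rep("test pcr swab test", 3),
             rep("sore throat ear ache cough", 3))
  tax <- taxonomy(list(
    list(id = "fruit", name = "F", topic = "information",
         keywords = list(en = c("apple", "banana", "grapes"))),
    list(id = "testing", name = "T", topic = "interventions",
         keywords = list(en = c("test", "pcr", "swab"))),
    list(id = "symptoms", name = "S", topic = "illness",
         keywords = list(en = c("sore throat", "ear ache", "cough")))
  ))
  posts <- make_posts(texts)
  res <- classify_corpus(posts, tax)
  expect_equal(res$categorized_fraction, 1.0)
  expect_equal(res$assignments$label,
               rep(c("fruit", "testing", "symptoms"), each = 3))

  hashtag_posts <- make_posts(c("#covid #vaccine", "@user #news", "#a #b"))
  res2 <- classify_corpus(hashtag_posts, tax)
  expect_equal(res2$categorized_fraction, 0)
  expect_true(all(res2$assignments$label == NOISE_LABEL))
})
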