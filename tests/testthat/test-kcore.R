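toy_graph <- data.frame(from = c("s", "s", "a", "b"),
                        to = c("a", "b", "b", "c"),
                        stringsAsFactors = FALSE)

test_that("the toy network prunes to the hand-computed cores", {
  expect_equal(modified_kcore(toy_graph, "s", k = 1), c("a", "b"))
  expect_equal(modified_kcore(toy_graph, "s", k = 2), c("a", "b"))
  expect_equal(modified_kcore(toy_graph, "s", k = 3), character())
  sc <- kcore_scores(toy_graph, "s", universe = c("a", "b", "c", "d"))
  expect_equal(sc, c(a = 2L, b = 2L, c = 0L, d = -1L))
})

test_that("the 1-core is exactly the non-seed neighborhood of the seeds", {
  set.seed(61)
  for (i in 1:20) {
    g <- random_graph_edges(10, 0.3)
    if (nrow(g) == 0) next
    seeds <- sample(unique(c(g$from, g$to)), 2)
    adj <- sh3map:::.adjacency(g)
    expected <- sort(setdiff(unique(unlist(adj[intersect(seeds,
                                                         names(adj))])),
                             seeds))
    expect_equal(modified_kcore(g, seeds, k = 1), expected)
  }
})

test_that("nodes with no seed connection are never members", {
  g <- rbind(toy_graph, data.frame(from = "x", to = "y"))
  for (k in 1:3) {
    expect_false(any(c("x", "y") %in% modified_kcore(g, "s", k)))
  }
})

test_that("a clique on the seeds gives score equal to the seed count", {
  nodes <- c(paste0("s", 1:5), "v")
  edges <- as.data.frame(t(utils::combn(nodes, 2)), stringsAsFactors = FALSE)
  sc <- kcore_scores(edges, paste0("s", 1:5), universe = "v")
  expect_equal(unname(sc["v"]), 5L)
})

test_that("the pruning fixpoint equals the exhaustive-subset oracle", {
  set.seed(67)
  for (i in 1:25) {
    n <- sample(6:12, 1)
    g <- random_graph_edges(n, runif(1, 0.15, 0.5))
    if (nrow(g) == 0) next
    nodes <- unique(c(g$from, g$to))
    seeds <- sample(nodes, min(2, length(nodes)))
    for (k in 1:3) {
      expect_equal(modified_kcore(g, seeds, k), kcore_oracle(g, seeds, k))
    }
  }
})

test_that("cores are nested and scores monotone under edge addition", {
  set.seed(71)
  for (i in 1:100) {
    g <- random_graph_edges(12, runif(1, 0.1, 0.4))
    if (nrow(g) < 2) next
    nodes <- unique(c(g$from, g$to))
    seeds <- sample(nodes, 2)
    prev <- NULL
    for (k in 1:4) {
      cur <- modified_kcore(g, seeds, k)
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
  # adding an edge never decreases any score
  set.seed(73)
  for (i in 1:10) {
    g <- random_graph_edges(10, 0.25)
    if (nrow(g) < 2) next
    nodes <- unique(c(g$from, g$to))
    seeds <- sample(nodes, 2)
    uni <- paste0("v", 1:10)
    s1 <- kcore_scores(g, seeds, universe = uni)
    extra <- setdiff(t(utils::combn(paste0("v", 1:10), 2)), NULL)
    pair <- sample(paste0("v", 1:10), 2)
    g2 <- rbind(g, data.frame(from = pair[1], to = pair[2]))
    s2 <- kcore_scores(g2, seeds, universe = uni)
    expect_true(all(s2 >= s1))
  }
})

test_that("seeds absent from the network are ignored with a warning", {
  expect_warning(modified_kcore(toy_graph, c("s", "ghost"), 1), "absent")
})

test_that("cross-validation separates a planted module from negatives", {
  w <- get_world()
  net <- suppressMessages(filter_candidates(w$candidates, w$evidence))
  g <- data.frame(from = sub("#.*", "", net$edges$bait_id),
                  to = net$edges$prey_id)
  cv <- cross_validate(g, w$seeds, w$negatives, folds = 10, seed = 1)
  expect_gte(cv$mean_auc, 0.9)
  expect_length(cv$fold_auc, 10)
  # ROC curves span the unit square corners
  for (roc in cv$roc) {
    expect_equal(roc$tpr[nrow(roc)], 1)
    expect_equal(roc$fpr[nrow(roc)], 1)
  }
})

test_that("shuffled labels yield chance-level cross-validated AUC", {
  w <- get_world()
  net <- suppressMessages(filter_candidates(w$candidates, w$evidence))
  g <- data.frame(from = sub("#.*", "", net$edges$bait_id),
                  to = net$edges$prey_id)
  universe <- w$universe_genes
  aucs <- sh3map:::with_seed(101, {
    vapply(1:5, function(i) {
      lab <- sample(universe, 60)
      cross_validate(g, lab[1:30], lab[31:60], folds = 10,
                     seed = i)$mean_auc
    }, numeric(1))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("all-tied scores give AUC one half", {
  # held-out positives and negatives all absent from the graph: score -1
  g <- data.frame(from = "a", to = "b")
  cv <- suppressWarnings(
    cross_validate(g, c("p1", "p2"), c("n1", "n2"), folds = 2, seed = 1))
  expect_equal(cv$mean_auc, 0.5)
})

test_that("the rank AUC agrees with an independent ROC implementation", {
  library(pROC)
  set.seed(79)
  pos <- sample(-1:5, 30, replace = TRUE)
  neg <- sample(-1:3, 40, replace = TRUE)
  mine <- sh3map:::.auc(pos, neg)
  ref <- as.numeric(pROC::auc(response = c(rep(1, 30), rep(0, 40)),
                              predictor = c(pos, neg), quiet = TRUE,
                              direction = "<"))
  expect_equal(mine, ref)
})

test_that("negatives overlapping seeds are rejected", {
  expect_error(cross_validate(toy_graph, c("s", "a"), c("a", "x"),
                              folds = 2), "disjoint")
})

test_that("novel predictions recover held-back module members, ranked", {
  w <- get_world()
  net <- suppressMessages(filter_candidates(w$candidates, w$evidence))
  g <- data.frame(from = sub("#.*", "", net$edges$bait_id),
                  to = net$edges$prey_id)
  preds <- predict_novel(g, w$seeds, k = 3)
  expect_false(any(preds$protein_id %in% w$seeds))
  expect_true(all(w$novel_module_proteins %in% preds$protein_id))
  expect_true(all(diff(preds$score) <= 0))
  # k beyond the maximum degree leaves nothing
  expect_equal(nrow(predict_novel(toy_graph, "s", k = 10)), 0)
})
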