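ev_row <- function(bait, prey, score = NA, lit = FALSE, tf = FALSE) {
  data.frame(bait_id = bait, prey_id = prey, pwm_score = score,
             literature_functional = lit, prey_is_TF = tf,
             stringsAsFactors = FALSE)
}

test_that("evidence rules keep and classify candidates correctly", {
  cands <- data.frame(
    bait_id = c("D1#1", "D1#1", "D1#1", "D2#1"),
    prey_id = c("p_multi", "p_motif", "p_weak", "p_lit"),
    colony_count = c(2, 1, 1, 1), stringsAsFactors = FALSE)
  ev <- rbind(ev_row("D1#1", "p_multi"),
              ev_row("D1#1", "p_motif", score = 1500),
              ev_row("D1#1", "p_weak", score = 900),
              ev_row("D2#1", "p_lit", lit = TRUE))
  net <- suppressMessages(filter_candidates(cands, ev))
  cls <- setNames(net$edges$evidence_class, net$edges$prey_id)
  expect_equal(unname(cls["p_multi"]), "multi_colony")
  expect_equal(unname(cls["p_motif"]), "motif")
  expect_equal(unname(cls["p_lit"]), "literature")
  expect_false("p_weak" %in% net$edges$prey_id)
  expect_equal(net$n_dropped, 1)
  # evidence classes partition the network
  expect_equal(sum(net$counts), nrow(net$edges))
})

test_that("colony counts are summed across screens before filtering", {
  cands <- data.frame(bait_id = c("D1#1", "D1#1"), prey_id = c("p", "p"),
                      colony_count = c(1, 1), stringsAsFactors = FALSE)
  net <- filter_candidates(cands, ev_row("D1#1", "p"))
  expect_equal(net$edges$colony_count, 2)
  expect_equal(net$edges$evidence_class, "multi_colony")
})

test_that("promiscuous TF preys are pruned, modest ones retained", {
  baits <- paste0("D", 1:6, "#1")
  cands <- data.frame(
    bait_id = c(baits, "D1#1", "D2#1"),
    prey_id = c(rep("tf_bad", 6), rep("tf_ok", 2)),
    colony_count = 2, stringsAsFactors = FALSE)
  ev <- rbind(do.call(rbind, lapply(baits, function(b)
                ev_row(b, "tf_bad", tf = TRUE))),
              ev_row("D1#1", "tf_ok", tf = TRUE),
              ev_row("D2#1", "tf_ok", tf = TRUE))
  net <- filter_candidates(cands, ev, tf_degree_max = 5)
  expect_false("tf_bad" %in% net$edges$prey_id)
  expect_equal(sum(net$edges$prey_id == "tf_ok"), 2)
  expect_equal(net$tf_removed, "tf_bad")
  # counts before TF removal retain the pruned edges
  expect_equal(sum(net$counts_before_tf), 8)
})

test_that("only SH3-domain baits qualify for the motif evidence class", {
  cands <- data.frame(bait_id = c("hub", "D1#1"), bait_type = c("full_length",
                      "sh3_domain"), prey_id = c("p1", "p2"),
                      colony_count = 1, stringsAsFactors = FALSE)
  ev <- rbind(ev_row("hub", "p1", score = 5000),
              ev_row("D1#1", "p2", score = 5000))
  net <- suppressMessages(filter_candidates(cands, ev))
  expect_equal(net$edges$prey_id, "p2")
})

test_that("filtering is idempotent", {
  w <- get_world()
  net <- suppressMessages(filter_candidates(w$candidates, w$evidence))
  again <- suppressMessages(filter_candidates(
    net$edges[, c("bait_id", "bait_type", "prey_id", "colony_count")],
    w$evidence))
  expect_equal(again$edges[, c("bait_id", "prey_id", "evidence_class")],
               net$edges[, c("bait_id", "prey_id", "evidence_class")])
})

test_that("the filtered synthetic screen is precise and sensitive", {
  w <- get_world()
  net <- suppressMessages(filter_candidates(w$candidates, w$evidence))
  kept <- paste(net$edges$bait_id, net$edges$prey_id)
  truth <- paste(w$true_edges$bait_id, w$true_edges$prey_id)
  expect_gte(mean(kept %in% truth), 0.95)   # precision
  expect_gte(mean(truth %in% kept), 0.95)   # planted-edge recovery
})

test_that("rank enrichment is maximal when all preys rank first", {
  ranks <- list(`D1#1` = data.frame(protein_id = paste0("p", 1:50),
                                    score = 50:1, rank = 1:50))
  edges <- data.frame(bait_id = "D1#1", bait_type = "sh3_domain",
                      prey_id = "p1", colony_count = 2,
                      evidence_class = "multi_colony",
                      stringsAsFactors = FALSE)
  net <- structure(list(edges = edges), class = "sh3_network")
  enr <- phage_overlap_enrichment(net, ranks, n_random = 1000, seed = 1)
  expect_equal(enr$auc, 1)
  expect_equal(enr$curve$cumulative[1], 1)
  # with a single edge the null can tie the observed AUC at rate 1/P
  expect_lt(enr$p_value, 0.05)
})

test_that("uniform random ranks give a null AUC near one half", {
  set.seed(31)
  P <- 2000
  ranks <- list(`D1#1` = data.frame(protein_id = paste0("p", 1:P),
                                    score = P:1, rank = 1:P))
  preys <- paste0("p", sample.int(P, 1000, replace = TRUE))
  edges <- data.frame(bait_id = "D1#1", bait_type = "sh3_domain",
                      prey_id = preys, colony_count = 2,
                      evidence_class = "multi_colony",
                      stringsAsFactors = FALSE)
  net <- structure(list(edges = edges), class = "sh3_network")
  enr <- phage_overlap_enrichment(net, ranks, n_random = 2000, seed = 2)
  expect_lt(abs(enr$auc - 0.5), 0.02)
  expect_gt(enr$p_value, 0.01)
})

test_that("a domain with all preys in the genomic top strata is significant", {
  set.seed(37)
  P <- 10000
  ranks <- list(`D1#1` = data.frame(protein_id = paste0("p", 1:P),
                                    score = P:1, rank = 1:P))
  edges <- data.frame(bait_id = "D1#1", bait_type = "sh3_domain",
                      prey_id = paste0("p", sample.int(100, 12)),
                      colony_count = 2, evidence_class = "multi_colony",
                      stringsAsFactors = FALSE)
  net <- structure(list(edges = edges), class = "sh3_network")
  enr <- phage_overlap_enrichment(net, ranks, n_random = 10000, seed = 3)
  expect_lt(enr$p_value, 0.001)
})

test_that("motif-class edges are excluded from the enrichment statistic", {
  ranks <- list(`D1#1` = data.frame(protein_id = paste0("p", 1:10),
                                    score = 10:1, rank = 1:10))
  edges <- data.frame(bait_id = "D1#1", bait_type = "sh3_domain",
                      prey_id = c("p1", "p2"), colony_count = c(2, 1),
                      evidence_class = c("multi_colony", "motif"),
                      stringsAsFactors = FALSE)
  net <- structure(list(edges = edges), class = "sh3_network")
  enr <- phage_overlap_enrichment(net, ranks, n_random = 100, seed = 1)
  expect_equal(enr$n_edges, 1)
  # nothing eligible -> error
  edges$evidence_class <- "motif"
  net2 <- structure(list(edges = edges), class = "sh3_network")
  expect_error(phage_overlap_enrichment(net2, ranks, n_random = 100),
               "eligible")
})
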