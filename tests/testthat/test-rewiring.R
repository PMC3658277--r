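# a controlled two-species micro-world for scenario classification
micro_case <- function(scenario) {
  pwm_s <- point_pwm(c("R", "W", "P", "F", "P"), domain_id = "DOM#1")
  motif <- "RWPFP"
  set.seed(55)
  # background avoids the motif residues so conservation calls are unambiguous
  bg <- paste(sample(c("A", "D", "E", "G", "H", "I", "L", "S", "T", "V"),
                     120, replace = TRUE), collapse = "")
  target_a <- paste0(substr(bg, 1, 40), motif, substr(bg, 46, 120))
  keep_motif <- scenario %in% c("i", "conserved_both")
  target_b <- if (keep_motif) target_a else
    paste0(substr(bg, 1, 40), "GGGGG", substr(bg, 46, 120))
  keep_spec <- scenario %in% c("ii", "conserved_both")
  pwm_t <- if (keep_spec) {
    new_pwm(pwm_s$prob, domain_id = "yDOM#1")
  } else point_pwm(c("E", "E", "Q", "Q", "N"), domain_id = "yDOM#1")
  list(
    interaction = list(domain_id = "DOM#1", target_id = "tgt"),
    pwms = list(source = list(`DOM#1` = pwm_s),
                target = list(`yDOM#1` = pwm_t)),
    omap = ortholog_map(c("DOM", "tgt"), c("yDOM", "ytgt")),
    sequences = list(source = c(tgt = target_a), target = c(ytgt = target_b)))
}

test_that("motif matching finds verbatim and absent motifs", {
  expect_equal(best_motif_match("RPLPP", paste0("AAAA", "RPLPP", "AA")),
               list(identity = 1, start = 5))
  expect_equal(best_motif_match("PPPPP", "AAAAAAAA")$identity, 0)
})

test_that("half-conserved motifs sit exactly at the decision boundary", {
  # 5 of 10 residues identical at the best offset
  motif <- "RPLPPWFKDE"
  seq <- paste0("GGGG", "RPLPPAAAAA", "GGGG")
  bm <- best_motif_match(motif, seq)
  expect_equal(bm$identity, 0.5)
  expect_equal(bm$start, 5)
})

test_that("an ortholog shorter than the motif counts overhang as mismatch", {
  bm <- best_motif_match("AAAAAA", "AAA")
  expect_equal(bm$identity, 0.5)  # best 3 of 6
})

test_that("ties in motif matching prefer the smallest start", {
  bm <- best_motif_match("AA", "AACAA")
  expect_equal(bm$start, 1)
})

test_that("ungapped identity uses the shorter sequence as the probe", {
  expect_equal(sequence_identity("PPLP", "GGPPLPGG"), 1)
  expect_equal(sequence_identity("GGPPLPGG", "PPLP"), 1)
})

test_that("each rewiring scenario is recovered from its construction", {
  for (scen in c("i", "ii", "iii", "conserved_both")) {
    mc <- micro_case(scen)
    call <- classify_rewiring(mc$interaction, mc$pwms, mc$omap, mc$sequences)
    expect_equal(call$scenario, scen)
    # scenario/flag consistency invariant
    if (call$scenario == "i") {
      expect_true(call$motif_conserved && !call$specificity_conserved)
    } else if (call$scenario == "ii") {
      expect_true(call$specificity_conserved && !call$motif_conserved)
    } else if (call$scenario == "iii") {
      expect_false(call$specificity_conserved || call$motif_conserved)
    }
  }
})

test_that("interactions without profiles or motifs are unmappable", {
  mc <- micro_case("conserved_both")
  # no PWM for the source domain
  mc2 <- mc; mc2$pwms$source <- list()
  expect_equal(classify_rewiring(mc2$interaction, mc2$pwms, mc2$omap,
                                 mc2$sequences)$scenario, "unmappable")
  # no motif reaches the threshold
  mc3 <- mc; mc3$sequences$source[["tgt"]] <- random_protein(100)
  set.seed(77)
  expect_equal(classify_rewiring(mc3$interaction, mc3$pwms, mc3$omap,
                                 mc3$sequences)$scenario, "unmappable")
  # no ortholog sequence for the target
  mc4 <- mc; mc4$sequences$target <- c(other = "AAAA")
  expect_equal(classify_rewiring(mc4$interaction, mc4$pwms, mc4$omap,
                                 mc4$sequences)$scenario, "unmappable")
})

test_that("a domain whose ortholog lacks an SH3 domain is not conserved", {
  mc <- micro_case("conserved_both")
  mc$pwms$target <- list()  # ortholog protein has no profiled domain
  call <- classify_rewiring(mc$interaction, mc$pwms, mc$omap, mc$sequences,
                            domain_seqs = list(source = list(), target = list()))
  expect_false(call$specificity_conserved)
  expect_equal(call$scenario, "i")
})

test_that("sequence-identity fallback rescues unprofiled ortholog domains", {
  mc <- micro_case("conserved_both")
  mc$pwms$target <- list()
  dseq <- random_protein(60)
  call <- classify_rewiring(
    mc$interaction, mc$pwms, mc$omap, mc$sequences,
    domain_seqs = list(source = list(`DOM#1` = dseq),
                       target = list(`yDOM#1` = dseq)))
  expect_true(call$specificity_conserved)
  expect_equal(call$scenario, "conserved_both")
})

test_that("planted rewiring scenarios are recovered on the synthetic world", {
  w <- get_world()
  calls <- classify_rewiring_table(
    w$rewired, pwms = list(source = w$pwms, target = w$pwms_b),
    omap = w$omap,
    sequences = list(source = w$proteome, target = w$proteome_b),
    T = w$config$T)
  mapped <- calls$scenario != "unmappable"
  acc <- mean(calls$scenario[mapped] == w$rewired$scenario[mapped])
  expect_gte(acc, 0.9)
  # scenario labels partition the mapped calls
  expect_true(all(calls$scenario %in%
                    c("i", "ii", "iii", "conserved_both", "unmappable")))
})

test_that("scenario calls are invariant to interaction ordering", {
  w <- get_world()
  idx <- rev(seq_len(nrow(w$rewired)))
  fwd <- classify_rewiring_table(
    w$rewired, pwms = list(source = w$pwms, target = w$pwms_b),
    omap = w$omap,
    sequences = list(source = w$proteome, target = w$proteome_b))
  rev_ <- classify_rewiring_table(
    w$rewired[idx, ], pwms = list(source = w$pwms, target = w$pwms_b),
    omap = w$omap,
    sequences = list(source = w$proteome, target = w$proteome_b))
  expect_equal(fwd$scenario, rev_$scenario[order(idx)])
})
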