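# Seeded generators for a complete synthetic study: specificity PWMs with
# class structure, phage peptide sets, a proteome with planted ligand
# motifs, a Y2H candidate table with false positives and sticky TF preys, a
# second species with controlled rewiring scenarios, a small ontology with
# planted functional modules, and seed/negative lists for function
# prediction. A single master seed fans out to per-component child seeds so
# every piece is independently reproducible.

CLASS_I_CONSENSUS <- "+XXPXXP"   # + = Arg/Lys
CLASS_II_CONSENSUS <- "PXXPX+"

# residues never used as identity/atypical anchors (reserved for the
# canonical proline / basic anchors)
.NEUTRAL_AA <- setdiff(AA_ALPHABET, c("P", "R", "K"))

#' Generate a synthetic specificity PWM
#'
#' Class I and II PWMs place the canonical anchors of the SH3 ligand
#' consensi (+XXPXXP and PXXPX+, + = Arg/Lys, the basic anchor choosing R or
#' K at random) and \code{sharpness} interpolates each anchor column between
#' uniform (0) and a deterministic point mass (1); non-anchor columns are
#' uniform. Atypical PWMs place three anchors at random positions with
#' random non-P/R/K residues. An optional identity anchor gives each
#' generated domain a private specificity determinant so motifs of same-class
#' domains do not cross-match.
#'
#' @param m number of columns (>= consensus length; extra columns are
#'   uniform padding on the right).
#' @param sharpness anchor concentration in (0, 1]; 0 yields a fully uniform
#'   PWM.
#' @param class_label \code{"I"}, \code{"II"} or \code{"atypical"}.
#' @param seed integer seed.
#' @param domain_id identifier stored in the PWM.
#' @param id_anchor optional list(pos =, res =) of extra anchor columns
#'   (vectors allowed), the domain-private specificity determinants.
#' @return an \code{"sh3_pwm"} with attribute \code{"class"}.
#' @export
gen_pwm <- function(m = 7, sharpness = 0.9,
                    class_label = c("I", "II", "atypical"), seed = 1,
                    domain_id = "synthetic#1", id_anchor = NULL) {
  class_label <- match.arg(class_label)
  stopifnot(m >= 4, sharpness >= 0, sharpness <= 1)
  anchors <- with_seed(seed, {
    basic <- sample(c("R", "K"), 1L)
    a <- switch(class_label,
      I  = list(pos = c(1L, 4L, 7L), res = c(basic, "P", "P")),
      II = list(pos = c(1L, 4L, 6L), res = c("P", "P", basic)),
      atypical = {
        pos <- sort(sample.int(m, 3L))
        list(pos = pos, res = sample(.NEUTRAL_AA, 3L, replace = TRUE))
      })
    a
  })
  need <- max(anchors$pos)
  if (m < need) stop("m must be at least ", need, " for class ", class_label)
  if (!is.null(id_anchor)) {
    keep <- !id_anchor$pos %in% anchors$pos
    anchors$pos <- c(anchors$pos, as.integer(id_anchor$pos[keep]))
    anchors$res <- c(anchors$res, id_anchor$res[keep])
  }
  prob <- matrix(1 / 20, nrow = 20, ncol = m, dimnames = list(AA_ALPHABET, NULL))
  for (i in seq_along(anchors$pos)) {
    col <- rep((1 - sharpness) / 20, 20)
    col[match(anchors$res[i], AA_ALPHABET)] <-
      sharpness + (1 - sharpness) / 20
    prob[, anchors$pos[i]] <- col
  }
  pwm <- new_pwm(prob, domain_id = domain_id, provenance = "synthetic")
  attr(pwm, "class_label") <- class_label
  attr(pwm, "anchors") <- anchors
  pwm
}

#' Sample aligned peptides from a PWM
#'
#' Residues are drawn column-independently from the PWM probabilities; each
#' residue is then replaced by a uniform random residue with probability
#' \code{noise_rate}, emulating phage-display selection noise.
#'
#' @param pwm an \code{"sh3_pwm"}.
#' @param n number of peptides (>= 1).
#' @param noise_rate per-residue mutation probability.
#' @param seed integer seed.
#' @return an [aligned_peptides()] set.
#' @export
sample_peptides <- function(pwm, n, noise_rate = 0, seed = 1) {
  stopifnot(n >= 1)
  peptides <- with_seed(seed, {
    mat <- vapply(seq_len(pwm$m), function(j) {
      sample(AA_ALPHABET, n, replace = TRUE, prob = pwm$prob[, j])
    }, character(n))
    mat <- matrix(mat, nrow = n)
    if (noise_rate > 0) {
      flip <- matrix(stats::runif(n * pwm$m) < noise_rate, nrow = n)
      mat[flip] <- sample(AA_ALPHABET, sum(flip), replace = TRUE)
    }
    apply(mat, 1L, paste, collapse = "")
  })
  aligned_peptides(pwm$domain_id, peptides, pwm$group_label)
}

# zero-truncated Poisson sampler
.rztpois <- function(n, lambda) {
  stats::qpois(stats::runif(n, stats::dpois(0, lambda), 1), lambda)
}

# random protein sequence
.rand_seq <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# sample a peptide from the PWM that scores >= T (falls back to consensus)
.plant_peptide <- function(pwm, T, tries = 50) {
  for (i in seq_len(tries)) {
    pep <- paste(vapply(seq_len(pwm$m), function(j) {
      sample(AA_ALPHABET, 1L, prob = pwm$prob[, j])
    }, character(1)), collapse = "")
    if (score_peptide(pwm, pep) >= T) return(pep)
  }
  paste(AA_ALPHABET[apply(pwm$prob, 2, which.max)], collapse = "")
}

#' Default configuration of the synthetic world
#'
#' Values emulate the scale and noise structure of an SH3 interactome study
#' at desk size: ~10 domains with ~40 phage peptides each (the study scale
#' was ~37 per domain), log-normal protein lengths with median 400, a dense
#' functional module plus background edges, zero-truncated Poisson colony
#' counts, single-colony false positives, a couple of promiscuous
#' activation-domain TF preys, 90% ortholog coverage and a fixed rewiring
#' scenario mixture.
#'
#' @param ... overrides of the default entries.
#' @return named list of configuration values.
#' @export
world_config <- function(...) {
  cfg <- list(
    n_domains = 10L,
    class_probs = c(I = 0.4, II = 0.4, atypical = 0.2),
    sharpness = 0.9,
    pwm_m = 10L,
    peptides_per_domain = 40L,
    peptide_noise = 0.1,
    n_proteins = 150L,
    protein_meanlog = log(400),
    protein_sdlog = 0.4,
    n_module_baits = 6L,
    n_module_preys = 20L,
    module_edges_per_prey = 3L,
    n_background_edges = 30L,
    n_false_positives = 40L,
    colony_lambda = 2.5,
    lit_rate = 0.5,
    n_sticky_tfs = 2L,
    tf_degree = 8L,
    ortholog_coverage = 0.9,
    n_rewired = 40L,
    scenario_mix = c(i = 0.15, ii = 0.30, iii = 0.40, conserved_both = 0.15),
    background_mut_rate = 0.05,
    annotation_rate = 0.5,
    n_negatives = 25L,
    T = 1000
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (abs(sum(cfg$scenario_mix) - 1) > 1e-9) {
    stop("scenario_mix fractions must sum to 1")
  }
  if (abs(sum(cfg$class_probs) - 1) > 1e-9) {
    stop("class_probs must sum to 1")
  }
  cfg
}

# largest-remainder apportionment of n into round(frac * n) integer counts
.apportion <- function(n, frac) {
  raw <- frac * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(frac))
}

#' Generate a complete synthetic study world
#'
#' Produces every input the analysis pipeline consumes, together with the
#' ground truth needed to verify recovery: specificity PWMs and sampled
#' phage peptide sets, a proteome with a registry of planted ligand motifs,
#' a true interaction network (a dense functional module plus background
#' edges), a raw Y2H candidate table with colony counts, false positives and
#' sticky TF preys, per-pair evidence annotations, a second species related
#' by a seeded ortholog map in which a subset of interactions is rewired
#' under controlled scenarios, a small ontology with module-term
#' annotations, and seed/negative lists for k-core function prediction.
#' Identical seeds give byte-identical worlds.
#'
#' @param config a [world_config()] list.
#' @param seed master integer seed.
#' @return object of class \code{"sh3_world"}; see the elements described in
#'   Details of the package vignette.
#' @export
gen_world <- function(config = world_config(), seed = 1) {
  cfg <- config
  T <- cfg$T

  ## 1. domains and PWMs ----------------------------------------------------
  prot_ids <- sprintf("SH3P%02d", seq_len(cfg$n_domains))
  domain_ids <- paste0(prot_ids, "#1")
  classes <- with_seed(child_seed(seed, 1), {
    sample(names(cfg$class_probs), cfg$n_domains, replace = TRUE,
           prob = cfg$class_probs)
  })
  id_res <- with_seed(child_seed(seed, 2), {
    cbind(sample(.NEUTRAL_AA, cfg$n_domains,
                 replace = cfg$n_domains > length(.NEUTRAL_AA)),
          sample(.NEUTRAL_AA, cfg$n_domains, replace = TRUE))
  })
  pwms <- lapply(seq_len(cfg$n_domains), function(i) {
    ia <- if (classes[i] == "atypical") NULL else
      list(pos = c(2L, 5L), res = id_res[i, ])
    gen_pwm(cfg$pwm_m, cfg$sharpness, classes[i],
            seed = child_seed(seed, 100 + i), domain_id = domain_ids[i],
            id_anchor = ia)
  })
  names(pwms) <- domain_ids

  ## 2. phage peptide sets --------------------------------------------------
  peptide_sets <- lapply(seq_len(cfg$n_domains), function(i) {
    sample_peptides(pwms[[i]], cfg$peptides_per_domain, cfg$peptide_noise,
                    seed = child_seed(seed, 200 + i))
  })
  names(peptide_sets) <- domain_ids

  ## 3. proteome ------------------------------------------------------------
  prey_ids <- sprintf("W%03d", seq_len(cfg$n_proteins))
  tf_ids <- if (cfg$n_sticky_tfs > 0) sprintf("TF%02d", seq_len(cfg$n_sticky_tfs))
            else character()
  proteome <- with_seed(child_seed(seed, 3), {
    lens <- pmax(60L, round(stats::rlnorm(cfg$n_proteins + length(tf_ids),
                                          cfg$protein_meanlog,
                                          cfg$protein_sdlog)))
    stats::setNames(vapply(lens, .rand_seq, character(1)),
                    c(prey_ids, tf_ids))
  })

  ## 4. true network: module + background ----------------------------------
  module_baits <- domain_ids[seq_len(min(cfg$n_module_baits, cfg$n_domains))]
  module_preys <- prey_ids[seq_len(min(cfg$n_module_preys, cfg$n_proteins))]
  true_edges <- with_seed(child_seed(seed, 4), {
    mod <- do.call(rbind, lapply(module_preys, function(p) {
      data.frame(bait_id = sample(module_baits,
                                  min(cfg$module_edges_per_prey,
                                      length(module_baits))),
                 prey_id = p, stringsAsFactors = FALSE)
    }))
    bg_preys <- setdiff(prey_ids, module_preys)
    bg <- data.frame(
      bait_id = sample(domain_ids, cfg$n_background_edges, replace = TRUE),
      prey_id = sample(bg_preys, cfg$n_background_edges, replace = TRUE),
      stringsAsFactors = FALSE)
    e <- rbind(mod, bg)
    e[!duplicated(paste(e$bait_id, e$prey_id)), , drop = FALSE]
  })
  rownames(true_edges) <- NULL

  ## 5. plant ligand motifs -------------------------------------------------
  registry <- with_seed(child_seed(seed, 5), {
    occupied <- stats::setNames(vector("list", length(proteome)),
                                names(proteome))
    rows <- vector("list", nrow(true_edges))
    for (i in seq_len(nrow(true_edges))) {
      d <- true_edges$bait_id[i]; p <- true_edges$prey_id[i]
      pwm <- pwms[[d]]
      pep <- .plant_peptide(pwm, T)
      L <- nchar(proteome[[p]])
      for (try in 1:100) {
        s <- sample.int(L - pwm$m + 1L, 1L)
        clash <- any(vapply(occupied[[p]], function(sp) {
          s <= sp[2] + 12L && sp[1] <= s + pwm$m - 1L + 12L
        }, logical(1)))
        if (!clash) break
      }
      substr(proteome[[p]], s, s + pwm$m - 1L) <- pep
      occupied[[p]] <- c(occupied[[p]], list(c(s, s + pwm$m - 1L)))
      rows[[i]] <- data.frame(protein_id = p, domain_id = d, start = s,
                              peptide = pep, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  # planting mutated `proteome` inside with_seed's frame; rebuild it here
  for (i in seq_len(nrow(registry))) {
    substr(proteome[[registry$protein_id[i]]], registry$start[i],
           registry$start[i] + nchar(registry$peptide[i]) - 1L) <-
      registry$peptide[i]
  }

  ## 6. Y2H candidates ------------------------------------------------------
  cand <- with_seed(child_seed(seed, 6), {
    tr <- true_edges
    tr$colony_count <- .rztpois(nrow(tr), cfg$colony_lambda)
    tr$is_true <- TRUE
    # uniform false positives: one colony, no support
    true_key <- paste(true_edges$bait_id, true_edges$prey_id)
    fp <- data.frame(
      bait_id = sample(domain_ids, cfg$n_false_positives * 3, replace = TRUE),
      prey_id = sample(prey_ids, cfg$n_false_positives * 3, replace = TRUE),
      stringsAsFactors = FALSE)
    fp <- fp[!paste(fp$bait_id, fp$prey_id) %in% true_key, , drop = FALSE]
    fp <- fp[!duplicated(paste(fp$bait_id, fp$prey_id)), , drop = FALSE]
    fp <- fp[seq_len(min(cfg$n_false_positives, nrow(fp))), , drop = FALSE]
    fp$colony_count <- 1L
    fp$is_true <- FALSE
    # sticky auto-activating TF preys hitting many baits with many colonies
    tf <- if (length(tf_ids)) do.call(rbind, lapply(tf_ids, function(tfp) {
      data.frame(bait_id = sample(domain_ids,
                                  min(cfg$tf_degree, length(domain_ids))),
                 prey_id = tfp, colony_count = 1L + .rztpois(
                   min(cfg$tf_degree, length(domain_ids)), cfg$colony_lambda),
                 is_true = FALSE, stringsAsFactors = FALSE)
    })) else NULL
    out <- rbind(tr, fp, tf)
    out$bait_type <- "sh3_domain"
    out$library <- "ORFeome"
    out
  })
  rownames(cand) <- NULL

  ## 7. evidence annotations ------------------------------------------------
  evidence <- with_seed(child_seed(seed, 7), {
    ev <- cand[, c("bait_id", "prey_id")]
    sc <- lapply(seq_len(nrow(ev)), function(i) {
      scan_protein(pwms[[ev$bait_id[i]]], proteome[[ev$prey_id[i]]],
                   ev$prey_id[i])$best
    })
    ev$pwm_score <- vapply(sc, function(b) b$score, numeric(1))
    ev$best_peptide <- vapply(sc, function(b) as.character(b$peptide),
                              character(1))
    ev$start <- vapply(sc, function(b) as.integer(b$start), integer(1))
    ev$prey_is_TF <- ev$prey_id %in% tf_ids
    single_true <- cand$is_true & cand$colony_count == 1L
    ev$literature_functional <- single_true & stats::runif(nrow(ev)) < cfg$lit_rate
    ev$in_WI8 <- FALSE
    ev$in_interolog_set <- FALSE
    ev$in_WormNet <- FALSE
    ev
  })

  ## 8. second species: orthologs and rewiring scenarios --------------------
  counts <- .apportion(min(cfg$n_rewired, nrow(true_edges)), cfg$scenario_mix)
  rew <- with_seed(child_seed(seed, 8), {
    # domains are split into a specificity-conserved and a non-conserved
    # group; edges of each group carry the compatible scenarios
    need_cons <- counts[["ii"]] + counts[["conserved_both"]]
    need_not <- counts[["i"]] + counts[["iii"]]
    shuffle <- function(x) x[sample.int(length(x))]
    by_dom <- split(seq_len(nrow(true_edges)), true_edges$bait_id)
    by_dom <- by_dom[sample.int(length(by_dom))]
    spec_flag <- stats::setNames(rep(NA, length(by_dom)), names(by_dom))
    picked_cons <- integer(); picked_not <- integer()
    for (d in names(by_dom)) {
      rows <- shuffle(by_dom[[d]])
      if (need_cons - length(picked_cons) >= need_not - length(picked_not)) {
        spec_flag[d] <- TRUE
        picked_cons <- c(picked_cons,
                         rows[seq_len(min(length(rows),
                                          need_cons - length(picked_cons)))])
      } else {
        spec_flag[d] <- FALSE
        picked_not <- c(picked_not,
                        rows[seq_len(min(length(rows),
                                         need_not - length(picked_not)))])
      }
      if (length(picked_cons) >= need_cons && length(picked_not) >= need_not)
        break
    }
    scen_cons <- shuffle(rep(c("ii", "conserved_both"),
                             c(counts[["ii"]], counts[["conserved_both"]]))
                         )[seq_along(picked_cons)]
    scen_not <- shuffle(rep(c("i", "iii"),
                            c(counts[["i"]], counts[["iii"]]))
                        )[seq_along(picked_not)]
    data.frame(
      row = c(picked_cons, picked_not),
      domain_id = true_edges$bait_id[c(picked_cons, picked_not)],
      target_id = true_edges$prey_id[c(picked_cons, picked_not)],
      scenario = c(scen_cons, scen_not),
      stringsAsFactors = FALSE)
  })
  spec_conserved_domains <- unique(rew$domain_id[rew$scenario %in%
                                                   c("ii", "conserved_both")])
  spec_lost_domains <- unique(rew$domain_id[rew$scenario %in% c("i", "iii")])

  orth_b <- function(x) paste0("y_", x)
  omap <- with_seed(child_seed(seed, 9), {
    covered <- names(proteome)[stats::runif(length(proteome)) <
                                 cfg$ortholog_coverage]
    covered <- union(covered, rew$target_id)        # rewired targets forced
    covered <- union(covered, prot_ids)             # domain proteins kept
    ortholog_map(covered, orth_b(covered))
  })

  # species-B proteome: mutated copies; planted motif spans are kept intact
  # or destroyed according to the scenario of their edge
  motif_fate <- stats::setNames(rep("keep", nrow(registry)),
                                paste(registry$domain_id, registry$protein_id))
  destroyed <- rew$scenario %in% c("ii", "iii")
  motif_fate[paste(rew$domain_id, rew$target_id)[destroyed]] <- "destroy"
  proteome_b <- with_seed(child_seed(seed, 10), {
    covered_preys <- intersect(omap$pairs$gene_A, names(proteome))
    out <- stats::setNames(character(length(covered_preys)),
                           orth_b(covered_preys))
    for (ii in seq_along(covered_preys)) {
      p <- covered_preys[ii]
      chars <- split_chars(proteome[[p]])
      protected <- integer()
      reg <- registry[registry$protein_id == p, , drop = FALSE]
      spans <- lapply(seq_len(nrow(reg)), function(r) {
        seq.int(reg$start[r], reg$start[r] + nchar(reg$peptide[r]) - 1L)
      })
      if (nrow(reg)) protected <- unlist(spans)
      mut <- which(stats::runif(length(chars)) < cfg$background_mut_rate)
      mut <- setdiff(mut, protected)
      chars[mut] <- sample(AA_ALPHABET, length(mut), replace = TRUE)
      if (nrow(reg)) for (r in seq_len(nrow(reg))) {
        if (motif_fate[[paste(reg$domain_id[r], p)]] == "destroy") {
          chars[spans[[r]]] <- sample(AA_ALPHABET, length(spans[[r]]),
                                      replace = TRUE)
        }
      }
      out[ii] <- paste(chars, collapse = "")
    }
    out
  })

  # species-B domain PWMs: identical profile when specificity is conserved,
  # an atypical profile otherwise
  pwms_b <- list()
  for (i in seq_len(cfg$n_domains)) {
    did <- domain_ids[i]
    bid <- paste0(orth_b(prot_ids[i]), "#1")
    if (did %in% spec_lost_domains) {
      pwms_b[[bid]] <- gen_pwm(cfg$pwm_m, cfg$sharpness, "atypical",
                               seed = child_seed(seed, 300 + i),
                               domain_id = bid)
    } else {
      pwms_b[[bid]] <- new_pwm(pwms[[did]]$prob, domain_id = bid,
                               provenance = "synthetic")
    }
  }

  ## 9. ontology, annotations, function-prediction lists --------------------
  ont <- ontology(
    ids = c("T:root", "T:process_a", "T:process_b", "T:module",
            paste0("T:other", 1:4)),
    parents = list(`T:root` = character(),
                   `T:process_a` = "T:root", `T:process_b` = "T:root",
                   `T:module` = "T:process_a",
                   `T:other1` = "T:process_b", `T:other2` = "T:process_b",
                   `T:other3` = "T:process_b", `T:other4` = "T:process_b"),
    namespace = "biological_process")
  module_proteins <- c(domain_protein(module_baits), module_preys)
  annotations <- with_seed(child_seed(seed, 11), {
    bg <- setdiff(c(prot_ids, prey_ids), module_proteins)
    bg <- bg[stats::runif(length(bg)) < cfg$annotation_rate]
    rbind(
      data.frame(gene = module_proteins, term = "T:module",
                 evidence = "EXP", stringsAsFactors = FALSE),
      data.frame(gene = bg,
                 term = sample(paste0("T:other", 1:4), length(bg),
                               replace = TRUE),
                 evidence = "EXP", stringsAsFactors = FALSE))
  })
  # seeds cover the module baits plus 60% of module preys; the held-back
  # preys are the "novel" module members the k-core should rediscover
  seeds_neg <- with_seed(child_seed(seed, 12), {
    non_module <- setdiff(prey_ids, module_preys)
    seed_preys <- sample(module_preys,
                         ceiling(0.6 * length(module_preys)))
    list(seeds = sort(c(domain_protein(module_baits), seed_preys)),
         novel = sort(setdiff(module_preys, seed_preys)),
         negatives = sort(sample(non_module,
                                 min(cfg$n_negatives, length(non_module)))))
  })

  structure(
    list(config = cfg, seed = seed,
         pwms = pwms, pwm_classes = stats::setNames(classes, domain_ids),
         peptide_sets = peptide_sets,
         proteome = proteome,
         motif_registry = registry,
         true_edges = true_edges,
         candidates = cand,
         evidence = evidence,
         tf_preys = tf_ids,
         omap = omap,
         proteome_b = proteome_b,
         pwms_b = pwms_b,
         rewired = rew[, c("domain_id", "target_id", "scenario")],
         module_proteins = module_proteins,
         seeds = seeds_neg$seeds,
         novel_module_proteins = seeds_neg$novel,
         negatives = seeds_neg$negatives,
         ontology = ont,
         annotations = annotations,
         universe_genes = c(prot_ids, prey_ids)),
    class = "sh3_world"
  )
}

#' @export
print.sh3_world <- function(x, ...) {
  cat(sprintf(paste0("Synthetic SH3 world (seed %d): %d domains, %d ",
                     "proteins, %d true edges, %d candidates, %d rewired\n"),
              x$seed, length(x$pwms), length(x$proteome),
              nrow(x$true_edges), nrow(x$candidates), nrow(x$rewired)))
  invisible(x)
}

#' Write a synthetic world to disk in the interchange formats
#'
#' Emits every generated input in the format its consuming reader expects
#' (peptide table, PWM matrices, FASTA proteomes, candidate and evidence
#' tables, ortholog map, ontology in OBO, annotation table, id lists) plus a
#' ground-truth ledger (planted motifs, true edges, rewiring scenarios).
#'
#' @param world an \code{"sh3_world"}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_peptides(world$peptide_sets, p("peptides.tsv"))
  dir.create(p("pwms"), showWarnings = FALSE)
  for (d in names(world$pwms)) {
    write_pwm(world$pwms[[d]], p("pwms", paste0(gsub("#", "_", d), ".tsv")))
  }
  write_proteome(world$proteome, p("proteome_a.fasta"))
  write_proteome(world$proteome_b, p("proteome_b.fasta"))
  utils::write.table(world$candidates, p("candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(world$evidence, p("evidence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_ortholog_map(world$omap, p("orthologs.tsv"))
  utils::write.table(world$annotations, p("annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_obo(world$ontology, p("ontology.obo"))
  writeLines(world$seeds, p("seeds.txt"))
  writeLines(world$negatives, p("negatives.txt"))
  utils::write.table(world$motif_registry, p("ground_truth_motifs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$true_edges, p("ground_truth_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$rewired, p("ground_truth_rewiring.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write an ontology in minimal OBO 1.2 format
#'
#' @param ont an [ontology()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_obo <- function(ont, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(ont$terms))) {
    id <- ont$terms$id[i]
    lines <- c("[Term]", paste0("id: ", id))
    if (!is.na(ont$terms$name[i])) {
      lines <- c(lines, paste0("name: ", ont$terms$name[i]))
    }
    lines <- c(lines, paste0("namespace: ", ont$terms$namespace[i]))
    if (length(ont$parents[[id]])) {
      lines <- c(lines, paste0("is_a: ", ont$parents[[id]]))
    }
    lines <- c(lines, "")
    writeLines(lines, con)
  }
  invisible(path)
}
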