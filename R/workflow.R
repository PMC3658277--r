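# End-to-end pipeline orchestration over a synthetic (or file-derived)
# world: staged execution with explicit dependencies, seeded throughout,
# returning a machine-readable report.

.PIPELINE_STAGES <- c("simulate", "pwms", "tree", "scan", "filter", "enrich",
                      "conserve", "rewire", "kcore", "gosim", "compete")

# upstream requirements per stage
.STAGE_DEPS <- list(
  simulate = character(),
  pwms = "simulate",
  tree = "pwms",
  scan = "pwms",
  filter = "simulate",
  enrich = c("filter", "scan"),
  conserve = "filter",
  rewire = "simulate",
  kcore = "filter",
  gosim = "filter",
  compete = c("filter", "pwms")
)

#' Run the SH3 interactome analysis pipeline on a synthetic world
#'
#' Executes the requested stages in dependency order: \code{simulate}
#' (generate the world), \code{pwms} (rebuild PWMs from the sampled phage
#' peptides), \code{tree} (specificity similarity matrix and tree),
#' \code{scan} (proteome-wide ranking per domain), \code{filter}
#' (evidence-based Y2H filtering), \code{enrich} (phage/Y2H rank
#' enrichment), \code{conserve} (cross-species conservation test),
#' \code{rewire} (scenario classification against the planted ground
#' truth), \code{kcore} (cross-validated function prediction), \code{gosim}
#' (annotation-similarity benchmark) and \code{compete} (motif-competition
#' correlations). Each stage reads only the outputs of its declared
#' upstream stages; requesting a stage whose upstream output is missing is
#' an explicit dependency error naming the stage.
#'
#' @param config a [world_config()] list.
#' @param seed master seed; every stage derives its own child seed.
#' @param stages character vector of stages to run (default: all).
#' @param n_random randomizations for the enrichment null.
#' @param n_networks,per_bait random-network benchmark size.
#' @param state optionally, the list returned by a previous call, to rerun
#'   later stages from cached upstream outputs.
#' @return object of class \code{"sh3_report"}: list of per-stage outputs
#'   plus a \code{summary} data frame of key statistics.
#' @export
run_pipeline <- function(config = world_config(), seed = 1,
                         stages = .PIPELINE_STAGES, n_random = 10000,
                         n_networks = 100, per_bait = 30, state = NULL) {
  stages <- match.arg(stages, .PIPELINE_STAGES, several.ok = TRUE)
  st <- if (is.null(state)) list() else unclass(state)
  st$summary <- NULL
  need <- function(stage, dep) {
    if (is.null(st[[dep]])) {
      stop("stage '", stage, "' requires output of stage '", dep,
           "' which has not been run")
    }
  }
  for (stage in .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages]) {
    for (dep in .STAGE_DEPS[[stage]]) need(stage, dep)
    st[[stage]] <- switch(stage,
      simulate = gen_world(config, seed),
      pwms = {
        w <- st$simulate
        lapply(w$peptide_sets, build_pwm)
      },
      tree = {
        simmat <- similarity_matrix(st$pwms)
        list(similarity = simmat, newick = build_specificity_tree(simmat))
      },
      scan = {
        w <- st$simulate
        lapply(st$pwms, rank_in_proteome, proteome = w$proteome)
      },
      filter = {
        w <- st$simulate
        filter_candidates(w$candidates, w$evidence, T = w$config$T)
      },
      enrich = phage_overlap_enrichment(st$filter, st$scan,
                                        n_random = n_random,
                                        seed = child_seed(seed, 21)),
      conserve = {
        w <- st$simulate
        proj <- project_by_orthology(st$filter, w$omap)
        uni <- universe_size(proj$n_baits_conserved, proj$n_preys_conserved,
                             proj$n_bp)
        # reference species-B interactions: the projections of the
        # conserved-scenario edges plus their rewired-away counterparts
        # are represented by the world's planted species-B network: the
        # projected true edges whose scenario is conserved_both
        keep <- w$rewired[w$rewired$scenario == "conserved_both", ,
                          drop = FALSE]
        ref <- data.frame(
          id_A = paste0("y_", domain_protein(keep$domain_id)),
          id_B = paste0("y_", keep$target_id), stringsAsFactors = FALSE)
        list(projection = proj, universe = uni,
             result = conservation_test(proj, ref, uni))
      },
      rewire = {
        w <- st$simulate
        calls <- classify_rewiring_table(
          w$rewired, pwms = list(source = w$pwms, target = w$pwms_b),
          omap = w$omap,
          sequences = list(source = w$proteome, target = w$proteome_b),
          T = w$config$T)
        calls$truth <- w$rewired$scenario
        mapped <- calls$scenario != "unmappable"
        list(calls = calls,
             accuracy = mean(calls$scenario[mapped] == calls$truth[mapped]),
             n_unmappable = sum(!mapped))
      },
      kcore = {
        w <- st$simulate
        g <- data.frame(from = domain_protein(st$filter$edges$bait_id),
                        to = st$filter$edges$prey_id)
        cv <- cross_validate(g, w$seeds, w$negatives,
                             folds = 10, seed = child_seed(seed, 22))
        list(graph = g, cv = cv,
             predictions = predict_novel(g, w$seeds, k = 3))
      },
      gosim = {
        w <- st$simulate
        corpus <- annotation_corpus(w$ontology, w$annotations)
        net <- data.frame(bait = domain_protein(st$filter$edges$bait_id),
                          prey = st$filter$edges$prey_id)
        network_benchmark(net, corpus, w$universe_genes,
                          n_networks = n_networks, per_bait = per_bait,
                          seed = child_seed(seed, 23))
      },
      compete = {
        w <- st$simulate
        tab <- build_cluster_table(st$filter, st$pwms, w$proteome,
                                   T = w$config$T)
        assoc <- if (nrow(tab$prey_table) >= 3 &&
                     stats::sd(tab$prey_table$n_motifs) > 0 &&
                     stats::sd(tab$prey_table$n_partners) > 0) {
          spearman_association(tab$prey_table$n_motifs,
                               tab$prey_table$n_partners)
        } else NULL
        list(table = tab, motif_vs_partners = assoc)
      })
  }

  sm <- list()
  add <- function(key, value) sm[[length(sm) + 1L]] <<- data.frame(
    key = key, value = as.character(value), stringsAsFactors = FALSE)
  if (!is.null(st$simulate)) {
    add("seed", seed)
    add("n_domains", length(st$simulate$pwms))
    add("n_true_edges", nrow(st$simulate$true_edges))
  }
  if (!is.null(st$filter)) {
    add("n_edges_filtered", nrow(st$filter$edges))
    for (cl in names(st$filter$counts)) {
      add(paste0("n_", cl), st$filter$counts[[cl]])
    }
  }
  if (!is.null(st$enrich)) {
    add("enrichment_auc", format(st$enrich$auc, digits = 6))
    add("enrichment_p", format(st$enrich$p_value, digits = 6))
  }
  if (!is.null(st$conserve)) {
    add("conservation_universe", st$conserve$universe)
    add("conservation_overlap", st$conserve$result$n_overlap)
    add("conservation_p", format(st$conserve$result$p_value, digits = 6))
  }
  if (!is.null(st$rewire)) {
    add("rewiring_accuracy", format(st$rewire$accuracy, digits = 6))
  }
  if (!is.null(st$kcore)) {
    add("kcore_mean_auc", format(st$kcore$cv$mean_auc, digits = 6))
    add("kcore_n_predictions", nrow(st$kcore$predictions))
  }
  if (!is.null(st$gosim)) {
    add("gosim_p_avg", format(st$gosim$p_value[["sim_avg"]], digits = 6))
  }
  if (!is.null(st$compete) && !is.null(st$compete$motif_vs_partners)) {
    add("compete_rho", format(st$compete$motif_vs_partners$rho, digits = 6))
  }
  st$summary <- do.call(rbind, sm)
  class(st) <- "sh3_report"
  st
}

#' @export
print.sh3_report <- function(x, ...) {
  cat("SH3 pipeline report\n")
  if (!is.null(x$summary)) {
    for (i in seq_len(nrow(x$summary))) {
      cat(sprintf("  %-24s %s\n", x$summary$key[i], x$summary$value[i]))
    }
  }
  invisible(x)
}

#' Write a pipeline report in a parseable key/value format
#'
#' @param report an \code{"sh3_report"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.table(report$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
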