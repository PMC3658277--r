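# Assembly of the high-confidence SH3 interactome from raw Y2H candidates,
# and the phage/Y2H agreement statistic.

#' Filter raw Y2H candidates into a high-confidence SH3 network
#'
#' A candidate bait--prey pair (colony counts summed across screens) is kept
#' when it is supported by two independent lines of evidence:
#' \itemize{
#'   \item \code{multi_colony}: at least two independent positive colonies;
#'   \item \code{literature}: a single colony but the pair is found in a
#'     published interaction set, a known interolog set, a functional
#'     interaction network, or is otherwise literature supported;
#'   \item \code{motif}: a single colony but the prey carries a sequence
#'     motif matching the bait's phage-derived specificity (best PWM score at
#'     least \code{T}); only SH3-domain baits are eligible for this class.
#' }
#' Afterwards every edge whose prey is a transcription factor connected to
#' more than \code{tf_degree_max} distinct baits in the kept network is
#' removed, as such promiscuous activation-domain TFs are likely
#' auto-activating preys.
#'
#' @param cands data frame of candidates with columns \code{bait_id},
#'   \code{prey_id}, \code{colony_count} (positive integers) and optionally
#'   \code{bait_type} (\code{"sh3_domain"}, \code{"full_length"} or
#'   \code{"fragment"}; default \code{"sh3_domain"}) and \code{library}.
#' @param ev data frame of per-pair evidence with columns \code{bait_id},
#'   \code{prey_id}, logical flags \code{in_WI8}, \code{in_interolog_set},
#'   \code{in_WormNet}, \code{literature_functional}, numeric
#'   \code{pwm_score} (NA when the bait has no PWM), logical
#'   \code{prey_is_TF}, and optionally \code{best_peptide}, \code{start},
#'   \code{rank}.
#' @param T PWM score threshold for the motif evidence class.
#' @param tf_degree_max maximum allowed bait degree for TF preys.
#' @return object of class \code{"sh3_network"}: list with \code{edges}
#'   (bait_id, bait_type, prey_id, colony_count, evidence_class, pwm_score,
#'   best_peptide, start, rank), \code{counts_before_tf} and \code{counts}
#'   (evidence-class tallies before/after TF removal), \code{n_dropped}
#'   (candidates failing all evidence rules) and \code{tf_removed} (prey ids
#'   pruned by the TF rule).
#' @export
filter_candidates <- function(cands, ev, T = 1000, tf_degree_max = 5) {
  stopifnot(all(c("bait_id", "prey_id", "colony_count") %in% names(cands)))
  if (!"bait_type" %in% names(cands)) cands$bait_type <- "sh3_domain"
  if (any(cands$colony_count < 1)) stop("colony counts must be >= 1")

  # deduplicate by pair, summing colony counts across screens
  key <- paste(cands$bait_id, cands$prey_id, sep = "\r")
  agg <- stats::aggregate(colony_count ~ key, data.frame(key = key,
         colony_count = cands$colony_count), sum)
  first <- cands[!duplicated(key), c("bait_id", "bait_type", "prey_id")]
  first$key <- key[!duplicated(key)]
  cand <- merge(first, agg, by = "key")
  cand$key <- NULL

  flag_cols <- c("in_WI8", "in_interolog_set", "in_WormNet",
                 "literature_functional")
  for (cc in c(flag_cols, "prey_is_TF")) if (!cc %in% names(ev)) ev[[cc]] <- FALSE
  for (cc in c("pwm_score", "best_peptide", "start", "rank")) {
    if (!cc %in% names(ev)) ev[[cc]] <- NA
  }
  m <- merge(cand, ev, by = c("bait_id", "prey_id"), all.x = TRUE)
  for (cc in c(flag_cols, "prey_is_TF")) m[[cc]][is.na(m[[cc]])] <- FALSE

  lit <- Reduce(`|`, m[flag_cols])
  motif_ok <- m$bait_type == "sh3_domain" & !is.na(m$pwm_score) & m$pwm_score >= T
  cls <- ifelse(m$colony_count >= 2, "multi_colony",
         ifelse(lit, "literature",
         ifelse(motif_ok, "motif", NA_character_)))
  n_dropped <- sum(is.na(cls))
  if (n_dropped > 0) {
    message(n_dropped, " single-colony candidate(s) without supporting ",
            "evidence dropped")
  }
  kept <- m[!is.na(cls), , drop = FALSE]
  kept$evidence_class <- cls[!is.na(cls)]
  counts_before <- table(factor(kept$evidence_class,
                                levels = c("multi_colony", "literature", "motif")))

  # TF rule: prune preys that are TFs hitting many distinct baits
  deg <- tapply(kept$bait_id, kept$prey_id, function(b) length(unique(b)))
  is_tf <- tapply(kept$prey_is_TF, kept$prey_id, any)
  bad_preys <- names(deg)[is_tf[names(deg)] & deg > tf_degree_max]
  out <- kept[!kept$prey_id %in% bad_preys, , drop = FALSE]

  edges <- out[, c("bait_id", "bait_type", "prey_id", "colony_count",
                   "evidence_class", "pwm_score", "best_peptide", "start",
                   "rank")]
  edges <- edges[order(edges$bait_id, edges$prey_id), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(edges = edges,
         counts_before_tf = counts_before,
         counts = table(factor(edges$evidence_class,
                               levels = c("multi_colony", "literature", "motif"))),
         n_dropped = n_dropped,
         tf_removed = bad_preys),
    class = "sh3_network"
  )
}

#' @export
print.sh3_network <- function(x, ...) {
  cat(sprintf("SH3 interactome: %d PPIs, %d baits, %d preys\n",
              nrow(x$edges), length(unique(x$edges$bait_id)),
              length(unique(x$edges$prey_id))))
  cat("  evidence classes:",
      paste(names(x$counts), as.integer(x$counts), sep = "=", collapse = ", "),
      "\n")
  if (length(x$tf_removed)) {
    cat("  TF preys removed:", paste(x$tf_removed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Enrichment of Y2H interactions among high PWM-scoring proteins
#'
#' Assigns each eligible Y2H interaction the genome-wide rank of its prey
#' under the bait's PWM and summarizes the rank distribution by the
#' (normalized) area under the cumulative curve F(x) = fraction of
#' interactions with rank at most x. Edges kept in the network only because
#' of the motif evidence class are excluded, to not bias the statistic, as
#' are baits without phage data. Significance is estimated against a null in
#' which each interaction receives a uniform random rank; the add-one
#' estimator keeps p strictly positive.
#'
#' @param net an \code{"sh3_network"}.
#' @param ranks named list (by bait_id) of ranked proteome tables from
#'   [rank_in_proteome()].
#' @param n_random number of null randomizations.
#' @param seed RNG seed for the null.
#' @return list with \code{curve} (data frame rank/cumulative fraction over
#'   the full proteome), \code{auc} in [0, 1], \code{p_value},
#'   \code{n_edges} used, and \code{observed_ranks}.
#' @export
phage_overlap_enrichment <- function(net, ranks, n_random = 100000, seed = 1) {
  stopifnot(inherits(net, "sh3_network"), length(ranks) > 0)
  P <- nrow(ranks[[1L]])
  edges <- net$edges
  edges <- edges[edges$evidence_class != "motif" &
                   edges$bait_id %in% names(ranks), , drop = FALSE]
  if (nrow(edges) == 0L) stop("no eligible edges (non-motif, bait with PWM)")
  r_obs <- mapply(function(b, p) {
    tab <- ranks[[b]]
    i <- match(p, tab$protein_id)
    if (is.na(i)) NA_integer_ else tab$rank[i]
  }, edges$bait_id, edges$prey_id)
  if (anyNA(r_obs)) {
    warning(sum(is.na(r_obs)), " prey(s) absent from the ranked proteome; ",
            "excluded")
    r_obs <- r_obs[!is.na(r_obs)]
  }
  E <- length(r_obs)
  # AUC of the cumulative rank curve: mean over x of F(x) reduces to a
  # closed form in the observed ranks
  auc_of <- function(r) (P + 1 - mean(r)) / P
  auc <- auc_of(r_obs)
  null_auc <- with_seed(seed, {
    rmat <- matrix(sample.int(P, E * n_random, replace = TRUE), nrow = E)
    (P + 1 - colMeans(rmat)) / P
  })
  p <- (1 + sum(null_auc >= auc)) / (1 + n_random)
  xs <- seq_len(P)
  curve <- data.frame(rank = xs,
                      cumulative = findInterval(xs, sort(r_obs)) / E)
  list(curve = curve, auc = auc, p_value = p, n_edges = E,
       observed_ranks = unname(r_obs))
}
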