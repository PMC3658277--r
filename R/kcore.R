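# Modified k-core guilt-by-association function prediction with
# cross-validated ROC evaluation.

# Coerce an edge data frame or igraph to a named adjacency list of character
# neighbor vectors (undirected, no self loops).
.adjacency <- function(net) {
  if (igraph::is_igraph(net)) {
    el <- igraph::as_edgelist(net, names = TRUE)
    a <- as.character(el[, 1L]); b <- as.character(el[, 2L])
    iso <- setdiff(igraph::V(net)$name, c(a, b))
  } else {
    stopifnot(is.data.frame(net), ncol(net) >= 2L)
    a <- as.character(net[[1L]]); b <- as.character(net[[2L]])
    iso <- character()
  }
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  adj <- split(c(b, a), c(a, b))
  adj <- lapply(adj, unique)
  for (v in iso) adj[[v]] <- character()
  adj
}

#' Modified k-core of a protein network around seed proteins
#'
#' The modified k-core is the maximal sub-network of non-seed proteins that
#' are (a) connected to at least one seed and (b) retain at least \code{k}
#' links to other members or to seeds. It is computed by iterative pruning
#' with simultaneous removal per round, whose fixpoint is unique and
#' order-independent.
#'
#' @param net undirected network: an igraph object or a two-column edge data
#'   frame of protein ids.
#' @param seeds character vector of seed proteins (e.g. known endocytosis
#'   genes); seeds absent from the network are ignored with a warning.
#' @param k minimum number of links (>= 1).
#' @return sorted character vector of member proteins (never includes seeds).
#' @examples
#' g <- data.frame(from = c("s", "s", "a", "b"), to = c("a", "b", "b", "c"))
#' modified_kcore(g, "s", k = 2)  # a, b
#' @export
modified_kcore <- function(net, seeds, k) {
  stopifnot(k >= 1L)
  adj <- .adjacency(net)
  if (length(adj) == 0L) return(character())
  seeds <- unique(as.character(seeds))
  missing <- setdiff(seeds, names(adj))
  if (length(missing)) {
    warning(length(missing), " seed(s) absent from the network ignored")
  }
  seeds <- intersect(seeds, names(adj))
  # members start as non-seed neighbors of seeds
  M <- setdiff(unique(unlist(adj[seeds], use.names = FALSE)), seeds)
  repeat {
    keep_set <- c(M, seeds)
    deg <- vapply(M, function(v) sum(adj[[v]] %in% keep_set), integer(1))
    drop <- M[deg < k]
    if (length(drop) == 0L) break
    M <- setdiff(M, drop)
  }
  sort(M)
}

#' k-core scores for all proteins of a universe
#'
#' The score of a protein is the maximal \code{k} at which it is a member of
#' the modified k-core; proteins present in the network but never members
#' score 0, and proteins absent from the network score -1. Seeds are the
#' conditioning set and are not scored.
#'
#' @inheritParams modified_kcore
#' @param universe character vector of proteins to score; defaults to all
#'   network nodes plus any ids in \code{extra}.
#' @return named integer vector of scores over \code{universe} (seeds
#'   removed).
#' @export
kcore_scores <- function(net, seeds, universe = NULL) {
  adj <- .adjacency(net)
  seeds <- unique(as.character(seeds))
  if (is.null(universe)) universe <- names(adj)
  universe <- setdiff(unique(as.character(universe)), seeds)
  scores <- ifelse(universe %in% names(adj), 0L, -1L)
  names(scores) <- universe
  k <- 1L
  repeat {
    members <- suppressWarnings(modified_kcore(net, seeds, k))
    if (length(members) == 0L) break
    hit <- intersect(members, universe)
    scores[hit] <- k
    k <- k + 1L
  }
  scores
}

# Rank-based AUC; with tied integer scores this equals the trapezoidal area
# under the ROC curve over score thresholds.
.auc <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) return(NA_real_)
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_along(pos_scores)]) -
     length(pos_scores) * (length(pos_scores) + 1) / 2) /
    (length(pos_scores) * length(neg_scores))
}

# ROC curve over the integer score thresholds (including -1 and 0).
.roc_curve <- function(pos_scores, neg_scores) {
  th <- sort(unique(c(-1L, 0L, pos_scores, neg_scores)), decreasing = TRUE)
  data.frame(
    threshold = th,
    tpr = vapply(th, function(t) mean(pos_scores >= t), numeric(1)),
    fpr = vapply(th, function(t) mean(neg_scores >= t), numeric(1))
  )
}

#' Cross-validated ROC evaluation of k-core function prediction
#'
#' Splits the seed list into \code{folds} sub-groups; each fold in turn is
#' held out, scores are computed by [kcore_scores()] conditioned on the
#' remaining seeds, and an ROC over the integer score scale (including the
#' -1 and 0 levels) compares held-out seeds against the negative examples.
#' The AUC uses the rank formula, equivalent to trapezoidal interpolation
#' across tied scores.
#'
#' @inheritParams modified_kcore
#' @param negatives character vector of negative example proteins, disjoint
#'   from the seeds.
#' @param folds number of cross-validation folds.
#' @param seed RNG seed controlling the fold shuffle.
#' @return list with \code{mean_auc}, \code{fold_auc} (numeric vector), and
#'   \code{roc} (list of per-fold ROC data frames).
#' @export
cross_validate <- function(net, seeds, negatives, folds = 10, seed = 1) {
  seeds <- unique(as.character(seeds))
  negatives <- unique(as.character(negatives))
  if (length(intersect(seeds, negatives))) {
    stop("negatives must be disjoint from seeds")
  }
  if (length(seeds) < folds) stop("need at least `folds` seeds")
  fold_of <- with_seed(seed, {
    sample(rep_len(seq_len(folds), length(seeds)))
  })
  fold_auc <- numeric(folds)
  rocs <- vector("list", folds)
  for (f in seq_len(folds)) {
    held <- seeds[fold_of == f]
    train <- seeds[fold_of != f]
    sc <- kcore_scores(net, train, universe = c(held, negatives))
    fold_auc[f] <- .auc(sc[held], sc[negatives])
    rocs[[f]] <- .roc_curve(sc[held], sc[negatives])
  }
  list(mean_auc = mean(fold_auc, na.rm = TRUE), fold_auc = fold_auc,
       roc = rocs)
}

#' Predict novel function-associated proteins by modified k-core
#'
#' Members of the modified k-core at level \code{k} (seeds excluded by
#' construction), ranked by k-core score, then by number of direct seed
#' neighbors, then by id.
#'
#' @inheritParams modified_kcore
#' @param k core level used for prediction.
#' @return data frame (protein_id, score, degree_to_seeds), best first.
#' @export
predict_novel <- function(net, seeds, k = 3) {
  members <- modified_kcore(net, seeds, k)
  if (length(members) == 0L) {
    return(data.frame(protein_id = character(), score = integer(),
                      degree_to_seeds = integer(), stringsAsFactors = FALSE))
  }
  adj <- .adjacency(net)
  seeds <- intersect(unique(as.character(seeds)), names(adj))
  scores <- kcore_scores(net, seeds, universe = members)
  deg <- vapply(members, function(v) sum(adj[[v]] %in% seeds), integer(1))
  out <- data.frame(protein_id = members, score = as.integer(scores[members]),
                    degree_to_seeds = deg, stringsAsFactors = FALSE)
  out <- out[order(-out$score, -out$degree_to_seeds, out$protein_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
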