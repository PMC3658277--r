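# Cross-species projection of the interactome by orthology and the
# interaction-conservation test with the corrected interaction universe.

#' Many-to-many ortholog map between two species
#'
#' @param gene_A,gene_B equal-length character vectors of corresponding gene
#'   identifiers in species A and B; duplicates are collapsed (the union over
#'   orthology sources is taken) and many-to-many correspondences are
#'   permitted.
#' @return object of class \code{"ortholog_map"} with element \code{pairs}
#'   (data frame gene_A, gene_B).
#' @export
ortholog_map <- function(gene_A, gene_B) {
  stopifnot(length(gene_A) == length(gene_B))
  df <- unique(data.frame(gene_A = as.character(gene_A),
                          gene_B = as.character(gene_B),
                          stringsAsFactors = FALSE))
  structure(list(pairs = df), class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("Ortholog map: %d pairs, %d genes in A, %d genes in B\n",
              nrow(x$pairs), length(unique(x$pairs$gene_A)),
              length(unique(x$pairs$gene_B))))
  invisible(x)
}

# Orthologs of one species-A gene.
.orthologs_of <- function(omap, gene) {
  omap$pairs$gene_B[omap$pairs$gene_A == gene]
}

#' Size of the interaction universe for the conservation test
#'
#' The number of possible bait--prey interactions among the conserved
#' proteins is the number of conserved baits times the number of conserved
#' preys, minus \code{n_bp * (n_bp - 1) / 2} where \code{n_bp} is the number
#' of conserved baits that also act as preys, to avoid counting the same
#' undirected interaction twice.
#'
#' @param n_baits,n_preys numbers of conserved baits and preys.
#' @param n_bp number of conserved baits that also act as preys.
#' @return integer universe size.
#' @examples
#' universe_size(10, 90, 2)  # 899
#' @export
universe_size <- function(n_baits, n_preys, n_bp) {
  if (any(c(n_baits, n_preys, n_bp) < 0)) stop("inputs must be nonnegative")
  if (n_bp > min(n_baits, n_preys)) {
    stop("n_bp cannot exceed min(n_baits, n_preys)")
  }
  as.integer(n_baits * n_preys - n_bp * (n_bp - 1) / 2)
}

#' Project a network into another species by orthology
#'
#' An edge projects when both endpoints have at least one ortholog; all
#' ortholog combinations are emitted and deduplicated as undirected pairs.
#' Bait identifiers of the form \code{protein#k} (SH3 domains) are mapped at
#' the protein level.
#'
#' @param net an \code{"sh3_network"} or a data frame of edges with columns
#'   \code{bait_id}, \code{prey_id} (and \code{bait_type} when
#'   \code{sh3_only} is used).
#' @param omap an [ortholog_map()] from the network's species to the target
#'   species.
#' @param sh3_only restrict to edges with SH3-domain baits.
#' @return list with \code{projected} (data frame id_A, id_B of undirected
#'   species-B edges), \code{conserved_baits} / \code{conserved_preys}
#'   (species-A protein ids with at least one ortholog),
#'   \code{n_baits_conserved}, \code{n_preys_conserved} and \code{n_bp}
#'   (conserved baits that also occur as preys).
#' @export
project_by_orthology <- function(net, omap, sh3_only = TRUE) {
  edges <- if (inherits(net, "sh3_network")) net$edges else net
  stopifnot(inherits(omap, "ortholog_map"))
  if (sh3_only && "bait_type" %in% names(edges)) {
    edges <- edges[edges$bait_type == "sh3_domain", , drop = FALSE]
  }
  bait_prot <- domain_protein(edges$bait_id)
  has_orth <- unique(omap$pairs$gene_A)

  baits <- unique(bait_prot)
  preys <- unique(edges$prey_id)
  conserved_baits <- sort(intersect(baits, has_orth))
  conserved_preys <- sort(intersect(preys, has_orth))
  n_bp <- length(intersect(conserved_baits, conserved_preys))

  proj <- vector("list", nrow(edges))
  for (i in seq_len(nrow(edges))) {
    ob <- .orthologs_of(omap, bait_prot[i])
    op <- .orthologs_of(omap, edges$prey_id[i])
    if (length(ob) && length(op)) {
      g <- expand.grid(id_A = ob, id_B = op, stringsAsFactors = FALSE)
      proj[[i]] <- g
    }
  }
  proj <- do.call(rbind, proj)
  if (is.null(proj)) {
    proj <- data.frame(id_A = character(), id_B = character(),
                       stringsAsFactors = FALSE)
  } else {
    proj <- proj[proj$id_A != proj$id_B, , drop = FALSE]  # drop self edges
    proj <- proj[!duplicated(undirected_key(proj$id_A, proj$id_B)), ,
                 drop = FALSE]
    rownames(proj) <- NULL
  }
  list(projected = proj,
       conserved_baits = conserved_baits,
       conserved_preys = conserved_preys,
       n_baits_conserved = length(conserved_baits),
       n_preys_conserved = length(conserved_preys),
       n_bp = n_bp)
}

#' Test interaction conservation against a reference interactome
#'
#' Counts the overlap between a projected edge set and a reference edge set
#' (edges identified by their unordered endpoint pair) and computes the
#' one-sided hypergeometric upper tail P(X >= overlap) with population size
#' \code{universe}, \code{|reference|} successes and \code{|projected|}
#' draws; this is the one-sided Fisher's exact test of the 2x2 overlap table.
#'
#' @param projected data frame (id_A, id_B) of projected edges, or the list
#'   returned by [project_by_orthology()].
#' @param reference data frame (id_A, id_B) of reference edges, restricted by
#'   the caller to the conserved-protein universe.
#' @param universe total number of possible interactions (see
#'   [universe_size()]).
#' @return object of class \code{"conservation_result"}: list with
#'   \code{n_A_interactions} (draws), \code{n_B_interactions} (successes),
#'   \code{n_overlap}, \code{universe} and \code{p_value}.
#' @export
conservation_test <- function(projected, reference, universe) {
  if (is.list(projected) && !is.data.frame(projected) &&
      !is.null(projected$projected)) {
    projected <- projected$projected
  }
  pk <- unique(undirected_key(projected$id_A, projected$id_B))
  rk <- unique(undirected_key(reference$id_A, reference$id_B))
  draws <- length(pk); succ <- length(rk)
  overlap <- length(intersect(pk, rk))
  if (universe < max(draws, succ)) {
    stop("universe (", universe, ") smaller than an interaction count")
  }
  p <- stats::phyper(overlap - 1, succ, universe - succ, draws,
                     lower.tail = FALSE)
  structure(
    list(n_A_interactions = draws, n_B_interactions = succ,
         n_overlap = overlap, universe = universe, p_value = p),
    class = "conservation_result"
  )
}

#' @export
print.conservation_result <- function(x, ...) {
  cat(sprintf(paste0("Interaction conservation: overlap %d of %d projected ",
                     "vs %d reference (universe %d), one-sided P = %.3g\n"),
              x$n_overlap, x$n_A_interactions, x$n_B_interactions,
              x$universe, x$p_value))
  invisible(x)
}
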