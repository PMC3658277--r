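# Motif-site clustering, the motifs/domains vs interaction-degree table,
# and the competition-avoidance correlation statistics.

#' Cluster predicted binding sites into well-separated representative sites
#'
#' Neighboring predicted motifs closer than \code{min_sep} residues (start to
#' start) describe the same physical binding site. Scanning left to right,
#' consecutive hits whose starts are less than \code{min_sep} apart are
#' chained into one run, and the highest-scoring hit of each run is kept as
#' the site representative (first on ties).
#'
#' @param hits data frame of motif hits on one protein (columns \code{start}
#'   and \code{score}), sorted or sortable by start.
#' @param min_sep minimal start-to-start distance (residues) between two
#'   accepted neighboring sites.
#' @return data frame of accepted sites, sorted by start.
#' @export
cluster_motif_sites <- function(hits, min_sep = 10) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order(hits$start), , drop = FALSE]
  run <- cumsum(c(1L, as.integer(diff(hits$start) >= min_sep)))
  keep <- unlist(lapply(split(seq_len(nrow(hits)), run), function(i) {
    i[which.max(hits$score[i])]
  }), use.names = FALSE)
  out <- hits[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tabulate clustered binding motifs and interaction partners
#'
#' Restricts the network to interactions whose bait domain has a PWM and
#' whose prey carries at least one binding motif (score >= \code{T}) under
#' some interacting domain's PWM, then tabulates, per prey, the number of
#' clustered motif sites (union of hits over all interacting domains'
#' PWMs) and the number of distinct SH3-containing interactor proteins;
#' and per SH3 protein, its number of distinct SH3 domains among the baits
#' and its interaction degree. Domain pairs binding one prey are flagged
#' \emph{competitive} when their accepted sites overlap in residue span and
#' \emph{coincident} otherwise.
#'
#' @param net an \code{"sh3_network"} or edge data frame (bait_id, prey_id).
#' @param pwms named list of \code{"sh3_pwm"} objects keyed by bait domain id.
#' @param proteome named character vector of prey sequences.
#' @param T binding-motif score threshold.
#' @param min_sep passed to [cluster_motif_sites()].
#' @return object of class \code{"motif_cluster_table"}: list with
#'   \code{prey_table} (prey_id, n_motifs, n_partners, degree),
#'   \code{bait_table} (protein_id, n_domains, degree), \code{pairs}
#'   (prey_id, domain_1, domain_2, relationship), and \code{n_ppis} mapped
#'   at binding-site detail.
#' @export
build_cluster_table <- function(net, pwms, proteome, T = 1000, min_sep = 10) {
  edges <- if (inherits(net, "sh3_network")) net$edges else net
  edges <- edges[edges$bait_id %in% names(pwms) &
                   edges$prey_id %in% names(proteome), , drop = FALSE]

  prey_rows <- list(); pair_rows <- list(); mapped_edges <- 0L
  for (prey in unique(edges$prey_id)) {
    doms <- unique(edges$bait_id[edges$prey_id == prey])
    per_dom <- lapply(doms, function(d) {
      h <- find_binding_motifs(pwms[[d]], proteome[[prey]], T = T,
                               protein_id = prey)
      if (nrow(h)) h$domain_id <- d
      h
    })
    names(per_dom) <- doms
    with_motif <- doms[vapply(per_dom, nrow, integer(1)) > 0L]
    if (length(with_motif) == 0L) next
    mapped_edges <- mapped_edges + length(with_motif)

    all_hits <- do.call(rbind, per_dom[with_motif])
    clustered <- cluster_motif_sites(all_hits, min_sep)
    partners <- unique(domain_protein(with_motif))
    prey_rows[[prey]] <- data.frame(
      prey_id = prey, n_motifs = nrow(clustered),
      n_partners = length(partners), degree = length(with_motif),
      stringsAsFactors = FALSE)

    # competitive vs coincident domain pairs on this prey
    if (length(with_motif) >= 2L) {
      sites <- lapply(per_dom[with_motif],
                      function(h) cluster_motif_sites(h, min_sep))
      cmb <- utils::combn(with_motif, 2L)
      for (ci in seq_len(ncol(cmb))) {
        s1 <- sites[[cmb[1L, ci]]]; s2 <- sites[[cmb[2L, ci]]]
        overlap <- any(outer(seq_len(nrow(s1)), seq_len(nrow(s2)),
                             Vectorize(function(i, j) {
                               s1$start[i] <= s2$end[j] && s2$start[j] <= s1$end[i]
                             })))
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          prey_id = prey, domain_1 = cmb[1L, ci], domain_2 = cmb[2L, ci],
          relationship = if (overlap) "competitive" else "coincident",
          stringsAsFactors = FALSE)
      }
    }
  }
  prey_table <- do.call(rbind, prey_rows)
  if (is.null(prey_table)) {
    prey_table <- data.frame(prey_id = character(), n_motifs = integer(),
                             n_partners = integer(), degree = integer())
  }
  rownames(prey_table) <- NULL

  bait_prot <- domain_protein(edges$bait_id)
  bait_table <- data.frame(
    protein_id = sort(unique(bait_prot)),
    stringsAsFactors = FALSE)
  bait_table$n_domains <- vapply(bait_table$protein_id, function(p) {
    length(unique(edges$bait_id[bait_prot == p]))
  }, integer(1))
  bait_table$degree <- vapply(bait_table$protein_id, function(p) {
    length(unique(edges$prey_id[bait_prot == p]))
  }, integer(1))
  rownames(bait_table) <- NULL

  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(prey_id = character(), domain_1 = character(),
               domain_2 = character(), relationship = character())
  structure(list(prey_table = prey_table, bait_table = bait_table,
                 pairs = pairs, n_ppis = mapped_edges),
            class = "motif_cluster_table")
}

#' @export
print.motif_cluster_table <- function(x, ...) {
  cat(sprintf(paste0("Motif cluster table: %d PPIs mapped at binding-site ",
                     "detail, %d preys, %d SH3 proteins\n"),
              x$n_ppis, nrow(x$prey_table), nrow(x$bait_table)))
  invisible(x)
}

# All permutations of 1..n (n small), as an n! x n matrix.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Spearman rank association with exact small-sample p-value
#'
#' Spearman's rank correlation with average ranks for ties. The two-sided
#' p-value is computed by exhaustive permutation enumeration for n <= 9 and
#' by the t approximation \code{t = rho * sqrt((n-2)/(1-rho^2))} otherwise.
#'
#' @param x,y equal-length numeric vectors, n >= 3; constant vectors are an
#'   error (rho undefined).
#' @return list with \code{rho}, \code{rho_squared}, \code{p_value},
#'   \code{n} and \code{method}.
#' @export
spearman_association <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3L) stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rho is undefined for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    perms <- .permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rho_perm <- as.vector((matrix(ryc[perms], nrow(perms)) %*% rxc) / denom)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, rho_squared = rho^2, p_value = p, n = n, method = method)
}
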