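# PWM-to-PWM distance, alignment-corrected similarity, and the
# average-linkage specificity tree.

# Sum of squared differences between two probability columns; `NULL`
# represents a non-overlapping position, treated as the uniform vector.
.col_dist2 <- function(p1, p2) {
  u <- rep(1 / 20, 20)
  if (is.null(p1)) p1 <- u
  if (is.null(p2)) p2 <- u
  sum((p1 - p2)^2)
}

#' Aligned and unaligned Euclidean distance between two PWMs
#'
#' For every relative offset of the two matrices with at least
#' \code{min_overlap} overlapping columns, the two PWMs are compared over the
#' union of their positions; where one PWM has no column the uniform
#' distribution (all residues equally weighted) is substituted. The distance
#' for one alignment of union length n is
#' \code{sqrt( (1/n) * sum_cols sum_residues (p1 - p2)^2 )}, and
#' \code{d_aligned} is its minimum over offsets (the best alignment). The
#' unaligned distance \code{d_unaligned} uses zero overlap, i.e. union length
#' \code{m_a + m_b}, comparing every informative column to uniform; it
#' captures the background similarity of non-specific positions.
#'
#' @param a,b \code{"sh3_pwm"} objects.
#' @param min_overlap minimum number of overlapping columns per offset.
#' @return list with \code{d_aligned}, \code{d_unaligned}, \code{best_offset}
#'   (position of b's first column relative to a's, 0 = left-aligned; ties
#'   take the smallest offset).
#' @export
pwm_pair_distance <- function(a, b, min_overlap = 1L) {
  stopifnot(inherits(a, "sh3_pwm"), inherits(b, "sh3_pwm"), min_overlap >= 1L)
  ma <- a$m; mb <- b$m
  pa <- a$prob; pb <- b$prob

  d_un <- sqrt((sum(sweep(pa, 1, 1 / 20)^2) + sum(sweep(pb, 1, 1 / 20)^2)) /
                 (ma + mb))

  best <- Inf; best_offset <- NA_integer_
  for (off in seq.int(-(mb - min_overlap), ma - min_overlap)) {
    lo <- min(1L, off + 1L)
    hi <- max(ma, off + mb)
    n <- hi - lo + 1L
    tot <- 0
    for (u in lo:hi) {
      p1 <- if (u >= 1L && u <= ma) pa[, u] else NULL
      p2 <- if (u - off >= 1L && u - off <= mb) pb[, u - off] else NULL
      tot <- tot + .col_dist2(p1, p2)
    }
    d <- sqrt(tot / n)
    if (d < best) { best <- d; best_offset <- off }
  }
  list(d_aligned = best, d_unaligned = d_un, best_offset = best_offset)
}

#' Alignment-corrected similarity between two PWMs
#'
#' Defined as \code{(d_unaligned - d_aligned) / d_unaligned}, clamped to
#' [0, 1]: the fraction of the background (unaligned) distance removed by the
#' best alignment. Two uniform PWMs (\code{d_unaligned = 0}) are assigned
#' similarity 1.
#'
#' @inheritParams pwm_pair_distance
#' @return numeric similarity in [0, 1].
#' @export
pwm_similarity <- function(a, b, min_overlap = 1L) {
  d <- pwm_pair_distance(a, b, min_overlap)
  if (d$d_unaligned == 0) return(1)
  min(max((d$d_unaligned - d$d_aligned) / d$d_unaligned, 0), 1)
}

#' All-against-all PWM similarity matrix
#'
#' @param pwms list of \code{"sh3_pwm"} objects; names default to
#'   \code{domain_id} (with \code{/group_label} when set).
#' @param min_overlap passed to [pwm_pair_distance()].
#' @return object of class \code{"sh3_simmat"}: list with \code{ids},
#'   symmetric \code{sim} matrix (unit diagonal), and \code{offsets} matrix
#'   of best alignment offsets.
#' @export
similarity_matrix <- function(pwms, min_overlap = 1L) {
  if (is.null(names(pwms))) {
    names(pwms) <- vapply(pwms, function(p) {
      if (nzchar(p$group_label)) paste(p$domain_id, p$group_label, sep = "/")
      else p$domain_id
    }, character(1))
  }
  ids <- names(pwms)
  n <- length(pwms)
  sim <- diag(1, n); offsets <- matrix(0L, n, n)
  dimnames(sim) <- dimnames(offsets) <- list(ids, ids)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      d <- pwm_pair_distance(pwms[[i]], pwms[[j]], min_overlap)
      s <- if (d$d_unaligned == 0) 1 else
        min(max((d$d_unaligned - d$d_aligned) / d$d_unaligned, 0), 1)
      sim[i, j] <- sim[j, i] <- s
      offsets[i, j] <- offsets[j, i] <- d$best_offset
    }
  }
  structure(list(ids = ids, sim = sim, offsets = offsets),
            class = "sh3_simmat")
}

#' Write / read a similarity matrix as a tab-separated square table
#' @param simmat an \code{"sh3_simmat"}.
#' @param path file path.
#' @return \code{path} invisibly (writer); \code{"sh3_simmat"} (reader).
#' @export
write_similarity_matrix <- function(simmat, path) {
  utils::write.table(format(simmat$sim, digits = 10), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  structure(list(ids = rownames(m), sim = m,
                 offsets = matrix(NA_integer_, nrow(m), ncol(m))),
            class = "sh3_simmat")
}

#' Average-linkage specificity tree from a similarity matrix
#'
#' Clusters the specificity profiles by average-linkage hierarchical
#' clustering on the dissimilarity \code{1 - sim} and returns the tree in
#' Newick text. Identifiers are sorted lexicographically before clustering,
#' which fixes the merge order for tied heights and makes the output
#' invariant to the input ordering.
#'
#' @param simmat an \code{"sh3_simmat"} with n >= 2 profiles.
#' @return Newick string (with branch lengths equal to merge heights); parses
#'   with \code{ape::read.tree}.
#' @export
build_specificity_tree <- function(simmat) {
  stopifnot(inherits(simmat, "sh3_simmat"))
  n <- length(simmat$ids)
  if (n < 2L) stop("at least two profiles are required to build a tree")
  ord <- order(simmat$ids)
  d <- stats::as.dist(1 - simmat$sim[ord, ord])
  hc <- stats::hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy)
}
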