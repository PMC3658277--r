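# Position weight matrices of SH3 binding specificity: construction from
# aligned phage-display peptides, peptide scoring, protein scanning, and
# proteome-wide ranking.

#' Aligned phage-display peptide set
#'
#' Container for the pre-aligned peptides selected for one SH3 domain (or one
#' specificity group of a dual-specificity domain). Peptides must be of equal
#' length over the 20 amino acids plus the gap character \code{"-"}.
#'
#' @param domain_id identifier of the SH3 domain, e.g. \code{"ABI-1#1"}.
#' @param peptides character vector of equal-length aligned peptides.
#' @param group_label specificity-group tag; dual-specificity domains are
#'   split into two sets with different labels. Default \code{""}.
#' @return An object of class \code{"aligned_peptides"}.
#' @export
aligned_peptides <- function(domain_id, peptides, group_label = "") {
  if (length(peptides) < 1L) stop("at least one peptide is required")
  peptides <- toupper(as.character(peptides))
  lens <- nchar(peptides)
  if (length(unique(lens)) != 1L) stop("all peptides must have identical length")
  if (lens[1L] < 1L) stop("peptide length must be >= 1")
  ok <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "-]+$"), peptides)
  if (!all(ok)) {
    stop("invalid characters in peptides: ", paste(peptides[!ok], collapse = ", "))
  }
  structure(
    list(domain_id = as.character(domain_id),
         group_label = as.character(group_label),
         peptides = peptides),
    class = "aligned_peptides"
  )
}

#' @export
print.aligned_peptides <- function(x, ...) {
  cat(sprintf("Aligned peptide set: %s%s, %d peptides of length %d\n",
              x$domain_id,
              if (nzchar(x$group_label)) paste0(" [", x$group_label, "]") else "",
              length(x$peptides), nchar(x$peptides[1L])))
  invisible(x)
}

#' Construct a PWM object
#'
#' Low-level constructor; most users build PWMs with [build_pwm()] or read
#' them with [read_pwm()]. Probabilities are stored as a 20 x m matrix (rows =
#' amino acids, alphabetical) and odds are normalized so that a uniform column
#' contributes a factor of 1 to any peptide score.
#'
#' @param prob 20 x m numeric matrix of per-position amino-acid probabilities.
#' @param domain_id,group_label identifiers (see [aligned_peptides()]).
#' @param trim_record list with integer vectors \code{left} and \code{right}:
#'   original column indices removed from each flank.
#' @param provenance free-text library tag (e.g. \code{"X12"}).
#' @param tol tolerance for the column-sum check; file-derived matrices stored
#'   at fixed precision use a looser tolerance than freshly built ones.
#' @return An object of class \code{"sh3_pwm"} with elements \code{domain_id},
#'   \code{group_label}, \code{m}, \code{prob}, \code{odds} (= 20 * prob),
#'   \code{trim_record}, \code{provenance}.
#' @export
new_pwm <- function(prob, domain_id = "", group_label = "",
                    trim_record = list(left = integer(), right = integer()),
                    provenance = "", tol = 1e-9) {
  prob <- as.matrix(prob)
  if (nrow(prob) != 20L) stop("prob must have 20 rows (amino acids)")
  if (ncol(prob) < 1L) stop("PWM must have at least one column")
  if (any(prob < 0)) stop("probabilities must be nonnegative")
  cs <- colSums(prob)
  if (any(abs(cs - 1) > max(tol, 1e-12))) {
    stop("each probability column must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  }
  rownames(prob) <- AA_ALPHABET
  colnames(prob) <- as.character(seq_len(ncol(prob)))
  structure(
    list(domain_id = as.character(domain_id),
         group_label = as.character(group_label),
         m = ncol(prob),
         prob = prob,
         odds = 20 * prob,
         trim_record = trim_record,
         provenance = as.character(provenance)),
    class = "sh3_pwm"
  )
}

#' @export
print.sh3_pwm <- function(x, ...) {
  cons <- paste(AA_ALPHABET[apply(x$prob, 2, which.max)], collapse = "")
  cat(sprintf("SH3 PWM %s%s: %d columns, consensus %s\n",
              x$domain_id,
              if (nzchar(x$group_label)) paste0(" [", x$group_label, "]") else "",
              x$m, cons))
  invisible(x)
}

#' A PWM with every column uniform
#'
#' Completely non-specific specificity model; scores every peptide exactly 1.
#'
#' @param m number of columns.
#' @inheritParams new_pwm
#' @return An \code{"sh3_pwm"}.
#' @export
uniform_pwm <- function(m, domain_id = "uniform", group_label = "") {
  new_pwm(matrix(1 / 20, nrow = 20, ncol = m),
          domain_id = domain_id, group_label = group_label)
}

# Raw counts per column with gap treatment: a gap adds 1/20 of a count to
# every residue of its column (gaps are non-specific amino acids).
.pwm_raw_counts <- function(peptides) {
  m <- nchar(peptides[1L])
  chars <- matrix(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(peptides), ncol = m, byrow = TRUE)
  counts <- matrix(0, nrow = 20L, ncol = m, dimnames = list(AA_ALPHABET, NULL))
  for (j in seq_len(m)) {
    tab <- table(factor(chars[, j], levels = c(AA_ALPHABET, GAP_CHAR)))
    counts[, j] <- as.numeric(tab[AA_ALPHABET]) + as.numeric(tab[GAP_CHAR]) / 20
  }
  counts
}

#' Build a binding-specificity PWM from aligned phage peptides
#'
#' Converts an aligned peptide set into a position weight matrix in five
#' steps: (1) raw per-column residue counts, a gap contributing 1/20 of a
#' count to every residue of its column; (2) an entropy-proportional
#' pseudocount \code{kappa * H_j / ln(20)} added to every residue of column
#' \code{j}, where \code{H_j} is the Shannon entropy (natural log) of the raw
#' column frequencies, so non-specific columns are smoothed toward uniform
#' while sharp columns are left essentially intact; (3) residues whose raw
#' count is not significantly above the background frequency 1/20 (one-sided
#' binomial test, p > \code{alpha}) have their values replaced by their joint
#' mean, preserving total column mass, to damp small fluctuations of
#' non-specific residues; (4) renormalization to probabilities, with odds =
#' 20 * prob so a completely non-specific PWM scores 1 for any peptide;
#' (5) iterative removal of low-specificity flanking columns whose normalized
#' entropy \code{H_j / ln(20)} is at or above \code{trim_threshold} (interior
#' columns are never removed; at least one column is always retained).
#'
#' @param peps an [aligned_peptides()] object.
#' @param alpha significance level of the binomial background test.
#' @param kappa pseudocount scale; 0 disables the pseudocount.
#' @param trim_threshold normalized-entropy cutoff in [0, 1] for flank
#'   trimming (high entropy = low specificity).
#' @param provenance library tag copied into the PWM.
#' @return An \code{"sh3_pwm"} object.
#' @examples
#' peps <- aligned_peptides("toy", rep("PPLP", 50))
#' pwm <- build_pwm(peps)
#' pwm$odds["P", 1]  # 20
#' @export
build_pwm <- function(peps, alpha = 0.05, kappa = 1.0, trim_threshold = 0.76,
                      provenance = "") {
  stopifnot(inherits(peps, "aligned_peptides"))
  n <- length(peps$peptides)
  counts <- .pwm_raw_counts(peps$peptides)
  m <- ncol(counts)

  # entropy-proportional pseudocount per column
  H_raw <- apply(counts, 2, shannon_entropy)
  beta <- kappa * H_raw / log(20)
  counts2 <- sweep(counts, 2, beta, "+")

  # background significance: one-sided binomial test of the raw integer count
  # (gap-derived fractions rounded down) against p = 1/20
  for (j in seq_len(m)) {
    n_int <- floor(counts[, j])
    pvals <- stats::pbinom(n_int - 1, size = n, prob = 1 / 20, lower.tail = FALSE)
    nonsig <- pvals > alpha
    if (any(nonsig)) counts2[nonsig, j] <- mean(counts2[nonsig, j])
  }

  prob <- sweep(counts2, 2, colSums(counts2), "/")

  # flank trimming on normalized entropy of the final probabilities
  h <- apply(prob, 2, shannon_entropy) / log(20)
  left <- 1L; right <- m
  while (left < right && h[left] >= trim_threshold) left <- left + 1L
  while (right > left && h[right] >= trim_threshold) right <- right - 1L
  if (left == right && h[left] >= trim_threshold) {
    # every column is non-specific at the threshold; keep the single most
    # specific (minimum-entropy) column, first index on ties
    keep <- which.min(h)
    warning("all PWM columns exceed the trimming threshold; retaining the ",
            "minimum-entropy column (", keep, ")")
    left <- right <- keep
  }
  trim_record <- list(left = seq_len(left - 1L),
                      right = if (right < m) seq.int(right + 1L, m) else integer())

  new_pwm(prob[, left:right, drop = FALSE],
          domain_id = peps$domain_id, group_label = peps$group_label,
          trim_record = trim_record, provenance = provenance)
}

#' Score a peptide against a PWM
#'
#' The score of an m-mer under an m-column PWM is the product over positions
#' of the odds \code{20 * p_ij}; equivalently the probability product
#' normalized by \code{20^-m}. A completely non-specific (uniform) PWM gives
#' a score of 1 for any peptide. Residues outside the 20-letter alphabet
#' (e.g. \code{X}) contribute a neutral factor of 1.
#'
#' @param pwm an \code{"sh3_pwm"}.
#' @param peptide character scalar of length \code{pwm$m}.
#' @return nonnegative numeric score.
#' @export
score_peptide <- function(pwm, peptide) {
  stopifnot(inherits(pwm, "sh3_pwm"))
  peptide <- toupper(peptide)
  if (nchar(peptide) != pwm$m) {
    stop("peptide length ", nchar(peptide), " does not match PWM length ", pwm$m)
  }
  idx <- aa_index(split_chars(peptide))
  f <- pwm$odds[cbind(idx, seq_len(pwm$m))]
  f[is.na(idx)] <- 1  # unknown residues are neutral
  prod(f)
}

# Scores of all full windows of width pwm$m along an integer-indexed protein.
# Vectorized over windows, looping over the m columns.
.window_scores <- function(pwm, idx) {
  m <- pwm$m
  nw <- length(idx) - m + 1L
  if (nw < 1L) return(numeric(0))
  odds_ext <- rbind(pwm$odds, 1)       # row 21: neutral unknown residue
  idx[is.na(idx)] <- 21L
  scores <- rep(1, nw)
  for (j in seq_len(m)) {
    scores <- scores * odds_ext[cbind(idx[seq_len(nw) + j - 1L], j)]
  }
  scores
}

.hit_frame <- function(protein_id, starts, m, protein, scores) {
  data.frame(
    protein_id = rep(protein_id, length(starts)),
    start = as.integer(starts),
    end = as.integer(starts + m - 1L),
    peptide = if (length(starts)) substring(protein, starts, starts + m - 1L)
              else character(),
    score = as.numeric(scores),
    stringsAsFactors = FALSE
  )
}

#' Scan a protein sequence with a PWM
#'
#' Slides all full windows of width \code{pwm$m} along the protein and scores
#' each with [score_peptide()] semantics. The protein score is the score of
#' the highest scoring window; ties are broken by the smallest start.
#' Coordinates are 1-based and inclusive.
#'
#' @param pwm an \code{"sh3_pwm"}.
#' @param protein character scalar amino-acid sequence.
#' @param protein_id identifier recorded in the hits.
#' @return list with \code{best} (1-row data frame: protein_id, start, end,
#'   peptide, score; score 0 and no window when the protein is shorter than
#'   the PWM) and \code{windows} (data frame of all windows).
#' @export
scan_protein <- function(pwm, protein, protein_id = "protein") {
  stopifnot(inherits(pwm, "sh3_pwm"), nchar(protein) >= 1L)
  protein <- toupper(protein)
  idx <- aa_index(split_chars(protein))
  scores <- .window_scores(pwm, idx)
  if (length(scores) == 0L) {
    best <- data.frame(protein_id = protein_id, start = NA_integer_,
                       end = NA_integer_, peptide = NA_character_, score = 0,
                       stringsAsFactors = FALSE)
    return(list(best = best,
                windows = .hit_frame(protein_id, integer(), pwm$m, protein,
                                     numeric())))
  }
  windows <- .hit_frame(protein_id, seq_along(scores), pwm$m, protein, scores)
  list(best = windows[which.max(scores), , drop = FALSE], windows = windows)
}

#' Rank all proteome proteins by their best PWM score
#'
#' Assigns each protein its best-window score under the PWM and the
#' genome-wide rank (1 = highest score). Tied scores receive the minimum rank
#' of the tied block.
#'
#' @param pwm an \code{"sh3_pwm"}.
#' @param proteome named character vector of sequences, or a
#'   \code{Biostrings::AAStringSet}.
#' @return data frame (protein_id, score, rank), ordered by rank then id.
#' @export
rank_in_proteome <- function(pwm, proteome) {
  proteome <- .as_seq_vector(proteome)
  if (length(proteome) == 0L) stop("proteome is empty")
  scores <- vapply(seq_along(proteome), function(i) {
    scan_protein(pwm, proteome[[i]], names(proteome)[i])$best$score
  }, numeric(1))
  res <- data.frame(protein_id = names(proteome), score = scores,
                    rank = rank(-scores, ties.method = "min"),
                    stringsAsFactors = FALSE)
  res[order(res$rank, res$protein_id), , drop = FALSE]
}

#' Predict binding motifs on a protein
#'
#' Binding motifs are windows whose PWM score reaches the threshold \code{T}
#' (default 1000); all qualifying windows are returned, sorted by start,
#' since a protein can carry more than one ligand motif.
#'
#' @inheritParams scan_protein
#' @param T score threshold defining a bona fide binding motif.
#' @return data frame of qualifying windows (possibly empty), sorted by start.
#' @export
find_binding_motifs <- function(pwm, protein, T = 1000, protein_id = "protein") {
  sc <- scan_protein(pwm, protein, protein_id)
  hits <- sc$windows[sc$windows$score >= T, , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Accept either a named character vector or an AAStringSet.
.as_seq_vector <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x))) stop("proteome sequences must be named")
    return(x)
  }
  stop("unsupported sequence container: ", class(x)[1L])
}
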