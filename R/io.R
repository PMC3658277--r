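# Readers and writers for the interchange formats: aligned peptide tables,
# PWM matrices, FASTA proteomes, motif-hit tables, edge tables, ortholog
# maps, and reference PPI sets. All tabular formats are plain tab-separated
# text with a header row.

#' Read aligned phage peptides from a tab-separated table
#'
#' Format: columns \code{domain_id}, \code{group_label}, \code{peptide}, one
#' row per peptide. Returns one [aligned_peptides()] set per
#' (domain_id, group_label) combination.
#'
#' @param path file path.
#' @return named list of \code{"aligned_peptides"} objects; names are
#'   \code{domain_id} or \code{domain_id/group_label} when the label is
#'   non-empty.
#' @export
read_peptides <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  stopifnot(all(c("domain_id", "group_label", "peptide") %in% names(df)))
  key <- ifelse(nzchar(df$group_label),
                paste(df$domain_id, df$group_label, sep = "/"), df$domain_id)
  out <- lapply(split(df, key), function(d) {
    aligned_peptides(d$domain_id[1L], d$peptide, d$group_label[1L])
  })
  out[order(names(out))]
}

#' Write aligned peptide sets to a tab-separated table
#'
#' @param peps a single [aligned_peptides()] object or a list of them.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_peptides <- function(peps, path) {
  if (inherits(peps, "aligned_peptides")) peps <- list(peps)
  df <- do.call(rbind, lapply(peps, function(p) {
    data.frame(domain_id = p$domain_id, group_label = p$group_label,
               peptide = p$peptides, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a PWM to a tab-separated matrix file
#'
#' On-disk format: 20 rows (amino acids, alphabetical, first column
#' \code{aa}) by m probability columns headed by the column index, printed at
#' 6 decimals. [read_pwm()] round-trips this file bit-exactly.
#'
#' @param pwm an \code{"sh3_pwm"}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_pwm <- function(pwm, path) {
  stopifnot(inherits(pwm, "sh3_pwm"))
  mat <- matrix(sprintf("%.6f", pwm$prob), nrow = 20)
  df <- data.frame(aa = AA_ALPHABET, mat, stringsAsFactors = FALSE)
  names(df) <- c("aa", seq_len(pwm$m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PWM from a tab-separated matrix file
#'
#' Probabilities are taken exactly as stored (no renormalization), so
#' write/read/write round-trips are bit-identical at the 6-decimal format
#' precision; the column-sum invariant is checked at a tolerance matching
#' that precision.
#'
#' @param path file path.
#' @param domain_id,group_label identifiers to attach (default: file stem).
#' @return an \code{"sh3_pwm"}.
#' @export
read_pwm <- function(path, domain_id = NULL, group_label = "") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(names(df)[1L] == "aa", identical(df$aa, AA_ALPHABET))
  prob <- as.matrix(df[, -1L, drop = FALSE])
  mode(prob) <- "numeric"
  if (is.null(domain_id)) domain_id <- sub("\\.[^.]*$", "", basename(path))
  new_pwm(prob, domain_id = domain_id, group_label = group_label, tol = 2e-5)
}

#' Read a proteome from FASTA
#'
#' @param path FASTA file path.
#' @return named character vector of amino-acid sequences.
#' @export
read_proteome <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write a proteome to FASTA
#'
#' @param proteome named character vector of sequences.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_proteome <- function(proteome, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteome), path)
  invisible(path)
}

#' Write motif hits to a tab-separated table
#'
#' Columns: protein_id, start, end, peptide, score, and rank when present.
#'
#' @param hits data frame of motif hits as produced by [find_binding_motifs()].
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_motif_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read motif hits written by [write_motif_hits()]
#' @param path file path.
#' @return data frame.
#' @export
read_motif_hits <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read an ortholog map
#'
#' Tab-separated with header (gene_A, gene_B, source); many-to-many pairs
#' permitted, duplicates collapsed (the union over sources is taken).
#'
#' @param path file path.
#' @return an [ortholog_map()].
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_A", "gene_B") %in% names(df)))
  ortholog_map(df$gene_A, df$gene_B)
}

#' Write an ortholog map
#' @param omap an [ortholog_map()].
#' @param path file path.
#' @param source source tag written in the third column.
#' @return \code{path}, invisibly.
#' @export
write_ortholog_map <- function(omap, path, source = "synthetic") {
  df <- data.frame(gene_A = omap$pairs$gene_A, gene_B = omap$pairs$gene_B,
                   source = source, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference PPI edge list
#'
#' Tab-separated with header (id_A, id_B, source); edges are undirected.
#'
#' @param path file path.
#' @return data frame (id_A, id_B) with duplicates (including reversed
#'   duplicates) removed.
#' @export
read_reference_ppis <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id_A", "id_B") %in% names(df)))
  key <- undirected_key(df$id_A, df$id_B)
  df[!duplicated(key), c("id_A", "id_B"), drop = FALSE]
}

#' Write a network edge table
#'
#' Serializes the edges of an \code{"sh3_network"} (or a compatible data
#' frame) in the tab-separated candidate/filtered edge format with header
#' (bait_id, bait_type, prey_id, colony_count, evidence_class, pwm_score,
#' best_peptide, start, rank); absent optional columns are written as NA.
#'
#' @param net an \code{"sh3_network"} or data frame of edges.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(net, path) {
  edges <- if (inherits(net, "sh3_network")) net$edges else net
  cols <- c("bait_id", "bait_type", "prey_id", "colony_count",
            "evidence_class", "pwm_score", "best_peptide", "start", "rank")
  for (cc in setdiff(cols, names(edges))) edges[[cc]] <- NA
  utils::write.table(edges[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a network edge table written by [write_network()]
#' @param path file path.
#' @return data frame of edges.
#' @export
read_network <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read gene/protein id lists (one id per line)
#' @param path file path.
#' @return character vector.
#' @export
read_id_list <- function(path) {
  ids <- readLines(path)
  ids[nzchar(trimws(ids))]
}
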