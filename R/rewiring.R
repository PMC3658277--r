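# Binding-site-resolution rewiring classification: motif conservation by
# ungapped best match, domain-specificity conservation by PWM similarity
# with sequence-identity fallback, and the three rewiring scenarios.

#' Best ungapped match of a motif in an ortholog sequence
#'
#' Slides the motif ungapped along the sequence and reports the maximal
#' fraction of identical aligned residues. When the sequence is shorter than
#' the motif, every overlapping placement is considered and overhanging
#' positions count as mismatches. Ties are broken by the smallest start.
#'
#' @param motif peptide to locate (length >= 1).
#' @param ortholog_seq sequence searched.
#' @return list with \code{identity} (fraction in [0, 1]) and \code{start}
#'   (1-based position of the motif's first residue; can be < 1 for
#'   overhanging placements on short sequences).
#' @export
best_motif_match <- function(motif, ortholog_seq) {
  stopifnot(nchar(motif) >= 1L, nchar(ortholog_seq) >= 1L)
  mc <- split_chars(toupper(motif))
  sc <- split_chars(toupper(ortholog_seq))
  m <- length(mc); L <- length(sc)
  starts <- if (L >= m) seq_len(L - m + 1L) else seq.int(2L - m, L)
  best_id <- -1; best_start <- NA_integer_
  for (s in starts) {
    pos <- s + seq_len(m) - 1L
    ok <- pos >= 1L & pos <= L
    matches <- sum(mc[ok] == sc[pos[ok]])
    ident <- matches / m
    if (ident > best_id) { best_id <- ident; best_start <- s }
  }
  list(identity = best_id, start = best_start)
}

#' Ungapped sliding sequence identity between two sequences
#'
#' Identity of the best ungapped alignment of the shorter sequence within
#' the longer, as a fraction of the shorter length. Used as the fallback
#' measure of SH3 domain conservation when no specificity profile exists for
#' one of the orthologous domains.
#'
#' @param a,b amino-acid sequences.
#' @return fraction in [0, 1].
#' @export
sequence_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  best_motif_match(a, b)$identity
}

#' Classify a non-conserved interaction into a rewiring scenario
#'
#' For an SH3-mediated interaction observed in one species but not in the
#' other (and not in the published cross-species reference), determines
#' whether the domain specificity and the ligand binding site are conserved
#' in the orthologs, and assigns one of the rewiring scenarios:
#' \describe{
#'   \item{\code{"i"}}{ligand motif conserved, domain specificity (or the
#'     SH3 domain itself) not conserved;}
#'   \item{\code{"ii"}}{domain specificity conserved, binding motif not
#'     found in the ortholog of the target;}
#'   \item{\code{"iii"}}{neither conserved;}
#'   \item{\code{"conserved_both"}}{both conserved (the interaction was lost
#'     for other reasons);}
#'   \item{\code{"unmappable"}}{no specificity profile for the source
#'     domain, no predicted motif reaching the score threshold, or a missing
#'     ortholog/sequence, so the interaction cannot be mapped at binding-site
#'     resolution.}
#' }
#'
#' Specificity conservation prefers PWM similarity when profiles exist for
#' both orthologous domains (threshold \code{sim_threshold}); otherwise it
#' falls back to ungapped domain sequence identity (threshold
#' \code{id_threshold}). An ortholog protein without any SH3 domain is not
#' conserved. Motif conservation requires some predicted motif (score >=
#' \code{T}) on the target whose best ungapped match in an ortholog of the
#' target reaches \code{id_threshold} identity.
#'
#' @param interaction list with \code{domain_id} (source-species SH3 domain,
#'   \code{protein#k}) and \code{target_id} (source-species target protein).
#' @param pwms list with named PWM lists \code{source} and \code{target}
#'   (keyed by domain id in the respective species).
#' @param omap [ortholog_map()] from source species to target species.
#' @param sequences list with named sequence vectors \code{source} and
#'   \code{target} (full-length proteins).
#' @param domain_seqs optional list with named vectors \code{source} and
#'   \code{target} of SH3 domain sequences (keyed by domain id), used by the
#'   sequence-identity fallback.
#' @param sim_threshold PWM similarity threshold for specificity conservation.
#' @param id_threshold sequence identity threshold for motif/domain
#'   conservation.
#' @param T PWM score threshold defining binding motifs.
#' @return object of class \code{"rewiring_call"}: list with
#'   \code{interaction}, logicals \code{specificity_conserved} and
#'   \code{motif_conserved}, \code{scenario}, \code{best_motif},
#'   \code{best_match}, \code{identity}, and \code{note} for unmappable
#'   calls.
#' @export
classify_rewiring <- function(interaction, pwms, omap, sequences,
                              domain_seqs = NULL, sim_threshold = 0.5,
                              id_threshold = 0.5, T = 1000) {
  call_out <- function(spec, motif, scenario, best_motif = NA_character_,
                       best_match = NA_character_, identity = NA_real_,
                       note = "") {
    structure(list(interaction = interaction,
                   specificity_conserved = spec, motif_conserved = motif,
                   scenario = scenario, best_motif = best_motif,
                   best_match = best_match, identity = identity, note = note),
              class = "rewiring_call")
  }
  did <- interaction$domain_id
  tid <- interaction$target_id

  pwm_s <- pwms$source[[did]]
  if (is.null(pwm_s)) {
    return(call_out(NA, NA, "unmappable", note = "no PWM for source domain"))
  }
  tseq <- sequences$source[[tid]]
  if (is.null(tseq) || is.na(tseq)) {
    return(call_out(NA, NA, "unmappable", note = "missing target sequence"))
  }
  motifs <- find_binding_motifs(pwm_s, tseq, T = T, protein_id = tid)
  if (nrow(motifs) == 0L) {
    return(call_out(NA, NA, "unmappable",
                    note = "no motif reaches the score threshold"))
  }

  # motif conservation: best match of any predicted motif in any target
  # ortholog of the interacting protein
  orth_t <- .orthologs_of(omap, tid)
  orth_t_seqs <- sequences$target[intersect(orth_t, names(sequences$target))]
  if (length(orth_t_seqs) == 0L) {
    return(call_out(NA, NA, "unmappable",
                    note = "no ortholog sequence for target"))
  }
  best <- list(identity = -1, motif = NA_character_, match = NA_character_)
  for (pep in motifs$peptide) {
    for (oseq in orth_t_seqs) {
      bm <- best_motif_match(pep, oseq)
      if (bm$identity > best$identity) {
        s <- max(bm$start, 1L)
        e <- min(bm$start + nchar(pep) - 1L, nchar(oseq))
        best <- list(identity = bm$identity, motif = pep,
                     match = substr(oseq, s, e))
      }
    }
  }
  motif_conserved <- best$identity >= id_threshold

  # specificity conservation of the domain in the other species
  dprot <- domain_protein(did)
  orth_d <- .orthologs_of(omap, dprot)
  specificity_conserved <- FALSE
  if (length(orth_d)) {
    orth_domains <- names(pwms$target)[domain_protein(names(pwms$target))
                                       %in% orth_d]
    if (length(orth_domains)) {
      sims <- vapply(orth_domains, function(od) {
        pwm_similarity(pwm_s, pwms$target[[od]])
      }, numeric(1))
      specificity_conserved <- max(sims) >= sim_threshold
    } else if (!is.null(domain_seqs)) {
      # fallback: ungapped domain sequence identity
      ds <- domain_seqs$source[[did]]
      od_ids <- names(domain_seqs$target)[domain_protein(names(domain_seqs$target))
                                          %in% orth_d]
      if (!is.null(ds) && length(od_ids)) {
        ids <- vapply(od_ids, function(od) {
          sequence_identity(ds, domain_seqs$target[[od]])
        }, numeric(1))
        specificity_conserved <- max(ids) >= id_threshold
      }
      # no SH3 domain in any ortholog: specificity not conserved
    }
  }

  scenario <- if (specificity_conserved && motif_conserved) "conserved_both"
    else if (motif_conserved) "i"
    else if (specificity_conserved) "ii"
    else "iii"
  call_out(specificity_conserved, motif_conserved, scenario,
           best_motif = best$motif, best_match = best$match,
           identity = best$identity)
}

#' @export
print.rewiring_call <- function(x, ...) {
  cat(sprintf("Rewiring call %s -> %s: scenario %s\n",
              x$interaction$domain_id, x$interaction$target_id, x$scenario))
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  if (!is.na(x$identity)) {
    cat(sprintf("  motif %s, best match %s, identity %.2f\n",
                x$best_motif, x$best_match, x$identity))
  }
  invisible(x)
}

#' Tabulate rewiring calls for a set of interactions
#'
#' @param interactions data frame with columns \code{domain_id},
#'   \code{target_id}.
#' @inheritParams classify_rewiring
#' @return data frame mirroring the per-interaction call fields
#'   (domain_id, target_id, specificity_conserved, motif_conserved,
#'   scenario, best_motif, best_match, identity).
#' @export
classify_rewiring_table <- function(interactions, pwms, omap, sequences,
                                    domain_seqs = NULL, sim_threshold = 0.5,
                                    id_threshold = 0.5, T = 1000) {
  calls <- lapply(seq_len(nrow(interactions)), function(i) {
    cl <- classify_rewiring(
      list(domain_id = interactions$domain_id[i],
           target_id = interactions$target_id[i]),
      pwms, omap, sequences, domain_seqs, sim_threshold, id_threshold, T)
    data.frame(domain_id = interactions$domain_id[i],
               target_id = interactions$target_id[i],
               specificity_conserved = cl$specificity_conserved,
               motif_conserved = cl$motif_conserved,
               scenario = cl$scenario,
               best_motif = cl$best_motif,
               best_match = cl$best_match,
               identity = cl$identity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
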