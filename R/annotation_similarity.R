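# Information-content-based annotation semantic similarity and the
# random-network benchmark of interactome quality.

#' Read an ontology from an OBO 1.2 file
#'
#' Minimal reader covering the fields the similarity analysis needs: term
#' id, name, namespace, \code{is_a} parents and \code{relationship: part_of}
#' parents; obsolete terms are skipped. Both edge types are treated as
#' subsumption for ancestor computation.
#'
#' @param path OBO file path.
#' @return an [ontology()] object.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  term_starts <- which(lines == "[Term]")
  ids <- character(); names_ <- character(); ns <- character()
  parents <- list()
  bounds <- c(term_starts, length(lines) + 1L)
  for (i in seq_along(term_starts)) {
    blk <- lines[seq.int(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    blk <- blk[nzchar(blk) & !startsWith(blk, "[")]
    get1 <- function(key) {
      v <- blk[startsWith(blk, paste0(key, ": "))]
      if (length(v)) sub("^[^:]+: ", "", v[1L]) else NA_character_
    }
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    isa <- sub(" !.*$", "", sub("^is_a: ", "", blk[startsWith(blk, "is_a: ")]))
    rel <- blk[startsWith(blk, "relationship: part_of ")]
    po <- sub(" !.*$", "", sub("^relationship: part_of ", "", rel))
    ids <- c(ids, id)
    names_ <- c(names_, get1("name"))
    n1 <- get1("namespace")
    ns <- c(ns, if (is.na(n1)) "default" else n1)
    parents[[id]] <- unique(c(isa, po))
  }
  ontology(ids, parents, namespace = ns, name = names_)
}

#' Construct an ontology DAG
#'
#' @param ids character vector of term identifiers.
#' @param parents named list mapping each term to its parent terms (empty
#'   for roots); every parent must itself be a listed term.
#' @param namespace character vector of namespaces per term (recycled).
#' @param name optional term names.
#' @return object of class \code{"ontology"} with elements \code{terms}
#'   (data frame id, name, namespace), \code{parents}, and memoized
#'   \code{ancestors(term)} lookup (a term is its own ancestor).
#' @export
ontology <- function(ids, parents, namespace = "default", name = NA) {
  stopifnot(!anyDuplicated(ids))
  parents <- parents[ids]
  names(parents) <- ids
  parents <- lapply(parents, function(p) if (is.null(p)) character() else p)
  unknown <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(unknown)) stop("unknown parent term(s): ",
                            paste(unknown, collapse = ", "))
  terms <- data.frame(id = ids, name = rep_len(name, length(ids)),
                      namespace = rep_len(namespace, length(ids)),
                      stringsAsFactors = FALSE)
  # acyclicity check + ancestor closure via igraph
  g <- igraph::graph_from_data_frame(
    data.frame(from = rep(ids, lengths(parents)),
               to = unlist(parents, use.names = FALSE)),
    directed = TRUE, vertices = ids)
  if (!igraph::is_dag(g)) stop("ontology graph contains a cycle")
  anc_cache <- new.env(parent = emptyenv())
  anc_fun <- function(term) {
    if (!is.null(anc_cache[[term]])) return(anc_cache[[term]])
    res <- names(igraph::subcomponent(g, term, mode = "out"))
    anc_cache[[term]] <- res
    res
  }
  structure(list(terms = terms, parents = parents, ancestors = anc_fun),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("Ontology: %d terms, %d namespace(s)\n", nrow(x$terms),
              length(unique(x$terms$namespace))))
  invisible(x)
}

#' Combine an ontology with gene annotations
#'
#' Counts, for every term, the annotation events mapping to it or to any of
#' its descendants (each gene--term assignment is one event, propagated to
#' all ancestors), separately tracking the per-namespace root totals that
#' normalize information content.
#'
#' @param ont an [ontology()].
#' @param annotations data frame with columns \code{gene}, \code{term} and
#'   optionally \code{evidence}.
#' @param exclude_evidence evidence codes to drop (e.g. \code{"IEA"}).
#' @return object of class \code{"annotation_corpus"}: the ontology plus
#'   \code{annotations}, per-term event counts \code{n_t}, per-namespace
#'   totals \code{n_root}, and \code{gene_terms} (gene -> term list).
#' @export
annotation_corpus <- function(ont, annotations, exclude_evidence = character()) {
  stopifnot(inherits(ont, "ontology"),
            all(c("gene", "term") %in% names(annotations)))
  if (length(exclude_evidence) && "evidence" %in% names(annotations)) {
    annotations <- annotations[!annotations$evidence %in% exclude_evidence, ,
                               drop = FALSE]
  }
  bad <- setdiff(annotations$term, ont$terms$id)
  if (length(bad)) stop("annotated term(s) not in ontology: ",
                        paste(unique(bad), collapse = ", "))
  n_t <- structure(numeric(nrow(ont$terms)), names = ont$terms$id)
  for (t in annotations$term) {
    anc <- ont$ancestors(t)
    n_t[anc] <- n_t[anc] + 1
  }
  ns <- structure(ont$terms$namespace, names = ont$terms$id)
  # per-namespace total = events annotated within that namespace
  n_root <- tapply(rep(1, nrow(annotations)), ns[annotations$term], sum)
  structure(
    list(ontology = ont, annotations = annotations, n_t = n_t,
         n_root = n_root, namespace = ns,
         gene_terms = split(annotations$term, annotations$gene)),
    class = "annotation_corpus"
  )
}

#' Information content of an ontology term
#'
#' \code{IC(t) = -ln(n_t / n_root)}, where \code{n_t} counts annotation
#' events mapping to the term or any descendant and \code{n_root} is the
#' total in the term's namespace. The namespace root has IC 0; a term with
#' no annotation events has undefined IC (\code{NA}) and is excluded from
#' pair maxima.
#'
#' @param corpus an [annotation_corpus()].
#' @param term term identifier.
#' @return nonnegative numeric, or NA when undefined.
#' @export
information_content <- function(corpus, term) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  if (!term %in% names(corpus$n_t)) stop("unknown term: ", term)
  n <- corpus$n_t[[term]]
  if (n == 0) return(NA_real_)
  -log(n / corpus$n_root[[corpus$namespace[[term]]]])
}

# Lin similarity of two same-namespace terms; Resnik behind the flag.
.term_similarity <- function(corpus, t1, t2, method = c("lin", "resnik")) {
  method <- match.arg(method)
  if (corpus$namespace[[t1]] != corpus$namespace[[t2]]) return(NA_real_)
  ic1 <- information_content(corpus, t1)
  ic2 <- information_content(corpus, t2)
  if (is.na(ic1) || is.na(ic2)) return(NA_real_)
  common <- intersect(corpus$ontology$ancestors(t1),
                      corpus$ontology$ancestors(t2))
  if (length(common) == 0L) return(NA_real_)
  ic_common <- corpus$n_t[common]
  ic_common <- -log(ic_common / corpus$n_root[[corpus$namespace[[t1]]]])
  mica <- max(ic_common)
  if (method == "resnik") return(mica)
  if (ic1 + ic2 == 0) return(0)  # both at the root
  2 * mica / (ic1 + ic2)
}

#' Semantic similarity between two annotated genes
#'
#' With gene A annotated by M terms and gene B by N terms, computes the
#' term-pair similarity for all M x N same-namespace pairs and returns the
#' highest score. The default term measure is the Lin form
#' \code{2 IC(MICA) / (IC(a) + IC(b))} (MICA = most informative common
#' ancestor), which ranges from 0 to 1; Resnik's unnormalized \code{IC(MICA)}
#' is available via \code{method}. Genes with no annotation do not receive a
#' score (\code{NA}); cross-namespace pairs are skipped, not scored 0.
#'
#' @param corpus an [annotation_corpus()].
#' @param gene_a,gene_b gene identifiers.
#' @param method \code{"lin"} (default) or \code{"resnik"}.
#' @return numeric similarity, or NA when undefined.
#' @export
protein_pair_similarity <- function(corpus, gene_a, gene_b, method = "lin") {
  ta <- corpus$gene_terms[[gene_a]]
  tb <- corpus$gene_terms[[gene_b]]
  if (is.null(ta) || is.null(tb)) return(NA_real_)
  best <- NA_real_
  for (t1 in unique(ta)) for (t2 in unique(tb)) {
    s <- .term_similarity(corpus, t1, t2, method)
    if (!is.na(s) && (is.na(best) || s > best)) best <- s
  }
  best
}

# Metrics (i)-(iv) over a set of gene pairs.
.sim_metrics <- function(corpus, pairs, method = "lin") {
  sims <- mapply(function(a, b) protein_pair_similarity(corpus, a, b, method),
                 pairs[[1L]], pairs[[2L]])
  n <- length(sims); nd <- sum(!is.na(sims)); s <- sum(sims, na.rm = TRUE)
  c(pct_scored = 100 * nd / n,
    sim_sum = s,
    sim_avg = if (nd > 0) s / nd else 0,
    sim_avg_overall = if (n > 0) s / n else 0)
}

#' Benchmark a network's annotation similarity against random networks
#'
#' Compares the real interactome with \code{n_networks} random networks in
#' which every bait gene receives \code{per_bait} random interactors drawn
#' from the gene universe. Four metrics are computed for each network:
#' (i) the percentage of interactions with a similarity score, (ii) the sum
#' of all scores, (iii) the average score over scored interactions, and
#' (iv) the overall average over all interactions. Empirical p-values use
#' the add-one estimator.
#'
#' @param net data frame of gene-level interactions (first two columns: bait
#'   gene, prey gene), or an \code{"sh3_network"} (bait ids mapped to
#'   proteins).
#' @param corpus an [annotation_corpus()].
#' @param universe character vector of candidate interactor genes.
#' @param n_networks number of random networks.
#' @param per_bait random interactors per bait gene.
#' @param seed RNG seed.
#' @param method term similarity variant, see [protein_pair_similarity()].
#' @return list with \code{real} (named metric vector), \code{random}
#'   (n_networks x 4 matrix), \code{null_mean}, \code{null_sd} and
#'   \code{p_value} per metric.
#' @export
network_benchmark <- function(net, corpus, universe, n_networks = 100,
                              per_bait = 100, seed = 1, method = "lin") {
  if (inherits(net, "sh3_network")) {
    net <- data.frame(bait = domain_protein(net$edges$bait_id),
                      prey = net$edges$prey_id, stringsAsFactors = FALSE)
  }
  baits <- unique(net[[1L]])
  real <- .sim_metrics(corpus, net, method)
  random <- with_seed(seed, {
    t(vapply(seq_len(n_networks), function(i) {
      rnd <- data.frame(
        bait = rep(baits, each = per_bait),
        prey = sample(universe, length(baits) * per_bait, replace = TRUE),
        stringsAsFactors = FALSE)
      .sim_metrics(corpus, rnd, method)
    }, numeric(4)))
  })
  p <- vapply(seq_along(real), function(j) {
    (1 + sum(random[, j] >= real[j])) / (1 + n_networks)
  }, numeric(1))
  names(p) <- names(real)
  list(real = real, random = random,
       null_mean = colMeans(random), null_sd = apply(random, 2, stats::sd),
       p_value = p)
}

#' Read GAF-style annotations
#'
#' Tab-separated with header (gene, term, evidence_code).
#'
#' @param path file path.
#' @param exclude_evidence evidence codes to drop (e.g. \code{"IEA"}).
#' @return data frame (gene, term, evidence).
#' @export
read_annotations <- function(path, exclude_evidence = character()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "evidence_code"] <- "evidence"
  if (length(exclude_evidence) && "evidence" %in% names(df)) {
    df <- df[!df$evidence %in% exclude_evidence, , drop = FALSE]
  }
  df
}
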