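# Shared fixtures and independent oracles, all built in code.

# one shared default synthetic world (seed 1), generated once per run
.world_cache <- new.env(parent = emptyenv())
get_world <- function() {
  if (is.null(.world_cache$w)) {
    .world_cache$w <- gen_world(world_config(), seed = 1)
  }
  .world_cache$w
}

# PWM with unit mass on the given residues (one per column)
point_pwm <- function(residues, domain_id = "point") {
  m <- length(residues)
  prob <- matrix(0, 20, m, dimnames = list(sh3map:::AA_ALPHABET, NULL))
  prob[cbind(match(residues, sh3map:::AA_ALPHABET), seq_len(m))] <- 1
  new_pwm(prob, domain_id = domain_id)
}

# random Dirichlet-ish PWM
random_pwm <- function(m, concentration = 0.5) {
  x <- matrix(stats::rgamma(20 * m, concentration), 20, m)
  new_pwm(sweep(x, 2, colSums(x), "/"))
}

random_peptide <- function(m) {
  paste(sample(sh3map:::AA_ALPHABET, m, replace = TRUE), collapse = "")
}

random_protein <- function(len) {
  paste(sample(sh3map:::AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# independent per-residue loop oracle for peptide scoring
score_oracle <- function(pwm, peptide) {
  chars <- strsplit(peptide, "")[[1]]
  s <- 1
  for (j in seq_along(chars)) {
    i <- match(chars[j], sh3map:::AA_ALPHABET)
    s <- s * (if (is.na(i)) 1 else 20 * pwm$prob[i, j])
  }
  s
}

# brute-force union-alignment distance oracle for a fixed offset
pair_distance_oracle <- function(a, b, offset) {
  u <- rep(1 / 20, 20)
  lo <- min(1, offset + 1)
  hi <- max(a$m, offset + b$m)
  tot <- 0
  for (pos in lo:hi) {
    p1 <- if (pos >= 1 && pos <= a$m) a$prob[, pos] else u
    p2 <- if (pos - offset >= 1 && pos - offset <= b$m) b$prob[, pos - offset]
          else u
    tot <- tot + sum((p1 - p2)^2)
  }
  sqrt(tot / (hi - lo + 1))
}

# exhaustive-subset oracle for the modified k-core: the union of all vertex
# subsets (excluding seeds) in which every member has >= 1 seed neighbor and
# >= k neighbors within the subset or the seeds
kcore_oracle <- function(edges, seeds, k) {
  adj <- sh3map:::.adjacency(edges)
  seeds <- intersect(seeds, names(adj))
  cand <- setdiff(names(adj), seeds)
  ok_nodes <- character()
  nc <- length(cand)
  if (nc == 0) return(character())
  for (mask in seq_len(2^nc) - 1L) {
    sub <- cand[bitwAnd(bitwShiftL(1L, seq_len(nc) - 1L), mask) != 0L]
    qualifies <- all(vapply(sub, function(v) {
      any(adj[[v]] %in% seeds) && sum(adj[[v]] %in% c(sub, seeds)) >= k
    }, logical(1)))
    if (qualifies) ok_nodes <- union(ok_nodes, sub)
  }
  sort(ok_nodes)
}

# random undirected edge list on n nodes
random_graph_edges <- function(n, p_edge) {
  pairs <- t(utils::combn(paste0("v", seq_len(n)), 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
             stringsAsFactors = FALSE)
}

# disjoint projected/reference edge sets with a prescribed overlap
overlap_sets <- function(n_proj, n_ref, n_overlap) {
  mk <- function(pa, pb, n) {
    data.frame(id_A = sprintf("%s%d", pa, seq_len(n)),
               id_B = sprintf("%s%d", pb, seq_len(n)),
               stringsAsFactors = FALSE)
  }
  shared <- mk("s", "t", n_overlap)
  list(proj = rbind(shared, mk("pa", "pb", n_proj - n_overlap)),
       ref = rbind(shared, mk("ra", "rb", n_ref - n_overlap)))
}

# small hand-checkable annotation corpus:
# root -> {A, B}; A -> {A1, A2}; annotations g1:A1 g2:A1 g3:A2 g4:B
toy_corpus <- function() {
  ont <- ontology(
    ids = c("root", "A", "B", "A1", "A2"),
    parents = list(root = character(), A = "root", B = "root",
                   A1 = "A", A2 = "A"),
    namespace = "bp")
  annotation_corpus(ont, data.frame(
    gene = c("g1", "g2", "g3", "g4"),
    term = c("A1", "A1", "A2", "B"),
    stringsAsFactors = FALSE))
}
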