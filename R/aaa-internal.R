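# Shared internal helpers: alphabet, seeded evaluation, id conventions.

# The 20 standard amino acids, alphabetical one-letter code. Column order of
# every PWM matrix and row order of the on-disk PWM format.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP_CHAR <- "-"

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{code} under \code{set.seed(seed)} and restores the caller's RNG
#' state afterwards, so seeded generators do not perturb the session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a child seed from a master seed
#'
#' Deterministic fan-out so each pipeline component gets an independent
#' reproducible stream. Result is always a positive 32-bit integer.
#'
#' @param master integer master seed.
#' @param index integer component index (>= 0).
#' @return integer child seed in [1, 2^31 - 2].
#' @export
child_seed <- function(master, index) {
  stopifnot(is.numeric(master), is.numeric(index))
  as.integer((abs(master) * 1009 + index * 9973) %% 2147483646 + 1)
}

# "ABI-1#1" -> "ABI-1": SH3 domains are named protein#domain-index.
domain_protein <- function(domain_id) {
  sub("#.*$", "", domain_id)
}

# Canonical undirected pair key, for endpoint-set edge identity.
undirected_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Character vector -> integer indices into AA_ALPHABET (NA for unknowns).
aa_index <- function(chars) {
  match(chars, AA_ALPHABET)
}

split_chars <- function(x) {
  strsplit(x, "", fixed = TRUE)[[1L]]
}

# Shannon entropy (natural log) of a nonnegative weight vector.
shannon_entropy <- function(w) {
  p <- w / sum(w)
  p <- p[p > 0]
  -sum(p * log(p))
}
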