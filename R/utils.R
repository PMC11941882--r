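#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded helpers do not perturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a stage seed from a global seed
#'
#' Per-stage seeds are `(seed * 1000003 + offset) mod 2^31 - 1` so every stage
#' of the pipeline can be rerun in isolation with a documented scheme.
#'
#' @param seed global integer seed.
#' @param offset integer stage counter.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(offset)) %% 2147483647)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(nch2(tab))
  sum_a <- sum(nch2(rowSums(tab)))
  sum_b <- sum(nch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / nch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Jaccard similarity of two sets
#'
#' @param a,b character vectors treated as sets.
#' @return |intersection| / |union|; 1 when both are empty.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# stop() with a classed condition so callers can test error categories
jf_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "jarflavor_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
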