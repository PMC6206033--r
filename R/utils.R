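# Internal helpers shared across modules.

#' Derive a reproducible substream seed from a master seed and a string key
#'
#' Cohort generation assigns every patient (and the peptide-level parameter
#' block) its own RNG substream so that generated cohorts do not depend on
#' the order in which patients are drawn. The substream seed is a simple
#' 31-bit polynomial hash of the key, mixed with the master seed.
#'
#' @param master integer master seed
#' @param key character key naming the substream
#' @return an integer seed in [0, 2^31 - 1)
#' @keywords internal
substream_seed <- function(master, key) {
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(as.character(key))) {
    h <- (h * 131 + c) %% m
  }
  as.integer((h + (as.numeric(master) %% m) * 48271) %% m)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x) && x >= 0
}

is_prob <- function(x) is.numeric(x) & is.finite(x) & x >= 0 & x <= 1

#' Stratified cross-validation fold assignment
#'
#' @param y factor or logical outcome
#' @param k number of folds
#' @param seed integer seed controlling the assignment
#' @return integer vector of fold ids in 1..k
#' @keywords internal
stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  folds <- integer(length(y))
  with_seed(seed, {
    for (lev in levels(y)) {
      idx <- which(y == lev)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

# AUC as pairwise concordance via the rank-sum identity (ties count 1/2).
# Used internally where a dependency-free AUC is needed (CV loops, oracles).
auc_rank <- function(scores, is_case) {
  n1 <- as.numeric(sum(is_case))
  n0 <- as.numeric(sum(!is_case))
  if (n1 == 0 || n0 == 0) stopf("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
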