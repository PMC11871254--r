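# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed` so seeded operations do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed, or NULL to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible child seed for a named pipeline stage
#'
#' Hashes the stage name into a 31-bit integer and combines it with the run
#' seed, so each stage of a pipeline run has its own reproducible random
#' stream and can be re-run in isolation.
#'
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return integer in [0, 2^31 - 1).
#' @export
childSeed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% m
  as.integer((h + as.numeric(seed)) %% m)
}

# log(mean(exp(x))) computed stably.
logMeanExp <- function(x) {
  mx <- max(x)
  mx + log(mean(exp(x - mx)))
}

# Allowed kingdom and protist feeding-mode vocabularies.
KINGDOMS <- c("bacteria", "protist")
SEASONS <- c("spring", "summer", "autumn", "winter")
FEEDING_MODES <- c("algivore", "bacterivore", "mycophage",
                   "nonselective omnivore", "parasite", "phototroph",
                   "raptor", "saprotroph", "unknown")

# Upper-triangle (i < j) values of a square matrix as a vector.
upperTri <- function(m) m[upper.tri(m)]

# All permutations of 1..n as a matrix (n! rows). Only used for small n.
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
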