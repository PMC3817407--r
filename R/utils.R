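#' @importFrom stats cor optim rlnorm runif setNames sd plogis qlogis rbinom
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`,
#' then restores the previous RNG state so callers are unaffected.  All
#' generators in the package use this, which makes each one a pure
#' function of its parameters and seed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage-local seed from a global seed
#'
#' Stable string hash of the stage name folded into the run seed, so each
#' pipeline stage gets its own reproducible random substream from one
#' global seed.  The result always lies in `[0, 2^31 - 2]`.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed for the stage.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% 2147483647
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

# strict-ish scalar checks used by validators throughout
is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x) && x >= min
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# encode a DNA string as base indices into DNA_BASES (NA for anything else)
seq_to_idx <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
}

idx_to_seq <- function(idx) paste(DNA_BASES[idx], collapse = "")

# i.i.d. background sampler at a given GC fraction (draws from current RNG)
random_background <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# lognormal multiplicative noise with mean exactly 1 and coefficient of
# variation cv (flow-cytometry style noise; see the methods vignette)
lognormal_noise <- function(n, cv) {
  if (cv < 0) stop("noise cv must be nonnegative")
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}
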