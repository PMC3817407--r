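# Bipartite promoter models: paired -35/-10 PWMs joined by an empirically
# penalised variable spacer.  All scores are log2-odds ("bits").

#' Build a position weight matrix from aligned sites
#'
#' Column probabilities are Laplace-smoothed with a pseudocount
#' distributed by the background:
#' `probs[b, i] = (count + pseudocount * background[b]) / (n + pseudocount)`,
#' and log-odds are `log2(probs / background)`.
#'
#' @param sites character vector of equal-length A/C/G/T strings.
#' @param background base frequency vector (A, C, G, T), summing to 1.
#' @param pseudocount nonnegative smoothing mass.
#' @return an object of class `ecf_pwm` with elements `width`, `probs`
#'   (4 x width, rows A/C/G/T), `logodds`, `background`, `pseudocount`.
#' @examples
#' pwm <- build_pwm(c("TGA", "TGA", "TGA", "TGC"))
#' pwm$probs["A", 3]   # (3 + 0.25) / 5 = 0.65
#' @export
build_pwm <- function(sites, background = rep(0.25, 4), pseudocount = 1) {
  if (length(sites) < 1L) stop("need at least one site")
  sites <- toupper(sites)
  w <- unique(nchar(sites))
  if (length(w) != 1L) stop("sites must all have the same length")
  if (w < 1L) stop("zero-width sites")
  if (any(!grepl("^[ACGT]+$", sites)))
    stop("sites must be unambiguous A/C/G/T strings")
  background <- check_background(background)
  if (!is_number(pseudocount) || pseudocount < 0)
    stop("pseudocount must be nonnegative")
  idx <- matrix(vapply(sites, seq_to_idx, integer(w)), nrow = w)  # w x n
  counts <- matrix(0, 4, w, dimnames = list(DNA_BASES, NULL))
  for (i in seq_len(w))
    counts[, i] <- tabulate(idx[i, ], nbins = 4)
  new_pwm_from_counts(counts, background, pseudocount, n_sites = length(sites))
}

new_pwm_from_counts <- function(counts, background, pseudocount, n_sites) {
  probs <- sweep(counts + pseudocount * background, 2,
                 n_sites + pseudocount, "/")
  structure(list(width = ncol(counts), probs = probs,
                 logodds = log2(probs / background),
                 background = background, pseudocount = pseudocount,
                 n_sites = n_sites),
            class = "ecf_pwm")
}

#' Construct a PWM directly from a probability matrix
#'
#' @param probs 4 x width matrix (rows A/C/G/T), columns summing to 1.
#' @inheritParams build_pwm
#' @return an `ecf_pwm`.
#' @export
pwm_from_probs <- function(probs, background = rep(0.25, 4), pseudocount = 0) {
  if (!is.matrix(probs) || nrow(probs) != 4 || ncol(probs) < 1)
    stop("probs must be a 4 x width matrix")
  if (any(abs(colSums(probs) - 1) > 1e-9))
    stop("probability columns must sum to 1")
  background <- check_background(background)
  rownames(probs) <- DNA_BASES
  structure(list(width = ncol(probs), probs = probs,
                 logodds = log2(probs / background),
                 background = background, pseudocount = pseudocount,
                 n_sites = NA_integer_),
            class = "ecf_pwm")
}

check_background <- function(background) {
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop("background must be 4 positive frequencies summing to 1")
  setNames(as.numeric(background), DNA_BASES)
}

#' @export
print.ecf_pwm <- function(x, ...) {
  cat(sprintf("PWM: width %d, consensus %s, %.2f bits total\n",
              x$width, consensus_seq(x), information_content(x)$total))
  invisible(x)
}

#' Consensus sequence of a PWM (column-wise most probable base)
#'
#' Ties are broken in favour of the alphabetically first base.
#'
#' @param pwm an `ecf_pwm`.
#' @return a DNA string of length `pwm$width`.
#' @export
consensus_seq <- function(pwm) {
  stopifnot(inherits(pwm, "ecf_pwm"))
  paste(DNA_BASES[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Score one block placement
#'
#' Sum of per-position log2-odds of `subseq` under the PWM.
#'
#' @param pwm an `ecf_pwm`.
#' @param subseq A/C/G/T string of length `pwm$width`.
#' @return log2-odds score in bits.
#' @export
score_block <- function(pwm, subseq) {
  stopifnot(inherits(pwm, "ecf_pwm"))
  if (nchar(subseq) != pwm$width)
    stop(sprintf("subsequence length %d does not match PWM width %d",
                 nchar(subseq), pwm$width))
  idx <- seq_to_idx(subseq)
  if (anyNA(idx)) stop("ambiguous base in subsequence (only A/C/G/T scorable)")
  sum(pwm$logodds[cbind(idx, seq_len(pwm$width))])
}

# vectorised block scores at every offset of an index-encoded sequence;
# returns scores for 0-based offsets 0..L-w (position i of the result is
# offset i-1).  NA bases propagate NA scores.
block_scores_all <- function(logodds, idx) {
  w <- ncol(logodds); L <- length(idx)
  n <- L - w + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  lo <- as.numeric(logodds)  # column-major: [(j-1)*4 + b]
  for (j in seq_len(w))
    s <- s + lo[(j - 1L) * 4L + idx[j:(j + n - 1L)]]
  s
}

#' Information content of a PWM
#'
#' Per-position Kullback-Leibler information relative to the background,
#' `IC_i = sum_b p[b,i] * log2(p[b,i] / background[b])`.  For a uniform
#' background this equals the familiar `2 + sum_b p log2 p` bits that set
#' sequence-logo letter heights.
#'
#' @param pwm an `ecf_pwm`.
#' @return list with `per_position` (bits) and `total` (bits).
#' @export
information_content <- function(pwm) {
  stopifnot(inherits(pwm, "ecf_pwm"))
  p <- pwm$probs
  terms <- p * log2(p / pwm$background)
  terms[p == 0] <- 0
  per <- colSums(terms)
  list(per_position = per, total = sum(per))
}

# ---------------------------------------------------------------------------
# Spacer model

#' Spacer-length model with log-odds penalty
#'
#' Observed spacer counts are smoothed with a pseudocount over the support
#' and converted into a penalty normalised to the modal length:
#' `penalty(L) = log2(phat(L) / phat(mode))`, which is 0 at the mode and
#' negative elsewhere.  Lengths outside the support are disallowed
#' (`-Inf`).
#'
#' @param counts named numeric vector of observed counts; names are spacer
#'   lengths in nt.
#' @param pseudocount nonnegative smoothing mass added to every length in
#'   the support.
#' @param support inclusive integer range of permitted lengths; defaults
#'   to the range of observed lengths.
#' @return object of class `ecf_spacer` with `counts`, `support`,
#'   `pseudocount`, `probs`, `penalties`, `mode`.
#' @examples
#' sp <- spacer_model(c(`16` = 10, `17` = 5), pseudocount = 1, support = 15:18)
#' spacer_penalty(sp, 17)  # log2(6/11)
#' @export
spacer_model <- function(counts, pseudocount = 1, support = NULL) {
  lens <- as.integer(names(counts))
  if (anyNA(lens) || any(counts < 0)) stop("counts must be named by integer lengths")
  support <- sort(unique(as.integer(support %||% seq(min(lens), max(lens)))))
  if (length(support) == 0L) stop("empty spacer support")
  if (any(diff(support) != 1L)) stop("spacer support must be a contiguous range")
  if (any(!lens %in% support)) stop("observed spacer length outside support")
  full <- setNames(numeric(length(support)), support)
  full[as.character(lens)] <- counts
  smoothed <- full + pseudocount
  probs <- smoothed / sum(smoothed)
  mode_len <- support[which.max(probs)]  # ties -> smallest length
  penalties <- log2(probs / max(probs))
  structure(list(counts = full, support = support, pseudocount = pseudocount,
                 probs = probs, penalties = penalties, mode = mode_len),
            class = "ecf_spacer")
}

#' @rdname spacer_model
#' @param model an `ecf_spacer`.
#' @param L spacer length in nt (vectorised).
#' @return penalty in bits, `<= 0`; `-Inf` outside the support.
#' @export
spacer_penalty <- function(model, L) {
  stopifnot(inherits(model, "ecf_spacer"))
  out <- rep(-Inf, length(L))
  hit <- match(as.integer(L), model$support)
  out[!is.na(hit)] <- model$penalties[hit[!is.na(hit)]]
  out
}

# ---------------------------------------------------------------------------
# Promoter model and scanning

#' Bipartite promoter model
#'
#' Couples a -35 PWM and a -10 PWM through a spacer-length penalty, with
#' an optional A/T-richness UP bonus upstream of the -35 block
#' (`up_beta`, off by default; see the methods vignette).
#'
#' @param subgroup integer ECF subgroup the model describes (NA allowed
#'   for discovered or host models).
#' @param pwm35,pwm10 `ecf_pwm` objects of width >= 4.
#' @param spacer an `ecf_spacer`.
#' @param up_beta nonnegative weight of the UP bonus in bits (default 0).
#' @param up_width width in nt of the upstream region the bonus looks at.
#' @return object of class `ecf_promoter_model`.
#' @export
promoter_model <- function(subgroup, pwm35, pwm10, spacer,
                           up_beta = 0, up_width = 23L) {
  stopifnot(inherits(pwm35, "ecf_pwm"), inherits(pwm10, "ecf_pwm"),
            inherits(spacer, "ecf_spacer"))
  if (pwm35$width < 4 || pwm10$width < 4) stop("PWM widths must be >= 4")
  if (!is_number(up_beta) || up_beta < 0) stop("up_beta must be nonnegative")
  structure(list(subgroup = if (is.null(subgroup)) NA_integer_ else as.integer(subgroup),
                 pwm35 = pwm35, pwm10 = pwm10, spacer = spacer,
                 up_beta = up_beta, up_width = as.integer(up_width)),
            class = "ecf_promoter_model")
}

#' @export
print.ecf_promoter_model <- function(x, ...) {
  cat(sprintf(
    "Promoter model (subgroup %s): -35 %s / spacer %d-%d (mode %d) / -10 %s\n",
    ifelse(is.na(x$subgroup), "?", x$subgroup), consensus_seq(x$pwm35),
    min(x$spacer$support), max(x$spacer$support), x$spacer$mode,
    consensus_seq(x$pwm10)))
  invisible(x)
}

#' Total score of a model's perfect promoter
#'
#' Sum over both blocks of the column-wise maximal log-odds (the score of
#' the consensus placed at the modal spacing, where the spacer penalty is
#' zero).  Used e.g. to set host-exclusion cutoffs.
#'
#' @param model an `ecf_promoter_model`.
#' @return score in bits.
#' @export
consensus_score <- function(model) {
  stopifnot(inherits(model, "ecf_promoter_model"))
  sum(apply(model$pwm35$logodds, 2, max)) +
    sum(apply(model$pwm10$logodds, 2, max))
}

#' Scan a sequence for the best bipartite promoter placement
#'
#' Enumerates every (-35 offset, spacer length) placement with the spacer
#' in the model support and returns the maximum of
#' `score35 + score10 + spacer_penalty + up_term`.  Ties are broken by
#' the smallest -35 offset, then the smallest spacer.  Scanning is
#' single-strand: promoters are directional, so callers
#' reverse-complement minus-strand regions first.
#'
#' @param model an `ecf_promoter_model`.
#' @param seq A/C/G/T string, at least `w35 + min(spacer) + w10` long.
#' @return object of class `ecf_promoter_hit`: list with 0-based offsets
#'   `start35`, `start10`, plus `spacer_length`, `score35`, `score10`,
#'   `spacer_penalty`, `up_term`, `total`.
#' @export
scan_promoter <- function(model, seq) {
  stopifnot(inherits(model, "ecf_promoter_model"))
  w35 <- model$pwm35$width; w10 <- model$pwm10$width
  support <- model$spacer$support
  L <- nchar(seq)
  min_foot <- w35 + min(support) + w10
  if (L < min_foot)
    stop(sprintf("sequence length %d below minimal footprint %d", L, min_foot))
  idx <- seq_to_idx(seq)
  if (anyNA(idx)) stop("ambiguous base in sequence; scanning needs A/C/G/T")
  s35 <- block_scores_all(model$pwm35$logodds, idx)
  s10 <- block_scores_all(model$pwm10$logodds, idx)
  up <- numeric(length(s35))
  if (model$up_beta > 0) {
    at <- cumsum(c(0L, idx == 1L | idx == 4L))
    o <- seq_along(s35) - 1L  # 0-based -35 offsets
    lo <- pmax(0L, o - model$up_width)
    up <- model$up_beta * (at[o + 1L] - at[lo + 1L]) / model$up_width
  }
  best <- NULL
  for (sp in support) {
    pen <- spacer_penalty(model$spacer, sp)
    n <- L - (w35 + sp + w10) + 1L
    if (n < 1L) next
    o35 <- seq_len(n) - 1L
    tot <- s35[seq_len(n)] + s10[o35 + w35 + sp + 1L] + pen + up[seq_len(n)]
    i <- which.max(tot)  # smallest offset among exact ties
    cand <- list(start35 = o35[i], spacer_length = sp, total = tot[i],
                 score35 = s35[i], score10 = s10[o35[i] + w35 + sp + 1L],
                 spacer_penalty = pen, up_term = up[i])
    if (is.null(best) || cand$total > best$total ||
        (cand$total == best$total && cand$start35 < best$start35))
      best <- cand
  }
  if (is.null(best)) stop("no feasible placement for any supported spacer")
  best$start10 <- best$start35 + w35 + best$spacer_length
  structure(best[c("start35", "start10", "spacer_length", "score35",
                   "score10", "spacer_penalty", "up_term", "total")],
            class = "ecf_promoter_hit")
}

#' @export
print.ecf_promoter_hit <- function(x, ...) {
  cat(sprintf(
    "Hit: -35 @%d, spacer %d, -10 @%d | %.2f + %.2f %+.2f %+.2f = %.2f bits\n",
    x$start35, x$spacer_length, x$start10, x$score35, x$score10,
    x$spacer_penalty, x$up_term, x$total))
  invisible(x)
}
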