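# Fold statistics, activity classification, orthogonal-subset selection,
# predicted-vs-measured comparison, and growth summaries.

CROSSTALK_KINDS <- c("fold_induction", "model_score", "fold_repression")

#' Sigma x promoter crosstalk matrix
#'
#' @param values numeric matrix, sigmas in rows, promoters in columns.
#' @param sigma_ids,promoter_ids id vectors; default to the dimnames.
#' @param kind one of `"fold_induction"`, `"model_score"`,
#'   `"fold_repression"`.  Fold matrices must be strictly positive.
#' @return object of class `ecf_crosstalk`.
#' @export
crosstalk_matrix <- function(values, sigma_ids = rownames(values),
                             promoter_ids = colnames(values),
                             kind = "fold_induction") {
  kind <- match.arg(kind, CROSSTALK_KINDS)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(sigma_ids) || is.null(promoter_ids))
    stop("sigma and promoter ids are required (as args or dimnames)")
  if (length(sigma_ids) != nrow(values) ||
      length(promoter_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions")
  if (kind != "model_score" && any(values <= 0))
    stop("fold matrices must be strictly positive")
  dimnames(values) <- list(sigma_ids, promoter_ids)
  structure(list(sigma_ids = sigma_ids, promoter_ids = promoter_ids,
                 values = values, kind = kind),
            class = "ecf_crosstalk")
}

#' @export
print.ecf_crosstalk <- function(x, ...) {
  cat(sprintf("Crosstalk matrix (%s): %d sigmas x %d promoters\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read / write crosstalk matrices as TSV
#'
#' Sigma rows by promoter columns, first column `sigma_id`, with the
#' matrix kind recorded in a `# kind: ...` comment header.
#'
#' @param path file path.
#' @return [read_crosstalk_tsv()] returns an `ecf_crosstalk`.
#' @export
read_crosstalk_tsv <- function(path) {
  first <- readLines(path, n = 5L)
  kindline <- grep("^#\\s*kind:", first, value = TRUE)
  kind <- if (length(kindline))
    sub("^#\\s*kind:\\s*", "", kindline[1]) else "fold_induction"
  df <- read_tsv_table(path, required = "sigma_id")
  m <- as.matrix(df[setdiff(names(df), "sigma_id")])
  rownames(m) <- df$sigma_id
  crosstalk_matrix(m, kind = kind)
}

#' @rdname read_crosstalk_tsv
#' @param x an `ecf_crosstalk`.
#' @export
write_crosstalk_tsv <- function(x, path) {
  stopifnot(inherits(x, "ecf_crosstalk"))
  df <- data.frame(sigma_id = x$sigma_ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_table(df, path, comments = paste("kind:", x$kind))
}

#' Compute a predicted (model-score) crosstalk matrix
#'
#' Scans every promoter against every subgroup model; the cell for
#' (sigma, promoter) is the best bipartite placement score in bits.
#' Sigmas of the same subgroup share a model, so rows are emitted per
#' model (named by subgroup) unless explicit sigma ids are supplied.
#'
#' @param models named list of `ecf_promoter_model`s (names = subgroup).
#' @param promoters promoter data.frame (`id`, `sequence`).
#' @param sigma_ids optional row ids, one per model.
#' @return an `ecf_crosstalk` of kind `model_score`.
#' @export
score_crosstalk <- function(models, promoters, sigma_ids = names(models)) {
  vals <- t(vapply(models, function(m)
    vapply(promoters$sequence, function(s) scan_promoter(m, s)$total,
           numeric(1), USE.NAMES = FALSE),
    numeric(nrow(promoters))))
  crosstalk_matrix(vals, sigma_ids = sigma_ids,
                   promoter_ids = promoters$id, kind = "model_score")
}

# ---------------------------------------------------------------------------
# Fold statistics

#' Geometric mean fluorescence of gated events
#'
#' Drops events with fluorescence `<= 0` (the flow-cytometry gate), then
#' returns `exp(mean(log(x)))`.
#'
#' @param events numeric fluorescence values.
#' @return positive geometric mean.
#' @examples
#' geometric_mean_fluorescence(c(-5, 10, 1000))  # 100
#' @export
geometric_mean_fluorescence <- function(events) {
  kept <- events[events > 0]
  if (length(kept) == 0L) stop("no positive events after gating")
  exp(mean(log(kept)))
}

#' Fold induction and fold repression
#'
#' Fold induction divides the fluorescence of cells carrying the sigma
#' and the reporter by that of cells carrying the reporter alone; fold
#' repression divides sigma-plus-reporter fluorescence by that of cells
#' additionally carrying the anti-sigma.
#'
#' @param with_sigma,reporter_only,sigma_only,sigma_plus_anti positive
#'   fluorescence values.
#' @return the fold ratio.
#' @export
fold_induction <- function(with_sigma, reporter_only) {
  if (any(reporter_only <= 0)) stop("reporter-only fluorescence must be positive")
  with_sigma / reporter_only
}

#' @rdname fold_induction
#' @export
fold_repression <- function(sigma_only, sigma_plus_anti) {
  if (any(sigma_only <= 0) || any(sigma_plus_anti <= 0))
    stop("fluorescence values must be positive")
  sigma_only / sigma_plus_anti
}

#' Classify active sigmas (or anti-sigmas) from a fold matrix
#'
#' A sigma is active iff its maximal fold induction over promoters
#' strictly exceeds `sigma_threshold` (default >5-fold); on a
#' `fold_repression` matrix, an anti-sigma is active iff its maximal
#' fold repression strictly exceeds `anti_threshold` (default >2-fold).
#' Boundary values are inactive.
#'
#' @param matrix an `ecf_crosstalk` of kind `fold_induction` or
#'   `fold_repression`.
#' @param sigma_threshold,anti_threshold strict fold thresholds.
#' @return list with `active_sigmas` (character) and
#'   `active_anti_sigmas` (character or `NULL` when not applicable).
#' @export
classify_activity <- function(matrix, sigma_threshold = 5,
                              anti_threshold = 2) {
  stopifnot(inherits(matrix, "ecf_crosstalk"))
  if (matrix$kind == "model_score")
    stop("activity thresholds apply to fold matrices, not model scores")
  rowmax <- apply(matrix$values, 1, max)
  if (matrix$kind == "fold_induction")
    list(active_sigmas = matrix$sigma_ids[rowmax > sigma_threshold],
         active_anti_sigmas = NULL)
  else
    list(active_sigmas = NULL,
         active_anti_sigmas = matrix$sigma_ids[rowmax > anti_threshold])
}

#' Off-target load of each cognate pair
#'
#' For a cognate pair (sigma s, promoter p) the load is the sum of
#' above-baseline folds in s's row (excluding p) plus those in p's
#' column (excluding s), where each cell contributes
#' `max(fold - 1, 0)`: a perfectly silent cell (fold 1, or repressed
#' below 1) contributes nothing, so a diagonal-only matrix has zero load
#' everywhere.
#'
#' @param matrix an `ecf_crosstalk` of kind `fold_induction`.
#' @param cognate_map named character vector, sigma id -> promoter id.
#' @return named nonnegative numeric vector of loads (names = sigma ids).
#' @export
offtarget_load <- function(matrix, cognate_map) {
  stopifnot(inherits(matrix, "ecf_crosstalk"))
  sig <- names(cognate_map); prom <- unname(cognate_map)
  if (!all(sig %in% matrix$sigma_ids))
    stop("cognate sigma(s) missing from matrix rows")
  if (!all(prom %in% matrix$promoter_ids))
    stop("cognate promoter(s) missing from matrix columns")
  ex <- pmax(matrix$values - 1, 0)
  vapply(seq_along(sig), function(i) {
    s <- sig[i]; p <- prom[i]
    sum(ex[s, colnames(ex) != p]) + sum(ex[rownames(ex) != s, p])
  }, numeric(1)) -> load
  setNames(load, sig)
}

#' Select the k most orthogonal sigma:promoter pairs
#'
#' Greedy elimination with swap refinement.  First, the cognate pair
#' with the largest off-target load is repeatedly dropped (loads
#' recomputed within the surviving submatrix after each removal;
#' elimination ties drop the lexicographically largest sigma id) until
#' `k` pairs remain.  A deterministic local search then tries exchanging
#' each survivor with each eliminated pair, accepting any swap that
#' lowers the subset's total load, until no swap improves it.  The
#' survivors are returned ordered by ascending load within the surviving
#' submatrix, ties by sigma id.
#'
#' @param matrix an `ecf_crosstalk` of kind `fold_induction`.
#' @param cognate_map named character vector, sigma id -> promoter id.
#' @param k number of pairs to keep (`<=` number of cognate pairs).
#' @return object of class `ecf_orthogonal_selection`: a data.frame with
#'   columns `sigma_id`, `promoter_id`, `offtarget_load`.
#' @export
select_orthogonal <- function(matrix, cognate_map, k) {
  stopifnot(inherits(matrix, "ecf_crosstalk"))
  if (!is_count(k, 1) || k > length(cognate_map))
    stop("k must be between 1 and the number of cognate pairs")
  cognate_map <- cognate_map[order(names(cognate_map))]
  sig <- names(cognate_map)
  if (!all(sig %in% matrix$sigma_ids) ||
      !all(cognate_map %in% matrix$promoter_ids))
    stop("cognate pair(s) missing from the matrix")
  # pairwise excess matrix aligned to cognate pairs: Ep[i, j] is the
  # above-baseline fold of sigma i on pair j's cognate promoter; the
  # load of pair i within a subset S is sum_j (Ep[i,j] + Ep[j,i]), and
  # the subset's total load is twice its off-diagonal sum
  Ep <- pmax(matrix$values, 1)[sig, unname(cognate_map), drop = FALSE] - 1
  dimnames(Ep) <- list(sig, sig)
  pair_loads <- function(S) {
    sub <- Ep[S, S, drop = FALSE]
    rowSums(sub) + colSums(sub) - 2 * diag(sub)
  }
  contrib <- function(x, S)  # x outside S
    sum(Ep[x, S]) + sum(Ep[S, x])

  S <- sig
  while (length(S) > k) {
    loads <- pair_loads(S)
    worst <- S[loads == max(loads)]
    S <- setdiff(S, max(worst))  # ties drop the lexicographically largest
  }

  # local search past greedy's horizon: exchange one (then two) selected
  # pairs for eliminated ones whenever the total load strictly drops
  repeat {
    improved <- FALSE
    outside <- setdiff(sig, S)
    for (a in S) {
      Sm <- setdiff(S, a)
      ca <- contrib(a, Sm)
      for (b in outside) {
        if (contrib(b, Sm) < ca - 1e-9) {
          S <- sort(c(Sm, b)); improved <- TRUE; break
        }
      }
      if (improved) break
    }
    if (!improved && length(S) >= 2L && length(outside) >= 2L) {
      pairs_in <- utils::combn(S, 2L, simplify = FALSE)
      pairs_out <- utils::combn(outside, 2L, simplify = FALSE)
      for (ab in pairs_in) {
        Sm <- setdiff(S, ab)
        cost_in <- contrib(ab[1], Sm) + contrib(ab[2], Sm) +
          Ep[ab[1], ab[2]] + Ep[ab[2], ab[1]]
        for (cd in pairs_out) {
          cost_out <- contrib(cd[1], Sm) + contrib(cd[2], Sm) +
            Ep[cd[1], cd[2]] + Ep[cd[2], cd[1]]
          if (cost_out < cost_in - 1e-9) {
            S <- sort(c(Sm, cd)); improved <- TRUE; break
          }
        }
        if (improved) break
      }
    }
    if (!improved) break
  }

  load <- pair_loads(S)
  ord <- order(load, S)
  out <- data.frame(sigma_id = S[ord],
                    promoter_id = unname(cognate_map[S[ord]]),
                    offtarget_load = unname(load[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("ecf_orthogonal_selection", class(out))
  out
}

#' Compare predicted promoter scores with measured fold inductions
#'
#' Matches the two matrices by id, emits the per-cell scatter table, and
#' reports the Spearman rank correlation between model score and log2
#' fold induction over all cells.
#'
#' @param scores an `ecf_crosstalk` of kind `model_score`.
#' @param folds an `ecf_crosstalk` of kind `fold_induction` with the
#'   same sigma and promoter ids.
#' @return list with `rho` and `table` (data.frame `sigma_id,
#'   promoter_id, score, fold, log2_fold, cognate`).
#' @export
compare_predicted_measured <- function(scores, folds) {
  stopifnot(inherits(scores, "ecf_crosstalk"), inherits(folds, "ecf_crosstalk"))
  if (scores$kind != "model_score" || folds$kind != "fold_induction")
    stop("expected a model_score and a fold_induction matrix")
  if (!setequal(scores$sigma_ids, folds$sigma_ids) ||
      !setequal(scores$promoter_ids, folds$promoter_ids) ||
      length(scores$sigma_ids) != length(folds$sigma_ids) ||
      length(scores$promoter_ids) != length(folds$promoter_ids))
    stop("matrices must share sigma and promoter ids")
  fv <- folds$values[scores$sigma_ids, scores$promoter_ids, drop = FALSE]
  tab <- data.frame(
    sigma_id = rep(scores$sigma_ids, times = length(scores$promoter_ids)),
    promoter_id = rep(scores$promoter_ids, each = length(scores$sigma_ids)),
    score = as.vector(scores$values), fold = as.vector(fv),
    log2_fold = log2(as.vector(fv)), stringsAsFactors = FALSE)
  rho <- suppressWarnings(cor(tab$score, tab$log2_fold, method = "spearman"))
  list(rho = rho, table = tab)
}

# ---------------------------------------------------------------------------
# Growth

#' Exponential growth rate from an OD curve
#'
#' Least-squares slope of `ln(OD600)` versus time over the chosen
#' window.  When `window` is `NULL` the maximal-slope contiguous window
#' of `window_size` points is used (the "linear section" of the
#' semilog plot).
#'
#' @param times hours, strictly increasing.
#' @param od600 positive optical densities (1-cm pathlength).
#' @param window integer index range, or `NULL` for automatic choice.
#' @param window_size width of the automatic window (>= 3).
#' @return growth rate mu in 1/h, with the used window as attribute
#'   `window`.
#' @examples
#' growth_rate(0:5, 0.01 * 2^(0:5))  # log(2) per hour
#' @export
growth_rate <- function(times, od600, window = NULL, window_size = 5L) {
  if (length(times) != length(od600)) stop("times and od600 lengths differ")
  if (length(times) < 3L) stop("need at least 3 points in the window")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(od600 <= 0)) stop("od600 must be positive")
  y <- log(od600)
  slope <- function(ix) {
    t <- times[ix]; v <- y[ix]
    sum((t - mean(t)) * (v - mean(v))) / sum((t - mean(t))^2)
  }
  if (is.null(window)) {
    window_size <- max(3L, min(window_size, length(times)))
    starts <- seq_len(length(times) - window_size + 1L)
    sl <- vapply(starts, function(s) slope(s:(s + window_size - 1L)),
                 numeric(1))
    best <- which.max(sl)
    window <- best:(best + window_size - 1L)
  }
  if (length(window) < 3L) stop("need at least 3 points in the window")
  structure(slope(window), window = window)
}

#' Growth as a percentage of wild type, with toxicity flag
#'
#' Expresses a strain's growth statistic as a percentage of the mean of
#' wild-type control cultures; values strictly below `toxic_below`
#' percent are flagged toxic (the boundary itself is not).
#'
#' @param value the strain's growth statistic (e.g. mu in 1/h).
#' @param wt_values the control cultures' statistics (positive mean).
#' @param toxic_below toxicity threshold in percent.
#' @return list with `percent` and logical `toxic`.
#' @export
percent_of_wt <- function(value, wt_values, toxic_below = 75) {
  if (length(wt_values) == 0L) stop("wt_values must be non-empty")
  m <- mean(wt_values)
  if (!is.finite(m) || m <= 0) stop("wild-type mean must be positive")
  pct <- 100 * value / m
  list(percent = pct, toxic = pct < toxic_below)
}
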