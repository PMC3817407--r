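# Collapsed Gibbs sampler for gapped two-block motif discovery: one
# (-35 offset, spacer) site per sequence, blocks of fixed widths joined by
# a variable spacer whose length distribution is learned alongside the
# PWMs.  This is an in-package reimplementation of the two-block search
# concept used for ECF promoter motifs; it wraps no external binary.

#' Discover a bipartite motif by collapsed Gibbs sampling
#'
#' Samples one site (a -35 block, a spacer length, a -10 block) per
#' sequence.  Each sweep removes a sequence's site from the count
#' matrices, scores every feasible placement under the leave-one-out
#' predictive model (smoothed PWMs plus the smoothed spacer length
#' distribution), and resamples the placement from the corresponding
#' Boltzmann weights.  After `iters` sweeps a greedy finalisation pass
#' reassigns sites one sequence at a time, accepting a move only if the
#' total model information content increases, so the reported IC is
#' non-decreasing across finalisation.  The best of `n_restarts`
#' restarts (highest total IC) is returned.  Deterministic for a fixed
#' seed.
#'
#' @param seqs character vector of >= 5 A/C/G/T sequences, each long
#'   enough for the minimal footprint `w35 + min(spacer_range) + w10`.
#' @param w35,w10 block widths in nt (>= 4).
#' @param spacer_range integer pair `c(min, max)` of permitted spacer
#'   lengths.
#' @param n_restarts,iters restarts and Gibbs sweeps per restart.
#' @param seed integer seed.
#' @param pseudocount PWM smoothing mass; `spacer_pseudocount` likewise
#'   for the spacer distribution.
#' @param background base frequencies; default estimated from `seqs`.
#' @param spacer_pseudocount smoothing mass for spacer lengths.
#' @return an `ecf_promoter_model` (subgroup `NA`) with attributes
#'   `ic` (total information content in bits) and `sites` (data.frame of
#'   the final per-sequence placements, 0-based offsets).
#' @export
discover_two_block <- function(seqs, w35, w10, spacer_range,
                               n_restarts = 3L, iters = 100L, seed = 1L,
                               pseudocount = 1, background = NULL,
                               spacer_pseudocount = 1) {
  if (length(seqs) < 5L) stop("need at least 5 sequences")
  if (!is_count(w35, 4) || !is_count(w10, 4)) stop("block widths must be >= 4")
  spacer_range <- as.integer(spacer_range)
  if (length(spacer_range) != 2L || spacer_range[2] < spacer_range[1] ||
      spacer_range[1] < 0L)
    stop("spacer_range must be c(min, max) with 0 <= min <= max")
  spacers <- seq.int(spacer_range[1], spacer_range[2])
  min_foot <- w35 + spacer_range[1] + w10
  lens <- nchar(seqs)
  if (any(lens < min_foot))
    stop("infeasible footprint: sequence(s) shorter than ", min_foot, " nt")

  idx_list <- lapply(seqs, seq_to_idx)
  if (any(vapply(idx_list, anyNA, logical(1))))
    stop("sequences must be unambiguous A/C/G/T")

  if (is.null(background)) {
    tab <- tabulate(unlist(idx_list), nbins = 4)
    background <- pmax(tab / sum(tab), 0.01)
    background <- background / sum(background)
  }
  background <- check_background(background)
  n <- length(seqs)
  nsp <- length(spacers)

  # per-sequence feasible placements: all (start35 0-based, spacer) pairs
  placements <- lapply(seq_len(n), function(i) {
    out <- do.call(rbind, lapply(seq_len(nsp), function(k) {
      m <- lens[i] - (w35 + spacers[k] + w10) + 1L
      if (m < 1L) return(NULL)
      cbind(start35 = seq_len(m) - 1L, sp = k)
    }))
    out
  })

  site_counts <- function(i, start35, spk) {
    st10 <- start35 + w35 + spacers[spk]
    list(b35 = idx_list[[i]][start35 + seq_len(w35)],
         b10 = idx_list[[i]][st10 + seq_len(w10)])
  }

  ic_of_counts <- function(counts, nn) {
    p <- sweep(counts + pseudocount * background, 2, nn + pseudocount, "/")
    sum(p * log2(p / background))
  }

  rebuild_counts <- function(st, spk) {
    c35 <- matrix(0, 4, w35); c10 <- matrix(0, 4, w10)
    csp <- numeric(nsp)
    for (i in seq_len(n)) {
      s <- site_counts(i, st[i], spk[i])
      c35[cbind(s$b35, seq_len(w35))] <- c35[cbind(s$b35, seq_len(w35))] + 1
      c10[cbind(s$b10, seq_len(w10))] <- c10[cbind(s$b10, seq_len(w10))] + 1
      csp[spk[i]] <- csp[spk[i]] + 1
    }
    list(c35 = c35, c10 = c10, csp = csp)
  }

  obj_of <- function(st, spk) {
    cc <- rebuild_counts(st, spk)
    ic_of_counts(cc$c35, n) + ic_of_counts(cc$c10, n)
  }

  # column-shift moves against the phase-shift degeneracy: slide all
  # sites together, or one block alone (trading spacer length), and
  # accept greedily when the total IC increases
  apply_shifts <- function(st, spk) {
    repeat {
      cur <- obj_of(st, spk)
      cands <- list()
      for (d in c(-1L, 1L)) {
        if (all(st + d >= 0L) &&
            all(st + d + w35 + spacers[spk] + w10 <= lens))
          cands <- c(cands, list(list(st = st + d, spk = spk)))
        spk35 <- spk - d  # -35 block alone: spacer absorbs the shift
        if (all(spk35 >= 1L) && all(spk35 <= nsp) && all(st + d >= 0L))
          cands <- c(cands, list(list(st = st + d, spk = spk35)))
        spk10 <- spk + d  # -10 block alone
        if (all(spk10 >= 1L) && all(spk10 <= nsp) &&
            all(st + w35 + spacers[spk10] + w10 <= lens))
          cands <- c(cands, list(list(st = st, spk = spk10)))
      }
      if (!length(cands)) return(list(st = st, spk = spk))
      objs <- vapply(cands, function(c0) obj_of(c0$st, c0$spk), numeric(1))
      if (max(objs) <= cur + 1e-12) return(list(st = st, spk = spk))
      b <- cands[[which.max(objs)]]
      st <- b$st; spk <- b$spk
    }
  }

  run_restart <- function() {
    # random initial placements
    st <- integer(n); spk <- integer(n)
    for (i in seq_len(n)) {
      r <- placements[[i]][sample.int(nrow(placements[[i]]), 1L), ]
      st[i] <- r[1]; spk[i] <- r[2]
    }
    c35 <- matrix(0, 4, w35); c10 <- matrix(0, 4, w10)
    csp <- numeric(nsp)
    for (i in seq_len(n)) {
      s <- site_counts(i, st[i], spk[i])
      c35[cbind(s$b35, seq_len(w35))] <- c35[cbind(s$b35, seq_len(w35))] + 1
      c10[cbind(s$b10, seq_len(w10))] <- c10[cbind(s$b10, seq_len(w10))] + 1
      csp[spk[i]] <- csp[spk[i]] + 1
    }

    for (it in seq_len(iters)) {
      for (i in seq_len(n)) {
        s <- site_counts(i, st[i], spk[i])
        c35[cbind(s$b35, seq_len(w35))] <- c35[cbind(s$b35, seq_len(w35))] - 1
        c10[cbind(s$b10, seq_len(w10))] <- c10[cbind(s$b10, seq_len(w10))] - 1
        csp[spk[i]] <- csp[spk[i]] - 1
        lo35 <- log2(sweep(c35 + pseudocount * background, 2,
                           n - 1 + pseudocount, "/") / background)
        lo10 <- log2(sweep(c10 + pseudocount * background, 2,
                           n - 1 + pseudocount, "/") / background)
        lsp <- log2((csp + spacer_pseudocount) /
                      (n - 1 + spacer_pseudocount * nsp))
        s35 <- block_scores_all(lo35, idx_list[[i]])
        s10 <- block_scores_all(lo10, idx_list[[i]])
        pl <- placements[[i]]
        w <- s35[pl[, 1] + 1L] +
          s10[pl[, 1] + w35 + spacers[pl[, 2]] + 1L] + lsp[pl[, 2]]
        p <- exp((w - max(w)) * log(2))
        j <- sample.int(nrow(pl), 1L, prob = p)
        st[i] <- pl[j, 1]; spk[i] <- pl[j, 2]
        s <- site_counts(i, st[i], spk[i])
        c35[cbind(s$b35, seq_len(w35))] <- c35[cbind(s$b35, seq_len(w35))] + 1
        c10[cbind(s$b10, seq_len(w10))] <- c10[cbind(s$b10, seq_len(w10))] + 1
        csp[spk[i]] <- csp[spk[i]] + 1
      }
      if (it %% 10L == 0L) {  # periodic phase-shift correction
        sh <- apply_shifts(st, spk)
        if (!identical(sh$st, st) || !identical(sh$spk, spk)) {
          st <- sh$st; spk <- sh$spk
          cc <- rebuild_counts(st, spk)
          c35 <- cc$c35; c10 <- cc$c10; csp <- cc$csp
        }
      }
    }

    # final phase-shift correction, then greedy finalisation that
    # accepts only IC-increasing reassignments
    sh <- apply_shifts(st, spk)
    st <- sh$st; spk <- sh$spk
    cc <- rebuild_counts(st, spk)
    c35 <- cc$c35; c10 <- cc$c10; csp <- cc$csp
    obj <- ic_of_counts(c35, n) + ic_of_counts(c10, n)
    for (pass in seq_len(20L)) {
      changed <- FALSE
      for (i in seq_len(n)) {
        s <- site_counts(i, st[i], spk[i])
        m35 <- c35; m10 <- c10
        m35[cbind(s$b35, seq_len(w35))] <- m35[cbind(s$b35, seq_len(w35))] - 1
        m10[cbind(s$b10, seq_len(w10))] <- m10[cbind(s$b10, seq_len(w10))] - 1
        pl <- placements[[i]]
        best_j <- 0L; best_obj <- obj
        for (j in seq_len(nrow(pl))) {
          s2 <- site_counts(i, pl[j, 1], pl[j, 2])
          t35 <- m35; t10 <- m10
          t35[cbind(s2$b35, seq_len(w35))] <- t35[cbind(s2$b35, seq_len(w35))] + 1
          t10[cbind(s2$b10, seq_len(w10))] <- t10[cbind(s2$b10, seq_len(w10))] + 1
          o <- ic_of_counts(t35, n) + ic_of_counts(t10, n)
          if (o > best_obj + 1e-12) { best_obj <- o; best_j <- j }
        }
        if (best_j > 0L) {
          csp[spk[i]] <- csp[spk[i]] - 1
          c35 <- m35; c10 <- m10
          st[i] <- pl[best_j, 1]; spk[i] <- pl[best_j, 2]
          s2 <- site_counts(i, st[i], spk[i])
          c35[cbind(s2$b35, seq_len(w35))] <- c35[cbind(s2$b35, seq_len(w35))] + 1
          c10[cbind(s2$b10, seq_len(w10))] <- c10[cbind(s2$b10, seq_len(w10))] + 1
          csp[spk[i]] <- csp[spk[i]] + 1
          obj <- best_obj; changed <- TRUE
        }
      }
      if (!changed) break
    }
    list(ic = obj, st = st, spk = spk)
  }

  best <- with_seed(seed, {
    res <- NULL
    for (r in seq_len(n_restarts)) {
      cand <- run_restart()
      if (is.null(res) || cand$ic > res$ic) res <- cand
    }
    res
  })

  sites35 <- vapply(seq_len(n), function(i)
    idx_to_seq(idx_list[[i]][best$st[i] + seq_len(w35)]), character(1))
  sites10 <- vapply(seq_len(n), function(i)
    idx_to_seq(idx_list[[i]][best$st[i] + w35 + spacers[best$spk[i]] +
                               seq_len(w10)]), character(1))
  sp_lens <- spacers[best$spk]
  sp_counts <- table(factor(sp_lens, levels = spacers))
  model <- promoter_model(
    NA_integer_,
    build_pwm(sites35, background = background, pseudocount = pseudocount),
    build_pwm(sites10, background = background, pseudocount = pseudocount),
    spacer_model(setNames(as.numeric(sp_counts), spacers),
                 pseudocount = spacer_pseudocount, support = spacers))
  attr(model, "ic") <- best$ic
  attr(model, "sites") <- data.frame(
    seq = seq_len(n), start35 = best$st, spacer_length = sp_lens,
    site35 = sites35, site10 = sites10, stringsAsFactors = FALSE)
  model
}
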