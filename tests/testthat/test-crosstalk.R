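test_that("fluorescence folds follow the gated-geometric-mean definitions", {
  expect_equal(geometric_mean_fluorescence(c(100, 100, 100)), 100)
  expect_equal(geometric_mean_fluorescence(c(10, 1000)), 100)
  expect_equal(geometric_mean_fluorescence(c(-5, 10, 1000)), 100)
  expect_error(geometric_mean_fluorescence(c(-1, 0)), "no positive")

  expect_equal(fold_induction(10, 10), 1)
  expect_equal(fold_induction(4800, 10), 480)
  expect_error(fold_induction(5, 0), "positive")
  expect_equal(fold_repression(700, 10), 70)
  expect_error(fold_repression(700, 0), "positive")
  # reciprocal composition
  expect_equal(fold_induction(20, 5), 1 / fold_induction(5, 20))
})

test_that("activity classification uses strict fold thresholds", {
  m <- crosstalk_matrix(matrix(c(5, 1, 5.01, 1), 2, 2, byrow = TRUE,
                               dimnames = list(c("ECF01_1", "ECF02_2"),
                                               c("P_01_1", "P_02_2"))))
  act <- classify_activity(m)
  expect_identical(act$active_sigmas, "ECF02_2")  # 5.0 is inactive, 5.01 active

  ones <- crosstalk_matrix(matrix(1, 3, 3, dimnames = list(
    paste0("ECF0", 1:3, "_", 1:3), paste0("P_0", 1:3, "_", 1:3))))
  expect_length(classify_activity(ones)$active_sigmas, 0)

  # 58-of-86 constructed fixture: rows with a cognate fold of 20 are active
  r <- packaged_roster()
  folds <- matrix(1, 86, 29, dimnames = list(r$sigmas$id, r$promoters$id))
  for (i in seq_len(86)) {
    g <- r$sigmas$subgroup[i]
    p <- r$promoters$id[r$promoters$cognate_subgroup == g]
    if (r$sigmas$active[i] && length(p)) folds[i, p[1]] <- 20
  }
  # sigmas of active subgroups without a promoter still need a row max > 5:
  # give them an off-target promoter, as the screen observed
  no_prom <- r$sigmas$active &
    !(r$sigmas$subgroup %in% r$promoters$cognate_subgroup)
  folds[no_prom, 1] <- 8
  act86 <- classify_activity(crosstalk_matrix(folds))
  expect_length(act86$active_sigmas, 58)

  # repression matrices classify anti-sigmas with the >2-fold rule
  rep_m <- crosstalk_matrix(matrix(c(70, 1.9), 2, 1, dimnames = list(
    c("AS11_987", "AS02_2817"), "ECF11_987")), kind = "fold_repression")
  expect_identical(classify_activity(rep_m)$active_anti_sigmas, "AS11_987")

  # monotone: raising any cell never removes an active sigma
  m2 <- m; m2$values[1, 1] <- 100
  expect_true(all(act$active_sigmas %in%
                    classify_activity(m2)$active_sigmas))
})

test_that("off-target load matches hand arithmetic and symmetries", {
  ids_s <- c("ECF01_1", "ECF02_2", "ECF03_3")
  ids_p <- c("P_01_1", "P_02_2", "P_03_3")
  cmap <- setNames(ids_p, ids_s)
  diag_m <- crosstalk_matrix(matrix(1, 3, 3, dimnames = list(ids_s, ids_p)) +
                               diag(c(99, 99, 99)))
  expect_equal(unname(offtarget_load(diag_m, cmap)), c(0, 0, 0))

  # one off-diagonal cell of 3 loads the two pairs sharing its row/column
  v <- matrix(1, 3, 3, dimnames = list(ids_s, ids_p)); diag(v) <- 100
  v["ECF01_1", "P_02_2"] <- 3
  load <- offtarget_load(crosstalk_matrix(v), cmap)
  expect_equal(unname(load), c(2, 2, 0))

  # invariant to row/column permutation
  perm <- crosstalk_matrix(v[c(3, 1, 2), c(2, 3, 1)])
  expect_equal(offtarget_load(perm, cmap)[ids_s], load[ids_s])
})

test_that("greedy orthogonal selection keeps clean pairs and orders by load", {
  tt <- truth_table(8)
  m <- gen_crosstalk_matrix(tt, 0, 1)
  sel <- select_orthogonal(m, tt$cognate_map, 8)
  expect_equal(nrow(sel), 8)
  expect_true(all(sel$offtarget_load == 0))
  expect_true(!is.unsorted(sel$offtarget_load))
  expect_error(select_orthogonal(m, tt$cognate_map, 9), "between 1")

  # planted truth: 20 clean + 10 promiscuous pairs under noise
  off <- matrix(1, 30, 30)
  promisc <- 21:30
  off[promisc, ] <- 4           # promiscuous sigmas activate everything
  tt30 <- truth_table(30, cognate_fold = 100, offtarget_fold = off)
  hits <- 0
  for (s in 1:100) {
    noisy <- gen_crosstalk_matrix(tt30, noise_cv = 0.3, seed = s)
    sel <- select_orthogonal(noisy, tt30$cognate_map, 20)
    if (setequal(sel$sigma_id, tt30$sigma_ids[1:20])) hits <- hits + 1
  }
  expect_gte(hits, 95)

  # invariant to input row/column order
  noisy <- gen_crosstalk_matrix(tt30, noise_cv = 0.3, seed = 7)
  shuf <- crosstalk_matrix(noisy$values[rev(seq_len(30)), c(16:30, 1:15)])
  expect_identical(select_orthogonal(shuf, tt30$cognate_map, 20),
                   select_orthogonal(noisy, tt30$cognate_map, 20))
})

test_that("greedy selection stays within 10% of the brute-force optimum", {
  total_load <- function(m, cmap, keep) {
    sub <- crosstalk_matrix(m$values[keep, unname(cmap[keep]), drop = FALSE])
    sum(offtarget_load(sub, cmap[keep]))
  }
  worst_gap <- 0
  for (s in 1:10) {
    tt <- truth_table(8, cognate_fold = 50,
                      offtarget_fold = with_seed(s, matrix(
                        exp(abs(stats::rnorm(64, 0, 1))), 8, 8)))
    m <- gen_crosstalk_matrix(tt, 0, 1)
    greedy <- select_orthogonal(m, tt$cognate_map, 4)
    g_load <- total_load(m, tt$cognate_map, greedy$sigma_id)
    combos <- utils::combn(tt$sigma_ids, 4, simplify = FALSE)
    best <- min(vapply(combos, function(k)
      total_load(m, tt$cognate_map, k), numeric(1)))
    gap <- if (best == 0) as.numeric(g_load > 0) else (g_load - best) / best
    worst_gap <- max(worst_gap, gap)
  }
  expect_lte(worst_gap, 0.10)
})

test_that("predicted scores track measured folds when they share a truth", {
  models <- list(`1` = toy_model(1, "TTGACAA", "CGTCTA"),
                 `2` = toy_model(2, "GGAACTT", "TCATGT"),
                 `3` = toy_model(3, "CCTTAAG", "AGAGAG"))
  proms <- rbind(
    gen_subgroup_promoters(spec_A(0.05), 1, seed = 1, subgroup = 1),
    gen_subgroup_promoters(spec_B(0.05), 1, seed = 2, subgroup = 2),
    gen_subgroup_promoters(motif_spec("CCTTAAG", "AGAGAG", 0.05), 1,
                           seed = 3, subgroup = 3))
  scores <- score_crosstalk(models, proms, sigma_ids = c("1", "2", "3"))
  # folds generated monotonically from the scores, no noise -> rho = 1
  folds <- crosstalk_matrix(2^(scores$values / 4 + 2),
                            sigma_ids = scores$sigma_ids,
                            promoter_ids = scores$promoter_ids)
  cmp <- compare_predicted_measured(scores, folds)
  expect_equal(cmp$rho, 1)
  expect_equal(nrow(cmp$table), 9)

  # independent shuffled folds decorrelate
  null_rhos <- vapply(1:100, function(s) {
    shuffled <- crosstalk_matrix(
      matrix(with_seed(s, sample(as.vector(folds$values))), 3, 3,
             dimnames = dimnames(folds$values)))
    compare_predicted_measured(scores, shuffled)$rho
  }, numeric(1))
  expect_gte(sum(abs(null_rhos) < 0.999), 95)  # 9 cells: perfect rank match is rare
  expect_lt(abs(mean(null_rhos)), 0.2)
})

test_that("growth rates come from the semilog slope with WT percentages", {
  t <- 0:6
  expect_equal(as.numeric(growth_rate(t, 0.01 * 2^t)), log(2),
               tolerance = 1e-12)
  expect_equal(as.numeric(growth_rate(t, rep(0.3, 7))), 0)
  expect_error(growth_rate(c(0, 1), c(1, 2)), "3 points")

  # noisy exponential recovered within 5%
  mu <- 0.8
  errs <- vapply(1:50, function(s) with_seed(s, {
    od <- 0.02 * exp(mu * t) * exp(stats::rnorm(7, 0, 0.02))
    abs(as.numeric(growth_rate(t, od)) - mu) / mu
  }), numeric(1))
  expect_lt(max(errs), 0.05)

  p <- percent_of_wt(1, rep(2, 8))
  expect_equal(p$percent, 50)
  expect_true(p$toxic)
  expect_false(percent_of_wt(0.75, rep(1, 8))$toxic)   # boundary not toxic
  expect_true(percent_of_wt(0.749, rep(1, 8))$toxic)
  expect_equal(percent_of_wt(3, rep(3, 4))$percent, 100)
})

test_that("crosstalk matrices round-trip through TSV with their kind", {
  tt <- truth_table(4)
  m <- gen_crosstalk_matrix(tt, 0.2, seed = 3)
  f <- tempfile(fileext = ".tsv")
  write_crosstalk_tsv(m, f)
  m2 <- read_crosstalk_tsv(f)
  expect_equal(m2$values, m$values, tolerance = 1e-12)
  expect_identical(m2$kind, "fold_induction")
})

test_that("predicted and measured matrices agree on the top-k orthogonal set", {
  # 8 subgroups; 7 and 8 are chimeric motifs (-35 of one clean subgroup,
  # -10 of another), so both the score route and the measured route see
  # them as the promiscuous pairs to exclude
  base <- list(c("TTGACAA", "CGTCTA"), c("GGAACTT", "TCATGT"),
               c("CCTTAAG", "AGAGAG"), c("ACACGCA", "TTCGAT"),
               c("GTGTTGC", "CCAATC"), c("TAGGCTA", "GAGTCC"))
  cons <- c(base, list(c(base[[1]][1], base[[2]][2]),
                       c(base[[3]][1], base[[4]][2])))
  models <- setNames(lapply(seq_along(cons), function(i)
    toy_model(i, cons[[i]][1], cons[[i]][2])), as.character(1:8))
  proms <- do.call(rbind, lapply(seq_along(cons), function(i)
    gen_subgroup_promoters(motif_spec(cons[[i]][1], cons[[i]][2], 0.05),
                           1, seed = 600 + i, subgroup = i)))
  cmap <- setNames(proms$id, as.character(1:8))

  scores <- score_crosstalk(models, proms, sigma_ids = as.character(1:8))
  # monotone score -> fold link: scores below a background-match level
  # (6 bits) mean no activation
  predicted_folds <- crosstalk_matrix(1 + pmax(scores$values - 6, 0),
                                      sigma_ids = scores$sigma_ids,
                                      promoter_ids = scores$promoter_ids)
  sel_pred <- select_orthogonal(predicted_folds, cmap, 6)
  expect_setequal(sel_pred$sigma_id, as.character(1:6))

  off <- matrix(1, 8, 8)
  for (ij in list(c(7, 1), c(1, 7), c(7, 2), c(2, 7),
                  c(8, 3), c(3, 8), c(8, 4), c(4, 8)))
    off[ij[1], ij[2]] <- 12
  tt <- truth_table(8, cognate_fold = 100, offtarget_fold = off,
                    sigma_ids = as.character(1:8), promoter_ids = proms$id)
  agree <- sum(vapply(1:100, function(s) {
    meas <- gen_crosstalk_matrix(tt, noise_cv = 0.3, seed = s)
    setequal(select_orthogonal(meas, cmap, 6)$sigma_id, sel_pred$sigma_id)
  }, logical(1)))
  expect_gte(agree, 90)
})
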