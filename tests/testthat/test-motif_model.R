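test_that("build_pwm matches hand-computed probabilities and log-odds", {
  # a column containing each base once, uniform background, no pseudocount:
  # all log-odds are zero
  pwm0 <- build_pwm(c("A", "C", "G", "T"), pseudocount = 0)
  expect_true(all(abs(pwm0$logodds) < 1e-12))

  pwm <- build_pwm(c("TGA", "TGA", "TGA", "TGC"), pseudocount = 1)
  expect_equal(unname(pwm$probs["A", 3]), 0.65)
  expect_equal(unname(pwm$logodds["A", 3]), log2(0.65 / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(colSums(pwm$probs)), rep(1, 3), tolerance = 1e-12)
  # invariant: logodds derived exactly from probs and background
  expect_equal(pwm$logodds, log2(pwm$probs / pwm$background))

  expect_error(build_pwm(c("ACG", "ACGT")), "same length")
  expect_error(build_pwm(character(0)), "at least one")
  # with a pseudocount no probability is 0 or 1, so no infinite log-odds
  p <- build_pwm(c("AAAA", "AAAA"), pseudocount = 0.5)
  expect_true(all(p$probs > 0 & p$probs < 1))
  expect_true(all(is.finite(p$logodds)))
})

test_that("score_block sums per-column log-odds and is maximal at consensus", {
  pwm <- build_pwm(c("TGA", "TGA", "TGA", "TGC"), pseudocount = 1)
  expect_equal(score_block(pwm, "TGA"),
               2 * log2(0.85 / 0.25) + log2(0.65 / 0.25), tolerance = 1e-12)
  cons <- consensus_seq(pwm)
  cons_score <- score_block(pwm, cons)
  # column-wise bound: no sequence outscores the consensus
  with_seed(42, for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
    expect_lte(score_block(pwm, s), cons_score)
  })
  expect_error(score_block(pwm, "TG"), "length")
  expect_error(score_block(pwm, "TGN"), "ambiguous")
})

test_that("spacer penalties are log-odds to the mode with -Inf off-support", {
  sp <- spacer_model(c(`16` = 10, `17` = 5), pseudocount = 1, support = 15:18)
  expect_equal(spacer_penalty(sp, 16), 0)
  expect_equal(spacer_penalty(sp, 17), log2(6 / 11), tolerance = 1e-12)
  expect_equal(spacer_penalty(sp, 15), log2(1 / 11), tolerance = 1e-12)
  expect_identical(spacer_penalty(sp, 14), -Inf)
  expect_true(all(spacer_penalty(sp, 15:18) <= 0))
})

test_that("information content follows the closed forms", {
  uni <- pwm_from_probs(matrix(0.25, 4, 2))
  expect_equal(information_content(uni)$per_position, c(0, 0),
               ignore_attr = TRUE)
  det <- pwm_from_probs(matrix(c(1, 0, 0, 0), 4, 1))
  expect_equal(information_content(det)$total, 2)
  half <- pwm_from_probs(matrix(c(0.5, 0.5, 0, 0), 4, 1))
  expect_equal(information_content(half)$total, 1)
})

test_that("scan_promoter equals the exhaustive brute-force oracle", {
  model <- toy_model()
  with_seed(99, {
    for (i in 1:50) {
      s <- random_dna(110, gc = runif(1, 0.3, 0.7))
      hit <- scan_promoter(model, s)
      oracle <- brute_force_scan(model, s)
      expect_equal(hit$start35, oracle$start35)
      expect_equal(hit$spacer_length, oracle$spacer_length)
      expect_equal(hit$total, oracle$total, tolerance = 1e-9)
      # hit invariants
      expect_equal(hit$start10, hit$start35 + 6 + hit$spacer_length)
      expect_equal(hit$total, hit$score35 + hit$score10 +
                     hit$spacer_penalty + hit$up_term, tolerance = 1e-12)
    }
  })
  expect_error(scan_promoter(model, "ACGTACGT"), "footprint")
})

test_that("scan_promoter recovers planted consensus sites exactly", {
  model <- toy_model()
  spec <- motif_spec("TTGACA", "TATAAT", mutation_rate = 0,
                     spacer_dist = c(`16` = 1))
  cons_total <- score_block(model$pwm35, "TTGACA") +
    score_block(model$pwm10, "TATAAT")
  for (seed in 1:20) {
    pr <- gen_subgroup_promoters(spec, 1, seed = seed)
    hit <- scan_promoter(model, pr$sequence[1])
    expect_equal(hit$start35, pr$planted_start35[1])
    expect_equal(hit$spacer_length, 16)
    expect_equal(hit$spacer_penalty, 0)
    expect_gte(hit$total, cons_total)  # equality unless background outscores
  }
})

test_that("adding flanking sequence never decreases the best scan score", {
  for (beta in c(0, 2)) {
    model <- toy_model(up_beta = beta)
    with_seed(7, for (i in 1:20) {
      s <- random_dna(80)
      flank <- random_dna(15)
      base <- scan_promoter(model, s)$total
      flanked <- scan_promoter(model, paste0(flank, s, flank))$total
      expect_gte(flanked, base - 1e-12)
    })
  }
})

test_that("two-block Gibbs discovery recovers planted motifs", {
  spec <- spec_B(rate = 0.1)
  ok <- 0
  for (seed in 1:5) {
    pr <- gen_subgroup_promoters(spec, 30, seed = 200 + seed)
    mod <- discover_two_block(pr$sequence, 7, 6, c(15, 17),
                              n_restarts = 3, iters = 60, seed = seed)
    f <- (7 * match_frac(consensus_seq(mod$pwm35), spec$consensus35) +
            6 * match_frac(consensus_seq(mod$pwm10), spec$consensus10)) / 13
    if (f >= 0.9) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("Gibbs discovery is deterministic and validates its inputs", {
  pr <- gen_subgroup_promoters(spec_A(), 10, seed = 3)
  m1 <- discover_two_block(pr$sequence, 7, 6, c(15, 17),
                           n_restarts = 1, iters = 10, seed = 9)
  m2 <- discover_two_block(pr$sequence, 7, 6, c(15, 17),
                           n_restarts = 1, iters = 10, seed = 9)
  expect_equal(attr(m1, "sites"), attr(m2, "sites"))
  expect_equal(m1$pwm35$probs, m2$pwm35$probs)
  expect_error(discover_two_block(pr$sequence, 7, 6, c(17, 15)),
               "spacer_range")
  expect_error(discover_two_block(pr$sequence[1:3], 7, 6, c(15, 17)),
               "at least 5")
  expect_error(discover_two_block(substr(pr$sequence, 1, 20), 7, 6, c(15, 17)),
               "footprint")
})

test_that("planted data yields higher model information than pure background", {
  wins <- 0
  for (seed in 1:5) {
    pr <- gen_subgroup_promoters(spec_A(0.1), 20, seed = 300 + seed)
    bg <- vapply(1:20, function(i) random_dna(80, seed = 7000 + 20 * seed + i),
                 character(1))
    ic_planted <- attr(discover_two_block(pr$sequence, 7, 6, c(15, 17),
                                          n_restarts = 1, iters = 30,
                                          seed = seed), "ic")
    ic_bg <- attr(discover_two_block(bg, 7, 6, c(15, 17),
                                     n_restarts = 1, iters = 30,
                                     seed = seed), "ic")
    if (ic_planted > ic_bg) wins <- wins + 1
  }
  expect_gte(wins, 4)
})
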