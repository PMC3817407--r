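test_that("upstream extraction walks operons and honours strand", {
  g <- gen_toy_genome(4, intergenic_gap = 200, seed = 11)
  for (k in seq_along(g$sigma_genes)) {
    sig <- g$sigma_genes[k]
    reg <- extract_upstream(g$genome, g$annotation, sig,
                            max_len = 300, operon_gap = 50)
    # two-gene operons (even k) must be walked to the head
    if (k %% 2 == 0) {
      expect_length(reg$operon_members, 2)
      expect_identical(reg$operon_members[2], sig)
    } else {
      expect_identical(reg$operon_members, sig)
    }
    # the planted motif (-60..-1 of the planted window) lies in the region
    planted60 <- substr(g$planted$promoter_seq[k], 1, 60)
    expect_true(grepl(planted60, reg$region, fixed = TRUE))
  }
  expect_error(extract_upstream(g$genome, g$annotation, "nope"), "not found")
})

test_that("upstream extraction truncates at the genome edge", {
  ann <- data.frame(gene_id = "g1", start = 10, end = 100, strand = "+",
                    contig = "c")
  genome <- strrep("ACGT", 50)
  reg <- extract_upstream(genome, ann, "g1", max_len = 300)
  expect_true(reg$truncated)
  expect_equal(reg$length, 9)
  expect_identical(reg$region, substr(genome, 1, 9))

  # minus strand: region is the reverse complement of the downstream segment
  ann2 <- data.frame(gene_id = "g2", start = 41, end = 80, strand = "-",
                     contig = "c")
  reg2 <- extract_upstream(genome, ann2, "g2", max_len = 50)
  expect_identical(reg2$region, revcomp(substr(genome, 81, 130)))
  expect_false(reg2$truncated)
})

test_that("candidate assessment classifies planted promoters to their cognates", {
  models <- list(`1` = toy_model(1, "TTGACAA", "CGTCTA"),
                 `2` = toy_model(2, "GGAACTT", "TCATGT"))
  prA <- gen_subgroup_promoters(spec_A(0.1), 20, seed = 1, subgroup = 1)
  prB <- gen_subgroup_promoters(spec_B(0.1), 20, seed = 2, subgroup = 2,
                                start_uid = 2000)
  prom <- rbind(prA, prB)
  cmap <- setNames(rep(c("1", "2"), each = 20), prom$id)
  res <- assess_candidates(prom, models, cmap)
  correct <- sum(res$margin > 0)
  expect_gte(correct, 38)

  # ranking invariant to input order
  shuf <- with_seed(5, prom[sample.int(nrow(prom)), ])
  res2 <- assess_candidates(shuf, models, cmap)
  expect_identical(res2$promoter_id, res$promoter_id)

  # degenerate competitor set: single model
  one <- assess_candidates(prA[1, ], models["1"], cmap[prA$id[1]])
  expect_identical(one$best_offtarget_score, -Inf)
  expect_identical(one$margin, Inf)

  # a promoter equal to a non-cognate consensus names that model off-target
  confuse <- promoter_record("P_01_9999", paste0(
    random_dna(25, seed = 3), "GGAACTT", random_dna(16, seed = 4), "TCATGT",
    random_dna(26, seed = 5)))
  r3 <- assess_candidates(confuse, models, setNames("1", "P_01_9999"))
  expect_identical(r3$offtarget_model, "2")
  expect_lt(r3$margin, 0)
})

test_that("host exclusion flags sigma70-like promoters, rarely background", {
  host <- host_promoter_models()
  hostlike <- paste0(random_dna(20, seed = 1), "TTGACA",
                     random_dna(17, seed = 2), "TATAAT",
                     random_dna(31, seed = 3))
  expect_true(host_exclusion_screen(hostlike, host))
  flagged <- sum(vapply(1:100, function(s)
    host_exclusion_screen(random_dna(80, seed = 1000 + s), host), logical(1)))
  expect_lte(flagged, 5)
  expect_false(host_exclusion_screen(hostlike, host, cutoff = Inf))
})

test_that("UP-element replacement renames and preserves -35..+20", {
  p <- promoter_record("P_15_436", random_dna(80, seed = 6))
  up <- apply_up_element(p)
  expect_identical(up$id, "P_15_UP436")
  expect_true(up$up_modified)
  expect_equal(nchar(up$sequence), 80)
  expect_identical(substr(up$sequence, 26, 80), substr(p$sequence, 26, 80))
  expect_identical(substr(up$sequence, 1, 25), default_up_element())
  expect_error(apply_up_element(p, "AAAA"), "25 nt")
  expect_error(apply_up_element(up), "already")
})

test_that("chimera enumeration multiplies distinct specificity classes", {
  # 16 distinct -35 classes x 10 distinct -10 classes -> 160 combinations
  cl <- specificity_classes(packaged_roster())
  expect_equal(length(unique(cl$classes35)), 16)
  expect_equal(length(unique(cl$classes10)), 10)
  expect_equal(enumerate_chimeras(cl)$count, 160)

  # 3 x 4 classes with 5 natural combos -> 12 total, 7 novel
  subs <- as.character(1:5)
  cl2 <- list(classes35 = setNames(c("a", "b", "c", "a", "b"), subs),
              classes10 = setNames(c("w", "x", "y", "z", "w"), subs))
  e <- enumerate_chimeras(cl2)
  expect_equal(e$count, 12)
  expect_equal(nrow(e$natural), 5)
  expect_equal(nrow(e$novel), 7)

  # single natural combination: nothing novel
  cl3 <- list(classes35 = c(`1` = "a"), classes10 = c(`1` = "w"))
  e3 <- enumerate_chimeras(cl3)
  expect_equal(e3$count, 1)
  expect_equal(nrow(e3$novel), 0)
})

test_that("chimeric promoters mix donor blocks at the requested spacer", {
  A <- toy_model(2, "GGAACTT", "GTCTGA", c(`15` = 1, `16` = 3, `17` = 1))
  B <- toy_model(11, "TGATCC", "CGTCTA", c(`16` = 2, `17` = 4))
  ctx <- promoter_record("P_02_100", random_dna(80, seed = 9))
  ch <- build_chimeric_promoter(A, B, 16, ctx)
  expect_identical(substr(ch$sequence, 26, 32), "GGAACTT")
  expect_identical(substr(ch$sequence, 33 + 16, 38 + 16), "CGTCTA")
  # downstream of the -10 block unchanged
  expect_identical(substr(ch$sequence, 55, 80), substr(ctx$sequence, 55, 80))
  expect_error(build_chimeric_promoter(A, B, 3, ctx), "outside")

  # identity case: chimera(A, A) at the modal spacer plants A's consensus
  chAA <- build_chimeric_promoter(A, A, A$spacer$mode, ctx)
  expect_identical(substr(chAA$sequence, 26, 32), "GGAACTT")
  expect_identical(substr(chAA$sequence, 26 + 7 + 16, 25 + 7 + 16 + 6),
                   "GTCTGA")

  # the chimeric model scores its chimera at the full consensus sum
  chim_model <- promoter_model(NA, A$pwm35, B$pwm10,
                               spacer_model(c(`16` = 1)))
  hit <- scan_promoter(chim_model, ch$sequence)
  expect_equal(hit$total, consensus_score(chim_model), tolerance = 1e-9)
  # and at least as high as either parent model scores it
  expect_gte(hit$total, scan_promoter(A, ch$sequence)$total - 1e-9)
  expect_gte(hit$total, scan_promoter(B, ch$sequence)$total - 1e-9)
})

test_that("bipartite margins exceed single-block margins on shared-block pairs", {
  # two subgroups sharing the -35 block but differing in -10 and spacer
  shared35 <- "TTGACA"
  m1 <- toy_model(1, shared35, "CGTCTA", c(`15` = 4, `16` = 1))
  m2 <- toy_model(2, shared35, "TCATGT", c(`17` = 1, `18` = 4))
  s1 <- gen_subgroup_promoters(
    motif_spec(shared35, "CGTCTA", 0, spacer_dist = c(`15` = 1)),
    10, seed = 31, subgroup = 1)
  best_block <- function(pwm, seq) {
    max(vapply(0:(nchar(seq) - pwm$width), function(o)
      score_block(pwm, substr(seq, o + 1, o + pwm$width)), numeric(1)))
  }
  strict <- 0
  for (i in seq_len(nrow(s1))) {
    seq <- s1$sequence[i]
    full_margin <- scan_promoter(m1, seq)$total - scan_promoter(m2, seq)$total
    b35_margin <- best_block(m1$pwm35, seq) - best_block(m2$pwm35, seq)  # 0
    b10_margin <- best_block(m1$pwm10, seq) - best_block(m2$pwm10, seq)
    expect_gt(full_margin, b35_margin)
    expect_gte(full_margin, b10_margin - 1e-9)
    if (full_margin > b10_margin + 1e-9) strict <- strict + 1
  }
  expect_gte(strict, 8)  # the spacer/-35 coupling adds real discrimination
})

test_that("end-to-end mining recovers planted promoters from a toy genome", {
  g <- gen_toy_genome(20, intergenic_gap = 250, seed = 77,
                      spec = example_motif_spec(1, mutation_rate = 0.05))
  regions <- lapply(g$sigma_genes, function(id)
    extract_upstream(g$genome, g$annotation, id, max_len = 200,
                     operon_gap = 50))
  seqs <- vapply(regions, `[[`, character(1), "region")
  expect_true(all(nchar(seqs) >= 60))
  mod <- discover_two_block(seqs, 7, 6, c(15, 17),
                            n_restarts = 2, iters = 50, seed = 3)
  # the planted -35 block sits 35 nt before each region's 3' end
  hits <- vapply(seqs, function(s)
    scan_promoter(mod, s)$start35, numeric(1))
  expected <- nchar(seqs) - 35
  recovered <- sum(abs(hits - expected) <= 2)
  expect_gte(recovered, ceiling(0.95 * length(seqs)))
})
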