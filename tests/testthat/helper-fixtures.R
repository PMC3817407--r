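# Shared fixtures and independent oracles used across test files.

# exhaustive brute-force scan oracle: enumerates every (-35 offset, spacer)
# placement by direct per-column summation, independent of scan_promoter()
brute_force_scan <- function(model, seq) {
  w35 <- model$pwm35$width; w10 <- model$pwm10$width
  best <- NULL
  chars <- strsplit(seq, "")[[1]]
  col_sum <- function(pwm, start0) {
    s <- 0
    for (j in seq_len(pwm$width))
      s <- s + unname(pwm$logodds[chars[start0 + j], j])
    s
  }
  for (sp in model$spacer$support) {
    pen <- spacer_penalty(model$spacer, sp)
    max35 <- nchar(seq) - (w35 + sp + w10)
    if (max35 < 0) next
    for (o in 0:max35) {
      tot <- col_sum(model$pwm35, o) + col_sum(model$pwm10, o + w35 + sp) + pen
      replace <- is.null(best) || tot > best$total ||
        (tot == best$total &&
           (o < best$start35 ||
              (o == best$start35 && sp < best$spacer_length)))
      if (replace) best <- list(start35 = o, spacer_length = sp, total = tot)
    }
  }
  best
}

# simple well-separated bipartite model for tests
toy_model <- function(subgroup = 1, c35 = "TTGACA", c10 = "TATAAT",
                      spacer_counts = c(`15` = 2, `16` = 5, `17` = 2),
                      up_beta = 0) {
  promoter_model(subgroup,
                 build_pwm(rep(c35, 8)), build_pwm(rep(c10, 8)),
                 spacer_model(spacer_counts), up_beta = up_beta)
}

# two clearly distinct motif specs used for planted-truth classification
spec_A <- function(rate = 0.1) motif_spec("TTGACAA", "CGTCTA", rate)
spec_B <- function(rate = 0.1) motif_spec("GGAACTT", "TCATGT", rate)

random_dna <- function(n, gc = 0.5, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                  prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                           (1 - gc) / 2)), collapse = "")
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# fraction of matching positions between two equal-length strings
match_frac <- function(a, b) {
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

# write a minimal roster to a temp dir and return the four paths
write_toy_roster <- function(dir = tempfile("roster")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- data.frame(id = c("ECF11_987", "ECF11_3726", "ECF02_2817", "ECF02_4"),
                    subgroup = c(11, 11, 2, 2),
                    organism = "toy",
                    domain2_class = c("a", "a", "b", "b"),
                    domain4_class = c("x", "x", "y", "y"),
                    stringsAsFactors = FALSE)
  anti <- data.frame(id = "AS11_987", cognate_sigma_id = "ECF11_987",
                     stringsAsFactors = FALSE)
  prom <- setNames(c(random_dna(80, seed = 1), random_dna(80, seed = 2)),
                   c("P_11_3726", "P_02_2817"))
  paths <- file.path(dir, c("sigmas.tsv", "anti_sigmas.tsv", "promoters.fasta"))
  write_tsv_table(sig, paths[1])
  write_tsv_table(anti, paths[2])
  write_fasta_dna(prom, paths[3])
  paths
}
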