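# Regenerates inst/extdata/roster_synthetic: a synthetic reconstruction of
# the study's library roster.  Counts match the published design (86 sigmas,
# two per subgroup; 62 anti-sigmas, 46 with an active sigma, 25 active;
# 29 promoters, 26 active; 58 active sigmas; 36 sigmas in the anti screen;
# 16 distinct -35 and 10 distinct -10 specificity classes); organisms and
# most uids are placeholders.  Run from the repo root after installing:
#   Rscript tools/make_roster.R

library(ecfortho)
`%||%` <- function(a, b) if (is.null(a)) b else a

out <- file.path("inst", "extdata", "roster_synthetic")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

subgroups <- 1:43
# ids the study's text prints, kept verbatim so examples read naturally
special <- list(`2` = c(2817), `11` = c(987, 3726), `15` = c(436),
                `16` = c(3622), `20` = c(992), `25` = c(4311))

uids <- with_seed(derive_seed(20260924L, "roster_uids"), {
  pool <- setdiff(sample(1000:9999), unlist(special))
  k <- 0L
  lapply(subgroups, function(g) {
    sp <- special[[as.character(g)]] %||% integer(0)
    need <- 2L - length(sp)
    extra <- pool[k + seq_len(need)]; k <<- k + need
    c(sp, extra)
  })
})

inactive_subgroups <- c(5:10, 14, 27, 36:40, 43)         # 14 -> 58 active
sigmas <- do.call(rbind, lapply(seq_along(subgroups), function(i) {
  g <- subgroups[i]
  data.frame(id = vapply(uids[[i]], function(u) sigma_id(g, u), character(1)),
             subgroup = g,
             organism = "synthetic placeholder",
             domain2_class = sprintf("c10_%02d", ((g - 1) %% 10) + 1),
             domain4_class = sprintf("c35_%02d", ((g - 1) %% 16) + 1),
             active = !(g %in% inactive_subgroups),
             stringsAsFactors = FALSE)
}))

# anti-sigmas: both sigmas of subgroups 1..31 (62 total; 46 of them have an
# active cognate sigma given the inactive subgroups above)
anti_sub <- 1:31
anti <- do.call(rbind, lapply(anti_sub, function(g) {
  i <- match(g, subgroups)
  data.frame(id = vapply(uids[[i]], function(u) anti_sigma_id(g, u), character(1)),
             cognate_sigma_id = vapply(uids[[i]], function(u) sigma_id(g, u),
                                       character(1)),
             stringsAsFactors = FALSE)
}))
with_active_sigma <- sigmas$active[match(anti$cognate_sigma_id, sigmas$id)]
stopifnot(sum(with_active_sigma) == 46)
anti$active <- FALSE
anti$active[which(with_active_sigma)[1:25]] <- TRUE     # 25 most active

# 36 sigmas assayed against the 25 active anti-sigmas
sigmas$anti_screened <- FALSE
sigmas$anti_screened[which(sigmas$active)[1:36]] <- TRUE

# promoters: the 29 subgroups with promoter models (FecI-like 5-10 excluded)
prom_sub <- c(1:4, 11:35)
prom_uid <- function(g) {
  sp <- special[[as.character(g)]]
  if (g == 11) 3726 else if (!is.null(sp)) sp[1] else uids[[match(g, subgroups)]][1]
}
up_sub <- c(15, 25)
inactive_prom <- c(14, 27, 33)                          # 26 active
records <- lapply(prom_sub, function(g) {
  spec <- example_motif_spec(g, mutation_rate = 0.05)
  seq <- gen_subgroup_promoters(spec, 1,
    seed = derive_seed(20260924L, paste0("roster_prom_", g)))$sequence[1]
  rec <- promoter_record(promoter_id(g, prom_uid(g)), seq,
                         source = "synthetic reconstruction")
  if (g %in% up_sub) rec <- apply_up_element(rec)
  rec
})
prom <- do.call(rbind, records)
prom$cognate_subgroup <- prom_sub
prom$active <- !(prom_sub %in% inactive_prom)

write_tsv_table(sigmas, file.path(out, "sigmas.tsv"),
  comments = "synthetic reconstruction of the 86-sigma library roster")
write_tsv_table(anti, file.path(out, "anti_sigmas.tsv"),
  comments = "synthetic reconstruction of the 62 anti-sigma roster")
write_fasta_dna(setNames(prom$sequence, prom$id),
                file.path(out, "promoters.fasta"))
write_tsv_table(prom[c("id", "cognate_subgroup", "active", "up_modified",
                       "source")],
                file.path(out, "promoter_meta.tsv"),
  comments = "synthetic reconstruction of the 29-promoter roster")

r <- load_roster(file.path(out, "sigmas.tsv"), file.path(out, "anti_sigmas.tsv"),
                 file.path(out, "promoters.fasta"),
                 file.path(out, "promoter_meta.tsv"))
print(r)
str(screen_design(r))
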