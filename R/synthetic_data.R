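# Seeded generators for every input the pipeline consumes: promoter sets
# with planted bipartite motifs, toy genomes with sigma operons, noisy
# crosstalk matrices, switch transfer functions, and presence/absence
# matrices.  Every generator is a pure function of (parameters, seed):
# it runs under with_seed() and leaves the caller's RNG untouched.

#' Specification of a planted bipartite motif
#'
#' @param consensus35,consensus10 consensus A/C/G/T strings of the two
#'   blocks.
#' @param mutation_rate per-position probability that a planted base is
#'   replaced by a different base chosen uniformly (in `[0, 0.5)`), so
#'   the per-position mismatch fraction versus the consensus equals the
#'   rate by construction.
#' @param spacer_dist named numeric vector of spacer-length probabilities
#'   (names are lengths in nt), summing to 1.
#' @param background_gc GC fraction of the i.i.d. background.
#' @return object of class `ecf_motif_spec`.
#' @export
motif_spec <- function(consensus35, consensus10, mutation_rate = 0.1,
                       spacer_dist = c(`15` = 0.25, `16` = 0.5, `17` = 0.25),
                       background_gc = 0.5) {
  consensus35 <- toupper(consensus35); consensus10 <- toupper(consensus10)
  if (!grepl("^[ACGT]+$", consensus35) || !grepl("^[ACGT]+$", consensus10))
    stop("consensus sequences must be A/C/G/T")
  if (!is_number(mutation_rate) || mutation_rate < 0 || mutation_rate >= 0.5)
    stop("mutation_rate must satisfy 0 <= rate < 0.5")
  lens <- as.integer(names(spacer_dist))
  if (anyNA(lens) || any(spacer_dist < 0) || abs(sum(spacer_dist) - 1) > 1e-9)
    stop("spacer_dist must be named by lengths and sum to 1")
  if (!is_number(background_gc) || background_gc < 0 || background_gc > 1)
    stop("background_gc must be in [0, 1]")
  structure(list(consensus35 = consensus35, consensus10 = consensus10,
                 mutation_rate = mutation_rate, spacer_dist = spacer_dist,
                 background_gc = background_gc),
            class = "ecf_motif_spec")
}

#' Canned motif specification for a subgroup
#'
#' Deterministic, distinct consensus pairs per subgroup used by the
#' packaged synthetic roster and examples.  Subgroup 0 returns the
#' sigma70-like pair (TTGACA/TATAAT, 15-19 nt spacers).
#'
#' @param subgroup integer subgroup number (0 for the sigma70-like spec).
#' @param mutation_rate,background_gc passed to [motif_spec()].
#' @return an `ecf_motif_spec`.
#' @export
example_motif_spec <- function(subgroup, mutation_rate = 0.1,
                               background_gc = 0.5) {
  if (subgroup == 0)
    return(motif_spec("TTGACA", "TATAAT", mutation_rate,
                      c(`15` = 0.1, `16` = 0.2, `17` = 0.4, `18` = 0.2,
                        `19` = 0.1), background_gc))
  cons <- with_seed(derive_seed(subgroup, "example_motif_spec"), {
    c(paste(sample(DNA_BASES, 7, replace = TRUE), collapse = ""),
      paste(sample(DNA_BASES, 6, replace = TRUE), collapse = ""))
  })
  motif_spec(cons[1], cons[2], mutation_rate,
             c(`15` = 0.2, `16` = 0.55, `17` = 0.25), background_gc)
}

mutate_consensus <- function(consensus, rate) {
  idx <- seq_to_idx(consensus)
  hit <- runif(length(idx)) < rate
  if (any(hit))
    idx[hit] <- vapply(idx[hit], function(b)
      sample(setdiff(1:4, b), 1L), integer(1))
  idx
}

#' Generate promoters with a planted bipartite motif
#'
#' Each 80-nt (-60..+20) record carries one planted -35 block and one
#' -10 block: per-position mutations at the spec rate, spacer drawn from
#' the spec distribution, i.i.d. background at the spec GC.  The -35
#' block is anchored at promoter position `anchor35` (default -35, the
#' position the window naming refers to).
#'
#' @param spec an `ecf_motif_spec`.
#' @param n number of promoters (>= 1).
#' @param seed integer seed; the same seed reproduces the output exactly.
#' @param subgroup subgroup used for the `P_XX_YYYY` ids.
#' @param start_uid first numeric uid.
#' @param window promoter window, default `c(-60, 20)`.
#' @param anchor35 promoter-relative position of the first -35 base.
#' @return data.frame of promoter records with planted-truth columns
#'   `planted_start35` (0-based offset) and `planted_spacer`.
#' @export
gen_subgroup_promoters <- function(spec, n, seed, subgroup = 1L,
                                   start_uid = 1000L,
                                   window = c(-60L, 20L), anchor35 = -35L) {
  stopifnot(inherits(spec, "ecf_motif_spec"))
  if (!is_count(n)) stop("n must be a positive count")
  span <- window_span(window)
  w35 <- nchar(spec$consensus35); w10 <- nchar(spec$consensus10)
  lens <- as.integer(names(spec$spacer_dist))
  off35 <- window_index(anchor35, window) - 1L  # 0-based planted offset
  if (off35 + w35 + max(lens) + w10 > span)
    stop("spacer length ", max(lens), " nt exceeds the promoter window")
  with_seed(seed, {
    recs <- lapply(seq_len(n), function(i) {
      sp <- lens[sample.int(length(lens), 1L, prob = spec$spacer_dist)]
      bg <- seq_to_idx(random_background(span, spec$background_gc))
      bg[off35 + seq_len(w35)] <-
        mutate_consensus(spec$consensus35, spec$mutation_rate)
      bg[off35 + w35 + sp + seq_len(w10)] <-
        mutate_consensus(spec$consensus10, spec$mutation_rate)
      cbind(promoter_record(promoter_id(subgroup, start_uid + i - 1L),
                            idx_to_seq(bg), window = window,
                            source = "synthetic planted motif"),
            planted_start35 = off35, planted_spacer = sp)
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}

# ---------------------------------------------------------------------------
# Toy genomes

#' Generate a toy genome with sigma operons and planted promoters
#'
#' Builds a single-contig genome in which every sigma gene is preceded
#' (on its own strand) by a planted 80-nt promoter window.  Alternate
#' sigma genes are placed as the second gene of a two-gene operon (30 nt
#' internal gap), so correct upstream extraction must walk to the operon
#' head; strands alternate as well.  Cassettes are separated by
#' `intergenic_gap` nt of background.
#'
#' @param n_sigma_operons number of sigma operons (>= 1).
#' @param intergenic_gap background nt between cassettes (should exceed
#'   the operon-calling gap used downstream).
#' @param seed integer seed.
#' @param spec motif spec of the planted promoters.
#' @param gene_len length of each synthetic ORF in nt.
#' @param operon_internal_gap gap between operon members in nt.
#' @return list with `genome` (string), `annotation` (data.frame
#'   `gene_id, start, end, strand, contig`; 1-based inclusive),
#'   `sigma_genes` (ids), and `planted` (data.frame with each planted
#'   promoter sequence and its genomic placement).
#' @export
gen_toy_genome <- function(n_sigma_operons, intergenic_gap = 200L, seed = 1L,
                           spec = example_motif_spec(1, mutation_rate = 0.05),
                           gene_len = 300L, operon_internal_gap = 30L) {
  if (!is_count(n_sigma_operons)) stop("n_sigma_operons must be >= 1")
  if (!is_count(intergenic_gap, 0)) stop("intergenic_gap must be >= 0")
  with_seed(seed, {
    pieces <- character(0); ann <- list(); planted <- list()
    sigma_genes <- character(0)
    pos <- 0L
    for (k in seq_len(n_sigma_operons)) {
      prom <- gen_subgroup_promoters(spec, 1L, seed = derive_seed(seed,
        paste0("toy_promoter_", k)), subgroup = 1L, start_uid = 1000L + k)
      pseq <- prom$sequence[1]
      two_gene <- k %% 2L == 0L
      strand <- if (k %% 4L %in% c(0L, 1L)) "+" else "-"
      sig_id <- sprintf("sig%02d", k)
      sigma_genes <- c(sigma_genes, sig_id)
      # build the cassette on the plus strand of the operon; the promoter
      # window is -60..+20, so the operon head ORF starts at window
      # position +1 (cassette index 61) and overlaps the last 20 nt
      if (gene_len <= 20L) stop("gene_len must exceed the +1..+20 overlap")
      cass <- pseq
      loc <- list()
      g1_start <- 61L
      cass <- paste0(cass, random_background(gene_len - 20L, spec$background_gc))
      if (two_gene) {
        loc[[1]] <- list(id = sprintf("lead%02d", k), start = g1_start,
                         end = g1_start + gene_len - 1L)
        g2_start <- nchar(cass) + operon_internal_gap + 1L
        cass <- paste0(cass,
                       random_background(operon_internal_gap, spec$background_gc),
                       random_background(gene_len, spec$background_gc))
        loc[[2]] <- list(id = sig_id, start = g2_start,
                         end = g2_start + gene_len - 1L)
      } else {
        loc[[1]] <- list(id = sig_id, start = g1_start,
                         end = g1_start + gene_len - 1L)
      }
      clen <- nchar(cass)
      prom_loc <- c(1L, 80L)
      if (strand == "-") {
        cass <- revcomp(cass)
        loc <- lapply(loc, function(g)
          list(id = g$id, start = clen - g$end + 1L, end = clen - g$start + 1L))
        prom_loc <- c(clen - 80L + 1L, clen)
      }
      for (g in loc)
        ann[[length(ann) + 1L]] <- data.frame(
          gene_id = g$id, start = pos + g$start, end = pos + g$end,
          strand = strand, contig = "toy1", stringsAsFactors = FALSE)
      planted[[length(planted) + 1L]] <- data.frame(
        gene_id = sig_id, promoter_seq = pseq,
        start = pos + prom_loc[1], end = pos + prom_loc[2], strand = strand,
        stringsAsFactors = FALSE)
      pieces <- c(pieces, cass,
                  random_background(intergenic_gap, spec$background_gc))
      pos <- pos + clen + intergenic_gap
    }
    list(genome = paste(pieces, collapse = ""),
         annotation = do.call(rbind, ann),
         sigma_genes = sigma_genes,
         planted = do.call(rbind, planted))
  })
}

# ---------------------------------------------------------------------------
# Crosstalk truth and noisy matrices

#' Ground-truth crosstalk table
#'
#' Defines the cognate pairing, the cognate fold induction, off-target
#' folds, and per-promoter leakiness for a synthetic sigma x promoter
#' library.  By default promoters lie on the diagonal of the fold matrix
#' and leak values are geometrically spaced so that
#' `max(leak) / min(leak) = leak_fold_range` (about 10-fold, the spread
#' the measured libraries show).
#'
#' @param n_pairs number of cognate sigma:promoter pairs.
#' @param cognate_fold fold induction of a cognate pair (> 1).
#' @param offtarget_fold either a scalar baseline (default 1, silent) or
#'   an `n_pairs` x `n_pairs` matrix of off-target folds (diagonal
#'   ignored).
#' @param leak_fold_range ratio of the largest to smallest promoter leak.
#' @param sigma_ids,promoter_ids optional id vectors; defaults follow the
#'   ECF naming convention with subgroups `1..n_pairs`.
#' @return object of class `ecf_truth` with elements `sigma_ids`,
#'   `promoter_ids`, `cognate_map` (named vector sigma -> promoter),
#'   `fold` (matrix), `leak` (named vector).
#' @export
truth_table <- function(n_pairs, cognate_fold = 100, offtarget_fold = 1,
                        leak_fold_range = 10,
                        sigma_ids = NULL, promoter_ids = NULL) {
  if (!is_count(n_pairs, 1)) stop("n_pairs must be >= 1")
  if (!is_number(cognate_fold) || cognate_fold <= 1)
    stop("cognate_fold must exceed 1")
  subgroups <- ((seq_len(n_pairs) - 1L) %% 43L) + 1L
  uid <- 1000L + seq_len(n_pairs)
  sigma_ids <- sigma_ids %||% mapply(sigma_id, subgroups, uid)
  promoter_ids <- promoter_ids %||% mapply(promoter_id, subgroups, uid)
  fold <- if (is.matrix(offtarget_fold)) {
    if (!all(dim(offtarget_fold) == n_pairs))
      stop("offtarget_fold matrix must be n_pairs x n_pairs")
    offtarget_fold
  } else matrix(offtarget_fold, n_pairs, n_pairs)
  if (any(fold <= 0)) stop("folds must be positive")
  diag(fold) <- cognate_fold
  dimnames(fold) <- list(sigma_ids, promoter_ids)
  leak <- if (n_pairs == 1L) 1 else
    leak_fold_range^(seq(0, 1, length.out = n_pairs))
  structure(list(sigma_ids = sigma_ids, promoter_ids = promoter_ids,
                 cognate_map = setNames(promoter_ids, sigma_ids),
                 fold = fold, leak = setNames(leak, promoter_ids)),
            class = "ecf_truth")
}

#' Generate a noisy measured crosstalk matrix from a truth table
#'
#' Each cell is the truth fold multiplied by lognormal noise with mean 1
#' and coefficient of variation `noise_cv` (flow-cytometry style
#' multiplicative noise).  `noise_cv = 0` returns the truth exactly.
#'
#' @param truth an `ecf_truth`.
#' @param noise_cv nonnegative coefficient of variation.
#' @param seed integer seed.
#' @return an `ecf_crosstalk` of kind `fold_induction`.
#' @export
gen_crosstalk_matrix <- function(truth, noise_cv = 0.3, seed = 1L) {
  stopifnot(inherits(truth, "ecf_truth"))
  if (!is_number(noise_cv) || noise_cv < 0) stop("noise_cv must be nonnegative")
  vals <- with_seed(seed, {
    truth$fold * matrix(lognormal_noise(length(truth$fold), noise_cv),
                        nrow(truth$fold))
  })
  crosstalk_matrix(vals, kind = "fold_induction")
}

#' Generate a noisy switch transfer function
#'
#' Simulates the titration model at the given inputs and multiplies the
#' outputs by lognormal noise (mean 1, CV `noise_cv`).
#'
#' @param params an `ecf_titration_params`.
#' @param inputs nonnegative input activity levels.
#' @param noise_cv nonnegative coefficient of variation.
#' @param seed integer seed.
#' @return an `ecf_transfer` data.frame (`input`, `output`).
#' @export
gen_switch_data <- function(params, inputs, noise_cv = 0.1, seed = 1L) {
  tf <- simulate_transfer(params, inputs)
  if (!is_number(noise_cv) || noise_cv < 0) stop("noise_cv must be nonnegative")
  tf$output <- with_seed(seed,
    tf$output * lognormal_noise(nrow(tf), noise_cv))
  tf
}

# ---------------------------------------------------------------------------
# Presence/absence matrices

#' Generate a subgroup-by-genome presence matrix with co-occurrence bias
#'
#' The first quarter of subgroups is designated "insulated" and the next
#' quarter "crosstalking"; the rest form an unbiased background.  A
#' positive `cooccurrence_bias` tilts insulated subgroups toward
#' subgroup-rich genomes and crosstalking subgroups toward subgroup-poor
#' genomes (on the logit scale, proportional to the standardised
#' background richness of each genome), so insulated subgroups acquire
#' more co-occurring partners.  At `cooccurrence_bias = 0` all subgroups
#' are i.i.d. Bernoulli(`p_base`).
#'
#' @param n_subgroups,n_genomes matrix dimensions (both >= 2).
#' @param cooccurrence_bias real bias on the logit scale.
#' @param seed integer seed.
#' @param p_base baseline presence probability.
#' @return object of class `ecf_presence`: list with logical matrix
#'   `present` (subgroups x genomes), `subgroup_ids`, `genome_ids`,
#'   `insulated`, `crosstalking`.
#' @export
gen_presence_matrix <- function(n_subgroups, n_genomes, cooccurrence_bias = 0,
                                seed = 1L, p_base = 0.4) {
  if (!is_count(n_subgroups, 2) || !is_count(n_genomes, 2))
    stop("need at least 2 subgroups and 2 genomes")
  if (!is_number(cooccurrence_bias)) stop("cooccurrence_bias must be a number")
  n_des <- max(2L, n_subgroups %/% 4L)
  if (2L * n_des > n_subgroups)
    stop("n_subgroups too small to designate two groups")
  sub_ids <- sprintf("SG%02d", seq_len(n_subgroups))
  gen_ids <- sprintf("G%03d", seq_len(n_genomes))
  ins <- sub_ids[seq_len(n_des)]
  cross <- sub_ids[n_des + seq_len(n_des)]
  bg <- setdiff(sub_ids, c(ins, cross))
  with_seed(seed, {
    m <- matrix(FALSE, n_subgroups, n_genomes,
                dimnames = list(sub_ids, gen_ids))
    m[bg, ] <- matrix(runif(length(bg) * n_genomes) < p_base, length(bg))
    rich <- if (length(bg)) colSums(m[bg, , drop = FALSE]) else rep(0, n_genomes)
    z <- if (sd(rich) > 0) (rich - mean(rich)) / sd(rich) else rep(0, n_genomes)
    p_ins <- plogis(qlogis(p_base) + cooccurrence_bias * z)
    p_cross <- plogis(qlogis(p_base) - cooccurrence_bias * z)
    m[ins, ] <- matrix(runif(length(ins) * n_genomes) <
                         rep(p_ins, each = length(ins)), length(ins))
    m[cross, ] <- matrix(runif(length(cross) * n_genomes) <
                           rep(p_cross, each = length(cross)), length(cross))
    # no all-absent subgroup rows (partner counts are undefined for them)
    for (i in which(rowSums(m) == 0L)) m[i, sample.int(n_genomes, 1L)] <- TRUE
    structure(list(present = m, subgroup_ids = sub_ids, genome_ids = gen_ids,
                   insulated = ins, crosstalking = cross),
              class = "ecf_presence")
  })
}

#' @export
print.ecf_presence <- function(x, ...) {
  cat(sprintf("Presence matrix: %d subgroups x %d genomes (%.0f%% filled)\n",
              nrow(x$present), ncol(x$present), 100 * mean(x$present)))
  invisible(x)
}
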