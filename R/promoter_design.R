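# Mining candidate promoters from annotated genomes, screening and
# redesigning them (host exclusion, UP element), and enumerating
# chimeric sigma/promoter combinations.

#' Extract the regulatory region upstream of a gene's putative operon
#'
#' Walks upstream across same-strand neighbours whose intergenic gap is
#' at most `operon_gap` (the putative operon), then returns up to
#' `max_len` nt upstream of the operon head, oriented with the gene
#' (minus-strand genes yield the reverse complement of the genomic
#' segment downstream in genome coordinates).
#'
#' @param genome single-contig DNA string (A/C/G/T/N).
#' @param annotation data.frame with columns `gene_id, start, end,
#'   strand, contig` (1-based inclusive coordinates, strand "+"/"-").
#' @param target_gene gene id present in the annotation.
#' @param max_len maximum region length in nt.
#' @param operon_gap maximum same-strand intergenic gap treated as
#'   operon-internal.
#' @return object of class `ecf_upstream_region`: list with `gene_id`,
#'   `region` (plus-strand-of-gene orientation), `length`,
#'   `operon_members` (head first), `truncated`.
#' @export
extract_upstream <- function(genome, annotation, target_gene,
                             max_len = 300L, operon_gap = 50L) {
  need <- c("gene_id", "start", "end", "strand", "contig")
  if (!all(need %in% names(annotation)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  row <- annotation[annotation$gene_id == target_gene, ]
  if (nrow(row) != 1L) stop("gene not found in annotation: ", target_gene)
  same <- annotation[annotation$contig == row$contig &
                       annotation$strand == row$strand, ]
  head_gene <- row
  members <- row$gene_id
  repeat {
    if (row$strand == "+") {
      ups <- same[same$end < head_gene$start, ]
      if (nrow(ups) == 0L) break
      nb <- ups[which.max(ups$end), ]
      gap <- head_gene$start - nb$end - 1L
    } else {
      dws <- same[same$start > head_gene$end, ]
      if (nrow(dws) == 0L) break
      nb <- dws[which.min(dws$start), ]
      gap <- nb$start - head_gene$end - 1L
    }
    if (gap > operon_gap) break
    head_gene <- nb
    members <- c(nb$gene_id, members)
  }
  glen <- nchar(genome)
  if (row$strand == "+") {
    to <- head_gene$start - 1L
    from <- max(1L, to - max_len + 1L)
    truncated <- (to - max_len + 1L) < 1L
    region <- if (to >= from) substr(genome, from, to) else ""
  } else {
    from <- head_gene$end + 1L
    to <- min(glen, from + max_len - 1L)
    truncated <- (from + max_len - 1L) > glen
    region <- if (to >= from) revcomp(substr(genome, from, to)) else ""
  }
  structure(list(gene_id = target_gene, region = region,
                 length = nchar(region), operon_members = members,
                 truncated = truncated),
            class = "ecf_upstream_region")
}

#' Score candidate promoters against all subgroup models
#'
#' Scans every promoter against every model, records the cognate score,
#' the best off-target score and which model produced it, and ranks
#' candidates the way the library was designed: host-flagged last, then
#' by descending orthogonality margin (cognate minus best off-target),
#' autoregulatory candidates first among ties.  With a single model the
#' best off-target score is `-Inf` and the margin `+Inf` ("no
#' competitor").
#'
#' @param promoters promoter data.frame (columns `id`, `sequence`).
#' @param models named list of `ecf_promoter_model`s, names are subgroup
#'   numbers.
#' @param cognate_map named character/integer vector mapping promoter id
#'   to its cognate subgroup.
#' @param autoregulatory,host_flagged optional named logical vectors by
#'   promoter id (default all `FALSE`).
#' @return data.frame of class `ecf_candidates`, ranked; columns
#'   `promoter_id, cognate_subgroup, cognate_score, best_offtarget_score,
#'   offtarget_model, margin, autoregulatory, host_flagged, rank`.
#' @export
assess_candidates <- function(promoters, models, cognate_map,
                              autoregulatory = NULL, host_flagged = NULL) {
  ids <- promoters$id
  if (!all(ids %in% names(cognate_map)))
    stop("cognate_map missing promoter(s): ",
         paste(setdiff(ids, names(cognate_map)), collapse = ", "))
  subs <- as.character(cognate_map[ids])
  if (!all(subs %in% names(models)))
    stop("no model for cognate subgroup(s): ",
         paste(setdiff(subs, names(models)), collapse = ", "))
  auto <- setNames(rep(FALSE, length(ids)), ids)
  if (!is.null(autoregulatory)) auto[names(autoregulatory)] <- autoregulatory
  host <- setNames(rep(FALSE, length(ids)), ids)
  if (!is.null(host_flagged)) host[names(host_flagged)] <- host_flagged

  scores <- vapply(models, function(m)
    vapply(promoters$sequence, function(s) scan_promoter(m, s)$total,
           numeric(1), USE.NAMES = FALSE),
    numeric(length(ids)))
  if (length(ids) == 1L) scores <- matrix(scores, nrow = 1L,
                                          dimnames = list(NULL, names(models)))
  out <- do.call(rbind, lapply(seq_along(ids), function(i) {
    cog <- scores[i, subs[i]]
    others <- scores[i, setdiff(colnames(scores), subs[i]), drop = TRUE]
    if (length(others) == 0L) {
      best_off <- -Inf; off_model <- NA_character_
    } else {
      best_off <- max(others)
      off_model <- names(others)[which.max(others)]
    }
    data.frame(promoter_id = ids[i], cognate_subgroup = subs[i],
               cognate_score = cog, best_offtarget_score = best_off,
               offtarget_model = off_model, margin = cog - best_off,
               autoregulatory = auto[[ids[i]]], host_flagged = host[[ids[i]]],
               stringsAsFactors = FALSE)
  }))
  ord <- order(out$host_flagged, -out$margin, !out$autoregulatory,
               out$promoter_id)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("ecf_candidates", class(out))
  out
}

#' Host promoter models for the exclusion screen
#'
#' Bipartite models for the host machinery a heterologous promoter must
#' avoid: an *E. coli* sigma70-like model built from the textbook
#' TTGACA / N17 / TATAAT consensus, and a FecI-like (ECF05-10) model
#' built from a synthetic stand-in consensus (the study's own FecI model
#' derives from unpublished supplementary data).
#'
#' @return named list of two `ecf_promoter_model`s (`sigma70`, `fecI`).
#' @export
host_promoter_models <- function() {
  mk <- function(c35, c10, counts) {
    promoter_model(NA_integer_,
                   build_pwm(rep(c35, 12), pseudocount = 4),
                   build_pwm(rep(c10, 12), pseudocount = 4),
                   spacer_model(counts, pseudocount = 1))
  }
  list(
    sigma70 = mk("TTGACA", "TATAAT",
                 c(`15` = 2, `16` = 5, `17` = 12, `18` = 5, `19` = 2)),
    fecI = mk("GAAAAT", "TCCTTT", c(`15` = 3, `16` = 8, `17` = 3)))
}

#' Screen a promoter against host models
#'
#' Flags a promoter whose best scan score under any host model reaches
#' the cutoff.  The default cutoff for each model is its consensus score
#' minus 6 bits.
#'
#' @param sequence promoter sequence (or a one-row promoter data.frame).
#' @param host_models list of `ecf_promoter_model`s.
#' @param cutoff numeric cutoff in bits (recycled over models), or
#'   `NULL` for the per-model default.
#' @return logical: `TRUE` if flagged (host-like).
#' @export
host_exclusion_screen <- function(sequence, host_models = host_promoter_models(),
                                  cutoff = NULL) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  cuts <- if (is.null(cutoff))
    vapply(host_models, function(m) consensus_score(m) - 6, numeric(1))
  else rep_len(cutoff, length(host_models))
  for (k in seq_along(host_models)) {
    if (is.infinite(cuts[k]) && cuts[k] > 0) next  # +Inf cutoff: never flagged
    if (scan_promoter(host_models[[k]], sequence)$total >= cuts[k])
      return(TRUE)
  }
  FALSE
}

#' Default synthetic A/T-rich UP element (25 nt)
#'
#' A packaged stand-in for the synthetic UP element used to rescue
#' promoters from GC-rich genomes; it replaces the -60..-36 window.
#'
#' @return a 25-nt A/T-rich DNA string.
#' @export
default_up_element <- function() "AAAATTTTAAAATTTTAAAATTTTA"

#' Replace the -60..-36 region of a promoter with an UP element
#'
#' Positions -60..-36 (the 25 nt upstream of the -35 element) are
#' replaced by `up_seq`; -35..+20 are untouched; the id is renamed
#' `P_XX_YYYY -> P_XX_UPYYYY` and `up_modified` set.
#'
#' @param promoter one-row promoter data.frame (from
#'   [promoter_record()]); its window must start at -60.
#' @param up_seq 25-nt A/T-rich replacement.
#' @return the modified promoter record.
#' @examples
#' p <- promoter_record("P_15_436", strrep("ACGT", 20))
#' apply_up_element(p)$id  # "P_15_UP436"
#' @export
apply_up_element <- function(promoter, up_seq = default_up_element()) {
  stopifnot(is.data.frame(promoter), nrow(promoter) == 1L)
  if (promoter$window_from != -60L)
    stop("UP replacement requires a window starting at -60")
  up_seq <- toupper(up_seq)
  span <- window_index(-36L, c(promoter$window_from, promoter$window_to))
  if (nchar(up_seq) != span)
    stop(sprintf("up_seq must be %d nt (spans -60..-36), got %d",
                 span, nchar(up_seq)))
  if (!grepl("^[ACGT]+$", up_seq)) stop("up_seq must be A/C/G/T")
  info <- parse_part_id(promoter$id)
  if (info$up) stop("promoter already carries an UP element: ", promoter$id)
  out <- promoter
  out$id <- promoter_id(info$subgroup, info$uid, up = TRUE)
  out$sequence <- paste0(up_seq, substr(promoter$sequence, span + 1L,
                                        nchar(promoter$sequence)))
  out$up_modified <- TRUE
  out
}

#' Enumerate chimeric sigma combinatorics from specificity classes
#'
#' The number of sequence-distinct chimeric sigmas is the product of the
#' number of distinct -35 (domain 4) classes and distinct -10 (domain 2)
#' classes; combinations not realised by any natural subgroup are the
#' novel set.
#'
#' @param classes list with named vectors `classes35`, `classes10`
#'   (per-subgroup class labels), e.g. from [specificity_classes()].
#' @return list with `count`, `combos` (data.frame of all class pairs),
#'   `natural` and `novel` subsets of `combos`.
#' @examples
#' cl <- list(classes35 = c(a = "x", b = "y"), classes10 = c(a = "u", b = "u"))
#' enumerate_chimeras(cl)$count  # 2 distinct -35 x 1 distinct -10 = 2
#' @export
enumerate_chimeras <- function(classes) {
  c35 <- classes$classes35; c10 <- classes$classes10
  if (length(c35) == 0L || length(c10) == 0L) stop("empty class maps")
  if (!identical(sort(names(c35)), sort(names(c10))))
    stop("classes35 and classes10 must cover the same subgroups")
  u35 <- sort(unique(c35)); u10 <- sort(unique(c10))
  combos <- expand.grid(class35 = u35, class10 = u10,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  natural <- unique(data.frame(class35 = unname(c35),
                               class10 = unname(c10[names(c35)]),
                               stringsAsFactors = FALSE))
  key <- function(d) paste(d$class35, d$class10, sep = "\r")
  novel <- combos[!key(combos) %in% key(natural), ]
  rownames(novel) <- NULL
  list(count = length(u35) * length(u10), combos = combos,
       natural = natural, novel = novel)
}

#' Build a chimeric promoter from two donor models
#'
#' Places the -35 consensus of `donor35` and the -10 consensus of
#' `donor10`, separated by the requested spacer, into a context promoter
#' (anchoring the -35 block at position -35); sequence downstream of the
#' -10 block is unchanged.  The spacer must lie in the union of the two
#' donors' spacer supports.
#'
#' @param donor35,donor10 `ecf_promoter_model`s donating the blocks.
#' @param spacer requested spacer length in nt.
#' @param context one-row promoter data.frame providing the backbone.
#' @return the chimeric promoter record (id
#'   `P_<g35>_X<g10>S<spacer>` when both donors have subgroups).
#' @export
build_chimeric_promoter <- function(donor35, donor10, spacer, context) {
  stopifnot(inherits(donor35, "ecf_promoter_model"),
            inherits(donor10, "ecf_promoter_model"),
            is.data.frame(context), nrow(context) == 1L)
  supp <- union(donor35$spacer$support, donor10$spacer$support)
  if (!spacer %in% supp)
    stop("requested spacer ", spacer,
         " nt outside the donors' supports {",
         paste(sort(supp), collapse = ","), "}")
  window <- c(context$window_from, context$window_to)
  i35 <- window_index(-35L, window)
  c35 <- consensus_seq(donor35$pwm35)
  c10 <- consensus_seq(donor10$pwm10)
  i10 <- i35 + nchar(c35) + spacer
  s <- context$sequence
  if (i10 + nchar(c10) - 1L > nchar(s))
    stop("blocks + spacer exceed the promoter window")
  substr(s, i35, i35 + nchar(c35) - 1L) <- c35
  substr(s, i10, i10 + nchar(c10) - 1L) <- c10
  out <- context
  g35 <- donor35$subgroup; g10 <- donor10$subgroup
  if (!is.na(g35) && !is.na(g10))
    out$id <- promoter_id(g35, sprintf("X%02dS%d", g10, spacer))
  out$sequence <- s
  out$source <- sprintf("chimeric: -35 from subgroup %s, -10 from subgroup %s, spacer %d",
                        g35, g10, spacer)
  out
}
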