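# Co-occurrence of ECF subgroups across genomes: partner counts and a
# permutation test comparing insulated (non-crosstalking) versus
# crosstalking subgroup sets.

#' Mean co-occurring partner count of a subgroup
#'
#' For one subgroup: the mean, over the genomes that contain it, of the
#' number of other subgroups present in the same genome.  With
#' `subgroup = NULL`, returns the vector for all subgroups.  Partner
#' counts always include every subgroup in the matrix, not just a tested
#' subset.
#'
#' @param pm an `ecf_presence` (or a logical subgroup x genome matrix).
#' @param subgroup subgroup id, or `NULL` for all.
#' @return mean partner count(s).
#' @export
partner_count <- function(pm, subgroup = NULL) {
  m <- if (inherits(pm, "ecf_presence")) pm$present else pm
  if (!is.matrix(m) || !is.logical(m)) stop("need a logical presence matrix")
  totals <- colSums(m)
  counts <- vapply(rownames(m), function(s) {
    g <- m[s, ]
    if (!any(g)) stop("subgroup absent from every genome: ", s)
    mean(totals[g] - 1)
  }, numeric(1))
  if (is.null(subgroup)) counts else {
    if (!all(subgroup %in% names(counts)))
      stop("unknown subgroup(s): ",
           paste(setdiff(subgroup, names(counts)), collapse = ", "))
    counts[subgroup]
  }
}

#' Permutation test comparing partner counts of two subgroup sets
#'
#' Computes the difference of mean partner counts between two disjoint
#' subgroup groups and a two-sided p-value from `n_perm` random
#' reassignments of the group labels over the union (add-one Monte
#' Carlo estimator).
#'
#' @param pm an `ecf_presence` (or logical matrix with rownames).
#' @param group_a,group_b disjoint, non-empty subgroup id sets.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return object of class `ecf_group_comparison`: list with
#'   `group_a_mean`, `group_b_mean`, `difference` (a minus b), `p_value`,
#'   `n_perm`.
#' @export
compare_groups <- function(pm, group_a, group_b, n_perm = 1000L, seed = 1L) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty")
  if (length(intersect(group_a, group_b)) > 0L)
    stop("groups must be disjoint")
  if (!is_count(n_perm)) stop("n_perm must be a positive count")
  pc <- partner_count(pm)
  if (!all(c(group_a, group_b) %in% names(pc)))
    stop("group member(s) absent from the matrix")
  a <- mean(pc[group_a]); b <- mean(pc[group_b])
  obs <- a - b
  pool <- pc[c(group_a, group_b)]
  na <- length(group_a); np <- length(pool)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    ix <- sample.int(np, na)
    mean(pool[ix]) - mean(pool[-ix])
  }, numeric(1)))
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  structure(list(group_a_mean = a, group_b_mean = b, difference = obs,
                 p_value = p, n_perm = n_perm),
            class = "ecf_group_comparison")
}

#' @export
print.ecf_group_comparison <- function(x, ...) {
  cat(sprintf(
    "Partner counts: group A %.2f vs group B %.2f (diff %+.2f), permutation P = %.4g (%d perms)\n",
    x$group_a_mean, x$group_b_mean, x$difference, x$p_value, x$n_perm))
  invisible(x)
}

#' Read / write presence matrices as TSV
#'
#' Subgroup rows by genome columns of 0/1 values, first column
#' `subgroup_id`.
#'
#' @param path file path.
#' @return [read_presence_tsv()] returns an `ecf_presence`.
#' @export
read_presence_tsv <- function(path) {
  df <- read_tsv_table(path, required = "subgroup_id")
  m <- as.matrix(df[setdiff(names(df), "subgroup_id")]) > 0
  rownames(m) <- df$subgroup_id
  structure(list(present = m, subgroup_ids = rownames(m),
                 genome_ids = colnames(m),
                 insulated = character(0), crosstalking = character(0)),
            class = "ecf_presence")
}

#' @rdname read_presence_tsv
#' @param pm an `ecf_presence`.
#' @export
write_presence_tsv <- function(pm, path) {
  stopifnot(inherits(pm, "ecf_presence"))
  df <- data.frame(subgroup_id = rownames(pm$present),
                   pm$present * 1L, check.names = FALSE)
  write_tsv_table(df, path)
}
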