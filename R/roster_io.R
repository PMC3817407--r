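# Part naming, FASTA/TSV readers, and the library roster container.
#
# Naming conventions follow the field's ECF part nomenclature:
#   sigmas      ECF<XX>_<YYYY>   (XX = zero-padded subgroup, YYYY = unique id)
#   anti-sigmas AS<XX>_<YYYY>    (same numbering as the cognate sigma)
#   promoters   P_<XX>_<YYYY> or P_<XX>_UP<YYYY> for UP-element variants

SIGMA_ID_RE    <- "^ECF([0-9]{2})_([A-Za-z0-9]+)$"
ANTI_ID_RE     <- "^AS([0-9]{2})_([A-Za-z0-9]+)$"
PROMOTER_ID_RE <- "^P_([0-9]{2})_((?:UP)?)([A-Za-z0-9]+)$"

#' Compose and parse ECF part identifiers
#'
#' `sigma_id()`, `anti_sigma_id()` and `promoter_id()` build canonical part
#' names; `parse_part_id()` inverts them.  Composition and parsing form a
#' bijection between `(type, subgroup, uid, up_flag)` tuples and id
#' strings; to keep it one, a `uid` may not itself begin with "UP".
#'
#' @param subgroup integer ECF subgroup, 1-43.
#' @param uid alphanumeric unique id (conventionally the id of the parent
#'   sigma for promoters).
#' @param up logical; promoter carries a synthetic UP element.
#' @return the id string.
#' @examples
#' sigma_id(11, 987)          # "ECF11_987"
#' promoter_id(15, 436, TRUE) # "P_15_UP436"
#' parse_part_id("AS11_987")
#' @export
sigma_id <- function(subgroup, uid) {
  check_subgroup_uid(subgroup, uid)
  sprintf("ECF%02d_%s", as.integer(subgroup), uid)
}

#' @rdname sigma_id
#' @export
anti_sigma_id <- function(subgroup, uid) {
  check_subgroup_uid(subgroup, uid)
  sprintf("AS%02d_%s", as.integer(subgroup), uid)
}

#' @rdname sigma_id
#' @export
promoter_id <- function(subgroup, uid, up = FALSE) {
  check_subgroup_uid(subgroup, uid)
  sprintf("P_%02d_%s%s", as.integer(subgroup), if (isTRUE(up)) "UP" else "", uid)
}

check_subgroup_uid <- function(subgroup, uid) {
  if (!is_count(subgroup) || subgroup < 1 || subgroup > 99)
    stop("subgroup must be an integer in 1..99")
  uid <- as.character(uid)
  if (!grepl("^[A-Za-z0-9]+$", uid)) stop("uid must be alphanumeric: ", uid)
  if (grepl("^UP", uid)) stop("uid may not begin with 'UP' (reserved flag): ", uid)
  invisible(TRUE)
}

#' @rdname sigma_id
#' @param id a part id string of any of the three types.
#' @export
parse_part_id <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  if (grepl(SIGMA_ID_RE, id)) {
    m <- regmatches(id, regexec(SIGMA_ID_RE, id))[[1]]
    return(list(type = "sigma", subgroup = as.integer(m[2]), uid = m[3], up = FALSE))
  }
  if (grepl(ANTI_ID_RE, id)) {
    m <- regmatches(id, regexec(ANTI_ID_RE, id))[[1]]
    return(list(type = "anti_sigma", subgroup = as.integer(m[2]), uid = m[3], up = FALSE))
  }
  if (grepl(PROMOTER_ID_RE, id, perl = TRUE)) {
    m <- regmatches(id, regexec(PROMOTER_ID_RE, id, perl = TRUE))[[1]]
    if (grepl("^UP", m[4])) stop("invalid promoter id (double UP prefix): ", id)
    return(list(type = "promoter", subgroup = as.integer(m[2]), uid = m[4],
                up = nzchar(m[3])))
  }
  stop("id does not match any part naming convention: ", id)
}

# ---------------------------------------------------------------------------
# FASTA

#' Read a DNA FASTA file
#'
#' Parses FASTA through Biostrings, upper-cases the sequences, and
#' validates the alphabet: only A, C, G, T, N are accepted (N only when
#' `allow_n = TRUE`, the genome-file convention; promoter windows must be
#' unambiguous).
#'
#' @param path path to a FASTA file.
#' @param allow_n logical, accept the ambiguity code N.
#' @return named character vector of sequences.
#' @export
read_fasta_dna <- function(path, allow_n = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path), error = function(e)
    stop("no records or malformed FASTA in ", path, ": ",
         conditionMessage(e)))
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(names(seqs)))) stop("malformed FASTA header (empty id) in ", path)
  if (anyDuplicated(names(seqs))) stop("duplicate FASTA ids in ", path)
  alphabet <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(alphabet, seqs)
  if (any(bad))
    stop("parse error: record(s) with characters outside {A,C,G,T",
         if (allow_n) ",N" else "", "}: ",
         paste(names(seqs)[bad], collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("parse error: empty sequence for record(s): ",
         paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  seqs
}

#' Write a DNA FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta_dna <- function(seqs, path) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# ---------------------------------------------------------------------------
# TSV (tab-delimited, UTF-8, mandatory header, '#' comment lines)

#' Read a pipeline TSV table
#'
#' @param path path to a tab-delimited file with a header row; lines
#'   starting with `#` are comments.
#' @param required character vector of column names that must be present.
#' @return a data.frame.
#' @export
read_tsv_table <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  df
}

#' @rdname read_tsv_table
#' @param df data.frame to write.
#' @param comments optional character vector written as leading `#` lines.
#' @export
write_tsv_table <- function(df, path, comments = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Promoter coordinates: bacterial convention with no position 0.
# Internally sequences are stored 0-based; these accessors map between the
# promoter-relative coordinate (-60..-1, +1..+20 by default) and string index.

#' Promoter window coordinates
#'
#' A promoter window `c(-60, 20)` spans positions -60..-1 and +1..+20
#' (there is no position 0), i.e. 80 nt.  `promoter_positions()` lists
#' the coordinates in order; `window_index()` maps a coordinate to its
#' 1-based index in the sequence string; `window_span()` gives the
#' sequence length implied by a window.
#'
#' @param window integer pair `c(from, to)` with `from < 0 < to`.
#' @return see individual descriptions.
#' @examples
#' window_span(c(-60, 20))      # 80
#' window_index(-60, c(-60, 20)) # 1
#' window_index(+1,  c(-60, 20)) # 61
#' @export
promoter_positions <- function(window = c(-60L, 20L)) {
  check_window(window)
  c(seq.int(window[1], -1L), seq.int(1L, window[2]))
}

#' @rdname promoter_positions
#' @export
window_span <- function(window = c(-60L, 20L)) {
  check_window(window)
  as.integer(-window[1] + window[2])
}

#' @rdname promoter_positions
#' @param pos promoter-relative position (never 0).
#' @export
window_index <- function(pos, window = c(-60L, 20L)) {
  check_window(window)
  if (any(pos == 0)) stop("promoter coordinates have no position 0")
  if (any(pos < window[1] | pos > window[2])) stop("position outside window")
  ifelse(pos < 0, pos - window[1] + 1L, pos - window[1])
}

check_window <- function(window) {
  if (length(window) != 2L || window[1] >= 0 || window[2] <= 0)
    stop("window must be c(from, to) with from < 0 < to")
  invisible(TRUE)
}

#' Construct a promoter record
#'
#' @param id promoter id (`P_XX_YYYY` / `P_XX_UPYYYY`).
#' @param sequence DNA string over A/C/G/T whose length equals the window
#'   span (80 nt for the default -60..+20 window).
#' @param window promoter-relative window, default `c(-60, 20)`.
#' @param flank5,flank3 optional vector-context flanking sequence.
#' @param up_modified logical; carries a synthetic UP element.
#' @param source free-text provenance.
#' @return one-row data.frame of class `ecf_promoter_record`.
#' @export
promoter_record <- function(id, sequence, window = c(-60L, 20L),
                            flank5 = "", flank3 = "",
                            up_modified = NA, source = "") {
  info <- parse_part_id(id)
  if (info$type != "promoter") stop("not a promoter id: ", id)
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence))
    stop("promoter sequence must be unambiguous A/C/G/T: ", id)
  if (nchar(sequence) != window_span(window))
    stop(sprintf("promoter %s: sequence length %d does not match window span %d",
                 id, nchar(sequence), window_span(window)))
  if (is.na(up_modified)) up_modified <- info$up
  if (isTRUE(up_modified) != info$up)
    stop("up_modified flag disagrees with id naming for ", id)
  out <- data.frame(id = id, sequence = sequence,
                    window_from = window[1], window_to = window[2],
                    flank5 = flank5, flank3 = flank3,
                    up_modified = up_modified, source = source,
                    stringsAsFactors = FALSE)
  class(out) <- c("ecf_promoter_record", class(out))
  out
}

# ---------------------------------------------------------------------------
# Roster

#' Load a library roster
#'
#' Reads the sigma and anti-sigma TSVs and the promoter FASTA (plus an
#' optional promoter metadata TSV keyed by FASTA id), validates every
#' naming convention, and resolves anti-sigma -> sigma cross-references.
#'
#' Required columns: sigma TSV `id, subgroup, organism, domain2_class,
#' domain4_class`; anti TSV `id, cognate_sigma_id`.  Optional logical
#' columns (`active`, `anti_screened`) are preserved.
#'
#' @param sigma_tsv,anti_tsv,promoter_fasta input paths.
#' @param promoter_meta_tsv optional promoter metadata TSV (column `id`).
#' @param window promoter window, default `c(-60, 20)`.
#' @return an object of class `ecf_roster`: a list with data.frames
#'   `sigmas`, `anti_sigmas`, `promoters`.
#' @export
load_roster <- function(sigma_tsv, anti_tsv, promoter_fasta,
                        promoter_meta_tsv = NULL, window = c(-60L, 20L)) {
  sig <- read_tsv_table(sigma_tsv,
    required = c("id", "subgroup", "organism", "domain2_class", "domain4_class"))
  anti <- read_tsv_table(anti_tsv, required = c("id", "cognate_sigma_id"))
  seqs <- read_fasta_dna(promoter_fasta, allow_n = FALSE)

  bad <- character(0)
  for (i in seq_len(nrow(sig))) {
    info <- tryCatch(parse_part_id(sig$id[i]), error = function(e) NULL)
    if (is.null(info) || info$type != "sigma" ||
        info$subgroup != as.integer(sig$subgroup[i]))
      bad <- c(bad, sig$id[i])
  }
  if (length(bad))
    stop("sigma naming/subgroup violations: ", paste(bad, collapse = ", "))

  bad <- character(0); dangling <- character(0)
  for (i in seq_len(nrow(anti))) {
    info <- tryCatch(parse_part_id(anti$id[i]), error = function(e) NULL)
    cog <- tryCatch(parse_part_id(anti$cognate_sigma_id[i]),
                    error = function(e) NULL)
    ok <- !is.null(info) && info$type == "anti_sigma" && !is.null(cog) &&
      cog$type == "sigma" && info$subgroup == cog$subgroup &&
      info$uid == cog$uid
    if (!ok) bad <- c(bad, anti$id[i])
    else if (!anti$cognate_sigma_id[i] %in% sig$id)
      dangling <- c(dangling, anti$id[i])
  }
  if (length(bad))
    stop("anti-sigma naming violations (id must mirror cognate numbering): ",
         paste(bad, collapse = ", "))
  if (length(dangling))
    stop("anti-sigma(s) with unresolved cognate sigma: ",
         paste(dangling, collapse = ", "))

  prom <- do.call(rbind, lapply(names(seqs), function(id)
    promoter_record(id, seqs[[id]], window = window)))
  if (!is.null(promoter_meta_tsv)) {
    meta <- read_tsv_table(promoter_meta_tsv, required = "id")
    unknown <- setdiff(meta$id, prom$id)
    if (length(unknown))
      stop("promoter metadata for ids absent from FASTA: ",
           paste(unknown, collapse = ", "))
    keep <- setdiff(names(meta), setdiff(names(prom), "id"))
    prom <- merge(prom, meta[keep], by = "id", all.x = TRUE, sort = FALSE)
  }

  structure(list(sigmas = sig, anti_sigmas = anti, promoters = prom),
            class = "ecf_roster")
}

#' Write a roster to a directory
#'
#' Inverse of [load_roster()]: emits `sigmas.tsv`, `anti_sigmas.tsv`,
#' `promoters.fasta` and `promoter_meta.tsv` so that reloading
#' reproduces the roster.
#'
#' @param roster an `ecf_roster`.
#' @param dir output directory (created if needed).
#' @return invisibly, the four paths.
#' @export
write_roster <- function(roster, dir) {
  stopifnot(inherits(roster, "ecf_roster"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("sigmas.tsv", "anti_sigmas.tsv",
                            "promoters.fasta", "promoter_meta.tsv"))
  write_tsv_table(roster$sigmas, paths[1])
  write_tsv_table(roster$anti_sigmas, paths[2])
  write_fasta_dna(setNames(roster$promoters$sequence, roster$promoters$id),
                  paths[3])
  write_tsv_table(roster$promoters[setdiff(names(roster$promoters), "sequence")],
                  paths[4])
  invisible(paths)
}

#' @export
print.ecf_roster <- function(x, ...) {
  cat(sprintf("ECF library roster: %d sigmas, %d anti-sigmas, %d promoters\n",
              nrow(x$sigmas), nrow(x$anti_sigmas), nrow(x$promoters)))
  invisible(x)
}

#' Load the packaged synthetic reconstruction of the study roster
#'
#' The package ships a reconstructed roster whose counts match the
#' published library design (86 sigmas, two per subgroup; 62 anti-sigmas;
#' 29 promoters) with placeholder organism fields and synthetic promoter
#' sequences.  See the methods vignette for what is and is not
#' reconstructed.
#'
#' @return an `ecf_roster`.
#' @export
packaged_roster <- function() {
  d <- system.file("extdata", "roster_synthetic", package = "ecfortho")
  load_roster(file.path(d, "sigmas.tsv"),
              file.path(d, "anti_sigmas.tsv"),
              file.path(d, "promoters.fasta"),
              file.path(d, "promoter_meta.tsv"))
}

#' Screen-design arithmetic for a roster
#'
#' Computes the sizes of the screens the library design implies: sigmas
#' per subgroup, the promoter-by-sigma activity map, the crossreaction
#' screen restricted to active promoters, the anti-sigma screen
#' (active anti-sigmas by screened sigmas), and the chimeric-sigma upper
#' bound from the distinct -35 and -10 specificity classes.
#'
#' @param roster an `ecf_roster`.  Uses optional logical columns `active`
#'   (sigmas, anti_sigmas, promoters) and `anti_screened` (sigmas).
#' @return a list of named counts.
#' @export
screen_design <- function(roster) {
  stopifnot(inherits(roster, "ecf_roster"))
  sig <- roster$sigmas
  per <- table(sig$subgroup)
  chim <- enumerate_chimeras(specificity_classes(roster))
  list(
    n_sigmas = nrow(sig),
    n_subgroups = length(per),
    sigmas_per_subgroup = if (length(unique(per)) == 1L) unname(unique(per)) else per,
    n_anti_sigmas = nrow(roster$anti_sigmas),
    n_promoters = nrow(roster$promoters),
    activity_map_points = nrow(roster$promoters) * nrow(sig),
    n_active_promoters = sum(roster$promoters$active %||% logical(0)),
    crossreaction_points = sum(roster$promoters$active %||% logical(0)) * nrow(sig),
    n_active_sigmas = sum(sig$active %||% logical(0)),
    n_active_anti_sigmas = sum(roster$anti_sigmas$active %||% logical(0)),
    n_screened_sigmas = sum(sig$anti_screened %||% logical(0)),
    anti_screen_points = sum(roster$anti_sigmas$active %||% logical(0)) *
      sum(sig$anti_screened %||% logical(0)),
    chimera_upper_bound = chim$count
  )
}

#' Specificity class maps from a roster
#'
#' Extracts the per-subgroup -35 (domain 4) and -10 (domain 2)
#' specificity class labels, checking that the two sigmas of a subgroup
#' agree.
#'
#' @param roster an `ecf_roster`.
#' @return list with named character vectors `classes35`, `classes10`
#'   (names are subgroup numbers).
#' @export
specificity_classes <- function(roster) {
  sig <- roster$sigmas
  sp <- split(sig, sig$subgroup)
  c35 <- vapply(sp, function(d) {
    u <- unique(d$domain4_class)
    if (length(u) != 1L) stop("inconsistent domain4_class within subgroup ",
                              d$subgroup[1])
    u
  }, character(1))
  c10 <- vapply(sp, function(d) {
    u <- unique(d$domain2_class)
    if (length(u) != 1L) stop("inconsistent domain2_class within subgroup ",
                              d$subgroup[1])
    u
  }, character(1))
  list(classes35 = c35, classes10 = c10)
}
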