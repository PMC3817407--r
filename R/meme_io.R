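# MEME minimal motif format serialisation of bipartite promoter models.
# Each model is written as two letter-probability motifs (the -35 and
# -10 blocks) plus comment headers carrying the spacer histogram and the
# scoring metadata the letter-probability blocks cannot hold.

#' Write a promoter model in MEME minimal motif format
#'
#' Serialises the two PWMs as position-probability blocks (one motif per
#' block, `<name>_m35` and `<name>_m10`), the background frequencies in
#' the standard header, and the spacer histogram, support, pseudocounts,
#' and UP-bonus weight as `#` comment lines.  Round-trips losslessly
#' (to numerical precision) with [read_motif_minimal()].
#'
#' @param model an `ecf_promoter_model`.
#' @param path output path.
#' @param name motif base name; defaults to `ECF<subgroup>` or `motif`.
#' @return invisibly, `path`.
#' @export
write_motif_minimal <- function(model, path, name = NULL) {
  stopifnot(inherits(model, "ecf_promoter_model"))
  if (model$pwm35$width < 1 || model$pwm10$width < 1) stop("zero-width PWM")
  name <- name %||% if (is.na(model$subgroup)) "motif" else
    sprintf("ECF%02d", model$subgroup)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  bg <- model$pwm35$background
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", DNA_BASES, bg), collapse = " "), "",
    sprintf("# subgroup %s", ifelse(is.na(model$subgroup), "NA", model$subgroup)),
    sprintf("# spacer_support %d %d",
            min(model$spacer$support), max(model$spacer$support)),
    sprintf("# spacer_count %d %.10g", model$spacer$support,
            unname(model$spacer$counts)),
    sprintf("# spacer_pseudocount %.10g", model$spacer$pseudocount),
    sprintf("# pwm_pseudocount %.10g %.10g",
            model$pwm35$pseudocount, model$pwm10$pseudocount),
    sprintf("# up_beta %.10g", model$up_beta),
    sprintf("# up_width %d", model$up_width),
    "")
  for (blk in c("m35", "m10")) {
    pwm <- if (blk == "m35") model$pwm35 else model$pwm10
    nsites <- if (is.na(pwm$n_sites)) sum(model$spacer$counts) else pwm$n_sites
    lines <- c(lines,
               sprintf("MOTIF %s_%s", name, blk),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       pwm$width, max(1, nsites)),
               apply(pwm$probs, 2, function(col)
                 paste(sprintf("%.10f", col), collapse = " ")),
               "")
  }
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_motif_minimal
#' @return [read_motif_minimal()] returns the reconstructed
#'   `ecf_promoter_model`.
#' @export
read_motif_minimal <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  grab <- function(re) {
    hits <- regmatches(lines, regexec(re, lines))
    hits[vapply(hits, length, integer(1)) > 0]
  }
  bg_i <- grep("^Background letter frequencies", lines)
  bg <- rep(0.25, 4)
  if (length(bg_i)) {
    tok <- strsplit(trimws(lines[bg_i[1] + 1L]), "\\s+")[[1]]
    bg <- as.numeric(tok[seq(2, 8, by = 2)])
  }
  num1 <- function(re, default = NA_real_) {
    h <- grab(re)
    if (length(h)) as.numeric(h[[1]][2]) else default
  }
  subgroup <- suppressWarnings(num1("^# subgroup (\\S+)"))
  sp_sup <- grab("^# spacer_support (\\d+) (\\d+)")
  if (!length(sp_sup)) stop("missing spacer support header in ", path)
  support <- seq.int(as.integer(sp_sup[[1]][2]), as.integer(sp_sup[[1]][3]))
  cnt_lines <- grab("^# spacer_count (\\d+) (\\S+)")
  counts <- setNames(numeric(length(support)), support)
  for (h in cnt_lines) counts[h[2]] <- as.numeric(h[3])
  sp_pc <- num1("^# spacer_pseudocount (\\S+)", 1)
  pwm_pc <- grab("^# pwm_pseudocount (\\S+) (\\S+)")
  pcs <- if (length(pwm_pc)) as.numeric(pwm_pc[[1]][2:3]) else c(1, 1)
  up_beta <- num1("^# up_beta (\\S+)", 0)
  up_width <- num1("^# up_width (\\d+)", 23)

  motif_i <- grep("^MOTIF ", lines)
  if (length(motif_i) != 2L)
    stop("expected exactly two MOTIF blocks (the -35 and -10 PWMs) in ", path)
  read_block <- function(start) {
    hdr <- lines[start + 1L]
    w <- as.integer(sub(".* w= *(\\d+).*", "\\1", hdr))
    rows <- lines[start + 1L + seq_len(w)]
    m <- t(vapply(strsplit(trimws(rows), "\\s+"),
                  function(x) as.numeric(x[1:4]), numeric(4)))
    probs <- t(m)  # 4 x w
    sweep(probs, 2, colSums(probs), "/")  # renormalise rounded columns
  }
  p35 <- read_block(motif_i[1])
  p10 <- read_block(motif_i[2])
  promoter_model(
    if (is.na(subgroup)) NA_integer_ else as.integer(subgroup),
    pwm_from_probs(p35, background = bg, pseudocount = pcs[1]),
    pwm_from_probs(p10, background = bg, pseudocount = pcs[2]),
    spacer_model(counts, pseudocount = sp_pc, support = support),
    up_beta = up_beta, up_width = as.integer(up_width))
}
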