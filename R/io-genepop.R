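#' Read a Genepop genotype file
#'
#' Parses the classic Genepop dialect: a title line, one locus name per line
#' (or a single comma-separated line), populations separated by `Pop` lines,
#' and individual rows `id , <code><code> ...` with concatenated 2- or 3-digit
#' allele codes.  Code width is auto-detected from the genotype token length
#' (4 characters = 2-digit, 6 = 3-digit); an all-zero code is a missing call.
#' Allele codes are taken to be allele sizes in bp.
#'
#' Genepop files carry no repeat-motif metadata, so motif lengths (needed for
#' R_ST and the M-ratio) must be supplied; they default to dinucleotide.
#'
#' @param path file path.
#' @param motifs integer vector of per-locus motif lengths (recycled).
#' @param pop_names optional population names; defaults to the ID of each
#'   population's last individual (the Genepop convention).
#' @return A [genotype_table()].
#' @export
read_genepop <- function(path, motifs = 2L, pop_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a Genepop file: too few lines")
  pop_idx <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (!length(pop_idx)) stop("not a Genepop file: no 'Pop' separator found")
  header <- lines[2:(pop_idx[1] - 1)]
  loci <- unlist(strsplit(header, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  if (!L) stop("no locus names before first 'Pop'")

  pop_of_line <- findInterval(seq_along(lines), pop_idx)
  ind_lines <- which(pop_of_line >= 1 & !(seq_along(lines) %in% pop_idx))
  if (!length(ind_lines)) stop("no individuals found")

  ids <- character(0); popv <- integer(0)
  rows <- list()
  width <- NA_integer_
  for (li in ind_lines) {
    parts <- strsplit(lines[li], ",")[[1]]
    if (length(parts) < 2)
      stop(sprintf("line %d: expected 'id , genotypes'", li))
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(toks) != L)
      stop(sprintf("line %d ('%s'): %d genotype fields but %d loci declared",
                   li, id, length(toks), L))
    w <- unique(nchar(toks))
    if (length(w) != 1 || !w %in% c(4L, 6L))
      stop(sprintf("line %d: unknown allele-code width (token lengths %s)",
                   li, paste(w, collapse = "/")))
    if (is.na(width)) width <- w / 2L
    else if (width != w / 2L)
      stop(sprintf("line %d: allele-code width changes mid-file", li))
    a1 <- as.integer(substr(toks, 1, width))
    a2 <- as.integer(substr(toks, width + 1, 2 * width))
    if (any(is.na(a1)) || any(is.na(a2)))
      stop(sprintf("line %d: non-numeric allele code", li))
    a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
    half <- xor(is.na(a1), is.na(a2))
    if (any(half))
      stop(sprintf("line %d: half-missing genotype (one allele zero)", li))
    ids <- c(ids, id); popv <- c(popv, pop_of_line[li])
    rows[[length(rows) + 1L]] <- cbind(a1, a2)
  }
  n <- length(rows)
  calls <- array(NA_integer_, c(n, L, 2))
  for (i in seq_len(n)) calls[i, , ] <- rows[[i]]
  if (is.null(pop_names)) {
    pop_names <- vapply(split(ids, popv), function(v) v[length(v)], "")
  }
  popf <- factor(pop_names[popv], levels = pop_names)
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  genotype_table(calls, popf, data.frame(locus = loci,
                                         motif = rep_len(as.integer(motifs), L)),
                 ids = ids)
}

#' Write a genotype table in Genepop format
#'
#' @param table a [genotype_table()].
#' @param path output path.
#' @param digits allele-code width, 2 or 3 (3 accommodates sizes up to 999).
#' @param title title line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(table, path, digits = 3L, title = "consgen export") {
  stopifnot(digits %in% c(2L, 3L))
  if (any(table$calls >= 10^digits, na.rm = TRUE))
    stop("allele sizes too large for ", digits, "-digit codes")
  fmt <- paste0("%0", digits, "d")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(table$loci$locus, con)
  for (p in levels(table$pop)) {
    writeLines("Pop", con)
    for (i in which(table$pop == p)) {
      a <- table$calls[i, , , drop = FALSE]
      codes <- vapply(seq_len(nrow(table$loci)), function(l) {
        x <- a[1, l, ]
        if (any(is.na(x))) paste0(sprintf(fmt, 0L), sprintf(fmt, 0L))
        else paste0(sprintf(fmt, x[1]), sprintf(fmt, x[2]))
      }, "")
      writeLines(paste(table$ids[i], ",", paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}
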