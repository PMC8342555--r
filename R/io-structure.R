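#' Write a Structure input file
#'
#' Two input flavours are supported, matching the two data types fed to the
#' admixture sampler:
#' \itemize{
#'   \item a [genotype_table()]: two rows per individual (one allele per row
#'     per locus), missing coded `-9`;
#'   \item an integer matrix (e.g. an allele/supertype presence-absence
#'     encoding with entries 1, 0 or -1): one row per individual, written
#'     as-is.
#' }
#' Columns are whitespace-delimited: individual ID, population index, then
#' one column per locus.
#'
#' @param x a `genotype_table` or integer matrix with rownames.
#' @param path output path.
#' @param pop optional population factor for the matrix flavour.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, pop = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (inherits(x, "genotype_table")) {
    for (i in seq_along(x$ids)) {
      for (slot in 1:2) {
        v <- x$calls[i, , slot]
        v[is.na(v)] <- -9L
        writeLines(paste(x$ids[i], as.integer(x$pop[i]),
                         paste(v, collapse = " ")), con)
      }
    }
  } else {
    x <- as.matrix(x)
    ids <- rownames(x)
    if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(x)))
    popi <- if (is.null(pop)) rep(1L, nrow(x)) else as.integer(factor(pop))
    for (i in seq_len(nrow(x)))
      writeLines(paste(ids[i], popi[i], paste(as.integer(x[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a Structure-format integer matrix
#'
#' Reads whitespace-delimited rows `id pop v1 v2 ...`.  Rows sharing an ID
#' (the two allele rows of a diploid individual) are kept as separate rows;
#' downstream code regroups them.
#'
#' @param path file path.
#' @return list with `ids`, `pop` (integer) and `data` (integer matrix).
#' @export
read_structure <- function(path) {
  raw <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  list(ids = as.character(raw[[1]]), pop = as.integer(raw[[2]]),
       data = as.matrix(raw[, -(1:2), drop = FALSE]))
}
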