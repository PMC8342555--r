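#' Diploid multilocus microsatellite genotype table
#'
#' Container for co-dominant microsatellite calls: an unordered pair of allele
#' sizes (integer base pairs) or missing, for every individual at every locus.
#' Each individual belongs to exactly one population and locus order is shared
#' by all populations.
#'
#' @param calls integer array of dimension `c(n_individuals, n_loci, 2)`;
#'   `NA` encodes a missing call (both slots must then be `NA`).
#' @param pop factor (or character) of population IDs, one per individual;
#'   factor level order defines population order.
#' @param loci data.frame with columns `locus` (names, matching the second
#'   dimension of `calls`) and `motif` (repeat motif length in bp).
#' @param ids optional individual IDs; defaults to `ind1..indn`.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(calls, pop, loci, ids = NULL) {
  if (length(dim(calls)) != 3L || dim(calls)[3] != 2L)
    stop("'calls' must be an n x loci x 2 array")
  n <- dim(calls)[1]
  L <- dim(calls)[2]
  if (!is.factor(pop)) pop <- factor(pop, levels = unique(pop))
  if (length(pop) != n) stop("'pop' length does not match individuals")
  if (!all(c("locus", "motif") %in% names(loci)))
    stop("'loci' needs columns 'locus' and 'motif'")
  if (nrow(loci) != L) stop("'loci' rows do not match call array")
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  bad <- xor(is.na(calls[, , 1, drop = FALSE]), is.na(calls[, , 2, drop = FALSE]))
  if (any(bad)) stop("half-missing calls: both alleles of a call must be NA or neither")
  if (any(calls <= 0, na.rm = TRUE)) stop("allele sizes must be positive integers")
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(ids, loci$locus, NULL)
  structure(list(calls = calls, pop = pop, loci = loci, ids = ids),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$ids), "individuals,",
      nrow(x$loci), "loci,", nlevels(x$pop), "populations\n")
  cat("populations:", paste(sprintf("%s (n=%d)", levels(x$pop),
                                    tabulate(x$pop)), collapse = ", "), "\n")
  miss <- mean(is.na(x$calls[, , 1]))
  cat(sprintf("missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(length(x$ids), nrow(x$loci))

#' Number of populations in a genotype table
#' @param table a [genotype_table()].
#' @return Integer count of populations.
#' @export
n_pops <- function(table) nlevels(table$pop)

#' Subset a genotype table by population
#' @param table a [genotype_table()].
#' @param pops character vector of population IDs to keep.
#' @return A `genotype_table` restricted to `pops` (level order preserved).
#' @export
subset_pops <- function(table, pops) {
  stopifnot(all(pops %in% levels(table$pop)))
  keep <- table$pop %in% pops
  genotype_table(table$calls[keep, , , drop = FALSE],
                 factor(as.character(table$pop[keep]), levels = pops),
                 table$loci, ids = table$ids[keep])
}

# Allele count table for one locus in one set of individuals.
# Returns a named integer vector (names = allele sizes as character).
allele_counts <- function(table, locus, which_ind = NULL) {
  a <- table$calls[, locus, , drop = FALSE]
  if (!is.null(which_ind)) a <- a[which_ind, , , drop = FALSE]
  v <- as.vector(a)
  v <- v[!is.na(v)]
  if (!length(v)) return(integer(0))
  tab <- table(v)
  setNames(as.integer(tab), names(tab))
}
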