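# CSV/FASTA export helpers for downstream plotting and reporting.

#' Write a structure run's Q matrix as CSV (wide and long formats)
#'
#' The wide file has one row per individual (`id`, `Q1..QK`); the long file
#' is bar-plot ready (`id`, `cluster`, `proportion`).
#'
#' @param run a `structure_run` from [admixture_gibbs()].
#' @param path output CSV path (wide format).
#' @param long_path optional long-format CSV path.
#' @return `path`, invisibly.
#' @export
write_q_matrix <- function(run, path, long_path = NULL) {
  Q <- run$Q
  colnames(Q) <- paste0("Q", seq_len(ncol(Q)))
  write.csv(data.frame(id = rownames(Q), Q, check.names = FALSE), path,
            row.names = FALSE)
  if (!is.null(long_path)) {
    long <- data.frame(id = rep(rownames(Q), ncol(Q)),
                       cluster = rep(seq_len(ncol(Q)), each = nrow(Q)),
                       proportion = as.vector(Q))
    write.csv(long, long_path, row.names = FALSE)
  }
  invisible(path)
}

#' Write supertype assignment and per-population frequency tables
#'
#' Emits `<prefix>_assignment.csv` (allele, supertype), and, when a catalog
#' is supplied, `<prefix>_frequencies.csv` (wide) plus
#' `<prefix>_frequencies_long.csv` (population, supertype, frequency) for
#' pie/bar plotting.
#'
#' @param assignment a `supertype_assignment` from [dapc_assign()].
#' @param prefix output path prefix.
#' @param catalog optional [allele_catalog()] for frequency tables.
#' @return The assignment CSV path, invisibly.
#' @export
write_supertype_tables <- function(assignment, prefix, catalog = NULL) {
  a_path <- paste0(prefix, "_assignment.csv")
  write.csv(data.frame(allele = names(assignment$assignment),
                       supertype = assignment$assignment),
            a_path, row.names = FALSE)
  if (!is.null(catalog)) {
    f <- supertype_frequencies(assignment, catalog)
    write.csv(data.frame(pop = rownames(f), f, check.names = FALSE),
              paste0(prefix, "_frequencies.csv"), row.names = FALSE)
    long <- data.frame(pop = rep(rownames(f), ncol(f)),
                       supertype = rep(colnames(f), each = nrow(f)),
                       frequency = as.vector(f))
    write.csv(long, paste0(prefix, "_frequencies_long.csv"),
              row.names = FALSE)
  }
  invisible(a_path)
}

#' Write a validated allele catalog as FASTA plus genotype CSV
#'
#' @param catalog an [allele_catalog()].
#' @param fasta_path path for the allele FASTA.
#' @param genotype_path optional path for the per-individual genotype CSV.
#' @return `fasta_path`, invisibly.
#' @export
write_catalog <- function(catalog, fasta_path, genotype_path = NULL) {
  write_fasta(catalog$alleles, fasta_path)
  if (!is.null(genotype_path))
    write.csv(catalog$genotypes, genotype_path, row.names = FALSE)
  invisible(fasta_path)
}
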