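# Population-level MHC diversity and differentiation.

#' Haplotype (allelic) diversity
#'
#' A_d = n/(n-1) (1 - sum p_i^2) over gene copies; 0 for a monomorphic
#' population.
#'
#' @param allele_counts named vector of allele copy counts.
#' @return Haplotype diversity in `[0, 1]`.
#' @export
haplotype_diversity <- function(allele_counts) {
  n <- sum(allele_counts)
  if (n < 2 || length(allele_counts) < 2) return(0)
  p <- allele_counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Nucleotide diversity per site
#'
#' Mean pairwise proportion of differing sites over gene copies with the
#' n/(n-1) small-sample correction:
#' pi = n/(n-1) * sum_{a<b} 2 f_a f_b d_ab / L.
#'
#' @param sequences named character vector of equal-length allele sequences.
#' @param counts copy count per allele (aligned with `sequences`).
#' @return Nucleotide diversity per site.
#' @export
nucleotide_diversity <- function(sequences, counts) {
  stopifnot(length(sequences) == length(counts))
  n <- sum(counts)
  if (n < 2 || length(sequences) < 2) return(0)
  L <- nchar(sequences[1])
  f <- counts / n
  pi0 <- 0
  for (i in seq_along(sequences)[-length(sequences)])
    for (j in (i + 1):length(sequences)) {
      d <- seq_diff_count(sequences[i], sequences[j]) / L
      pi0 <- pi0 + 2 * f[i] * f[j] * d
    }
  n / (n - 1) * pi0
}

#' Count differing sites between two equal-length sequences
#' @param a,b sequences.
#' @return Integer number of mismatching positions.
#' @export
seq_diff_count <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Per-population MHC diversity summary
#'
#' @param catalog an [allele_catalog()].
#' @param single_allele copy convention for single-allele individuals.
#' @return data.frame per population: `pop`, `n` (typed individuals), `A_M`
#'   (allele count), `A_d` (haplotype diversity), `pi` (nucleotide
#'   diversity).
#' @export
mhc_pop_summary <- function(catalog, single_allele = c("homozygote", "haploid")) {
  single_allele <- match.arg(single_allele)
  g <- catalog$genotypes
  out <- list()
  for (p in unique(g$pop)) {
    gp <- g[g$pop == p, , drop = FALSE]
    copies <- .mhc_copies(gp, single_allele)
    if (!length(copies)) next
    cnt <- table(copies)
    seqs <- catalog$alleles[names(cnt)]
    out[[p]] <- data.frame(
      pop = p, n = sum(!is.na(gp$allele1)),
      A_M = length(cnt),
      A_d = haplotype_diversity(as.integer(cnt)),
      pi = nucleotide_diversity(seqs, as.integer(cnt)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.mhc_copies <- function(gp, single_allele = "homozygote") {
  copies <- character(0)
  for (i in seq_len(nrow(gp))) {
    a1 <- gp$allele1[i]; a2 <- gp$allele2[i]
    if (is.na(a1)) next
    if (is.na(a2)) a2 <- if (single_allele == "homozygote") a1 else NA
    copies <- c(copies, a1, if (!is.na(a2)) a2)
  }
  copies
}

#' Pairwise phi_ST from sequence distances
#'
#' AMOVA-style ratio of among-population to total variance computed from raw
#' pairwise nucleotide-difference distances between gene copies (no
#' substitution-model correction; the intra-species alignments are short).
#' Significance by permuting gene copies among populations.
#'
#' @param catalog an [allele_catalog()] (uses its genotypes and sequences).
#' @param permutations permutation count (default 1000).
#' @param seed optional seed.
#' @param single_allele copy convention for single-allele individuals.
#' @return A [pairwise_stat_matrix()] with p-values.
#' @export
phi_st <- function(catalog, permutations = 1000, seed = NULL,
                   single_allele = c("homozygote", "haploid")) {
  single_allele <- match.arg(single_allele)
  if (!is.null(seed)) set.seed(seed)
  g <- catalog$genotypes
  pops <- unique(g$pop)
  copies <- list()
  for (p in pops)
    copies[[p]] <- .mhc_copies(g[g$pop == p, , drop = FALSE], single_allele)
  pops <- pops[lengths(copies[pops]) > 0]
  k <- length(pops)
  V <- matrix(0, k, k, dimnames = list(pops, pops))
  P <- V + NA
  # allele-level distance matrix (squared Euclidean = difference count)
  alle <- names(catalog$alleles)
  D2 <- matrix(0, length(alle), length(alle), dimnames = list(alle, alle))
  for (i in seq_along(alle)) for (j in seq_along(alle)) if (i < j)
    D2[i, j] <- D2[j, i] <- seq_diff_count(catalog$alleles[alle[i]],
                                           catalog$alleles[alle[j]])
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- copies[[pops[i]]]; y <- copies[[pops[j]]]
    obs <- .phi_st_two(x, y, D2)
    V[i, j] <- V[j, i] <- obs
    pooled <- c(x, y)
    ge <- 0L
    for (b in seq_len(permutations)) {
      perm <- sample(pooled)
      if (.phi_st_two(perm[seq_along(x)], perm[-seq_along(x)], D2) >= obs)
        ge <- ge + 1L
    }
    P[i, j] <- P[j, i] <- (ge + 1) / (permutations + 1)
  }
  pairwise_stat_matrix(V, "phi_ST", P)
}

# two-population AMOVA on copy labels with a squared-distance matrix
.phi_st_two <- function(x, y, D2) {
  groups <- list(x, y)
  N <- length(x) + length(y)
  all_lab <- c(x, y)
  ssd <- function(lab) {
    if (length(lab) < 2) return(0)
    sub <- D2[lab, lab, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(lab)
  }
  SS_total <- ssd(all_lab)
  SS_within <- sum(vapply(groups, ssd, 0))
  n_g <- lengths(groups)
  P <- 2
  sigma_w <- SS_within / (N - P)
  MS_a <- (SS_total - SS_within) / (P - 1)
  n_prime <- (N - sum(n_g^2) / N) / (P - 1)
  sigma_a <- (MS_a - sigma_w) / n_prime
  if (sigma_a + sigma_w <= 0) return(0)
  sigma_a / (sigma_a + sigma_w)
}

#' Binary Structure encoding of MHC data
#'
#' One row per individual, one column per allele (or supertype): 1 when the
#' individual carries it, 0 when typed but not carrying it, and -1 across a
#' locus's columns when the individual is untyped there (missing data).
#'
#' @param catalog an [allele_catalog()].
#' @param mode `"allele"` or `"supertype"`.
#' @param assignment a `supertype_assignment` (required for supertype mode).
#' @param individuals optional row universe (defaults to the catalog's
#'   genotyped individuals); individuals absent from the catalog get -1 rows.
#' @return Integer matrix with rownames = individuals.
#' @export
encode_for_structure <- function(catalog, mode = c("allele", "supertype"),
                                 assignment = NULL, individuals = NULL) {
  mode <- match.arg(mode)
  g <- catalog$genotypes
  if (is.null(individuals)) individuals <- g$individual
  cols <- if (mode == "allele") names(catalog$alleles) else {
    if (is.null(assignment)) stop("supertype mode needs an assignment")
    paste0("ST", sort(unique(assignment$assignment)))
  }
  M <- matrix(-1L, length(individuals), length(cols),
              dimnames = list(individuals, cols))
  for (i in seq_along(individuals)) {
    row <- g[g$individual == individuals[i], , drop = FALSE]
    if (!nrow(row) || is.na(row$allele1[1])) next
    carried <- na.omit(c(row$allele1[1], row$allele2[1]))
    if (mode == "supertype")
      carried <- paste0("ST", assignment$assignment[carried])
    M[i, ] <- 0L
    M[i, unique(carried)] <- 1L
  }
  M
}
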