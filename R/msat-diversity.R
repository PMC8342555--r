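#' Per-locus, per-population diversity summaries
#'
#' For every locus x population combination computes the allele count A,
#' rarefied allelic richness A_R, observed heterozygosity H_O, Nei's unbiased
#' expected heterozygosity H_E = 2n/(2n-1) (1 - sum p_i^2), the fixation
#' index F_IS = 1 - H_O/H_E, and (optionally) the Hardy-Weinberg exact-test
#' p-value.
#'
#' Allelic richness uses hypergeometric rarefaction to `rarefaction_g` gene
#' copies: A_R = sum_a (1 - choose(2n - N_a, g) / choose(2n, g)).  By the
#' usual convention `g` defaults to the smallest per-population gene-copy
#' count across the dataset (per locus, counting non-missing calls).
#'
#' @param table a [genotype_table()].
#' @param rarefaction_g gene-copy count for rarefaction, or `NULL` for the
#'   dataset minimum.
#' @param hwe compute HWE exact p-values (Markov-chain test)?
#' @param config a [run_config()] supplying chain parameters and the seed.
#' @return data.frame with one row per locus x population: `pop`, `locus`,
#'   `n` (typed individuals), `A`, `A_R`, `H_O`, `H_E`, `F_IS`, `hwe_p`.
#'   Monomorphic loci report `F_IS = NA`.
#' @export
locus_summaries <- function(table, rarefaction_g = NULL, hwe = FALSE,
                            config = run_config()) {
  pops <- levels(table$pop)
  loci <- table$loci$locus
  # smallest 2n over pops and loci (non-missing)
  n_mat <- sapply(loci, function(l) sapply(pops, function(p)
    sum(!is.na(table$calls[table$pop == p, l, 1]))))
  if (is.null(rarefaction_g)) rarefaction_g <- 2L * min(n_mat)
  if (rarefaction_g > 2L * min(n_mat[n_mat > 0]))
    stop("rarefaction_g exceeds the smallest per-population gene-copy count")
  if (hwe) set.seed(config$seed)
  out <- list()
  for (p in pops) for (l in loci) {
    sel <- table$pop == p
    a <- table$calls[sel, l, , drop = FALSE]
    ok <- !is.na(a[, 1, 1])
    n <- sum(ok)
    if (n == 0) stop("no non-missing calls for locus ", l, " in ", p)
    a1 <- a[ok, 1, 1]; a2 <- a[ok, 1, 2]
    cnt <- allele_counts(table, l, which_ind = which(sel))
    A <- length(cnt)
    two_n <- 2L * n
    pfreq <- cnt / two_n
    HE <- unbiased_het(cnt)
    HO <- mean(a1 != a2)
    FIS <- if (HE > 0) 1 - HO / HE else NA_real_
    AR <- allelic_richness(cnt, rarefaction_g)
    hp <- NA_real_
    if (hwe && A > 1) {
      hp <- hwe_exact_test(cbind(a1, a2), batches = config$hwe_batches,
                           iters = config$hwe_iters,
                           burnin = config$hwe_burnin)$p
    } else if (hwe) hp <- 1
    out[[length(out) + 1L]] <- data.frame(
      pop = p, locus = l, n = n, A = A, A_R = AR, H_O = HO, H_E = HE,
      F_IS = FIS, hwe_p = hp)
  }
  do.call(rbind, out)
}

#' Nei's unbiased expected heterozygosity
#' @param counts named integer vector of allele counts (gene copies).
#' @return H_E = 2n/(2n-1) (1 - sum p_i^2) where 2n = total gene copies.
#' @export
unbiased_het <- function(counts) {
  tn <- sum(counts)
  if (tn < 2) return(NA_real_)
  p <- counts / tn
  tn / (tn - 1) * (1 - sum(p^2))
}

#' Rarefied allelic richness
#' @param counts allele counts (gene copies).
#' @param g rarefaction gene-copy count (g <= sum(counts)).
#' @return Expected allele count in a sample of `g` gene copies.
#' @export
allelic_richness <- function(counts, g) {
  tn <- sum(counts)
  if (g > tn) stop("g exceeds available gene copies")
  # 1 - P(allele absent from a hypergeometric subsample of size g)
  sum(1 - exp(lchoose(tn - counts, g) - lchoose(tn, g)))
}

#' Bonferroni multiple-testing adjustment
#' @param p_values numeric vector of p-values.
#' @param alpha family-wise error rate.
#' @return Logical vector: significant at the Bonferroni-adjusted threshold
#'   `alpha / length(p_values)`.
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  p_values < alpha / length(p_values)
}
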