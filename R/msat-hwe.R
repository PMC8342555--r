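#' Markov-chain exact test of Hardy-Weinberg proportions
#'
#' Estimates the Fisher-style exact-test p-value of Guo & Thompson by running
#' a Markov chain over genotype tables with the observed allele counts.  The
#' chain swaps gene copies between individuals; because a uniform random
#' pairing of gene copies induces exactly the HWE conditional distribution of
#' tables given allele counts, the symmetric swap proposal needs no
#' Metropolis correction.  The p-value is the chain fraction of tables whose
#' conditional probability does not exceed the observed table's, with a
#' standard error from the between-batch variance.
#'
#' @param genotypes two-column matrix, one row per individual (any allele
#'   coding; rows with `NA` are dropped).
#' @param batches,iters,burnin chain parameters (defaults follow the classic
#'   exact-test settings: 1000 batches of 10000 iterations).
#' @param seed optional seed (set it here or via `set.seed` upstream).
#' @return list with `p` and `se`.
#' @export
hwe_exact_test <- function(genotypes, batches = 1000, iters = 10000,
                           burnin = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genotypes <- genotypes[complete.cases(genotypes), , drop = FALSE]
  if (!nrow(genotypes)) stop("no complete genotypes")
  codes <- factor(c(genotypes[, 1], genotypes[, 2]))
  m <- matrix(as.integer(codes), ncol = 2)
  res <- hwe_mc_chain(m, as.integer(batches), as.integer(iters),
                      as.integer(burnin))
  list(p = res$p, se = res$se)
}

#' Markov-chain exact test of genotypic linkage disequilibrium
#'
#' Tests independence of the genotype classes at two loci with a Markov chain
#' over contingency tables with fixed margins (genotypes at one locus are
#' shuffled among individuals; a uniform shuffle induces the conditional
#' distribution given margins).  Monomorphic loci give p = 1.
#'
#' @param table a [genotype_table()].
#' @param locus_pair character vector of two locus names.
#' @param pop optional population to restrict to (default: all individuals).
#' @param batches,iters,burnin chain parameters.
#' @param seed optional seed.
#' @return list with `p` and `se`.
#' @export
ld_exact_test <- function(table, locus_pair, pop = NULL, batches = 1000,
                          iters = 10000, burnin = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(locus_pair) == 2)
  sel <- if (is.null(pop)) rep(TRUE, length(table$ids)) else table$pop == pop
  g_class <- function(l) {
    a <- table$calls[sel, l, , drop = FALSE]
    lo <- pmin(a[, 1, 1], a[, 1, 2]); hi <- pmax(a[, 1, 1], a[, 1, 2])
    paste(lo, hi, sep = "/")
  }
  g1 <- g_class(locus_pair[1]); g2 <- g_class(locus_pair[2])
  ok <- !grepl("NA", g1) & !grepl("NA", g2)
  if (!sum(ok)) stop("no individuals typed at both loci")
  res <- contingency_mc_chain(as.integer(factor(g1[ok])),
                              as.integer(factor(g2[ok])),
                              as.integer(batches), as.integer(iters),
                              as.integer(burnin))
  list(p = res$p, se = res$se)
}

#' Null-allele screen (homozygote excess)
#'
#' Estimates the null-allele frequency with the Brookfield-1 estimator
#' r = (H_E - H_O) / (1 + H_E) and flags the locus when the observed
#' homozygote count exceeds the 95th percentile of counts simulated under
#' HWE from the observed allele frequencies.
#'
#' @param table a [genotype_table()].
#' @param locus locus name.
#' @param pop optional population restriction.
#' @param sims number of HWE simulations for the homozygote-excess flag.
#' @param seed optional seed.
#' @return list with `r` (null frequency estimate, floored at 0), `flag`
#'   (homozygote excess), `H_O`, `H_E`.
#' @export
null_allele_screen <- function(table, locus, pop = NULL, sims = 1000,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sel <- if (is.null(pop)) rep(TRUE, length(table$ids)) else table$pop == pop
  a <- table$calls[sel, locus, , drop = FALSE]
  ok <- !is.na(a[, 1, 1])
  a1 <- a[ok, 1, 1]; a2 <- a[ok, 1, 2]
  n <- length(a1)
  cnt <- allele_counts(table, locus, which_ind = which(sel))
  HE <- unbiased_het(cnt)
  HO <- mean(a1 != a2)
  r <- max(0, (HE - HO) / (1 + HE))
  p <- cnt / sum(cnt)
  hom_obs <- sum(a1 == a2)
  # genotype draws under HWE: two independent gametes per individual
  hom_sim <- vapply(seq_len(sims), function(i) {
    g1 <- sample(names(p), n, replace = TRUE, prob = p)
    g2 <- sample(names(p), n, replace = TRUE, prob = p)
    sum(g1 == g2)
  }, 0L)
  list(r = r, flag = hom_obs > quantile(hom_sim, 0.95), H_O = HO, H_E = HE)
}
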