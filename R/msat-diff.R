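# Among-population differentiation statistics.

# Per-locus Weir-Cockerham (1984) variance components a, b, c summed over
# alleles.  calls: n x 2 allele matrix for one locus; popfac: factor.
.wc_components <- function(a1, a2, popfac) {
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]; popfac <- droplevels(popfac[ok])
  r <- nlevels(popfac)
  if (r < 2) return(c(a = 0, b = 0, c = 0))
  n_i <- as.vector(table(popfac))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  alleles <- unique(c(a1, a2))
  if (length(alleles) < 2) return(c(a = 0, b = 0, c = 0))
  A <- B <- C <- 0
  for (u in alleles) {
    cnt_u <- (a1 == u) + (a2 == u)
    p_iu <- tapply(cnt_u, popfac, sum) / (2 * n_i)
    h_iu <- tapply(cnt_u == 1L, popfac, mean)
    pbar <- sum(n_i * p_iu) / (r * nbar)
    s2 <- sum(n_i * (p_iu - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_iu) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  c(a = A, b = B, c = C)
}

.wc_theta <- function(table, pops) {
  sel <- table$pop %in% pops
  popfac <- factor(as.character(table$pop[sel]), levels = pops)
  comp <- rowSums(vapply(table$loci$locus, function(l) {
    .wc_components(table$calls[sel, l, 1], table$calls[sel, l, 2], popfac)
  }, c(a = 0, b = 0, c = 0)))
  unname(comp["a"] / sum(comp))
}

#' Weir-Cockerham F_ST (theta)
#'
#' Multi-allelic, multi-locus theta from the Weir-Cockerham (1984) variance
#' components, loci and alleles combined by summing components.  Negative
#' estimates are reported as computed.  Pairwise p-values come from permuting
#' individuals among the two populations.
#'
#' @param table a [genotype_table()].
#' @param pops population subset (default all).
#' @param permutations permutation count for pairwise p-values (0 = none).
#' @param seed optional seed for the permutations.
#' @return list with `global` (theta over all `pops`) and `matrix`
#'   (a [pairwise_stat_matrix()] of pairwise theta, with p-values when
#'   `permutations > 0`).
#' @export
fst_weir_cockerham <- function(table, pops = levels(table$pop),
                               permutations = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  global <- .wc_theta(table, pops)
  k <- length(pops)
  V <- matrix(0, k, k, dimnames = list(pops, pops))
  P <- if (permutations > 0) V + NA else NULL
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    pr <- c(pops[i], pops[j])
    th <- .wc_theta(table, pr)
    V[i, j] <- V[j, i] <- th
    if (permutations > 0) {
      sub <- subset_pops(table, pr)
      ge <- 0L
      for (b in seq_len(permutations)) {
        sub_perm <- sub
        sub_perm$pop <- sample(sub$pop)
        if (.wc_theta(sub_perm, pr) >= th) ge <- ge + 1L
      }
      P[i, j] <- P[j, i] <- (ge + 1) / (permutations + 1)
    }
  }
  list(global = global, matrix = pairwise_stat_matrix(V, "F_ST", P))
}

# Nested ANOVA variance components on a quantitative per-copy value
# (allele size in repeat units): populations / individuals / copies.
.size_components <- function(x1, x2, popfac) {
  ok <- !is.na(x1)
  x1 <- x1[ok]; x2 <- x2[ok]; popfac <- droplevels(popfac[ok])
  r <- nlevels(popfac)
  N <- length(x1)
  if (r < 2 || N < 2) return(c(P = 0, I = 0, G = 0))
  n_i <- as.vector(table(popfac))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  xbar_ind <- (x1 + x2) / 2
  xbar_pop <- tapply(c(x1, x2), rep(popfac, 2), mean)
  xbar <- mean(c(x1, x2))
  SSG <- sum((x1 - x2)^2) / 2
  SSI <- 2 * sum((xbar_ind - xbar_pop[popfac])^2)
  SSP <- 2 * sum(n_i * (xbar_pop - xbar)^2)
  MSG <- SSG / N
  MSI <- SSI / (N - r)
  MSP <- SSP / (r - 1)
  sG <- MSG
  sI <- (MSI - MSG) / 2
  sP <- (MSP - MSI) / (2 * nc)
  c(P = sP, I = sI, G = sG)
}

.rst_value <- function(table, pops) {
  sel <- table$pop %in% pops
  popfac <- factor(as.character(table$pop[sel]), levels = pops)
  comp <- rowSums(vapply(seq_len(nrow(table$loci)), function(li) {
    l <- table$loci$locus[li]; m <- table$loci$motif[li]
    .size_components(table$calls[sel, l, 1] / m, table$calls[sel, l, 2] / m,
                     popfac)
  }, c(P = 0, I = 0, G = 0)))
  unname(comp["P"] / sum(comp))
}

#' Slatkin's R_ST from allele sizes
#'
#' Same nested ANOVA as the F_ST estimator but on allele sizes expressed in
#' repeat units (bp divided by the locus motif length), so stepwise mutation
#' memory is retained.  Loci are combined by summing variance components.
#'
#' @inheritParams fst_weir_cockerham
#' @return list with `global` and `matrix` (statistic `R_ST`).
#' @export
rst_slatkin <- function(table, pops = levels(table$pop), permutations = 0,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  global <- .rst_value(table, pops)
  k <- length(pops)
  V <- matrix(0, k, k, dimnames = list(pops, pops))
  P <- if (permutations > 0) V + NA else NULL
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    pr <- c(pops[i], pops[j])
    rs <- .rst_value(table, pr)
    V[i, j] <- V[j, i] <- rs
    if (permutations > 0) {
      sub <- subset_pops(table, pr)
      ge <- 0L
      for (b in seq_len(permutations)) {
        sub_perm <- sub
        sub_perm$pop <- sample(sub$pop)
        if (.rst_value(sub_perm, pr) >= rs) ge <- ge + 1L
      }
      P[i, j] <- P[j, i] <- (ge + 1) / (permutations + 1)
    }
  }
  list(global = global, matrix = pairwise_stat_matrix(V, "R_ST", P))
}

#' Nei's G_ST
#'
#' G_ST = (H_T - H_S) / H_T with H_S the unweighted mean within-population
#' gene diversity and H_T the gene diversity of unweighted mean allele
#' frequencies; H_S and H_T are averaged over loci before taking the ratio.
#'
#' @param table a [genotype_table()].
#' @param pops population subset.
#' @return list with `global` and `matrix` (statistic `G_ST`).
#' @export
gst_nei <- function(table, pops = levels(table$pop)) {
  gst_pair <- function(pp) {
    hs <- ht <- numeric(0)
    for (l in table$loci$locus) {
      freqs <- lapply(pp, function(p) {
        cnt <- allele_counts(table, l, which_ind = which(table$pop == p))
        cnt / sum(cnt)
      })
      alle <- unique(unlist(lapply(freqs, names)))
      pm <- sapply(freqs, function(f) {
        v <- setNames(numeric(length(alle)), alle)
        v[names(f)] <- f
        v
      })
      pm <- matrix(pm, nrow = length(alle))
      hs <- c(hs, mean(1 - colSums(pm^2)))
      ht <- c(ht, 1 - sum(rowMeans(pm)^2))
    }
    (mean(ht) - mean(hs)) / mean(ht)
  }
  global <- gst_pair(pops)
  k <- length(pops)
  V <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    V[i, j] <- V[j, i] <- gst_pair(c(pops[i], pops[j]))
  list(global = global, matrix = pairwise_stat_matrix(V, "G_ST"))
}
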