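#' Heterozygosity-excess bottleneck test
#'
#' For each polymorphic locus, draws mutation-drift-equilibrium samples from
#' the coalescent conditional on the observed allele count k (theta initial
#' guess from the Ewens expectation of k under IAM, then rejection until the
#' simulated allele count equals k), computes the equilibrium heterozygosity
#' distribution, and standardises the observed Nei heterozygosity as
#' DH = (H_E - mean(H_eq)) / sd(H_eq).  A one-tailed Wilcoxon signed-rank
#' test across loci asks whether H_E systematically exceeds equilibrium
#' expectation, the transient signature of a recent bottleneck.
#'
#' @param table a [genotype_table()].
#' @param pop population to test (default: the only population).
#' @param model mutation model for the equilibrium simulations; the headline
#'   convention is the two-phase model with 90% single-step and 10%
#'   multi-step (infinite-allele-like) mutations.
#' @param p_single TPM single-step proportion.
#' @param geom_p TPM multi-step geometric parameter.
#' @param sims_per_locus accepted equilibrium samples required per locus.
#' @param max_attempts rejection-sampling cap per locus.
#' @param seed integer seed.
#' @param shared_theta calibrate a single theta from the across-locus mean
#'   allele count instead of per locus.  Per-locus calibration (the
#'   classical protocol, the default) couples each locus's reference
#'   distribution to its own observed k and makes the test slightly
#'   anticonservative; the pooled estimate is preferable when loci share a
#'   mutation rate.
#' @return list of class `bottleneck_result`: `per_locus` (data.frame with
#'   `locus`, `k`, `H_E`, `H_eq_mean`, `H_eq_sd`, `DH`), `p` (one-tailed
#'   Wilcoxon for excess), `mode_shift`, `class_frequencies` (10 bins of
#'   width 0.1).  Monomorphic loci are excluded with a log notice.
#' @export
het_excess_test <- function(table, pop = levels(table$pop)[1],
                            model = c("TPM", "SMM", "IAM"), p_single = 0.9,
                            geom_p = 0.5, sims_per_locus = 1000,
                            max_attempts = 50000, seed = 1,
                            shared_theta = FALSE) {
  model <- match.arg(model)
  set.seed(seed)
  sel <- which(table$pop == pop)
  theta_shared <- if (shared_theta)
    .calibrate_theta_mean_k(table, sel, model, p_single, geom_p) else NULL
  rows <- list()
  for (l in table$loci$locus) {
    cnt <- allele_counts(table, l, which_ind = sel)
    n_genes <- sum(cnt)
    k <- length(cnt)
    if (k < 2) {
      consgen_log(sprintf("locus %s monomorphic in %s: excluded from het-excess test", l, pop))
      next
    }
    HE <- unbiased_het(cnt)
    mcode <- match(model, c("IAM", "SMM", "TPM")) - 1L
    theta <- if (shared_theta) theta_shared
             else .calibrate_theta(k, n_genes, model, p_single, geom_p)
    sim <- coal_msat_hdist(as.integer(n_genes), theta / (4 * 500), mcode,
                           p_single, geom_p, 500, as.integer(k),
                           as.integer(sims_per_locus),
                           as.integer(max_attempts))
    hsim <- sim$H
    if (length(hsim) < 2) {
      consgen_log(sprintf("locus %s: conditional simulation failed (k=%d)", l, k),
                  level = "WARN")
      next
    }
    mu_h <- mean(hsim); sd_h <- sd(hsim)
    rows[[length(rows) + 1L]] <- data.frame(
      locus = l, k = k, H_E = HE, H_eq_mean = mu_h, H_eq_sd = sd_h,
      DH = if (sd_h > 0) (HE - mu_h) / sd_h else 0)
  }
  if (!length(rows)) stop("no polymorphic loci available for the test")
  per_locus <- do.call(rbind, rows)
  if (nrow(per_locus) < 4)
    consgen_log("fewer than 4 polymorphic loci: Wilcoxon ranks are weak", level = "WARN")
  dh <- per_locus$DH
  p <- if (all(dh == 0)) 1 else
    suppressWarnings(wilcox.test(dh, alternative = "greater")$p.value)
  ms <- mode_shift(table, pop = pop)
  structure(list(per_locus = per_locus, p = p,
                 mode_shift = ms$shape, class_frequencies = ms$bins),
            class = "bottleneck_result")
}

# Solve the Ewens sampling expectation E[k | theta, n] = k for theta.
.ewens_theta <- function(k, n) {
  f <- function(th) sum(th / (th + 0:(n - 1))) - k
  stats::uniroot(f, c(1e-6, 1e6), tol = 1e-8)$root
}

# Ewens (IAM) solution is only a starting point: stepwise models reach a
# given allele count at higher theta (size homoplasy), and an uncalibrated
# theta biases the conditional H distribution.  A short pilot search matches
# the simulated mean allele count to the target.
.calibrate_theta <- function(k_target, n_genes, model, p_single, geom_p) {
  theta <- .ewens_theta(k_target, n_genes)
  for (it in 1:6) {
    ks <- vapply(1:40, function(i) {
      length(unique(coalescent_msat(n_genes, theta / (4 * 500), model,
                                    data.frame(t = 0, N = 500),
                                    p_single, geom_p)))
    }, 0L)
    ratio <- (k_target - 1) / max(mean(ks) - 1, 0.1)
    if (abs(ratio - 1) < 0.05) break
    theta <- theta * min(max(ratio, 0.5), 2)
  }
  theta
}

# Pooled theta across loci (use when loci are exchangeable, i.e. share a
# mutation rate): calibrating theta to each locus's own k couples the
# reference distribution to the observed draw and inflates the one-tailed
# test slightly; the pooled estimate removes most of that coupling.
.calibrate_theta_mean_k <- function(table, sel, model, p_single, geom_p) {
  ks <- ns <- c()
  for (l in table$loci$locus) {
    cnt <- allele_counts(table, l, which_ind = sel)
    if (length(cnt) >= 2) { ks <- c(ks, length(cnt)); ns <- c(ns, sum(cnt)) }
  }
  if (!length(ks)) stop("no polymorphic loci available for the test")
  .calibrate_theta(mean(ks), as.integer(round(mean(ns))), model,
                   p_single, geom_p)
}

#' Allele-frequency mode-shift indicator
#'
#' Pools alleles across loci, bins their frequencies into ten classes of
#' width 0.1, and reports "L-shaped" when the lowest class (0, 0.1] holds the
#' largest allele count (ties classified L-shaped, conservative toward no
#' bottleneck), otherwise "shifted".
#'
#' @param table a [genotype_table()].
#' @param pop population (default: first).
#' @return list with `shape` ("L-shaped" or "shifted") and `bins`
#'   (proportions over the 10 classes; they sum to 1).
#' @export
mode_shift <- function(table, pop = levels(table$pop)[1]) {
  sel <- which(table$pop == pop)
  freqs <- unlist(lapply(table$loci$locus, function(l) {
    cnt <- allele_counts(table, l, which_ind = sel)
    cnt / sum(cnt)
  }))
  bins <- table(cut(freqs, breaks = seq(0, 1, 0.1), include.lowest = FALSE))
  shape <- if (bins[1] >= max(bins[-1])) "L-shaped" else "shifted"
  list(shape = shape, bins = as.vector(bins) / sum(bins))
}

#' Garza-Williamson M-ratio
#'
#' Per locus M = k / (r + 1) with r the allele-size range in repeat units
#' ((max - min) / motif length); the population value is the mean over loci.
#' Prolonged demographic declines erode allele counts faster than size range,
#' depressing M; values below the conventional 0.68 threshold flag a decline.
#' Monomorphic loci give M = 1 (k = 1, r = 0).
#'
#' @param table a [genotype_table()].
#' @param pop population (default: first).
#' @return list with `per_locus` (named vector of M), `mean`, and `flag`
#'   (`TRUE` when mean M < 0.68).
#' @export
m_ratio <- function(table, pop = levels(table$pop)[1]) {
  sel <- which(table$pop == pop)
  M <- vapply(seq_len(nrow(table$loci)), function(li) {
    l <- table$loci$locus[li]
    cnt <- allele_counts(table, l, which_ind = sel)
    sizes <- as.integer(names(cnt))
    k <- length(cnt)
    r <- (max(sizes) - min(sizes)) / table$loci$motif[li]
    k / (r + 1)
  }, 0)
  names(M) <- table$loci$locus
  list(per_locus = M, mean = mean(M), flag = mean(M) < 0.68)
}
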