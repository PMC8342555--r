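#' Admixture-model Bayesian clustering (Gibbs sampler)
#'
#' Standard admixture-model conditional updates: cluster allele frequencies
#' from Dirichlet(lambda + counts), copy origins from their multinomial full
#' conditional, per-individual admixture proportions Q from
#' Dirichlet(alpha + origin counts), and the symmetric Dirichlet parameter
#' alpha by a Metropolis random walk with a uniform prior on (0, 10].
#' Frequencies are independent across clusters (no correlated-frequencies
#' prior).  L(K) is the posterior mean of the mixture log-likelihood.
#'
#' @param data either a [genotype_table()] (diploid allele-coded loci) or an
#'   integer matrix of binary presence/absence columns (1/0, -1 = missing),
#'   treated as haploid two-state loci.
#' @param K number of clusters (must not exceed the individual count).
#' @param burnin,generations sampler schedule.
#' @param seed integer seed.
#' @param lambda Dirichlet frequency prior parameter.
#' @param thin record the log-likelihood every `thin` sweeps.
#' @return list of class `structure_run`: `K`, `Q` (posterior mean admixture,
#'   rows sum to 1), `P` (posterior mean frequencies), `loglik` (recorded
#'   samples), `L` (their mean), `lnPD` (the harmonic model-evidence estimate
#'   `mean - var/2`, the quantity the delta-K method is applied to), `alpha`.
#'   During the first half of burn-in the origin updates are tempered
#'   (temperature 3 annealed to 1) and alpha is held fixed, which prevents
#'   chains locking into poor labelling modes; recorded samples are untouched.
#' @export
admixture_gibbs <- function(data, K, burnin = 1e5, generations = 4e5,
                            seed = 1, lambda = 1, thin = 10) {
  set.seed(seed)
  enc <- .encode_structure_data(data)
  if (K > nrow(enc$geno)) stop("K exceeds the number of individuals")
  res <- gibbs_admixture_cpp(enc$geno, enc$J, enc$ploidy, as.integer(K),
                             as.integer(burnin), as.integer(generations),
                             lambda, 1.0, 10.0, 0.25, as.integer(thin))
  rownames(res$Q) <- enc$ids
  ll <- res$loglik
  structure(list(K = K, Q = res$Q, P = res$P, loglik = ll,
                 L = mean(ll),
                 # the model-evidence estimate the delta-K method consumes:
                 # ln P(D) ~ mean(lnL) - var(lnL)/2 (harmonic approximation)
                 lnPD = mean(ll) - var(ll) / 2,
                 alpha = res$alpha, ids = enc$ids),
            class = "structure_run")
}

# Encode input for the C++ sampler: N x (L * ploidy), codes 1..J, 0 missing.
.encode_structure_data <- function(data) {
  if (inherits(data, "genotype_table")) {
    n <- length(data$ids); L <- nrow(data$loci)
    geno <- matrix(0L, n, 2 * L)
    J <- integer(L)
    for (l in seq_len(L)) {
      a <- data$calls[, l, , drop = FALSE]
      lv <- sort(unique(as.vector(a)))
      J[l] <- max(length(lv), 1L)
      for (c in 1:2) {
        code <- match(a[, 1, c], lv)
        code[is.na(code)] <- 0L
        geno[, 2 * (l - 1) + c] <- code
      }
    }
    list(geno = geno, J = J, ploidy = 2L, ids = data$ids)
  } else {
    m <- as.matrix(data)
    ids <- rownames(m)
    if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(m)))
    geno <- matrix(0L, nrow(m), ncol(m))
    geno[m == 0] <- 1L
    geno[m == 1] <- 2L
    # -1 (missing) stays 0 and is skipped by the sampler
    list(geno = geno, J = rep(2L, ncol(m)), ploidy = 1L, ids = ids)
  }
}

#' Evanno delta-K from a table of run log-likelihoods
#'
#' DeltaK(K) = mean(|L(K+1) - 2 L(K) + L(K-1)|) / sd(L(K)), computed across
#' replicate runs; endpoints are undefined.  The argmax over interior K is
#' the supported cluster number.
#'
#' @param L_table numeric matrix: rows = replicate runs (>= 3), columns =
#'   consecutive K values (named with the K each column represents, >= 3
#'   columns).
#' @return list with `delta_k` (named vector over interior K) and `K`
#'   (argmax).
#' @export
evanno_delta_k <- function(L_table) {
  L_table <- as.matrix(L_table)
  if (nrow(L_table) < 3) stop("need at least 3 runs per K")
  if (ncol(L_table) < 3) stop("need at least 3 consecutive K values")
  ks <- as.integer(colnames(L_table))
  if (any(is.na(ks))) ks <- seq_len(ncol(L_table))
  if (any(diff(ks) != 1)) stop("K values must be consecutive")
  sds <- apply(L_table, 2, sd)
  interior <- 2:(ncol(L_table) - 1)
  if (any(sds[interior] == 0))
    stop("sd(L(K)) is zero for some K (division by zero); jitter runs advised")
  dk <- vapply(interior, function(j) {
    second <- L_table[, j + 1] - 2 * L_table[, j] + L_table[, j - 1]
    mean(abs(second)) / sds[j]
  }, 0)
  names(dk) <- ks[interior]
  list(delta_k = dk, K = ks[interior][which.max(dk)])
}

#' Match cluster labels across runs
#'
#' Greedily permutes the columns of `Q` to maximise agreement with a
#' reference run's Q matrix, resolving label switching.
#'
#' @param Q admixture matrix to relabel.
#' @param Q_ref reference admixture matrix (same shape).
#' @return `Q` with columns permuted to match `Q_ref`.
#' @export
match_clusters <- function(Q, Q_ref) {
  K <- ncol(Q)
  stopifnot(ncol(Q_ref) == K)
  perm <- integer(K)
  avail <- seq_len(K)
  for (k in seq_len(K)) {
    sims <- vapply(avail, function(j) sum(Q[, j] * Q_ref[, k]), 0)
    pick <- avail[which.max(sims)]
    perm[k] <- pick
    avail <- setdiff(avail, pick)
  }
  Q[, perm, drop = FALSE]
}

#' Cluster-assignment accuracy up to label permutation
#'
#' Hard-assigns individuals to their max-Q cluster and reports the best
#' agreement with true labels over all label permutations.
#'
#' @param Q admixture matrix.
#' @param truth vector of true group labels.
#' @return Accuracy in `[0, 1]`.
#' @export
assignment_accuracy <- function(Q, truth) {
  hard <- apply(Q, 1, which.max)
  truth <- as.integer(factor(truth))
  K <- max(ncol(Q), max(truth))
  perms <- .permutations(seq_len(K))
  best <- 0
  for (i in seq_len(nrow(perms))) {
    acc <- mean(perms[i, hard] == truth)
    if (acc > best) best <- acc
  }
  best
}

.permutations <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- .permutations(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}
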