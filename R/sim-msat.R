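#' Multi-population microsatellite simulation model
#'
#' Forward-time Wright-Fisher model with migration, stepwise/infinite-alleles/
#' two-phase mutation and an optional bottleneck.  Forward simulation (rather
#' than the coalescent) keeps the model transparent at desk scale (Ne <= 500).
#'
#' @param P number of populations.
#' @param Ne diploid effective sizes (recycled to length `P`).
#' @param migration P x P row-stochastic matrix: entry (i, j) is the
#'   probability that an offspring born in population i draws its parent from
#'   population j.  Row sums must be <= 1 (the remainder stays philopatric).
#' @param mu per-locus per-generation mutation rate.
#' @param model one of `"SMM"`, `"IAM"`, `"TPM"`.
#' @param p_single for TPM: probability a mutation is a single repeat step
#'   (the remaining mutations jump `1 + Geometric(geom_p)` repeats, sign
#'   equiprobable). The classic two-phase parameterisation used by
#'   heterozygosity-excess software corresponds to `p_single = 0.9`.
#' @param geom_p geometric parameter of multi-step jump sizes.
#' @param generations number of generations to simulate.
#' @param bottleneck optional `list(start =, duration =, Ne =)` in forward
#'   time (generation indices) applied to every population.
#' @return An object of class `sim_pop_model`.
#' @export
sim_pop_model <- function(P, Ne, migration = diag(0, P), mu = 5e-4,
                          model = c("TPM", "SMM", "IAM"), p_single = 0.9,
                          geom_p = 0.5, generations = 1000L,
                          bottleneck = NULL) {
  model <- match.arg(model)
  Ne <- rep_len(as.integer(Ne), P)
  migration <- as.matrix(migration)
  if (!all(dim(migration) == c(P, P))) stop("migration must be P x P")
  diag(migration) <- 0
  if (any(migration < 0) || any(migration > 1)) stop("migration rates must lie in [0,1]")
  if (any(rowSums(migration) > 1 + 1e-12)) stop("migration row sums must be <= 1")
  if (mu < 0 || mu > 1) stop("mu must lie in [0,1]")
  if (p_single < 0 || p_single > 1) stop("p_single must lie in [0,1]")
  if (generations < 1) stop("generations must be >= 1")
  if (any(Ne < 1)) stop("Ne must be positive")
  structure(list(P = P, Ne = Ne, migration = migration, mu = mu,
                 model = model, p_single = p_single, geom_p = geom_p,
                 generations = as.integer(generations), bottleneck = bottleneck),
            class = "sim_pop_model")
}

#' Island-model migration matrix
#'
#' A fraction `m` of each population is replaced each generation by migrants
#' drawn equally from the other `d - 1` populations (off-diagonal entries
#' `m / (d - 1)`).  The Weir-Cockerham theta estimated from two demes at
#' equilibrium under this convention has the classical expectation
#' theta ~ 1 / (1 + 8 Ne m): theta references the between-deme comparison,
#' i.e. theta = 1 - T_within / T_between in coalescent-time terms.
#'
#' @param d number of populations.
#' @param m total immigration rate per population.
#' @return d x d migration matrix suitable for [sim_pop_model()].
#' @export
island_migration_matrix <- function(d, m) {
  M <- matrix(m / (d - 1), d, d)
  diag(M) <- 0
  M
}

# one mutation-size draw per mutating gene copy, in repeat units
.mut_steps <- function(k, model, p_single, geom_p) {
  if (k == 0L) return(integer(0))
  sign <- ifelse(runif(k) < 0.5, -1L, 1L)
  if (model == "SMM") return(sign)
  if (model == "TPM") {
    multi <- runif(k) >= p_single
    step <- rep(1L, k)
    step[multi] <- 1L + rgeom(sum(multi), geom_p)
    return(sign * step)
  }
  stop("internal: IAM handled separately")
}

#' Simulate multi-population microsatellite genotypes
#'
#' Runs the forward Wright-Fisher model and samples `n` diploids per
#' population.  Allele states are repeat counts (initialised uniformly on
#' 15..24 repeats so standing variation exists at generation zero) and are
#' converted to bp via each locus's motif length plus a 100 bp flank.
#'
#' @param model a [sim_pop_model()].
#' @param L number of loci.
#' @param n sample sizes per population (recycled).
#' @param seed integer seed.
#' @param motif motif lengths in bp (recycled over loci).
#' @return A [genotype_table()] with populations `pop1..popP`.
#' @export
simulate_msat <- function(model, L, n, seed, motif = 4L) {
  set.seed(seed)
  P <- model$P
  n <- rep_len(as.integer(n), P)
  motif <- rep_len(as.integer(motif), L)
  # state: per population, a (2*Ne) x L integer matrix of repeat counts
  state <- lapply(model$Ne, function(N)
    matrix(sample(15:24, 2 * N * L, replace = TRUE), 2 * N, L))
  iam_counter <- 1000L
  for (g in seq_len(model$generations)) {
    Ne_now <- model$Ne
    bn <- model$bottleneck
    if (!is.null(bn) && g >= bn$start && g < bn$start + bn$duration)
      Ne_now <- rep_len(as.integer(bn$Ne), P)
    if (any(Ne_now < 1)) stop("Ne fell to zero mid-simulation")
    new_state <- vector("list", P)
    for (p in seq_len(P)) {
      ncopies <- 2L * Ne_now[p]
      src <- sample.int(P, ncopies, replace = TRUE,
                        prob = {
                          pr <- model$migration[p, ]
                          pr[p] <- pr[p] + 1 - sum(pr)
                          pr
                        })
      out <- matrix(0L, ncopies, L)
      for (sp in unique(src)) {
        rows <- which(src == sp)
        out[rows, ] <- state[[sp]][sample.int(nrow(state[[sp]]), length(rows),
                                              replace = TRUE), , drop = FALSE]
      }
      nmut <- rbinom(1L, ncopies * L, model$mu)
      if (nmut > 0) {
        idx <- sample.int(ncopies * L, nmut)
        if (model$model == "IAM") {
          out[idx] <- iam_counter + seq_len(nmut)
          iam_counter <- iam_counter + nmut
        } else {
          out[idx] <- out[idx] + .mut_steps(nmut, model$model,
                                            model$p_single, model$geom_p)
        }
      }
      new_state[[p]] <- out
    }
    state <- new_state
  }
  # sample n diploids per population; map repeat counts to bp
  calls <- array(NA_integer_, c(sum(n), L, 2))
  popv <- rep(paste0("pop", seq_len(P)), n)
  row0 <- 0L
  for (p in seq_len(P)) {
    copies <- state[[p]]
    pick <- sample.int(nrow(copies) %/% 2L, n[p])
    for (i in seq_len(n[p])) {
      g1 <- copies[2L * pick[i] - 1L, ]
      g2 <- copies[2L * pick[i], ]
      calls[row0 + i, , 1] <- 100L + motif * .compact_state(g1)
      calls[row0 + i, , 2] <- 100L + motif * .compact_state(g2)
    }
    row0 <- row0 + n[p]
  }
  genotype_table(calls, factor(popv, levels = paste0("pop", seq_len(P))),
                 data.frame(locus = sprintf("L%02d", seq_len(L)), motif = motif))
}

# IAM states carry unique labels >= 1000; fold them into an unused part of
# the repeat ladder so bp sizes stay 3-digit-representable yet distinct.
.compact_state <- function(s) {
  big <- s >= 1000L
  if (any(big)) s[big] <- 100L + (s[big] %% 80L)
  s
}

#' Coalescent sample of microsatellite gene copies
#'
#' Draws `n_genes` allele states for one locus from a single panmictic
#' population under IAM, SMM or TPM mutation and a piecewise-constant size
#' history.  Used for mutation-drift-equilibrium reference distributions
#' (heterozygosity-excess testing) and for fast equilibrium/decline scenarios.
#'
#' @param n_genes number of gene copies.
#' @param mu per-generation mutation rate.
#' @param model `"IAM"`, `"SMM"` or `"TPM"`.
#' @param history data.frame with columns `t` (generations ago, ascending,
#'   first row 0) and `N` (diploid size in force from that time backwards).
#' @param p_single,geom_p TPM parameters (see [sim_pop_model()]).
#' @return Integer vector of allele states (repeat offsets; IAM labels are
#'   unique integers >= 100000).
#' @export
coalescent_msat <- function(n_genes, mu, model = c("TPM", "SMM", "IAM"),
                            history = data.frame(t = 0, N = 500),
                            p_single = 0.9, geom_p = 0.5) {
  model <- match.arg(model)
  if (history$t[1] != 0) stop("history must start at time 0")
  mcode <- match(model, c("IAM", "SMM", "TPM")) - 1L
  coal_msat_cpp(as.integer(n_genes), mu, mcode, p_single, geom_p,
                as.numeric(history$t), as.numeric(history$N))
}

#' Build a genotype table from coalescent locus samples
#'
#' Pairs gene copies at random into diploids, one population.
#'
#' @param L number of loci.
#' @param n diploid sample size.
#' @param mu,model,history,p_single,geom_p passed to [coalescent_msat()].
#' @param motif motif length (bp).
#' @param pop population label.
#' @return A [genotype_table()].
#' @export
coalescent_msat_table <- function(L, n, mu, model = "TPM",
                                  history = data.frame(t = 0, N = 500),
                                  p_single = 0.9, geom_p = 0.5,
                                  motif = 4L, pop = "pop1") {
  calls <- array(NA_integer_, c(n, L, 2))
  motif <- rep_len(as.integer(motif), L)
  for (l in seq_len(L)) {
    s <- coalescent_msat(2L * n, mu, model, history, p_single, geom_p)
    step <- s < 100000L
    if (any(step)) s[step] <- s[step] - min(s[step]) + 15L  # anchor the ladder
    s <- 100L + motif[l] * .compact_state(s)
    calls[, l, 1] <- s[seq(1, 2 * n, 2)]
    calls[, l, 2] <- s[seq(2, 2 * n, 2)]
  }
  genotype_table(calls, factor(rep(pop, n)),
                 data.frame(locus = sprintf("L%02d", seq_len(L)),
                            motif = rep_len(as.integer(motif), L)))
}
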