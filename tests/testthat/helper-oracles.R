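# Independent brute-force oracles.  These re-derive each statistic by a
# different route from the package implementation (mean-squares ANOVA vs
# closed-form variance components, pairwise-distance identities, recursive
# pathway enumeration, exact enumeration) so agreement is informative.

# Weir-Cockerham theta via the nested ANOVA mean squares on allele
# indicator variables (populations / individuals / gene copies).
oracle_theta_anova <- function(table, pops = levels(table$pop)) {
  sel <- table$pop %in% pops
  popf <- droplevels(factor(as.character(table$pop[sel]), levels = pops))
  num <- den <- 0
  for (l in table$loci$locus) {
    a1 <- table$calls[sel, l, 1]; a2 <- table$calls[sel, l, 2]
    ok <- !is.na(a1)
    x1 <- a1[ok]; x2 <- a2[ok]; pf <- droplevels(popf[ok])
    r <- nlevels(pf)
    if (r < 2) next
    n_i <- as.vector(table(pf))
    N <- length(x1)
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (u in unique(c(x1, x2))) {
      y1 <- as.numeric(x1 == u); y2 <- as.numeric(x2 == u)
      ybar_ind <- (y1 + y2) / 2
      ybar_pop <- tapply(c(y1, y2), rep(pf, 2), mean)
      ybar <- mean(c(y1, y2))
      SSG <- sum((y1 - y2)^2) / 2
      SSI <- 2 * sum((ybar_ind - ybar_pop[pf])^2)
      SSP <- 2 * sum(n_i * (ybar_pop - ybar)^2)
      MSG <- SSG / N
      MSI <- SSI / (N - r)
      MSP <- SSP / (r - 1)
      sG <- MSG
      sI <- (MSI - MSG) / 2
      sP <- (MSP - MSI) / (2 * nc)
      num <- num + sP
      den <- den + sP + sI + sG
    }
  }
  num / den
}

# R_ST via pairwise-squared-difference identities (sum of squares from
# distances rather than centred means).
oracle_rst_dist <- function(table, pops = levels(table$pop)) {
  sel <- table$pop %in% pops
  popf <- droplevels(factor(as.character(table$pop[sel]), levels = pops))
  num <- den <- 0
  for (li in seq_len(nrow(table$loci))) {
    l <- table$loci$locus[li]; mot <- table$loci$motif[li]
    a1 <- table$calls[sel, l, 1] / mot; a2 <- table$calls[sel, l, 2] / mot
    ok <- !is.na(a1)
    x1 <- a1[ok]; x2 <- a2[ok]; pf <- droplevels(popf[ok])
    r <- nlevels(pf)
    if (r < 2) next
    n_i <- as.vector(table(pf))
    N <- length(x1)
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    SSG <- sum((x1 - x2)^2) / 2
    xm <- (x1 + x2) / 2
    SSI <- 0
    for (p in levels(pf)) {
      v <- xm[pf == p]
      if (length(v) > 1) {
        s <- 0
        for (i in seq_along(v)[-length(v)]) for (j in (i + 1):length(v))
          s <- s + (v[i] - v[j])^2
        SSI <- SSI + 2 * s / length(v)
      }
    }
    pm <- tapply(c(x1, x2), rep(pf, 2), mean)
    SSP <- 0
    for (i in seq_len(r - 1)) for (j in (i + 1):r)
      SSP <- SSP + 2 * n_i[i] * n_i[j] * (pm[i] - pm[j])^2 / N
    MSG <- SSG / N; MSI <- SSI / (N - r); MSP <- SSP / (r - 1)
    sG <- MSG; sI <- (MSI - MSG) / 2; sP <- (MSP - MSI) / (2 * nc)
    num <- num + sP
    den <- den + sP + sI + sG
  }
  unname(num / den)
}

# two-population phi_ST by direct double loops over gene copies.
# The number of differing sites IS the squared Euclidean distance in the
# per-site 0/1 embedding, so it enters the sums of squares unsquared.
oracle_phi_st <- function(seqs_x, seqs_y) {
  dd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  all <- c(seqs_x, seqs_y)
  N <- length(all); P <- 2
  SS_t <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) SS_t <- SS_t + dd(all[i], all[j])
  SS_t <- SS_t / N
  SS_w <- ssd_grp2(seqs_x) + ssd_grp2(seqs_y)
  sw <- SS_w / (N - P)
  MSa <- (SS_t - SS_w) / (P - 1)
  nprime <- (N - (length(seqs_x)^2 + length(seqs_y)^2) / N) / (P - 1)
  sa <- (MSa - sw) / nprime
  if (sa + sw <= 0) return(0)
  sa / (sa + sw)
}

ssd_grp2 <- function(v) {
  dd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(v) < 2) return(0)
  s <- 0
  for (i in seq_along(v)[-length(v)]) for (j in (i + 1):length(v))
    s <- s + dd(v[i], v[j])
  s / length(v)
}

# nucleotide diversity by expanding copies and averaging over all copy pairs
# (algebraically equals the frequency-weighted corrected form)
oracle_pi <- function(sequences, counts) {
  copies <- rep(sequences, counts)
  n <- length(copies)
  if (n < 2) return(0)
  L <- nchar(copies[1])
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + sum(strsplit(copies[i], "")[[1]] != strsplit(copies[j], "")[[1]]) / L
  s / choose(n, 2)
}

# Nei-Gojobori per-codon-pair counts by independent recursive enumeration
# (uses the genetic code directly, no shared cache with the implementation)
oracle_ng_pair <- function(c1, c2) {
  gc_tab <- Biostrings::GENETIC_CODE
  if (c1 == c2) return(c(sd = 0, nd = 0))
  recurse <- function(cur, target) {
    dpos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(dpos)) return(list(c(sd = 0, nd = 0, w = 1)))
    out <- list()
    for (p in dpos) {
      ch <- strsplit(cur, "")[[1]]
      ch[p] <- strsplit(target, "")[[1]][p]
      nxt <- paste(ch, collapse = "")
      step_syn <- gc_tab[[nxt]] == gc_tab[[cur]]
      blocked <- gc_tab[[nxt]] == "*"
      for (sub in recurse(nxt, target)) {
        out[[length(out) + 1L]] <- c(
          sd = unname(sub["sd"]) + as.numeric(step_syn && !blocked),
          nd = unname(sub["nd"]) + as.numeric(!step_syn && !blocked),
          w = unname(sub["w"]) * ifelse(blocked, NA, 1))
      }
    }
    out
  }
  paths <- recurse(c1, c2)
  m <- do.call(rbind, paths)
  ok <- !is.na(m[, "w"])
  if (!any(ok)) {
    # all pathways pass a stop codon: fall back to counting every step
    # (mirror of the implementation's documented fallback)
    m2 <- oracle_ng_pair_all(c1, c2)
    return(m2)
  }
  c(sd = mean(m[ok, "sd"]), nd = mean(m[ok, "nd"]))
}

oracle_ng_pair_all <- function(c1, c2) {
  gc_tab <- Biostrings::GENETIC_CODE
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (rest in perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  dpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  res <- NULL
  for (ord in perms(dpos)) {
    cur <- strsplit(c1, "")[[1]]; sd <- 0; nd <- 0
    for (p in ord) {
      prev <- paste(cur, collapse = "")
      cur[p] <- strsplit(c2, "")[[1]][p]
      nxt <- paste(cur, collapse = "")
      if (gc_tab[[nxt]] == gc_tab[[prev]]) sd <- sd + 1 else nd <- nd + 1
    }
    res <- rbind(res, c(sd, nd))
  }
  c(sd = mean(res[, 1]), nd = mean(res[, 2]))
}

# exact HWE p-value for two alleles by complete enumeration over
# heterozygote counts with fixed allele counts
oracle_hwe_exact_2allele <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(hets, function(h) {
    aa1 <- (nA - h) / 2
    aa2 <- n - h - aa1
    if (aa1 < 0 || aa2 < 0) return(-Inf)
    lfactorial(n) - lfactorial(aa1) - lfactorial(h) - lfactorial(aa2) +
      h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  }, 0)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- match(nAa, hets)
  sum(p[p <= p[obs] + 1e-12])
}

# random small genotype table generator for oracle-equivalence sweeps
random_table <- function(seed, P = NULL, L = NULL, n = NULL, miss = 0.05) {
  set.seed(seed)
  if (is.null(P)) P <- sample(2:4, 1)
  if (is.null(L)) L <- sample(2:4, 1)
  if (is.null(n)) n <- sample(5:12, 1)
  motif <- sample(c(2L, 4L), L, replace = TRUE)
  N <- P * n
  calls <- array(NA_integer_, c(N, L, 2))
  for (l in seq_len(L)) {
    sizes <- 100L + motif[l] * sort(sample(0:8, sample(2:5, 1)))
    for (p in seq_len(P)) {
      pr <- rgamma(length(sizes), 1); pr <- pr / sum(pr)
      rows <- ((p - 1) * n + 1):(p * n)
      calls[rows, l, 1] <- sample(sizes, n, replace = TRUE, prob = pr)
      calls[rows, l, 2] <- sample(sizes, n, replace = TRUE, prob = pr)
    }
  }
  if (miss > 0) {
    drop <- which(runif(N * L) < miss)
    for (d in drop) {
      i <- ((d - 1) %% N) + 1; l <- ((d - 1) %/% N) + 1
      calls[i, l, ] <- NA_integer_
    }
  }
  genotype_table(calls, rep(paste0("pop", seq_len(P)), each = n),
                 data.frame(locus = sprintf("L%d", seq_len(L)), motif = motif))
}

# random codon pair without stops
random_codon_pair <- function(seed) {
  set.seed(seed)
  gc_tab <- Biostrings::GENETIC_CODE
  nonstop <- names(gc_tab)[gc_tab != "*"]
  sample(nonstop, 2, replace = TRUE)
}
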