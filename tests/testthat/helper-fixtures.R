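# Small builders shared across test files.

# deterministic toy genotype table: 2 pops x 2 loci, one missing call
toy_table <- function() {
  calls <- array(NA_integer_, c(4, 2, 2))
  calls[1, , ] <- matrix(c(100L, 102L, 150L, 150L), 2, 2, byrow = TRUE)
  calls[2, , ] <- matrix(c(100L, 100L, 150L, 154L), 2, 2, byrow = TRUE)
  calls[3, , ] <- matrix(c(104L, 102L, 154L, 154L), 2, 2, byrow = TRUE)
  calls[4, 1, ] <- c(102L, 102L)           # locus 2 missing for ind4
  genotype_table(calls, c("P1", "P1", "P2", "P2"),
                 data.frame(locus = c("LA", "LB"), motif = c(2L, 2L)),
                 ids = paste0("i", 1:4))
}

# fixed-difference two-population table (theta = R_ST = 1)
fixed_table <- function(n = 4, s1 = 100L, s2 = 120L, motif = 4L) {
  calls <- array(NA_integer_, c(2 * n, 1, 2))
  calls[1:n, 1, ] <- s1
  calls[(n + 1):(2 * n), 1, ] <- s2
  genotype_table(calls, rep(c("A", "B"), each = n),
                 data.frame(locus = "L1", motif = motif))
}

# one panmictic sample split under two labels
split_panmixia <- function(seed = 1, n = 100, L = 6) {
  m <- sim_pop_model(P = 1, Ne = 200, generations = 150, mu = 1e-3,
                     model = "SMM")
  tab <- simulate_msat(m, L = L, n = 2 * n, seed = seed)
  tab$pop <- factor(rep(c("X", "Y"), n), levels = c("X", "Y"))
  tab
}

# random DAB-like allele set: distinct PBR residues drawn from an amino-acid
# pool, constant elsewhere
random_dab_alleles <- function(n_alleles, pool, seed, n_codons = 73) {
  set.seed(seed)
  gc_tab <- Biostrings::GENETIC_CODE
  aa2codon <- function(aas)
    vapply(aas, function(a) sample(names(gc_tab)[gc_tab == a], 1L), "")
  pbr_idx <- match(default_pbr_positions(), seq_len(n_codons) + 8L)
  seqs <- vapply(seq_len(n_alleles), function(i) {
    aas <- rep("L", n_codons)
    aas[pbr_idx] <- sample(pool, length(pbr_idx), replace = TRUE)
    paste(aa2codon(aas), collapse = "")
  }, "")
  setNames(seqs, paste0("al", seq_len(n_alleles)))
}

# equal-length random nucleotide alleles differing by point mutations
random_nt_alleles <- function(n_alleles, len = 212, min_diff = 4, seed = 1) {
  set.seed(seed)
  base <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                collapse = "")
  out <- c(base)
  while (length(out) < n_alleles) {
    v <- strsplit(base, "")[[1]]
    pos <- sample(len, min_diff + sample(0:6, 1))
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    cand <- paste(v, collapse = "")
    if (!cand %in% out) out <- c(out, cand)
  }
  setNames(out, paste0("A", seq_len(n_alleles)))
}

# genotypes where every allele is carried by >= 2 individuals (so the truth
# is recoverable under the two-rule validation protocol)
balanced_genotypes <- function(allele_names, n_ind, pop = "P1", seed = 1) {
  set.seed(seed)
  k <- length(allele_names)
  repeat {
    a1 <- sample(allele_names, n_ind, replace = TRUE)
    a2 <- sample(allele_names, n_ind, replace = TRUE)
    if (all(table(factor(c(a1, a2), levels = allele_names)) > 0) &&
        all(sapply(allele_names, function(a)
          sum(a1 == a | a2 == a) >= 2)))
      break
  }
  data.frame(individual = sprintf("%s_i%02d", pop, seq_len(n_ind)), pop = pop,
             allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
}
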