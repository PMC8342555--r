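test_that("haplotype diversity follows the unbiased formula", {
  expect_equal(haplotype_diversity(c(a = 7)), 0)            # monomorphic
  expect_equal(haplotype_diversity(c(a = 1, b = 1)), 1)     # n = 2
  expect_equal(haplotype_diversity(c(a = 3, b = 1)),
               (4 / 3) * (1 - (9 + 1) / 16))                # = 0.5
})

test_that("nucleotide diversity matches the brute-force pair loop", {
  s <- c(a = strrep("A", 100), b = paste0(strrep("A", 99), "T"))
  expect_equal(unname(nucleotide_diversity(s, c(1, 1))), 0.01)  # single pair
  expect_equal(nucleotide_diversity(s, c(1, 1)), oracle_pi(s, c(1, 1)))
  expect_equal(nucleotide_diversity(c(a = "ACGT"), 5), 0)   # identical copies
  # weighted case equals the expanded-copy loop
  set.seed(131)
  for (i in 1:5) {
    seqs <- random_nt_alleles(3, len = 40, seed = 130 + i)
    cnt <- sample(1:4, 3, replace = TRUE)
    expect_equal(nucleotide_diversity(seqs, cnt), oracle_pi(seqs, cnt))
  }
  # scaling every copy count 10x moves pi only through the n/(n-1) term
  seqs <- random_nt_alleles(3, len = 40, seed = 140)
  p1 <- nucleotide_diversity(seqs, c(2, 3, 1))
  p10 <- nucleotide_diversity(seqs, c(20, 30, 10))
  expect_lt(abs(p1 * (60 / 59) / (6 / 5) - p10) / p10, 1e-9)
})

test_that("MHC population summary reports A_M, A_d and pi per population", {
  seqs <- random_nt_alleles(3, len = 60, seed = 141)
  g <- data.frame(individual = paste0("i", 1:5),
                  pop = c("DC", "DC", "DC", "MH", "MH"),
                  allele1 = c("A1", "A1", "A2", "A3", "A3"),
                  allele2 = c("A2", "A1", "A2", NA, "A3"))
  cat1 <- allele_catalog("DAB3", seqs, g)
  s <- mhc_pop_summary(cat1)
  # MH fixed for one allele: the Table-1-style "1 / 0 (0)" pattern
  mh <- s[s$pop == "MH", ]
  expect_equal(mh$A_M, 1L)
  expect_equal(mh$A_d, 0)
  expect_equal(mh$pi, 0)
  dc <- s[s$pop == "DC", ]
  expect_equal(dc$A_M, 2L)
  cnt <- c(3, 3)  # A1 and A2 copies in DC
  expect_equal(dc$A_d, haplotype_diversity(cnt))
  # haploid convention counts the single-allele individual once
  s2 <- mhc_pop_summary(cat1, single_allele = "haploid")
  expect_equal(s2[s2$pop == "MH", "A_d"], 0)
})

test_that("phi_ST has the expected fixed points and matches the oracle", {
  seqs <- c(A1 = strrep("A", 50),
            A2 = paste0(strrep("A", 40), strrep("T", 10)),
            A3 = paste0(strrep("C", 10), strrep("A", 40)))
  # identical composition in both populations (large enough that the
  # finite-sample negative bias of the variance-component ratio is small)
  g_same <- data.frame(individual = paste0("i", 1:40),
                       pop = rep(c("X", "Y"), each = 20),
                       allele1 = rep(rep(c("A1", "A1", "A2", "A2"), 5), 2),
                       allele2 = rep(rep(c("A2", "A1", "A2", "A1"), 5), 2))
  cat_same <- allele_catalog("DAB1", seqs, g_same)
  r_same <- phi_st(cat_same, permutations = 200, seed = 151)
  expect_lt(abs(r_same$values["X", "Y"]), 0.05)
  expect_gt(r_same$pvalues["X", "Y"], 0.05)
  # no shared alleles, divergent sequences
  g_div <- data.frame(individual = paste0("i", 1:10),
                      pop = rep(c("X", "Y"), each = 5),
                      allele1 = c(rep("A1", 5), rep("A2", 5)),
                      allele2 = c(rep("A1", 5), rep("A2", 5)))
  cat_div <- allele_catalog("DAB1", seqs[1:2], g_div)
  r_div <- phi_st(cat_div, permutations = 999, seed = 152)
  expect_gt(r_div$values["X", "Y"], 0.9)
  expect_lte(r_div$pvalues["X", "Y"], 0.001 + 1e-9)  # floor 1/(B+1)
  # small mixed case equals the independently coded AMOVA oracle
  g_mix <- data.frame(individual = paste0("i", 1:6),
                      pop = rep(c("X", "Y"), each = 3),
                      allele1 = c("A1", "A1", "A2", "A2", "A3", "A3"),
                      allele2 = c("A1", "A2", "A2", "A3", "A3", "A3"))
  cat_mix <- allele_catalog("DAB1", seqs, g_mix)
  r_mix <- phi_st(cat_mix, permutations = 50, seed = 153)
  copies_x <- seqs[consgen:::.mhc_copies(g_mix[g_mix$pop == "X", ])]
  copies_y <- seqs[consgen:::.mhc_copies(g_mix[g_mix$pop == "Y", ])]
  expect_equal(unname(r_mix$values["X", "Y"]),
               oracle_phi_st(unname(copies_x), unname(copies_y)))
  # invariance to population relabeling
  g_rel <- g_mix
  g_rel$pop <- c("Y", "Y", "Y", "X", "X", "X")
  r_rel <- phi_st(allele_catalog("DAB1", seqs, g_rel),
                  permutations = 50, seed = 154)
  expect_equal(unname(r_rel$values["X", "Y"]),
               unname(r_mix$values["X", "Y"]))
})

test_that("binary Structure encoding covers carriers, absences and missing", {
  seqs <- random_nt_alleles(3, len = 30, seed = 161)
  g <- data.frame(individual = c("c1", "c2", "fail"),
                  pop = "P1",
                  allele1 = c("A1", "A2", NA),
                  allele2 = c(NA, "A3", NA))
  cat1 <- allele_catalog("DAB1", seqs, g)
  M <- encode_for_structure(cat1)
  expect_equal(unname(M["c1", ]), c(1L, 0L, 0L))      # carries A1 only
  expect_equal(unname(M["c2", ]), c(0L, 1L, 1L))
  expect_equal(unname(M["fail", ]), c(-1L, -1L, -1L)) # failed amplification
  # supertype mode collapses columns by assignment
  asg <- structure(list(assignment = setNames(c(1L, 1L, 2L), names(seqs)),
                        K = 2L), class = "supertype_assignment")
  Ms <- encode_for_structure(cat1, mode = "supertype", assignment = asg)
  expect_equal(unname(Ms["c2", ]), c(1L, 1L))
  expect_equal(unname(Ms["c1", ]), c(1L, 0L))
  # encodings feed the Structure writer directly
  f <- withr::local_tempfile()
  write_structure(M, f, pop = g$pop)
  expect_equal(nrow(read_structure(f)$data), 3L)
})
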