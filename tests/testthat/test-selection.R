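test_that("codon alignment constructor enforces frame and stop rules", {
  expect_error(codon_alignment(c(a = "ATGC", b = "ATGC")), "divisible by 3")
  expect_error(codon_alignment(c(a = "ATGTAA", b = "ATGTAA"), offset = 1),
               "stop codon")
  expect_error(codon_alignment(c(a = "ATG", b = "ATGATG"), offset = 1),
               "equal length")
  aln <- codon_alignment(c(a = "ATGTTT", b = "ATGTTC"), offset = 9,
                         pbr_mask = 10)
  expect_equal(aln$codon_numbers, c(9L, 10L))
  expect_error(codon_alignment(c(a = "ATGTTT"), offset = 9, pbr_mask = 99),
               "outside codon range")
})

test_that("hand-counted codon pairs give the textbook Nei-Gojobori values", {
  # identical sequences
  same <- codon_alignment(c(a = "ATGTTT", b = "ATGTTT"), offset = 1)
  r0 <- nei_gojobori(same, bootstrap = 50, seed = 1)
  expect_equal(r0$dN, 0)
  expect_equal(r0$dS, 0)
  expect_gte(r0$p, 0.5)
  # TTT <-> TTC: synonymous change at the third position; TTT carries 1/3
  # synonymous site there, so pS = 1 / mean(S) = 3 and dN = 0
  phe <- codon_alignment(c(a = "TTT", b = "TTC"), offset = 1)
  r1 <- nei_gojobori(phe, bootstrap = 50, seed = 2, correction = "none")
  expect_equal(r1$dN, 0)
  expect_equal(r1$dS, 3)
  # ATG <-> ATA: Met -> Ile, nonsynonymous; S = (0 + 2/3)/2 = 1/3,
  # so pN = 1/(8/3) and pS = 0
  met <- codon_alignment(c(a = "ATG", b = "ATA"), offset = 1)
  r2 <- nei_gojobori(met, bootstrap = 50, seed = 3, correction = "none")
  expect_equal(r2$dS, 0)
  expect_equal(r2$dN, 1 / (8 / 3))
})

test_that("Jukes-Cantor correction evaluates and errors on its domain", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.1), -0.75 * log(1 - 0.4 / 3))
  expect_equal(jukes_cantor(0.1), 0.10732, tolerance = 1e-4)
  expect_error(jukes_cantor(0.75), "undefined")
})

test_that("PBR partitioning matches the default beta-1 mask", {
  pbr <- default_pbr_positions()
  expect_length(pbr, 17L)
  aln <- codon_alignment(setNames(rep(strrep("ATG", 73), 2), c("a", "b")),
                         offset = 9, pbr_mask = pbr)
  parts <- partition_alignment(aln)
  expect_length(parts$pbr$codon_numbers, 17L)    # DAB1: codons 9-81
  expect_length(parts$non_pbr$codon_numbers, 56L)
  # mask covering everything leaves an empty complement
  all_mask <- partition_alignment(aln, aln$codon_numbers)
  expect_null(all_mask$non_pbr)
  expect_error(partition_alignment(aln, 999), "outside")
})

test_that("pairwise counts agree with the brute-force pathway oracle", {
  # scaled sample here; the full 100-pair sweep runs in the acceptance suite
  for (s in 1:25) {
    cp <- random_codon_pair(s)
    impl <- consgen:::.codon_pair_diffs(cp[1], cp[2])
    orac <- oracle_ng_pair(cp[1], cp[2])
    expect_equal(unname(impl), unname(orac), tolerance = 1e-12)
  }
})

test_that("dN/dS is invariant to sequence order and duplication", {
  set.seed(91)
  tr <- ape::rcoal(6)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * 0.3
  aln <- simulate_codon_alignment(tr, rep(0.8, 30), seed = 92, offset = 1L)
  r <- nei_gojobori(aln, bootstrap = 100, seed = 93)
  perm <- sample(seq_along(aln$sequences))
  aln2 <- codon_alignment(aln$sequences[perm], offset = 1)
  r2 <- nei_gojobori(aln2, bootstrap = 100, seed = 94)
  expect_equal(r2$dN, r$dN)
  expect_equal(r2$dS, r$dS)
  # duplicating one sequence adds only zero-distance pairs with itself and
  # reweights means identically for the duplicated pair set
  aln3 <- codon_alignment(c(aln$sequences,
                            dup = unname(aln$sequences[1])), offset = 1)
  r3 <- nei_gojobori(aln3, bootstrap = 100, seed = 95)
  expect_lt(abs(r3$omega - r$omega) / max(r$omega, 1e-6), 0.35)
})

test_that("bootstrap standard errors stabilise at the default depth", {
  set.seed(96)
  tr <- ape::rcoal(8)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * 0.3
  aln <- simulate_codon_alignment(tr, rep(1, 50), seed = 97, offset = 1L)
  rA <- nei_gojobori(aln, bootstrap = 2000, seed = 98)
  rB <- nei_gojobori(aln, bootstrap = 2000, seed = 99)
  expect_lt(abs(rA$SE_dN - rB$SE_dN) / rA$SE_dN, 0.1)
  expect_lt(abs(rA$SE_dS - rB$SE_dS) / rA$SE_dS, 0.1)
})

test_that("PHYLIP export is parseable by an independent reader", {
  aln <- codon_alignment(c(s1 = "ATGTTTAAA", s2 = "ATGTTCAAA"), offset = 1)
  f <- withr::local_tempfile(fileext = ".phy")
  write_phylip(aln, f)
  back <- ape::read.dna(f, format = "interleaved", as.character = TRUE)
  expect_equal(toupper(paste(back[1, ], collapse = "")), "ATGTTTAAA")
})
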