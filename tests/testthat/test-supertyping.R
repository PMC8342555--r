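test_that("descriptor rows are exact z-scale lookups", {
  z <- z_scales()
  expect_equal(dim(z), c(20L, 5L))
  # single-PBR toy: Ala (GCT) vs Trp (TGG) at codon 9, Leu elsewhere
  seqs <- c(alaA = paste0("GCT", strrep("CTG", 72)),
            trpA = paste0("TGG", strrep("CTG", 72)))
  M <- build_descriptor_matrix(seqs, pbr_positions = 9)
  expect_equal(ncol(M), 5L)   # 5 descriptors x 1 PBR
  expect_equal(unname(M["alaA", ]), unname(unlist(z["A", ])))
  expect_equal(unname(M["trpA", ]), unname(unlist(z["W", ])))
  # synonymous PBR codons give identical rows
  seqs2 <- c(x = paste0("GCT", strrep("CTG", 72)),
             y = paste0("GCA", strrep("TTG", 72)))  # Ala again, Leu again
  M2 <- build_descriptor_matrix(seqs2, pbr_positions = 9)
  expect_equal(unname(M2["x", ]), unname(M2["y", ]))
  # in-frame stop is an error
  bad <- c(z = paste0("TAA", strrep("CTG", 72)))
  expect_error(build_descriptor_matrix(bad, pbr_positions = 9), "stop")
})

test_that("majority-rule K selection finds planted cluster counts", {
  basic <- c("K", "R", "H")
  hydro <- c("F", "W", "I", "L")
  acidic <- c("D", "E", "N", "Q")
  two <- build_descriptor_matrix(
    c(random_dab_alleles(6, basic, seed = 101),
      setNames(random_dab_alleles(6, hydro, seed = 102),
               paste0("bl", 1:6))))
  ck2 <- choose_k(two, seed = 103)
  expect_equal(ck2$K, 2L)
  # all-identical rows are degenerate
  same <- build_descriptor_matrix(
    setNames(rep(paste0("GCT", strrep("CTG", 72)), 3), paste0("s", 1:3)))
  expect_error(choose_k(same, seed = 1), "identical")
  # three planted blobs, several seeds (scaled from the 20-seed design)
  hits <- vapply(1:6, function(s) {
    M3 <- build_descriptor_matrix(
      c(random_dab_alleles(6, basic, seed = 200 + s),
        setNames(random_dab_alleles(6, hydro, seed = 300 + s),
                 paste0("b", 1:6)),
        setNames(random_dab_alleles(6, acidic, seed = 400 + s),
                 paste0("c", 1:6))))
    choose_k(M3, seed = s)$K == 3L
  }, TRUE)
  expect_gte(mean(hits), 5 / 6)
  # determinism under a fixed seed
  expect_identical(choose_k(two, seed = 103)$votes, ck2$votes)
})

test_that("DAPC assignment recovers planted groups and co-assigns duplicates", {
  M <- build_descriptor_matrix(
    c(random_dab_alleles(6, c("K", "R", "H"), seed = 111),
      setNames(random_dab_alleles(6, c("F", "W", "I"), seed = 112),
               paste0("b", 1:6))))
  asg <- dapc_assign(M, 2, seed = 113)
  truth <- rep(1:2, each = 6)
  acc <- max(mean(asg$assignment == truth), mean(asg$assignment == 3 - truth))
  expect_equal(acc, 1)
  # K = 1: single label, no discriminants
  asg1 <- dapc_assign(M, 1)
  expect_true(all(asg1$assignment == 1L))
  expect_null(asg1$coordinates)
  # duplicated rows always land in the same supertype
  Mdup <- rbind(M, M[1, , drop = FALSE])
  rownames(Mdup)[nrow(Mdup)] <- "dup"
  asgd <- dapc_assign(Mdup, 2, seed = 114)
  expect_equal(unname(asgd$assignment["dup"]),
               unname(asgd$assignment[rownames(M)[1]]))
  # label-permutation invariance under allele reordering
  perm <- sample(nrow(M))
  asgp <- dapc_assign(M[perm, ], 2, seed = 115)
  agree <- mean(asgp$assignment[rownames(M)] == asg$assignment)
  expect_true(agree %in% c(0, 1))
})

test_that("the FASTA-to-supertypes pipeline runs end to end", {
  seqs <- c(random_dab_alleles(5, c("K", "R", "H"), seed = 131),
            setNames(random_dab_alleles(5, c("F", "W", "I"), seed = 132),
                     paste0("b", 1:5)))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, fa)
  res <- supertype_pipeline(fa, seed = 133)
  expect_equal(res$K, 2L)
  expect_length(res$assignment$assignment, 10L)
  expect_equal(ncol(res$matrix), 5L * 17L)
})

test_that("supertype frequencies aggregate catalog frequencies", {
  seqs <- random_dab_alleles(4, c("K", "R", "F", "W"), seed = 121)
  g <- data.frame(individual = paste0("i", 1:4),
                  pop = c("P1", "P1", "P2", "P2"),
                  allele1 = c("al1", "al1", "al3", "al3"),
                  allele2 = c("al2", "al1", "al3", "al4"))
  cat1 <- allele_catalog("DAB1", seqs, g)
  asg <- structure(list(assignment = setNames(c(1L, 1L, 2L, 2L), names(seqs)),
                        K = 2L), class = "supertype_assignment")
  f <- supertype_frequencies(asg, cat1)
  expect_equal(rowSums(f), c(P1 = 1, P2 = 1))
  expect_equal(f["P2", "ST2"], 1)   # population fixed for one supertype
  expect_equal(f["P1", "ST1"], 1)
})
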