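test_that("quality filter applies the Q30 / N / length-window rules", {
  reads <- data.frame(
    id = c("good", "withN", "short6", "short5", "lowq"),
    seq = c(strrep("A", 100), paste0(strrep("A", 50), "N", strrep("A", 49)),
            strrep("A", 94), strrep("A", 95), strrep("A", 100)),
    qual = c(strrep("I", 100), strrep("I", 100), strrep("I", 94),
             strrep("I", 95), strrep("#", 100)))  # '#' = Phred 2
  out <- quality_filter(reads, expected_len = 100)
  expect_setequal(out$id, c("good", "short5"))
  acc <- attr(out, "accounting")
  expect_equal(acc$input, 5)
  expect_equal(acc$passed, 2)
  # strict per-base mode drops a read with a single low-quality base
  reads2 <- data.frame(id = "mixed", seq = strrep("A", 10),
                       qual = paste0(strrep("I", 9), "#"))
  expect_equal(nrow(quality_filter(reads2, 10, quality_mode = "min")), 0)
  expect_equal(nrow(quality_filter(reads2, 10, quality_mode = "mean")), 1)
})

test_that("draft mapping assigns by best gapless identity", {
  set.seed(81)
  drafts <- c(DAB1_d1 = paste(sample(c("A", "C", "G", "T"), 120, TRUE),
                              collapse = ""),
              DAB3_d1 = paste(sample(c("A", "C", "G", "T"), 120, TRUE),
                              collapse = ""))
  one_sub <- drafts[["DAB1_d1"]]
  substr(one_sub, 60, 60) <- setdiff(c("A", "C", "G", "T"),
                                     substr(one_sub, 60, 60))[1]
  reads <- data.frame(
    id = c("exact", "onesub", "random"),
    seq = c(drafts[["DAB1_d1"]], one_sub,
            paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")))
  out <- map_to_draft(reads, drafts)
  expect_equal(out$locus[out$id == "exact"], "DAB1")
  expect_equal(out$locus[out$id == "onesub"], "DAB1")
  expect_false("random" %in% out$id)   # identity ~ 0.25 << 0.85
})

test_that("demultiplexing requires exact indices and near-exact primers", {
  al <- random_nt_alleles(2, len = 150, seed = 82)
  g <- data.frame(individual = c("i1", "i2"), pop = "P1",
                  allele1 = c("A1", "A2"), allele2 = c("A2", "A2"))
  mod <- amplicon_sim_model(al, g, depth = 30, error_rate = 0,
                            chimera_rate = 0)
  rs <- simulate_amplicon_reads(mod, seed = 83)
  it <- data.frame(individual = c("i1", "i2"),
                   index_f = c("AAAACCCC", "GGGGTTTT"),
                   index_r = c("ACACACAC", "GTGTGTGT"), pop = "P1")
  pf <- "CATGGATACTACTRKTCTCGGTGG"   # degenerate bases R and K
  pr <- "AGCTGCCTGWYWKAKTTCAGCA"
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_amplicon_fastq(rs, it, pf, pr, fq)
  reads <- read_fastq(fq)
  dm <- demultiplex_and_trim(reads, it, pf, pr)
  expect_setequal(names(dm), c("i1", "i2"))
  expect_setequal(dm$i1$variants$seq, unname(al))
  expect_equal(dm$i2$variants$seq, unname(al["A2"]))
  expect_equal(sum(vapply(dm, function(r) r$total, 0L)), nrow(reads))

  # a single index mismatch voids the read
  reads_bad <- reads
  substr(reads_bad$seq[1], 1, 1) <- if (substr(reads_bad$seq[1], 1, 1) == "A")
    "C" else "A"
  dm2 <- demultiplex_and_trim(reads_bad, it, pf, pr)
  expect_equal(attr(dm2, "accounting")$index_matched,
               attr(dm, "accounting")$index_matched - 1L)

  # IUPAC semantics: R in the primer matches A or G but not C
  expect_equal(consgen:::iupac_mismatches("CATA", "CATR"), 0)
  expect_equal(consgen:::iupac_mismatches("CATG", "CATR"), 0)
  expect_equal(consgen:::iupac_mismatches("CATC", "CATR"), 1)
})

test_that("two-rule validation accepts and rejects as specified", {
  seqs <- random_nt_alleles(4, len = 80, seed = 84)
  mk <- function(ind, v, n) amplicon_read_set(ind, "DAB1",
    data.frame(seq = unname(seqs[v]), count = n), pop = "P1")
  # variant with 1200 reads in two individuals -> allele (read rule)
  # variant with 500 reads at frequency 0.05 in one individual -> rejected
  rs <- list(
    i1 = mk("i1", c("A1", "A2"), c(9500, 500)),      # A2 freq 0.05, 500 reads
    i2 = mk("i2", c("A1", "A3"), c(1200, 1200)),
    i3 = mk("i3", c("A3", "A1"), c(1300, 1200)))
  cat1 <- validate_alleles(rs)
  expect_setequal(unname(cat1$alleles), unname(seqs[c("A1", "A3")]))
  g1 <- cat1$genotypes
  expect_true(is.na(g1$allele2[g1$individual == "i1"]))  # i1 left homozygous

  # heterozygote exception: private variant at frequency 0.4 alongside a
  # retained allele is accepted
  rs2 <- list(
    i1 = mk("i1", c("A1", "A4"), c(600, 400)),   # A4 private, freq 0.4
    i2 = mk("i2", c("A1", "A1"), c(800, 100)),
    i3 = mk("i3", "A1", 900))
  cat2 <- validate_alleles(rs2, min_reads = 1000)
  expect_true(unname(seqs["A4"]) %in% unname(cat2$alleles))

  # two private variants with no shared anchor stay out
  rs3 <- list(
    i1 = mk("i1", c("A3", "A4"), c(600, 400)),
    i2 = mk("i2", c("A1", "A2"), c(500, 500)),
    i3 = mk("i3", c("A1", "A2"), c(300, 700)))
  cat3 <- validate_alleles(rs3)
  expect_false(any(unname(seqs[c("A3", "A4")]) %in% unname(cat3$alleles)))

  # "and" mode demands both clauses
  rs4 <- list(i1 = mk("i1", c("A1", "A2"), c(1500, 900)),
              i2 = mk("i2", c("A1", "A2"), c(1500, 900)))
  expect_setequal(unname(validate_alleles(rs4, rule = "and")$alleles),
                  unname(seqs["A1"]))
})

test_that(">2 validated variants are flagged and trimmed to the top two", {
  seqs <- random_nt_alleles(3, len = 60, seed = 85)
  mk <- function(ind, v, n) amplicon_read_set(ind, "DAB1",
    data.frame(seq = unname(seqs[v]), count = n), pop = "P1")
  rs <- list(i1 = mk("i1", c("A1", "A2", "A3"), c(4000, 3000, 2000)),
             i2 = mk("i2", c("A1", "A2", "A3"), c(4000, 3000, 2000)))
  expect_message(cat1 <- validate_alleles(rs), "putative contamination")
  g <- cat1$genotypes
  carried <- unname(cat1$alleles[c(g$allele1[1], g$allele2[1])])
  expect_setequal(carried, unname(seqs[c("A1", "A2")]))
})

test_that("validation is idempotent and bounded by the input variants", {
  al <- random_nt_alleles(4, len = 100, min_diff = 8, seed = 86)
  g <- balanced_genotypes(names(al), 10, seed = 87)
  mod <- amplicon_sim_model(al, g, depth = 1500, error_rate = 0.002,
                            chimera_rate = 0.04)
  rs <- simulate_amplicon_reads(mod, seed = 88)
  cat1 <- validate_alleles(rs)
  n_input_variants <- length(unique(unlist(
    lapply(rs, function(r) r$variants$seq))))
  expect_lte(length(cat1$alleles), n_input_variants)
  expect_true(all(na.omit(c(cat1$genotypes$allele1, cat1$genotypes$allele2))
                  %in% names(cat1$alleles)))
  # restrict read support to the validated alleles and validate again
  rs_clean <- lapply(rs, function(r) {
    v <- r$variants[r$variants$seq %in% cat1$alleles, , drop = FALSE]
    amplicon_read_set(r$individual, r$locus, v, r$pop)
  })
  names(rs_clean) <- names(rs)
  cat2 <- validate_alleles(rs_clean)
  expect_setequal(unname(cat2$alleles), unname(cat1$alleles))
  g1 <- cat1$genotypes[order(cat1$genotypes$individual), c("allele1", "allele2")]
  g2 <- cat2$genotypes[order(cat2$genotypes$individual), c("allele1", "allele2")]
  m1 <- cat1$alleles[as.matrix(g1)]
  m2 <- cat2$alleles[as.matrix(g2)]
  expect_identical(m1, m2)
})

test_that("depth summary reports mean +/- sd with range", {
  tot <- c(1040L, 8569L, 22155L)
  ds <- amplicon_depth_summary(tot)
  expect_equal(ds$mean, mean(tot))
  expect_equal(ds$sd, sd(tot))
  expect_match(ds$label, "\\d+ \\+/- \\d+ \\(1040-22155\\)")
})
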