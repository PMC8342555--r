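test_that("diversity summaries match closed forms", {
  # counts {a:5, b:5} from 5 diploids: unbiased H_E = (10/9)(1 - 0.5)
  expect_equal(unbiased_het(c(a = 5, b = 5)), 10 / 9 * 0.5)
  # rarefaction of counts {2,2} to g = 2: brute force over all C(4,2)
  # two-copy subsamples gives (1 + 4*2 + 1)/6 = 5/3 distinct alleles
  expect_equal(allelic_richness(c(2, 2), 2), 5 / 3)
  expect_error(allelic_richness(c(2, 2), 5), "exceeds")

  calls <- array(100L, c(3, 1, 2))
  mono <- genotype_table(calls, rep("P", 3),
                         data.frame(locus = "L1", motif = 2L))
  s <- locus_summaries(mono)
  expect_equal(s$A, 1L)
  expect_equal(s$H_E, 0)
  expect_equal(s$H_O, 0)
  expect_true(is.na(s$F_IS))

  tab <- toy_table()
  ls <- locus_summaries(tab)
  expect_error(locus_summaries(tab, rarefaction_g = 100), "exceeds")
  # H_E recomputed independently per row
  for (r in seq_len(nrow(ls))) {
    cnt <- consgen:::allele_counts(tab, ls$locus[r],
                                   which_ind = which(tab$pop == ls$pop[r]))
    expect_equal(ls$H_E[r], unbiased_het(cnt))
    expect_lte(ls$A_R[r], ls$A[r])
  }
})

test_that("H_E estimator is unbiased under multinomial resampling", {
  set.seed(31)
  p <- c(0.5, 0.3, 0.2)
  n <- 8
  hes <- replicate(1000, {
    cnt <- as.vector(rmultinom(1, 2 * n, p))
    unbiased_het(cnt[cnt > 0])
  })
  expect_lt(abs(mean(hes) - (1 - sum(p^2))), 0.01)
})

test_that("bonferroni uses the strict family-wise threshold", {
  expect_true(bonferroni(c(0.002, rep(0.5, 19)))[1])   # 0.002 < 0.05/20
  expect_false(bonferroni(c(0.003, rep(0.5, 19)))[1])  # 0.003 > 0.0025
  expect_true(bonferroni(0.049))                       # single test: alpha
})

test_that("HWE Markov-chain test matches exact enumeration", {
  # single observed genotype: only one table is possible
  expect_equal(hwe_exact_test(matrix(c(1, 1), 1, 2), 10, 100, 100)$p, 1)
  # balanced 25/50/25: the modal table, p ~ 1
  gm <- rbind(matrix(c(1, 1), 25, 2, byrow = TRUE),
              matrix(c(1, 2), 50, 2, byrow = TRUE),
              matrix(c(2, 2), 25, 2, byrow = TRUE))
  set.seed(1)
  p1 <- hwe_exact_test(gm, batches = 50, iters = 2000, burnin = 2000)$p
  expect_gt(p1, 0.95)
  # all homozygotes: extreme heterozygote deficit
  gm2 <- rbind(matrix(c(1, 1), 50, 2, byrow = TRUE),
               matrix(c(2, 2), 50, 2, byrow = TRUE))
  set.seed(2)
  expect_lt(hwe_exact_test(gm2, batches = 50, iters = 2000, burnin = 2000)$p,
            0.001)
  # enumeration oracle on a moderate two-allele table
  set.seed(3)
  res <- hwe_exact_test(rbind(matrix(c(1, 1), 6, 2, byrow = TRUE),
                              matrix(c(1, 2), 3, 2, byrow = TRUE),
                              matrix(c(2, 2), 6, 2, byrow = TRUE)),
                        batches = 100, iters = 5000, burnin = 5000)
  expect_lt(abs(res$p - oracle_hwe_exact_2allele(6, 3, 6)), 3 * res$se)
})

test_that("LD exact test distinguishes linkage from independence", {
  set.seed(41)
  # perfectly correlated loci
  n <- 40
  a <- sample(1:3, n, replace = TRUE)
  b <- sample(1:3, n, replace = TRUE)
  calls <- array(NA_integer_, c(n, 2, 2))
  calls[, 1, 1] <- 100L + 2L * a; calls[, 1, 2] <- 100L + 2L * b
  calls[, 2, 1] <- 200L + 2L * a; calls[, 2, 2] <- 200L + 2L * b
  tab <- genotype_table(calls, rep("P", n),
                        data.frame(locus = c("L1", "L2"), motif = c(2L, 2L)))
  p_link <- ld_exact_test(tab, c("L1", "L2"), batches = 60, iters = 3000,
                          burnin = 3000, seed = 5)$p
  expect_lt(p_link, 0.01)
  # one locus monomorphic -> p = 1
  calls2 <- calls; calls2[, 2, ] <- 200L
  tab2 <- genotype_table(calls2, rep("P", n),
                         data.frame(locus = c("L1", "L2"), motif = c(2L, 2L)))
  expect_equal(ld_exact_test(tab2, c("L1", "L2"), seed = 6)$p, 1)
  # independent loci: p roughly uniform (scaled to 40 replicates)
  ps <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    calls3 <- array(100L + 2L * sample(1:4, n * 4, replace = TRUE),
                    c(n, 2, 2))
    t3 <- genotype_table(calls3, rep("P", n),
                         data.frame(locus = c("L1", "L2"), motif = c(2L, 2L)))
    ld_exact_test(t3, c("L1", "L2"), batches = 20, iters = 1500,
                  burnin = 1500)$p
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.005)
})

test_that("null-allele screen estimates Brookfield-1 and flags excess", {
  tab <- split_panmixia(seed = 8, n = 40, L = 1)
  res <- null_allele_screen(tab, "L01", sims = 300, seed = 9)
  expect_equal(res$r, max(0, (res$H_E - res$H_O) / (1 + res$H_E)))
  # closed form: H_E = 0.6, H_O = 0.4 -> r = 0.125
  expect_equal((0.6 - 0.4) / (1 + 0.6), 0.125)
  # 20% null-allele data raises the flag (scaled: 25 replicates)
  flags <- vapply(1:25, function(s) {
    set.seed(2000 + s)
    n <- 60
    alle <- c(102L, 104L, 106L, 108L, 0L)      # 0 = null
    pr <- c(0.2, 0.2, 0.2, 0.2, 0.2)
    a1 <- sample(alle, n, TRUE, pr); a2 <- sample(alle, n, TRUE, pr)
    vis1 <- ifelse(a1 == 0L, a2, a1)           # null homozygotes drop out
    vis2 <- ifelse(a2 == 0L, a1, a2)
    keep <- vis1 != 0L
    calls <- array(c(vis1[keep], vis2[keep]), c(sum(keep), 1, 2))
    tb <- genotype_table(calls, rep("P", sum(keep)),
                         data.frame(locus = "L1", motif = 2L))
    null_allele_screen(tb, "L1", sims = 200)$flag
  }, TRUE)
  expect_gte(mean(flags), 0.8)
})

test_that("Weir-Cockerham theta has the expected fixed points", {
  expect_equal(fst_weir_cockerham(fixed_table())$global, 1)
  tab <- split_panmixia(seed = 12, n = 60)
  res <- fst_weir_cockerham(tab, permutations = 200, seed = 13)
  expect_lt(res$global, 0.02)   # negative estimates allowed, not truncated
  expect_gt(res$matrix$pvalues[1, 2], 0.05)
  # theta invariant to allele relabeling
  tab2 <- toy_table()
  tab3 <- tab2
  tab3$calls[, 1, ][tab3$calls[, 1, ] == 100L] <- 998L
  expect_equal(fst_weir_cockerham(tab3)$global,
               fst_weir_cockerham(tab2)$global)
})

test_that("R_ST fixed points and shift invariance hold", {
  expect_equal(rst_slatkin(fixed_table())$global, 1)
  tab <- split_panmixia(seed = 14, n = 60)
  expect_lt(abs(rst_slatkin(tab)$global), 0.03)
  # adding a constant number of repeats to all sizes leaves R_ST unchanged
  tab2 <- toy_table()
  tab3 <- tab2
  tab3$calls <- tab3$calls + 20L   # +10 repeat units at motif 2
  expect_equal(rst_slatkin(tab3)$global, rst_slatkin(tab2)$global)
})

test_that("G_ST reproduces the textbook two-population case", {
  # p = (0.2, 0.8) vs (0.8, 0.2): H_S = 0.32, H_T = 0.5, G_ST = 0.36
  n <- 5
  calls <- array(NA_integer_, c(2 * n, 1, 2))
  calls[1:n, 1, 1] <- c(100L, rep(102L, 4))
  calls[1:n, 1, 2] <- c(100L, rep(102L, 4))
  calls[(n + 1):(2 * n), 1, 1] <- c(rep(100L, 4), 102L)
  calls[(n + 1):(2 * n), 1, 2] <- c(rep(100L, 4), 102L)
  tab <- genotype_table(calls, rep(c("A", "B"), each = n),
                        data.frame(locus = "L1", motif = 2L))
  expect_equal(gst_nei(tab)$global, (0.5 - 0.32) / 0.5)
  expect_equal(gst_nei(fixed_table())$global, 1)
  # identical frequencies -> 0
  tabeq <- tab; tabeq$calls[(n + 1):(2 * n), , ] <- tabeq$calls[1:n, , ]
  expect_equal(gst_nei(tabeq)$global, 0)
})

test_that("IBD regression and Mantel test behave on constructed matrices", {
  set.seed(51)
  k <- 7
  D <- matrix(0, k, k, dimnames = list(letters[1:k], letters[1:k]))
  D[lower.tri(D)] <- runif(k * (k - 1) / 2, 5, 80)
  D <- D + t(D)
  G <- 0.001 * D
  res <- ibd_test(pairwise_stat_matrix(G, "G_ST"),
                  pairwise_stat_matrix(D, "km"),
                  permutations = 999, seed = 52)
  expect_equal(res$r, 1)
  expect_equal(res$slope, 0.001)
  expect_equal(res$intercept, 0, tolerance = 1e-12)
  expect_lt(res$p, 0.01)
  # 3x3 slope equals closed-form least squares on the 3 pairs
  D3 <- matrix(c(0, 10, 20, 10, 0, 15, 20, 15, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  G3 <- matrix(c(0, .02, .05, .02, 0, .02, .05, .02, 0), 3,
               dimnames = dimnames(D3))
  r3 <- ibd_test(pairwise_stat_matrix(G3, "G_ST"),
                 pairwise_stat_matrix(D3, "km"), permutations = 99, seed = 3)
  fit <- lm(c(.02, .05, .02) ~ c(10, 20, 15))
  expect_equal(r3$slope, unname(coef(fit)[2]))
  expect_equal(r3$intercept, unname(coef(fit)[1]))
  # agreement with an established Mantel implementation
  vr <- vegan::mantel(stats::as.dist(D), stats::as.dist(G),
                      permutations = 99)
  expect_equal(res$r, unname(vr$statistic))
})

test_that("principal coordinates reproduce distances and symmetries", {
  labs <- c("A", "B")
  V <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(labs, labs))
  pc <- pcoa_from_fst(pairwise_stat_matrix(V, "F_ST"))
  expect_equal(unname(sort(abs(pc$coordinates[, 1]))), c(0.2, 0.2))
  # three equidistant populations: two equal positive eigenvalues
  E <- matrix(0.3, 3, 3); diag(E) <- 0
  dimnames(E) <- list(c("A", "B", "C"), c("A", "B", "C"))
  pc3 <- pcoa_from_fst(pairwise_stat_matrix(E, "F_ST"))
  pos <- pc3$eigenvalues[pc3$eigenvalues > 1e-10]
  expect_equal(length(pos), 2L)
  expect_equal(pos[1], pos[2])
  # Euclidean input: recovered inter-point distances equal the input
  set.seed(53)
  pts <- matrix(rnorm(8), 4, 2)
  DE <- as.matrix(dist(pts))
  dimnames(DE) <- list(letters[1:4], letters[1:4])
  pce <- pcoa_from_fst(pairwise_stat_matrix(DE, "d"))
  rec <- as.matrix(dist(pce$coordinates))
  expect_equal(unname(rec), unname(DE), tolerance = 1e-8)
})
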