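panel2 <- data.frame(snp_id = c("snp1", "snp2"), allele1 = c("A", "C"),
                     allele2 = c("G", "T"), chrom = "1",
                     pos = c(1000L, 2000L), stringsAsFactors = FALSE)

test_that("pc_pgs_weights passes signed loadings through, oriented to the panel", {
  d <- make_decomposition(cbind(c(0.6, -0.8)), 2, matrix(1, 1, 1),
                          snp_ids = c("snp1", "snp2"))
  w <- pc_pgs_weights(d, 1, panel2)
  expect_equal(w$weight, c(0.6, -0.8))
  expect_equal(w$effect_allele, c("A", "C"))
  # squared variant equals the contribution column
  w2 <- pc_pgs_weights(d, 1, panel2, squared = TRUE)
  expect_equal(w2$weight, c(0.36, 0.64))
  # component orientation flips the signed weights
  d_flipped <- d
  d_flipped$snp_vectors <- -d_flipped$snp_vectors
  d_flipped$pheno_vectors <- -d_flipped$pheno_vectors
  expect_equal(pc_pgs_weights(d_flipped, 1, panel2)$weight, c(-0.6, 0.8))
})

test_that("meta_subtract inverts inverse-variance meta-analysis exactly", {
  a <- make_records("rs1", beta = 0.2, se = 0.1)
  b <- make_records("rs1", beta = 0.0, se = 0.1)
  meta <- ivw_meta(a, b)
  expect_equal(meta$beta, 0.1)
  expect_equal(meta$se, sqrt(1 / 200), tolerance = 1e-12)
  back <- meta_subtract(meta, b)
  expect_equal(back$beta, 0.2, tolerance = 1e-12)
  expect_equal(back$se, 0.1, tolerance = 1e-12)

  # subtracting the meta itself is degenerate: dropped with a warning
  expect_warning(out <- meta_subtract(meta, meta), "dropped")
  expect_equal(nrow(out), 0)

  # three cohorts: meta minus one equals the meta of the other two
  set.seed(44)
  n <- 50
  cohorts <- lapply(1:3, function(i) {
    make_records(sprintf("rs%02d", 1:n), beta = stats::rnorm(n),
                 se = stats::runif(n, 0.05, 0.3))
  })
  meta3 <- ivw_meta(ivw_meta(cohorts[[1]], cohorts[[2]]), cohorts[[3]])
  left <- meta_subtract(meta3, cohorts[[2]])
  want <- oracle_ivw(list(cohorts[[1]]$beta, cohorts[[3]]$beta),
                     list(cohorts[[1]]$se, cohorts[[3]]$se))
  expect_lt(max(abs(left$beta - want$beta)), 1e-10)
  expect_lt(max(abs(left$se - want$se)), 1e-10)
})

test_that("reconstruct_counts recovers frequencies in both modes", {
  # null odds ratio: case frequency equals control frequency
  rec <- make_records("rs1", beta = 0, eaf = 0.3, n_case = 100,
                      n_control = 200)
  ct <- reconstruct_counts(rec, "control")
  expect_equal(ct$f_case, 0.3)
  expect_equal(ct$a + ct$b, 200)  # 2 * n_case
  expect_equal(ct$c + ct$d, 400)

  # OR = 2.25 takes control odds 2/3 to case odds 3/2
  rec2 <- make_records("rs1", beta = log(2.25), eaf = 0.4, n_case = 100,
                       n_control = 100)
  expect_equal(reconstruct_counts(rec2, "control")$f_case, 0.6)

  # pooled mode round-trips generating frequencies
  set.seed(55)
  n <- 200
  f_case <- stats::runif(n, 0.1, 0.9)
  f_ctrl <- stats::runif(n, 0.1, 0.9)
  rec3 <- records_from_freqs(f_case, f_ctrl, 1500, 2500, freq_is = "pooled")
  ct3 <- reconstruct_counts(rec3, "pooled")
  expect_equal(nrow(ct3), n)
  expect_lt(max(abs(ct3$f_case - f_case)), 1e-10)
  expect_lt(max(abs(ct3$f_ctrl - f_ctrl)), 1e-10)

  # missing eaf / sample sizes are dropped with a warning
  rec4 <- make_records(c("a", "b"), eaf = c(NA, 0.3))
  expect_warning(ct4 <- reconstruct_counts(rec4, "control"), "dropped")
  expect_equal(ct4$snp_id, "b")
  expect_equal(attr(ct4, "n_dropped"), 1L)
})

test_that("group_pgs matches the single-SNP closed form and nulls out", {
  rec <- records_from_freqs(0.6, 0.5, 1000, 1000)
  w <- data.frame(snp_id = rec$snp_id, effect_allele = "A", weight = 0.5,
                  stringsAsFactors = FALSE)
  g <- group_pgs(w, rec)
  expect_equal(g$mean_a, 0.6)
  expect_equal(g$mean_b, 0.5)
  expect_equal(g$sd_a, sqrt(0.25 * 2 * 0.6 * 0.4))
  expect_equal(g$sd_b, sqrt(0.25 * 2 * 0.5 * 0.5))
  expect_equal(g$r2, g$t^2 / (g$t^2 + g$df))

  # equal frequencies in both groups: t = 0, r2 = 0
  set.seed(66)
  f <- stats::runif(20, 0.2, 0.8)
  rec0 <- records_from_freqs(f, f, 5000, 5000)
  w0 <- data.frame(snp_id = rec0$snp_id, effect_allele = "A",
                   weight = stats::rnorm(20), stringsAsFactors = FALSE)
  g0 <- group_pgs(w0, rec0)
  expect_equal(g0$t, 0)
  expect_equal(g0$r2, 0)

  # SNPs absent from the target are dropped and counted
  w_extra <- rbind(w0, data.frame(snp_id = "rs_nowhere",
                                  effect_allele = "A", weight = 1))
  g1 <- group_pgs(w_extra, rec0)
  expect_equal(g1$n_snps, 20L)
  expect_equal(attr(g1, "n_missing"), 1L)
  expect_error(group_pgs(w0, rec0[0, ]), "no SNP shared")
})

test_that("group_pgs t is antisymmetric under swapping the groups", {
  set.seed(77)
  n <- 40
  f_case <- stats::runif(n, 0.2, 0.8)
  f_ctrl <- stats::runif(n, 0.2, 0.8)
  rec_ab <- records_from_freqs(f_case, f_ctrl, 3000, 3000)
  # swap roles: controls become cases, odds ratio inverts
  rec_ba <- records_from_freqs(f_ctrl, f_case, 3000, 3000)
  w <- data.frame(snp_id = rec_ab$snp_id, effect_allele = "A",
                  weight = stats::rnorm(n), stringsAsFactors = FALSE)
  g_ab <- group_pgs(w, rec_ab)
  g_ba <- group_pgs(w, rec_ba)
  expect_equal(g_ba$t, -g_ab$t, tolerance = 1e-10)
  expect_equal(g_ba$df, g_ab$df, tolerance = 1e-10)
  expect_equal(g_ba$r2, g_ab$r2, tolerance = 1e-10)
})

test_that("r2_from_t follows t^2 / (t^2 + df)", {
  expect_equal(r2_from_t(0, 10), 0)
  expect_equal(r2_from_t(3, 100), 9 / 109)
  expect_gt(r2_from_t(1e8, 10), 1 - 1e-10)  # limit towards 1
  expect_error(r2_from_t(1, 0))
})

test_that("cc_gwas reproduces the direct two-by-two computation", {
  # equal case frequencies: null association
  recA <- records_from_freqs(0.5, 0.4, 2000, 3000)
  recB <- records_from_freqs(0.5, 0.45, 2500, 3500)
  cc0 <- cc_gwas(recA, recB)
  expect_equal(cc0$beta, 0)

  # 0.6 vs 0.4 case frequencies: odds ratio 2.25
  recA2 <- records_from_freqs(0.6, 0.5, 2000, 3000)
  recB2 <- records_from_freqs(0.4, 0.5, 2500, 3500)
  cc1 <- cc_gwas(recA2, recB2)
  expect_equal(exp(cc1$beta), 2.25, tolerance = 1e-12)
  # Woolf SE over the reconstructed case counts
  expect_equal(cc1$se, sqrt(1 / (2 * 2000 * 0.6) + 1 / (2 * 2000 * 0.4) +
                              1 / (2 * 2500 * 0.4) + 1 / (2 * 2500 * 0.6)))

  # random pairs against the direct computation on the generating tables
  set.seed(88)
  n <- 100
  fA <- stats::runif(n, 0.1, 0.9)
  fB <- stats::runif(n, 0.1, 0.9)
  ccr <- cc_gwas(records_from_freqs(fA, stats::runif(n, 0.2, 0.8), 4000, 4000),
                 records_from_freqs(fB, stats::runif(n, 0.2, 0.8), 5000, 5000))
  beta_direct <- log((fA / (1 - fA)) / (fB / (1 - fB)))
  expect_lt(max(abs(ccr$beta - beta_direct)), 1e-10)

  # self-contrast is exactly null everywhere
  cc_self <- cc_gwas(recA2, recA2)
  expect_true(all(cc_self$beta == 0))

  # output orientation supports downstream group comparison: group B's case
  # frequency is the reported eaf
  expect_equal(cc1$eaf, 0.4)
  expect_equal(cc1$n_case, 2000)
  expect_equal(cc1$n_control, 2500)
})

test_that("adjust_bonferroni flags p below alpha over m", {
  expect_true(adjust_bonferroni(0.016, 3))
  expect_false(adjust_bonferroni(0.02, 3))
  expect_true(adjust_bonferroni(0.04, 1))
  expect_equal(adjust_bonferroni(c(0.001, 0.02, 0.5), 3),
               c(TRUE, FALSE, FALSE))
})
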