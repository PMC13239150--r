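test_that("threshold_z zeroes entries at or above the p-value threshold", {
  expect_equal(threshold_z(3.5, 5e-4, 1e-3), 3.5)
  expect_equal(threshold_z(3.5, 2e-3, 1e-3), 0)
  expect_equal(threshold_z(3.5, 2e-3, 0.05), 3.5)  # looser secondary threshold
  expect_equal(threshold_z(c(1, -2, 3), c(1e-4, 0.5, 1e-3), 1e-3),
               c(1, 0, 0))  # boundary p == alpha is zeroed
  expect_error(threshold_z(1, 0.5, 1.5))
})

test_that("assemble_matrix builds the union with structural zeros and a p-mask", {
  a <- make_records(c("rs1", "rs2"), beta = c(0.2, 0.1), se = 0.05,
                    p_value = c(1e-4, 0.5), pos = c(1000L, 2000L))
  b <- make_records("rs1", beta = -0.3, se = 0.1, p_value = 1e-5,
                    pos = 1000L)
  m <- assemble_matrix(list(A = a, B = b), alpha = 1e-3)
  expect_equal(dim(m$z), c(2L, 2L))
  expect_equal(m$z["rs1", ], c(A = 4, B = -3))
  expect_true(all(m$mask["rs1", ]))
  # rs2 fails alpha in A and is absent from B
  expect_equal(unname(m$z["rs2", ]), c(0, 0))
  expect_equal(unname(m$mask["rs2", ]), c(FALSE, FALSE))

  dup <- rbind(a, a[1, ])
  expect_error(assemble_matrix(list(A = dup, B = b), alpha = 1e-3),
               "duplicate SNP within trait A")
})

test_that("assembled mask equals elementwise p < alpha", {
  set.seed(11)
  traits <- lapply(1:3, function(i) {
    make_records(sprintf("rs%02d", 1:10), beta = stats::rnorm(10),
                 se = stats::runif(10, 0.01, 0.2),
                 p_value = stats::runif(10), pos = (1:10) * 1000L)
  })
  names(traits) <- c("x", "y", "z")
  alpha <- 0.3
  m <- assemble_matrix(traits, alpha = alpha)
  for (j in 1:3) {
    r <- traits[[j]]
    expect_equal(unname(m$mask[r$snp_id, j]), r$p_value < alpha)
    expect_equal(unname(m$z[r$snp_id, j]),
                 ifelse(r$p_value < alpha, r$beta / r$se, 0))
  }
})

test_that("filter_min_traits keeps rows supported by enough traits", {
  z <- matrix(1, 3, 2)
  mask <- rbind(c(TRUE, FALSE), c(TRUE, TRUE), c(FALSE, FALSE))
  m <- zmatrix(z, mask, c("a", "b", "c"), c("t1", "t2"))
  out <- filter_min_traits(m, 2)
  expect_equal(out$snp_ids, "b")
  expect_equal(out$trait_ids, m$trait_ids)
  expect_error(filter_min_traits(m, 3), "no SNP")

  # brute-force agreement on random masks
  set.seed(5)
  mask10 <- matrix(stats::runif(40) < 0.5, 10, 4)
  mask10[1, ] <- TRUE  # guarantee a survivor
  m10 <- zmatrix(matrix(stats::rnorm(40), 10, 4), mask10,
                 sprintf("s%02d", 1:10), paste0("t", 1:4))
  for (k in 1:3) {
    keep_bf <- vapply(seq_len(10), function(i) sum(mask10[i, ]) >= k,
                      logical(1))
    expect_equal(filter_min_traits(m10, k)$snp_ids, m10$snp_ids[keep_bf])
  }
})

test_that("ld_source is symmetric with unit diagonal and zero default", {
  ld <- ld_source(data.frame(snp_a = "a", snp_b = "b", r2 = 0.7))
  expect_equal(ld_r2(ld, "a", "b"), 0.7)
  expect_equal(ld_r2(ld, "b", "a"), 0.7)
  expect_equal(ld_r2(ld, "a", "a"), 1)
  expect_equal(ld_r2(ld, "a", "zz"), 0)
})

test_that("clump honours the physical window and the disorder-count priority", {
  # 600 kb apart in strong LD: both retained
  z <- matrix(c(3, 2), 2, 1)
  mask <- matrix(TRUE, 2, 1)
  pos <- data.frame(snp_id = c("a", "b"), chrom = "1",
                    pos = c(1L, 600001L), stringsAsFactors = FALSE)
  m <- zmatrix(z, mask, c("a", "b"), "t1", positions = pos)
  ld <- ld_source(data.frame(snp_a = "a", snp_b = "b", r2 = 0.9))
  expect_equal(clump(m, ld, window_bp = 500000, r2_max = 0.2)$snp_ids,
               c("a", "b"))

  # three co-located SNPs with pairwise r2 0.5 and priorities 3/2/1:
  # only the count-3 index survives
  z3 <- matrix(stats::rnorm(9), 3, 3)
  mask3 <- rbind(c(TRUE, TRUE, TRUE), c(TRUE, TRUE, FALSE),
                 c(TRUE, FALSE, FALSE))
  pos3 <- data.frame(snp_id = c("x", "y", "w"), chrom = "1",
                     pos = c(1000L, 2000L, 3000L), stringsAsFactors = FALSE)
  m3 <- zmatrix(z3, mask3, c("x", "y", "w"), paste0("t", 1:3),
                positions = pos3)
  ld3 <- ld_source(data.frame(snp_a = c("x", "x", "y"),
                              snp_b = c("y", "w", "w"), r2 = 0.5))
  expect_equal(clump(m3, ld3)$snp_ids, "x")

  # missing position is fatal and names the SNP
  m_bad <- zmatrix(z, mask, c("a", "b"), "t1",
                   positions = pos[1, , drop = FALSE])
  expect_error(clump(m_bad, ld), "missing position for SNP: b")
})

test_that("clump matches the brute-force greedy oracle on random instances", {
  for (seed in 1:30) {
    inst <- random_clump_instance(seed)
    got <- clump(inst$m, ld_source(inst$ld_pairs),
                 window_bp = 500000, r2_max = 0.2)$snp_ids
    want <- oracle_clump(inst$cand, inst$ld_pairs,
                         window_bp = 500000, r2_max = 0.2)
    expect_setequal(got, want)
    # output preserves the input row order and is a subset of it
    expect_equal(got, inst$m$snp_ids[inst$m$snp_ids %in% got])
  }
})

test_that("standardise_columns gives population-SD mean-0 unit-SD columns", {
  z <- matrix(c(1, 3, 5, 7), 2, 2)
  m <- zmatrix(z, matrix(TRUE, 2, 2), c("a", "b"), c("t1", "t2"))
  out <- standardise_columns(m)
  expect_equal(unname(out$z[, 1]), c(-1, 1))
  expect_equal(unname(out$z[, 2]), c(-1, 1))
  expect_equal(out$mask, m$mask)

  set.seed(3)
  zr <- matrix(stats::rnorm(200), 50, 4)
  mr <- zmatrix(zr, zr > 0, sprintf("s%02d", 1:50), paste0("t", 1:4))
  s1 <- standardise_columns(mr)
  expect_lt(max(abs(colMeans(s1$z))), 1e-12)
  expect_lt(max(abs(sqrt(colMeans(s1$z^2)) - 1)), 1e-12)
  # idempotent
  s2 <- standardise_columns(s1)
  expect_lt(max(abs(s2$z - s1$z)), 1e-10)

  z0 <- zr; z0[, 2] <- 5
  m0 <- zmatrix(z0, zr > 0, sprintf("s%02d", 1:50), paste0("t", 1:4))
  expect_error(standardise_columns(m0), "zero-variance column for trait: t2")
})

test_that("exclude_region removes rows inside the inclusive bounds", {
  pos <- data.frame(snp_id = c("a", "b", "c", "d"),
                    chrom = c("6", "6", "6", "7"),
                    pos = c(30000000L, 25477796L, 25477797L, 30000000L),
                    stringsAsFactors = FALSE)
  m <- zmatrix(matrix(1, 4, 2), matrix(TRUE, 4, 2), pos$snp_id,
               c("t1", "t2"), positions = pos)
  out <- exclude_region(m, "6", 25477797, 36448354)
  expect_setequal(out$snp_ids, c("b", "d"))  # below start / other chromosome
  expect_error(exclude_region(m, "6", 10, 5))
})

test_that("the fixed pipeline order threshold-filter-clump-standardise holds together", {
  study <- small_study()
  h <- lapply(study$sumstats, harmonise, panel = study$panel)
  m <- assemble_matrix(h, alpha = 1e-3)
  mf <- filter_min_traits(m, 2)
  mc <- clump(mf, ld_source(study$ld))
  ms <- standardise_columns(mc)
  expect_lte(nrow(mf$z), nrow(m$z))
  expect_lte(nrow(mc$z), nrow(mf$z))
  expect_true(all(mc$snp_ids %in% mf$snp_ids))
  expect_equal(dim(ms$z), dim(mc$z))
  # standardisation after clumping: clumped rows standardised, not the input
  expect_lt(max(abs(colMeans(ms$z))), 1e-12)
})
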