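write_sumstats_file <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

base_map <- c(snp_id = "SNP", chrom = "CHR", pos = "BP",
              effect_allele = "A1", other_allele = "A2",
              se = "SE", p_value = "P")

test_that("read_sumstats converts odds ratios to log scale and passes betas through", {
  df <- data.frame(SNP = c("rs1", "rs2"), CHR = "1", BP = c(100, 200),
                   A1 = "A", A2 = "G", OR = c(1.0, 2.0), SE = 0.1, P = 0.01)
  path <- write_sumstats_file(df)
  rec <- read_sumstats(path, c(base_map, or = "OR"))
  expect_equal(rec$beta, c(0, log(2)))

  df$BETA <- c(0.2, -0.3)
  path2 <- write_sumstats_file(df)
  rec2 <- read_sumstats(path2, c(base_map, beta = "BETA"))
  expect_equal(rec2$beta, c(0.2, -0.3))
})

test_that("read_sumstats skips and counts invalid rows, fails on empty result", {
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"), CHR = "1",
                   BP = c(100, 200, 300), A1 = c("A", "A", "A"),
                   A2 = c("G", "G", "G"), BETA = 0.1,
                   SE = c(0.1, NA, 0.1), P = c(0.01, 0.01, 0.01))
  path <- write_sumstats_file(df)
  rec <- read_sumstats(path, c(base_map, beta = "BETA"))
  expect_equal(nrow(rec), 2)
  expect_equal(attr(rec, "n_skipped"), 1)

  # invalid p, non-positive se, identical alleles, bad base all skipped
  df2 <- data.frame(SNP = c("rs1", "rs2", "rs3", "rs4", "rs5"), CHR = "1",
                    BP = 100, A1 = c("A", "A", "A", "A", "N"),
                    A2 = c("G", "G", "G", "A", "G"), BETA = 0.1,
                    SE = c(0.1, 0.1, -1, 0.1, 0.1),
                    P = c(0.5, 1.5, 0.5, 0.5, 0.5))
  rec2 <- read_sumstats(write_sumstats_file(df2), c(base_map, beta = "BETA"))
  expect_equal(rec2$snp_id, "rs1")
  expect_equal(attr(rec2, "n_skipped"), 4)

  df3 <- df2[df2$SNP != "rs1", ]
  expect_error(read_sumstats(write_sumstats_file(df3),
                             c(base_map, beta = "BETA")), "no valid rows")
  expect_error(read_sumstats("/nonexistent/file", c(base_map, beta = "BETA")),
               "not found")
  expect_error(read_sumstats(path, c(base_map, beta = "MISSING_COL")),
               "absent")
  expect_error(read_sumstats(path, c(base_map, beta = "BETA", or = "OR")),
               "exactly one")
})

test_that("compute_z returns beta / se signed to the effect allele", {
  rec <- make_records(c("a", "b", "c"), beta = c(0.1, 0, -0.3),
                      se = c(0.05, 0.2, 0.1))
  expect_equal(compute_z(rec), c(2, 0, -3))
  rec$se[1] <- 0
  expect_error(compute_z(rec), "positive SE")
})

panel_fixture <- data.frame(
  snp_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
  allele1 = c("A", "A", "C", "A", "A"),
  allele2 = c("G", "G", "T", "G", "T"),
  chrom = "1", pos = c(100, 200, 300, 400, 500) * 1000L,
  stringsAsFactors = FALSE
)

test_that("harmonise aligns, flips, complements and drops as specified", {
  rec <- make_records(
    c("rs1", "rs2", "rs3", "rs4", "rs5", "rs9"),
    effect_allele = c("A", "G", "A", "T", "A", "A"),
    other_allele  = c("G", "A", "G", "C", "T", "G"),
    beta = c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2),
    eaf = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3)
  )
  # rs1 same; rs2 swapped; rs3 A/G complements to T/C, the reverse of panel
  # C/T -> complement-swapped; rs4 T/C complements to A/G -> complement-same;
  # rs5 A/T ambiguous; rs9 not in panel
  h <- harmonise(rec, panel_fixture)
  rep <- attr(h, "report")
  expect_equal(unname(rep["kept"]), 4L)
  expect_equal(unname(rep["flipped"]), 2L)
  expect_equal(unname(rep["complemented"]), 2L)
  expect_equal(unname(rep["dropped_ambiguous"]), 1L)
  expect_equal(unname(rep["dropped_not_in_panel"]), 1L)

  expect_equal(h$beta[h$snp_id == "rs1"], 0.2)
  expect_equal(h$beta[h$snp_id == "rs2"], -0.2)
  expect_equal(h$eaf[h$snp_id == "rs2"], 0.7)
  expect_equal(h$beta[h$snp_id == "rs3"], -0.2)  # complement then swap
  expect_equal(h$beta[h$snp_id == "rs4"], 0.2)   # complement, same order
  expect_true(all(h$effect_allele ==
                    panel_fixture$allele1[match(h$snp_id, panel_fixture$snp_id)]))

  # ambiguous kept (unflipped, matching) when drop_ambiguous is off
  h2 <- harmonise(rec, panel_fixture, drop_ambiguous = FALSE)
  expect_true("rs5" %in% h2$snp_id)

  # irreconcilable alleles dropped and counted
  rec_bad <- make_records("rs1", effect_allele = "A", other_allele = "C")
  h3 <- harmonise(rec_bad, panel_fixture)
  expect_equal(nrow(h3), 0)
  expect_equal(unname(attr(h3, "report")["dropped_unmatched"]), 1L)
})

test_that("harmonise is idempotent and flips negate the Z-score", {
  set.seed(42)
  n <- 50
  alleles <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  pick <- sample(4, n, replace = TRUE)
  panel <- data.frame(
    snp_id = sprintf("rs%03d", 1:n),
    allele1 = vapply(pick, function(i) alleles[[i]][1], character(1)),
    allele2 = vapply(pick, function(i) alleles[[i]][2], character(1)),
    chrom = "1", pos = (1:n) * 1000L, stringsAsFactors = FALSE
  )
  swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
  rec <- make_records(
    panel$snp_id,
    effect_allele = ifelse(swap, panel$allele2, panel$allele1),
    other_allele = ifelse(swap, panel$allele1, panel$allele2),
    beta = stats::rnorm(n), eaf = stats::runif(n)
  )
  h1 <- harmonise(rec, panel)
  h2 <- harmonise(h1, panel)
  expect_equal(h2$beta, h1$beta)
  expect_equal(h2$eaf, h1$eaf)
  expect_equal(unname(attr(h2, "report")["flipped"]), 0L)

  # swapped records give the negated Z relative to the original orientation
  z_orig <- stats::setNames(compute_z(rec), rec$snp_id)
  z_harm <- stats::setNames(compute_z(h1), h1$snp_id)
  expect_equal(z_harm[rec$snp_id[swap]], -z_orig[rec$snp_id[swap]])
  expect_equal(z_harm[rec$snp_id[!swap]], z_orig[rec$snp_id[!swap]])

  # output SNPs always a subset of the panel
  expect_true(all(h1$snp_id %in% panel$snp_id))
})
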