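# Evaluate component polygenic scores from summary statistics alone: derive
# signed PC-PGS weights, remove an overlapping cohort from one target by
# inverse-variance subtraction, compare analytic case/control score
# distributions with a Welch t-test, and contrast two case groups by
# case-case GWAS with Bonferroni control over three comparisons.

source("analysis/00_config.R")

study <- make_study()
zm <- utils::read.table(file.path(RESULTS_DIR, "zmatrix.tsv"),
                        header = TRUE, check.names = FALSE)
z <- as.matrix(zm[, -1])
rownames(z) <- zm$snp_id
d <- svd_decompose(zmatrix(z, z != 0, zm$snp_id, colnames(z)))

w1 <- pc_pgs_weights(d, 1, study$panel)
write_weights(w1, file.path(RESULTS_DIR, "pc1_weights.tsv"))

# two target cohorts whose case groups are shifted along +/- the component-1
# weights, and a small overlapping cohort folded into target A's discovery
# statistics
tcA <- generate_target_cohort(w1, 2000, 2000, effect_shift = 0.03,
                              seed = SEED + 21, panel = study$panel,
                              return_genotypes = FALSE)
tcB <- generate_target_cohort(w1, 2000, 2000, effect_shift = -0.03,
                              seed = SEED + 22, panel = study$panel,
                              return_genotypes = FALSE)
overlap <- generate_target_cohort(w1, 500, 500, effect_shift = 0,
                                  seed = SEED + 23, panel = study$panel,
                                  return_genotypes = FALSE)

res <- run_pipeline(study$sumstats, study$panel, study$ld,
                    config = default_config(),
                    targets = list(A = ivw_meta(tcA$records, overlap$records),
                                   B = tcB$records),
                    subtract = list(A = overlap$records),
                    ccgwas_pairs = list(c("A", "B")))

utils::write.table(res$pgs, file.path(RESULTS_DIR, "group_pgs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(res$ccgwas$A_vs_B,
                   file.path(RESULTS_DIR, "ccgwas_A_vs_B.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

p1 <- res$pgs[res$pgs$component == 1, ]
cat("component-1 PGS, case vs control (mean | SE | R2 | p):\n")
for (i in seq_len(nrow(p1))) {
  cat(sprintf("  target %s: %.3e | %.1e vs %.3e | %.1e | R2 %.3f | p %.2g\n",
              p1$target[i], p1$mean_a[i], p1$se_mean_a[i], p1$mean_b[i],
              p1$se_mean_b[i], p1$r2[i], p1$p_value[i]))
}

# the two case groups, contrasted directly through the case-case GWAS
gcc <- group_pgs(w1, res$ccgwas$A_vs_B, group_a = "cases_A",
                 group_b = "cases_B")
cat(sprintf("case-case comparison on component 1: t = %.1f, R2 = %.3f, p = %.2g; Bonferroni (0.05/3) significant: %s\n",
            gcc$t, gcc$r2, gcc$p_value,
            adjust_bonferroni(gcc$p_value, 3)))
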