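# Read the study back from disk, harmonise every trait onto the reference
# panel, and build the standardised SNP-by-disorder Z matrix: p < 1e-3
# zeroing, retention in >= 2 disorders, 500 kb / r2 0.2 priority clumping.

source("analysis/00_config.R")

panel <- read_reference_panel(file.path(STUDY_DIR, "panel.tsv"))
ld <- read_ld_table(file.path(STUDY_DIR, "ld.tsv"))
column_map <- c(snp_id = "snp_id", chrom = "chrom", pos = "pos",
                effect_allele = "effect_allele",
                other_allele = "other_allele", beta = "beta", se = "se",
                p_value = "p_value", eaf = "eaf", n_case = "n_case",
                n_control = "n_control")
files <- list.files(STUDY_DIR, pattern = "sumstats\\.tsv$",
                    full.names = TRUE)
sumstats <- lapply(files, read_sumstats, column_map = column_map)
names(sumstats) <- sub("\\.sumstats\\.tsv$", "", basename(files))

harmonised <- lapply(sumstats, harmonise, panel = panel)
for (tid in names(harmonised)) {
  cat(tid, ":", harmonisation_report(harmonised[[tid]]), "\n")
}

m <- assemble_matrix(harmonised, alpha = 1e-3)
cat("assembled:", nrow(m$z), "SNPs with any sub-threshold association\n")
m <- filter_min_traits(m, 2)
cat("retained in >= 2 disorders:", nrow(m$z), "SNPs\n")
m <- clump(m, ld, window_bp = 500000, r2_max = 0.2)
cat("after clumping:", nrow(m$z), "independent SNPs\n")
m <- standardise_columns(m)

write_zmatrix(m, file.path(RESULTS_DIR, "zmatrix.tsv"))
cat("standardised matrix written to", file.path(RESULTS_DIR, "zmatrix.tsv"),
    "\n")
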