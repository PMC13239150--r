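# Generate the synthetic multi-trait GWAS study that stands in for the
# consortium downloads: eight disorder GWAS sharing three planted latent
# components, written in the delimited formats the readers consume.

source("analysis/00_config.R")

study <- make_study()
paths <- write_study(study, STUDY_DIR)

cat("Synthetic study written to", STUDY_DIR, "\n")
cat("  traits:", length(study$sumstats),
    " SNPs:", nrow(study$panel),
    " LD pairs:", nrow(study$ld), "\n")
cat("  planted components at scales",
    paste(study$truth$factor_scales, collapse = "/"),
    "with noise SD", study$params$noise_sd, "\n")
sig <- vapply(study$sumstats, function(s) sum(s$p_value < 1e-3), integer(1))
cat("  SNPs at p < 1e-3 per trait:", paste(sig, collapse = " "), "\n")
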