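# Decompose the standardised matrix by SVD and derive the attribution
# statistics that characterise each latent component, checking recovery of
# the planted phenotype factors.

source("analysis/00_config.R")

zm <- utils::read.table(file.path(RESULTS_DIR, "zmatrix.tsv"),
                        header = TRUE, check.names = FALSE)
z <- as.matrix(zm[, -1])
rownames(z) <- zm$snp_id
m <- zmatrix(z, z != 0, zm$snp_id, colnames(z))

d <- svd_decompose(m)
st <- attribution_stats(d)

cat("variance explained (%):",
    paste(sprintf("%.1f", 100 * st$variance_explained), collapse = " "), "\n")
cat("reconstruction error:", format(max(abs(reconstruct(d) - m$z))), "\n")

study <- make_study()
congr <- match_congruence(study$truth$pheno_factors,
                          d$pheno_vectors[, 1:3, drop = FALSE])
cat("Tucker congruence with the planted phenotype factors:",
    paste(sprintf("%.3f", congr), collapse = " "), "\n")

wt <- function(x, name) utils::write.table(
  x, file.path(RESULTS_DIR, name), sep = "\t", quote = FALSE,
  row.names = FALSE)
wt(data.frame(component = seq_along(d$singular_values),
              singular_value = d$singular_values,
              variance_explained = st$variance_explained), "components.tsv")
wt(data.frame(trait = d$trait_ids, d$pheno_vectors), "pheno_vectors.tsv")
wt(data.frame(snp_id = d$snp_ids, d$snp_vectors), "snp_vectors.tsv")
wt(data.frame(trait = d$trait_ids, st$squared_cosines),
   "squared_cosines.tsv")
cat("component tables written under", RESULTS_DIR, "\n")
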