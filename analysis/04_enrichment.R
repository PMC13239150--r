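# Gene-set over-representation of the component-defining SNPs: take the
# SNPs cumulatively carrying 50% of each component's variance, map them to
# genes, and test annotated sets (20-500 genes) by the hypergeometric test
# with BH FDR.

source("analysis/00_config.R")

study <- make_study()
zm <- utils::read.table(file.path(RESULTS_DIR, "zmatrix.tsv"),
                        header = TRUE, check.names = FALSE)
z <- as.matrix(zm[, -1])
rownames(z) <- zm$snp_id
d <- svd_decompose(zmatrix(z, z != 0, zm$snp_id, colnames(z)))
st <- attribution_stats(d)

map <- generate_snp_gene_map(study$panel$snp_id, span = 5)
coll <- generate_gene_collections(map, study$truth, n_random = 20,
                                  set_size = 60, seed = SEED + 2)
coll <- filter_sets(coll, 20, 500)
cat("testing", length(coll$sets), "gene sets over a background of",
    length(coll$background), "genes\n")

for (k in 1:3) {
  top <- cumulative_top_snps(st, k, fraction = 0.5)
  genes <- map_snps_to_genes(top, map)
  res <- suppressWarnings(hypergeom_ora(genes, coll))
  hit <- res[res$fdr < 0.05, ]
  cat(sprintf("component %d: %d SNPs -> %d genes; %d sets at FDR < 0.05; top: %s (ratio %.1f, FDR %.2g)\n",
              k, length(top), length(genes), nrow(hit), res$set_name[1],
              res$enrichment_ratio[1], res$fdr[1]))
  utils::write.table(res,
                     file.path(RESULTS_DIR,
                               sprintf("enrichment_component_%d.tsv", k)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
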