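# allele pairs that are valid and not strand-ambiguous (no A/T, no C/G)
#' @keywords internal
.SAFE_PAIRS <- matrix(c(
  "A", "C", "A", "G", "C", "A", "C", "T",
  "G", "A", "G", "T", "T", "C", "T", "G"
), ncol = 2, byrow = TRUE)

#' Generate a planted low-rank factor model
#'
#' Defines the latent structure a decomposition of multi-trait GWAS
#' Z-scores is meant to recover: orthonormal phenotype factors, sparse SNP
#' factors with standard-normal nonzero entries, and per-component scales.
#' Deterministic given the seed.
#'
#' @param n_traits,n_snps,n_components dimensions with
#'   `n_components <= n_traits <= n_snps`.
#' @param sparsity probability that a SNP-factor entry is nonzero, in (0, 1].
#' @param scales positive per-component signal scales (length
#'   `n_components`).
#' @param seed integer RNG seed.
#' @return object of class `planted_model`: list with `pheno_factors`
#'   (n_traits x K, orthonormal columns), `snp_factors` (n_snps x K),
#'   `factor_scales`, dimensions and `seed`.
#' @export
generate_model <- function(n_traits = 8, n_snps = 2000, n_components = 3,
                           sparsity = 0.15, scales = c(10, 7, 5),
                           seed = 1) {
  if (!(n_components <= n_traits && n_traits <= n_snps)) {
    stop("need n_components <= n_traits <= n_snps")
  }
  stopifnot(sparsity > 0, sparsity <= 1,
            length(scales) == n_components, all(scales > 0))
  set.seed(seed)
  pheno <- qr.Q(qr(matrix(stats::rnorm(n_traits * n_components),
                          nrow = n_traits)))[, seq_len(n_components),
                                             drop = FALSE]
  nz <- matrix(stats::runif(n_snps * n_components) < sparsity,
               nrow = n_snps)
  snp <- matrix(stats::rnorm(n_snps * n_components), nrow = n_snps) * nz
  structure(
    list(n_traits = n_traits, n_snps = n_snps, n_components = n_components,
         pheno_factors = pheno, snp_factors = snp,
         factor_scales = scales, sparsity = sparsity, seed = seed),
    class = "planted_model"
  )
}

#' Block-structured LD table and SNP positions
#'
#' Consecutive SNPs are grouped into blocks; every pair within a block gets
#' r-squared `r2_within`, pairs across blocks 0 (absent from the table).
#' Positions are laid out on one synthetic chromosome so that a block spans
#' well under 500 kb while distinct blocks are more than 500 kb apart. The
#' layout carries no randomness; `seed` is accepted for signature
#' compatibility and ignored.
#'
#' @param n_snps number of SNPs (or a character vector of SNP ids).
#' @param block_size SNPs per block (last block may be smaller).
#' @param r2_within within-block r-squared in [0, 1].
#' @param seed ignored.
#' @param chrom chromosome label for the positions.
#' @return list with `ld` (data.frame `snp_a, snp_b, r2`) and `positions`
#'   (data.frame `snp_id, chrom, pos`).
#' @export
generate_ld_blocks <- function(n_snps, block_size = 5, r2_within = 0.8,
                               seed = NULL, chrom = "1") {
  stopifnot(block_size >= 1, r2_within >= 0, r2_within <= 1)
  if (is.character(n_snps)) {
    snp_ids <- n_snps
    n_snps <- length(snp_ids)
  } else {
    snp_ids <- sprintf("rs%06d", seq_len(n_snps))
  }
  block <- (seq_len(n_snps) - 1L) %/% block_size
  within <- (seq_len(n_snps) - 1L) %% block_size
  pos <- 1L + block * 1000000L + within * 1000L
  positions <- data.frame(snp_id = snp_ids, chrom = chrom, pos = pos,
                          stringsAsFactors = FALSE)
  pairs <- list()
  for (b in unique(block)) {
    members <- snp_ids[block == b]
    if (length(members) >= 2) {
      cmb <- utils::combn(members, 2)
      pairs[[length(pairs) + 1L]] <- data.frame(
        snp_a = cmb[1, ], snp_b = cmb[2, ], r2 = r2_within,
        stringsAsFactors = FALSE)
    }
  }
  ld <- if (length(pairs) > 0) do.call(rbind, pairs) else
    data.frame(snp_a = character(0), snp_b = character(0), r2 = numeric(0),
               stringsAsFactors = FALSE)
  list(ld = ld, positions = positions)
}

#' Generate a synthetic multi-trait GWAS study
#'
#' Builds per-trait summary statistics around a planted model. The true
#' Z-signal matrix is `snp_factors diag(scales) pheno_factors'`; observed
#' Z-scores add independent normal noise of SD `noise_sd`. P-values are
#' two-sided normal tails of the observed Z; betas are back-derived as
#' `z * se` with `se = 1 / sqrt(2 f (1 - f) n_eff)`,
#' `n_eff = 4 / (1/n_case + 1/n_control)` and per-SNP allele frequency `f`
#' drawn uniformly from `maf_range`. Alleles come from a generated
#' strand-unambiguous reference panel, so harmonisation keeps every record.
#'
#' @param model a [generate_model()] result.
#' @param n_per_trait named list (trait -> c(n_case, n_control)); default
#'   20000 cases / 30000 controls for every trait.
#' @param noise_sd SD of the additive noise on the Z scale.
#' @param maf_range range of the per-SNP effect-allele frequency.
#' @param block_size,r2_within LD-block layout (see [generate_ld_blocks()]).
#' @param seed integer RNG seed.
#' @return object of class `synthetic_study`: list with `sumstats` (named
#'   list of record tables), `panel`, `ld` (data.frame), `positions`,
#'   `z_true`, `z_obs`, `truth` (the model) and `params`.
#' @export
generate_sumstats <- function(model, n_per_trait = NULL, noise_sd = 1,
                              maf_range = c(0.05, 0.5), block_size = 5,
                              r2_within = 0.8, seed = model$seed + 1000L) {
  stopifnot(inherits(model, "planted_model"))
  n_snps <- model$n_snps
  n_traits <- model$n_traits
  trait_ids <- sprintf("trait%02d", seq_len(n_traits))
  if (is.null(n_per_trait)) {
    n_per_trait <- stats::setNames(
      rep(list(c(n_case = 20000, n_control = 30000)), n_traits), trait_ids)
  }
  stopifnot(length(n_per_trait) == n_traits)
  if (is.null(names(n_per_trait))) names(n_per_trait) <- trait_ids
  trait_ids <- names(n_per_trait)

  set.seed(seed)
  snp_ids <- sprintf("rs%06d", seq_len(n_snps))
  layout <- generate_ld_blocks(snp_ids, block_size = block_size,
                               r2_within = r2_within)
  pair_idx <- sample.int(nrow(.SAFE_PAIRS), n_snps, replace = TRUE)
  panel <- data.frame(
    snp_id = snp_ids,
    allele1 = .SAFE_PAIRS[pair_idx, 1],
    allele2 = .SAFE_PAIRS[pair_idx, 2],
    chrom = layout$positions$chrom,
    pos = layout$positions$pos,
    stringsAsFactors = FALSE
  )
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  z_true <- model$snp_factors %*% (model$factor_scales *
                                     t(model$pheno_factors))
  z_obs <- z_true + noise_sd * matrix(stats::rnorm(n_snps * n_traits),
                                      nrow = n_snps)
  colnames(z_true) <- colnames(z_obs) <- trait_ids
  rownames(z_true) <- rownames(z_obs) <- snp_ids

  sumstats <- stats::setNames(vector("list", n_traits), trait_ids)
  for (j in seq_len(n_traits)) {
    ns <- n_per_trait[[j]]
    n_eff <- 4 / (1 / ns[[1]] + 1 / ns[[2]])
    se <- 1 / sqrt(2 * maf * (1 - maf) * n_eff)
    z <- z_obs[, j]
    sumstats[[j]] <- data.frame(
      snp_id = snp_ids, chrom = panel$chrom, pos = panel$pos,
      effect_allele = panel$allele1, other_allele = panel$allele2,
      beta = z * se, se = se,
      p_value = pmin(1, 2 * stats::pnorm(-abs(z))),
      eaf = maf, n_case = ns[[1]], n_control = ns[[2]],
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(sumstats = sumstats, panel = panel, ld = layout$ld,
         positions = layout$positions, z_true = z_true, z_obs = z_obs,
         truth = model,
         params = list(noise_sd = noise_sd, maf_range = maf_range,
                       block_size = block_size, r2_within = r2_within,
                       seed = seed)),
    class = "synthetic_study"
  )
}

#' Interval-based SNP-to-gene map for a synthetic study
#'
#' Gene g_j owns `span` consecutive SNPs; each SNP maps to its owner gene
#' with the top variant-to-gene score, and every third SNP additionally maps
#' to the next gene with a transcription start site flagged within 100 kb.
#'
#' @param snp_ids character vector of SNP ids (layout order).
#' @param span SNPs per gene.
#' @return data.frame `snp_id, gene, v2g_score, within_100kb`.
#' @export
generate_snp_gene_map <- function(snp_ids, span = 5) {
  n <- length(snp_ids)
  owner <- (seq_len(n) - 1L) %/% span + 1L
  n_genes <- max(owner)
  gene_of <- function(j) sprintf("G%05d", j)
  map <- data.frame(
    snp_id = snp_ids, gene = gene_of(owner),
    v2g_score = 1, within_100kb = TRUE,
    stringsAsFactors = FALSE
  )
  extra_idx <- which(seq_len(n) %% 3L == 0L & owner < n_genes)
  if (length(extra_idx) > 0) {
    map <- rbind(map, data.frame(
      snp_id = snp_ids[extra_idx], gene = gene_of(owner[extra_idx] + 1L),
      v2g_score = 0.5, within_100kb = FALSE,
      stringsAsFactors = FALSE
    ))
  }
  map[order(map$snp_id, -map$v2g_score), , drop = FALSE]
}

#' Gene-set collections with sets enriched for planted components
#'
#' Builds one "planted" set per component from the genes of its
#' top-loading SNPs, plus random sets, over the background of all mapped
#' genes; exercises the over-representation analysis end to end.
#'
#' @param mapping a [generate_snp_gene_map()] table.
#' @param model the [generate_model()] truth.
#' @param n_random number of random sets.
#' @param set_size size of each random set.
#' @param top_snps how many top-loading SNPs seed each planted set.
#' @param seed integer RNG seed.
#' @return a [gene_set_collection()].
#' @export
generate_gene_collections <- function(mapping, model, n_random = 30,
                                      set_size = 40, top_snps = 150,
                                      seed = 1) {
  background <- sort(unique(mapping$gene))
  snp_order <- sort(unique(mapping$snp_id))
  set.seed(seed)
  sets <- list()
  for (k in seq_len(model$n_components)) {
    load <- abs(model$snp_factors[, k])
    top <- order(-load)[seq_len(min(top_snps, length(load)))]
    top_ids <- sprintf("rs%06d", top)
    genes <- mapping$gene[mapping$snp_id %in% top_ids]
    sets[[sprintf("planted_component_%d", k)]] <- unique(genes)
  }
  for (i in seq_len(n_random)) {
    sets[[sprintf("random_%03d", i)]] <-
      sample(background, min(set_size, length(background)))
  }
  gene_set_collection(sets, background)
}

#' Synthetic external GWAS driven by one planted component
#'
#' Per-SNP Z is `signal_scale` times the planted SNP factor of the chosen
#' component plus independent normal noise; records are laid over the
#' study's panel so they harmonise without drops.
#'
#' @param study a [generate_sumstats()] study.
#' @param component planted component index.
#' @param signal_scale multiplier on the planted SNP factor.
#' @param noise_sd SD of the additive Z noise.
#' @param n_case,n_control nominal sample sizes for the back-derived betas.
#' @param seed integer RNG seed.
#' @return a record table.
#' @export
generate_external_gwas <- function(study, component, signal_scale = 5,
                                   noise_sd = 1, n_case = 50000,
                                   n_control = 50000, seed = 1) {
  stopifnot(inherits(study, "synthetic_study"))
  model <- study$truth
  stopifnot(component >= 1, component <= model$n_components)
  set.seed(seed)
  n <- model$n_snps
  z <- signal_scale * model$snp_factors[, component] +
    noise_sd * stats::rnorm(n)
  maf <- study$sumstats[[1]]$eaf
  n_eff <- 4 / (1 / n_case + 1 / n_control)
  se <- 1 / sqrt(2 * maf * (1 - maf) * n_eff)
  data.frame(
    snp_id = study$panel$snp_id, chrom = study$panel$chrom,
    pos = study$panel$pos,
    effect_allele = study$panel$allele1, other_allele = study$panel$allele2,
    beta = z * se, se = se, p_value = pmin(1, 2 * stats::pnorm(-abs(z))),
    eaf = maf, n_case = n_case, n_control = n_control,
    stringsAsFactors = FALSE
  )
}

#' Simulate a target cohort and its case-control summary statistics
#'
#' Control allele frequencies are drawn uniformly in (0.2, 0.8); case
#' frequencies are shifted along each weight's sign by `effect_shift`
#' (clipped to (0.05, 0.95)). Genotypes for all individuals are drawn
#' binomial(2, f_group) per SNP, and the summary statistics (OR, Woolf SE,
#' p, allele frequency) are computed from the realised allelic counts, so
#' count reconstruction can be validated against the truth.
#'
#' @param weights a [pc_pgs_weights()] table.
#' @param n_case,n_control individuals per group.
#' @param effect_shift case-frequency shift per unit weight sign.
#' @param seed integer RNG seed.
#' @param freq_is which frequency the records report as `eaf`: the realised
#'   control frequency or the realised pooled frequency.
#' @param panel optional reference panel supplying alleles and positions;
#'   defaults to the weight set's effect allele with a constant other
#'   allele.
#' @param return_genotypes keep the individual-level genotype matrices.
#' @return list with `records` (summary statistics), `f_case_true`,
#'   `f_ctrl_true`, `f_case_obs`, `f_ctrl_obs`, and if requested
#'   `genotypes_case`, `genotypes_control` (individuals x SNPs, effect-allele
#'   dosage).
#' @export
generate_target_cohort <- function(weights, n_case, n_control,
                                   effect_shift = 0, seed = 1,
                                   freq_is = c("control", "pooled"),
                                   panel = NULL, return_genotypes = TRUE) {
  freq_is <- match.arg(freq_is)
  stopifnot(nrow(weights) > 0)
  m <- nrow(weights)
  set.seed(seed)
  f_ctrl <- stats::runif(m, 0.2, 0.8)
  f_case <- pmin(pmax(f_ctrl + effect_shift * sign(weights$weight), 0.05),
                 0.95)
  geno_case <- matrix(stats::rbinom(n_case * m, 2L, rep(f_case, each = n_case)),
                      nrow = n_case)
  geno_ctrl <- matrix(stats::rbinom(n_control * m, 2L,
                                    rep(f_ctrl, each = n_control)),
                      nrow = n_control)
  a <- colSums(geno_case)
  c_ <- colSums(geno_ctrl)
  b <- 2 * n_case - a
  d <- 2 * n_control - c_
  or <- (a * d) / (b * c_)
  beta <- log(or)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  f_case_obs <- a / (2 * n_case)
  f_ctrl_obs <- c_ / (2 * n_control)
  eaf <- if (freq_is == "control") f_ctrl_obs else
    (a + c_) / (2 * (n_case + n_control))
  if (is.null(panel)) {
    chrom <- "1"
    pos <- seq_len(m)
    effect_allele <- weights$effect_allele
    other_allele <- ifelse(weights$effect_allele == "A", "G", "A")
  } else {
    idx <- match(weights$snp_id, panel$snp_id)
    chrom <- panel$chrom[idx]
    pos <- panel$pos[idx]
    effect_allele <- panel$allele1[idx]
    other_allele <- panel$allele2[idx]
  }
  records <- data.frame(
    snp_id = weights$snp_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    beta = beta, se = se,
    p_value = pmin(1, 2 * stats::pnorm(-abs(beta / se))),
    eaf = eaf, n_case = n_case, n_control = n_control,
    stringsAsFactors = FALSE
  )
  out <- list(records = records, f_case_true = f_case, f_ctrl_true = f_ctrl,
              f_case_obs = f_case_obs, f_ctrl_obs = f_ctrl_obs,
              freq_is = freq_is)
  if (return_genotypes) {
    out$genotypes_case <- geno_case
    out$genotypes_control <- geno_ctrl
  }
  out
}

#' Write a synthetic study to disk in the formats the readers consume
#'
#' Per-trait sumstats, the reference panel and the LD table as tab-delimited
#' text, plus a manifest recording the seeds and parameters.
#'
#' @param study a [generate_sumstats()] study.
#' @param dir output directory (created if absent).
#' @return named list of written paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (tid in names(study$sumstats)) {
    p <- file.path(dir, paste0(tid, ".sumstats.tsv"))
    utils::write.table(study$sumstats[[tid]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[[tid]] <- p
  }
  paths$panel <- file.path(dir, "panel.tsv")
  utils::write.table(study$panel, paths$panel, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$ld <- file.path(dir, "ld.tsv")
  utils::write.table(study$ld, paths$ld, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$manifest <- file.path(dir, "manifest.txt")
  manifest <- c(
    paste0("model_seed: ", study$truth$seed),
    paste0("study_seed: ", study$params$seed),
    paste0("n_traits: ", study$truth$n_traits),
    paste0("n_snps: ", study$truth$n_snps),
    paste0("n_components: ", study$truth$n_components),
    paste0("scales: ", paste(study$truth$factor_scales, collapse = ",")),
    paste0("sparsity: ", study$truth$sparsity),
    paste0("noise_sd: ", study$params$noise_sd),
    paste0("maf_range: ", paste(study$params$maf_range, collapse = ",")),
    paste0("block_size: ", study$params$block_size),
    paste0("r2_within: ", study$params$r2_within)
  )
  writeLines(manifest, paths$manifest)
  paths
}
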