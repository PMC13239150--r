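# In-code fixtures shared across test files.

# A record table with sensible defaults, overridable per column.
make_records <- function(snp_id, ...) {
  n <- length(snp_id)
  defaults <- list(
    chrom = rep("1", n), pos = seq_len(n) * 1000L,
    effect_allele = rep("A", n), other_allele = rep("G", n),
    beta = rep(0.1, n), se = rep(0.05, n), p_value = rep(1e-4, n),
    eaf = rep(0.3, n), n_case = rep(10000, n), n_control = rep(10000, n)
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(data.frame,
          c(list(snp_id = snp_id, stringsAsFactors = FALSE), defaults))
}

# Exact case-control summary statistics implied by known group frequencies
# (beta is the log allelic odds ratio; eaf reports the control or pooled
# frequency). Used to validate reconstruction against the generating truth.
records_from_freqs <- function(f_case, f_ctrl, n_case, n_control,
                               freq_is = "control",
                               snp_id = sprintf("rs%06d", seq_along(f_case))) {
  or <- (f_case / (1 - f_case)) / (f_ctrl / (1 - f_ctrl))
  eaf <- if (freq_is == "control") f_ctrl else
    (n_case * f_case + n_control * f_ctrl) / (n_case + n_control)
  make_records(snp_id, beta = log(or), se = 0.05, eaf = eaf,
               n_case = n_case, n_control = n_control)
}

# Hand-built decomposition object for attribution-statistic tests.
make_decomposition <- function(u, d, v,
                               snp_ids = paste0("s", seq_len(nrow(u))),
                               trait_ids = paste0("t", seq_len(nrow(v)))) {
  structure(
    list(snp_vectors = u, singular_values = d, pheno_vectors = v,
         snp_ids = snp_ids, trait_ids = trait_ids),
    class = "pc_decomposition"
  )
}

# A random clumping instance: SNPs scattered over two chromosomes with
# random LD pairs among close neighbours and random priorities.
random_clump_instance <- function(seed) {
  set.seed(seed)
  n <- sample(20:100, 1)
  snp_id <- sprintf("rs%04d", sample(9999, n))
  chrom <- sample(c("1", "2"), n, replace = TRUE)
  pos <- sample.int(3e6, n)
  n_hits <- sample(1:8, n, replace = TRUE)
  z <- matrix(stats::rnorm(n * 4), nrow = n)
  mask <- matrix(FALSE, nrow = n, ncol = 4)
  for (i in seq_len(n)) mask[i, seq_len(min(n_hits[i], 4))] <- TRUE
  # make the mask count equal n_hits via extra columns when n_hits > 4
  extra <- matrix(FALSE, nrow = n, ncol = 4)
  for (i in seq_len(n)) if (n_hits[i] > 4) extra[i, seq_len(n_hits[i] - 4)] <- TRUE
  mask <- cbind(mask, extra)
  z <- cbind(z, matrix(stats::rnorm(n * 4), nrow = n))
  # random LD among pairs within 750 kb on the same chromosome
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (chrom[i] == chrom[j] && abs(pos[i] - pos[j]) <= 750000 &&
          stats::runif(1) < 0.5) {
        pairs[[length(pairs) + 1L]] <-
          data.frame(snp_a = snp_id[i], snp_b = snp_id[j],
                     r2 = stats::runif(1), stringsAsFactors = FALSE)
      }
    }
  }
  ld_pairs <- if (length(pairs) > 0) do.call(rbind, pairs) else
    data.frame(snp_a = character(0), snp_b = character(0), r2 = numeric(0))
  positions <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                          stringsAsFactors = FALSE)
  m <- zmatrix(z, mask, snp_id, paste0("t", 1:8), positions = positions)
  cand <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                     n_hits = rowSums(mask),
                     max_abs_z = apply(abs(z), 1, max),
                     stringsAsFactors = FALSE)
  list(m = m, ld_pairs = ld_pairs, cand = cand)
}

# A small end-to-end synthetic study shared by slower tests.
small_study <- function(seed = 7, n_snps = 600) {
  model <- generate_model(n_traits = 6, n_snps = n_snps, n_components = 2,
                          sparsity = 0.2, scales = c(10, 6), seed = seed)
  generate_sumstats(model, seed = seed + 1)
}
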