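#' Component polygenic-score weights
#'
#' The weight of each SNP for a component's polygenic score is its signed
#' entry in the component's SNP singular vector, oriented to the reference
#' panel's first allele. A squared-contribution variant (weights equal to
#' the SNP's contribution, losing direction of effect) is available behind
#' `squared` for comparison.
#'
#' @param d a `pc_decomposition`.
#' @param k component index.
#' @param panel reference panel data.frame; effect alleles are taken from its
#'   `allele1` column.
#' @param squared use squared contributions instead of signed loadings.
#' @return data.frame with columns `snp_id, effect_allele, weight` and
#'   attribute `component`.
#' @export
pc_pgs_weights <- function(d, k, panel, squared = FALSE) {
  stopifnot(inherits(d, "pc_decomposition"),
            k >= 1, k <= length(d$singular_values))
  idx <- match(d$snp_ids, panel$snp_id)
  if (anyNA(idx)) {
    stop("decomposition SNP absent from panel: ",
         d$snp_ids[which(is.na(idx))[1]])
  }
  w <- d$snp_vectors[, k]
  if (squared) w <- w^2 / sum(w^2)
  out <- data.frame(
    snp_id = d$snp_ids,
    effect_allele = panel$allele1[idx],
    weight = w,
    stringsAsFactors = FALSE
  )
  attr(out, "component") <- k
  out
}

#' Write a weight set as a 3-column score file
#'
#' @param weights output of [pc_pgs_weights()].
#' @param path output path (tab-delimited: snp_id, effect_allele, weight).
#' @export
write_weights <- function(weights, path) {
  utils::write.table(weights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Inverse-variance meta-analysis of two record tables
#'
#' Fixed-effect inverse-variance meta over the shared SNPs, used to set up
#' overlap-subtraction scenarios. Sample sizes are summed.
#'
#' @param a,b harmonised record tables with identical allele orientation.
#' @return record table of the shared SNPs with meta beta/SE/p.
#' @export
ivw_meta <- function(a, b) {
  shared <- intersect(a$snp_id, b$snp_id)
  ia <- match(shared, a$snp_id)
  ib <- match(shared, b$snp_id)
  wa <- 1 / a$se[ia]^2
  wb <- 1 / b$se[ib]^2
  beta <- (wa * a$beta[ia] + wb * b$beta[ib]) / (wa + wb)
  se <- 1 / sqrt(wa + wb)
  out <- a[ia, , drop = FALSE]
  out$beta <- beta
  out$se <- se
  out$p_value <- 2 * stats::pnorm(-abs(beta / se))
  out$n_case <- a$n_case[ia] + b$n_case[ib]
  out$n_control <- a$n_control[ia] + b$n_control[ib]
  rownames(out) <- NULL
  out
}

#' Subtract a cohort from an inverse-variance meta-analysis
#'
#' Removes one cohort's contribution from fixed-effect inverse-variance
#' meta-analysed summary statistics, eliminating sample overlap with a
#' target dataset: beta = (w_m b_m - w_c b_c) / (w_m - w_c),
#' SE = (w_m - w_c)^(-1/2) with w = 1/SE^2; p recomputed from the normal.
#' SNPs where the cohort's weight is not smaller than the meta's are dropped
#' with a warning, as are SNPs absent from either table.
#'
#' @param meta,cohort harmonised record tables with identical allele
#'   orientation (matched by `snp_id`).
#' @return record table of the surviving SNPs with subtracted beta/SE/p and
#'   attribute `n_dropped` (degenerate subtractions).
#' @export
meta_subtract <- function(meta, cohort) {
  shared <- intersect(meta$snp_id, cohort$snp_id)
  im <- match(shared, meta$snp_id)
  ic <- match(shared, cohort$snp_id)
  wm <- 1 / meta$se[im]^2
  wc <- 1 / cohort$se[ic]^2
  ok <- wm > wc
  if (any(!ok)) {
    warning(sum(!ok), " SNPs dropped: cohort weight >= meta weight")
  }
  im <- im[ok]
  ic <- ic[ok]
  w_diff <- wm[ok] - wc[ok]
  beta <- (wm[ok] * meta$beta[im] - wc[ok] * cohort$beta[ic]) / w_diff
  se <- w_diff^(-0.5)
  out <- meta[im, , drop = FALSE]
  out$beta <- beta
  out$se <- se
  out$p_value <- 2 * stats::pnorm(-abs(beta / se))
  nc <- meta$n_case[im] - cohort$n_case[ic]
  nt <- meta$n_control[im] - cohort$n_control[ic]
  out$n_case <- ifelse(is.na(nc) | nc < 0, NA_real_, nc)
  out$n_control <- ifelse(is.na(nt) | nt < 0, NA_real_, nt)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Reconstruct case/control allelic counts from summary statistics
#'
#' Recovers the 2x2 allelic count table per SNP from the odds ratio, allele
#' frequency and sample sizes. With `freq_is = "control"` the reported eaf is
#' the control frequency and the case frequency follows from the odds ratio;
#' with `freq_is = "pooled"` the eaf is the pooled frequency and the control
#' frequency solves the implied quadratic, taking the root with both
#' frequencies in (0, 1). SNPs with no valid root, or missing eaf or sample
#' sizes, are dropped with a warning.
#'
#' @param records harmonised record table with `eaf`, `n_case`, `n_control`.
#' @param freq_is interpretation of `eaf`: `"control"` or `"pooled"`.
#' @return data.frame with columns `snp_id, f_case, f_ctrl, a, b, c, d,
#'   n_case, n_control` (a/b: effect/other allele counts in cases; c/d in
#'   controls) and attribute `n_dropped`.
#' @export
reconstruct_counts <- function(records, freq_is = c("control", "pooled")) {
  freq_is <- match.arg(freq_is)
  usable <- is.finite(records$eaf) & records$eaf > 0 & records$eaf < 1 &
    is.finite(records$n_case) & records$n_case > 0 &
    is.finite(records$n_control) & records$n_control > 0 &
    is.finite(records$beta)
  rec <- records[usable, , drop = FALSE]
  or <- exp(rec$beta)
  if (freq_is == "control") {
    f_ctrl <- rec$eaf
    f_case <- or * f_ctrl / (1 - f_ctrl + or * f_ctrl)
  } else {
    f_ctrl <- .solve_pooled_fctrl(or, rec$eaf, rec$n_case, rec$n_control)
    f_case <- or * f_ctrl / (1 - f_ctrl + or * f_ctrl)
  }
  valid <- is.finite(f_ctrl) & is.finite(f_case) &
    f_ctrl > 0 & f_ctrl < 1 & f_case > 0 & f_case < 1
  n_dropped <- sum(!usable) + sum(!valid)
  if (any(!valid) || any(!usable)) {
    warning(n_dropped, " SNPs dropped during count reconstruction")
  }
  rec <- rec[valid, , drop = FALSE]
  f_case <- f_case[valid]
  f_ctrl <- f_ctrl[valid]
  out <- data.frame(
    snp_id = rec$snp_id,
    f_case = f_case, f_ctrl = f_ctrl,
    a = 2 * rec$n_case * f_case, b = 2 * rec$n_case * (1 - f_case),
    c = 2 * rec$n_control * f_ctrl, d = 2 * rec$n_control * (1 - f_ctrl),
    n_case = rec$n_case, n_control = rec$n_control,
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

# control frequency solving n_case f_case + n_control f_ctrl = N f_pool with
# f_case = OR f / (1 - f + OR f); quadratic in f_ctrl, linear when OR = 1
#' @keywords internal
.solve_pooled_fctrl <- function(or, f_pool, n_case, n_control) {
  n_tot <- n_case + n_control
  qa <- n_control * (or - 1)
  qb <- n_control + n_case * or - n_tot * f_pool * (or - 1)
  qc <- -n_tot * f_pool
  out <- rep(NA_real_, length(or))
  lin <- abs(qa) < 1e-12
  out[lin] <- f_pool[lin]
  qu <- !lin
  disc <- qb[qu]^2 - 4 * qa[qu] * qc[qu]
  disc[disc < 0] <- NA_real_
  r1 <- (-qb[qu] + sqrt(disc)) / (2 * qa[qu])
  r2 <- (-qb[qu] - sqrt(disc)) / (2 * qa[qu])
  pick <- ifelse(is.finite(r1) & r1 > 0 & r1 < 1, r1,
                 ifelse(is.finite(r2) & r2 > 0 & r2 < 1, r2, NA_real_))
  out[qu] <- pick
  out
}

#' Proportion of variance explained from a t-statistic
#'
#' @param t t-statistic.
#' @param df degrees of freedom (> 0).
#' @return t^2 / (t^2 + df).
#' @export
r2_from_t <- function(t, df) {
  stopifnot(all(df > 0))
  t^2 / (t^2 + df)
}

#' Group-wise polygenic score from summary statistics
#'
#' Reconstructs group allele frequencies from the target GWAS and computes
#' the analytic per-individual mean and standard deviation of the component
#' polygenic score in each group under Hardy-Weinberg sampling, treating
#' post-clumping SNPs as independent:
#' mean_g = (1/M) sum_i 2 f_gi w_i and
#' sd_g = (1/M) sqrt(sum_i w_i^2 2 f_gi (1 - f_gi)), with M the number of
#' SNPs used. Groups are compared with a Welch two-sample t-test
#' (Welch-Satterthwaite df) and R^2 = t^2 / (t^2 + df).
#'
#' @param weights a [pc_pgs_weights()] table.
#' @param target harmonised record table of the target GWAS (same allele
#'   orientation as the weights).
#' @param freq_is interpretation of the target's `eaf` (see
#'   [reconstruct_counts()]).
#' @param group_a,group_b labels for the two groups (cases, controls).
#' @return one-row data.frame with `group_a, group_b, n_snps, mean_a, mean_b,
#'   sd_a, sd_b, se_mean_a, se_mean_b, n_a, n_b, t, df, p_value, r2`.
#' @export
group_pgs <- function(weights, target, freq_is = c("control", "pooled"),
                      group_a = "cases", group_b = "controls") {
  freq_is <- match.arg(freq_is)
  shared <- intersect(weights$snp_id, target$snp_id)
  if (length(shared) == 0) {
    stop("no SNP shared between weight set and target GWAS")
  }
  n_missing <- length(setdiff(weights$snp_id, target$snp_id))
  tgt <- target[match(shared, target$snp_id), , drop = FALSE]
  counts <- suppressWarnings(reconstruct_counts(tgt, freq_is = freq_is))
  if (nrow(counts) == 0) stop("no reconstructable SNP in target GWAS")
  w <- weights$weight[match(counts$snp_id, weights$snp_id)]
  m <- nrow(counts)
  mean_a <- sum(2 * counts$f_case * w) / m
  mean_b <- sum(2 * counts$f_ctrl * w) / m
  var_a <- sum(w^2 * 2 * counts$f_case * (1 - counts$f_case)) / m^2
  var_b <- sum(w^2 * 2 * counts$f_ctrl * (1 - counts$f_ctrl)) / m^2
  n_a <- counts$n_case[1]
  n_b <- counts$n_control[1]
  sa2 <- var_a / n_a
  sb2 <- var_b / n_b
  t <- (mean_a - mean_b) / sqrt(sa2 + sb2)
  df <- (sa2 + sb2)^2 / (sa2^2 / (n_a - 1) + sb2^2 / (n_b - 1))
  out <- data.frame(
    group_a = group_a, group_b = group_b, n_snps = m,
    mean_a = mean_a, mean_b = mean_b,
    sd_a = sqrt(var_a), sd_b = sqrt(var_b),
    se_mean_a = sqrt(sa2), se_mean_b = sqrt(sb2),
    n_a = n_a, n_b = n_b,
    t = t, df = df,
    p_value = 2 * stats::pt(-abs(t), df = df),
    r2 = r2_from_t(t, df),
    stringsAsFactors = FALSE
  )
  attr(out, "n_missing") <- n_missing
  out
}

#' Case-case GWAS from two case-control GWAS
#'
#' For each shared SNP, case allele frequencies of both disorders are
#' reconstructed from their case-control summary statistics; the case-case
#' odds ratio is the ratio of the two case-allele odds, with the Woolf SE
#' sqrt(1/a_A + 1/b_A + 1/a_B + 1/b_B) on the reconstructed case counts and
#' a normal p-value. SNPs monomorphic after reconstruction are dropped.
#'
#' The output records are oriented so that group A's cases play the role of
#' cases and group B's cases the role of controls (eaf is B's case
#' frequency), so the standard control-frequency reconstruction recovers
#' both case-group frequencies downstream.
#'
#' @param gwas_a,gwas_b harmonised record tables of the two case-control
#'   GWAS (same panel orientation).
#' @param freq_is interpretation of each GWAS's `eaf` (see
#'   [reconstruct_counts()]).
#' @return record table of case-case associations.
#' @export
cc_gwas <- function(gwas_a, gwas_b, freq_is = c("control", "pooled")) {
  freq_is <- match.arg(freq_is)
  shared <- intersect(gwas_a$snp_id, gwas_b$snp_id)
  if (length(shared) == 0) stop("no SNP shared between the two GWAS")
  ra <- gwas_a[match(shared, gwas_a$snp_id), , drop = FALSE]
  rb <- gwas_b[match(shared, gwas_b$snp_id), , drop = FALSE]
  ca <- suppressWarnings(reconstruct_counts(ra, freq_is = freq_is))
  cb <- suppressWarnings(reconstruct_counts(rb, freq_is = freq_is))
  shared2 <- intersect(ca$snp_id, cb$snp_id)
  ca <- ca[match(shared2, ca$snp_id), , drop = FALSE]
  cb <- cb[match(shared2, cb$snp_id), , drop = FALSE]
  eps <- .Machine$double.eps
  poly <- ca$f_case > eps & ca$f_case < 1 - eps &
    cb$f_case > eps & cb$f_case < 1 - eps
  ca <- ca[poly, , drop = FALSE]
  cb <- cb[poly, , drop = FALSE]
  or <- (ca$f_case / (1 - ca$f_case)) / (cb$f_case / (1 - cb$f_case))
  beta <- log(or)
  se <- sqrt(1 / ca$a + 1 / ca$b + 1 / cb$a + 1 / cb$b)
  ia <- match(ca$snp_id, gwas_a$snp_id)
  out <- gwas_a[ia, , drop = FALSE]
  out$beta <- beta
  out$se <- se
  out$p_value <- 2 * stats::pnorm(-abs(beta / se))
  out$eaf <- cb$f_case
  out$n_case <- ca$n_case
  out$n_control <- cb$n_case
  rownames(out) <- NULL
  out
}

#' Bonferroni significance flags
#'
#' @param p_values numeric vector.
#' @param m number of independent comparisons.
#' @param alpha family-wise error rate (default 0.05).
#' @return logical vector: `TRUE` where p < alpha / m.
#' @export
adjust_bonferroni <- function(p_values, m, alpha = 0.05) {
  stopifnot(m >= 1)
  p_values < alpha / m
}
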