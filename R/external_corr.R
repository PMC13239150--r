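#' Correlate component SNP-loading Z-scores with an external GWAS
#'
#' Pearson correlation over the SNP intersection between the component's
#' loading Z-scores and the external GWAS Z-scores; SNPs missing from the
#' external GWAS are excluded, not zero-filled. Two-sided p from the t
#' transform t = r sqrt((n-2)/(1-r^2)) with n-2 degrees of freedom.
#'
#' @param pc_z named numeric vector (SNP id -> loading Z-score), e.g. from
#'   [loading_zscores()].
#' @param external harmonised record table of the external GWAS, aligned to
#'   the same panel and allele orientation as the matrix.
#' @param component,trait labels carried into the result.
#' @return one-row data.frame with `component, trait, n_snps, r, p_value`.
#' @export
correlate_component <- function(pc_z, external, component = NA_integer_,
                                trait = NA_character_) {
  ext_z <- stats::setNames(compute_z(external), external$snp_id)
  shared <- intersect(names(pc_z), names(ext_z))
  if (length(shared) < 3) {
    stop("fewer than 3 shared SNPs with external trait ", trait)
  }
  x <- pc_z[shared]
  y <- ext_z[shared]
  n <- length(shared)
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  data.frame(component = component, trait = trait, n_snps = n,
             r = r, p_value = p, stringsAsFactors = FALSE)
}

#' Component-by-trait correlation grid
#'
#' All component x external-trait Pearson correlations, with
#' Benjamini-Hochberg FDR computed across the full grid.
#'
#' @param decomp_z list (component index -> named loading Z-score vector) or
#'   a `pc_decomposition`, in which case [loading_zscores()] is applied to
#'   every component.
#' @param externals named list (trait -> harmonised record table).
#' @return long-format data.frame with one row per component-trait pair and
#'   columns `component, trait, n_snps, r, p_value, fdr`.
#' @export
correlation_grid <- function(decomp_z, externals) {
  if (inherits(decomp_z, "pc_decomposition")) {
    ks <- seq_along(decomp_z$singular_values)
    decomp_z <- lapply(ks, function(k) loading_zscores(decomp_z, k))
  }
  stopifnot(length(decomp_z) >= 1, length(externals) >= 1,
            !is.null(names(externals)))
  rows <- list()
  for (k in seq_along(decomp_z)) {
    for (tr in names(externals)) {
      rows[[length(rows) + 1L]] <- correlate_component(
        decomp_z[[k]], externals[[tr]], component = k, trait = tr)
    }
  }
  grid <- do.call(rbind, rows)
  grid$fdr <- stats::p.adjust(grid$p_value, method = "BH")
  rownames(grid) <- NULL
  grid
}
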