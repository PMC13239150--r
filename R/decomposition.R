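#' Singular value decomposition of the Z-score matrix
#'
#' Decomposes the standardised SNP-by-trait matrix into SNP singular vectors,
#' singular values and phenotype singular vectors, keeping all
#' K = n_traits components. Component signs are canonicalised so that each
#' component's largest-magnitude phenotype loading is positive.
#'
#' @param m a [zmatrix()] or a plain numeric matrix with more rows than
#'   columns.
#' @return an object of class `pc_decomposition`: list with `snp_vectors`
#'   (n_snps x K), `singular_values` (length K, non-increasing),
#'   `pheno_vectors` (n_traits x K), `snp_ids`, `trait_ids`.
#' @export
svd_decompose <- function(m) {
  if (inherits(m, "zmatrix")) {
    z <- m$z
    snp_ids <- m$snp_ids
    trait_ids <- m$trait_ids
  } else {
    z <- as.matrix(m)
    snp_ids <- rownames(z)
    trait_ids <- colnames(z)
    if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(nrow(z)))
    if (is.null(trait_ids)) trait_ids <- paste0("trait", seq_len(ncol(z)))
  }
  if (!all(is.finite(z))) stop("matrix contains non-finite entries")
  stopifnot(nrow(z) >= ncol(z), ncol(z) >= 2)
  s <- svd(z)
  d <- structure(
    list(snp_vectors = s$u, singular_values = s$d, pheno_vectors = s$v,
         snp_ids = snp_ids, trait_ids = trait_ids),
    class = "pc_decomposition"
  )
  canonicalise_signs(d)
}

#' Canonicalise component signs
#'
#' The SVD leaves each component's sign arbitrary. For each component, if the
#' phenotype loading of largest magnitude is negative, both the phenotype and
#' the matching SNP singular-vector columns are negated; the reconstruction
#' is unchanged.
#'
#' @param d a `pc_decomposition`.
#' @return the sign-canonicalised decomposition.
#' @export
canonicalise_signs <- function(d) {
  stopifnot(inherits(d, "pc_decomposition"))
  for (k in seq_along(d$singular_values)) {
    v <- d$pheno_vectors[, k]
    if (v[which.max(abs(v))] < 0) {
      d$pheno_vectors[, k] <- -v
      d$snp_vectors[, k] <- -d$snp_vectors[, k]
    }
  }
  d
}

#' @export
print.pc_decomposition <- function(x, ...) {
  cat("Decomposition:", length(x$snp_ids), "SNPs x", length(x$trait_ids),
      "traits,", length(x$singular_values), "components\n")
  cat("variance explained:",
      paste0(round(100 * variance_explained(x$singular_values), 1), "%",
             collapse = " "), "\n")
  invisible(x)
}

#' Reconstruct the matrix from a decomposition
#'
#' @param d a `pc_decomposition`.
#' @return numeric matrix U diag(s) V'.
#' @export
reconstruct <- function(d) {
  d$snp_vectors %*% (d$singular_values * t(d$pheno_vectors))
}

#' Fraction of variance explained by each component
#'
#' The variance explained by a component is the ratio of its squared singular
#' value to the sum of all squared singular values.
#'
#' @param singular_values non-negative numeric vector (or a
#'   `pc_decomposition`).
#' @return numeric vector of fractions summing to 1.
#' @export
variance_explained <- function(singular_values) {
  if (inherits(singular_values, "pc_decomposition")) {
    singular_values <- singular_values$singular_values
  }
  stopifnot(all(singular_values >= 0))
  tot <- sum(singular_values^2)
  if (tot == 0) stop("all singular values are zero")
  singular_values^2 / tot
}

#' Contributions of rows to components
#'
#' The contribution of a SNP (or phenotype) to a component is the squared
#' entry of the corresponding unit-norm singular-vector column; each column
#' of the result sums to 1.
#'
#' @param vectors matrix with unit-norm columns.
#' @return matrix of squared entries.
#' @export
contributions <- function(vectors) {
  vectors^2
}

#' Squared cosines of phenotypes on components
#'
#' The share of one phenotype's representation attributable to each
#' component, computed on singular-value-scaled loadings:
#' cos2(t, k) = (v_tk d_k)^2 / sum_j (v_tj d_j)^2. Rows sum to 1.
#'
#' @param d a `pc_decomposition`.
#' @return n_traits x K matrix.
#' @export
squared_cosines <- function(d) {
  stopifnot(inherits(d, "pc_decomposition"))
  sc <- sweep(d$pheno_vectors, 2, d$singular_values, "*")^2
  tot <- rowSums(sc)
  if (any(tot <= 0)) {
    stop("trait with all-zero projections: ",
         paste(d$trait_ids[tot <= 0], collapse = ", "))
  }
  sweep(sc, 1, tot, "/")
}

#' All attribution statistics of a decomposition
#'
#' @param d a `pc_decomposition`.
#' @return list with `variance_explained`, `snp_contribution`,
#'   `pheno_contribution`, `squared_cosines`.
#' @export
attribution_stats <- function(d) {
  stopifnot(inherits(d, "pc_decomposition"))
  snp_c <- contributions(d$snp_vectors)
  pheno_c <- contributions(d$pheno_vectors)
  sc <- squared_cosines(d)
  rownames(snp_c) <- d$snp_ids
  rownames(pheno_c) <- rownames(sc) <- d$trait_ids
  list(
    variance_explained = variance_explained(d$singular_values),
    snp_contribution = snp_c,
    pheno_contribution = pheno_c,
    squared_cosines = sc
  )
}

#' SNP-loading Z-scores for one component
#'
#' The component's SNP loadings standardised to mean 0, SD 1 across SNPs
#' (population SD convention), used downstream for correlation with external
#' GWAS Z-scores.
#'
#' @param d a `pc_decomposition`.
#' @param k component index.
#' @return named numeric vector (names are SNP ids).
#' @export
loading_zscores <- function(d, k) {
  stopifnot(inherits(d, "pc_decomposition"),
            k >= 1, k <= length(d$singular_values))
  v <- d$snp_vectors[, k]
  sdev <- sqrt(mean((v - mean(v))^2))
  if (sdev <= 0) stop("zero-variance loading column for component ", k)
  stats::setNames((v - mean(v)) / sdev, d$snp_ids)
}

#' SNPs cumulatively accounting for a fraction of a component's variance
#'
#' SNPs are sorted by their contribution to the component (descending, ties
#' broken by SNP id); the shortest prefix whose contribution sum reaches
#' `fraction` is returned.
#'
#' @param stats output of [attribution_stats()] (or a `pc_decomposition`).
#' @param k component index.
#' @param fraction cumulative contribution target in (0, 1].
#' @return character vector of SNP ids, in contribution order.
#' @export
cumulative_top_snps <- function(stats, k, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  if (inherits(stats, "pc_decomposition")) {
    snp_ids <- stats$snp_ids
    contrib <- contributions(stats$snp_vectors)[, k]
  } else {
    snp_ids <- rownames(stats$snp_contribution)
    if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(nrow(stats$snp_contribution)))
    contrib <- stats$snp_contribution[, k]
  }
  ord <- order(-contrib, snp_ids)
  csum <- cumsum(contrib[ord])
  n_take <- which(csum >= fraction - 1e-12)[1]
  if (is.na(n_take)) n_take <- length(ord)
  snp_ids[ord[seq_len(n_take)]]
}

#' Tucker congruence between two factor vectors
#'
#' Cosine similarity sum(a b) / sqrt(sum(a^2) sum(b^2)); used to score
#' recovery of planted factors.
#'
#' @param a,b numeric vectors of equal length.
#' @return numeric scalar in [-1, 1].
#' @export
tucker_congruence <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Match planted factors to recovered singular vectors
#'
#' For each planted factor column, the absolute Tucker congruence with its
#' best-matching recovered column.
#'
#' @param planted matrix of planted factor columns.
#' @param recovered matrix of recovered singular-vector columns.
#' @return numeric vector, one absolute congruence per planted column.
#' @export
match_congruence <- function(planted, recovered) {
  vapply(seq_len(ncol(planted)), function(k) {
    max(vapply(seq_len(ncol(recovered)), function(j) {
      abs(tucker_congruence(planted[, k], recovered[, j]))
    }, numeric(1)))
  }, numeric(1))
}
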