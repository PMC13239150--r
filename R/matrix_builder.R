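#' Construct a SNP-by-trait Z-score matrix object
#'
#' @param z numeric matrix (SNPs x traits).
#' @param mask logical matrix of the same dimension; `TRUE` where the entry
#'   carried a sub-threshold association before any standardisation.
#' @param snp_ids,trait_ids row / column identifiers.
#' @param positions data.frame with columns `snp_id, chrom, pos` covering at
#'   least every row SNP.
#' @return an object of class `zmatrix`.
#' @export
zmatrix <- function(z, mask, snp_ids, trait_ids, positions = NULL) {
  z <- as.matrix(z)
  mask <- as.matrix(mask)
  stopifnot(identical(dim(z), dim(mask)),
            length(snp_ids) == nrow(z),
            length(trait_ids) == ncol(z),
            !anyDuplicated(snp_ids), !anyDuplicated(trait_ids))
  dimnames(z) <- dimnames(mask) <- list(snp_ids, trait_ids)
  structure(
    list(z = z, mask = mask, snp_ids = as.character(snp_ids),
         trait_ids = as.character(trait_ids), positions = positions),
    class = "zmatrix"
  )
}

#' @export
print.zmatrix <- function(x, ...) {
  cat("Z-score matrix:", length(x$snp_ids), "SNPs x",
      length(x$trait_ids), "traits;",
      sum(x$mask), "sub-threshold entries\n")
  invisible(x)
}

#' @export
dim.zmatrix <- function(x) dim(x$z)

#' Zero Z-scores whose p-value misses the significance threshold
#'
#' Entries with p >= alpha are set to zero so that only reliable associations
#' contribute to the matrix; the accompanying mask records p < alpha.
#'
#' @param z numeric vector of Z-scores.
#' @param p numeric vector of p-values.
#' @param alpha significance threshold in (0, 1).
#' @return numeric vector: `z` where `p < alpha`, else 0.
#' @export
threshold_z <- function(z, p, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  ifelse(p < alpha, z, 0)
}

#' Assemble the per-trait records into a Z-score matrix
#'
#' Rows are the union of SNPs appearing in any trait, ordered by chromosome,
#' position, then SNP id. A (snp, trait) pair missing from that trait's GWAS
#' is a structural zero with a `FALSE` mask entry; present pairs pass through
#' [threshold_z()].
#'
#' @param per_trait_records named list (trait id -> harmonised record table).
#' @param alpha p-value threshold used for zeroing.
#' @return a [zmatrix()] with positions collected from the records.
#' @export
assemble_matrix <- function(per_trait_records, alpha) {
  stopifnot(length(per_trait_records) >= 2, !is.null(names(per_trait_records)))
  trait_ids <- names(per_trait_records)
  for (tid in trait_ids) {
    dup <- duplicated(per_trait_records[[tid]]$snp_id)
    if (any(dup)) {
      stop("duplicate SNP within trait ", tid, ": ",
           per_trait_records[[tid]]$snp_id[which(dup)[1]])
    }
  }
  pos_all <- unique(do.call(rbind, lapply(per_trait_records, function(r) {
    r[c("snp_id", "chrom", "pos")]
  })))
  if (anyDuplicated(pos_all$snp_id)) {
    stop("inconsistent chrom/pos for a SNP across traits")
  }
  ord <- order(pos_all$chrom, pos_all$pos, pos_all$snp_id)
  pos_all <- pos_all[ord, , drop = FALSE]
  rownames(pos_all) <- NULL
  snp_ids <- pos_all$snp_id

  z <- matrix(0, nrow = length(snp_ids), ncol = length(trait_ids))
  mask <- matrix(FALSE, nrow = length(snp_ids), ncol = length(trait_ids))
  for (j in seq_along(trait_ids)) {
    r <- per_trait_records[[j]]
    i <- match(r$snp_id, snp_ids)
    zj <- compute_z(r)
    keep <- r$p_value < alpha
    z[i, j] <- threshold_z(zj, r$p_value, alpha)
    mask[i, j] <- keep
  }
  zmatrix(z, mask, snp_ids, trait_ids, positions = pos_all)
}

#' Retain SNPs with sub-threshold associations in enough traits
#'
#' @param m a [zmatrix()].
#' @param min_traits minimum number of traits with a `TRUE` mask entry.
#' @return the filtered `zmatrix`; column order preserved.
#' @export
filter_min_traits <- function(m, min_traits) {
  stopifnot(inherits(m, "zmatrix"), min_traits >= 1)
  keep <- rowSums(m$mask) >= min_traits
  if (!any(keep)) {
    stop("no SNP has sub-threshold associations in at least ",
         min_traits, " traits")
  }
  zmatrix(m$z[keep, , drop = FALSE], m$mask[keep, , drop = FALSE],
          m$snp_ids[keep], m$trait_ids, positions = m$positions)
}

#' Build an LD lookup from a pairwise r-squared table
#'
#' Pairs absent from the table are treated as r-squared 0; r-squared of a SNP
#' with itself is 1. The lookup is symmetric.
#'
#' @param pairs data.frame with columns `snp_a, snp_b, r2`.
#' @return an object of class `ld_source`.
#' @export
ld_source <- function(pairs) {
  if (nrow(pairs) > 0) {
    stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(pairs)),
              all(pairs$r2 >= 0), all(pairs$r2 <= 1))
  }
  env <- new.env(parent = emptyenv(), size = max(16L, 2L * nrow(pairs)))
  if (nrow(pairs) > 0) {
    key <- ifelse(pairs$snp_a < pairs$snp_b,
                  paste(pairs$snp_a, pairs$snp_b, sep = "\r"),
                  paste(pairs$snp_b, pairs$snp_a, sep = "\r"))
    for (i in seq_len(nrow(pairs))) assign(key[i], pairs$r2[i], envir = env)
  }
  structure(list(env = env), class = "ld_source")
}

#' Pairwise r-squared from an LD source
#'
#' @param ld an [ld_source()].
#' @param a,b SNP id vectors (recycled to common length).
#' @return numeric vector of r-squared values.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_source"))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (a[i] == b[i]) {
      out[i] <- 1
    } else {
      v <- get0(key[i], envir = ld$env, inherits = FALSE)
      out[i] <- if (is.null(v)) 0 else v
    }
  }
  out
}

#' Read a 3-column LD table from delimited text
#'
#' @param path file with header `snp_a snp_b r2`.
#' @return an [ld_source()].
#' @export
read_ld_table <- function(path) {
  ld <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(ld)))
  ld_source(ld)
}

#' Priority-based greedy LD clumping
#'
#' Candidate SNPs are ordered by the number of traits with sub-threshold
#' associations (descending), then by maximum absolute Z (descending), then
#' by SNP id (ascending, for determinism). The top unclaimed SNP becomes an
#' index; every unclaimed SNP on the same chromosome within `window_bp` whose
#' r-squared with the index exceeds `r2_max` is claimed and removed. Indices
#' form the output, in their original row order.
#'
#' @param m a [zmatrix()] whose `positions` cover every row SNP.
#' @param ld an [ld_source()].
#' @param window_bp physical window in base pairs (pairwise distance,
#'   inclusive).
#' @param r2_max r-squared above which a neighbour is claimed.
#' @return the clumped `zmatrix`.
#' @export
clump <- function(m, ld, window_bp = 500000, r2_max = 0.2) {
  stopifnot(inherits(m, "zmatrix"), inherits(ld, "ld_source"))
  pos_idx <- match(m$snp_ids, m$positions$snp_id)
  if (anyNA(pos_idx)) {
    stop("missing position for SNP: ", m$snp_ids[which(is.na(pos_idx))[1]])
  }
  chrom <- m$positions$chrom[pos_idx]
  pos <- m$positions$pos[pos_idx]
  n_traits_hit <- rowSums(m$mask)
  max_abs_z <- apply(abs(m$z), 1, max)

  ord <- order(-n_traits_hit, -max_abs_z, m$snp_ids)
  unclaimed <- rep(TRUE, length(ord))  # indexed in original row order
  selected <- logical(length(ord))
  for (i in ord) {
    if (!unclaimed[i]) next
    selected[i] <- TRUE
    unclaimed[i] <- FALSE
    near <- which(unclaimed & chrom == chrom[i] &
                    abs(pos - pos[i]) <= window_bp)
    if (length(near) > 0) {
      r2 <- ld_r2(ld, m$snp_ids[i], m$snp_ids[near])
      unclaimed[near[r2 > r2_max]] <- FALSE
    }
  }
  zmatrix(m$z[selected, , drop = FALSE], m$mask[selected, , drop = FALSE],
          m$snp_ids[selected], m$trait_ids, positions = m$positions)
}

#' Standardise matrix columns to mean zero and unit standard deviation
#'
#' Uses the population convention (SD denominator n); structural and
#' thresholded zeros are standardised like any other entry. The mask is
#' unchanged.
#'
#' @param m a [zmatrix()].
#' @return the standardised `zmatrix`.
#' @export
standardise_columns <- function(m) {
  stopifnot(inherits(m, "zmatrix"))
  n <- nrow(m$z)
  mu <- colMeans(m$z)
  sdev <- sqrt(colMeans(sweep(m$z, 2, mu)^2))
  zero_var <- sdev <= 0 | !is.finite(sdev)
  if (any(zero_var)) {
    stop("zero-variance column for trait: ",
         paste(m$trait_ids[zero_var], collapse = ", "))
  }
  z <- sweep(sweep(m$z, 2, mu), 2, sdev, "/")
  zmatrix(z, m$mask, m$snp_ids, m$trait_ids, positions = m$positions)
}

#' Remove SNPs inside a genomic region
#'
#' Used to exclude long-range LD regions such as the MHC
#' (chr6:25,477,797-36,448,354, hg19) prior to clumping.
#'
#' @param m a [zmatrix()] with positions.
#' @param chrom chromosome name.
#' @param start,end inclusive bounds in base pairs, `start < end`.
#' @return the filtered `zmatrix`.
#' @export
exclude_region <- function(m, chrom, start, end) {
  stopifnot(inherits(m, "zmatrix"), start < end)
  pos_idx <- match(m$snp_ids, m$positions$snp_id)
  inside <- m$positions$chrom[pos_idx] == chrom &
    m$positions$pos[pos_idx] >= start & m$positions$pos[pos_idx] <= end
  keep <- !inside
  zmatrix(m$z[keep, , drop = FALSE], m$mask[keep, , drop = FALSE],
          m$snp_ids[keep], m$trait_ids, positions = m$positions)
}

#' Write a Z-score matrix as delimited text
#'
#' @param m a [zmatrix()].
#' @param path output path; tab-delimited with a `snp_id` column followed by
#'   one column per trait.
#' @export
write_zmatrix <- function(m, path) {
  out <- data.frame(snp_id = m$snp_ids, m$z, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
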