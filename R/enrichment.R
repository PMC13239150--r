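#' Build a gene-set collection over a background
#'
#' Each set is restricted to the background; set names must be unique.
#'
#' @param sets named list of character vectors of gene symbols.
#' @param background character vector of background gene symbols.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, background) {
  stopifnot(!is.null(names(sets)), !anyDuplicated(names(sets)))
  background <- unique(as.character(background))
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)), background))
  structure(list(sets = sets, background = background),
            class = "gene_set_collection")
}

#' Read gene sets from a GMT file
#'
#' GMT: one set per line — name, description, then tab-separated genes.
#'
#' @param path GMT file path.
#' @param background background gene symbols; defaults to the union of all
#'   set members.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1)
  if (is.null(background)) background <- unique(unlist(sets))
  gene_set_collection(sets, background)
}

#' Write gene sets to a GMT file
#'
#' @param coll a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(coll, path) {
  lines <- vapply(names(coll$sets), function(nm) {
    paste(c(nm, "na", coll$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Map SNPs to genes through a variant-to-gene table
#'
#' For each SNP the top-scoring gene is selected, together with every gene
#' flagged as having a transcription start site within 100 kb; the result is
#' the union over SNPs. SNPs absent from the table contribute nothing and
#' are counted.
#'
#' @param snps character vector of SNP ids.
#' @param mapping data.frame with columns `snp_id, gene, v2g_score,
#'   within_100kb` (one row per SNP-gene pair).
#' @return character vector of genes with attribute `n_unmapped`.
#' @export
map_snps_to_genes <- function(snps, mapping) {
  stopifnot(all(c("snp_id", "gene", "v2g_score", "within_100kb") %in%
                  names(mapping)))
  snps <- unique(as.character(snps))
  sub <- mapping[mapping$snp_id %in% snps, , drop = FALSE]
  genes <- character(0)
  if (nrow(sub) > 0) {
    # top-scoring gene per SNP, ties broken by gene name for determinism
    ord <- order(sub$snp_id, -sub$v2g_score, sub$gene)
    sub_ord <- sub[ord, , drop = FALSE]
    top <- sub_ord$gene[!duplicated(sub_ord$snp_id)]
    near <- sub$gene[as.logical(sub$within_100kb)]
    genes <- unique(c(top, near))
  }
  n_unmapped <- sum(!(snps %in% mapping$snp_id))
  structure(sort(genes), n_unmapped = n_unmapped)
}

#' Filter gene sets by size
#'
#' Sets are restricted to the background first; sets whose restricted size is
#' outside `[min_size, max_size]` (inclusive) are removed.
#'
#' @param coll a [gene_set_collection()].
#' @param min_size,max_size inclusive size bounds.
#' @return the filtered collection.
#' @export
filter_sets <- function(coll, min_size = 20, max_size = 500) {
  stopifnot(inherits(coll, "gene_set_collection"), min_size <= max_size)
  sizes <- lengths(coll$sets)
  keep <- sizes >= min_size & sizes <= max_size
  gene_set_collection(coll$sets[keep], coll$background)
}

#' Hypergeometric over-representation analysis
#'
#' For each set, the upper-tail hypergeometric probability
#' P(X >= n_overlap) with population `n_background`, `n_set` successes and
#' `n_query` draws; the enrichment ratio is the observed overlap divided by
#' the expected overlap under the null. FDR by Benjamini-Hochberg across all
#' tested sets. Query genes absent from the background are dropped with a
#' warning.
#'
#' @param query character vector of genes.
#' @param coll a [gene_set_collection()].
#' @return data.frame with columns `set_name, n_overlap, n_query, n_set,
#'   n_background, expected, enrichment_ratio, p_value, fdr`, sorted by FDR
#'   then p-value.
#' @export
hypergeom_ora <- function(query, coll) {
  stopifnot(inherits(coll, "gene_set_collection"))
  query <- unique(as.character(query))
  outside <- setdiff(query, coll$background)
  if (length(outside) > 0) {
    warning(length(outside), " query genes absent from the background were dropped")
    query <- intersect(query, coll$background)
  }
  if (length(query) == 0) stop("empty query after background restriction")
  n_bg <- length(coll$background)
  n_q <- length(query)
  res <- do.call(rbind, lapply(names(coll$sets), function(nm) {
    s <- coll$sets[[nm]]
    k <- length(intersect(query, s))
    n_s <- length(s)
    expected <- n_q * n_s / n_bg
    data.frame(
      set_name = nm, n_overlap = k, n_query = n_q, n_set = n_s,
      n_background = n_bg, expected = expected,
      enrichment_ratio = if (expected > 0) k / expected else NA_real_,
      p_value = stats::phyper(k - 1, n_s, n_bg - n_s, n_q,
                              lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  }))
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$fdr, res$p_value, res$set_name), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Over-representation of a query in developmental-stage expression sets
#'
#' The same hypergeometric over-representation computation as
#' [hypergeom_ora()], applied to stage-specific differentially expressed
#' gene sets (e.g. the 11 general brain developmental stages); FDR across
#' stages.
#'
#' @param query character vector of genes.
#' @param stage_sets a [gene_set_collection()] of stage-specific sets.
#' @return data.frame as [hypergeom_ora()].
#' @export
stage_expression_test <- function(query, stage_sets) {
  hypergeom_ora(query, stage_sets)
}
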