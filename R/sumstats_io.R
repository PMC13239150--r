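#' @keywords internal
.BASES <- c("A", "C", "G", "T")

#' @keywords internal
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# canonical column set of a harmonised variant record table
#' @keywords internal
.RECORD_COLS <- c(
  "snp_id", "chrom", "pos", "effect_allele", "other_allele",
  "beta", "se", "p_value", "eaf", "n_case", "n_control"
)

#' Is an allele pair strand-ambiguous?
#'
#' A/T and C/G pairs cannot be disambiguated between strands and are dropped
#' by default during harmonisation.
#'
#' @param a1,a2 character vectors of single-base alleles.
#' @return logical vector.
#' @keywords internal
.is_ambiguous_pair <- function(a1, a2) {
  unname(.COMPLEMENT[a1] == a2)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file of per-variant association results and returns
#' a harmonisable record table with one row per valid variant. Rows missing a
#' mandatory field, with non-positive SE, p-values outside (0, 1], invalid
#' allele codes, or identical effect/other alleles are counted and skipped.
#' Effect sizes reported as odds ratios are converted to log-odds betas.
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map named character vector mapping canonical field names to
#'   file column names. Mandatory fields: `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `se`, `p_value`, and exactly one of
#'   `beta` or `or`. Optional: `eaf`, `n_case`, `n_control`.
#' @param delim field delimiter; `""` (default) splits on any whitespace.
#' @return a `data.frame` of variant records with columns
#'   `snp_id, chrom, pos, effect_allele, other_allele, beta, se, p_value,
#'   eaf, n_case, n_control` and an attribute `n_skipped` giving the number
#'   of rows dropped during validation.
#' @export
read_sumstats <- function(path, column_map, delim = "") {
  if (!file.exists(path)) {
    stop("sumstats file not found: ", path)
  }
  mandatory <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                 "se", "p_value")
  has_beta <- "beta" %in% names(column_map)
  has_or <- "or" %in% names(column_map)
  if (has_beta == has_or) {
    stop("column_map must name exactly one of 'beta' or 'or'")
  }
  missing_map <- setdiff(mandatory, names(column_map))
  if (length(missing_map) > 0) {
    stop("column_map missing mandatory fields: ",
         paste(missing_map, collapse = ", "))
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent) > 0) {
    stop("mapped columns absent from file: ", paste(absent, collapse = ", "))
  }
  get_col <- function(field) raw[[column_map[[field]]]]
  n <- nrow(raw)
  opt_num <- function(field) {
    if (field %in% names(column_map)) suppressWarnings(as.numeric(get_col(field)))
    else rep(NA_real_, n)
  }
  rec <- data.frame(
    snp_id = as.character(get_col("snp_id")),
    chrom = as.character(get_col("chrom")),
    pos = suppressWarnings(as.integer(get_col("pos"))),
    effect_allele = toupper(as.character(get_col("effect_allele"))),
    other_allele = toupper(as.character(get_col("other_allele"))),
    beta = if (has_beta) suppressWarnings(as.numeric(get_col("beta")))
           else suppressWarnings(log(as.numeric(get_col("or")))),
    se = suppressWarnings(as.numeric(get_col("se"))),
    p_value = suppressWarnings(as.numeric(get_col("p_value"))),
    eaf = opt_num("eaf"),
    n_case = opt_num("n_case"),
    n_control = opt_num("n_control"),
    stringsAsFactors = FALSE
  )
  valid <- !is.na(rec$snp_id) & nzchar(rec$snp_id) &
    !is.na(rec$pos) & rec$pos >= 1 &
    rec$effect_allele %in% .BASES & rec$other_allele %in% .BASES &
    rec$effect_allele != rec$other_allele &
    is.finite(rec$beta) &
    is.finite(rec$se) & rec$se > 0 &
    is.finite(rec$p_value) & rec$p_value > 0 & rec$p_value <= 1
  out <- rec[valid, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) {
    stop("no valid rows in sumstats file: ", path)
  }
  attr(out, "n_skipped") <- sum(!valid)
  out
}

#' Read a reference variant panel
#'
#' @param path 5-column delimited text file with header:
#'   `snp_id, allele1, allele2, chrom, pos`.
#' @return data.frame with those columns; `snp_id` values are unique.
#' @export
read_reference_panel <- function(path) {
  panel <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  needed <- c("snp_id", "allele1", "allele2", "chrom", "pos")
  if (!all(needed %in% names(panel))) {
    stop("reference panel requires columns: ", paste(needed, collapse = ", "))
  }
  panel <- panel[needed]
  panel$snp_id <- as.character(panel$snp_id)
  panel$allele1 <- toupper(as.character(panel$allele1))
  panel$allele2 <- toupper(as.character(panel$allele2))
  if (anyDuplicated(panel$snp_id)) {
    stop("duplicate snp_id in reference panel")
  }
  if (!all(panel$allele1 %in% .BASES) || !all(panel$allele2 %in% .BASES)) {
    stop("invalid allele codes in reference panel")
  }
  panel
}

#' Signed association Z-scores
#'
#' Z = beta / SE, oriented to each record's effect allele.
#'
#' @param records a variant record table (see [read_sumstats()]).
#' @return numeric vector of Z-scores, one per record.
#' @export
compute_z <- function(records) {
  if (any(records$se <= 0)) {
    stop("compute_z requires positive SE for every record")
  }
  records$beta / records$se
}

#' Harmonise variant records onto a reference panel
#'
#' Aligns each record's effect allele to the panel's first allele. Records
#' whose alleles are swapped relative to the panel have beta negated and eaf
#' replaced by 1 - eaf; records matching only after strand complementation
#' (A<->T, C<->G) are complemented first and then aligned. Strand-ambiguous
#' variants (A/T or C/G pairs) are dropped when `drop_ambiguous` is set;
#' variants absent from the panel or with irreconcilable alleles are dropped.
#'
#' @param records variant record table.
#' @param panel reference panel data.frame (see [read_reference_panel()]).
#' @param drop_ambiguous drop strand-ambiguous variants (default `TRUE`).
#' @return harmonised record table whose SNPs are a subset of the panel, with
#'   chrom/pos taken from the panel and an attribute `report`: a named integer
#'   vector with counts `kept`, `flipped`, `complemented`, `dropped_ambiguous`,
#'   `dropped_not_in_panel`, `dropped_unmatched`.
#' @export
harmonise <- function(records, panel, drop_ambiguous = TRUE) {
  if (nrow(panel) == 0) stop("reference panel is empty")
  idx <- match(records$snp_id, panel$snp_id)
  in_panel <- !is.na(idx)
  n_not_in_panel <- sum(!in_panel)
  rec <- records[in_panel, , drop = FALSE]
  idx <- idx[in_panel]
  a1 <- panel$allele1[idx]
  a2 <- panel$allele2[idx]

  ambiguous <- .is_ambiguous_pair(rec$effect_allele, rec$other_allele)
  n_ambiguous <- 0L
  if (drop_ambiguous) {
    n_ambiguous <- sum(ambiguous)
    keep <- !ambiguous
    rec <- rec[keep, , drop = FALSE]
    a1 <- a1[keep]
    a2 <- a2[keep]
    idx <- idx[keep]
  }

  ea <- rec$effect_allele
  oa <- rec$other_allele
  same <- ea == a1 & oa == a2
  swapped <- ea == a2 & oa == a1
  comp_same <- !same & !swapped &
    unname(.COMPLEMENT[ea]) == a1 & unname(.COMPLEMENT[oa]) == a2
  comp_swapped <- !same & !swapped &
    unname(.COMPLEMENT[ea]) == a2 & unname(.COMPLEMENT[oa]) == a1
  matched <- same | swapped | comp_same | comp_swapped
  n_unmatched <- sum(!matched)

  rec <- rec[matched, , drop = FALSE]
  idx <- idx[matched]
  flip <- (swapped | comp_swapped)[matched]
  complemented <- (comp_same | comp_swapped)[matched]

  rec$beta[flip] <- -rec$beta[flip]
  rec$eaf[flip] <- 1 - rec$eaf[flip]
  rec$effect_allele <- panel$allele1[idx]
  rec$other_allele <- panel$allele2[idx]
  rec$chrom <- panel$chrom[idx]
  rec$pos <- panel$pos[idx]
  rownames(rec) <- NULL
  attr(rec, "report") <- c(
    kept = nrow(rec),
    flipped = sum(flip),
    complemented = sum(complemented),
    dropped_ambiguous = n_ambiguous,
    dropped_not_in_panel = n_not_in_panel,
    dropped_unmatched = n_unmatched
  )
  rec
}

#' One-line harmonisation report
#'
#' @param records output of [harmonise()].
#' @return a single character string summarising kept/flipped/complemented/
#'   dropped counts, suitable for a run log.
#' @export
harmonisation_report <- function(records) {
  r <- attr(records, "report")
  if (is.null(r)) stop("records carry no harmonisation report")
  paste0("kept=", r[["kept"]], " flipped=", r[["flipped"]],
         " complemented=", r[["complemented"]],
         " dropped_ambiguous=", r[["dropped_ambiguous"]],
         " dropped_not_in_panel=", r[["dropped_not_in_panel"]],
         " dropped_unmatched=", r[["dropped_unmatched"]])
}
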