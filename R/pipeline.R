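#' Default pipeline configuration
#'
#' The defaults reproduce the primary analysis settings: p-value threshold
#' 1e-3 for Z-score zeroing, retention in at least 2 traits, 500 kb / r-sq
#' 0.2 priority clumping, 50% cumulative contribution for component-defining
#' SNP selection, gene-set sizes 20-500, FDR 0.05 and Bonferroni over 3
#' case-case comparisons. Secondary analyses (alpha 1e-5 or 0.05, region
#' exclusion, alternative discovery GWAS) are configuration changes only.
#'
#' @param ... overrides of individual fields.
#' @return named list of parameters.
#' @export
default_config <- function(...) {
  config <- list(
    alpha = 1e-3,
    min_traits = 2,
    window_bp = 500000,
    r2_max = 0.2,
    cumulative_fraction = 0.5,
    set_size = c(20, 500),
    fdr_alpha = 0.05,
    bonferroni_m = 3,
    exclude_regions = NULL,
    freq_is = "control",
    drop_ambiguous = TRUE,
    seed = 1
  )
  overrides <- list(...)
  config[names(overrides)] <- overrides
  config
}

#' Validate a pipeline configuration
#'
#' @param config named list as produced by [default_config()].
#' @return character vector of violation messages, each naming the offending
#'   field; empty when the configuration is valid.
#' @export
validate_config <- function(config) {
  errors <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  chk(is.numeric(config$alpha) && config$alpha > 0 && config$alpha < 1,
      "alpha must be in (0, 1)")
  chk(is.numeric(config$min_traits) && config$min_traits >= 1,
      "min_traits must be >= 1")
  chk(is.numeric(config$window_bp) && config$window_bp > 0,
      "window_bp must be positive")
  chk(is.numeric(config$r2_max) && config$r2_max >= 0 && config$r2_max <= 1,
      "r2_max must be in [0, 1]")
  chk(is.numeric(config$cumulative_fraction) &&
        config$cumulative_fraction > 0 && config$cumulative_fraction <= 1,
      "cumulative_fraction must be in (0, 1]")
  chk(is.numeric(config$set_size) && length(config$set_size) == 2 &&
        config$set_size[1] <= config$set_size[2] && config$set_size[1] >= 1,
      "set_size must be two increasing positive bounds")
  chk(is.numeric(config$fdr_alpha) && config$fdr_alpha > 0 &&
        config$fdr_alpha < 1, "fdr_alpha must be in (0, 1)")
  chk(is.numeric(config$bonferroni_m) && config$bonferroni_m >= 1,
      "bonferroni_m must be >= 1")
  chk(config$freq_is %in% c("control", "pooled"),
      "freq_is must be 'control' or 'pooled'")
  if (!is.null(config$exclude_regions)) {
    ok <- is.data.frame(config$exclude_regions) &&
      all(c("chrom", "start", "end") %in% names(config$exclude_regions)) &&
      all(config$exclude_regions$start < config$exclude_regions$end)
    chk(ok, "exclude_regions must be a data.frame with chrom, start < end")
  }
  errors
}

#' @keywords internal
.stage_log <- function(log, stage, msg) {
  c(log, paste0("[", stage, "] ", msg))
}

#' Run the full decomposition pipeline
#'
#' Stages, in fixed order: ingest/harmonise each trait onto the panel;
#' assemble the thresholded Z matrix; optional region exclusion (before
#' clumping); minimum-trait retention; priority LD clumping; column
#' standardisation; SVD and attribution statistics; then, when their inputs
#' are supplied, gene-set over-representation of the component-defining
#' SNPs, external-GWAS correlations, and polygenic-score evaluation (with
#' optional overlap subtraction and case-case GWAS). Each stage appends a
#' log line with input/output row counts; optional stages are skipped with a
#' notice when their inputs are absent.
#'
#' @param sumstats named list (trait -> record table) or paths readable by
#'   [read_sumstats()] together with `column_map`.
#' @param panel reference panel data.frame or path.
#' @param ld an [ld_source()], a pair table, or a path.
#' @param config configuration list (see [default_config()]).
#' @param column_map column map used when `sumstats` holds file paths.
#' @param annotations optional list with `mapping` (SNP-to-gene table) and
#'   `collection` (a [gene_set_collection()]).
#' @param externals optional named list (trait -> record table) of external
#'   GWAS.
#' @param targets optional named list (label -> record table) of target
#'   GWAS for component-PGS evaluation; all components are evaluated against
#'   each target.
#' @param subtract optional named list (target label -> cohort record table)
#'   of overlapping cohorts subtracted from the corresponding target's
#'   discovery-side records before PGS evaluation.
#' @param ccgwas_pairs optional list of character pairs of target labels;
#'   each pair is contrasted by case-case GWAS and the matching component
#'   scores are compared between the two case groups.
#' @param outdir optional directory; when given, every stage writes its
#'   table there.
#' @return list with `matrix` (the standardised [zmatrix()]),
#'   `decomposition`, `stats` ([attribution_stats()]), `enrichment`,
#'   `correlations`, `pgs`, `ccgwas`, `harmonisation`, `config` and `log`.
#' @export
run_pipeline <- function(sumstats, panel, ld, config = default_config(),
                         column_map = NULL, annotations = NULL,
                         externals = NULL, targets = NULL, subtract = NULL,
                         ccgwas_pairs = NULL, outdir = NULL) {
  errors <- validate_config(config)
  if (length(errors) > 0) {
    stop("invalid configuration: ", paste(errors, collapse = "; "))
  }
  log <- character(0)
  if (is.character(panel)) panel <- read_reference_panel(panel)
  if (is.character(ld)) ld <- read_ld_table(ld)
  if (is.data.frame(ld)) ld <- ld_source(ld)

  # stage 1: ingest + harmonise
  harmonised <- list()
  reports <- list()
  for (tid in names(sumstats)) {
    rec <- sumstats[[tid]]
    if (is.character(rec)) rec <- read_sumstats(rec, column_map)
    h <- harmonise(rec, panel, drop_ambiguous = config$drop_ambiguous)
    harmonised[[tid]] <- h
    reports[[tid]] <- attr(h, "report")
    log <- .stage_log(log, "harmonise",
                      paste0(tid, ": in=", nrow(rec), " ",
                             harmonisation_report(h)))
  }

  # stage 2: matrix construction
  m <- assemble_matrix(harmonised, alpha = config$alpha)
  log <- .stage_log(log, "assemble",
                    paste0("rows=", nrow(m$z), " traits=", ncol(m$z),
                           " alpha=", config$alpha))
  if (!is.null(config$exclude_regions)) {
    for (i in seq_len(nrow(config$exclude_regions))) {
      rg <- config$exclude_regions[i, ]
      before <- nrow(m$z)
      m <- exclude_region(m, rg$chrom, rg$start, rg$end)
      log <- .stage_log(log, "exclude_region",
                        paste0(rg$chrom, ":", rg$start, "-", rg$end,
                               " removed=", before - nrow(m$z)))
    }
  }
  m <- filter_min_traits(m, config$min_traits)
  log <- .stage_log(log, "filter_min_traits", paste0("rows=", nrow(m$z)))
  m <- clump(m, ld, window_bp = config$window_bp, r2_max = config$r2_max)
  log <- .stage_log(log, "clump", paste0("rows=", nrow(m$z)))
  m <- standardise_columns(m)
  log <- .stage_log(log, "standardise", "columns to mean 0, SD 1")

  # stage 3: decomposition + attribution
  d <- svd_decompose(m)
  stats <- attribution_stats(d)
  log <- .stage_log(log, "svd",
                    paste0("components=", length(d$singular_values),
                           " ve1=", signif(stats$variance_explained[1], 4)))

  # stage 4 (optional): enrichment
  enrichment <- NULL
  if (!is.null(annotations)) {
    coll <- filter_sets(annotations$collection,
                        config$set_size[1], config$set_size[2])
    enrichment <- list()
    for (k in seq_along(d$singular_values)) {
      top <- cumulative_top_snps(stats, k,
                                 fraction = config$cumulative_fraction)
      genes <- map_snps_to_genes(top, annotations$mapping)
      if (length(genes) == 0) {
        log <- .stage_log(log, "enrichment",
                          paste0("component ", k, ": no mapped genes, skipped"))
        next
      }
      enrichment[[k]] <- suppressWarnings(hypergeom_ora(genes, coll))
      log <- .stage_log(log, "enrichment",
                        paste0("component ", k, ": snps=", length(top),
                               " genes=", length(genes),
                               " sets=", nrow(enrichment[[k]]),
                               " fdr<", config$fdr_alpha, "=",
                               sum(enrichment[[k]]$fdr < config$fdr_alpha)))
    }
  } else {
    log <- .stage_log(log, "enrichment", "skipped: no annotations supplied")
  }

  # stage 5 (optional): external correlations
  correlations <- NULL
  if (!is.null(externals)) {
    ext_h <- lapply(externals, function(e) {
      harmonise(e, panel, drop_ambiguous = config$drop_ambiguous)
    })
    for (tid in names(ext_h)) {
      log <- .stage_log(log, "external_corr",
                        paste0(tid, ": ", harmonisation_report(ext_h[[tid]])))
    }
    correlations <- correlation_grid(d, ext_h)
    log <- .stage_log(log, "external_corr",
                      paste0("grid=", nrow(correlations), " fdr<",
                             config$fdr_alpha, "=",
                             sum(correlations$fdr < config$fdr_alpha)))
  } else {
    log <- .stage_log(log, "external_corr", "skipped: no externals supplied")
  }

  # stage 6 (optional): component PGS evaluation
  pgs <- NULL
  ccgwas <- NULL
  if (!is.null(targets)) {
    targets <- lapply(targets, function(t) {
      harmonise(t, panel, drop_ambiguous = config$drop_ambiguous)
    })
    if (!is.null(subtract)) {
      for (lbl in names(subtract)) {
        if (!lbl %in% names(targets)) next
        before <- nrow(targets[[lbl]])
        cohort <- harmonise(subtract[[lbl]], panel,
                            drop_ambiguous = config$drop_ambiguous)
        targets[[lbl]] <- suppressWarnings(
          meta_subtract(targets[[lbl]], cohort))
        log <- .stage_log(log, "meta_subtract",
                          paste0(lbl, ": in=", before, " out=",
                                 nrow(targets[[lbl]])))
      }
    }
    rows <- list()
    for (lbl in names(targets)) {
      for (k in seq_along(d$singular_values)) {
        w <- pc_pgs_weights(d, k, panel)
        res <- group_pgs(w, targets[[lbl]], freq_is = config$freq_is)
        res <- cbind(data.frame(target = lbl, component = k,
                                stringsAsFactors = FALSE), res)
        rows[[length(rows) + 1L]] <- res
      }
      log <- .stage_log(log, "group_pgs",
                        paste0(lbl, ": components=",
                               length(d$singular_values)))
    }
    pgs <- do.call(rbind, rows)
    pgs$bonferroni_significant <-
      adjust_bonferroni(pgs$p_value, config$bonferroni_m)
    if (!is.null(ccgwas_pairs)) {
      ccgwas <- list()
      for (pair in ccgwas_pairs) {
        key <- paste(pair, collapse = "_vs_")
        cc <- cc_gwas(targets[[pair[1]]], targets[[pair[2]]],
                      freq_is = config$freq_is)
        ccgwas[[key]] <- cc
        log <- .stage_log(log, "ccgwas",
                          paste0(key, ": snps=", nrow(cc)))
      }
    }
  } else {
    log <- .stage_log(log, "pgs", "skipped: no targets supplied")
  }

  result <- list(matrix = m, decomposition = d, stats = stats,
                 enrichment = enrichment, correlations = correlations,
                 pgs = pgs, ccgwas = ccgwas, harmonisation = reports,
                 config = config, log = log)
  if (!is.null(outdir)) .write_pipeline_outputs(result, outdir)
  result
}

#' @keywords internal
.write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) {
    utils::write.table(x, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_zmatrix(result$matrix, file.path(outdir, "zmatrix.tsv"))
  d <- result$decomposition
  wt(data.frame(component = seq_along(d$singular_values),
                singular_value = d$singular_values,
                variance_explained = result$stats$variance_explained),
     "components.tsv")
  wt(data.frame(trait = d$trait_ids, d$pheno_vectors), "pheno_vectors.tsv")
  wt(data.frame(snp_id = d$snp_ids, d$snp_vectors), "snp_vectors.tsv")
  wt(data.frame(trait = d$trait_ids, result$stats$squared_cosines),
     "squared_cosines.tsv")
  if (!is.null(result$correlations)) wt(result$correlations,
                                        "external_correlations.tsv")
  if (!is.null(result$pgs)) wt(result$pgs, "group_pgs.tsv")
  if (!is.null(result$enrichment)) {
    for (k in seq_along(result$enrichment)) {
      if (!is.null(result$enrichment[[k]])) {
        wt(result$enrichment[[k]], sprintf("enrichment_component_%d.tsv", k))
      }
    }
  }
  if (!is.null(result$ccgwas)) {
    for (key in names(result$ccgwas)) {
      wt(result$ccgwas[[key]], sprintf("ccgwas_%s.tsv", key))
    }
  }
  writeLines(result$log, file.path(outdir, "run.log"))
  invisible(outdir)
}
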