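#' Run configuration for the full pipeline
#'
#' @param cross a cross object or path to a rotated-header cross CSV.
#' @param expr an [expression_set()], or `c(matrix_path, annot_path)`, or
#'   `NULL` (eQTL and downstream stages are then skipped or halt if
#'   requested).
#' @param out_dir output directory (created).
#' @param traits traits to map (default: all phenotype columns).
#' @param sexes which sexes to map separately (default `c("F", "M")`).
#' @param covariates base covariates for phenotype scans.
#' @param step_cM pseudomarker step (default 1).
#' @param alpha genome-wide significance level (default 0.05).
#' @param n_perm phenotype-scan permutations (default 1000).
#' @param eqtl_n_iter,eqtl_subsample eQTL permutation scheme (defaults
#'   1000 and 100; 10000 iterations at full scale).
#' @param k_pcs genotype principal components added as covariates.
#' @param drop LOD drop for support intervals (default 1.8).
#' @param hotspot_n_iter null iterations for hotspot calling.
#' @param stages which stages to run.
#' @param seed master seed; stage seeds derive from it.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(cross, expr = NULL, out_dir, traits = NULL,
                       sexes = c("F", "M"), covariates = c("batch", "body_weight"),
                       step_cM = 1, alpha = 0.05, n_perm = 1000,
                       eqtl_n_iter = 1000, eqtl_subsample = 100, k_pcs = 0,
                       drop = 1.8, hotspot_n_iter = 1000,
                       stages = c("qtl", "eqtl", "candidates", "hotspots"),
                       seed = 1L) {
  structure(list(cross = cross, expr = expr, out_dir = out_dir,
                 traits = traits, sexes = sexes, covariates = covariates,
                 step_cM = step_cM, alpha = alpha, n_perm = n_perm,
                 eqtl_n_iter = eqtl_n_iter, eqtl_subsample = eqtl_subsample,
                 k_pcs = k_pcs, drop = drop,
                 hotspot_n_iter = hotspot_n_iter, stages = stages,
                 seed = as.integer(seed)), class = "run_config")
}

#' Execute the full analysis pipeline
#'
#' Stages: genotype probabilities, per-trait per-sex phenotype QTL scans
#' with permutation thresholds and support intervals; female eQTL scans
#' with the dual cis/trans permutation thresholds; candidate gene calls
#' from QTL x cis-eQTL overlap in Mb; trans-eQTL hotspot calls. Each stage
#' writes its table before the next starts, so a failing stage leaves
#' completed outputs intact. Outputs are pure functions of (inputs,
#' config, seed).
#'
#' @param config a [run_config()].
#' @return the output directory, invisibly; per-stage tables, a summary
#'   JSON and a run-metadata JSON are written there.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cross <- if (is.character(config$cross)) read_rqtl_csv(config$cross)
           else config$cross
  expr <- config$expr
  if (is.character(expr)) expr <- read_expression_set(expr[1], expr[2])
  traits <- config$traits %||% names(cross$pheno)
  meta <- list(seed = config$seed, alpha = config$alpha,
               n_perm = config$n_perm, step_cM = config$step_cM,
               thresholds = list())

  probs <- calc_genoprob(cross, step_cM = config$step_cM)

  qtl_rows <- list()
  if ("qtl" %in% config$stages) {
    for (sx in config$sexes) {
      sub <- subset_cross(cross, sex = sx)
      subprobs <- calc_genoprob(sub, step_cM = config$step_cM)
      for (tr in traits) {
        if (all(is.na(sub$pheno[[tr]]))) next
        covs <- config$covariates
        if (sx == "F" && "eggs" %in% names(sub$covar)) {
          dec <- select_egg_covariate(sub, tr, base_covariates = covs)
          covs <- dec$covariates
        }
        cv <- build_covar_matrix(sub, covs)
        if (config$k_pcs > 0)
          cv <- cbind(cv, pca_covariates(sub, config$k_pcs))
        thr <- permutation_threshold(subprobs, sub, tr, cv,
                                     n_perm = config$n_perm,
                                     alpha = config$alpha,
                                     seed = config$seed + 11L)
        meta$thresholds[[paste(tr, sx, sep = ".")]] <- thr
        sc <- scanone(subprobs, sub, tr, cv)
        for (cc in unique(sc$chr)) {
          pk <- max_scan(sc, cc)
          if (pk$lod >= thr) {
            ci <- lod_support_interval(sc, pk, config$drop, sub$map)
            qtl_rows[[length(qtl_rows) + 1]] <- data.frame(
              trait = tr, sex = sx, chr = cc, peak_cM = pk$pos_cM,
              lod = pk$lod, threshold = thr, ci_lo = ci$start,
              ci_hi = ci$end, stringsAsFactors = FALSE)
          }
        }
      }
    }
    qtl_tab <- if (length(qtl_rows)) do.call(rbind, qtl_rows) else
      data.frame(trait = character(0), sex = character(0), chr = character(0),
                 peak_cM = numeric(0), lod = numeric(0),
                 threshold = numeric(0), ci_lo = numeric(0),
                 ci_hi = numeric(0))
    utils::write.table(qtl_tab, file.path(config$out_dir, "qtl.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  need_expr <- intersect(c("eqtl", "candidates", "hotspots"), config$stages)
  if (length(need_expr) && is.null(expr))
    stop("stage '", need_expr[1], "' requires expression data; ",
         "completed stages are preserved in ", config$out_dir)

  eq <- NULL
  if ("eqtl" %in% config$stages) {
    fem <- subset_cross(cross, sex = "F")
    fprobs <- calc_genoprob(fem, step_cM = config$step_cM)
    nss <- min(config$eqtl_subsample, nrow(expr$matrix))
    thr_cis <- eqtl_permutation_threshold(fprobs, fem, expr, "cis",
                                          n_iter = config$eqtl_n_iter,
                                          n_subsample = nss,
                                          alpha = config$alpha,
                                          seed = config$seed + 21L)
    thr_trans <- eqtl_permutation_threshold(fprobs, fem, expr, "trans",
                                            n_iter = config$eqtl_n_iter,
                                            n_subsample = nss,
                                            alpha = config$alpha,
                                            seed = config$seed + 22L)
    meta$thresholds$eqtl_cis <- as.numeric(thr_cis)
    meta$thresholds$eqtl_trans <- as.numeric(thr_trans)
    eq <- eqtl_scan(fprobs, fem, expr,
                    list(cis = as.numeric(thr_cis),
                         trans = as.numeric(thr_trans)),
                    drop = config$drop)
    utils::write.table(eq, file.path(config$out_dir, "eqtl.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cand <- NULL
  if ("candidates" %in% config$stages && !is.null(eq) && length(qtl_rows)) {
    fq <- do.call(rbind, qtl_rows)
    fq <- fq[fq$sex == "F", , drop = FALSE]
    cand <- empty_candidates()
    if (nrow(fq) && any(eq$kind == "cis")) {
      qtl_iv <- genomic_intervals(fq$chr, fq$ci_lo, fq$ci_hi, unit = "cM",
                                  kind = "qtl", label = fq$trait,
                                  peak_lod = fq$lod)
      qtl_mb <- coordinate_convert(qtl_iv, cross$map, "cM2Mb")
      cis_mb <- coordinate_convert(eqtl_intervals(eq, "cis"), cross$map,
                                   "cM2Mb")
      pairs <- overlap_pairs(qtl_mb, cis_mb)
      cand <- call_candidates(pairs, subset_cross(cross, sex = "F"), expr,
                              alpha = config$alpha)
    }
    write_candidate_table(cand, file.path(config$out_dir, "candidates.tsv"))
  }

  hs <- NULL
  if ("hotspots" %in% config$stages && !is.null(eq)) {
    trans_iv <- eqtl_intervals(eq, "trans")
    if (nrow(trans_iv)) {
      genome <- tapply(cross$map$pos_cM, cross$map$chr, max)
      genome <- genome[unique(cross$map$chr)]
      qtl_iv <- if (length(qtl_rows)) {
        fq <- do.call(rbind, qtl_rows)
        genomic_intervals(fq$chr, fq$ci_lo, fq$ci_hi, unit = "cM",
                          kind = "qtl", label = paste(fq$trait, fq$sex))
      } else NULL
      hs <- call_hotspots(trans_iv, genome, n_iter = config$hotspot_n_iter,
                          alpha = config$alpha, seed = config$seed + 31L,
                          qtl = qtl_iv)
      meta$thresholds$hotspot_depth <- hs$threshold
      utils::write.table(as.data.frame(hs$calls),
                         file.path(config$out_dir, "hotspots.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      utils::write.table(data.frame(), file.path(config$out_dir, "hotspots.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  qtl_n <- length(qtl_rows)
  fq <- if (qtl_n) do.call(rbind, qtl_rows) else NULL
  merged_counts <- list()
  if (qtl_n) for (sx in unique(fq$sex)) {
    sv <- fq[fq$sex == sx, , drop = FALSE]
    merged_counts[[sx]] <- nrow(merge_regions(
      genomic_intervals(sv$chr, sv$ci_lo, sv$ci_hi, unit = "cM")))
  }
  summary <- list(
    n_qtl = qtl_n,
    merged_regions = merged_counts,
    n_cis_eqtl = if (is.null(eq)) NA else sum(eq$kind == "cis"),
    n_trans_eqtl = if (is.null(eq)) NA else sum(eq$kind == "trans"),
    n_candidates = if (is.null(cand)) NA else sum(cand$pass),
    n_hotspots = if (is.null(hs)) NA else nrow(hs$calls))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(meta, file.path(config$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$out_dir)
}

empty_candidates <- function() {
  out <- data.frame(trait = character(0), gene = character(0),
                    chromosome = character(0), position_Mb = numeric(0),
                    eqtl_lod = numeric(0), p_value = numeric(0),
                    m = integer(0), p_adjusted = numeric(0),
                    pass = logical(0))
  class(out) <- c("candidate_table", "data.frame")
  out
}
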