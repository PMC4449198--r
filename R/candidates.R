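#' Overlap QTL and eQTL support intervals
#'
#' All (QTL, eQTL) pairs on the same chromosome whose closed intervals
#' intersect; touching endpoints count as overlap. Both sets must be in
#' the same coordinate unit.
#'
#' @param qtl,eqtl [genomic_intervals()] sets.
#' @return data.frame with one row per overlapping pair: `chr`,
#'   `qtl_id`, `qtl_label`, `qtl_start`, `qtl_end`, `eqtl_id`,
#'   `eqtl_label`, `eqtl_lod`, `eqtl_start`, `eqtl_end`.
#' @export
overlap_pairs <- function(qtl, eqtl) {
  stop_if_mixed_units(qtl, eqtl)
  out <- list()
  for (i in seq_len(nrow(qtl))) {
    j <- which(eqtl$chr == qtl$chr[i] &
                 eqtl$start <= qtl$end[i] & eqtl$end >= qtl$start[i])
    if (length(j))
      out[[length(out) + 1]] <- data.frame(
        chr = qtl$chr[i], qtl_id = i, qtl_label = qtl$label[i],
        qtl_start = qtl$start[i], qtl_end = qtl$end[i],
        eqtl_id = j, eqtl_label = eqtl$label[j], eqtl_lod = eqtl$peak_lod[j],
        eqtl_start = eqtl$start[j], eqtl_end = eqtl$end[j],
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chr = character(0), qtl_id = integer(0),
                      qtl_label = character(0), qtl_start = numeric(0),
                      qtl_end = numeric(0), eqtl_id = integer(0),
                      eqtl_label = character(0), eqtl_lod = numeric(0),
                      eqtl_start = numeric(0), eqtl_end = numeric(0)))
  do.call(rbind, out)
}

#' Merge overlapping intervals into disjoint regions
#'
#' Per chromosome, unions overlapping or touching intervals into maximal
#' disjoint regions — the operation behind "loci for different variables
#' form N separate genomic regions" style counts.
#'
#' @param intervals a [genomic_intervals()] set.
#' @return a [genomic_intervals()] set of disjoint regions (same unit),
#'   with a column `n_members` counting merged inputs.
#' @export
merge_regions <- function(intervals) {
  if (nrow(intervals) == 0) {
    out <- intervals
    out$n_members <- integer(0)
    return(out)
  }
  res <- list()
  for (cc in unique(intervals$chr)) {
    sub <- intervals[intervals$chr == cc, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    cs <- sub$start[1]; ce <- sub$end[1]; k <- 1L
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] <= ce) {  # touching counts as overlap
        ce <- max(ce, sub$end[i]); k <- k + 1L
      } else {
        res[[length(res) + 1]] <- data.frame(chr = cc, start = cs, end = ce,
                                             n_members = k)
        cs <- sub$start[i]; ce <- sub$end[i]; k <- 1L
      }
    }
    res[[length(res) + 1]] <- data.frame(chr = cc, start = cs, end = ce,
                                         n_members = k)
  }
  res <- do.call(rbind, res)
  out <- genomic_intervals(chr = res$chr, start = res$start, end = res$end,
                           unit = interval_unit(intervals),
                           kind = intervals$kind[1])
  out$n_members <- res$n_members
  out
}

#' Association between a trait and a probeset's expression
#'
#' Least-squares regression of the trait on the probeset's expression plus
#' body weight (and, when the QTL in question was detected with the egg
#' covariate, the egg column); the reported p is the two-sided t-test on
#' the expression coefficient. `mode = "residual"` regresses
#' covariate-residualised trait on expression instead (the scatterplot
#' convention); the default keeps covariates in the model.
#'
#' @param cross a cross object.
#' @param expr an [expression_set()].
#' @param trait phenotype column name.
#' @param probeset probeset id.
#' @param covariates covariate names (default body weight).
#' @param mode `"in_model"` or `"residual"`.
#' @return list: `p_value`, `coefficient`, `n`.
#' @export
association_test <- function(cross, expr, trait, probeset,
                             covariates = "body_weight",
                             mode = c("in_model", "residual")) {
  mode <- match.arg(mode)
  ids <- intersect(colnames(expr$matrix), rownames(cross$geno))
  ri <- match(ids, rownames(cross$geno))
  y <- cross$pheno[[trait]][ri]
  if (is.null(cross$pheno[[trait]])) stop("trait '", trait, "' not found")
  e <- expr$matrix[probeset, ids]
  C <- build_covar_matrix(cross, covariates)[ri, , drop = FALSE]
  ok <- !is.na(y) & !is.na(e)
  if (ncol(C)) ok <- ok & stats::complete.cases(C)
  if (sum(ok) < 10)
    stop("only ", sum(ok), " complete cases for ", trait, " ~ ", probeset,
         "; need >= 10")
  y <- y[ok]; e <- e[ok]; C <- C[ok, , drop = FALSE]
  if (mode == "residual" && ncol(C)) {
    y <- stats::lm.fit(cbind(1, C), y)$residuals
    C <- C[, 0, drop = FALSE]
  }
  dat <- data.frame(y = y, expr = e, C)
  fit <- stats::lm(y ~ ., data = dat)
  sm <- summary(fit)$coefficients
  list(p_value = sm["expr", "Pr(>|t|)"], coefficient = sm["expr", "Estimate"],
       n = length(y))
}

#' Number of uncorrelated cis-eQTL genes in an interval
#'
#' Bonferroni denominator for the candidate association test: genes whose
#' expression vectors are pairwise correlated (correlation-test
#' p <= `alpha`) are linked, and `m` is the number of connected components
#' of the link graph — each correlated cluster counts once, each
#' independent gene counts once. `mode = "pairwise"` instead counts genes
#' uncorrelated with every other gene (plus one cluster if any correlated
#' genes exist); component counting is the default because it always gives
#' `m >= 1` and agrees in the all-independent and all-correlated extremes.
#'
#' @param exprmat numeric matrix, genes x individuals (>= 1 row).
#' @param alpha correlation-test significance cut (default 0.05).
#' @param method correlation test: `"pearson"` (default) or
#'   `"spearman"`.
#' @param mode `"components"` or `"pairwise"`.
#' @return integer `m >= 1` (components mode).
#' @export
count_uncorrelated <- function(exprmat, alpha = 0.05, method = "pearson",
                               mode = c("components", "pairwise")) {
  mode <- match.arg(mode)
  g <- nrow(exprmat)
  stopifnot(g >= 1)
  if (g == 1) return(1L)
  linked <- matrix(FALSE, g, g)
  for (i in seq_len(g - 1)) for (j in seq(i + 1, g)) {
    p <- stats::cor.test(exprmat[i, ], exprmat[j, ], method = method,
                         exact = FALSE)$p.value
    linked[i, j] <- linked[j, i] <- is.finite(p) && p <= alpha
  }
  if (mode == "pairwise") {
    iso <- sum(rowSums(linked) == 0)
    return(as.integer(iso + as.integer(iso < g)))
  }
  # connected components by union-find
  parent <- seq_len(g)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(g - 1)) for (j in seq(i + 1, g)) if (linked[i, j]) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <- ri
  }
  length(unique(vapply(seq_len(g), find, integer(1))))
}

#' Two-phase candidate quantitative-trait-gene calls
#'
#' Phase 1 is the interval overlap ([overlap_pairs()]); phase 2 tests, for
#' each overlapping (QTL, eQTL) pair, the association between the
#' probeset's expression and the QTL's trait ([association_test()]), and
#' Bonferroni-adjusts the p-value by the number of uncorrelated cis-eQTL
#' genes overlapping that QTL interval ([count_uncorrelated()]).
#'
#' @param pairs result of [overlap_pairs()] (QTL x cis-eQTL overlaps).
#' @param cross a cross object.
#' @param expr an [expression_set()] (probe annotation provides the
#'   reported gene position in Mb).
#' @param alpha pass threshold on the adjusted p (default 0.05).
#' @param covariates base covariates for the association (body weight).
#' @param egg_traits traits whose QTL were detected with the egg
#'   covariate; their associations add `eggs` to the covariates.
#' @param cor_alpha correlation-test cut for [count_uncorrelated()].
#' @param mode association mode, see [association_test()].
#' @return data.frame of class `"candidate_table"`, sorted by trait then
#'   chromosome: `trait`, `gene`, `chromosome`, `position_Mb`,
#'   `eqtl_lod`, `p_value`, `m`, `p_adjusted`, `pass`.
#' @export
call_candidates <- function(pairs, cross, expr, alpha = 0.05,
                            covariates = "body_weight",
                            egg_traits = character(0), cor_alpha = 0.05,
                            mode = "in_model") {
  empty <- data.frame(trait = character(0), gene = character(0),
                      chromosome = character(0), position_Mb = numeric(0),
                      eqtl_lod = numeric(0), p_value = numeric(0),
                      m = integer(0), p_adjusted = numeric(0),
                      pass = logical(0))
  class(empty) <- c("candidate_table", "data.frame")
  if (nrow(pairs) == 0) return(empty)
  ids <- intersect(colnames(expr$matrix), rownames(cross$geno))
  ann <- expr$annotation
  rows <- list()
  for (q in unique(pairs$qtl_id)) {
    sub <- pairs[pairs$qtl_id == q, , drop = FALSE]
    genes <- unique(sub$eqtl_label)
    genes <- genes[genes %in% rownames(expr$matrix)]
    if (!length(genes)) next
    m <- count_uncorrelated(expr$matrix[genes, ids, drop = FALSE],
                            alpha = cor_alpha)
    trait <- sub$qtl_label[1]
    cv <- if (trait %in% egg_traits) c(covariates, "eggs") else covariates
    for (i in seq_len(nrow(sub))) {
      gene <- sub$eqtl_label[i]
      if (!(gene %in% genes)) next
      at <- association_test(cross, expr, trait, gene, cv, mode = mode)
      aj <- match(gene, ann$probeset)
      rows[[length(rows) + 1]] <- data.frame(
        trait = trait, gene = gene, chromosome = sub$chr[i],
        position_Mb = if (!is.na(aj)) ann$pos_Mb[aj] else NA_real_,
        eqtl_lod = sub$eqtl_lod[i], p_value = at$p_value, m = m,
        p_adjusted = min(1, at$p_value * m),
        pass = min(1, at$p_value * m) < alpha, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$trait, out$chromosome, out$position_Mb), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Write a candidate table
#'
#' Columns, in order: trait, gene, chromosome, position_Mb, eqtl_lod,
#' p_value, m, p_adjusted, pass.
#'
#' @param candidates a [call_candidates()] table.
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
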