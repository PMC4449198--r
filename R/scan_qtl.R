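#' Single-locus Haley-Knott genome scan
#'
#' At every position in the genotype-probability grid, regresses the trait
#' on the covariates plus the additive dosage `x = P(BB) - P(AA)` and the
#' dominance regressor `z = P(AB)`, and reports
#' `LOD = (n/2) * log10(RSS0 / RSS1)` against the covariates-only null.
#' Individuals with a missing trait value or incomplete covariates are
#' dropped listwise; `n` in the LOD is the number actually used.
#'
#' @param probs a [calc_genoprob()] result.
#' @param cross the cross the probabilities were computed from.
#' @param trait phenotype column name.
#' @param covariates character vector of covariate names (columns of the
#'   cross covariate or phenotype tables; factors are dummy-coded), or a
#'   numeric matrix with one row per individual.
#' @return data.frame of class `"scan_result"` with columns `chr`,
#'   `pos_cM`, `name`, `lod`, and attributes `trait`, `covariates`,
#'   `n_used`, `rss0`.
#' @export
scanone <- function(probs, cross, trait, covariates = NULL) {
  y <- cross$pheno[[trait]]
  if (is.null(y)) stop("trait '", trait, "' not found")
  C <- build_covar_matrix(cross, covariates)
  ok <- complete_rows(y, C)
  if (sum(ok) < 5) stop("fewer than 5 complete individuals for '", trait, "'")
  y <- y[ok]
  if (stats::var(y) == 0) stop("trait '", trait, "' is constant")
  C <- C[ok, , drop = FALSE]
  check_full_rank(C, colnames(C))
  X <- dosage_x(probs)[ok, , drop = FALSE]
  Z <- dosage_z(probs)[ok, , drop = FALSE]
  eng <- hk_engine(X, Z, matrix(y, ncol = 1), C)
  out <- cbind(probs$positions, lod = as.numeric(eng$lod))
  attr(out, "trait") <- trait
  attr(out, "covariates") <- if (is.matrix(covariates)) colnames(covariates) else covariates
  attr(out, "n_used") <- eng$n
  attr(out, "rss0") <- eng$rss0
  attr(out, "perfect_fit") <- as.logical(apply(eng$capped, 1, any))
  if (any(eng$capped))
    message("scanone[", trait, "]: perfect fit at ",
            sum(apply(eng$capped, 1, any)), " position(s); LOD capped")
  class(out) <- c("scan_result", "data.frame")
  out
}

# scan many aligned response columns at once (used by eQTL scans and
# permutation machinery); Y rows must already match cross individuals
scan_matrix <- function(probs, cross, Y, covariates = NULL, rows = NULL) {
  C <- build_covar_matrix(cross, covariates)
  if (is.null(rows)) rows <- seq_len(n_ind(cross))
  X <- dosage_x(probs)[rows, , drop = FALSE]
  Z <- dosage_z(probs)[rows, , drop = FALSE]
  hk_engine(X, Z, Y, C[rows, , drop = FALSE])$lod
}

#' Peak of a scan
#'
#' @param scan a [scanone()] result.
#' @param chr optional chromosome restriction.
#' @return the row of the scan at the maximum LOD; ties break to the
#'   lowest position on the earliest chromosome (deterministic).
#' @export
max_scan <- function(scan, chr = NULL) {
  s <- if (is.null(chr)) scan else scan[scan$chr %in% chr, , drop = FALSE]
  s[which.max(s$lod), , drop = FALSE]
}

#' Genome-wide permutation maxima
#'
#' Repeatedly permutes the trait rows jointly with the covariate rows
#' against the genotypes (preserving both the trait-covariate structure
#' and the genotype correlation structure), rescans, and records the
#' genome-wide maximum LOD of each permutation. Several traits sharing one
#' covariate set can be permuted together, one column each.
#'
#' @param probs,cross as in [scanone()].
#' @param traits one trait name or several (all sharing `covariates`).
#' @param covariates as in [scanone()].
#' @param n_perm number of permutations (>= 100 recommended).
#' @param seed optional integer seed.
#' @return `n_perm` x `length(traits)` matrix of maximum LOD scores.
#' @export
permutation_maxima <- function(probs, cross, traits, covariates = NULL,
                               n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Y <- as.matrix(cross$pheno[, traits, drop = FALSE])
  C <- build_covar_matrix(cross, covariates)
  ok <- stats::complete.cases(Y)
  if (ncol(C) > 0) ok <- ok & stats::complete.cases(C)
  Y <- Y[ok, , drop = FALSE]
  C <- C[ok, , drop = FALSE]
  X <- dosage_x(probs)[ok, , drop = FALSE]
  Z <- dosage_z(probs)[ok, , drop = FALSE]
  n <- nrow(Y)
  out <- matrix(NA_real_, n_perm, length(traits),
                dimnames = list(NULL, traits))
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n)
    lod <- hk_engine(X, Z, Y[idx, , drop = FALSE], C[idx, , drop = FALSE])$lod
    out[i, ] <- apply(lod, 2, max)
  }
  out
}

#' Genome-wide permutation significance threshold
#'
#' Empirical `(1 - alpha)` quantile of the genome-wide maximum LOD over
#' permutations of the (trait, covariates) rows against the genotypes.
#'
#' @inheritParams permutation_maxima
#' @param trait single trait name.
#' @param alpha genome-wide type-I error rate; `alpha = 0` returns the
#'   maximum of the permutation maxima.
#' @return the LOD threshold (scalar).
#' @export
permutation_threshold <- function(probs, cross, trait, covariates = NULL,
                                  n_perm = 1000, alpha = 0.05, seed = NULL) {
  stopifnot(n_perm >= 1, alpha >= 0, alpha <= 1)
  mx <- permutation_maxima(probs, cross, trait, covariates, n_perm, seed)
  as.numeric(stats::quantile(mx[, 1], 1 - alpha, names = FALSE))
}

#' Genotype principal components for structure correction
#'
#' Encodes genotypes as -1/0/1, mean-imputes missing values per marker,
#' and returns the first `k` principal-component scores as covariate
#' columns for relatedness/structure adjustment in the scans.
#'
#' @param cross a cross object.
#' @param k number of components; `k = 0` gives a zero-column matrix.
#' @return numeric matrix, individuals x `k`, columns `PC1..PCk`.
#' @export
pca_covariates <- function(cross, k) {
  n <- n_ind(cross)
  if (k >= n) stop("k must be smaller than the number of individuals (", n, ")")
  if (k == 0) return(matrix(numeric(0), n, 0))
  G <- cross$geno - 2
  mu <- colMeans(G, na.rm = TRUE)
  for (j in seq_len(ncol(G))) G[is.na(G[, j]), j] <- mu[j]
  G <- G[, apply(G, 2, stats::var) > 0, drop = FALSE]
  pc <- stats::prcomp(G, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(k, ncol(pc$x))), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

#' Subset a cross by individuals or sex
#'
#' @param cross a cross object.
#' @param ids individual ids to keep, or
#' @param sex `"F"` or `"M"` to keep one sex.
#' @return the subsetted cross.
#' @export
subset_cross <- function(cross, ids = NULL, sex = NULL) {
  keep <- rep(TRUE, n_ind(cross))
  if (!is.null(sex)) keep <- keep & cross$covar$sex %in% sex
  if (!is.null(ids)) keep <- keep & rownames(cross$geno) %in% ids
  make_cross(cross$map, cross$geno[keep, , drop = FALSE],
             cross$pheno[keep, , drop = FALSE],
             cross$covar[keep, , drop = FALSE])
}

#' Decide whether the egg covariate enters a female trait's model
#'
#' For female traits, egg production (total mass of eggs laid in the
#' fecundity trial) is included as a covariate only when it is itself
#' associated with the bone trait: the trait is regressed on the egg
#' column plus body weight, and the egg covariate is included iff the egg
#' coefficient's p-value is below `alpha`.
#'
#' @param cross a female-only cross (an error is raised if males are
#'   present: the egg covariate is undefined for males).
#' @param trait phenotype column name.
#' @param base_covariates covariates always present (default body weight).
#' @param alpha inclusion threshold (default 0.05).
#' @return list with `include` (logical), `p_value`, and `covariates`
#'   (base covariates plus `"eggs"` when included). The decision is
#'   reported via `message()` for audit.
#' @export
select_egg_covariate <- function(cross, trait,
                                 base_covariates = "body_weight",
                                 alpha = 0.05) {
  if (any(cross$covar$sex == "M"))
    stop("egg covariate selection requires a female-only cross; subset first")
  if (!("eggs" %in% names(cross$covar)))
    stop("no 'eggs' covariate column in cross")
  y <- cross$pheno[[trait]]
  eggs <- cross$covar$eggs
  if (all(is.na(eggs))) {
    message("egg covariate all-missing for trait '", trait, "'; skipped")
    return(list(include = FALSE, p_value = NA_real_,
                covariates = base_covariates))
  }
  C <- build_covar_matrix(cross, base_covariates)
  dat <- data.frame(y = y, eggs = eggs, C)
  fit <- stats::lm(y ~ ., data = dat)
  p <- summary(fit)$coefficients["eggs", "Pr(>|t|)"]
  include <- is.finite(p) && p < alpha
  message("egg covariate for '", trait, "': p = ", signif(p, 3),
          if (include) " -> included" else " -> not included")
  list(include = include, p_value = p,
       covariates = if (include) c(base_covariates, "eggs") else base_covariates)
}

#' Two-locus Haley-Knott scan for epistasis
#'
#' For every pair of distinct positions, fits the full model (both loci's
#' additive and dominance terms plus all four pairwise products) and the
#' additive model (no products), each against the covariates-only null:
#' `lod_full`, `lod_add`, and the interaction score
#' `lod_int = lod_full - lod_add`.
#'
#' @inheritParams scanone
#' @param positions optional subset of position names to grid over;
#'   default is marker positions only (pseudomarkers excluded to bound the
#'   quadratic cost).
#' @return data.frame of class `"pairscan_result"` with one row per
#'   unordered pair: `name1`, `chr1`, `pos1`, `name2`, `chr2`, `pos2`,
#'   `lod_full`, `lod_add`, `lod_int`.
#' @export
scantwo <- function(probs, cross, trait, covariates = NULL, positions = NULL) {
  y <- cross$pheno[[trait]]
  if (is.null(y)) stop("trait '", trait, "' not found")
  C <- build_covar_matrix(cross, covariates)
  ok <- complete_rows(y, C)
  y <- y[ok]
  C <- C[ok, , drop = FALSE]
  check_full_rank(C, colnames(C))
  pos <- probs$positions
  sel <- if (is.null(positions)) which(pos$is_marker)
         else match(positions, pos$name)
  X <- dosage_x(probs)[ok, sel, drop = FALSE]
  Z <- dosage_z(probs)[ok, sel, drop = FALSE]
  n <- length(y)
  M0 <- cbind(1, C)
  rss0 <- sum(stats::lm.fit(M0, y)$residuals^2)
  pairs <- utils::combn(length(sel), 2)
  # drop degenerate pairs at identical (chr, pos)
  same <- pos$chr[sel[pairs[1, ]]] == pos$chr[sel[pairs[2, ]]] &
    pos$pos_cM[sel[pairs[1, ]]] == pos$pos_cM[sel[pairs[2, ]]]
  pairs <- pairs[, !same, drop = FALSE]
  np <- ncol(pairs)
  lod_full <- lod_add <- numeric(np)
  for (i in seq_len(np)) {
    a <- pairs[1, i]; b <- pairs[2, i]
    x1 <- X[, a]; z1 <- Z[, a]; x2 <- X[, b]; z2 <- Z[, b]
    Madd <- cbind(M0, x1, z1, x2, z2)
    Mfull <- cbind(Madd, x1 * x2, x1 * z2, z1 * x2, z1 * z2)
    rss_a <- sum(stats::lm.fit(Madd, y)$residuals^2)
    rss_f <- sum(stats::lm.fit(Mfull, y)$residuals^2)
    floor_rss <- max(rss0 * 1e-15, .Machine$double.xmin)
    lod_add[i] <- n / 2 * log10(rss0 / max(rss_a, floor_rss))
    lod_full[i] <- n / 2 * log10(rss0 / max(rss_f, floor_rss))
  }
  out <- data.frame(name1 = pos$name[sel[pairs[1, ]]],
                    chr1 = pos$chr[sel[pairs[1, ]]],
                    pos1 = pos$pos_cM[sel[pairs[1, ]]],
                    name2 = pos$name[sel[pairs[2, ]]],
                    chr2 = pos$chr[sel[pairs[2, ]]],
                    pos2 = pos$pos_cM[sel[pairs[2, ]]],
                    lod_full = lod_full, lod_add = lod_add,
                    lod_int = lod_full - lod_add,
                    stringsAsFactors = FALSE)
  attr(out, "trait") <- trait
  attr(out, "n_used") <- n
  class(out) <- c("pairscan_result", "data.frame")
  out
}

#' Permutation threshold for the two-locus interaction score
#'
#' Permutes (trait, covariates) rows against genotypes, recomputes the
#' pair scan, and records the maximum `lod_int` per permutation.
#'
#' @inheritParams scantwo
#' @param n_perm permutations.
#' @param alpha genome-wide error rate.
#' @param seed optional seed.
#' @return the `(1 - alpha)` quantile of the interaction maxima.
#' @export
scantwo_permutation_threshold <- function(probs, cross, trait,
                                          covariates = NULL, positions = NULL,
                                          n_perm = 1000, alpha = 0.05,
                                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- cross$pheno[[trait]]
  C <- build_covar_matrix(cross, covariates)
  ok <- complete_rows(y, C)
  n <- sum(ok)
  cr <- cross
  mx <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n_ind(cross))
    # permute phenotype + covariate rows jointly
    cr$pheno <- cross$pheno[idx, , drop = FALSE]
    cr$covar <- cross$covar[idx, , drop = FALSE]
    s2 <- scantwo(probs, cr, trait, covariates, positions)
    mx[i] <- max(s2$lod_int)
  }
  as.numeric(stats::quantile(mx, 1 - alpha, names = FALSE))
}

#' LOD-drop support interval around a peak
#'
#' The smallest contiguous region around the peak in which the LOD curve
#' stays within `drop` of the peak value, then expanded outward to the
#' closest flanking markers (so interval endpoints are marker positions).
#' The conventional `drop = 1.8` gives an approximate 95% support
#' interval for an advanced-intercross scan.
#'
#' @param scan a [scanone()] result.
#' @param peak peak row (as returned by [max_scan()]), or a position name.
#' @param drop LOD units to descend from the peak (default 1.8).
#' @param map the genetic map (for marker expansion).
#' @return one-row [genomic_intervals()] in cM with extra logical columns
#'   `truncated` (region hit a chromosome end before dropping) and
#'   `degenerate` (flat curve: whole chromosome).
#' @export
lod_support_interval <- function(scan, peak, drop = 1.8, map) {
  if (is.character(peak)) peak <- scan[scan$name == peak, , drop = FALSE]
  stopifnot(nrow(peak) == 1)
  s <- scan[scan$chr == peak$chr, , drop = FALSE]
  s <- s[order(s$pos_cM), , drop = FALSE]
  pi <- which(s$name == peak$name)
  if (length(pi) != 1) stop("peak position not found on its chromosome")
  cut <- s$lod[pi] - drop
  lo <- pi
  while (lo > 1 && s$lod[lo - 1] >= cut) lo <- lo - 1
  hi <- pi
  while (hi < nrow(s) && s$lod[hi + 1] >= cut) hi <- hi + 1
  truncated <- (lo == 1 && s$lod[1] >= cut) ||
    (hi == nrow(s) && s$lod[nrow(s)] >= cut)
  degenerate <- lo == 1 && hi == nrow(s) && max(s$lod) - min(s$lod) < 1e-12
  mpos <- sort(map$pos_cM[map$chr == peak$chr])
  left <- s$pos_cM[lo]
  right <- s$pos_cM[hi]
  below <- mpos[mpos <= left + 1e-9]
  above <- mpos[mpos >= right - 1e-9]
  left <- if (length(below)) max(below) else min(mpos)
  right <- if (length(above)) min(above) else max(mpos)
  out <- genomic_intervals(chr = peak$chr, start = left, end = right,
                           unit = "cM", kind = "qtl",
                           label = attr(scan, "trait"),
                           peak_lod = peak$lod)
  out$peak_cM <- peak$pos_cM
  out$truncated <- truncated
  out$degenerate <- degenerate
  out
}

#' Forward selection of a multiple-QTL model
#'
#' Iteratively adds the locus with the highest conditional LOD (a genome
#' scan with the already-selected loci's dosages as covariates) while that
#' LOD exceeds the single-locus threshold; afterwards, screens locus pairs
#' with [scantwo()] and adds interaction terms whose `lod_int` exceeds the
#' interaction threshold. Every decision is reported via `message()`.
#'
#' @inheritParams scanone
#' @param thresholds list with elements `main` (single-locus LOD
#'   threshold) and optionally `interaction` (pair interaction threshold;
#'   `Inf` disables the epistasis phase).
#' @param max_qtl safety cap on selected loci.
#' @return list of class `"qtl_model"`: `loci` (data.frame `chr`, `pos_cM`,
#'   `name`, `a`, `d`), `pairs` (interaction terms with effects), `lod`
#'   (model vs covariates-only), `pve` (percent variance explained),
#'   `pve_terms`, plus the trait/covariate bookkeeping needed to refit.
#' @export
forward_select <- function(probs, cross, trait, covariates = NULL,
                           thresholds, max_qtl = 6) {
  stopifnot(!is.null(thresholds$main))
  int_thr <- if (is.null(thresholds$interaction)) Inf else thresholds$interaction
  y <- cross$pheno[[trait]]
  C <- build_covar_matrix(cross, covariates)
  ok <- complete_rows(y, C)
  Xall <- dosage_x(probs)
  Zall <- dosage_z(probs)
  sel <- character(0)
  repeat {
    extra <- if (length(sel))
      cbind(C, Xall[, sel, drop = FALSE], Zall[, sel, drop = FALSE]) else C
    okr <- complete_rows(y, extra)
    eng <- hk_engine(Xall[okr, , drop = FALSE], Zall[okr, , drop = FALSE],
                     matrix(y[okr], ncol = 1), extra[okr, , drop = FALSE])
    lod <- as.numeric(eng$lod)
    lod[match(sel, probs$positions$name)] <- -Inf
    best <- which.max(lod)
    if (lod[best] < thresholds$main || length(sel) >= max_qtl) {
      if (length(sel) < max_qtl)
        message("forward_select[", trait, "]: stop, best conditional LOD ",
                round(lod[best], 2), " < ", round(thresholds$main, 2))
      break
    }
    sel <- c(sel, probs$positions$name[best])
    message("forward_select[", trait, "]: added ",
            probs$positions$name[best], " (conditional LOD ",
            round(lod[best], 2), ")")
  }

  pairs_kept <- NULL
  if (is.finite(int_thr) && length(sel) >= 2) {
    s2 <- scantwo(probs, cross, trait, covariates, positions = sel)
    hit <- s2[s2$lod_int > int_thr, , drop = FALSE]
    if (nrow(hit)) {
      pairs_kept <- hit[order(-hit$lod_int), , drop = FALSE]
      message("forward_select[", trait, "]: ", nrow(pairs_kept),
              " epistatic pair(s) above interaction threshold")
    }
  }
  fit_qtl_model(probs, cross, trait, covariates, sel,
                if (is.null(pairs_kept)) NULL
                else pairs_kept[, c("name1", "name2")])
}

#' Fit (or refit) a declared multiple-QTL model
#'
#' Least-squares fit of trait ~ covariates + per-locus (x, z) terms +
#' per-pair interaction products; used both to finish [forward_select()]
#' and to verify stored models.
#'
#' @inheritParams scanone
#' @param loci character vector of position names.
#' @param pairs optional data.frame with columns `name1`, `name2`.
#' @return a `"qtl_model"` (see [forward_select()]).
#' @export
fit_qtl_model <- function(probs, cross, trait, covariates = NULL,
                          loci = character(0), pairs = NULL) {
  y <- cross$pheno[[trait]]
  C <- build_covar_matrix(cross, covariates)
  X <- dosage_x(probs)
  Z <- dosage_z(probs)
  cols <- list()
  for (l in loci) {
    cols[[paste0("a:", l)]] <- X[, l]
    cols[[paste0("d:", l)]] <- Z[, l]
  }
  if (!is.null(pairs)) for (i in seq_len(nrow(pairs))) {
    l1 <- pairs$name1[i]; l2 <- pairs$name2[i]
    cols[[paste0("i:", l1, "*", l2)]] <- X[, l1] * X[, l2]
  }
  Q <- if (length(cols)) do.call(cbind, cols) else matrix(numeric(0), length(y), 0)
  ok <- complete_rows(y, cbind(C, Q))
  n <- sum(ok)
  M0 <- cbind(1, C[ok, , drop = FALSE])
  Mf <- cbind(M0, Q[ok, , drop = FALSE])
  yv <- y[ok]
  rss0 <- sum(stats::lm.fit(M0, yv)$residuals^2)
  fit <- stats::lm.fit(Mf, yv)
  rssf <- sum(fit$residuals^2)
  tss <- sum((yv - mean(yv))^2)
  lod <- n / 2 * log10(rss0 / max(rssf, rss0 * 1e-15))
  pve <- 100 * (rss0 - rssf) / tss
  coefs <- fit$coefficients
  names(coefs) <- c("(Intercept)",
                    if (ncol(C)) colnames(C) else NULL, names(cols))
  # drop-one percent variance explained per QTL term
  pve_terms <- numeric(0)
  qn <- names(cols)
  for (nm in qn) {
    keep <- setdiff(qn, nm)
    Md <- cbind(M0, Q[ok, keep, drop = FALSE])
    rssd <- sum(stats::lm.fit(Md, yv)$residuals^2)
    pve_terms[nm] <- 100 * (rssd - rssf) / tss
  }
  pos <- probs$positions
  li <- match(loci, pos$name)
  loci_df <- if (length(loci))
    data.frame(name = loci, chr = pos$chr[li], pos_cM = pos$pos_cM[li],
               a = unname(coefs[paste0("a:", loci)]),
               d = unname(coefs[paste0("d:", loci)]),
               stringsAsFactors = FALSE)
  else data.frame(name = character(0), chr = character(0),
                  pos_cM = numeric(0), a = numeric(0), d = numeric(0))
  structure(list(
    trait = trait, covariates = covariates,
    loci = loci_df,
    pairs = if (is.null(pairs) || !nrow(pairs)) NULL else
      data.frame(pairs,
                 effect = unname(coefs[paste0("i:", pairs$name1, "*", pairs$name2)])),
    lod = lod, pve = pve, pve_terms = pve_terms,
    n_used = n, coefficients = coefs), class = "qtl_model")
}

#' @export
print.qtl_model <- function(x, ...) {
  cat("qtl_model for '", x$trait, "': ", nrow(x$loci), " loci, ",
      if (is.null(x$pairs)) 0 else nrow(x$pairs), " interaction(s); LOD ",
      round(x$lod, 3), ", PVE ", round(x$pve, 2), "%\n", sep = "")
  if (nrow(x$loci)) print(x$loci)
  invisible(x)
}
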