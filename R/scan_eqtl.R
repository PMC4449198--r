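#' Convert between genetic (cM) and physical (Mb) coordinates
#'
#' Piecewise-linear interpolation between anchor markers that carry both
#' a cM and an Mb position. Beyond the terminal anchors of a chromosome,
#' positions are extrapolated with the nearest segment's slope and flagged.
#'
#' @param x a [genomic_intervals()] set (whose `start`/`end` are
#'   converted) or a data.frame with columns `chr` and `pos` (converted in
#'   place).
#' @param map a [genetic_map()] with `pos_Mb` on >= 2 markers per
#'   chromosome used.
#' @param direction `"cM2Mb"` or `"Mb2cM"`.
#' @return the converted object, same shape, with a logical
#'   `extrapolated` column; interval sets get their `unit` attribute
#'   switched.
#' @export
coordinate_convert <- function(x, map, direction = c("cM2Mb", "Mb2cM")) {
  direction <- match.arg(direction)
  conv <- function(chr, pos) {
    out <- rep(NA_real_, length(pos))
    extr <- rep(FALSE, length(pos))
    for (cc in unique(chr)) {
      sub <- map[map$chr == cc & !is.na(map$pos_Mb), , drop = FALSE]
      if (nrow(sub) < 2)
        stop("chromosome ", cc, " has fewer than 2 cM/Mb anchor markers")
      from <- if (direction == "cM2Mb") sub$pos_cM else sub$pos_Mb
      to <- if (direction == "cM2Mb") sub$pos_Mb else sub$pos_cM
      sel <- which(chr == cc)
      p <- pos[sel]
      # interior: linear interpolation; exterior: nearest segment's slope
      res <- stats::approx(from, to, xout = p, ties = "ordered")$y
      k <- length(from)
      lo <- p < from[1]
      hi <- p > from[k]
      if (any(lo)) {
        sl <- (to[2] - to[1]) / (from[2] - from[1])
        res[lo] <- to[1] + sl * (p[lo] - from[1])
      }
      if (any(hi)) {
        sl <- (to[k] - to[k - 1]) / (from[k] - from[k - 1])
        res[hi] <- to[k] + sl * (p[hi] - from[k])
      }
      out[sel] <- res
      extr[sel] <- lo | hi
    }
    list(pos = out, extrapolated = extr)
  }
  if (inherits(x, "genomic_intervals")) {
    want <- if (direction == "cM2Mb") "cM" else "Mb"
    if (!identical(interval_unit(x), want))
      stop("intervals are in ", interval_unit(x), ", cannot apply ", direction)
    a <- conv(x$chr, x$start)
    b <- conv(x$chr, x$end)
    x$start <- pmin(a$pos, b$pos)
    x$end <- pmax(a$pos, b$pos)
    x$extrapolated <- a$extrapolated | b$extrapolated
    attr(x, "unit") <- if (direction == "cM2Mb") "Mb" else "cM"
    x
  } else {
    r <- conv(x$chr, x$pos)
    x$pos <- r$pos
    x$extrapolated <- r$extrapolated
    x
  }
}

#' Local window for cis-eQTL testing
#'
#' A probeset's local window is the 100 cM interval centred on its genetic
#' position, with each endpoint moved outward to the nearest marker at
#' distance >= 50 cM; where no such marker exists the window is truncated
#' at the chromosome end and flagged.
#'
#' @param chr,pos_cM probeset location on the genetic map.
#' @param map a [genetic_map()].
#' @param half_window one-sided window size in cM (default 50).
#' @return list: `chr`, `start`, `end`, `truncated_start`,
#'   `truncated_end`.
#' @export
build_local_window <- function(chr, pos_cM, map, half_window = 50) {
  mpos <- sort(map$pos_cM[map$chr == as.character(chr)])
  if (!length(mpos))
    stop("chromosome ", chr, " absent from the map")
  lt <- pos_cM - half_window
  rt <- pos_cM + half_window
  below <- mpos[mpos <= lt + 1e-9]
  above <- mpos[mpos >= rt - 1e-9]
  trunc_l <- length(below) == 0
  trunc_r <- length(above) == 0
  list(chr = as.character(chr),
       start = if (trunc_l) min(0, mpos[1]) else max(below),
       end = if (trunc_r) max(mpos) else min(above),
       truncated_start = trunc_l, truncated_end = trunc_r)
}

# window position index per probeset; NULL when the probe has no mappable
# location (trans-only scan)
probe_windows <- function(expr, map, positions, half_window = 50) {
  ann <- expr$annotation
  if (any(is.na(ann$pos_cM))) {
    need <- is.na(ann$pos_cM) & !is.na(ann$pos_Mb) & ann$chr %in% map$chr
    if (any(need)) {
      pts <- coordinate_convert(
        data.frame(chr = ann$chr[need], pos = ann$pos_Mb[need]),
        map, "Mb2cM")
      ann$pos_cM[need] <- pts$pos
    }
  }
  out <- vector("list", nrow(ann))
  names(out) <- ann$probeset
  for (i in seq_len(nrow(ann))) {
    if (is.na(ann$pos_cM[i]) || !(ann$chr[i] %in% map$chr)) {
      message("probeset ", ann$probeset[i],
              " has no mapped location; trans-only scan")
      next
    }
    w <- build_local_window(ann$chr[i], ann$pos_cM[i], map, half_window)
    out[[i]] <- which(positions$chr == w$chr &
                        positions$pos_cM >= w$start - 1e-9 &
                        positions$pos_cM <= w$end + 1e-9)
  }
  out
}

#' Dual-threshold permutation for eQTL significance
#'
#' Each iteration permutes the expression-to-genotype individual mapping,
#' subsamples `n_subsample` probesets without replacement, scans each one
#' (within its local window for `scope = "cis"`, genome-wide for
#' `scope = "trans"`), and saves the maximum LOD over the subsample. The
#' `(1 - alpha)` percentile of the saved maxima is the threshold. The
#' genome-wide maximum stochastically dominates the window maximum, so the
#' trans threshold is the higher of the two.
#'
#' @param probs,cross as in [scanone()].
#' @param expr an [expression_set()]; its individuals must be a subset of
#'   the cross individuals.
#' @param scope `"cis"` (window maxima) or `"trans"` (genome-wide maxima).
#' @param n_iter iterations (10000 at full scale; smaller for desk runs).
#' @param n_subsample probesets drawn per iteration.
#' @param alpha percentile tail (default 0.05: 95th percentile).
#' @param seed optional seed.
#' @param covariates optional covariates for the expression scans
#'   (default none).
#' @return the threshold LOD (scalar); the vector of per-iteration maxima
#'   is attached as attribute `"maxima"`.
#' @export
eqtl_permutation_threshold <- function(probs, cross, expr,
                                       scope = c("cis", "trans"),
                                       n_iter = 10000, n_subsample = 100,
                                       alpha = 0.05, seed = NULL,
                                       covariates = NULL) {
  scope <- match.arg(scope)
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(expr$matrix)
  if (n_subsample > m)
    stop("n_subsample (", n_subsample, ") exceeds probeset count (", m, ")")
  ids <- intersect(colnames(expr$matrix), rownames(cross$geno))
  rows <- match(ids, rownames(cross$geno))
  Y <- t(expr$matrix[, ids, drop = FALSE])
  wins <- if (scope == "cis")
    probe_windows(expr, cross$map, probs$positions) else NULL
  n <- length(ids)
  mx <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    perm <- sample.int(n)
    sub <- sample.int(m, n_subsample)
    lod <- scan_matrix(probs, cross, Y[perm, sub, drop = FALSE],
                       covariates, rows)
    if (scope == "trans") {
      mx[it] <- max(lod)
    } else {
      best <- -Inf
      for (j in seq_along(sub)) {
        w <- wins[[sub[j]]]
        if (is.null(w) || !length(w)) next
        best <- max(best, max(lod[w, j]))
      }
      mx[it] <- if (is.finite(best)) best else 0
    }
  }
  thr <- as.numeric(stats::quantile(mx, 1 - alpha, names = FALSE))
  attr(thr, "maxima") <- mx
  thr
}

#' Map local (cis) and distal (trans) eQTL
#'
#' Scans every probeset's expression genome-wide with Haley-Knott
#' regression. A probeset gets a cis record when its LOD passes the cis
#' threshold at any position inside its local window, and a trans record
#' when it passes the (higher) trans threshold somewhere outside the
#' window. Each record carries a 1.8-LOD-drop support interval expanded to
#' the closest markers.
#'
#' @inheritParams eqtl_permutation_threshold
#' @param thresholds list with elements `cis` and `trans` (LOD cutoffs).
#' @param drop LOD drop for support intervals (default 1.8).
#' @return data.frame of class `"eqtl_records"`: `probeset`, `kind`,
#'   `chr`, `pos_cM`, `lod`, `ci_lo`, `ci_hi` (cM, marker-expanded).
#' @export
eqtl_scan <- function(probs, cross, expr, thresholds, covariates = NULL,
                      drop = 1.8) {
  stopifnot(!is.null(thresholds$cis), !is.null(thresholds$trans))
  ids <- intersect(colnames(expr$matrix), rownames(cross$geno))
  if (!length(ids)) stop("no shared individuals between expression and cross")
  rows <- match(ids, rownames(cross$geno))
  Y <- t(expr$matrix[, ids, drop = FALSE])
  lod <- scan_matrix(probs, cross, Y, covariates, rows)
  pos <- probs$positions
  wins <- probe_windows(expr, cross$map, pos)
  probes <- rownames(expr$matrix)

  rec <- list()
  for (j in seq_along(probes)) {
    lj <- lod[, j]
    w <- wins[[probes[j]]]
    scan_j <- cbind(pos, lod = lj)
    class(scan_j) <- c("scan_result", "data.frame")
    attr(scan_j, "trait") <- probes[j]
    if (!is.null(w) && length(w) && max(lj[w]) >= thresholds$cis) {
      k <- w[which.max(lj[w])]
      ci <- lod_support_interval(scan_j, scan_j[k, ], drop, cross$map)
      rec[[length(rec) + 1]] <- data.frame(
        probeset = probes[j], kind = "cis", chr = pos$chr[k],
        pos_cM = pos$pos_cM[k], lod = lj[k],
        ci_lo = ci$start, ci_hi = ci$end, stringsAsFactors = FALSE)
    }
    outside <- if (is.null(w)) seq_along(lj) else setdiff(seq_along(lj), w)
    if (length(outside) && max(lj[outside]) >= thresholds$trans) {
      k <- outside[which.max(lj[outside])]
      ci <- lod_support_interval(scan_j, scan_j[k, ], drop, cross$map)
      rec[[length(rec) + 1]] <- data.frame(
        probeset = probes[j], kind = "trans", chr = pos$chr[k],
        pos_cM = pos$pos_cM[k], lod = lj[k],
        ci_lo = ci$start, ci_hi = ci$end, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rec)) do.call(rbind, rec) else
    data.frame(probeset = character(0), kind = character(0),
               chr = character(0), pos_cM = numeric(0), lod = numeric(0),
               ci_lo = numeric(0), ci_hi = numeric(0))
  class(out) <- c("eqtl_records", "data.frame")
  out
}

#' Support intervals of eQTL records as a genomic interval set
#'
#' @param records an [eqtl_scan()] result.
#' @param kind optionally restrict to `"cis"` or `"trans"` records.
#' @return a [genomic_intervals()] set in cM, `kind = "eqtl"`, labelled by
#'   probeset, carrying peak LOD.
#' @export
eqtl_intervals <- function(records, kind = NULL) {
  r <- if (is.null(kind)) records else records[records$kind == kind, , drop = FALSE]
  genomic_intervals(chr = r$chr, start = r$ci_lo, end = r$ci_hi,
                    unit = "cM", kind = "eqtl", label = r$probeset,
                    peak_lod = r$lod)
}
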