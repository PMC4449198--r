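# Core least-squares machinery for Haley-Knott scans.
#
# Everything is expressed through one vectorised engine: regress (possibly
# many) response columns on the additive dosage x and dominance regressor z
# at every position simultaneously, after projecting out the covariates.
# For a single position the explained sum of squares of (x, z) on the
# covariate-residualised response has the closed 2x2 form used below, so a
# whole-genome scan is a handful of matrix products.

# numeric covariate model matrix (no intercept column; the engine adds it)
build_covar_matrix <- function(cross, covariates) {
  if (is.null(covariates) || length(covariates) == 0)
    return(matrix(numeric(0), n_ind(cross), 0))
  if (is.matrix(covariates)) return(covariates)
  cols <- list()
  for (nm in covariates) {
    v <- if (nm %in% names(cross$covar)) cross$covar[[nm]]
         else if (nm %in% names(cross$pheno)) cross$pheno[[nm]]
         else stop("covariate '", nm, "' not found in cross")
    if (is.numeric(v)) {
      cols[[nm]] <- v
    } else {
      lev <- sort(unique(v[!is.na(v)]))
      for (l in lev[-1]) cols[[paste0(nm, l)]] <-
          ifelse(is.na(v), NA_real_, as.numeric(v == l))
    }
  }
  do.call(cbind, cols)
}

check_full_rank <- function(C, names) {
  if (ncol(C) == 0) return(invisible(TRUE))
  q <- qr(cbind(1, C))
  if (q$rank < ncol(C) + 1) {
    aliased <- setdiff(colnames(C), colnames(C)[q$pivot[seq_len(q$rank)] - 1])
    stop("covariate matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  invisible(TRUE)
}

# LOD matrix (positions x responses) for Y ~ C + x + z at every position.
# X, Z: n x P; Y: n x m; C: n x k (without intercept). Rows must be
# complete. Returns list(lod = P x m matrix, rss0 = per-response null RSS).
hk_engine <- function(X, Z, Y, C) {
  n <- nrow(Y)
  M <- cbind(rep(1, n), C)
  Qc <- qr.Q(qr(M))
  resid_on <- function(A) A - Qc %*% crossprod(Qc, A)
  Yr <- resid_on(Y)
  Xr <- resid_on(X)
  Zr <- resid_on(Z)
  rss0 <- colSums(Yr^2)
  sxx <- colSums(Xr^2)
  szz <- colSums(Zr^2)
  sxz <- colSums(Xr * Zr)
  sxy <- crossprod(Xr, Yr)            # P x m
  szy <- crossprod(Zr, Yr)
  det <- sxx * szz - sxz^2
  scale <- pmax(sxx * szz, .Machine$double.eps)
  ok2 <- det > 1e-12 * scale
  expl <- matrix(0, nrow(sxy), ncol(sxy))
  if (any(ok2)) {
    expl[ok2, ] <- (szz[ok2] * sxy[ok2, , drop = FALSE]^2 -
                      2 * sxz[ok2] * sxy[ok2, , drop = FALSE] *
                        szy[ok2, , drop = FALSE] +
                      sxx[ok2] * szy[ok2, , drop = FALSE]^2) / det[ok2]
  }
  one <- which(!ok2)
  for (p in one) {
    if (sxx[p] > 1e-12) expl[p, ] <- sxy[p, ]^2 / sxx[p]
    else if (szz[p] > 1e-12) expl[p, ] <- szy[p, ]^2 / szz[p]
  }
  rss1 <- sweep(-expl, 2, rss0, `+`)
  floor_rss <- pmax(rss0 * 1e-15, .Machine$double.xmin)
  capped <- rss1 <= rep(floor_rss, each = nrow(rss1))
  rss1 <- pmax(rss1, rep(floor_rss, each = nrow(rss1)))
  lod <- sweep(log10(rss1), 2, log10(rss0), `-`) * (-n / 2)
  lod[lod < 0] <- 0   # clip tiny negative rounding noise
  list(lod = lod, rss0 = rss0, n = n, capped = capped)
}

# complete-case row filter over a trait vector and covariate matrix
complete_rows <- function(y, C) {
  ok <- !is.na(y)
  if (ncol(C) > 0) ok <- ok & stats::complete.cases(C)
  ok
}
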