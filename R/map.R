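#' Construct a genetic map
#'
#' A genetic map is an ordered table of markers with chromosome assignment,
#' genetic position in centimorgan and (optionally) physical position in
#' megabase. It is the backbone for genome scans, pseudomarker grids and
#' cM/Mb coordinate conversion.
#'
#' @param marker character vector of unique marker identifiers.
#' @param chr character (or coercible) chromosome labels.
#' @param pos_cM non-negative genetic positions in centimorgan.
#' @param pos_Mb optional physical positions in megabase (`NA` allowed).
#'
#' @return A `data.frame` of class `"genetic_map"` with columns
#'   `marker`, `chr`, `pos_cM`, `pos_Mb`, ordered by chromosome then
#'   position. Chromosome order follows first appearance in the input.
#'
#' @details Within each chromosome positions must be strictly increasing in
#' cM. When at least two markers on a chromosome carry physical positions,
#' those must be non-decreasing with cM; violations are rejected because
#' downstream piecewise-linear coordinate conversion assumes colinearity.
#'
#' @export
genetic_map <- function(marker, chr, pos_cM, pos_Mb = NULL) {
  marker <- as.character(marker)
  chr <- rep_len(as.character(chr), length(marker))
  if (is.null(pos_Mb)) pos_Mb <- rep(NA_real_, length(marker))
  stopifnot(length(pos_cM) == length(marker), length(pos_Mb) == length(marker))
  if (anyDuplicated(marker))
    stop("duplicated marker ids: ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  if (any(!is.finite(pos_cM)) || any(pos_cM < 0))
    stop("pos_cM must be finite and non-negative")
  map <- data.frame(marker = marker, chr = chr, pos_cM = as.numeric(pos_cM),
                    pos_Mb = as.numeric(pos_Mb), stringsAsFactors = FALSE)
  # the given order is the map order: chromosomes must form contiguous
  # blocks and positions must increase within each block (no silent sorting,
  # so files with out-of-order markers are rejected, not repaired)
  blocks <- rle(chr)$values
  if (anyDuplicated(blocks))
    stop("chromosome blocks are interleaved: ",
         blocks[duplicated(blocks)][1])
  rownames(map) <- NULL
  validate_map(map)
  class(map) <- c("genetic_map", "data.frame")
  map
}

validate_map <- function(map) {
  for (cc in unique(map$chr)) {
    sub <- map[map$chr == cc, , drop = FALSE]
    d <- diff(sub$pos_cM)
    if (any(d <= 0)) {
      bad <- sub$marker[which(d <= 0)[1] + 1L]
      stop("genetic map not strictly increasing on chromosome ", cc,
           " at marker ", bad)
    }
    has_mb <- !is.na(sub$pos_Mb)
    if (sum(has_mb) >= 2) {
      mb <- sub$pos_Mb[has_mb]
      if (any(diff(mb) < 0))
        stop("physical positions decrease with genetic position on chromosome ",
             cc)
    }
  }
  invisible(TRUE)
}

#' Expand a genetic map by a constant factor
#'
#' Multiplies every cM position by `factor`. Scanning advanced-intercross
#' data with F2-generation machinery understates the recombination actually
#' accumulated over extra generations of intermating; rescaling the map is
#' the standard approximation when the map distances were estimated in an
#' earlier generation.
#'
#' @param map a [genetic_map()].
#' @param factor expansion factor, `>= 1`.
#' @return the map with all `pos_cM` multiplied by `factor`.
#' @export
map_expand <- function(map, factor) {
  stopifnot(inherits(map, "genetic_map"), is.numeric(factor), factor >= 1)
  map$pos_cM <- map$pos_cM * factor
  map
}

#' Assemble a cross object
#'
#' Bundles a genotyped, phenotyped mapping population: a genetic map, a
#' genotype matrix, a phenotype table and a covariate table, all keyed to
#' the same individuals.
#'
#' @param map a [genetic_map()].
#' @param geno integer matrix, individuals x markers, coded 1/2/3 for
#'   AA/AB/BB with `NA` for missing; column names must equal the map's
#'   marker ids in map order.
#' @param pheno data.frame of quantitative traits (one row per individual).
#' @param covar data.frame of covariates (`sex`, `batch`, `body_weight`,
#'   optional `eggs`), one row per individual.
#' @return list of class `"cross_ail"`.
#' @export
make_cross <- function(map, geno, pheno, covar) {
  stopifnot(inherits(map, "genetic_map"))
  geno <- as.matrix(geno)
  if (is.null(colnames(geno)) || !identical(colnames(geno), map$marker))
    stop("genotype columns must match the map marker order exactly")
  if (nrow(pheno) != nrow(geno) || nrow(covar) != nrow(geno))
    stop("phenotype/covariate rows must match genotype rows one-to-one")
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% 1:3))
    stop("genotype codes must be 1 (AA), 2 (AB) or 3 (BB), or NA")
  if (is.null(rownames(geno))) rownames(geno) <- sprintf("ind%03d", seq_len(nrow(geno)))
  structure(list(map = map, geno = geno,
                 pheno = as.data.frame(pheno), covar = as.data.frame(covar)),
            class = "cross_ail")
}

#' @export
print.cross_ail <- function(x, ...) {
  cat("cross_ail: ", nrow(x$geno), " individuals, ", ncol(x$geno),
      " markers on ", length(unique(x$map$chr)), " chromosomes\n", sep = "")
  cat("traits:    ", paste(names(x$pheno), collapse = ", "), "\n", sep = "")
  cat("covariates:", paste(names(x$covar), collapse = ", "), "\n")
  invisible(x)
}

n_ind <- function(cross) nrow(cross$geno)

#' Construct a set of genomic intervals
#'
#' The common currency of support-interval overlap, region merging and
#' hotspot coverage. Every interval set carries an explicit coordinate unit
#' (`"cM"` or `"Mb"`); mixing units without conversion is refused downstream.
#'
#' @param chr chromosome labels.
#' @param start,end interval endpoints, `start <= end`.
#' @param unit `"cM"` or `"Mb"` (single value for the whole set).
#' @param kind provenance: `"qtl"`, `"eqtl"` or `"f2_qtl"`.
#' @param label trait name or probeset id per interval.
#' @param peak_lod optional peak LOD score per interval.
#' @return data.frame of class `"genomic_intervals"` with attribute `unit`.
#' @export
genomic_intervals <- function(chr, start, end, unit, kind = "qtl",
                              label = NA_character_, peak_lod = NA_real_) {
  unit <- match.arg(unit, c("cM", "Mb"))
  n <- max(length(chr), length(start), length(end))
  chr <- rep_len(as.character(chr), n)
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  kind <- rep_len(as.character(kind), n)
  if (!all(kind %in% c("qtl", "eqtl", "f2_qtl")))
    stop("kind must be one of qtl, eqtl, f2_qtl")
  out <- data.frame(chr = as.character(chr), start = as.numeric(start),
                    end = as.numeric(end), kind = kind,
                    label = rep_len(as.character(label), n),
                    peak_lod = rep_len(as.numeric(peak_lod), n),
                    stringsAsFactors = FALSE)
  bad <- which(out$end < out$start)
  if (length(bad))
    stop("interval end < start at row(s): ", paste(bad, collapse = ", "))
  attr(out, "unit") <- unit
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

interval_unit <- function(x) attr(x, "unit")

#' @export
`[.genomic_intervals` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "unit") <- attr(x, "unit")
    class(out) <- class(x)
  }
  out
}

#' Concatenate interval sets
#'
#' Base `rbind()` on data.frame subclasses drops the `unit` attribute;
#' this keeps it and refuses to mix units.
#'
#' @param ... [genomic_intervals()] sets with identical units.
#' @return one combined interval set.
#' @export
bind_intervals <- function(...) {
  parts <- list(...)
  units <- unique(vapply(parts, function(p) interval_unit(p), character(1)))
  if (length(units) != 1)
    stop("cannot bind intervals with different units: ",
         paste(units, collapse = ", "))
  out <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(out) <- NULL
  attr(out, "unit") <- units
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

stop_if_mixed_units <- function(a, b) {
  if (!identical(interval_unit(a), interval_unit(b)))
    stop("interval sets are in different units (", interval_unit(a), " vs ",
         interval_unit(b), "); convert with coordinate_convert() first")
  invisible(TRUE)
}

#' Assemble an expression set
#'
#' @param matrix numeric matrix, probesets x individuals (log-scale
#'   intensities assumed); rownames are probeset ids, colnames individual
#'   ids.
#' @param annotation data.frame with columns `probeset`, `chr`, `pos_Mb`
#'   and optionally `pos_cM`, giving the genomic location of each probeset.
#' @return list of class `"expression_set"`.
#' @export
expression_set <- function(matrix, annotation) {
  matrix <- as.matrix(matrix)
  if (is.null(rownames(matrix))) stop("expression matrix needs probeset rownames")
  if (is.null(colnames(matrix))) stop("expression matrix needs individual colnames")
  annotation <- as.data.frame(annotation)
  req <- c("probeset", "chr", "pos_Mb")
  if (!all(req %in% names(annotation)))
    stop("annotation needs columns: ", paste(req, collapse = ", "))
  if (!("pos_cM" %in% names(annotation))) annotation$pos_cM <- NA_real_
  structure(list(matrix = matrix, annotation = annotation),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("expression_set: ", nrow(x$matrix), " probesets x ", ncol(x$matrix),
      " individuals (", sum(!is.na(x$annotation$pos_Mb)), " annotated)\n",
      sep = "")
  invisible(x)
}
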