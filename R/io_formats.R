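#' Read a rotated-header cross CSV
#'
#' Reads the cross-CSV dialect in which row 1 holds column names (phenotypes
#' and covariates first, then markers), row 2 the chromosome of each marker
#' column (blank for phenotype columns), row 3 the cM position, and all
#' subsequent rows one individual each. Phenotype/covariate columns are
#' auto-detected as the columns whose chromosome cell is blank.
#'
#' @param path file path.
#' @param genotype_codes named character vector mapping file codes to
#'   genotypes; default `c(A = "AA", H = "AB", B = "BB")`.
#' @param na_codes strings treated as missing genotype/phenotype
#'   (default empty and `"-"`).
#' @param covariate_cols names treated as covariates rather than traits.
#' @return a [make_cross()] object.
#' @export
read_rqtl_csv <- function(path,
                          genotype_codes = c(A = "AA", H = "AB", B = "BB"),
                          na_codes = c("", "-", "NA"),
                          covariate_cols = c("sex", "batch", "body_weight", "eggs")) {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) < 4) stop("cross CSV needs 3 header rows plus individuals")
  cn <- as.character(raw[1, ])
  chr_row <- trimws(as.character(raw[2, ]))
  pos_row <- trimws(as.character(raw[3, ]))
  is_marker <- chr_row != ""
  if (!any(is_marker)) stop("no marker columns found (chromosome row all blank)")

  map <- genetic_map(marker = cn[is_marker], chr = chr_row[is_marker],
                     pos_cM = as.numeric(pos_row[is_marker]))

  body <- raw[-(1:3), , drop = FALSE]
  geno_chr <- as.matrix(body[, is_marker, drop = FALSE])
  geno_chr[geno_chr %in% na_codes] <- NA
  known <- names(genotype_codes)
  bad <- which(!is.na(geno_chr) & !(geno_chr %in% known), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("unknown genotype code '", geno_chr[bad[1, 1], bad[1, 2]],
         "' at individual row ", bad[1, 1], ", marker ",
         map$marker[bad[1, 2]])
  }
  code_num <- c(AA = 1L, AB = 2L, BB = 3L)[genotype_codes]
  names(code_num) <- known
  geno <- matrix(NA_integer_, nrow(geno_chr), ncol(geno_chr),
                 dimnames = list(NULL, map$marker))
  ok <- !is.na(geno_chr)
  geno[ok] <- code_num[geno_chr[ok]]

  phen_raw <- body[, !is_marker, drop = FALSE]
  names(phen_raw) <- cn[!is_marker]
  id_col <- intersect(c("id", "ID", "individual"), names(phen_raw))
  ids <- if (length(id_col)) phen_raw[[id_col[1]]] else sprintf("ind%03d", seq_len(nrow(body)))
  phen_raw <- phen_raw[, setdiff(names(phen_raw), id_col), drop = FALSE]
  rownames(geno) <- ids

  to_num <- function(v) {
    v[v %in% na_codes] <- NA
    suppressWarnings(num <- as.numeric(v))
    if (all(is.na(num) == is.na(v))) num else { v[is.na(v)] <- NA; v }
  }
  cols <- lapply(phen_raw, to_num)
  covn <- intersect(covariate_cols, names(cols))
  covar <- as.data.frame(cols[covn], stringsAsFactors = FALSE, optional = TRUE)
  pheno <- as.data.frame(cols[setdiff(names(cols), covn)],
                         stringsAsFactors = FALSE, optional = TRUE)
  if (!nrow(covar)) covar <- data.frame(row.names = seq_along(ids))
  make_cross(map, geno, pheno, covar)
}

#' Write a cross in the rotated-header CSV dialect
#'
#' Inverse of [read_rqtl_csv()]; used both as the fixture writer in tests
#' and to persist simulated crosses.
#'
#' @param cross a cross object.
#' @param path output path.
#' @param genotype_codes named mapping as in [read_rqtl_csv()].
#' @return `path`, invisibly.
#' @export
write_rqtl_csv <- function(cross, path,
                           genotype_codes = c(A = "AA", H = "AB", B = "BB")) {
  map <- cross$map
  rev_code <- names(genotype_codes)[match(c("AA", "AB", "BB"), genotype_codes)]
  gm <- matrix("", nrow(cross$geno), ncol(cross$geno))
  ok <- !is.na(cross$geno)
  gm[ok] <- rev_code[cross$geno[ok]]
  ph <- cbind(data.frame(id = rownames(cross$geno), stringsAsFactors = FALSE),
              cross$pheno, cross$covar)
  fmt <- function(v) { s <- ifelse(is.na(v), "", as.character(v)); s }
  ph_chr <- vapply(ph, fmt, character(nrow(ph)))
  if (nrow(ph) == 1) ph_chr <- matrix(ph_chr, nrow = 1)
  header <- c(names(ph), map$marker)
  chr_row <- c(rep("", ncol(ph)), map$chr)
  pos_row <- c(rep("", ncol(ph)), format(map$pos_cM, trim = TRUE, digits = 12))
  out <- rbind(header, chr_row, pos_row, cbind(ph_chr, gm))
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a delimited interval table
#'
#' Parses support-interval tables (e.g. QTL or eQTL lists) whose column
#' names vary between sources; the header-to-field mapping is therefore
#' configuration, with defaults matching this package's own writers.
#'
#' @param path file path (tab- or comma-delimited, autodetected by
#'   extension: `.csv` is comma, anything else tab).
#' @param unit coordinate unit of `start`/`end`: `"cM"` or `"Mb"`.
#' @param kind provenance tag: `"qtl"`, `"eqtl"` or `"f2_qtl"`.
#' @param columns named character vector mapping fields
#'   (`chr`, `start`, `end`, `label`, `peak_lod`) to header names;
#'   `label`/`peak_lod` may be absent from the file.
#' @return a [genomic_intervals()] set.
#' @export
read_interval_table <- function(path, unit, kind = "qtl",
                                columns = c(chr = "chr", start = "start",
                                            end = "end", label = "label",
                                            peak_lod = "peak_lod")) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (f in c("chr", "start", "end")) {
    if (!(columns[[f]] %in% names(tab)))
      stop("required column '", columns[[f]], "' (field ", f,
           ") missing from ", path)
  }
  start <- as.numeric(tab[[columns[["start"]]]])
  end <- as.numeric(tab[[columns[["end"]]]])
  bad <- which(end < start)
  if (length(bad))
    stop("interval end < start at data row(s) ", paste(bad, collapse = ", "),
         " of ", path)
  lab <- if (!is.na(columns["label"]) && columns[["label"]] %in% names(tab))
    as.character(tab[[columns[["label"]]]]) else NA_character_
  lod <- if (!is.na(columns["peak_lod"]) && columns[["peak_lod"]] %in% names(tab))
    as.numeric(tab[[columns[["peak_lod"]]]]) else NA_real_
  genomic_intervals(chr = tab[[columns[["chr"]]]], start = start, end = end,
                    unit = unit, kind = kind, label = lab, peak_lod = lod)
}

#' Write an interval set as a delimited table
#'
#' @param intervals a [genomic_intervals()] set.
#' @param path output path (`.csv` comma, else tab).
#' @return `path`, invisibly.
#' @export
write_interval_table <- function(intervals, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(as.data.frame(intervals), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write intervals as BED
#'
#' Emits 0-based half-open BED with bp coordinates `round(Mb * 1e6)`,
#' interval labels in the name column and peak LOD in the score column
#' when present.
#'
#' @param intervals a [genomic_intervals()] set in Mb units.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (!identical(interval_unit(intervals), "Mb"))
    stop("BED output requires Mb units; convert cM intervals with ",
         "coordinate_convert() first")
  if (nrow(intervals) == 0) {
    file.create(path)
    return(invisible(path))
  }
  score <- ifelse(is.na(intervals$peak_lod), ".",
                  format(intervals$peak_lod, trim = TRUE))
  name <- ifelse(is.na(intervals$label), ".", intervals$label)
  bed <- data.frame(chr = intervals$chr,
                    start = format(round(intervals$start * 1e6), scientific = FALSE, trim = TRUE),
                    end = format(round(intervals$end * 1e6), scientific = FALSE, trim = TRUE),
                    name = name, score = score)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an expression set as plain tables
#'
#' @param expr an [expression_set()].
#' @param matrix_path path for the probesets x individuals matrix (TSV,
#'   first column `probeset`).
#' @param annot_path path for the probe annotation table (TSV).
#' @return invisibly, the two paths.
#' @export
write_expression_set <- function(expr, matrix_path, annot_path) {
  m <- data.frame(probeset = rownames(expr$matrix), expr$matrix,
                  check.names = FALSE)
  utils::write.table(m, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$annotation, annot_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, annot_path))
}

#' Read an expression matrix and annotation table
#'
#' @param matrix_path TSV with first column `probeset`, remaining columns
#'   one individual each.
#' @param annot_path TSV with columns `probeset`, `chr`, `pos_Mb`
#'   (optional `pos_cM`).
#' @return an [expression_set()].
#' @export
read_expression_set <- function(matrix_path, annot_path) {
  m <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(m[, -1, drop = FALSE])
  rownames(mat) <- m[[1]]
  ann <- utils::read.table(annot_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  expression_set(mat, ann)
}
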