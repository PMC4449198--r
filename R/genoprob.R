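#' Haldane map function and its inverse
#'
#' `haldane()` converts genetic distance in cM to a recombination fraction
#' assuming no crossover interference; `haldane_inv()` converts back.
#'
#' @param d_cM distance in centimorgan.
#' @param r recombination fraction in `[0, 0.5)`.
#' @return recombination fraction, or distance in cM.
#' @export
haldane <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

#' @rdname haldane
#' @export
haldane_inv <- function(r) -50 * log(1 - 2 * r)

# F2 intercross genotype transition matrix over recombination fraction r.
# States: 1 = AA, 2 = AB, 3 = BB. Rows = from, columns = to.
f2_transition <- function(r) {
  matrix(c((1 - r)^2,     2 * r * (1 - r),       r^2,
           r * (1 - r),   (1 - r)^2 + r^2,       r * (1 - r),
           r^2,           2 * r * (1 - r),       (1 - r)^2),
         nrow = 3, byrow = TRUE)
}

f2_prior <- c(0.25, 0.5, 0.25)

#' Conditional genotype probabilities on a pseudomarker grid
#'
#' Computes P(AA), P(AB), P(BB) at every marker and at pseudomarker
#' positions inserted every `step_cM`, for each individual, by
#' forward-backward smoothing of the F2-intercross hidden Markov model:
#' genotype states follow a Markov chain along the chromosome with
#' transition probabilities built from Haldane recombination fractions,
#' and typed markers emit the observed code with probability
#' `1 - error_prob` (the two wrong codes share `error_prob`). Missing
#' genotypes are marginalised.
#'
#' These probabilities are the substrate for Haley-Knott regression: the
#' additive dosage is `x = P(BB) - P(AA)` and the dominance regressor is
#' `z = P(AB)`.
#'
#' @param cross a cross object.
#' @param step_cM pseudomarker spacing; 0 keeps markers only.
#' @param error_prob genotyping error rate in `[0, 0.5)`.
#' @return list of class `"genoprobs"`: `positions` (data.frame `chr`,
#'   `pos_cM`, `name`, `is_marker`) and `prob` (array individuals x
#'   positions x 3).
#' @export
calc_genoprob <- function(cross, step_cM = 1, error_prob = 0) {
  stopifnot(step_cM >= 0, error_prob >= 0, error_prob < 0.5)
  map <- cross$map
  n <- n_ind(cross)
  chrs <- unique(map$chr)

  pos_list <- list()
  prob_list <- list()
  for (cc in chrs) {
    mi <- which(map$chr == cc)
    if (!length(mi)) { message("chromosome ", cc, " has no markers; skipped"); next }
    mpos <- map$pos_cM[mi]
    grid <- mpos
    if (step_cM > 0 && length(mpos) > 1) {
      g <- seq(min(mpos), max(mpos), by = step_cM)
      grid <- sort(unique(c(mpos, g)))
    }
    typed <- match(round(grid, 9), round(mpos, 9))  # marker index or NA
    name <- ifelse(is.na(typed), sprintf("loc_%s_%g", cc, grid),
                   map$marker[mi][typed])
    K <- length(grid)

    # emissions: n x 3 per position (all-ones at pseudomarkers/missing)
    emis <- vector("list", K)
    for (k in seq_len(K)) {
      E <- matrix(1, n, 3)
      if (!is.na(typed[k])) {
        g <- cross$geno[, mi[typed[k]]]
        obs <- !is.na(g)
        if (any(obs)) {
          Eo <- matrix(error_prob / 2, sum(obs), 3)
          Eo[cbind(seq_len(sum(obs)), g[obs])] <- 1 - error_prob
          E[obs, ] <- Eo
        }
      }
      emis[[k]] <- E
    }
    trans <- lapply(haldane(diff(grid)), f2_transition)

    alpha <- vector("list", K)
    a <- sweep(emis[[1]], 2, f2_prior, `*`)
    alpha[[1]] <- a / rowSums(a)
    for (k in seq_len(K - 1)) {
      a <- (alpha[[k]] %*% trans[[k]]) * emis[[k + 1]]
      alpha[[k + 1]] <- a / rowSums(a)
    }
    post <- array(NA_real_, c(n, K, 3))
    b <- matrix(1, n, 3)
    post[, K, ] <- alpha[[K]]
    for (k in rev(seq_len(K - 1))) {
      b <- (b * emis[[k + 1]]) %*% t(trans[[k]])
      b <- b / rowSums(b)
      p <- alpha[[k]] * b
      post[, k, ] <- p / rowSums(p)
    }
    pos_list[[cc]] <- data.frame(chr = cc, pos_cM = grid, name = name,
                                 is_marker = !is.na(typed),
                                 stringsAsFactors = FALSE)
    prob_list[[cc]] <- post
  }
  positions <- do.call(rbind, pos_list)
  rownames(positions) <- NULL
  prob <- array(NA_real_, c(n, nrow(positions), 3),
                dimnames = list(rownames(cross$geno), positions$name,
                                c("AA", "AB", "BB")))
  at <- 0
  for (cc in names(prob_list)) {
    K <- dim(prob_list[[cc]])[2]
    prob[, at + seq_len(K), ] <- prob_list[[cc]]
    at <- at + K
  }
  structure(list(positions = positions, prob = prob),
            class = "genoprobs")
}

#' Haley-Knott regressors from genotype probabilities
#'
#' @param gp a [calc_genoprob()] result.
#' @return `dosage_x()`: individuals x positions matrix of expected allele
#'   dosages `P(BB) - P(AA)`; `dosage_z()`: heterozygote probabilities.
#' @export
dosage_x <- function(gp) gp$prob[, , 3] - gp$prob[, , 1]

#' @rdname dosage_x
#' @export
dosage_z <- function(gp) gp$prob[, , 2]
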