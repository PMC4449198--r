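#' Configuration for the synthetic advanced intercross
#'
#' Defaults emulate the study design the package targets: a two-line
#' (wild x domestic) intercross expanded for mapping at generation eight,
#' kept at roughly one hundred birds per intermating generation, genotyped
#' for 652 markers and phenotyped in 456 individuals, with expression
#' measured in a 125-female subset. Map geometry is 20 autosomes of 150 cM
#' with a constant physical scale of 0.33 Mb/cM (a chicken-like ~1 Gb
#' genome over ~3000 cM).
#'
#' @param n_markers total markers, spread evenly over chromosomes.
#' @param n_chromosomes number of autosomes.
#' @param chrom_length_cM genetic length of each chromosome.
#' @param mb_per_cM physical scale used for the marker `pos_Mb`.
#' @param n_founder_pairs founder pairs; founders are fixed for alternate
#'   alleles at every marker (line-cross idealisation).
#' @param generations final intercross generation (>= 2; 2 = F2).
#' @param pop_per_generation individuals per intermating generation.
#' @param n_individuals_final individuals in the mapped generation.
#' @param qtl_spec data.frame(`chr`, `pos_cM`, `a`, `d`, `trait`): additive
#'   and dominance effects at map loci.
#' @param epistasis_spec data.frame(`chr1`, `pos1`, `chr2`, `pos2`,
#'   `effect`, `trait`): digenic interaction terms (`effect * x1 * x2`).
#' @param eqtl_spec data.frame(`probeset`, `chr`, `pos_cM`, `effect`,
#'   `cis`): per-probeset genetic effects; `cis = TRUE` places the probe
#'   annotation at the driving locus, `FALSE` elsewhere.
#' @param hotspot_spec data.frame(`chr`, `pos_cM`, `n_targets`,
#'   `effect_mean`, `effect_sd`): trans-regulator loci hitting many
#'   probesets.
#' @param mediation_spec data.frame(`probeset`, `trait`, `slope`):
#'   expression-mediated trait effects (trait <- expression <- genotype).
#' @param n_probesets probesets on the synthetic array.
#' @param n_expr_individuals females with expression data.
#' @param trait_noise_sd,probe_noise_sd residual standard deviations.
#' @param sex_effect,batch_sd,weight_slope covariate effect sizes on
#'   traits (grams-scale body weight is centred and scaled internally).
#' @param geno_missing,pheno_missing dropout rates injected by
#'   [simulate_study()].
#' @param seed integer seed; fully determines all outputs.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_markers = 652, n_chromosomes = 20,
                       chrom_length_cM = 150, mb_per_cM = 0.33,
                       n_founder_pairs = 1, generations = 8,
                       pop_per_generation = 100, n_individuals_final = 456,
                       qtl_spec = NULL, epistasis_spec = NULL,
                       eqtl_spec = NULL, hotspot_spec = NULL,
                       mediation_spec = NULL,
                       n_probesets = 200, n_expr_individuals = 125,
                       trait_noise_sd = 1, probe_noise_sd = 1,
                       sex_effect = 1, batch_sd = 0.25, weight_slope = 0.5,
                       geno_missing = 0.02, pheno_missing = 0.02,
                       seed = 1L) {
  stopifnot(generations >= 2, n_markers >= 2 * n_chromosomes,
            pop_per_generation >= 4, n_founder_pairs >= 1)
  cfg <- list(n_markers = n_markers, n_chromosomes = n_chromosomes,
              chrom_length_cM = chrom_length_cM, mb_per_cM = mb_per_cM,
              n_founder_pairs = n_founder_pairs, generations = generations,
              pop_per_generation = pop_per_generation,
              n_individuals_final = n_individuals_final,
              qtl_spec = qtl_spec, epistasis_spec = epistasis_spec,
              eqtl_spec = eqtl_spec, hotspot_spec = hotspot_spec,
              mediation_spec = mediation_spec,
              n_probesets = n_probesets,
              n_expr_individuals = n_expr_individuals,
              trait_noise_sd = trait_noise_sd,
              probe_noise_sd = probe_noise_sd,
              sex_effect = sex_effect, batch_sd = batch_sd,
              weight_slope = weight_slope,
              geno_missing = geno_missing, pheno_missing = pheno_missing,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Map implied by a simulation configuration
#'
#' Markers are evenly spaced over each chromosome (first at 0 cM). Effect
#' loci in a configuration must sit on this map.
#'
#' @param config a [sim_config()].
#' @return a [genetic_map()] with both cM and Mb positions.
#' @export
sim_map <- function(config) {
  per <- rep(config$n_markers %/% config$n_chromosomes, config$n_chromosomes)
  rem <- config$n_markers %% config$n_chromosomes
  if (rem > 0) per[seq_len(rem)] <- per[seq_len(rem)] + 1L
  chr <- rep(as.character(seq_len(config$n_chromosomes)), per)
  pos <- unlist(lapply(per, function(k) seq(0, config$chrom_length_cM, length.out = k)))
  genetic_map(marker = sprintf("m_%s_%04.0f", chr, round(pos * 10)),
              chr = chr, pos_cM = pos, pos_Mb = pos * config$mb_per_cM)
}

locus_index <- function(map, chr, pos_cM, what = "locus") {
  idx <- which(map$chr == as.character(chr) &
                 abs(map$pos_cM - pos_cM) < 1e-8)
  if (length(idx) != 1)
    stop(what, " at chr ", chr, ", ", pos_cM,
         " cM is not on the generated map")
  idx
}

# recombination fractions between adjacent map columns; 0.5 across
# chromosome boundaries (independent assortment)
adjacent_r <- function(map) {
  d <- diff(map$pos_cM)
  r <- haldane(d)
  r[diff(match(map$chr, unique(map$chr))) != 0] <- 0.5
  r
}

# one gamete per row of parent haplotype matrices, Markov crossover process
# (Haldane: independent recombination events between adjacent markers)
make_gametes <- function(h1, h2, parent_idx, r) {
  n <- length(parent_idx)
  m <- ncol(h1)
  pick <- matrix(0L, n, m)
  pick[, 1] <- sample(0:1, n, replace = TRUE)
  for (k in 2:m) {
    flip <- stats::rbinom(n, 1L, r[k - 1])
    pick[, k] <- (pick[, k - 1] + flip) %% 2L
  }
  a <- h1[parent_idx, , drop = FALSE]
  b <- h2[parent_idx, , drop = FALSE]
  sel <- pick == 1L
  a[sel] <- b[sel]
  a
}

#' Simulate advanced-intercross genotypes and covariates
#'
#' Founders are fixed for alternate alleles at every marker (the line-cross
#' idealisation that underlies F2-coded analysis); meioses follow Haldane's
#' map function with no crossover interference; each generation is produced
#' by random mating with distinct dams and sires. Covariates: balanced sex,
#' five hatch batches, sex-shifted Gaussian body weight (grams), and a
#' total-egg-mass column for females.
#'
#' @param config a [sim_config()].
#' @return list with elements `cross` (a [make_cross()] object with an
#'   empty phenotype table) and `truth` (realised simulation record,
#'   extended by the trait/expression simulators).
#' @export
simulate_ail <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  map <- sim_map(config)
  validate_effect_loci(config, map)
  set.seed(config$seed)
  m <- nrow(map)
  r <- adjacent_r(map)

  # F1: every individual heterozygous at every marker
  n_f1 <- max(2L * config$n_founder_pairs, 4L)
  h1 <- matrix(0L, n_f1, m)
  h2 <- matrix(1L, n_f1, m)
  sex <- rep_len(c("F", "M"), n_f1)

  for (g in seq(2, config$generations)) {
    n_next <- if (g == config$generations) config$n_individuals_final
              else config$pop_per_generation
    dams <- which(sex == "F")
    sires <- which(sex == "M")
    dam_idx <- sample(dams, n_next, replace = TRUE)
    sire_idx <- sample(sires, n_next, replace = TRUE)
    nh1 <- make_gametes(h1, h2, dam_idx, r)
    nh2 <- make_gametes(h1, h2, sire_idx, r)
    h1 <- nh1; h2 <- nh2
    sex <- sample(rep_len(c("F", "M"), n_next))
  }

  geno <- h1 + h2 + 1L   # 1 = AA, 2 = AB, 3 = BB
  colnames(geno) <- map$marker
  rownames(geno) <- sprintf("ind%04d", seq_len(nrow(geno)))

  n <- nrow(geno)
  batch <- sample(paste0("b", 1:5), n, replace = TRUE)
  weight <- ifelse(sex == "F", stats::rnorm(n, 1500, 150),
                   stats::rnorm(n, 2000, 200))
  eggs <- ifelse(sex == "F", pmax(stats::rnorm(n, 350, 80), 0), NA_real_)
  covar <- data.frame(sex = sex, batch = batch, body_weight = weight,
                      eggs = eggs, stringsAsFactors = FALSE)
  cross <- make_cross(map, geno, data.frame(row.names = seq_len(n)), covar)
  truth <- structure(list(config = config, map = map,
                          qtl = config$qtl_spec,
                          epistasis = config$epistasis_spec,
                          eqtl = NULL, hotspot_targets = NULL,
                          mediation = config$mediation_spec),
                     class = "sim_truth")
  list(cross = cross, truth = truth)
}

validate_effect_loci <- function(config, map) {
  chk <- function(chr, pos, what)
    for (i in seq_along(chr)) locus_index(map, chr[i], pos[i], what)
  if (!is.null(config$qtl_spec))
    chk(config$qtl_spec$chr, config$qtl_spec$pos_cM, "QTL")
  if (!is.null(config$epistasis_spec)) {
    chk(config$epistasis_spec$chr1, config$epistasis_spec$pos1, "epistatic locus")
    chk(config$epistasis_spec$chr2, config$epistasis_spec$pos2, "epistatic locus")
  }
  if (!is.null(config$eqtl_spec))
    chk(config$eqtl_spec$chr, config$eqtl_spec$pos_cM, "eQTL")
  if (!is.null(config$hotspot_spec))
    chk(config$hotspot_spec$chr, config$hotspot_spec$pos_cM, "hotspot locus")
  invisible(TRUE)
}

# additive dosage in {-1, 0, 1} and heterozygote indicator from codes
geno_x <- function(geno) geno - 2L
geno_z <- function(geno) as.integer(geno == 2L)

#' Simulate expression values on a cross
#'
#' Each probeset is baseline plus an optional cis effect (an additive
#' effect of a local locus), optional trans effects from shared hotspot
#' regulator loci, and Gaussian noise. The annotation places cis probesets
#' at their driving locus and all other probesets at uniformly drawn map
#' positions, so window-based cis/trans classification has ground truth.
#'
#' Expression is generated for every individual in the cross (the
#' measured female subset is taken later, by [simulate_study()]), so
#' expression-mediated trait effects are defined population-wide.
#'
#' @param cross cross from [simulate_ail()].
#' @param config the same [sim_config()].
#' @param truth the truth record to extend.
#' @return list `expr` (an [expression_set()] over all individuals) and
#'   `truth` (with realised eQTL and hotspot-target records).
#' @export
simulate_expression <- function(cross, config, truth) {
  map <- cross$map
  np <- config$n_probesets
  probes <- sprintf("ps%04d", seq_len(np))
  n <- n_ind(cross)
  mat <- matrix(stats::rnorm(np * n, 0, config$probe_noise_sd), np, n,
                dimnames = list(probes, rownames(cross$geno)))
  mat <- mat + stats::rnorm(np, 8, 1)  # per-probe baseline (log-scale-like)

  # annotation: uniform placement, overwritten for cis probesets below
  ann_idx <- sample.int(nrow(map), np, replace = TRUE)
  ann <- data.frame(probeset = probes, chr = map$chr[ann_idx],
                    pos_Mb = map$pos_Mb[ann_idx], pos_cM = map$pos_cM[ann_idx],
                    stringsAsFactors = FALSE)

  eq <- config$eqtl_spec
  if (!is.null(eq)) {
    for (i in seq_len(nrow(eq))) {
      j <- match(eq$probeset[i], probes)
      if (is.na(j)) stop("eqtl_spec probeset not on the array: ", eq$probeset[i])
      li <- locus_index(map, eq$chr[i], eq$pos_cM[i], "eQTL")
      x <- geno_x(cross$geno[, li])
      mat[j, ] <- mat[j, ] + eq$effect[i] * x
      if (isTRUE(eq$cis[i])) {
        ann$chr[j] <- map$chr[li]
        ann$pos_cM[j] <- map$pos_cM[li]
        ann$pos_Mb[j] <- map$pos_Mb[li]
      } else if (ann$chr[j] == map$chr[li]) {
        # keep trans targets genuinely distal: move annotation off-chromosome
        k <- which(map$chr != map$chr[li])[1]
        ann$chr[j] <- map$chr[k]; ann$pos_cM[j] <- map$pos_cM[k]
        ann$pos_Mb[j] <- map$pos_Mb[k]
      }
    }
  }

  hot_targets <- NULL
  hs <- config$hotspot_spec
  if (!is.null(hs)) {
    for (i in seq_len(nrow(hs))) {
      if (hs$n_targets[i] > np)
        stop("hotspot target count (", hs$n_targets[i],
             ") exceeds probeset count (", np, ")")
      li <- locus_index(map, hs$chr[i], hs$pos_cM[i], "hotspot locus")
      x <- geno_x(cross$geno[, li])
      # targets drawn among probesets not annotated to the regulator's
      # chromosome, so the induced eQTL are distal by construction
      pool <- which(ann$chr != map$chr[li])
      if (length(pool) < hs$n_targets[i])
        stop("not enough off-chromosome probesets for hotspot ", i)
      tgt <- sample(pool, hs$n_targets[i])
      eff <- stats::rnorm(hs$n_targets[i], hs$effect_mean[i], hs$effect_sd[i]) *
        sample(c(-1, 1), hs$n_targets[i], replace = TRUE)
      mat[tgt, ] <- mat[tgt, ] + outer(eff, x)
      hot_targets <- rbind(hot_targets,
                           data.frame(hotspot = i, chr = hs$chr[i],
                                      pos_cM = hs$pos_cM[i],
                                      probeset = probes[tgt], effect = eff,
                                      stringsAsFactors = FALSE))
    }
  }
  truth$eqtl <- eq
  truth$hotspot_targets <- hot_targets
  list(expr = expression_set(mat, ann), truth = truth)
}

#' Simulate quantitative traits on a cross
#'
#' Builds each trait named in the configuration as
#' intercept + sex effect + batch effects + body-weight term +
#' sum of additive/dominance terms (`a*x + d*z`, with `x` in -1/0/1 and
#' `z` the heterozygote indicator) + digenic interaction terms
#' (`effect * x1 * x2`) + expression-mediated terms + Gaussian noise.
#'
#' @param cross cross from [simulate_ail()].
#' @param config the same [sim_config()].
#' @param expr optional full-population [expression_set()] (required when
#'   `mediation_spec` is set).
#' @return the cross with phenotype columns filled in.
#' @export
simulate_traits <- function(cross, config, expr = NULL) {
  traits <- unique(c(config$qtl_spec$trait, config$epistasis_spec$trait,
                     config$mediation_spec$trait))
  if (!length(traits)) traits <- "trait1"
  n <- n_ind(cross)
  map <- cross$map
  sexM <- as.numeric(cross$covar$sex == "M")
  bl <- sort(unique(cross$covar$batch))
  beff <- stats::rnorm(length(bl), 0, config$batch_sd)
  wt <- as.numeric(scale(cross$covar$body_weight))
  noise_sd <- config$trait_noise_sd
  if (is.null(names(noise_sd))) noise_sd <- stats::setNames(
    rep_len(noise_sd, length(traits)), traits)

  for (tr in traits) {
    y <- config$sex_effect * sexM + beff[match(cross$covar$batch, bl)] +
      config$weight_slope * wt
    qs <- config$qtl_spec
    if (!is.null(qs)) for (i in which(qs$trait == tr)) {
      li <- locus_index(map, qs$chr[i], qs$pos_cM[i], "QTL")
      g <- cross$geno[, li]
      y <- y + qs$a[i] * geno_x(g) + qs$d[i] * geno_z(g)
    }
    es <- config$epistasis_spec
    if (!is.null(es)) for (i in which(es$trait == tr)) {
      l1 <- locus_index(map, es$chr1[i], es$pos1[i], "epistatic locus")
      l2 <- locus_index(map, es$chr2[i], es$pos2[i], "epistatic locus")
      y <- y + es$effect[i] * geno_x(cross$geno[, l1]) * geno_x(cross$geno[, l2])
    }
    ms <- config$mediation_spec
    if (!is.null(ms) && any(ms$trait == tr)) {
      if (is.null(expr)) stop("mediation_spec set but no expression supplied")
      for (i in which(ms$trait == tr)) {
        e <- expr$matrix[ms$probeset[i], rownames(cross$geno)]
        y <- y + ms$slope[i] * (e - mean(e))
      }
    }
    sdv <- if (tr %in% names(noise_sd)) noise_sd[[tr]] else noise_sd[[1]]
    cross$pheno[[tr]] <- y + stats::rnorm(n, 0, sdv)
  }
  cross
}

#' Inject missingness into genotypes and phenotypes
#'
#' @param cross a cross object.
#' @param geno_rate,pheno_rate independent per-cell dropout probabilities.
#' @return the cross with `NA`s injected.
#' @export
inject_missing <- function(cross, geno_rate = 0.02, pheno_rate = 0.02) {
  if (geno_rate > 0) {
    drop <- matrix(stats::runif(length(cross$geno)) < geno_rate,
                   nrow(cross$geno))
    cross$geno[drop] <- NA_integer_
  }
  if (pheno_rate > 0 && ncol(cross$pheno) > 0) {
    for (j in seq_along(cross$pheno)) {
      drop <- stats::runif(nrow(cross$pheno)) < pheno_rate
      cross$pheno[[j]][drop] <- NA
    }
  }
  cross
}

#' Simulate a complete study: cross, expression, traits, truth
#'
#' Runs [simulate_ail()], [simulate_expression()] and [simulate_traits()]
#' under one seed, injects missingness, and restricts the returned
#' expression set to a female subset of the configured size (expression is
#' measured only in female bone samples in the emulated design).
#'
#' @param config a [sim_config()].
#' @return list with `cross`, `expr` (female subset), `truth`.
#' @export
simulate_study <- function(config) {
  sim <- simulate_ail(config)
  ex <- simulate_expression(sim$cross, config, sim$truth)
  cross <- simulate_traits(sim$cross, config, ex$expr)
  females <- rownames(cross$geno)[cross$covar$sex == "F"]
  n_expr <- min(config$n_expr_individuals, length(females))
  keep <- sort(sample(females, n_expr))
  expr <- expression_set(ex$expr$matrix[, keep, drop = FALSE],
                         ex$expr$annotation)
  cross <- inject_missing(cross, config$geno_missing, config$pheno_missing)
  list(cross = cross, expr = expr, truth = ex$truth)
}

#' Additive effect size giving a target variance fraction
#'
#' Solves `a^2 var(x) / (a^2 var(x) + sd^2) = r2` for `a` using the
#' realised additive-dosage variance at a locus, so simulations can state
#' effect sizes as fractions of trait variance.
#'
#' @param cross a simulated cross.
#' @param chr,pos_cM locus (must be a marker).
#' @param r2 target fraction of variance explained.
#' @param noise_sd residual standard deviation of the trait.
#' @return the additive effect `a`.
#' @export
additive_effect_for_r2 <- function(cross, chr, pos_cM, r2, noise_sd = 1) {
  li <- locus_index(cross$map, chr, pos_cM, "locus")
  vx <- stats::var(geno_x(cross$geno[, li]), na.rm = TRUE)
  noise_sd * sqrt(r2 / (1 - r2)) / sqrt(vx)
}
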