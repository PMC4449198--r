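make_scan_df <- function(pos, lod, chr = "1", trait = "t") {
  s <- data.frame(chr = chr, pos_cM = pos, name = paste0("m", seq_along(pos)),
                  is_marker = TRUE, lod = lod, stringsAsFactors = FALSE)
  class(s) <- c("scan_result", "data.frame")
  attr(s, "trait") <- trait
  s
}

test_that("scanone matches the hand-computed RSS ratio on an 8-individual fixture", {
  geno <- matrix(c(1, 1, 2, 2, 3, 3, 2, 1,
                   3, 2, 1, 2, 1, 3, 3, 2), 8,
                 dimnames = list(NULL, c("m1", "m2")))
  map <- genetic_map(c("m1", "m2"), "1", c(0, 30))
  y <- c(0.2, -0.1, 1.1, 0.9, 2.3, 1.8, 1.2, 0.4)
  cr <- make_cross(map, geno, data.frame(y = y),
                   data.frame(sex = rep("F", 8)))
  gp <- calc_genoprob(cr, step_cM = 0)
  sc <- scanone(gp, cr, "y")
  for (m in 1:2) {
    x <- geno[, m] - 2
    z <- as.numeric(geno[, m] == 2)
    rss0 <- sum(lm(y ~ 1)$residuals^2)
    rss1 <- sum(lm(y ~ x + z)$residuals^2)
    lod_hand <- (8 / 2) * log10(rss0 / rss1)
    expect_equal(sc$lod[sc$name == paste0("m", m)], lod_hand,
                 tolerance = 1e-10)
  }
  expect_equal(attr(sc, "n_used"), 8)
})

test_that("scanone LOD equals an independent lm recomputation everywhere", {
  st <- simulate_ail(small_sim_config(
    seed = 21, qtl_spec = data.frame(chr = "2", pos_cM = 50, a = 0.5,
                                     d = 0.2, trait = "t")))
  cfg <- small_sim_config(seed = 21,
                          qtl_spec = data.frame(chr = "2", pos_cM = 50,
                                                a = 0.5, d = 0.2, trait = "t"))
  cr <- simulate_traits(st$cross, cfg)
  gp <- calc_genoprob(cr, step_cM = 5)
  covs <- c("sex", "body_weight")
  sc <- scanone(gp, cr, "t", covs)
  C <- aviqtl:::build_covar_matrix(cr, covs)
  X <- dosage_x(gp); Z <- dosage_z(gp)
  y <- cr$pheno$t
  n <- length(y)
  rss0 <- sum(lm(y ~ C)$residuals^2)
  for (j in seq(1, nrow(sc), by = 17)) {
    rss1 <- sum(lm(y ~ C + X[, j] + Z[, j])$residuals^2)
    expect_equal(sc$lod[j], (n / 2) * log10(rss0 / rss1), tolerance = 1e-8)
  }
})

test_that("noise-free trait equal to dosage is flagged as a capped perfect fit", {
  geno <- matrix(rep(1:3, each = 4), 12, 2,
                 dimnames = list(NULL, c("m1", "m2")))
  geno[, 2] <- sample(1:3, 12, replace = TRUE)
  map <- genetic_map(c("m1", "m2"), "1", c(0, 40))
  cr <- make_cross(map, geno, data.frame(y = as.numeric(geno[, 1] - 2)),
                   data.frame(sex = rep("F", 12)))
  gp <- calc_genoprob(cr, step_cM = 0)
  expect_message(sc <- scanone(gp, cr, "y"), "perfect fit")
  expect_true(attr(sc, "perfect_fit")[1])
  expect_gt(sc$lod[1], 50)   # capped but very large
  expect_true(is.finite(sc$lod[1]))
})

test_that("rank-deficient covariates raise an error naming the alias", {
  cr <- tiny_cross(geno = matrix(sample(1:3, 30, replace = TRUE), 10),
                   pheno = data.frame(y = rnorm(10)),
                   covar = data.frame(sex = rep("F", 10),
                                      batch = rep("b1", 10),
                                      body_weight = rnorm(10, 1500),
                                      eggs = NA_real_))
  cv <- aviqtl:::build_covar_matrix(cr, "body_weight")
  cv <- cbind(cv, dup = cv[, 1])
  gp <- calc_genoprob(cr, step_cM = 0)
  expect_error(scanone(gp, cr, "y", cv), "rank deficient.*dup")
})

test_that("permutation threshold: alpha = 0 gives the max; seeds are stable", {
  cfg <- small_sim_config(seed = 31, n_markers = 20, n_chromosomes = 2,
                          n_individuals_final = 100)
  st <- simulate_ail(cfg)
  cr <- simulate_traits(st$cross, cfg)
  gp <- calc_genoprob(cr, step_cM = 0)
  mx <- permutation_maxima(gp, cr, "trait1", n_perm = 25, seed = 123)
  thr0 <- permutation_threshold(gp, cr, "trait1", n_perm = 25, alpha = 0,
                                seed = 123)
  expect_equal(thr0, max(mx))
  t1 <- permutation_threshold(gp, cr, "trait1", n_perm = 1000, seed = 1)
  t2 <- permutation_threshold(gp, cr, "trait1", n_perm = 1000, seed = 2)
  expect_lt(abs(t1 - t2) / t1, 0.10)
})

test_that("genotype PCs: k = 0 empty, orthogonal scores, subpopulation split", {
  cfg <- small_sim_config(seed = 41, n_individuals_final = 80)
  st <- simulate_ail(cfg)
  cr <- st$cross
  expect_equal(ncol(pca_covariates(cr, 0)), 0)
  expect_error(pca_covariates(cr, 1000), "smaller")
  pc <- pca_covariates(cr, 4)
  cc <- cor(pc)
  expect_true(all(abs(cc[upper.tri(cc)]) < 1e-8))
  # two diverged subpopulations: flip genotype coding in half the individuals
  g2 <- cr$geno
  half <- seq_len(40)
  g2[half, ] <- 4L - g2[half, ]
  # make the pops allele-frequency-diverged by zeroing hets in pop 1
  g2[half, ][g2[half, ] == 2L] <- 1L
  cr2 <- make_cross(cr$map, g2, cr$pheno, cr$covar)
  pc2 <- pca_covariates(cr2, 1)
  lab <- as.numeric(seq_len(80) %in% half)
  expect_gt(abs(cor(pc2[, 1], lab)), 0.9)
})

test_that("egg covariate decision: forced inclusion, male error, all-missing", {
  cfg <- small_sim_config(seed = 51)
  st <- simulate_ail(cfg)
  cr <- simulate_traits(st$cross, cfg)
  fem <- subset_cross(cr, sex = "F")
  expect_error(select_egg_covariate(cr, "trait1"), "female-only")
  # trait built directly from eggs -> must be included
  fem$pheno$eggy <- 2 * fem$covar$eggs + rnorm(nrow(fem$geno), 0, 1)
  dec <- suppressMessages(select_egg_covariate(fem, "eggy"))
  expect_true(dec$include)
  expect_true("eggs" %in% dec$covariates)
  fem2 <- fem
  fem2$covar$eggs <- NA_real_
  expect_message(dec2 <- select_egg_covariate(fem2, "trait1"), "skipped")
  expect_false(dec2$include)
})

test_that("scantwo: degenerate pairs excluded, surfaces nested", {
  cfg <- small_sim_config(seed = 61, n_markers = 12, n_chromosomes = 3,
                          n_individuals_final = 150,
                          qtl_spec = data.frame(chr = c("1", "2"),
                                                pos_cM = c(60, 30),
                                                a = c(0.6, 0.5), d = 0,
                                                trait = "t"))
  st <- simulate_ail(cfg)
  cr <- simulate_traits(st$cross, cfg)
  gp <- calc_genoprob(cr, step_cM = 0)
  s2 <- scantwo(gp, cr, "t", c("sex", "body_weight"))
  expect_false(any(s2$name1 == s2$name2))
  expect_true(all(s2$lod_int <= s2$lod_full + 1e-8))
  expect_true(all(s2$lod_int >= -1e-8))
  s1 <- scanone(gp, cr, "t", c("sex", "body_weight"))
  # additive two-locus model nests each single-locus model
  for (k in sample(nrow(s2), 20)) {
    m <- max(s1$lod[s1$name == s2$name1[k]], s1$lod[s1$name == s2$name2[k]])
    expect_gte(s2$lod_add[k], m - 1e-8)
  }
})

test_that("forward selection: stored model refits to the same LOD", {
  cfg <- small_sim_config(seed = 71, n_individuals_final = 250,
                          qtl_spec = data.frame(chr = c("1", "3"),
                                                pos_cM = c(40, 70),
                                                a = c(0.8, 0.7), d = 0,
                                                trait = "t"))
  st <- simulate_ail(cfg)
  cr <- simulate_traits(st$cross, cfg)
  gp <- calc_genoprob(cr, step_cM = 2)
  mod <- suppressMessages(
    forward_select(gp, cr, "t", c("sex", "body_weight"),
                   thresholds = list(main = 3.5, interaction = Inf)))
  expect_gte(nrow(mod$loci), 1)
  refit <- fit_qtl_model(gp, cr, "t", c("sex", "body_weight"),
                         loci = mod$loci$name,
                         pairs = if (is.null(mod$pairs)) NULL else
                           mod$pairs[, c("name1", "name2")])
  expect_equal(refit$lod, mod$lod, tolerance = 1e-6)
  expect_equal(refit$pve, mod$pve, tolerance = 1e-6)
  expect_true(all(mod$pve_terms >= -1e-8))
  # null trait: empty model at a stringent threshold
  set.seed(72)
  cr$pheno$null <- rnorm(nrow(cr$geno))
  mod0 <- suppressMessages(
    forward_select(gp, cr, "null", c("sex", "body_weight"),
                   thresholds = list(main = 4.5)))
  expect_equal(nrow(mod0$loci), 0)
})

test_that("LOD support interval follows the drop definition and expands to markers", {
  pos <- seq(0, 80, by = 10)   # m1..m9
  lod <- c(0.5, 1.0, 3.2, 4.4, 5.0, 4.4, 3.2, 1.0, 0.5)
  map <- genetic_map(paste0("m", 1:9), "1", pos)
  s <- make_scan_df(pos, lod)
  ci <- lod_support_interval(s, s[5, ], drop = 1.8, map)
  expect_equal(c(ci$start, ci$end), c(20, 60))   # falls exactly at m3/m7
  expect_false(ci$truncated)
  # flat curve: whole chromosome, degenerate
  s2 <- make_scan_df(pos, rep(2, 9))
  ci2 <- lod_support_interval(s2, s2[5, ], drop = 1.8, map)
  expect_equal(c(ci2$start, ci2$end), c(0, 80))
  expect_true(ci2$degenerate)
  expect_true(ci2$truncated)
  # peak at chromosome edge: truncated flag
  s3 <- make_scan_df(pos, c(5, 4.8, 4, 3, 2, 1, 0.5, 0.2, 0.1))
  ci3 <- lod_support_interval(s3, s3[1, ], drop = 1.8, map)
  expect_equal(ci3$start, 0)
  expect_true(ci3$truncated)
})

test_that("pseudomarker interval endpoints expand outward to markers", {
  map <- genetic_map(paste0("m", 1:5), "1", c(0, 25, 50, 75, 100))
  pos <- seq(0, 100, by = 5)
  lod <- 5 - abs(pos - 50) / 10   # drops below 5 - 1.8 outside (32, 68)
  s <- make_scan_df(pos, lod)
  s$name <- sprintf("p%02d", seq_along(pos))
  ci <- lod_support_interval(s, s[which.max(lod), ], drop = 1.8, map)
  expect_equal(c(ci$start, ci$end), c(25, 75))
})

test_that("scantwo recovers pure epistasis and stays null for additive pairs", {
  # pure interaction: effect only through x1*x2, no marginal terms
  hits <- logical(10)
  int_at_true <- numeric(10)
  for (s in 1:10) {
    cfg <- small_sim_config(seed = 400 + s, n_markers = 20,
                            n_chromosomes = 2, n_individuals_final = 250,
                            epistasis_spec = data.frame(chr1 = "1", pos1 = 40,
                                                        chr2 = "2", pos2 = 50,
                                                        effect = 0.8,
                                                        trait = "t"),
                            sex_effect = 0, batch_sd = 0, weight_slope = 0)
    st <- simulate_ail(cfg)
    cr <- simulate_traits(st$cross, cfg)
    gp <- calc_genoprob(cr, step_cM = 0)
    s2 <- scantwo(gp, cr, "t")
    best <- s2[which.max(s2$lod_int), ]
    hits[s] <- best$chr1 == "1" && best$chr2 == "2" &&
      abs(best$pos1 - 40) <= 15 && abs(best$pos2 - 50) <= 15
    at_true <- s2[s2$chr1 == "1" & s2$pos1 == 40 &
                    s2$chr2 == "2" & s2$pos2 == 50, ]
    int_at_true[s] <- at_true$lod_int
  }
  expect_gte(mean(hits), 0.8)
  expect_gt(mean(int_at_true), 2)

  # purely additive two-QTL world: interaction LOD at the true pair stays
  # below its permutation threshold
  cfg <- small_sim_config(seed = 420, n_markers = 20, n_chromosomes = 2,
                          n_individuals_final = 250,
                          qtl_spec = data.frame(chr = c("1", "2"),
                                                pos_cM = c(40, 50),
                                                a = c(0.7, 0.6), d = 0,
                                                trait = "t"))
  st <- simulate_ail(cfg)
  cr <- simulate_traits(st$cross, cfg)
  gp <- calc_genoprob(cr, step_cM = 0)
  s2 <- scantwo(gp, cr, "t")
  at_true <- s2[s2$chr1 == "1" & s2$pos1 == 40 &
                  s2$chr2 == "2" & s2$pos2 == 50, ]
  thr <- scantwo_permutation_threshold(gp, cr, "t", n_perm = 60, seed = 421)
  expect_lt(at_true$lod_int, thr)
})
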