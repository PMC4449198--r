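# Shared fixtures and independent oracles. Everything here is built in
# code at test time; no stored data.

# tiny deterministic cross: explicit genotypes, no simulation involved
tiny_cross <- function(geno = NULL, pheno = NULL, covar = NULL,
                       pos = c(0, 20, 40), chr = rep("1", length(pos))) {
  map <- genetic_map(marker = paste0("m", seq_along(pos)), chr = chr,
                     pos_cM = pos, pos_Mb = pos * 0.4)
  n <- if (is.null(geno)) 6 else nrow(geno)
  if (is.null(geno)) {
    set.seed(99)
    geno <- matrix(sample(1:3, n * length(pos), replace = TRUE), n,
                   dimnames = list(NULL, map$marker))
  } else colnames(geno) <- map$marker
  if (is.null(pheno)) pheno <- data.frame(y = seq_len(n) + 0.5)
  pheno <- as.data.frame(lapply(pheno, rep_len, n))
  if (is.null(covar))
    covar <- data.frame(sex = rep_len(c("F", "M"), n),
                        batch = rep_len(paste0("b", 1:2), n),
                        body_weight = 1500 + seq_len(n) * 10,
                        eggs = ifelse(rep_len(c(TRUE, FALSE), n), 300, NA))
  make_cross(map, geno, pheno, covar)
}

# small simulated study shared by several test files; 10 markers per
# chromosome at 0, 10, ..., 90 cM so round positions are on the map
small_sim_config <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(n_markers = 50, n_chromosomes = 5, chrom_length_cM = 90,
         n_individuals_final = 200, pop_per_generation = 80,
         n_probesets = 60, n_expr_individuals = 60,
         geno_missing = 0, pheno_missing = 0, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# ---- independent oracles -------------------------------------------------

# exhaustive hidden-state enumeration for the intercross HMM posterior:
# positions in cM on one chromosome, obs in {1,2,3, NA} at each position
enum_genoprob <- function(pos, obs, error_prob = 0) {
  K <- length(pos)
  states <- as.matrix(expand.grid(rep(list(1:3), K)))
  prior <- c(0.25, 0.5, 0.25)
  tr <- lapply(haldane(diff(pos)), function(r)
    matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
             r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
             r^2, 2 * r * (1 - r), (1 - r)^2), 3, byrow = TRUE))
  emis <- function(s, o) {
    if (is.na(o)) 1
    else if (s == o) 1 - error_prob
    else error_prob / 2
  }
  w <- apply(states, 1, function(g) {
    p <- prior[g[1]] * emis(g[1], obs[1])
    if (K > 1) for (k in 2:K)
      p <- p * tr[[k - 1]][g[k - 1], g[k]] * emis(g[k], obs[k])
    p
  })
  post <- matrix(0, K, 3)
  for (k in 1:K) for (s in 1:3) post[k, s] <- sum(w[states[, k] == s])
  post / rowSums(post)
}

# quadratic all-pairs interval overlap (closed intervals)
brute_overlap <- function(qtl, eqtl) {
  hits <- list()
  for (i in seq_len(nrow(qtl))) for (j in seq_len(nrow(eqtl))) {
    if (qtl$chr[i] == eqtl$chr[j] &&
        max(qtl$start[i], eqtl$start[j]) <= min(qtl$end[i], eqtl$end[j]))
      hits[[length(hits) + 1]] <- c(i, j)
  }
  if (!length(hits)) matrix(integer(0), 0, 2) else do.call(rbind, hits)
}

# independent region merge: event sweep over sorted endpoints
sweep_merge <- function(intervals) {
  out <- list()
  for (cc in unique(intervals$chr)) {
    sub <- intervals[intervals$chr == cc, ]
    ev <- rbind(data.frame(p = sub$start, d = 1), data.frame(p = sub$end, d = -1))
    ev <- ev[order(ev$p, -ev$d), ]   # starts before ends at ties: touching merges
    depth <- 0; open_at <- NA
    for (i in seq_len(nrow(ev))) {
      if (depth == 0 && ev$d[i] == 1) open_at <- ev$p[i]
      depth <- depth + ev$d[i]
      if (depth == 0)
        out[[length(out) + 1]] <- data.frame(chr = cc, start = open_at,
                                             end = ev$p[i])
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chr, res$start), ]
}

# brute-force coverage by counting intervals over cell midpoints
grid_coverage_max <- function(intervals, genome, cells = 1e4) {
  best <- 0
  for (cc in names(genome)) {
    mids <- seq(0, genome[[cc]], length.out = cells)[-1] -
      genome[[cc]] / (2 * (cells - 1))
    sub <- intervals[intervals$chr == cc, ]
    if (!nrow(sub)) next
    depth <- vapply(mids, function(p) sum(sub$start <= p & sub$end >= p),
                    numeric(1))
    best <- max(best, depth)
  }
  best
}
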