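test_that("VanRaden kinship reflects relatedness and supports LOCO", {
  pop <- generate_population(40, 300, k_pops = 2, fst = 0.3,
                             admixture_alpha = 0.05, n_chromosomes = 3,
                             seed = 8)
  K <- vanraden_kinship(pop$genotypes)
  expect_equal(K, t(K), tolerance = 1e-12)
  expect_true(all(diag(K) > 0))

  # duplicated accession: off-diagonal equals the diagonal
  dd <- pop$genotypes$dosage[c(1, 1, 2:20), ]
  rownames(dd) <- paste0("z", 1:21)
  gd <- genotype_matrix(dd, chrom = pop$genotypes$chrom, pos = pop$genotypes$pos)
  Kd <- vanraden_kinship(gd)
  expect_equal(Kd[1, 2], Kd[1, 1], tolerance = 1e-12)

  # within-population mean kinship exceeds between-population
  grp <- pop$genotypes$groups
  same <- outer(grp, grp, "==") & upper.tri(K)
  diff_ <- outer(grp, grp, "!=") & upper.tri(K)
  expect_gt(mean(K[same]), mean(K[diff_]))

  # LOCO removes the excluded chromosome's markers; single-chromosome fails
  Kl <- vanraden_kinship(pop$genotypes, exclude_chromosome = "chr1")
  expect_false(isTRUE(all.equal(K, Kl)))
  g1 <- subset_genotypes(pop$genotypes,
                         markers = pop$genotypes$chrom == "chr1")
  expect_error(vanraden_kinship(g1, exclude_chromosome = "chr1"),
               "polymorphic")
})

test_that("MLM p-values equal the dense GLS oracle", {
  pop <- generate_population(40, 120, k_pops = 2, fst = 0.2,
                             admixture_alpha = 0.1, n_chromosomes = 3, seed = 7)
  g <- impute_dosage(pop$genotypes)
  set.seed(1)
  y <- rnorm(40) + g[, 5] * 0.8
  names(y) <- rownames(g)
  tab <- mlm_scan(y, pop$genotypes, "K")
  nf <- attr(tab, "null_fit")$all
  K <- vanraden_kinship(pop$genotypes)
  pe <- dense_gls_pvalues(y, g, K, nf$sigma_g2, nf$sigma_e2)
  ok <- !is.na(pe) & !is.na(tab$p)
  expect_gt(sum(ok), 100)
  expect_lt(max(abs(tab$p[ok] - pe[ok])), 1e-6)
  expect_true(all(tab$p > 0 & tab$p <= 1, na.rm = TRUE))
  expect_true(all(tab$score >= 0, na.rm = TRUE))
})

test_that("the scan collapses to ordinary regression without genetic variance", {
  # phenotype independent of the (weak, unstructured) kinship
  pop <- generate_population(45, 200, k_pops = 1, fst = 0.2, seed = 9)
  g <- impute_dosage(pop$genotypes)
  set.seed(4)
  y <- stats::setNames(rnorm(45), rownames(g))
  tab <- mlm_scan(y, pop$genotypes, "K")
  pl <- vapply(seq_len(ncol(g)), function(j) {
    if (stats::var(g[, j]) == 0) return(NA_real_)
    summary(stats::lm(y ~ g[, j]))$coefficients[2, 4]
  }, numeric(1))
  ok <- !is.na(pl) & !is.na(tab$p)
  # delta is driven to the boundary, so GLS degenerates to OLS
  expect_lt(max(abs(tab$p[ok] - pl[ok])), 1e-6)
})

test_that("K-LOCO matches K closely on unstructured null data", {
  pop <- generate_population(50, 300, k_pops = 1, fst = 0.2,
                             n_chromosomes = 3, seed = 10)
  set.seed(5)
  y <- stats::setNames(rnorm(50), rownames(pop$genotypes$dosage))
  tk <- mlm_scan(y, pop$genotypes, "K")
  tl <- mlm_scan(y, pop$genotypes, "K-LOCO")
  ok <- !is.na(tk$p) & !is.na(tl$p)
  expect_gt(stats::cor(tk$score[ok], tl$score[ok]), 0.95)
  expect_equal(names(attr(tl, "null_fit")),
               unique(pop$genotypes$chrom))
})

test_that("Bonferroni thresholds reproduce the panel values", {
  expect_equal(round(bonferroni_threshold(6001), 1), 5.1)
  expect_equal(round(bonferroni_threshold(7263), 1), 5.2)
  expect_equal(bonferroni_threshold(1), -log10(0.05), tolerance = 1e-12)
  expect_error(bonferroni_threshold(0), "count")
})

test_that("inflation lambda is calibrated, monotone, and order-free", {
  n <- 2000
  p_unif <- (seq_len(n) - 0.5) / n
  expect_equal(inflation_lambda(p_unif), 1, tolerance = 0.01)
  expect_gt(inflation_lambda(p_unif / 10), inflation_lambda(p_unif))
  set.seed(2)
  expect_identical(inflation_lambda(sample(p_unif)), inflation_lambda(p_unif))
  expect_error(inflation_lambda(runif(5)), "10")
})

test_that("marker PVE spans its closed-form extremes", {
  set.seed(11)
  x <- rbinom(100, 2, 0.4)
  expect_equal(marker_pve(x, x * 1.7), 100)
  # zero estimated slope -> zero PVE
  y_orth <- stats::resid(stats::lm(rnorm(100) ~ x))
  expect_lt(marker_pve(x, y_orth), 1e-12)
  y_ind <- rnorm(100)
  expect_lt(marker_pve(x, y_ind), 10)
  expect_error(marker_pve(rep(1, 50), rnorm(50)), "monomorphic")
})

test_that("consensus QTL calling implements the two-model / two-panel rule", {
  mk_tab <- function(model, panel, score, pos = 1e6, chrom = "chr1") {
    data.frame(marker = paste0(chrom, "_", pos), chrom = chrom, pos = pos,
               beta = 1, se = 0.1, p = 10^-score, score = score, pve = 12,
               model = model, panel = panel, stringsAsFactors = FALSE)
  }
  thr <- c(full = 5, subset = 5)

  # significant in two models of one panel -> one call
  out <- consensus_qtl(list(mk_tab("K", "full", 6), mk_tab("K-LOCO", "full", 7)),
                       thr)
  expect_equal(nrow(out), 1)
  expect_equal(out$mean_score, 6.5)
  expect_match(out$models, "K,K-LOCO")

  # significant in exactly one model, one panel -> no call
  expect_equal(nrow(consensus_qtl(list(mk_tab("K", "full", 6),
                                       mk_tab("K-LOCO", "full", 3)), thr)), 0)

  # one model in each of two panels -> call
  out2 <- consensus_qtl(list(mk_tab("K", "full", 6), mk_tab("K", "subset", 6)),
                        thr)
  expect_equal(nrow(out2), 1)
  expect_match(out2$panels, "full,subset")

  # two passing markers 82 kb apart merge at a 100 kb radius
  t1 <- rbind(mk_tab("K", "full", 6, pos = 1e6),
              mk_tab("K", "full", 6, pos = 1e6 + 82000))
  t2 <- rbind(mk_tab("K-LOCO", "full", 6, pos = 1e6),
              mk_tab("K-LOCO", "full", 6, pos = 1e6 + 82000))
  out3 <- consensus_qtl(list(t1, t2), thr, merge_radius_bp = 1e5)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$n_markers, 2)
  # ... but stay separate at a 50 kb radius
  expect_equal(nrow(consensus_qtl(list(t1, t2), thr, merge_radius_bp = 5e4)), 2)

  # invariance to table input order
  out4 <- consensus_qtl(list(t2, t1), thr, merge_radius_bp = 1e5)
  expect_identical(out3, out4)

  expect_error(consensus_qtl(list(mk_tab("K", "other", 6)), thr), "threshold")
})

test_that("LD decay finds the r2 crossing distance", {
  # construct decaying LD: marker j copies a base marker with an
  # index-dependent resampling fraction, so r^2 falls with distance
  set.seed(12)
  n <- 300
  spacing <- 2e4
  # Markov chain along the chromosome: each marker copies the previous one,
  # resampling each individual with probability 1 - rho, so
  # cor(m_j, m_k) = rho^|j-k| and r2(d) = exp(-d / (3 * spacing)) for
  # rho = exp(-1/6)
  rho <- exp(-1 / 6)
  cols <- vector("list", 30)
  cols[[1]] <- rbinom(n, 2, 0.5)
  for (j in 2:30) {
    res <- rbinom(n, 1, 1 - rho)
    cols[[j]] <- ifelse(res == 1, rbinom(n, 2, 0.5), cols[[j - 1]])
  }
  dos <- do.call(cbind, cols)
  colnames(dos) <- sprintf("m%02d", 1:30)
  geno <- genotype_matrix(dos, chrom = rep("chr1", 30),
                          pos = as.integer((0:29) * spacing + 1))
  ld <- ld_decay(geno, max_dist_bp = 6e5, bin_width_bp = 2e4, r2_target = 0.1)
  # r(d) ~ exp(-d/(6*spacing)) => r2 crosses 0.1 near -ln(0.1)/2 * 6 * 2e4 = 138 kb
  expect_lt(abs(ld$crossing_bp - 1.38e5), 4e4)   # within ~2 bins
  expect_true(all(diff(ld$curve$smoothed_r2) <= 1e-12))

  # duplicated adjacent markers: first bin r2 = 1
  dup <- genotype_matrix(cbind(a = cols[[1]], b = cols[[1]]),
                         chrom = c("chr1", "chr1"), pos = c(1L, 1000L))
  ld2 <- ld_decay(dup, max_dist_bp = 1e4, bin_width_bp = 1e4)
  expect_equal(ld2$curve$mean_r2[1], 1)

  # unlinked markers: mean r2 small, near 1/(n-1)
  set.seed(13)
  ind <- matrix(rbinom(n * 20, 2, 0.5), n, 20)
  colnames(ind) <- paste0("u", 1:20)
  gu <- genotype_matrix(ind, chrom = rep("chr1", 20),
                        pos = as.integer(1:20 * 1e4))
  ldu <- ld_decay(gu, max_dist_bp = 2e5, bin_width_bp = 2e5)
  expect_lt(ldu$curve$mean_r2[1], 3 / (n - 1) + 0.01)
})

test_that("a strong causal marker is found under population structure", {
  pop <- generate_population(200, 500, k_pops = 2, fst = 0.15,
                             admixture_alpha = 0.3, seed = 18)
  g <- impute_dosage(pop$genotypes)
  j <- which(apply(g, 2, stats::var) > 0.3)[10]
  set.seed(6)
  x <- g[, j]
  y <- stats::setNames(x * sqrt(0.3 / 0.7) / stats::sd(x) + rnorm(200),
                       rownames(g))
  tab <- mlm_scan(y, pop$genotypes, "K")
  expect_equal(which.max(tab$score), j, ignore_attr = TRUE)
  expect_gte(tab$score[j], bonferroni_threshold(sum(!is.na(tab$p))))
})
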