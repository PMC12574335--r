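test_that("marker filtering enforces the panel retention rules", {
  set.seed(1)
  N <- 234
  # marker A: 4 hom-alt individuals -> fails min_per_hom_class
  a <- c(rep(2, 4), rep(1, 30), rep(0, N - 34))
  # marker B: modal genotype 230/234 = 0.983 > 1 - 5/234 -> fails
  b <- c(rep(0, 230), rep(1, 2), rep(2, 2))
  b2 <- c(rep(0, 150), rep(1, 40), rep(2, 44))  # modal 0.641, hom classes ok
  # marker C: perfectly balanced -> retained
  cc <- rep(0:2, each = 78)
  dos <- cbind(A = sample(a), B = sample(b), B2 = sample(b2), C = sample(cc))
  geno <- genotype_matrix(dos, chrom = rep("chr1", 4),
                          pos = c(10L, 20L, 30L, 40L))
  fl <- filter_markers(geno)
  expect_setequal(colnames(fl$genotypes$dosage), c("B2", "C"))
  expect_gte(fl$log["min_per_hom_class"], 1)
  expect_gte(fl$log["max_genotype_freq"], 1)
  expect_error(filter_markers(subset_genotypes(geno, markers = "B")),
               "all markers removed")
})

test_that("LD pruning matches the brute-force oracle and window semantics", {
  # two identical markers 1 kb apart: the later one is dropped
  dup <- cbind(m1 = c(0, 1, 2, 0, 1, 2, 1, 0), m2 = c(0, 1, 2, 0, 1, 2, 1, 0),
               m3 = c(2, 0, 1, 1, 0, 2, 0, 1))
  g1 <- genotype_matrix(dup, chrom = rep("chr1", 3),
                        pos = c(1000L, 2000L, 200000L))
  kept <- ld_prune(g1, window_kb = 50, r2_cutoff = 0.02)
  expect_setequal(kept, c("m1", "m3"))

  # identical markers beyond the window are both kept
  g2 <- genotype_matrix(dup[, 1:2], chrom = rep("chr1", 2),
                        pos = c(1000L, 200000L))
  expect_setequal(ld_prune(g2, window_kb = 50, r2_cutoff = 0.02), c("m1", "m2"))

  # random blocky instance equals the brute-force oracle
  set.seed(42)
  base <- matrix(rbinom(30 * 5, 2, 0.4), 30, 5)
  cols <- lapply(1:40, function(j) {
    src <- base[, (j - 1) %/% 8 + 1]
    flip <- rbinom(30, 1, 0.2)
    ifelse(flip == 1, rbinom(30, 2, 0.5), src)
  })
  dos <- do.call(cbind, cols)
  colnames(dos) <- sprintf("m%02d", 1:40)
  g3 <- genotype_matrix(dos, chrom = rep("chr1", 40),
                        pos = sort(sample.int(3e5, 40)))
  expect_identical(ld_prune(g3, window_kb = 50, r2_cutoff = 0.2),
                   brute_force_prune(g3, window_kb = 50, r2_cutoff = 0.2))
})

test_that("genotype PCA separates populations and is order-invariant", {
  pop <- generate_population(60, 400, k_pops = 2, fst = 0.3,
                             admixture_alpha = 0.05, seed = 12)
  pca <- pca_genotypes(pop$genotypes)
  grp <- pop$genotypes$groups
  s1 <- pca$scores[, 1]
  expect_true(prod(sign(tapply(s1, grp, mean))) < 0)
  expect_lte(sum(pca$pct_var), 100 + 1e-9)

  # duplicated accessions get identical scores
  dd <- pop$genotypes$dosage[c(1, 1, 2:10), ]
  rownames(dd) <- paste0("x", 1:11)
  gd <- genotype_matrix(dd, chrom = pop$genotypes$chrom, pos = pop$genotypes$pos)
  sc <- pca_genotypes(gd)$scores
  expect_equal(sc[1, ], sc[2, ], tolerance = 1e-9)

  # marker order invariance (scores up to sign)
  set.seed(3)
  perm <- sample(ncol(pop$genotypes$dosage))
  gp <- genotype_matrix(pop$genotypes$dosage[, perm],
                        chrom = pop$genotypes$chrom,
                        pos = pop$genotypes$pos)   # same map, shuffled columns
  pc2 <- pca_genotypes(gp)
  expect_equal(abs(pc2$scores[, 1]), abs(pca$scores[, 1]), tolerance = 1e-8)
})

test_that("admixture EM has its closed form at k=1 and a monotone loglik", {
  pop <- generate_population(40, 150, k_pops = 2, fst = 0.3,
                             admixture_alpha = 0.1, seed = 14)
  g <- impute_dosage(pop$genotypes)
  f1 <- admixture_em(g, 1, seed = 2, n_restarts = 1)
  expect_equal(as.numeric(f1$f), unname(colMeans(g) / 2), tolerance = 1e-6)
  expect_equal(as.numeric(f1$q), rep(1, 40))
  p <- pmin(pmax(colMeans(g) / 2, 1e-10), 1 - 1e-10)
  ll_binom <- sum(t(g) * log(p) + (2 - t(g)) * log(1 - p))
  expect_equal(f1$loglik, ll_binom, tolerance = 1e-4)

  f2 <- admixture_em(g, 2, seed = 2)
  expect_true(all(diff(f2$loglik_trace) > -1e-6))
  expect_equal(unname(rowSums(f2$q)), rep(1, 40), tolerance = 1e-8)
  expect_error(admixture_em(g, 100), "exceed")

  # two fixed disjoint populations: memberships recovered to 0/1
  dos <- rbind(matrix(rep(c(2, 0), each = 10 * 25), 10),
               matrix(rep(c(0, 2), each = 10 * 25), 10))
  colnames(dos) <- paste0("m", 1:50)
  fit <- admixture_em(dos, 2, seed = 5)
  qa <- round(fit$q)
  expect_true(all(qa[1:10, ] == rep(qa[1, ], each = 10)))
  expect_true(all(abs(fit$q - qa) < 0.01))
  expect_false(all(qa[1, ] == qa[11, ]))
})

test_that("admixture CV folds are seed-stable and recover k on separated pops", {
  pop <- generate_population(60, 250, k_pops = 3, fst = 0.3,
                             admixture_alpha = 0.05, seed = 15)
  g <- impute_dosage(pop$genotypes)
  cv1 <- admixture_cv(g, k_range = 1:4, seed = 7, max_iter = 250, tol = 2e-4)
  cv2 <- admixture_cv(g, k_range = 1:4, seed = 7, max_iter = 250, tol = 2e-4)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$cv_error, cv2$cv_error)
  expect_equal(cv1$k_selected, 3)
})

test_that("Nei 1972 distances match hand calculations", {
  # identical frequency vectors
  p <- rbind(a = c(0.3, 0.7, 0.5), b = c(0.3, 0.7, 0.5))
  expect_equal(nei_distance(p)[1, 2], 0, tolerance = 1e-12)

  # one locus, x fixed, y = 0.5: D = -ln(0.5 / sqrt(0.5)) = ln(sqrt(2))
  p2 <- rbind(a = 1, b = 0.5)
  expect_equal(nei_distance(p2)[1, 2], -log(0.5 / sqrt(0.5)), tolerance = 1e-12)
  expect_equal(nei_distance(p2)[1, 2], 0.34657359, tolerance = 1e-6)

  # opposite fixation: infinite distance reported as the capped sentinel
  p3 <- rbind(a = 1, b = 0)
  expect_warning(D <- nei_distance(p3), "capped")
  expect_equal(D[1, 2], -log(.Machine$double.eps))
})

test_that("NJ reconstructs additive trees and tolerates label permutation", {
  fx <- additive_tree_fixture()
  tr <- nj_tree(fx$dist)
  expect_equal(unname(ape::cophenetic.phylo(tr)[rownames(fx$dist), colnames(fx$dist)]),
               unname(fx$dist), tolerance = 1e-9)
  # topology AB|CD
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")))

  # larger additive instance: random tree distances reproduced exactly
  set.seed(20)
  rt <- ape::rtree(8)
  dd <- ape::cophenetic.phylo(rt)
  tr8 <- nj_tree(dd)
  expect_equal(unname(ape::cophenetic.phylo(tr8)[rownames(dd), colnames(dd)]),
               unname(dd), tolerance = 1e-8)

  # permuting labels yields an isomorphic tree
  perm <- c(3, 1, 2, 4)
  dp <- fx$dist[perm, perm]
  tp <- nj_tree(dp)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tp))[1], 0)

  # equidistant 3 taxa: star with equal branches
  d3 <- matrix(2, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  t3 <- nj_tree(d3)
  expect_equal(unname(t3$edge.length), rep(1, 3), tolerance = 1e-12)

  # negative-branch clamping: no negative lengths on noisy input
  set.seed(21)
  dn <- as.matrix(dist(matrix(rnorm(12), 6)))
  expect_true(all(nj_tree(dn)$edge.length >= 0))
})

test_that("pairwise Fst matches fixtures and rises with divergence", {
  # opposite fixation at every locus: Fst = 1 under both estimators
  dos <- rbind(matrix(2, 5, 20), matrix(0, 5, 20))
  rownames(dos) <- paste0("a", 1:10)
  colnames(dos) <- paste0("m", 1:20)
  geno <- genotype_matrix(dos, chrom = rep("chr1", 20), pos = 1:20 * 100L)
  grp <- rep(c("p1", "p2"), each = 5)
  expect_equal(pairwise_fst(geno, grp, method = "gst")[1, 2], 1)
  expect_equal(pairwise_fst(geno, grp, method = "nei87")[1, 2], 1)

  # duplicated group: Fst 0 (clamped estimator noise)
  dup <- rbind(dos[1:5, ], dos[1:5, ])
  rownames(dup) <- paste0("b", 1:10)
  gd <- genotype_matrix(dup, chrom = rep("chr1", 20), pos = 1:20 * 100L)
  expect_equal(pairwise_fst(gd, grp, method = "nei87")[1, 2], 0)

  # hand fixture p1 = 0.2, p2 = 0.8 (one locus):
  # Gst: Ht = 0.5, Hs = 0.32 -> 0.36
  d1 <- rbind(matrix(c(0, 0, 0, 1, 1), 5, 1),     # p = 0.2 in 5 diploids
              matrix(c(2, 2, 2, 1, 1), 5, 1))     # p = 0.8
  rownames(d1) <- paste0("c", 1:10)
  g1 <- genotype_matrix(cbind(m1 = d1[, 1]), chrom = "chr1", pos = 1L)
  expect_equal(pairwise_fst(g1, grp, method = "gst")[1, 2], 0.36,
               tolerance = 1e-6)
  # Nei87 with n = 5 per group: Hs = (10/9)*0.32, Ht = 0.5 + Hs/20,
  # Dst' = 2*(Ht - Hs), Fst = Dst'/(Hs + Dst')
  hs <- (10 / 9) * 0.32
  ht <- 0.5 + hs / 20
  dstp <- 2 * (ht - hs)
  expect_equal(pairwise_fst(g1, grp, method = "nei87")[1, 2],
               dstp / (hs + dstp), tolerance = 1e-9)

  # monotone in the Balding-Nichols parameter
  est <- vapply(c(0.05, 0.1, 0.2, 0.4), function(f) {
    pop <- generate_population(60, 1500, k_pops = 2, fst = f,
                               admixture_alpha = 0.02, seed = 31)
    pairwise_fst(pop$genotypes)[1, 2]
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_true(all(est >= 0 & est <= 1))
})
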