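# Shared fixtures, all built in code at test time.

# A tiny hand-specified genotype matrix (5 accessions x 4 markers).
tiny_genotypes <- function() {
  dos <- rbind(
    acc1 = c(0, 1, 2, 0),
    acc2 = c(0, 1, 2, 1),
    acc3 = c(1, 0, 1, 2),
    acc4 = c(2, 2, 0, 2),
    acc5 = c(1, 0, 0, 1)
  )
  genotype_matrix(dos, chrom = c("chr1", "chr1", "chr2", "chr2"),
                  pos = c(100L, 5000L, 200L, 9000L))
}

# Balanced two-environment records with exactly known cell means and no
# random effects: value = mu + g_i (g given), same in every block.
balanced_records <- function(gvals, n_env = 2, n_blocks = 2, mu = 10,
                             noise_sd = 0, seed = 1) {
  acc <- names(gvals)
  grid <- expand.grid(accession = acc,
                      block = paste0("block", seq_len(n_blocks)),
                      env = paste0("env", seq_len(n_env)),
                      stringsAsFactors = FALSE)
  grid$plot <- paste(grid$env, grid$block, grid$accession, sep = ":")
  grid$root <- 1L
  grid$trait <- "y"
  set.seed(seed)
  grid$value <- mu + gvals[grid$accession] + stats::rnorm(nrow(grid), 0, noise_sd)
  grid
}

# Brute-force LD pruning oracle: same rule as ld_prune, O(n^2) restated.
brute_force_prune <- function(genotypes, window_kb, r2_cutoff) {
  g <- genotypes$dosage
  retained <- character(0)
  for (ch in unique(genotypes$chrom)) {
    idx <- which(genotypes$chrom == ch)
    idx <- idx[order(genotypes$pos[idx])]
    kept <- integer(0)
    for (j in idx) {
      bad <- FALSE
      for (k in kept) {
        if (genotypes$pos[j] - genotypes$pos[k] <= window_kb * 1000) {
          r <- suppressWarnings(stats::cor(g[, j], g[, k], use = "complete.obs"))
          if (is.finite(r) && r^2 > r2_cutoff) bad <- TRUE
        }
      }
      if (!bad) kept <- c(kept, j)
    }
    retained <- c(retained, colnames(g)[kept])
  }
  retained
}

# Dense-matrix GLS association oracle at given variance components.
dense_gls_pvalues <- function(y, g, K, sigma_g2, sigma_e2) {
  n <- length(y)
  V <- sigma_g2 * K + sigma_e2 * diag(n)
  Vi <- solve(V)
  vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j]
    if (stats::var(x) == 0) return(NA_real_)
    X <- cbind(1, x)
    A <- t(X) %*% Vi %*% X
    b <- solve(A, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    df <- n - 2
    s2 <- as.numeric(t(r) %*% Vi %*% r) / df
    vb <- s2 * solve(A)[2, 2]
    2 * stats::pt(-abs(b[2] / sqrt(vb)), df)
  }, numeric(1))
}

# A 4-taxon additive tree and its exact path-length distance matrix.
additive_tree_fixture <- function() {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):0);")
  list(tree = tr, dist = ape::cophenetic.phylo(tr))
}
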