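#' Filter markers by quality-control rules
#'
#' Applies the panel's marker-retention rules: biallelic/polymorphic only;
#' at least `min_per_hom_class` individuals in each homozygous class; modal
#' genotype frequency no greater than `1 - 5/N` (markers where nearly every
#' accession carries the same genotype are uninformative); optional mean
#' read-depth and genotype-quality minima, applied only when the matrices
#' are present on the genotype object.
#'
#' @param genotypes A [genotype_matrix()].
#' @param rules List overriding any of `biallelic` (TRUE), `min_per_hom_class`
#'   (5), `max_genotype_freq` (default `1 - 5/N`; set `NA` to disable),
#'   `min_depth` (NA), `min_gq` (NA).
#' @return List with `genotypes` (filtered) and `log` (markers removed per
#'   rule; a marker failing several rules is counted under each).
#' @export
filter_markers <- function(genotypes, rules = list()) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  g <- genotypes$dosage
  N <- nrow(g)
  if (N < 6) stop_param("need at least 6 accessions for the homozygote rule")
  def <- list(biallelic = TRUE, min_per_hom_class = 5,
              max_genotype_freq = 1 - 5 / N, min_depth = NA, min_gq = NA)
  def[names(rules)] <- rules
  r <- def

  keep <- rep(TRUE, ncol(g))
  log <- c(monomorphic = 0L, min_per_hom_class = 0L, max_genotype_freq = 0L,
           min_depth = 0L, min_gq = 0L)

  n0 <- colSums(g == 0, na.rm = TRUE)
  n1 <- colSums(g == 1, na.rm = TRUE)
  n2 <- colSums(g == 2, na.rm = TRUE)
  nn <- n0 + n1 + n2

  if (isTRUE(r$biallelic)) {
    bad <- (n0 + n1 == 0) | (n2 + n1 == 0)   # no alternate or no reference allele
    log["monomorphic"] <- sum(bad)
    keep <- keep & !bad
  }
  if (is.finite(r$min_per_hom_class) && r$min_per_hom_class > 0) {
    bad <- n0 < r$min_per_hom_class | n2 < r$min_per_hom_class
    log["min_per_hom_class"] <- sum(bad)
    keep <- keep & !bad
  }
  if (is.finite(r$max_genotype_freq)) {
    modal <- pmax(n0, n1, n2) / pmax(nn, 1)
    bad <- modal > r$max_genotype_freq
    log["max_genotype_freq"] <- sum(bad)
    keep <- keep & !bad
  }
  if (is.finite(r$min_depth) && !is.null(genotypes$depth)) {
    bad <- colMeans(genotypes$depth, na.rm = TRUE) < r$min_depth
    log["min_depth"] <- sum(bad, na.rm = TRUE)
    keep <- keep & !(bad %in% TRUE)
  }
  if (is.finite(r$min_gq) && !is.null(genotypes$gq)) {
    bad <- colMeans(genotypes$gq, na.rm = TRUE) < r$min_gq
    log["min_gq"] <- sum(bad, na.rm = TRUE)
    keep <- keep & !(bad %in% TRUE)
  }
  if (!any(keep)) stop_param("all markers removed by the filtering rules")
  list(genotypes = subset_genotypes(genotypes, markers = keep),
       log = c(log, retained = sum(keep), removed = sum(!keep)))
}

#' Prune markers by linkage disequilibrium
#'
#' Greedy positional scan per chromosome: markers are visited in position
#' order and a marker is dropped when its squared dosage correlation with
#' any already-retained marker within `window_kb` upstream exceeds
#' `r2_cutoff` (composite LD on unphased dosages; pairs with missing data
#' use complete observations).
#'
#' @param genotypes A [genotype_matrix()].
#' @param window_kb Window size in kb (default 50).
#' @param step_kb Window step in kb; accepted for interface compatibility
#'   with sliding-window pruners (the scan here is marker-anchored, the
#'   dense-window limit).
#' @param r2_cutoff Squared-correlation threshold above which the later
#'   marker of a pair is dropped (default 0.02).
#' @return Character vector of retained marker ids.
#' @export
ld_prune <- function(genotypes, window_kb = 50, step_kb = 5, r2_cutoff = 0.02) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  g <- genotypes$dosage
  win <- window_kb * 1000
  retained <- character(0)
  for (ch in unique(genotypes$chrom)) {
    idx <- which(genotypes$chrom == ch)
    idx <- idx[order(genotypes$pos[idx])]
    kept <- integer(0)
    for (j in idx) {
      near <- kept[genotypes$pos[j] - genotypes$pos[kept] <= win]
      drop <- FALSE
      for (k in near) {
        r <- suppressWarnings(stats::cor(g[, j], g[, k],
                                         use = "complete.obs"))
        if (is.finite(r) && r^2 > r2_cutoff) { drop <- TRUE; break }
      }
      if (!drop) kept <- c(kept, j)
    }
    retained <- c(retained, colnames(g)[kept])
  }
  retained
}

#' Principal component analysis of the dosage matrix
#'
#' Missing dosages are mean-imputed per marker, columns are centered, and
#' the scores/eigenvalue shares come from the singular value decomposition
#' (via [stats::prcomp()]).
#'
#' @param genotypes A [genotype_matrix()].
#' @param n_comp Number of components to return.
#' @return List with `scores` (accessions x components), `pct_var` (percent
#'   of total variance per returned component), and `loadings`.
#' @export
pca_genotypes <- function(genotypes, n_comp = 10) {
  g <- impute_dosage(genotypes)
  pc <- stats::prcomp(g, center = TRUE, scale. = FALSE)
  n_comp <- min(n_comp, ncol(pc$x))
  list(scores = pc$x[, seq_len(n_comp), drop = FALSE],
       pct_var = 100 * pc$sdev[seq_len(n_comp)]^2 / sum(pc$sdev^2),
       loadings = pc$rotation[, seq_len(n_comp), drop = FALSE])
}

# Binomial admixture log-likelihood; W is an optional 0/1 inclusion mask.
admixture_loglik <- function(G, Q, F_, W = NULL) {
  P <- Q %*% F_
  P <- pmin(pmax(P, 1e-10), 1 - 1e-10)
  ll <- G * log(P) + (2 - G) * log(1 - P)
  if (!is.null(W)) ll <- ll * W
  sum(ll)
}

#' Maximum-likelihood admixture inference by EM
#'
#' Models each dosage as Binomial(2, sum_k q_ik f_kj) and maximizes the
#' log-likelihood by alternating multiplicative EM updates of the ancestry
#' proportions Q and ancestral frequencies F. The log-likelihood is
#' non-decreasing at every iteration; several random restarts guard against
#' local optima and the best fit is kept.
#'
#' @param genotypes A [genotype_matrix()] or dosage matrix without missing
#'   values (impute first, e.g. [impute_dosage()]).
#' @param k Number of ancestral populations (>= 1).
#' @param seed Integer seed (initialization).
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Stop when the log-likelihood gain per iteration falls below
#'   this.
#' @param n_restarts Random restarts (default 3).
#' @param mask Optional accession x marker 0/1 matrix; zero entries are
#'   excluded from the likelihood (used by [admixture_cv()]).
#' @return An `admixture_fit`: `q` (accessions x k, rows summing to 1), `f`
#'   (k x markers), `loglik`, `loglik_trace`, `k`, `n_iter`, `seed`.
#' @export
admixture_em <- function(genotypes, k, seed = 1, max_iter = 2000, tol = 1e-6,
                         n_restarts = 3, mask = NULL) {
  G <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else as.matrix(genotypes)
  if (anyNA(G)) stop_param("missing dosages: impute before admixture_em")
  n <- nrow(G); m <- ncol(G)
  if (!is_count(k)) stop_param("k must be a positive count")
  if (k > n) stop_param("k cannot exceed the number of accessions")
  W <- mask
  tw <- if (is.null(W)) rep(2 * m, n) else 2 * rowSums(W)
  eps <- 1e-8

  run_once <- function(rs) {
    with_seed(derive_seed(seed, paste0("adm", rs)), {
      Q <- matrix(stats::rgamma(n * k, 1), n, k)
      Q <- Q / rowSums(Q)
      p_obs <- if (is.null(W)) colMeans(G) / 2 else colSums(G * W) / pmax(1, 2 * colSums(W))
      F_ <- matrix(pmin(pmax(rep(p_obs, each = k) +
                               stats::rnorm(k * m, 0, 0.05), eps), 1 - eps),
                   nrow = k)
      ll_old <- -Inf
      trace <- numeric(0)
      it <- 0L
      G2 <- 2 - G
      for (it in seq_len(max_iter)) {
        P <- Q %*% F_
        P <- pmin(pmax(P, 1e-10), 1 - 1e-10)
        A <- G / P
        B <- G2 / (1 - P)
        if (!is.null(W)) { A <- A * W; B <- B * W }
        Qn <- Q * (A %*% t(F_) + B %*% t(1 - F_)) / tw
        Qn <- Qn / rowSums(Qn)
        num <- F_ * crossprod(Q, A)          # uses Q from this iteration's E-step
        den <- num + (1 - F_) * crossprod(Q, B)
        Fn <- ifelse(den > 0, num / den, F_)
        Q <- Qn
        F_ <- pmin(pmax(Fn, eps), 1 - eps)
        ll <- admixture_loglik(G, Q, F_, W)
        trace <- c(trace, ll)
        if (is.finite(ll_old) && ll - ll_old < tol) break
        ll_old <- ll
      }
      list(q = Q, f = F_, loglik = ll, loglik_trace = trace, n_iter = it)
    })
  }
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    cand <- run_once(rs)
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }
  rownames(best$q) <- rownames(G)
  colnames(best$q) <- paste0("pop", seq_len(k))
  structure(c(best, list(k = k, seed = seed)), class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("admixture_fit: k =", x$k, "| loglik =", format(x$loglik), "|",
      x$n_iter, "EM iterations\n")
  invisible(x)
}

#' Cross-validated choice of the number of ancestral populations
#'
#' Masks random folds of individual genotype entries (accession x marker
#' cells), refits the admixture model on the unmasked entries, and scores
#' the masked entries by their mean binomial deviance against the predicted
#' dose `2 * sum_k q_ik f_kj`. The k minimizing the mean cross-validation
#' error is selected.
#'
#' @param genotypes Dosage matrix or [genotype_matrix()] without missing
#'   values.
#' @param k_range Integer vector of k values to score.
#' @param n_folds Number of entry folds (default 5).
#' @param seed Integer seed (fold assignment and EM starts).
#' @param max_iter,tol EM settings per fit (CV fits use a single restart).
#' @return List with `cv_error` (named by k), `k_selected`, and `folds`.
#' @export
admixture_cv <- function(genotypes, k_range = 1:5, n_folds = 5, seed = 1,
                         max_iter = 500, tol = 1e-4) {
  G <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else as.matrix(genotypes)
  if (anyNA(G)) stop_param("missing dosages: impute before admixture_cv")
  n <- nrow(G); m <- ncol(G)
  folds <- with_seed(derive_seed(seed, "folds"),
                     matrix(sample(rep(seq_len(n_folds), length.out = n * m)), n, m))
  dev_entry <- function(g, mu) {
    mu <- pmin(pmax(mu, 1e-10), 2 - 1e-10)
    t1 <- ifelse(g > 0, g * log(g / mu), 0)
    t2 <- ifelse(g < 2, (2 - g) * log((2 - g) / (2 - mu)), 0)
    2 * (t1 + t2)
  }
  cv <- stats::setNames(numeric(length(k_range)), k_range)
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    err <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      W <- matrix(as.numeric(folds != f), n, m)
      fit <- admixture_em(G, k, seed = derive_seed(seed, paste0("cv", k, "_", f)),
                          max_iter = max_iter, tol = tol, n_restarts = 1,
                          mask = W)
      mu <- 2 * (fit$q %*% fit$f)
      held <- folds == f
      err[f] <- mean(dev_entry(G[held], mu[held]))
    }
    cv[ki] <- mean(err)
  }
  list(cv_error = cv, k_selected = k_range[which.min(cv)], folds = folds)
}

# Allele-frequency matrix (units x markers) for accessions or groups.
unit_allele_freq <- function(genotypes, unit, groups) {
  g <- genotypes$dosage
  if (unit == "accession") {
    p <- g / 2
    rownames(p) <- rownames(g)
    return(p)
  }
  if (is.null(groups)) groups <- genotypes$groups
  if (is.null(groups)) stop_param("group-level frequencies need group labels")
  groups <- as.factor(groups)
  p <- t(vapply(levels(groups), function(gr) {
    colMeans(g[groups == gr, , drop = FALSE], na.rm = TRUE) / 2
  }, numeric(ncol(g))))
  rownames(p) <- levels(groups)
  p
}

#' Nei (1972) standard genetic distance
#'
#' `D = -ln( Jxy / sqrt(Jx * Jy) )` with gene identities averaged over loci:
#' `Jxy = mean_l (x p y p + x q y q)`, `Jx = mean_l (x p^2 + x q^2)` over the
#' two alleles of each biallelic locus. Units are accessions (dosage/2
#' frequencies) or groups (pooled frequencies). Pairs with no shared alleles
#' have infinite distance and are capped at `-ln` of machine epsilon with a
#' warning.
#'
#' @param genotypes A [genotype_matrix()], or a units x markers allele
#'   frequency matrix.
#' @param unit `"accession"` or `"group"`.
#' @param groups Group labels (defaults to the object's `groups`).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
nei_distance <- function(genotypes, unit = c("group", "accession"),
                         groups = NULL) {
  unit <- match.arg(unit)
  p <- if (inherits(genotypes, "genotype_matrix"))
    unit_allele_freq(genotypes, unit, groups) else as.matrix(genotypes)
  if (anyNA(p)) {
    warning("missing frequencies dropped locus-wise per pair")
  }
  nu <- nrow(p)
  D <- matrix(0, nu, nu, dimnames = list(rownames(p), rownames(p)))
  cap <- -log(.Machine$double.eps)
  capped <- FALSE
  for (i in seq_len(nu)) for (j in seq_len(nu)) {
    if (j <= i) next
    ok <- is.finite(p[i, ]) & is.finite(p[j, ])
    x <- p[i, ok]; y <- p[j, ok]
    jxy <- mean(x * y + (1 - x) * (1 - y))
    jx <- mean(x^2 + (1 - x)^2)
    jy <- mean(y^2 + (1 - y)^2)
    d <- if (jxy <= 0) { capped <- TRUE; cap } else -log(jxy / sqrt(jx * jy))
    D[i, j] <- D[j, i] <- max(0, d)
  }
  if (capped)
    warning("pairs with no shared alleles: distance capped at ", format(cap))
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via \pkg{ape}). Negative branch lengths, which
#' NJ can produce on non-additive input, are clamped to zero with the
#' negative amount transferred to the adjacent branch so path lengths
#' through the node are preserved.
#'
#' @param distances Symmetric matrix or `dist` (n >= 3).
#' @return An [ape::nj()] `phylo` tree with non-negative branch lengths.
#' @export
nj_tree <- function(distances) {
  d <- as.matrix(distances)
  if (nrow(d) < 3) stop_param("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop_param("distance matrix must be symmetric")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    amt <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    child <- tr$edge[e, 2]
    adj <- which(tr$edge[, 1] == child)
    if (length(adj) == 0) adj <- setdiff(which(tr$edge[, 1] == tr$edge[e, 1]), e)
    if (length(adj)) tr$edge.length[adj[1]] <- tr$edge.length[adj[1]] + amt
  }
  tr
}

#' Pairwise Fst between groups
#'
#' Multilocus ratio-of-sums fixation index for every pair of groups.
#' `method = "nei87"` (default) is the sample-size-corrected Nei (1987)
#' estimator used for population pairs: per locus,
#' `Hs = (2n/(2n-1)) * mean_k 2 p_k q_k` with `n` the harmonic mean sample
#' size, `Ht = 2 pbar qbar + Hs/(4n)`, `Dst' = 2 (Ht - Hs)` (the k/(k-1)
#' correction at k = 2) and `Ht' = Hs + Dst'`; Fst is `sum(Dst')/sum(Ht')`
#' over loci. Its expectation equals the Balding-Nichols differentiation
#' parameter. `method = "gst"` is the uncorrected Nei (1973) Gst,
#' `sum(Ht - Hs) / sum(Ht)`, kept for hand-checkable arithmetic.
#'
#' @param genotypes A [genotype_matrix()].
#' @param groups Group labels per accession (defaults to the object's
#'   `groups`).
#' @param method `"nei87"` or `"gst"`.
#' @return Symmetric group x group matrix in \[0, 1\] with `NA` diagonal.
#' @export
pairwise_fst <- function(genotypes, groups = NULL,
                         method = c("nei87", "gst")) {
  method <- match.arg(method)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  groups <- as.factor(groups %||% genotypes$groups)
  if (is.null(groups)) stop_param("pairwise_fst needs group labels")
  if (any(table(groups) < 2)) stop_param("each group needs >= 2 accessions")
  g <- genotypes$dosage
  lv <- levels(groups)
  out <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j <= i) next
    gi <- g[groups == lv[i], , drop = FALSE]
    gj <- g[groups == lv[j], , drop = FALSE]
    ni <- colSums(!is.na(gi)); nj <- colSums(!is.na(gj))
    ok <- ni > 0 & nj > 0
    p1 <- colMeans(gi, na.rm = TRUE)[ok] / 2
    p2 <- colMeans(gj, na.rm = TRUE)[ok] / 2
    hs_raw <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
    pbar <- (p1 + p2) / 2
    ht_raw <- 2 * pbar * (1 - pbar)
    fst <- if (method == "gst") {
      if (sum(ht_raw) <= 0) 0 else sum(ht_raw - hs_raw) / sum(ht_raw)
    } else {
      nh <- 2 / (1 / ni[ok] + 1 / nj[ok])           # harmonic mean sample size
      hs <- (2 * nh / (2 * nh - 1)) * hs_raw
      ht <- ht_raw + hs / (4 * nh)
      dst_p <- 2 * (ht - hs)
      ht_p <- hs + dst_p
      if (sum(ht_p) <= 0) 0 else sum(dst_p) / sum(ht_p)
    }
    out[i, j] <- out[j, i] <- min(1, max(0, fst))
  }
  out
}
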