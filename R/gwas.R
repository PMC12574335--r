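#' VanRaden genomic relationship matrix
#'
#' `K = W W' / (2 * sum_j p_j (1 - p_j))` with `W` the dosage matrix centered
#' by twice the allele frequency. Monomorphic markers are skipped; missing
#' dosages are mean-imputed. Excluding a chromosome implements the
#' leave-one-chromosome-out (LOCO) kinship.
#'
#' @param genotypes A [genotype_matrix()].
#' @param exclude_chromosome Optional chromosome label to leave out.
#' @return A symmetric positive semidefinite accession x accession matrix
#'   with attributes `method` and `loco_chromosome`.
#' @export
vanraden_kinship <- function(genotypes, exclude_chromosome = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  sel <- rep(TRUE, ncol(genotypes$dosage))
  if (!is.null(exclude_chromosome)) sel <- genotypes$chrom != exclude_chromosome
  g <- impute_dosage(genotypes)[, sel, drop = FALSE]
  p <- colMeans(g) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2)
    stop_param("fewer than 2 polymorphic markers remain",
               if (!is.null(exclude_chromosome))
                 paste0(" after excluding ", exclude_chromosome))
  W <- sweep(g[, poly, drop = FALSE], 2, 2 * p[poly])
  K <- tcrossprod(W) / (2 * sum(p[poly] * (1 - p[poly])))
  dimnames(K) <- list(rownames(g), rownames(g))
  attr(K, "method") <- "vanraden"
  attr(K, "loco_chromosome") <- exclude_chromosome
  K
}

# Null-model REML for y = X0 b + g + e, Var = sg2 * K + se2 * I, via the
# spectral decomposition of K and a bounded scalar search over
# log(delta) = log(se2/sg2) in [-10, 10].
mlm_null_reml <- function(y, X0, K, log_delta_bounds = c(-25, 25)) {
  n <- length(y)
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X0)
  p <- ncol(X0)
  reml_ll <- function(logd) {
    w <- d + exp(logd)
    A <- crossprod(Xt, Xt / w)
    b <- solve(A, crossprod(Xt, yt / w))
    r <- yt - Xt %*% b
    rss <- sum(r^2 / w)
    sg2 <- rss / (n - p)
    -0.5 * ((n - p) * log(sg2) + sum(log(w)) +
              determinant(A, logarithm = TRUE)$modulus + (n - p))
  }
  opt <- stats::optimize(reml_ll, interval = log_delta_bounds,
                         maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  w <- d + delta
  A <- crossprod(Xt, Xt / w)
  b <- solve(A, crossprod(Xt, yt / w))
  rss <- sum((yt - Xt %*% b)^2 / w)
  sg2 <- rss / (n - p)
  list(U = U, d = d, delta = delta, sigma_g2 = sg2, sigma_e2 = sg2 * delta,
       reml_ll = opt$objective, beta0 = as.numeric(b))
}

#' Mixed-linear-model association scan with kinship control
#'
#' For each trait's accession-level values (typically BLUEs), variance
#' components of the null kinship model are estimated once by REML through
#' the spectral decomposition of K; every marker is then tested by
#' generalized least squares in the rotated (whitened) space, with a Wald
#' t-test on the marker effect. `kinship_mode = "K-LOCO"` re-estimates the
#' null per chromosome with that chromosome excluded from the kinship,
#' avoiding proximal contamination. Markers collinear with the covariates
#' are skipped and logged.
#'
#' @param blues Named numeric vector of phenotype values (names are
#'   accession ids present in `genotypes`).
#' @param genotypes A [genotype_matrix()].
#' @param kinship_mode `"K"` or `"K-LOCO"`.
#' @param covariates Optional accession x q matrix of fixed covariates
#'   (e.g. principal components), rownames matching accessions.
#' @param model_label Label stored in the `model` column (defaults to the
#'   kinship mode, plus `"+PC"` when covariates are supplied).
#' @param panel Panel label carried into [consensus_qtl()].
#' @return A `gwas_table` data.frame (marker, chrom, pos, beta, se, p,
#'   score = -log10 p, pve, model, panel) with attributes `null_fit`
#'   (per-chromosome list for LOCO) and `skipped`.
#' @export
mlm_scan <- function(blues, genotypes, kinship_mode = c("K", "K-LOCO"),
                     covariates = NULL, model_label = NULL, panel = "full") {
  kinship_mode <- match.arg(kinship_mode)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  blues <- blues[is.finite(blues)]
  acc <- intersect(names(blues), rownames(genotypes$dosage))
  if (length(acc) < 10) stop_param("fewer than 10 accessions shared between phenotypes and genotypes")
  geno <- subset_genotypes(genotypes, accessions = acc)
  y <- as.numeric(blues[acc])
  g <- impute_dosage(geno)
  n <- length(y)
  X0 <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (!is.null(rownames(cv))) cv <- cv[acc, , drop = FALSE]
    X0 <- cbind(X0, cv)
  }
  model_label <- model_label %||%
    paste0(kinship_mode, if (!is.null(covariates)) "+PC" else "")

  m <- ncol(g)
  beta <- se <- pval <- rep(NA_real_, m)
  skipped <- character(0)
  nulls <- list()

  scan_block <- function(cols, K) {
    nf <- mlm_null_reml(y, X0, K)
    w <- nf$d + nf$delta
    yt <- crossprod(nf$U, y)
    Xt <- crossprod(nf$U, X0)
    Gt <- crossprod(nf$U, g[, cols, drop = FALSE])
    p0 <- ncol(X0)
    df <- n - p0 - 1
    for (ii in seq_along(cols)) {
      xt <- Gt[, ii]
      Xa <- cbind(Xt, xt)
      A <- crossprod(Xa, Xa / w)
      ok <- TRUE
      bhat <- tryCatch(solve(A, crossprod(Xa, yt / w)),
                       error = function(e) { ok <<- FALSE; NULL })
      if (!ok || !is.finite(A[p0 + 1, p0 + 1]) ||
          rcond(A) < .Machine$double.eps * 100) {
        skipped <<- c(skipped, colnames(g)[cols[ii]])
        next
      }
      r <- yt - Xa %*% bhat
      s2 <- sum(r^2 / w) / df
      vb <- s2 * solve(A)[p0 + 1, p0 + 1]
      if (!is.finite(vb) || vb <= 0) {
        skipped <<- c(skipped, colnames(g)[cols[ii]])
        next
      }
      j <- cols[ii]
      beta[j] <<- bhat[p0 + 1]
      se[j] <<- sqrt(vb)
      pval[j] <<- 2 * stats::pt(-abs(bhat[p0 + 1] / se[j]), df)
    }
    nf[c("delta", "sigma_g2", "sigma_e2")]
  }

  if (kinship_mode == "K") {
    K <- vanraden_kinship(geno)
    nulls[["all"]] <- scan_block(seq_len(m), K)
  } else {
    for (ch in unique(geno$chrom)) {
      K <- vanraden_kinship(geno, exclude_chromosome = ch)
      nulls[[ch]] <- scan_block(which(geno$chrom == ch), K)
    }
  }

  vy <- stats::var(y)
  vx <- apply(g, 2, stats::var)
  pve <- 100 * beta^2 * vx / vy
  pve <- pmin(pve, 100)

  out <- data.frame(
    marker = colnames(g), chrom = geno$chrom, pos = geno$pos,
    beta = beta, se = se, p = pval,
    score = -log10(pval), pve = pve,
    model = model_label, panel = panel, stringsAsFactors = FALSE
  )
  class(out) <- c("gwas_table", "data.frame")
  attr(out, "null_fit") <- nulls
  attr(out, "skipped") <- skipped
  attr(out, "n") <- n
  out
}

#' Bonferroni significance threshold on the -log10 scale
#'
#' @param n_markers Number of tests.
#' @param alpha Family-wise error rate (default 0.05).
#' @return `-log10(alpha / n_markers)`.
#' @export
bonferroni_threshold <- function(n_markers, alpha = 0.05) {
  if (!is_count(n_markers)) stop_param("n_markers must be a positive count")
  -log10(alpha / n_markers)
}

#' Genomic inflation factor from observed vs expected quantiles
#'
#' Sorts the observed `-log10(p)` values, pairs them with the expected
#' uniform order-statistic quantiles `-log10((i - 0.5)/n)`, and returns the
#' slope of the no-intercept regression of observed on expected. Well
#' calibrated tests give 1.
#'
#' @param p_values Numeric vector of p-values (>= 10).
#' @return The inflation slope lambda.
#' @export
inflation_lambda <- function(p_values) {
  p <- p_values[is.finite(p_values) & p_values > 0 & p_values <= 1]
  n <- length(p)
  if (n < 10) stop_param("need at least 10 p-values")
  obs <- sort(-log10(p), decreasing = TRUE)
  expd <- -log10((seq_len(n) - 0.5) / n)
  sum(obs * expd) / sum(expd^2)
}

#' Percent phenotypic variance explained by one marker
#'
#' `PVE = 100 * beta^2 * Var(dosage) / Var(phenotype)` from the
#' single-marker regression, capped at 100.
#'
#' @param dosage Numeric marker dosages.
#' @param blues Phenotype values, same accessions.
#' @return Percent in \[0, 100\].
#' @export
marker_pve <- function(dosage, blues) {
  ok <- is.finite(dosage) & is.finite(blues)
  x <- dosage[ok]; y <- blues[ok]
  if (stats::var(x) == 0) stop_param("marker is monomorphic")
  b <- stats::cov(x, y) / stats::var(x)
  min(100, 100 * b^2 * stats::var(x) / stats::var(y))
}

#' Consensus QTL calling across models and panels
#'
#' A marker is deemed significant when its score reaches the panel's
#' threshold in at least two models within a panel, or in at least one model
#' of each of two panels. Passing markers within `merge_radius_bp` on the
#' same chromosome are merged into one QTL call; the reported score and PVE
#' are means over the supporting (significant) model entries, and the
#' reported position is the member marker with the highest mean score.
#' Output is invariant to the order of the input tables.
#'
#' @param tables List of `gwas_table`s (each carrying `model` and `panel`
#'   columns); scans of the same trait.
#' @param thresholds Named numeric vector of -log10 thresholds per panel.
#' @param merge_radius_bp Merge radius (default 1e5, i.e. 100 kb).
#' @param trait Optional trait label carried through.
#' @return Data.frame of QTL calls: chrom, position_bp, trait, n_markers,
#'   models, panels, mean_score, mean_pve, members.
#' @export
consensus_qtl <- function(tables, thresholds, merge_radius_bp = 1e5,
                          trait = NA_character_) {
  all_t <- do.call(rbind, lapply(tables, as.data.frame))
  if (is.null(all_t) || nrow(all_t) == 0) return(empty_qtl_frame())
  miss <- setdiff(unique(all_t$panel), names(thresholds))
  if (length(miss)) stop_param("no threshold for panel(s): ",
                               paste(miss, collapse = ", "))
  all_t$sig <- is.finite(all_t$score) &
    all_t$score >= thresholds[all_t$panel]
  sig <- all_t[all_t$sig, , drop = FALSE]
  if (nrow(sig) == 0) return(empty_qtl_frame())

  key <- paste(sig$chrom, sig$pos, sep = ":")
  pass <- vapply(split(sig, key), function(s) {
    by_panel <- tapply(s$model, s$panel, function(m) length(unique(m)))
    any(by_panel >= 2) || length(by_panel) >= 2
  }, TRUE)
  passing <- sig[key %in% names(pass)[pass], , drop = FALSE]
  if (nrow(passing) == 0) return(empty_qtl_frame())

  mk <- unique(passing[order(passing$chrom, passing$pos),
                       c("chrom", "pos", "marker")])
  mk$cluster <- NA_integer_
  cl <- 0L
  for (ch in unique(mk$chrom)) {
    i <- which(mk$chrom == ch)
    brk <- c(TRUE, diff(mk$pos[i]) > merge_radius_bp)
    mk$cluster[i] <- cl + cumsum(brk)
    cl <- max(mk$cluster[i])
  }
  calls <- lapply(split(mk, mk$cluster), function(grp) {
    rows <- passing[passing$chrom == grp$chrom[1] &
                      passing$pos %in% grp$pos, , drop = FALSE]
    per_marker <- tapply(rows$score, rows$pos, mean)
    top_pos <- as.integer(names(per_marker)[which.max(per_marker)])
    data.frame(
      chrom = grp$chrom[1], position_bp = top_pos, trait = trait,
      n_markers = nrow(grp),
      models = paste(sort(unique(rows$model)), collapse = ","),
      panels = paste(sort(unique(rows$panel)), collapse = ","),
      mean_score = mean(rows$score),
      mean_pve = mean(rows$pve, na.rm = TRUE),
      members = paste(sort(unique(rows$marker)), collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  out <- out[order(out$chrom, out$position_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_qtl_frame <- function() {
  data.frame(chrom = character(0), position_bp = integer(0),
             trait = character(0), n_markers = integer(0),
             models = character(0), panels = character(0),
             mean_score = numeric(0), mean_pve = numeric(0),
             members = character(0), stringsAsFactors = FALSE)
}

#' Linkage-disequilibrium decay with distance
#'
#' Computes pairwise dosage r-squared for marker pairs within
#' `max_dist_bp` on the same chromosome, bins them by distance, and reports
#' the mean r-squared per bin together with the LD block size: the first
#' bin midpoint at which the monotone (isotonic decreasing) smoothed curve
#' drops below `r2_target`.
#'
#' @param genotypes A [genotype_matrix()].
#' @param max_dist_bp Maximum pair distance (default 1 Mb).
#' @param bin_width_bp Bin width (default 10 kb).
#' @param r2_target Threshold defining the block size (default 0.1).
#' @return List with `curve` (data.frame: mid_bp, mean_r2, smoothed_r2,
#'   n_pairs), `crossing_bp` (genome-wide), and `per_chrom` crossing
#'   distances.
#' @export
ld_decay <- function(genotypes, max_dist_bp = 1e6, bin_width_bp = 1e4,
                     r2_target = 0.1) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  g <- impute_dosage(genotypes)
  dist_all <- r2_all <- chrom_all <- NULL
  for (ch in unique(genotypes$chrom)) {
    idx <- which(genotypes$chrom == ch)
    if (length(idx) < 2) next
    idx <- idx[order(genotypes$pos[idx])]
    pos <- genotypes$pos[idx]
    gc <- g[, idx, drop = FALSE]
    sdv <- apply(gc, 2, stats::sd)
    for (a in seq_len(length(idx) - 1)) {
      b <- which(pos > pos[a] & pos - pos[a] <= max_dist_bp)
      b <- b[b > a]
      if (!length(b) || sdv[a] == 0) next
      ok <- sdv[b] > 0
      if (!any(ok)) next
      r <- suppressWarnings(as.numeric(stats::cor(gc[, a], gc[, b[ok], drop = FALSE])))
      dist_all <- c(dist_all, pos[b[ok]] - pos[a])
      r2_all <- c(r2_all, r^2)
      chrom_all <- c(chrom_all, rep(ch, sum(ok)))
    }
  }
  if (is.null(r2_all)) stop_param("no marker pairs within max_dist_bp")
  bin <- pmin(floor(dist_all / bin_width_bp),
              floor((max_dist_bp - 1) / bin_width_bp))
  crossing <- function(d, r2) {
    b <- pmin(floor(d / bin_width_bp), floor((max_dist_bp - 1) / bin_width_bp))
    mr <- tapply(r2, b, mean)
    mids <- (as.numeric(names(mr)) + 0.5) * bin_width_bp
    sm <- -stats::isoreg(mids, -mr)$yf        # monotone non-increasing fit
    below <- which(sm < r2_target)
    list(mid = mids, mean = as.numeric(mr), smooth = sm,
         n = as.numeric(table(b)),
         cross = if (length(below)) mids[below[1]] else NA_real_)
  }
  gw <- crossing(dist_all, r2_all)
  per_chrom <- vapply(unique(chrom_all), function(ch) {
    i <- chrom_all == ch
    crossing(dist_all[i], r2_all[i])$cross
  }, numeric(1))
  list(curve = data.frame(mid_bp = gw$mid, mean_r2 = gw$mean,
                          smoothed_r2 = gw$smooth, n_pairs = gw$n),
       crossing_bp = gw$cross, per_chrom = per_chrom)
}
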