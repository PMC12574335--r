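#' Ridge-regression BLUP of marker effects and GEBVs
#'
#' Solves the RR-BLUP model `y = mu + W u + e` with `u ~ N(0, sigma_u^2 I)`.
#' The ridge parameter `lambda = sigma_e^2 / sigma_u^2` is estimated by REML
#' through the eigendecomposition of `W W'` (the equivalent kinship
#' formulation), after which the marker effects are
#' `u_hat = W' (W W' + lambda I)^{-1} (y - mu_hat)` and the genomic
#' estimated breeding values are `W u_hat` — identical, by algebra, to the
#' GBLUP predictions from the kinship form.
#'
#' @param blues Named numeric phenotype vector (accession ids).
#' @param genotypes A [genotype_matrix()] (missing dosages mean-imputed).
#' @param lambda Optional fixed ridge parameter; estimated by REML when
#'   `NULL`.
#' @return A `prediction_result`: `marker_effects`, `gebv` (named, centered
#'   at the fitted intercept being removed), `mu`, `lambda_ridge`,
#'   `sigma_u2`, `sigma_e2`, `center` (marker means used to center W).
#' @export
rrblup_fit <- function(blues, genotypes, lambda = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  blues <- blues[is.finite(blues)]
  acc <- intersect(names(blues), rownames(genotypes$dosage))
  if (length(acc) < 3) stop_param("too few accessions shared with genotypes")
  g <- impute_dosage(subset_genotypes(genotypes, accessions = acc))
  y <- as.numeric(blues[acc])
  ctr <- colMeans(g)
  W <- sweep(g, 2, ctr)
  if (sum(apply(W, 2, stats::var)) == 0)
    stop_param("zero marker variance: nothing to fit")
  K <- tcrossprod(W)
  n <- length(y)
  X0 <- cbind(rep(1, n))
  if (is.null(lambda)) {
    nf <- mlm_null_reml(y, X0, K)
    lambda <- nf$delta
    sigma_u2 <- nf$sigma_g2
    sigma_e2 <- nf$sigma_e2
    mu <- nf$beta0[1]
  } else {
    Vi <- solve(K + lambda * diag(n))
    mu <- as.numeric(sum(Vi %*% y) / sum(Vi))
    sigma_u2 <- NA_real_; sigma_e2 <- NA_real_
  }
  alpha <- solve(K + lambda * diag(n), y - mu)
  u <- as.numeric(crossprod(W, alpha))
  names(u) <- colnames(g)
  gebv <- as.numeric(W %*% u)
  names(gebv) <- acc
  structure(list(marker_effects = u, gebv = gebv, mu = mu,
                 lambda_ridge = lambda, sigma_u2 = sigma_u2,
                 sigma_e2 = sigma_e2, center = ctr, accessions = acc),
            class = "prediction_result")
}

#' Predict GEBVs for new accessions from a fitted RR-BLUP model
#'
#' @param fit A `prediction_result` from [rrblup_fit()].
#' @param genotypes A [genotype_matrix()] holding the accessions to predict.
#' @param accessions Which accessions to predict (default all in
#'   `genotypes`).
#' @return Named vector of predicted breeding values (relative to the
#'   training mean; add `fit$mu` for phenotype-scale predictions).
#' @export
predict_gebv <- function(fit, genotypes, accessions = NULL) {
  stopifnot(inherits(fit, "prediction_result"))
  g <- impute_dosage(genotypes)
  if (!is.null(accessions)) g <- g[accessions, , drop = FALSE]
  W <- sweep(g[, names(fit$marker_effects), drop = FALSE], 2, fit$center)
  out <- as.numeric(W %*% fit$marker_effects)
  names(out) <- rownames(g)
  out
}

#' Cross-validated genomic prediction accuracy
#'
#' Repeatedly splits the accessions into a training fraction and a held-out
#' test set, fits RR-BLUP on the training set, predicts test GEBVs, and
#' computes the Pearson correlation between predictions and observed values
#' in the test set. The reported accuracy is the mean correlation over
#' replicates, and the coefficient of determination its square.
#'
#' @param blues Named phenotype vector.
#' @param genotypes A [genotype_matrix()].
#' @param split Training fraction (default 0.8).
#' @param n_reps Number of random splits (default 50).
#' @param seed Integer seed; identical seeds give identical partitions.
#' @return List with `cv_accuracy_r` (mean r), `cv_r2` (= mean r squared),
#'   `r_per_rep`, `se_r`, `n_reps`, `split`, `seed`.
#' @export
cv_accuracy <- function(blues, genotypes, split = 0.8, n_reps = 50, seed = 1) {
  if (split <= 0 || split >= 1) stop_param("split must lie in (0, 1)")
  if (!is_count(n_reps)) stop_param("n_reps must be a positive count")
  blues <- blues[is.finite(blues)]
  acc <- intersect(names(blues), rownames(genotypes$dosage))
  geno <- subset_genotypes(genotypes, accessions = acc)
  n <- length(acc)
  rs <- with_seed(derive_seed(seed, "cv"), {
    vapply(seq_len(n_reps), function(rep_i) {
      tr <- sample(acc, floor(split * n))
      te <- setdiff(acc, tr)
      fit <- rrblup_fit(blues[tr], subset_genotypes(geno, accessions = tr))
      pred <- predict_gebv(fit, geno, accessions = te)
      stats::cor(pred, as.numeric(blues[te]))
    }, numeric(1))
  })
  mean_r <- mean(rs)
  list(cv_accuracy_r = mean_r, cv_r2 = mean_r^2, r_per_rep = rs,
       se_r = stats::sd(rs) / sqrt(n_reps), n_reps = n_reps, split = split,
       seed = seed)
}

#' Read a GFF3 gene annotation
#'
#' Parses gene features from a GFF3 file (via \pkg{ape}) into the flat
#' annotation table used by [candidate_genes()].
#'
#' @param path GFF3 file path.
#' @param feature Feature type to keep (default `"gene"`).
#' @return Data.frame with gene_id, chrom, start, end, strand, label.
#' @export
read_gene_annotation <- function(path, feature = "gene") {
  gff <- ape::read.gff(path)
  gff <- gff[gff$type == feature, , drop = FALSE]
  get_attr <- function(attr, key) {
    m <- regmatches(attr, regexec(paste0(key, "=([^;]+)"), attr))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  ids <- get_attr(gff$attributes, "ID")
  ids[is.na(ids)] <- get_attr(gff$attributes[is.na(ids)], "Name")
  data.frame(gene_id = ids, chrom = as.character(gff$seqid),
             start = gff$start, end = gff$end,
             strand = as.character(gff$strand),
             label = get_attr(gff$attributes, "Note"),
             stringsAsFactors = FALSE)
}

#' Candidate genes within a window of QTL positions
#'
#' Returns the genes whose bodies (closed intervals `[start, end]`)
#' intersect the closed window `[position - window_bp, position + window_bp]`
#' on the QTL's chromosome. Target designation is supplied externally (e.g.
#' an expert-curated id list) and recorded as a 0/1 flag.
#'
#' @param qtl Data.frame of QTL calls with columns `chrom` and
#'   `position_bp` (see [consensus_qtl()]).
#' @param annotation Gene table: gene_id, chrom, start, end (1-based,
#'   inclusive), plus optional columns carried through.
#' @param window_bp Half-window size (default 500 kb).
#' @param target_genes Character vector of gene ids to flag as targets.
#' @return Data.frame: qtl_chrom, qtl_position_bp, gene columns,
#'   distance_bp (0 when the gene overlaps the QTL position), target.
#' @export
candidate_genes <- function(qtl, annotation, window_bp = 5e5,
                            target_genes = character(0)) {
  stopifnot(all(c("chrom", "position_bp") %in% names(qtl)),
            all(c("gene_id", "chrom", "start", "end") %in% names(annotation)))
  out <- lapply(seq_len(nrow(qtl)), function(i) {
    ch <- qtl$chrom[i]; pos <- qtl$position_bp[i]
    hit <- annotation$chrom == ch &
      annotation$start <= pos + window_bp &
      annotation$end >= pos - window_bp
    if (!any(hit)) return(NULL)
    genes <- annotation[hit, , drop = FALSE]
    dist <- pmax(0, pmax(genes$start - pos, pos - genes$end))
    cbind(data.frame(qtl_chrom = ch, qtl_position_bp = pos,
                     stringsAsFactors = FALSE),
          genes, distance_bp = dist)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(qtl_chrom = character(0), qtl_position_bp = integer(0),
                      gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      distance_bp = numeric(0))
  out$target <- as.integer(out$gene_id %in% target_genes)
  rownames(out) <- NULL
  out
}

#' Fisher-exact GO term enrichment of a target gene set
#'
#' For each GO term, builds the 2x2 table of target/background vs
#' annotated/not over the gene universe and computes the one-sided
#' (enrichment) Fisher exact p-value. Terms annotating no gene in the
#' universe get p = 1. Results are ranked by ascending p.
#'
#' @param target_flags Named 0/1 (or logical) vector over the gene
#'   universe; 1 marks target genes.
#' @param gene2go Data.frame with columns `gene_id`, `go_id` and optionally
#'   `term`.
#' @param top_n Optionally keep only the best `top_n` terms.
#' @return Data.frame: go_id, term, target_with, target_without,
#'   background_with, background_without, p; ascending in p.
#' @export
go_enrichment <- function(target_flags, gene2go, top_n = NULL) {
  flags <- as.integer(target_flags > 0)
  names(flags) <- names(target_flags)
  if (sum(flags) < 1 || sum(flags == 0) < 1)
    stop_param("need at least one target and one background gene")
  universe <- names(flags)
  g2g <- gene2go[gene2go$gene_id %in% universe, , drop = FALSE]
  terms <- unique(gene2go$go_id)
  n_t <- sum(flags)
  n_b <- sum(flags == 0)
  res <- lapply(terms, function(tm) {
    with_term <- unique(g2g$gene_id[g2g$go_id == tm])
    a <- sum(flags[with_term])          # target, annotated
    c_ <- length(with_term) - a         # background, annotated
    tab <- matrix(c(a, n_t - a, c_, n_b - c_), 2, byrow = TRUE)
    p <- if (length(with_term) == 0) 1 else
      stats::fisher.test(tab, alternative = "greater")$p.value
    term_lab <- if ("term" %in% names(gene2go))
      gene2go$term[match(tm, gene2go$go_id)] else NA_character_
    data.frame(go_id = tm, term = term_lab, target_with = a,
               target_without = n_t - a, background_with = c_,
               background_without = n_b - c_, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  out
}
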