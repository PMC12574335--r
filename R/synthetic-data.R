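#' Simulate a structured diversity panel under the Balding-Nichols model
#'
#' Draws ancestral allele frequencies, differentiates them into `k_pops`
#' subpopulation frequency vectors with a Balding-Nichols beta model at a
#' target fixation index, draws per-accession ancestry proportions from a
#' Dirichlet distribution, and samples biallelic dosages binomially from the
#' admixed individual frequencies.
#'
#' The beta draw for population `k` at marker `j` has mean equal to the
#' ancestral frequency and variance `fst * p * (1 - p)`, so the parameter
#' `fst` is the expected fixation index among the (unadmixed) ancestral
#' populations.
#'
#' @param n_accessions Number of accessions (rows).
#' @param n_markers Number of biallelic markers (columns).
#' @param k_pops Number of ancestral populations (>= 1).
#' @param fst Balding-Nichols differentiation parameter, strictly in (0, 1).
#' @param admixture_alpha Dirichlet concentration for ancestry proportions;
#'   small values give near-pure individuals, large values heavy admixture.
#' @param n_chromosomes Number of chromosomes over which markers are spread.
#' @param chrom_length_bp Chromosome length in bp (positions drawn uniformly).
#' @param anc_freq_range Range of ancestral allele frequencies.
#' @param missing_rate Fraction of dosage entries set missing (default 0).
#' @param seed Integer seed; the same seed reproduces the same panel.
#'
#' @return A list with elements `genotypes` (a [genotype_matrix()], with
#'   `groups` set to the maximum-ancestry population of each accession) and
#'   `truth` (list: `q_true`, `f_true`, `p_ancestral`, `fst`, plus the call
#'   parameters) for recovery tests.
#' @export
generate_population <- function(n_accessions, n_markers, k_pops = 3,
                                fst = 0.2, admixture_alpha = 0.2,
                                n_chromosomes = 9, chrom_length_bp = 5e7,
                                anc_freq_range = c(0.1, 0.9),
                                missing_rate = 0, seed = 1) {
  if (!is_count(n_accessions) || !is_count(n_markers) || !is_count(n_chromosomes))
    stop_param("n_accessions, n_markers and n_chromosomes must be positive counts")
  if (!is_count(k_pops)) stop_param("k_pops must be a positive count")
  if (!is.numeric(fst) || length(fst) != 1 || fst <= 0 || fst >= 1)
    stop_param("fst must lie strictly in (0, 1)")
  if (admixture_alpha <= 0) stop_param("admixture_alpha must be positive")
  if (n_markers < k_pops) stop_param("need n_markers >= k_pops")
  if (missing_rate < 0 || missing_rate >= 1) stop_param("missing_rate must be in [0, 1)")

  with_seed(seed, {
    p_anc <- stats::runif(n_markers, anc_freq_range[1], anc_freq_range[2])
    shape_scale <- (1 - fst) / fst
    f <- matrix(stats::rbeta(k_pops * n_markers,
                             rep(p_anc, each = k_pops) * shape_scale,
                             rep(1 - p_anc, each = k_pops) * shape_scale),
                nrow = k_pops)
    # guard against numerically fixed frequencies
    f <- pmin(pmax(f, 1e-6), 1 - 1e-6)

    gam <- matrix(stats::rgamma(n_accessions * k_pops, shape = admixture_alpha),
                  nrow = n_accessions)
    zero <- rowSums(gam) < .Machine$double.xmin
    if (any(zero))
      gam[cbind(which(zero), sample.int(k_pops, sum(zero), replace = TRUE))] <- 1
    q <- gam / rowSums(gam)

    p_ind <- q %*% f                      # accession x marker allele freq
    dosage <- matrix(stats::rbinom(n_accessions * n_markers, 2, p_ind),
                     nrow = n_accessions)
    if (missing_rate > 0) {
      drop <- stats::runif(length(dosage)) < missing_rate
      dosage[drop] <- NA
    }

    per_chr <- diff(round(seq(0, n_markers, length.out = n_chromosomes + 1)))
    chrom <- rep(paste0("chr", seq_len(n_chromosomes)), per_chr)
    pos <- unlist(lapply(per_chr, function(nc)
      sort(sample.int(chrom_length_bp, nc))), use.names = FALSE)

    acc <- sprintf("acc%03d", seq_len(n_accessions))
    rownames(dosage) <- acc
    rownames(q) <- acc
    colnames(q) <- paste0("pop", seq_len(k_pops))
    assigned <- factor(colnames(q)[max.col(q, ties.method = "first")],
                       levels = colnames(q))

    geno <- genotype_matrix(dosage, chrom = chrom, pos = pos, groups = assigned)
    list(genotypes = geno,
         truth = list(q_true = q, f_true = f, p_ancestral = p_anc, fst = fst,
                      k_pops = k_pops, admixture_alpha = admixture_alpha,
                      seed = seed))
  })
}

#' Simulate multi-environment phenotype records with known ground truth
#'
#' Generates long-format observations from the additive model
#' `y = mu + g_i + e_j + ge_ij + b_k(j) + p_l(jk) + eps`, where `g_i` is the
#' genetic value (sum of causal-marker dosages times their additive effects,
#' plus an optional polygenic normal deviation), and the remaining terms are
#' independent normal draws at the requested variances. One plot per
#' accession per block (randomized complete block design) with `n_roots`
#' roots sampled per plot.
#'
#' @param genotypes A [genotype_matrix()]; its accessions form the panel.
#' @param qtl_spec `NULL`, or a data.frame with columns `marker` (marker id
#'   or column index), `trait`, `effect` giving additive allele-substitution
#'   effects per trait.
#' @param variance_spec Named numeric vector with entries `env`, `gxe`,
#'   `block`, `plot`, `residual` (all >= 0), or a named list of such vectors
#'   keyed by trait.
#' @param design List with counts `n_env`, `n_blocks`, `n_roots`.
#' @param mu Named vector of trait intercepts (recycled if length 1).
#' @param traits Trait names to simulate; defaults to those in `qtl_spec`
#'   or `"trait1"`.
#' @param polygenic_var Variance of an additional polygenic normal genetic
#'   term per trait (named vector or scalar; default 0).
#' @param seed Integer seed.
#'
#' @return List with `records` (long data.frame: accession, env, block,
#'   plot, root, trait, value) and `truth` (genetic values per accession and
#'   trait, the variance components, and the causal-marker table).
#' @export
simulate_phenotypes <- function(genotypes, qtl_spec = NULL,
                                variance_spec = c(env = 0.25, gxe = 0.25,
                                                  block = 0.25, plot = 0,
                                                  residual = 0.25),
                                design = list(n_env = 4, n_blocks = 3, n_roots = 1),
                                mu = 10, traits = NULL, polygenic_var = 0,
                                seed = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n_env <- design$n_env %||% 4
  n_blocks <- design$n_blocks %||% 3
  n_roots <- design$n_roots %||% 1
  if (!is_count(n_env) || !is_count(n_blocks) || !is_count(n_roots))
    stop_param("design counts must be positive integers")
  traits <- traits %||% (if (!is.null(qtl_spec)) unique(qtl_spec$trait) else "trait1")
  vspec <- function(tr) {
    v <- if (is.list(variance_spec)) variance_spec[[tr]] else variance_spec
    need <- c("env", "gxe", "block", "plot", "residual")
    miss <- setdiff(need, names(v))
    if (length(miss))
      stop_param("variance_spec must name: ", paste(miss, collapse = ", "))
    v <- v[need]
    if (any(v < 0)) stop_param("variances must be non-negative")
    v
  }
  mu <- if (length(mu) == 1) stats::setNames(rep(mu, length(traits)), traits) else mu
  pg <- if (length(polygenic_var) == 1)
    stats::setNames(rep(polygenic_var, length(traits)), traits) else polygenic_var

  acc <- rownames(genotypes$dosage)
  n_acc <- length(acc)
  g_imp <- NULL

  with_seed(seed, {
    gvals <- matrix(0, n_acc, length(traits), dimnames = list(acc, traits))
    if (!is.null(qtl_spec)) {
      g_imp <- impute_dosage(genotypes)
      for (r in seq_len(nrow(qtl_spec))) {
        mk <- qtl_spec$marker[r]
        j <- if (is.character(mk)) match(mk, colnames(g_imp)) else as.integer(mk)
        if (is.na(j) || j < 1 || j > ncol(g_imp))
          stop_param("qtl_spec marker not found: ", mk)
        gvals[, qtl_spec$trait[r]] <- gvals[, qtl_spec$trait[r]] +
          g_imp[, j] * qtl_spec$effect[r]
      }
    }
    for (tr in traits) if (pg[tr] > 0)
      gvals[, tr] <- gvals[, tr] + stats::rnorm(n_acc, 0, sqrt(pg[tr]))

    env_id <- paste0("env", seq_len(n_env))
    grid <- expand.grid(root = seq_len(n_roots), accession = acc,
                        block = paste0("block", seq_len(n_blocks)),
                        env = env_id, stringsAsFactors = FALSE)
    grid$plot <- paste(grid$env, grid$block, grid$accession, sep = ":")

    out <- vector("list", length(traits))
    for (ti in seq_along(traits)) {
      tr <- traits[ti]
      v <- vspec(tr)
      e_j <- stats::setNames(stats::rnorm(n_env, 0, sqrt(v["env"])), env_id)
      ge <- matrix(stats::rnorm(n_acc * n_env, 0, sqrt(v["gxe"])), n_acc,
                   dimnames = list(acc, env_id))
      blk <- stats::setNames(
        stats::rnorm(n_env * n_blocks, 0, sqrt(v["block"])),
        as.vector(outer(paste0("block", seq_len(n_blocks)), env_id,
                        function(b, e) paste(e, b, sep = ":"))))
      plots <- unique(grid$plot)
      p_l <- stats::setNames(stats::rnorm(length(plots), 0, sqrt(v["plot"])), plots)
      eps <- stats::rnorm(nrow(grid), 0, sqrt(v["residual"]))
      val <- mu[tr] + gvals[grid$accession, tr] + e_j[grid$env] +
        ge[cbind(grid$accession, grid$env)] +
        blk[paste(grid$env, grid$block, sep = ":")] + p_l[grid$plot] + eps
      out[[ti]] <- data.frame(grid[c("accession", "env", "block", "plot", "root")],
                              trait = tr, value = as.numeric(val),
                              stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, out)
    rownames(records) <- NULL
    list(records = records,
         truth = list(genetic_values = gvals, qtl_spec = qtl_spec,
                      variance_spec = variance_spec, mu = mu,
                      polygenic_var = pg, design = design, seed = seed))
  })
}

#' Shape parameters for a synthetic root silhouette
#'
#' Four interpretable parameters span the observed range of storage-root
#' silhouettes from globose (round/flat) through cylindrical and conical to
#' thin unswollen taproots.
#'
#' @param length_mm Root length, crown to tip (mm, > 0).
#' @param max_width_mm Maximum width (mm, > 0). For `family = "taproot"` the
#'   ratio `max_width_mm / length_mm` must be < 0.15.
#' @param bulge_position Fraction of length from the crown at which width
#'   peaks (globose family only), in \[0, 1\].
#' @param taper_exponent Positive exponent controlling tip sharpness.
#'   Defaults per family: globose 0.5 (an exact circle at bulge 0.5),
#'   cylindrical unused, conical 1 (linear taper), taproot 2.5.
#' @param family One of `"globose"`, `"cylindrical"`, `"conical"`,
#'   `"taproot"`.
#' @param cap_fraction For the cylindrical family, fraction of the length
#'   occupied by an elliptical tip cap; 0 (default) gives a flat bottom.
#' @return An object of class `shape_params`.
#' @export
shape_params <- function(length_mm, max_width_mm, bulge_position = 0.5,
                         taper_exponent = NULL,
                         family = c("globose", "cylindrical", "conical", "taproot"),
                         cap_fraction = 0) {
  family <- match.arg(family)
  if (!is.numeric(length_mm) || length_mm <= 0) stop_param("length_mm must be > 0")
  if (!is.numeric(max_width_mm) || max_width_mm <= 0) stop_param("max_width_mm must be > 0")
  if (bulge_position < 0 || bulge_position > 1)
    stop_param("bulge_position must lie in [0, 1]")
  taper_exponent <- taper_exponent %||%
    switch(family, globose = 0.5, cylindrical = 1, conical = 1, taproot = 2.5)
  if (taper_exponent <= 0) stop_param("taper_exponent must be positive")
  if (family == "taproot" && max_width_mm / length_mm >= 0.15)
    stop_param("taproot family requires max_width_mm / length_mm < 0.15")
  if (cap_fraction < 0 || cap_fraction > 1)
    stop_param("cap_fraction must lie in [0, 1]")
  structure(list(length_mm = length_mm, max_width_mm = max_width_mm,
                 bulge_position = bulge_position,
                 taper_exponent = taper_exponent, family = family,
                 cap_fraction = cap_fraction),
            class = "shape_params")
}

#' Half-width profile of a shape family
#'
#' Returns the half-width (mm) of the silhouette at fractional depths
#' `t` in \[0, 1\] from the crown. The profile underlying each family:
#' globose, a power-of-parabola bulge `(4 m (1-m))^e` with the depth warp
#' `m(t)` placing the peak at `bulge_position`; cylindrical, constant width
#' with an optional elliptical tip cap; conical and taproot, power-law taper
#' `(1-t)^e`.
#'
#' @param params A [shape_params()].
#' @param t Numeric vector of fractional depths in \[0, 1\].
#' @return Half-widths in mm, same length as `t`.
#' @export
shape_profile <- function(params, t) {
  stopifnot(inherits(params, "shape_params"))
  if (any(t < 0 | t > 1)) stop_param("t must lie in [0, 1]")
  b <- params$bulge_position
  e <- params$taper_exponent
  s <- switch(params$family,
    globose = {
      m <- ifelse(t <= b,
                  if (b > 0) t / (2 * b) else 0.5,
                  if (b < 1) 0.5 + (t - b) / (2 * (1 - b)) else 0.5)
      (4 * m * (1 - m))^e
    },
    cylindrical = {
      cf <- params$cap_fraction
      if (cf > 0) {
        u <- (t - (1 - cf)) / cf
        ifelse(t <= 1 - cf, 1, sqrt(pmax(0, 1 - u^2)))
      } else rep(1, length(t))
    },
    conical = (1 - t)^e,
    taproot = (1 - t)^e
  )
  (params$max_width_mm / 2) * s
}

#' Analytic silhouette area of a shape profile
#'
#' Integrates `2 * w(t)` over the length; the reference value against which
#' rendered mask areas are checked.
#'
#' @param params A [shape_params()].
#' @return Area in mm^2.
#' @export
shape_area <- function(params) {
  2 * params$length_mm *
    stats::integrate(function(t) shape_profile(params, t), 0, 1,
                     rel.tol = 1e-10)$value
}

#' Render a binary root mask from shape parameters
#'
#' Rasterizes the silhouette onto a binary grid, crown at the top row,
#' vertically oriented and horizontally centered. A pixel is foreground when
#' its center lies strictly inside the analytic half-width at the row's
#' fractional depth (midpoint sampling), so the mask area converges to the
#' analytic profile integral as `pixel_scale` shrinks.
#'
#' @param params A [shape_params()].
#' @param pixel_scale mm per pixel (> 0).
#' @param margin_px Background margin around the silhouette, in pixels.
#' @param dim Optional `c(n_rows, n_cols)` image size; an error is raised if
#'   the silhouette does not fit.
#' @return An object of class `root_mask`: list with `mask` (0/1 integer
#'   matrix, row 1 = crown side) and `pixel_scale`.
#' @export
render_root_mask <- function(params, pixel_scale = 0.5, margin_px = 2,
                             dim = NULL) {
  stopifnot(inherits(params, "shape_params"))
  if (pixel_scale <= 0) stop_param("pixel_scale must be positive")
  n_rows_root <- max(1L, round(params$length_mm / pixel_scale))
  half_cols <- ceiling(params$max_width_mm / 2 / pixel_scale) + 1L
  nr <- n_rows_root + 2L * margin_px
  nc <- 2L * half_cols + 2L * margin_px
  if (!is.null(dim)) {
    if (dim[1] < nr || dim[2] < nc)
      stop_param("silhouette (", nr, "x", nc, " px) clipped by image bounds (",
                 dim[1], "x", dim[2], ")")
    nr <- dim[1]; nc <- dim[2]
  }
  t_mid <- (seq_len(n_rows_root) - 0.5) / n_rows_root
  hw_px <- shape_profile(params, t_mid) / pixel_scale
  if (max(hw_px) < 0.5)
    stop_param("degenerate shape: silhouette narrower than one pixel everywhere")
  cx <- margin_px + half_cols + 0.5     # between two columns: symmetric fill
  mask <- matrix(0L, nr, nc)
  col_dist <- abs(seq_len(nc) - cx)
  for (i in seq_len(n_rows_root)) {
    fg <- col_dist < hw_px[i]
    # rows whose analytic width is positive but sub-pixel keep a 2-px center
    # line so the rendered length matches the profile length
    if (!any(fg) && hw_px[i] > 0) fg <- col_dist < 1
    if (any(fg)) mask[margin_px + i, fg] <- 1L
  }
  if (sum(mask) == 0)
    stop_param("degenerate shape: rendered mask is empty at this pixel_scale")
  structure(list(mask = mask, pixel_scale = pixel_scale), class = "root_mask")
}

#' @export
print.root_mask <- function(x, ...) {
  cat("root_mask:", nrow(x$mask), "x", ncol(x$mask), "px at",
      x$pixel_scale, "mm/px;", sum(x$mask), "foreground px\n")
  invisible(x)
}

#' Write / read a binary mask as 8-bit PNG
#'
#' Foreground is written as 255, background as 0.
#'
#' @param mask A `root_mask`.
#' @param path PNG file path.
#' @return `path` (write) or a `root_mask` (read).
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "root_mask"))
  png::writePNG(mask$mask * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @param pixel_scale mm per pixel of the stored image.
#' @export
read_mask_png <- function(path, pixel_scale) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  structure(list(mask = matrix(as.integer(img > 0.5), nrow(img), ncol(img)),
                 pixel_scale = pixel_scale), class = "root_mask")
}

#' Generate a synthetic gene annotation and GO map
#'
#' Creates a synthetic set of non-overlapping genes tiled along the simulated
#' chromosomes together with a random gene-to-GO-term mapping, used to
#' exercise the candidate-gene and enrichment stages when no real annotation
#' is supplied. Clearly synthetic: ids are `geneNNNN` / `GO:SYNxxxx`.
#'
#' @param genotypes A [genotype_matrix()] whose chromosomes define the space.
#' @param n_genes Number of genes.
#' @param n_terms Number of GO terms.
#' @param mean_terms_per_gene Average number of terms assigned per gene.
#' @param gene_length_bp Gene body length.
#' @param seed Integer seed.
#' @return List with `annotation` (data.frame: gene_id, chrom, start, end,
#'   strand, label) and `gene2go` (data.frame: gene_id, go_id, term).
#' @export
simulate_annotation <- function(genotypes, n_genes = 200, n_terms = 20,
                                mean_terms_per_gene = 2, gene_length_bp = 3000,
                                seed = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  chrs <- unique(genotypes$chrom)
  with_seed(seed, {
    chrom <- sample(chrs, n_genes, replace = TRUE)
    max_pos <- stats::setNames(
      vapply(chrs, function(ch) max(genotypes$pos[genotypes$chrom == ch]), 0),
      chrs)
    start <- floor(stats::runif(n_genes, 1, pmax(2, max_pos[chrom] - gene_length_bp)))
    ann <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      chrom = chrom, start = as.integer(start),
      end = as.integer(start + gene_length_bp - 1),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      label = "synthetic gene", stringsAsFactors = FALSE)
    terms <- sprintf("GO:SYN%04d", seq_len(n_terms))
    n_per <- pmax(1, stats::rpois(n_genes, mean_terms_per_gene))
    g2g <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
      tt <- sample(terms, min(n_per[i], n_terms))
      data.frame(gene_id = ann$gene_id[i], go_id = tt,
                 term = paste("synthetic process", sub("GO:SYN", "", tt)),
                 stringsAsFactors = FALSE)
    }))
    list(annotation = ann, gene2go = g2g)
  })
}
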