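#' Extract the cleaned contour of a root mask
#'
#' Keeps the largest connected foreground component, fills interior holes,
#' and locates the crown and tip anchors. The crown anchor is the midpoint
#' of the topmost foreground row span, the tip anchor the midpoint of the
#' bottommost span (row 1 is the crown side).
#'
#' @param mask A `root_mask` (see [render_root_mask()] / [read_mask_png()]).
#' @return An object of class `root_contour`: the filled binary mask, the
#'   per-row left/right column extents, the crown/tip anchors (row, col, in
#'   pixel units with fractional columns allowed), the closed contour
#'   polygon, and the pixel scale.
#' @export
extract_contour <- function(mask) {
  stopifnot(inherits(mask, "root_mask"))
  m <- mask$mask
  if (sum(m) == 0) stop_param("empty mask: no foreground pixels")
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(lab[lab > 0])
  big <- max(sizes)
  winners <- which(sizes == big)
  if (length(winners) > 1)
    stop_param(length(winners), " equal-size largest components; cannot pick one")
  keep <- matrix(as.integer(lab == winners), nrow(m), ncol(m))
  keep <- matrix(as.integer(EBImage::fillHull(keep) > 0), nrow(m), ncol(m))

  fg_rows <- which(rowSums(keep) > 0)
  left <- right <- rep(NA_integer_, nrow(keep))
  for (r in fg_rows) {
    cols <- which(keep[r, ] == 1L)
    left[r] <- cols[1]
    right[r] <- cols[length(cols)]
  }
  crown_row <- fg_rows[1]
  tip_row <- fg_rows[length(fg_rows)]
  crown <- c(row = crown_row, col = (left[crown_row] + right[crown_row]) / 2)
  tip <- c(row = tip_row, col = (left[tip_row] + right[tip_row]) / 2)

  poly <- rbind(
    cbind(row = fg_rows, col = right[fg_rows]),               # down the right
    cbind(row = rev(fg_rows), col = left[rev(fg_rows)])       # up the left
  )
  structure(list(mask = keep, rows = fg_rows, left = left, right = right,
                 crown = crown, tip = tip, polygon = poly,
                 pixel_scale = mask$pixel_scale),
            class = "root_contour")
}

#' Width profile along the root axis
#'
#' Length is the vertical crown-to-tip anchor distance; at each of `stations`
#' fractional depths `t` the width is the horizontal foreground extent
#' (rightmost minus leftmost column plus one pixel) of the row nearest depth
#' `crown + t * length`. The maximum width is taken over all rows, and
#' `width50` is the station width at t = 0.5 (the "width at 50% of length"
#' diameter).
#'
#' @param contour A `root_contour` from [extract_contour()].
#' @param stations Number of equally spaced fractional depths (>= 11).
#' @return An object of class `width_profile`: `stations` (fractions),
#'   `widths_mm`, `length_mm`, `max_width_mm`, `width50_mm`.
#' @export
width_profile <- function(contour, stations = 101) {
  stopifnot(inherits(contour, "root_contour"))
  if (stations < 11) stop_param("need at least 11 stations")
  sc <- contour$pixel_scale
  len_px <- contour$tip["row"] - contour$crown["row"]
  if (len_px <= 0) stop_param("zero-length root: crown and tip coincide")
  t <- seq(0, 1, length.out = stations)
  rows <- contour$crown["row"] + round(t * len_px)
  w_px <- ifelse(is.na(contour$left[rows]), 0,
                 contour$right[rows] - contour$left[rows] + 1L)
  all_w <- contour$right[contour$rows] - contour$left[contour$rows] + 1L
  structure(list(stations = t,
                 widths_mm = as.numeric(w_px) * sc,
                 length_mm = as.numeric(len_px) * sc,
                 max_width_mm = max(all_w) * sc,
                 width50_mm = as.numeric(w_px[which.min(abs(t - 0.5))]) * sc),
            class = "width_profile")
}

#' Interior tip angle of a root contour
#'
#' The angle at the tip anchor subtended by the left and right contour
#' points located 10% of the root length above the tip, in degrees.
#'
#' @param contour A `root_contour`.
#' @param height_fraction Fraction of the length above the tip at which the
#'   flanking contour points are taken (default 0.1).
#' @return Angle in degrees, in (0, 180].
#' @export
tip_angle <- function(contour, height_fraction = 0.1) {
  stopifnot(inherits(contour, "root_contour"))
  len_px <- contour$tip["row"] - contour$crown["row"]
  if (len_px <= 10) stop_param("root shorter than 10 px; tip angle undefined")
  target <- contour$tip["row"] - round(height_fraction * len_px)
  if (target < contour$crown["row"]) stop_param("height_fraction reaches above the crown")
  if (is.na(contour$left[target]))
    stop_param("contour row at the 10%-height is empty")
  tipc <- contour$tip
  # flank points sit on the outer pixel edge (the silhouette boundary), half
  # a pixel beyond the outermost foreground centers
  vL <- c(contour$left[target] - 0.5 - tipc["col"], target - tipc["row"])
  vR <- c(contour$right[target] + 0.5 - tipc["col"], target - tipc["row"])
  cosang <- sum(vL * vR) / sqrt(sum(vL^2) * sum(vR^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Measure the shape traits of a single root mask
#'
#' Computes digital biomass (foreground area in mm^2 after hole filling),
#' length, maximum width, width at 50% length, the natural-log
#' length-to-width ratio `ln(length / max width)`, and the tip angle. The
#' population-referenced contour score is left `NA`; fill it with
#' [contour_pca()] over the whole dataset.
#'
#' @param mask A `root_mask`.
#' @param stations Stations for the width profile.
#' @return A one-row data.frame with columns `digital_biomass_mm2`,
#'   `length_mm`, `max_width_mm`, `width50_mm`, `lw_ratio_log`,
#'   `tip_angle_deg`, `contour_pc`.
#' @export
measure_traits <- function(mask, stations = 101) {
  ct <- extract_contour(mask)
  wp <- width_profile(ct, stations)
  data.frame(
    digital_biomass_mm2 = sum(ct$mask) * ct$pixel_scale^2,
    length_mm = wp$length_mm,
    max_width_mm = wp$max_width_mm,
    width50_mm = wp$width50_mm,
    lw_ratio_log = log(wp$length_mm / wp$max_width_mm),
    tip_angle_deg = tip_angle(ct),
    contour_pc = NA_real_
  )
}

#' Size-normalized contour PCA across a collection of roots
#'
#' Each width profile is normalized to its own maximum width (making the
#' descriptor size-independent), profiles are assembled at the shared
#' fractional stations, and a principal component analysis of the centered
#' matrix yields the contour score: the PC1 projection, with its sign fixed
#' so that positive scores indicate mass shifted toward the crown
#' (fractional depth < 0.5). Supplying `reference_loadings` projects onto a
#' previously fitted shape space instead of refitting.
#'
#' @param profiles List of `width_profile` objects with identical stations.
#' @param reference_loadings Optional list with elements `center` and
#'   `loading` from a previous fit.
#' @return List with `scores` (one per profile), `loadings` (list with
#'   `center`, `loading`, `stations`), and `pct_var` (percent of variance on
#'   PC1; 0 for degenerate input).
#' @export
contour_pca <- function(profiles, reference_loadings = NULL) {
  if (length(profiles) < 3 && is.null(reference_loadings))
    stop_param("need at least 3 profiles to fit a contour shape space")
  S <- length(profiles[[1]]$stations)
  ok <- vapply(profiles, function(p) length(p$stations) == S &&
                 max(abs(p$stations - profiles[[1]]$stations)) < 1e-12, TRUE)
  if (!all(ok)) stop_param("profiles differ in their stations")
  X <- t(vapply(profiles, function(p) {
    mx <- max(p$widths_mm)
    if (mx <= 0) stop_param("profile with zero maximum width")
    p$widths_mm / mx
  }, numeric(S)))
  tfrac <- profiles[[1]]$stations

  if (!is.null(reference_loadings)) {
    ctr <- reference_loadings$center
    ld <- reference_loadings$loading
    scores <- as.numeric(sweep(X, 2, ctr) %*% ld)
    return(list(scores = scores, loadings = reference_loadings, pct_var = NA_real_))
  }

  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  totvar <- sum(Xc^2)
  if (totvar < 1e-24) {
    ld <- rep(0, S)
    return(list(scores = rep(0, nrow(X)),
                loadings = list(center = ctr, loading = ld, stations = tfrac),
                pct_var = 0))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ld <- pc$rotation[, 1]
  scores <- as.numeric(Xc %*% ld)
  crown_mass <- rowSums(X[, tfrac < 0.5, drop = FALSE]) -
    rowSums(X[, tfrac > 0.5, drop = FALSE])
  flip <- if (stats::sd(crown_mass) > 0 && stats::sd(scores) > 0)
    stats::cor(scores, crown_mass) < 0
  else sum(ld[tfrac < 0.5]) - sum(ld[tfrac > 0.5]) < 0
  if (isTRUE(flip)) {
    ld <- -ld
    scores <- -scores
  }
  pct <- 100 * pc$sdev[1]^2 / sum(pc$sdev^2)
  list(scores = scores,
       loadings = list(center = ctr, loading = ld, stations = tfrac),
       pct_var = pct)
}

#' Flag and remove trait outliers by z-score
#'
#' Within each trait, observations whose absolute z-score (computed from the
#' unfiltered single-pass mean and standard deviation) strictly exceeds
#' `sd_threshold` are removed. A zero standard deviation removes nothing.
#'
#' @param trait_table Long data.frame with columns `trait` and `value` (plus
#'   any id columns, which are carried into the removal log).
#' @param sd_threshold Removal threshold in standard-deviation units
#'   (default 3).
#' @return List with `data` (kept rows) and `removed` (dropped rows with
#'   their z-scores).
#' @export
outlier_filter <- function(trait_table, sd_threshold = 3.0) {
  stopifnot(all(c("trait", "value") %in% names(trait_table)))
  z <- rep(0, nrow(trait_table))
  for (tr in unique(trait_table$trait)) {
    i <- which(trait_table$trait == tr)
    if (length(i) < 3) stop_param("need >= 3 observations per trait (", tr, ")")
    v <- trait_table$value[i]
    s <- sqrt(mean((v - mean(v))^2))    # population SD, single pass
    if (is.finite(s) && s > 0) z[i] <- (v - mean(v)) / s
  }
  drop <- abs(z) > sd_threshold
  removed <- trait_table[drop, , drop = FALSE]
  if (nrow(removed)) removed$z <- z[drop]
  else removed$z <- numeric(0)
  list(data = trait_table[!drop, , drop = FALSE], removed = removed)
}

#' Measure traits for a set of masks and attach contour scores
#'
#' Convenience wrapper: runs [measure_traits()] on each mask, fits one
#' contour shape space over all their width profiles, and fills the
#' `contour_pc` column with the PC1 scores.
#'
#' @param masks List of `root_mask` objects (optionally named).
#' @param stations Stations for the width profiles.
#' @param reference_loadings Optional loadings to project onto (see
#'   [contour_pca()]).
#' @return List with `traits` (data.frame, one row per mask) and `loadings`.
#' @export
measure_trait_set <- function(masks, stations = 101, reference_loadings = NULL) {
  contours <- lapply(masks, extract_contour)
  profiles <- lapply(contours, width_profile, stations = stations)
  tab <- do.call(rbind, lapply(masks, measure_traits, stations = stations))
  cp <- contour_pca(profiles, reference_loadings)
  tab$contour_pc <- cp$scores
  if (!is.null(names(masks))) tab$mask_id <- names(masks)
  rownames(tab) <- NULL
  list(traits = tab, loadings = cp$loadings)
}
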