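#' Manhattan plot of an association scan
#'
#' @param gwas_table A `gwas_table` from [mlm_scan()].
#' @param threshold Optional -log10 significance line.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the per-marker x coordinates.
#' @export
plot_manhattan <- function(gwas_table, threshold = NULL, ...) {
  d <- as.data.frame(gwas_table)
  d <- d[order(d$chrom, d$pos), ]
  offs <- c(0, cumsum(tapply(d$pos, d$chrom, max)))
  chroms <- sort(unique(d$chrom))
  x <- d$pos + offs[match(d$chrom, chroms)]
  cols <- (match(d$chrom, chroms) %% 2) + 1
  graphics::plot(x, d$score, pch = 16, cex = 0.5,
                 col = c("grey40", "steelblue")[cols],
                 xlab = "genome position", ylab = expression(-log[10](p)), ...)
  if (!is.null(threshold)) graphics::abline(h = threshold, lty = 2, col = "red")
  invisible(x)
}

#' Quantile-quantile plot of association p-values
#'
#' @param p_values Numeric p-values.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the inflation factor lambda.
#' @export
plot_qq <- function(p_values, ...) {
  p <- sort(p_values[is.finite(p_values) & p_values > 0])
  n <- length(p)
  expd <- -log10((seq_len(n) - 0.5) / n)
  obs <- sort(-log10(p), decreasing = TRUE)
  graphics::plot(sort(expd), sort(obs), pch = 16, cex = 0.5,
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)), ...)
  graphics::abline(0, 1, col = "red")
  invisible(inflation_lambda(p_values))
}

#' Display a root mask
#'
#' @param x A `root_mask`.
#' @param ... Ignored.
#' @export
plot.root_mask <- function(x, ...) {
  graphics::image(t(x$mask[nrow(x$mask):1, ]), col = c("white", "black"),
                  axes = FALSE, asp = nrow(x$mask) / ncol(x$mask))
  invisible(x)
}
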