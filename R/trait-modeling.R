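#' Fit the multi-environment mixed model to one trait
#'
#' Fits `value = mu + g_i + e_j + ge_ij + b_k(j) + p_l(jk) + eps` by REML.
#' Environment, genotype-by-environment, block-in-environment and
#' plot-in-(environment, block) are random; the genotype term is fixed
#' (yielding BLUEs) or random (yielding the genetic variance, BLUPs and
#' their full prediction-error covariance, the inputs to the Cullis
#' heritability) according to `genotype_as`. When every plot holds a single
#' root the plot term is confounded with the residual and is dropped with a
#' message.
#'
#' REML estimation is delegated to \pkg{lme4}; the prediction-error
#' covariance of the genotype BLUPs is then computed in-package from
#' Henderson's mixed-model equations at the converged variance components,
#' since the average pairwise prediction error variance needs the full
#' covariance, not only its diagonal.
#'
#' @param records Long data.frame with columns `accession`, `env`, `block`,
#'   `plot`, `trait`, `value` (see [simulate_phenotypes()]).
#' @param trait Trait name to fit.
#' @param genotype_as `"fixed"` or `"random"`.
#' @return An object of class `trait_model_fit` with elements `mu`, `blues`
#'   (fixed fit) or `blups`/`pev_mat` (random fit), `varcomp` (named vector
#'   `g`, `env`, `gxe`, `block`, `plot`, `residual`; `NA` for terms not in
#'   the fit), `loglik`, `converged`, `n_iter`, `genotype_as`,
#'   `dropped_terms`.
#' @export
fit_trait_model <- function(records, trait, genotype_as = c("fixed", "random")) {
  genotype_as <- match.arg(genotype_as)
  stopifnot(all(c("accession", "env", "block", "value") %in% names(records)))
  if (!"trait" %in% names(records)) records$trait <- trait
  d <- records[records$trait == trait & is.finite(records$value), , drop = FALSE]
  if (nrow(d) == 0) stop_param("trait not found in records: ", trait)
  d$accession <- factor(d$accession)
  d$env <- factor(d$env)
  d$blk <- factor(paste(d$env, d$block, sep = ":"))
  d$gxe <- factor(paste(d$accession, d$env, sep = ":"))
  if (!"plot" %in% names(d)) d$plot <- paste(d$blk, d$accession, sep = ":")
  d$plotf <- factor(paste(d$blk, d$plot, sep = ":"))
  if (nlevels(d$env) < 2) stop_param("need >= 2 environments")

  dropped <- character(0)
  use_plot <- max(table(d$plotf)) > 1 && nlevels(d$plotf) < nrow(d)
  if (!use_plot) {
    dropped <- "plot"
    message("plot term dropped: one observation per plot (confounded with residual)")
  }
  rterms <- c("(1 | env)", "(1 | gxe)", "(1 | blk)", if (use_plot) "(1 | plotf)")
  fixed <- if (genotype_as == "fixed") "0 + accession" else "1"
  if (genotype_as == "random") rterms <- c("(1 | accession)", rterms)
  fml <- stats::as.formula(paste("value ~", fixed, "+", paste(rterms, collapse = " + ")))

  ctl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                           check.nobs.vs.nRE = "ignore",
                           calc.derivs = FALSE)
  fit <- suppressMessages(suppressWarnings(lme4::lmer(fml, data = d, REML = TRUE,
                                                      control = ctl)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(term) {
    i <- match(term, vc$grp)
    if (is.na(i)) NA_real_ else vc$vcov[i]
  }
  varcomp <- c(
    g = if (genotype_as == "random") getv("accession") else NA_real_,
    env = getv("env"), gxe = getv("gxe"), block = getv("blk"),
    plot = if (use_plot) getv("plotf") else NA_real_,
    residual = getv("Residual")
  )
  conv_msgs <- fit@optinfo$conv$lme4$messages
  out <- list(
    trait = trait, genotype_as = genotype_as, varcomp = varcomp,
    loglik = as.numeric(stats::logLik(fit)),
    converged = is.null(conv_msgs) || length(conv_msgs) == 0,
    n_iter = fit@optinfo$feval %||% NA_integer_,
    dropped_terms = dropped, n_obs = nrow(d),
    accessions = levels(d$accession)
  )
  if (genotype_as == "fixed") {
    b <- lme4::fixef(fit)
    names(b) <- sub("^accession", "", names(b))
    out$blues <- b[levels(d$accession)]
    out$mu <- mean(out$blues)
  } else {
    pe <- blup_pev(d, varcomp, use_plot)
    out$mu <- as.numeric(lme4::fixef(fit)[1])
    out$blups <- pe$blup
    out$pev_mat <- pe$pev
  }
  class(out) <- "trait_model_fit"
  out
}

# Genotype BLUPs and their full prediction-error covariance from Henderson's
# mixed-model equations at fixed variance components. Sparse; the inverse is
# only formed for the genotype block.
blup_pev <- function(d, varcomp, use_plot) {
  se2 <- varcomp["residual"]
  terms <- list(accession = varcomp["g"], env = varcomp["env"],
                gxe = varcomp["gxe"], blk = varcomp["block"])
  if (use_plot) terms$plotf <- varcomp["plot"]
  # terms with (numerically) zero variance contribute nothing; keep the
  # genotype term always so the PEV block exists (ridge with huge lambda)
  lam <- vapply(names(terms), function(nm) {
    v <- terms[[nm]]
    if (!is.finite(v) || v < 1e-10 * se2) {
      if (nm == "accession") 1e10 else NA_real_
    } else as.numeric(se2 / v)
  }, numeric(1))
  keep <- names(lam)[is.finite(lam)]
  lam <- lam[keep]

  X <- Matrix::sparseMatrix(i = seq_len(nrow(d)), j = rep(1, nrow(d)), x = 1)
  Zs <- lapply(keep, function(nm)
    Matrix::sparse.model.matrix(stats::as.formula(paste("~ 0 +", nm)), data = d))
  q <- vapply(Zs, ncol, 0L)
  Z <- do.call(cbind, Zs)
  y <- d$value
  C <- rbind(
    cbind(Matrix::crossprod(X), Matrix::crossprod(X, Z)),
    cbind(Matrix::crossprod(Z, X),
          Matrix::crossprod(Z) + Matrix::Diagonal(x = rep(lam, q)))
  )
  rhs <- c(as.numeric(Matrix::crossprod(X, y)), as.numeric(Matrix::crossprod(Z, y)))
  sol <- Matrix::solve(C, rhs)
  gi <- 1 + seq_len(q[1])                       # genotype columns follow the intercept
  acc_names <- sub("^accession", "", colnames(Zs[[1]]))
  blup <- stats::setNames(as.numeric(sol[gi + 0]), acc_names)
  E <- Matrix::sparseMatrix(i = gi, j = seq_along(gi), x = 1,
                            dims = c(nrow(C), length(gi)))
  Cinv_g <- Matrix::solve(C, E)[gi, , drop = FALSE]
  pev <- as.matrix(Cinv_g) * as.numeric(se2)
  dimnames(pev) <- list(acc_names, acc_names)
  list(blup = blup, pev = (pev + t(pev)) / 2)
}

#' @export
print.trait_model_fit <- function(x, ...) {
  cat("trait_model_fit:", x$trait, "| genotype", x$genotype_as, "|",
      x$n_obs, "obs\n")
  vc <- x$varcomp[is.finite(x$varcomp)]
  cat("  varcomp:", paste(sprintf("%s=%.4g", names(vc), vc), collapse = ", "), "\n")
  if (!is.null(x$dropped_terms) && length(x$dropped_terms))
    cat("  dropped:", paste(x$dropped_terms, collapse = ", "), "\n")
  invisible(x)
}

#' Cullis broad-sense heritability
#'
#' `H^2 = 1 - PEV / sigma_g^2`, where PEV is half the average pairwise
#' prediction error variance of genotype BLUP differences,
#' `mean over pairs of Var(BLUP_i - BLUP_j) / 2`. Clamped to \[0, 1\]; a
#' zero genetic variance returns 0 by convention.
#'
#' @param fit A `trait_model_fit` with `genotype_as = "random"`.
#' @return Heritability in \[0, 1\].
#' @export
cullis_h2 <- function(fit) {
  stopifnot(inherits(fit, "trait_model_fit"))
  if (fit$genotype_as != "random" || is.null(fit$pev_mat))
    stop_param("cullis_h2 needs a genotype-random fit with a PEV matrix")
  sg2 <- fit$varcomp["g"]
  if (!is.finite(sg2) || sg2 <= 0) return(0)
  P <- fit$pev_mat
  n <- nrow(P)
  if (n < 2) return(0)
  # mean over i<j of (P_ii + P_jj - 2 P_ij)
  mean_vd <- ((n - 1) * sum(diag(P)) - (sum(P) - sum(diag(P)))) / choose(n, 2)
  pev <- mean_vd / 2
  max(0, min(1, 1 - pev / sg2))
}

#' Proportion of phenotypic variance per source
#'
#' Shares of the estimated variance components (genotype, environment,
#' genotype-by-environment, block, plot, residual) in their total; terms not
#' present in the fit are omitted. Shares sum to one.
#'
#' @param fit A `trait_model_fit` with `genotype_as = "random"`.
#' @return Named numeric vector of proportions.
#' @export
variance_partition <- function(fit) {
  stopifnot(inherits(fit, "trait_model_fit"))
  if (fit$genotype_as != "random")
    stop_param("variance_partition needs a genotype-random fit")
  v <- fit$varcomp[is.finite(fit$varcomp)]
  v / sum(v)
}

#' Per-environment BLUEs
#'
#' Within each environment, fits `value = mu + g_i + b_k + p_l + eps` with
#' genotype fixed and block/plot random, and returns the genotype BLUEs as
#' an accession x environment matrix. Environments with a single block fall
#' back to per-accession means. Missing accession-environment cells stay
#' `NA` (not imputed).
#'
#' @param records Long phenotype records.
#' @param trait Trait to fit.
#' @return Numeric matrix, accessions x environments.
#' @export
per_env_blues <- function(records, trait) {
  if (!"trait" %in% names(records)) records$trait <- trait
  d <- records[records$trait == trait & is.finite(records$value), , drop = FALSE]
  if (nrow(d) == 0) stop_param("trait not found: ", trait)
  envs <- sort(unique(d$env))
  accs <- sort(unique(d$accession))
  out <- matrix(NA_real_, length(accs), length(envs),
                dimnames = list(accs, envs))
  ctl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                           check.nobs.vs.nRE = "ignore", calc.derivs = FALSE)
  for (ej in envs) {
    de <- d[d$env == ej, , drop = FALSE]
    de$accession <- factor(de$accession)
    nb <- length(unique(de$block))
    if (!"plot" %in% names(de)) de$plot <- paste(de$block, de$accession, sep = ":")
    de$plotf <- factor(paste(de$block, de$plot, sep = ":"))
    use_plot <- max(table(de$plotf)) > 1 && nlevels(de$plotf) < nrow(de)
    b <- if (nb < 2) {
      tapply(de$value, de$accession, mean)
    } else {
      rt <- c("(1 | block)", if (use_plot) "(1 | plotf)")
      fml <- stats::as.formula(paste("value ~ 0 + accession +",
                                     paste(rt, collapse = " + ")))
      f <- suppressMessages(suppressWarnings(
        lme4::lmer(fml, data = de, REML = TRUE, control = ctl)))
      stats::setNames(lme4::fixef(f), sub("^accession", "", names(lme4::fixef(f))))
    }
    out[names(b), ej] <- as.numeric(b)
  }
  out
}

#' Finlay-Wilkinson stability regression
#'
#' Regresses each accession's per-environment value on the environment mean
#' (the mean over accessions within the environment). A slope of 1 is
#' average environmental sensitivity, below 1 is stability, above 1 is
#' hyper-responsiveness.
#'
#' @param per_env_table Accession x environment matrix (see
#'   [per_env_blues()]).
#' @param complete_only Restrict both the environment means and the
#'   regressions to accessions observed in every environment (the
#'   complete-replication subset; default `TRUE`).
#' @return List with `stability` (data.frame: accession, fw_slope,
#'   fw_intercept, mse, n_env) and `environment_means`.
#' @export
fw_regression <- function(per_env_table, complete_only = TRUE) {
  tab <- as.matrix(per_env_table)
  if (complete_only) {
    keep <- rowSums(is.na(tab)) == 0
    if (!any(keep)) stop_param("no accession has complete replication")
    tab <- tab[keep, , drop = FALSE]
  }
  env_means <- colMeans(tab, na.rm = TRUE)
  res <- lapply(rownames(tab), function(a) {
    y <- tab[a, ]
    ok <- is.finite(y)
    if (sum(ok) < 2)
      return(data.frame(accession = a, fw_slope = NA_real_,
                        fw_intercept = NA_real_, mse = NA_real_,
                        n_env = sum(ok)))
    f <- stats::lm(y[ok] ~ env_means[ok])
    mse <- if (f$df.residual > 0) sum(stats::resid(f)^2) / f$df.residual else 0
    data.frame(accession = a, fw_slope = unname(stats::coef(f)[2]),
               fw_intercept = unname(stats::coef(f)[1]), mse = mse,
               n_env = sum(ok))
  })
  list(stability = do.call(rbind, res), environment_means = env_means)
}

#' Pairwise correlations of a trait between environments
#'
#' Pearson correlations over the accessions shared by each environment pair,
#' plus their upper-triangle average.
#'
#' @param per_env_table Accession x environment matrix.
#' @return List with `correlations` (env x env matrix, unit diagonal) and
#'   `average`.
#' @export
env_pair_correlations <- function(per_env_table) {
  tab <- as.matrix(per_env_table)
  ne <- ncol(tab)
  if (ne < 2) stop_param("need >= 2 environments")
  cm <- matrix(NA_real_, ne, ne, dimnames = list(colnames(tab), colnames(tab)))
  diag(cm) <- 1
  for (i in seq_len(ne - 1)) for (j in (i + 1):ne) {
    ok <- is.finite(tab[, i]) & is.finite(tab[, j])
    if (sum(ok) >= 2)
      cm[i, j] <- cm[j, i] <- stats::cor(tab[ok, i], tab[ok, j])
  }
  list(correlations = cm, average = mean(cm[upper.tri(cm)], na.rm = TRUE))
}

#' Pearson correlations between trait BLUEs
#'
#' @param blues_by_trait Data.frame or matrix, accessions in rows and traits
#'   in columns.
#' @return Trait x trait correlation matrix (pairwise complete).
#' @export
trait_correlations <- function(blues_by_trait) {
  stats::cor(as.matrix(blues_by_trait), use = "pairwise.complete.obs")
}
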