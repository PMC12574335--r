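test_that("BLUEs collapse to accession means in the noise-free balanced case", {
  g <- stats::setNames(c(1, -2, 0.5, 3), paste0("acc", 1:4))
  rec <- balanced_records(g, noise_sd = 0)
  fit <- suppressMessages(fit_trait_model(rec, "y", "fixed"))
  expect_equal(unname(fit$blues[names(g)]), unname(10 + g), tolerance = 1e-6)
  expect_equal(fit$mu, 10 + mean(g), tolerance = 1e-6)
  expect_error(fit_trait_model(rec, "nope"), "not found")
})

test_that("REML estimates are invariant to ordering and location shifts", {
  pop <- generate_population(60, 30, k_pops = 1, fst = 0.2, seed = 3)
  sim <- simulate_phenotypes(pop$genotypes,
                             variance_spec = c(env = 0.3, gxe = 0.2,
                                               block = 0.1, plot = 0,
                                               residual = 0.5),
                             polygenic_var = 1, seed = 17)
  rec <- sim$records
  f1 <- suppressMessages(fit_trait_model(rec, "trait1", "random"))
  set.seed(99)
  shuf <- rec[sample(nrow(rec)), ]
  f2 <- suppressMessages(fit_trait_model(shuf, "trait1", "random"))
  expect_equal(f1$varcomp, f2$varcomp, tolerance = 1e-6)

  rec3 <- rec; rec3$value <- rec3$value + 100
  f3 <- suppressMessages(fit_trait_model(rec3, "trait1", "random"))
  expect_equal(f3$varcomp, f1$varcomp, tolerance = 1e-5)
  expect_equal(f3$mu, f1$mu + 100, tolerance = 1e-5)
})

test_that("Cullis H2 follows its definition and conventions", {
  pop <- generate_population(80, 30, k_pops = 1, fst = 0.2, seed = 5)
  sim <- simulate_phenotypes(pop$genotypes,
                             variance_spec = c(env = 0.1, gxe = 0.1,
                                               block = 0.1, plot = 0,
                                               residual = 1),
                             polygenic_var = 2, seed = 23)
  fit <- suppressMessages(fit_trait_model(sim$records, "trait1", "random"))
  h2 <- cullis_h2(fit)
  expect_true(h2 >= 0 && h2 <= 1)
  # recompute from the PEV matrix definition
  P <- fit$pev_mat
  n <- nrow(P)
  mean_vd <- ((n - 1) * sum(diag(P)) - (sum(P) - sum(diag(P)))) / choose(n, 2)
  expect_equal(h2, 1 - (mean_vd / 2) / fit$varcomp["g"],
               ignore_attr = TRUE, tolerance = 1e-12)

  # arithmetic convention: PEV = 0.1 sigma_g^2 -> 0.9
  fake <- fit
  fake$varcomp["g"] <- 1
  fake$pev_mat <- diag(0.1, 4)          # Var(diff) = 0.2, /2 = 0.1
  expect_equal(cullis_h2(fake), 0.9)
  fake$varcomp["g"] <- 0
  expect_equal(cullis_h2(fake), 0)

  # balanced design: close to the plot-mean formula
  nrep <- 4 * 3                         # env x block replicates per accession
  sg2 <- fit$varcomp["g"]
  eff_err <- fit$varcomp["gxe"] / 4 + fit$varcomp["residual"] / nrep
  expect_equal(h2, unname(sg2 / (sg2 + eff_err)), tolerance = 0.05)

  # H2 rises with simulated genetic variance
  h2s <- vapply(c(0.3, 1, 4), function(vg) {
    s <- simulate_phenotypes(pop$genotypes,
                             variance_spec = c(env = 0.1, gxe = 0.2,
                                               block = 0.1, plot = 0,
                                               residual = 1),
                             polygenic_var = vg, seed = 31)
    cullis_h2(suppressMessages(fit_trait_model(s$records, "trait1", "random")))
  }, numeric(1))
  expect_true(all(diff(h2s) > 0))
})

test_that("variance partition is a proper composition", {
  pop <- generate_population(50, 30, k_pops = 1, fst = 0.2, seed = 6)
  sim <- simulate_phenotypes(pop$genotypes,
                             variance_spec = c(env = 0.2, gxe = 0, block = 0.2,
                                               plot = 0, residual = 0.5),
                             polygenic_var = 1, seed = 41)
  fit <- suppressMessages(fit_trait_model(sim$records, "trait1", "random"))
  pr <- variance_partition(fit)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_true(all(pr >= 0))
  expect_lt(pr["gxe"], 0.05)            # simulated zero interaction
  expect_error(variance_partition(
    suppressMessages(fit_trait_model(sim$records, "trait1", "fixed"))),
    "random")
})

test_that("per-environment BLUEs respect single-block and missing cells", {
  g <- stats::setNames(c(2, 0, -1), paste0("acc", 1:3))
  rec <- balanced_records(g, n_env = 2, n_blocks = 1, noise_sd = 0)
  pe <- per_env_blues(rec, "y")
  expect_equal(unname(pe[, "env1"]), unname(10 + g), tolerance = 1e-9)

  # two blocks, no block variance: matches mean of plot means
  rec2 <- balanced_records(g, n_env = 2, n_blocks = 2, noise_sd = 0)
  pe2 <- per_env_blues(rec2, "y")
  expect_equal(unname(pe2[, "env2"]), unname(10 + g), tolerance = 1e-6)

  # missing accession-environment cell is absent, not imputed
  rec3 <- rec[!(rec$accession == "acc3" & rec$env == "env2"), ]
  pe3 <- per_env_blues(rec3, "y")
  expect_true(is.na(pe3["acc3", "env2"]))
  expect_false(anyNA(pe3[, "env1"]))
})

test_that("Finlay-Wilkinson slopes match hand regressions", {
  tab <- rbind(avg = c(10, 20, 30),
               sens = c(12, 24, 36),
               flat = c(20, 20, 20))
  colnames(tab) <- paste0("env", 1:3)
  # environment means: (14, 21.33, 28.67); regression of each row on them
  fw <- fw_regression(tab)
  st <- fw$stability
  expect_equal(st$fw_slope[st$accession == "sens"],
               unname(stats::coef(stats::lm(tab["sens", ] ~ fw$environment_means))[2]),
               tolerance = 1e-12)
  expect_equal(st$fw_slope[st$accession == "flat"], 0, tolerance = 1e-12)
  # an accession tracking the environment means exactly has slope 1, mse 0
  tab2 <- rbind(tab, track = colMeans(tab))
  fw2 <- fw_regression(tab2)
  tr <- fw2$stability[fw2$stability$accession == "track", ]
  expect_equal(tr$fw_slope, 1, tolerance = 1e-9)
  expect_equal(tr$mse, 0, tolerance = 1e-12)
  # the spec-style 1.2 case: accession = 1.2 x env means
  em <- c(10, 20, 30)
  tab3 <- rbind(a = em * 1.2, b = em * 0.8)
  fw3 <- fw_regression(tab3)
  expect_equal(fw3$stability$fw_slope, c(1.2, 0.8), tolerance = 1e-9)
})

test_that("environment-pair and trait correlations behave", {
  set.seed(8)
  base <- rnorm(40)
  tab <- cbind(env1 = base, env2 = base, env3 = -base + rnorm(40, 0, 1e-8))
  rownames(tab) <- paste0("a", 1:40)
  ec <- env_pair_correlations(tab)
  expect_equal(ec$correlations["env1", "env2"], 1, tolerance = 1e-12)
  expect_equal(ec$correlations["env1", "env3"], -1, tolerance = 1e-6)

  # independent environments: average correlation shrinks toward 0
  set.seed(9)
  big <- matrix(rnorm(500 * 4), 500, 4,
                dimnames = list(NULL, paste0("env", 1:4)))
  expect_lt(abs(env_pair_correlations(big)$average), 0.1)

  # trait correlations: unit diagonal, collinear traits at 1, and a
  # constructed independence: ln(L/W) vs area when L, W are independent
  set.seed(10)
  L <- exp(rnorm(800)); W <- exp(rnorm(800))
  tc <- trait_correlations(cbind(lw = log(L / W), area = log(L * W),
                                 dup = 2 * log(L / W)))
  expect_equal(diag(tc), c(lw = 1, area = 1, dup = 1))
  expect_equal(tc["lw", "dup"], 1, tolerance = 1e-12)
  expect_lt(abs(tc["lw", "area"]), 0.1)
})

test_that("single-root plots drop the plot term with a message", {
  g <- stats::setNames(rnorm(8), paste0("acc", 1:8))
  rec <- balanced_records(g, noise_sd = 0.1)
  expect_message(fit_trait_model(rec, "y", "random"), "plot term dropped")
  fit <- suppressMessages(fit_trait_model(rec, "y", "random"))
  expect_true(is.na(fit$varcomp["plot"]))
  expect_identical(fit$dropped_terms, "plot")
})
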