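#' Build a validated pipeline run configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]: either a
#' synthetic-generation block (the built-in end-to-end demonstration) or a
#' set of input paths, plus stage toggles and per-stage parameters. Defaults
#' give a small structured panel with genetic control of root length and
#' width, two environments with two blocks and two roots per plot, and a
#' dual-panel GWAS (full panel plus the largest-population subset) feeding
#' the consensus rule.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed; all stage seeds derive from it.
#' @param stages Named logical list enabling `simulate`, `phenotype`,
#'   `model`, `structure`, `gwas`, `predict`, `annotate`.
#' @param synthetic Parameters of the synthetic panel (see Details in the
#'   package vignette); ignored when `paths` is given.
#' @param paths Optional named list of real inputs: `phenotypes` (long CSV),
#'   `vcf`, `gff`, `gene2go` (TSV gene_id, go_id), `masks_dir` +
#'   `pixel_scale`. Exactly one of `paths`/`synthetic` drives each data
#'   stream.
#' @param params Stage parameters; see defaults in the function body.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("rootqg_run_"), seed = 1,
                       stages = list(), synthetic = list(), paths = NULL,
                       params = list()) {
  def_stages <- list(simulate = TRUE, phenotype = TRUE, model = TRUE,
                     structure = TRUE, gwas = TRUE, predict = TRUE,
                     annotate = TRUE)
  def_stages[names(stages)] <- stages
  def_syn <- list(
    n_accessions = 100, n_markers = 1200, k_pops = 3, fst = 0.25,
    admixture_alpha = 0.1, n_chromosomes = 5, chrom_length_bp = 5e7,
    n_env = 2, n_blocks = 2, n_roots = 2,
    n_qtl = 3, qtl_effect = 0.12,
    mu_log_length = log(110), mu_log_width = log(45),
    latent_variance = c(env = 0.004, gxe = 0.002, block = 0.001,
                        plot = 0.002, residual = 0.01),
    polygenic_var = 0.01, pixel_scale = 1
  )
  def_syn[names(synthetic)] <- synthetic
  def_params <- list(
    stations = 101, sd_threshold = 3,
    filter_rules = list(min_per_hom_class = 2),
    ld_window_kb = 50, ld_step_kb = 5, ld_r2_cutoff = 0.2,
    k_range = 2:4, cv_folds = 3, admixture_max_iter = 300,
    gwas_alpha = 0.05, merge_radius_bp = 1e5,
    subset_group = NULL,                 # default: largest assigned population
    window_bp = 5e5, cv_reps = 10, cv_split = 0.8,
    traits = NULL                        # default: all measured traits
  )
  def_params[names(params)] <- params
  if (!is.null(paths)) {
    need <- intersect(c("phenotypes", "vcf", "masks_dir"), names(paths))
    for (p in need) if (!file.exists(paths[[p]]))
      stop_param("input path does not exist: ", paths[[p]])
  }
  structure(list(out_dir = out_dir, seed = seed, stages = def_stages,
                 synthetic = def_syn, paths = paths, params = def_params),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate (or load),
#' phenotype, trait modeling, population structure, GWAS, genomic
#' prediction, candidate-gene annotation — writing each stage's artifacts
#' to fresh files under `config$out_dir` and returning a run report with
#' per-stage summaries and a checksummed file manifest. Rerunning with the
#' same configuration and seed reproduces identical outputs. Stages whose
#' upstream dependencies are disabled are skipped with a notice.
#'
#' @param config A [run_config()].
#' @return A `run_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  P <- config$params
  report <- list(stages = list(), config = config,
                 version = as.character(utils::packageVersion("rootqg")))
  t_all <- Sys.time()
  state <- new.env(parent = emptyenv())

  note <- function(stage, ...) {
    report$stages[[stage]] <<- c(report$stages[[stage]], list(...))
  }
  outfile <- function(name) file.path(config$out_dir, name)

  ## ---- simulate -----------------------------------------------------------
  if (config$stages$simulate && is.null(config$paths)) {
    syn <- config$synthetic
    pop <- generate_population(syn$n_accessions, syn$n_markers, syn$k_pops,
                               fst = syn$fst,
                               admixture_alpha = syn$admixture_alpha,
                               n_chromosomes = syn$n_chromosomes,
                               chrom_length_bp = syn$chrom_length_bp,
                               seed = derive_seed(seed, "pop"))
    state$genotypes <- pop$genotypes
    state$truth <- pop$truth
    # causal markers for the two latent shape axes
    m <- ncol(pop$genotypes$dosage)
    idx <- with_seed(derive_seed(seed, "qtl"),
                     sample.int(m, 2 * syn$n_qtl))
    qtl_spec <- data.frame(
      marker = colnames(pop$genotypes$dosage)[idx],
      trait = rep(c("log_length", "log_width"), each = syn$n_qtl),
      effect = syn$qtl_effect)
    sim <- simulate_phenotypes(
      pop$genotypes, qtl_spec = qtl_spec,
      variance_spec = syn$latent_variance,
      design = list(n_env = syn$n_env, n_blocks = syn$n_blocks,
                    n_roots = syn$n_roots),
      mu = c(log_length = syn$mu_log_length, log_width = syn$mu_log_width),
      traits = c("log_length", "log_width"),
      polygenic_var = syn$polygenic_var,
      seed = derive_seed(seed, "pheno"))
    state$latent <- sim$records
    state$truth$phenotype <- sim$truth
    write_vcf(pop$genotypes, outfile("genotypes.vcf"))
    utils::write.csv(sim$records, outfile("latent_phenotypes.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(q_true = unname(as.matrix(pop$truth$q_true)),
           qtl = qtl_spec, fst = syn$fst, seed = seed),
      outfile("sim_truth.json"), auto_unbox = TRUE, digits = NA)
    note("simulate", n_accessions = syn$n_accessions, n_markers = m,
         n_qtl = nrow(qtl_spec))
  } else if (!is.null(config$paths)) {
    if (!is.null(config$paths$vcf)) state$genotypes <- read_vcf(config$paths$vcf)
    if (!is.null(config$paths$phenotypes))
      state$records <- utils::read.csv(config$paths$phenotypes)
    note("simulate", skipped = "real inputs supplied")
  } else note("simulate", skipped = "stage disabled")

  ## ---- phenotype ----------------------------------------------------------
  if (config$stages$phenotype && !is.null(state$latent)) {
    syn <- config$synthetic
    lat <- state$latent
    ll <- lat[lat$trait == "log_length", ]
    lw <- lat[lat$trait == "log_width", ]
    stopifnot(nrow(ll) == nrow(lw))
    L <- exp(ll$value); Wd <- exp(lw$value)
    # family per accession from its expected length-to-width ratio
    gv <- state$truth$phenotype$genetic_values
    ratio_acc <- exp((syn$mu_log_length + gv[, "log_length"]) -
                       (syn$mu_log_width + gv[, "log_width"]))
    fam_acc <- cut(ratio_acc, c(0, 1.5, 3, 20 / 3, Inf),
                   labels = c("globose", "cylindrical", "conical", "taproot"))
    names(fam_acc) <- rownames(gv)
    bulge_acc <- with_seed(derive_seed(seed, "bulge"),
                           stats::setNames(stats::runif(nrow(gv), 0.3, 0.7),
                                           rownames(gv)))
    masks <- vector("list", nrow(ll))
    for (i in seq_len(nrow(ll))) {
      fam <- as.character(fam_acc[ll$accession[i]])
      w_i <- Wd[i]
      if (fam == "taproot" && w_i / L[i] >= 0.15) w_i <- 0.149 * L[i]
      sp <- shape_params(L[i], w_i, bulge_position = bulge_acc[ll$accession[i]],
                         family = fam)
      masks[[i]] <- render_root_mask(sp, pixel_scale = syn$pixel_scale)
    }
    names(masks) <- sprintf("root%05d", seq_along(masks))
    mt <- measure_trait_set(masks, stations = P$stations)
    ids <- ll[c("accession", "env", "block", "plot", "root")]
    wide <- cbind(ids, mt$traits[setdiff(names(mt$traits), "mask_id")])
    trait_cols <- c("digital_biomass_mm2", "length_mm", "max_width_mm",
                    "width50_mm", "lw_ratio_log", "tip_angle_deg",
                    "contour_pc")
    long <- do.call(rbind, lapply(trait_cols, function(tc)
      cbind(ids, trait = tc, value = wide[[tc]])))
    filt <- outlier_filter(long, sd_threshold = P$sd_threshold)
    state$records <- filt$data
    utils::write.csv(wide, outfile("shape_traits_per_root.csv"),
                     row.names = FALSE)
    utils::write.csv(filt$removed, outfile("outliers_removed.csv"),
                     row.names = FALSE)
    jsonlite::write_json(mt$loadings, outfile("contour_loadings.json"),
                         auto_unbox = TRUE, digits = NA)
    note("phenotype", n_roots = nrow(wide), n_outliers = nrow(filt$removed),
         families = as.list(table(fam_acc)))
  } else if (config$stages$phenotype && !is.null(config$paths$masks_dir)) {
    files <- list.files(config$paths$masks_dir, pattern = "\\.png$",
                        full.names = TRUE)
    masks <- lapply(files, read_mask_png,
                    pixel_scale = config$paths$pixel_scale %||% 1)
    names(masks) <- basename(files)
    mt <- measure_trait_set(masks, stations = P$stations)
    utils::write.csv(mt$traits, outfile("shape_traits_per_root.csv"),
                     row.names = FALSE)
    note("phenotype", n_roots = length(masks))
  } else note("phenotype", skipped = "no masks or latent phenotypes")

  ## ---- model --------------------------------------------------------------
  if (config$stages$model && !is.null(state$records)) {
    traits <- P$traits %||% unique(state$records$trait)
    blues <- list(); h2 <- vc <- list(); per_env <- list()
    for (tr in traits) {
      ffix <- suppressMessages(fit_trait_model(state$records, tr, "fixed"))
      fran <- suppressMessages(fit_trait_model(state$records, tr, "random"))
      blues[[tr]] <- ffix$blues
      h2[[tr]] <- cullis_h2(fran)
      vc[[tr]] <- fran$varcomp
      per_env[[tr]] <- per_env_blues(state$records, tr)
    }
    accs <- sort(unique(unlist(lapply(blues, names))))
    blue_mat <- vapply(traits, function(tr) blues[[tr]][accs], numeric(length(accs)))
    rownames(blue_mat) <- accs
    state$blues <- blue_mat
    state$per_env <- per_env
    fw <- fw_regression(per_env[[traits[1]]])
    ec <- env_pair_correlations(per_env[[traits[1]]])
    utils::write.csv(data.frame(accession = accs, blue_mat),
                     outfile("blues.csv"), row.names = FALSE)
    utils::write.csv(data.frame(trait = names(h2), h2 = unlist(h2)),
                     outfile("heritability.csv"), row.names = FALSE)
    jsonlite::write_json(lapply(vc, function(v) as.list(v[is.finite(v)])),
                         outfile("variance_components.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(fw$stability, outfile("finlay_wilkinson.csv"),
                     row.names = FALSE)
    utils::write.csv(trait_correlations(blue_mat),
                     outfile("trait_correlations.csv"))
    note("model", traits = traits, h2 = h2,
         mean_env_correlation = ec$average)
  } else note("model", skipped = "no phenotype records")

  ## ---- structure ----------------------------------------------------------
  if (config$stages$structure && !is.null(state$genotypes)) {
    fl <- filter_markers(state$genotypes, P$filter_rules)
    state$geno_filt <- fl$genotypes
    pruned_ids <- ld_prune(fl$genotypes, window_kb = P$ld_window_kb,
                           step_kb = P$ld_step_kb, r2_cutoff = P$ld_r2_cutoff)
    geno_pruned <- subset_genotypes(fl$genotypes, markers = pruned_ids)
    pca <- pca_genotypes(geno_pruned, n_comp = 5)
    gi <- impute_dosage(geno_pruned)
    cv <- admixture_cv(gi, k_range = P$k_range, n_folds = P$cv_folds,
                       seed = derive_seed(seed, "admcv"),
                       max_iter = P$admixture_max_iter)
    adm <- admixture_em(gi, cv$k_selected,
                        seed = derive_seed(seed, "adm"),
                        max_iter = 2 * P$admixture_max_iter)
    assigned <- factor(max.col(adm$q, ties.method = "first"))
    state$structure_groups <- assigned
    nd <- nei_distance(state$genotypes, unit = "group", groups = assigned)
    fst <- pairwise_fst(state$genotypes, groups = assigned)
    if (nrow(nd) >= 3) {
      tr <- nj_tree(nd)
      ape::write.tree(tr, outfile("nj_tree.nwk"))
    }
    utils::write.csv(data.frame(accession = rownames(adm$q), adm$q,
                                assigned = assigned),
                     outfile("admixture_q.csv"), row.names = FALSE)
    utils::write.csv(data.frame(k = names(cv$cv_error), cv_error = cv$cv_error),
                     outfile("admixture_cv.csv"), row.names = FALSE)
    utils::write.csv(pca$scores, outfile("pca_scores.csv"))
    utils::write.csv(fst, outfile("fst_populations.csv"))
    writeLines(pruned_ids, outfile("pruned_markers.txt"))
    note("structure", markers_retained = as.integer(fl$log["retained"]),
         markers_pruned_set = length(pruned_ids),
         k_selected = cv$k_selected,
         pc1_pct = pca$pct_var[1])
  } else note("structure", skipped = "no genotypes or stage disabled")

  ## ---- gwas ---------------------------------------------------------------
  if (config$stages$gwas && !is.null(state$blues) && !is.null(state$genotypes)) {
    geno_full <- state$geno_filt %||% state$genotypes
    grp <- state$structure_groups %||% geno_full$groups
    sub_group <- P$subset_group %||% names(which.max(table(grp)))
    sub_acc <- rownames(geno_full$dosage)[as.character(grp) == sub_group]
    panels <- list(full = geno_full)
    if (length(sub_acc) >= 30) {
      # the subset panel is re-filtered with the same rules, so it carries
      # its own marker count and Bonferroni threshold
      panels$subset <- tryCatch(
        filter_markers(subset_genotypes(geno_full, accessions = sub_acc),
                       P$filter_rules)$genotypes,
        error = function(e) NULL)
      if (is.null(panels$subset)) panels$subset <- NULL
    }
    thresholds <- vapply(panels, function(gp)
      bonferroni_threshold(ncol(gp$dosage), P$gwas_alpha), 0)
    qtl_all <- list()
    for (tr in colnames(state$blues)) {
      tabs <- list()
      for (pn in names(panels)) {
        yy <- state$blues[, tr]
        yy <- yy[intersect(names(yy), rownames(panels[[pn]]$dosage))]
        for (km in c("K", "K-LOCO")) {
          tabs[[paste(pn, km)]] <- mlm_scan(yy, panels[[pn]],
                                            kinship_mode = km, panel = pn)
        }
      }
      per_model <- do.call(rbind, lapply(tabs, as.data.frame))
      utils::write.csv(per_model,
                       outfile(paste0("gwas_", tr, ".csv")), row.names = FALSE)
      qtl_all[[tr]] <- consensus_qtl(tabs, thresholds,
                                     merge_radius_bp = P$merge_radius_bp,
                                     trait = tr)
    }
    qtl <- do.call(rbind, qtl_all)
    rownames(qtl) <- NULL
    state$qtl <- qtl
    utils::write.csv(qtl, outfile("consensus_qtl.csv"), row.names = FALSE)
    ld <- tryCatch(ld_decay(geno_full), error = function(e) NULL)
    if (!is.null(ld))
      utils::write.csv(ld$curve, outfile("ld_decay.csv"), row.names = FALSE)
    note("gwas", panels = names(panels),
         thresholds = as.list(round(thresholds, 2)),
         n_qtl = nrow(qtl),
         ld_block_bp = if (!is.null(ld)) ld$crossing_bp else NA)
  } else note("gwas", skipped = "needs BLUEs and genotypes")

  ## ---- predict ------------------------------------------------------------
  if (config$stages$predict && !is.null(state$blues) && !is.null(state$genotypes)) {
    geno <- state$geno_filt %||% state$genotypes
    gebv <- list(); cvres <- list()
    for (tr in colnames(state$blues)) {
      yy <- state$blues[, tr]
      fit <- rrblup_fit(yy, geno)
      gebv[[tr]] <- fit$gebv
      cvres[[tr]] <- cv_accuracy(yy, geno, split = P$cv_split,
                                 n_reps = P$cv_reps,
                                 seed = derive_seed(seed, paste0("cv_", tr)))
    }
    accs <- names(gebv[[1]])
    gm <- vapply(gebv, function(g) g[accs], numeric(length(accs)))
    utils::write.csv(data.frame(accession = accs, gm),
                     outfile("gebv.csv"), row.names = FALSE)
    cv_tab <- data.frame(
      trait = names(cvres),
      cv_accuracy_r = vapply(cvres, `[[`, 0, "cv_accuracy_r"),
      cv_r2 = vapply(cvres, `[[`, 0, "cv_r2"),
      se_r = vapply(cvres, `[[`, 0, "se_r"))
    utils::write.csv(cv_tab, outfile("cv_accuracy.csv"), row.names = FALSE)
    state$cv <- cv_tab
    note("predict", accuracy = stats::setNames(as.list(round(cv_tab$cv_accuracy_r, 3)),
                                               cv_tab$trait))
  } else note("predict", skipped = "needs BLUEs and genotypes")

  ## ---- annotate -----------------------------------------------------------
  if (config$stages$annotate && !is.null(state$qtl) && nrow(state$qtl) > 0) {
    if (!is.null(config$paths$gff)) {
      ann <- read_gene_annotation(config$paths$gff)
      g2g <- utils::read.delim(config$paths$gene2go,
                               col.names = c("gene_id", "go_id"))
      targets <- character(0)
    } else {
      sa <- simulate_annotation(state$genotypes, n_genes = 600,
                                seed = derive_seed(seed, "annot"))
      ann <- sa$annotation
      g2g <- sa$gene2go
      # demo target curation: genes near a true causal marker
      qs <- state$truth$phenotype$qtl_spec
      gmk <- state$genotypes
      ci <- match(qs$marker, colnames(gmk$dosage))
      targets <- unique(unlist(lapply(ci, function(j)
        ann$gene_id[ann$chrom == gmk$chrom[j] &
                      ann$start <= gmk$pos[j] + 2e5 &
                      ann$end >= gmk$pos[j] - 2e5])))
    }
    cand <- candidate_genes(state$qtl, ann, window_bp = P$window_bp,
                            target_genes = targets)
    utils::write.csv(cand, outfile("candidate_genes.csv"), row.names = FALSE)
    enr <- NULL
    if (nrow(cand) > 0 && any(cand$target == 1) && any(cand$target == 0)) {
      flags <- tapply(cand$target, cand$gene_id, max)
      enr <- go_enrichment(flags, g2g)
      utils::write.csv(enr, outfile("go_enrichment.csv"), row.names = FALSE)
    }
    note("annotate", n_candidates = length(unique(cand$gene_id)),
         n_targets = sum(tapply(cand$target, cand$gene_id, max)),
         top_term = if (!is.null(enr) && nrow(enr)) enr$go_id[1] else NA)
  } else note("annotate", skipped = "no QTL calls or stage disabled")

  files <- list.files(config$out_dir, full.names = TRUE)
  report$manifest <- data.frame(
    file = basename(files),
    md5 = as.character(tools::md5sum(files)),
    bytes = file.size(files), stringsAsFactors = FALSE)
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("rootqg run report (v", x$version, ") — ",
      sprintf("%.1f s", x$elapsed_s), "\n", sep = "")
  for (st in names(x$stages)) {
    s <- x$stages[[st]]
    if (!is.null(s$skipped)) cat(sprintf("  %-10s skipped (%s)\n", st, s$skipped))
    else cat(sprintf("  %-10s %s\n", st,
                     paste(names(s), vapply(s, function(v)
                       paste(format(unlist(v)), collapse = "/"), ""),
                       sep = "=", collapse = ", ")))
  }
  cat("  artifacts:", nrow(x$manifest), "files in", x$config$out_dir, "\n")
  invisible(x)
}
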