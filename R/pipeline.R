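#' Configuration for the end-to-end analysis
#'
#' One master seed drives every stochastic stage (per-stage seeds are derived
#' deterministically), so a report fully determines a rerun. The `"paper"`
#' preset records the study-scale settings: 20 million MCMC iterations with
#' 1 million burn-in and thinning 1,500, 500 null simulations, prevalence
#' threshold 0.5, and the first two PC axes for the convergence search.
#'
#' @param prevalence_threshold component retention fraction; default 0.5.
#' @param pglmm a [pglmm_config()].
#' @param clr_validation refit on clr-transformed data and compare
#'   significance masks and DIC? Default `TRUE`.
#' @param n_pc_axes number of phylomorphospace axes handed to the
#'   convergence search; default 2.
#' @param surface_forward_threshold,surface_backward_threshold AICc
#'   improvements needed to accept a forward shift (default 10, a
#'   multiplicity allowance for scanning every branch) or a backward merge
#'   (default 0); see [run_surface()].
#' @param n_null null simulations for the convergence p-value; default 50
#'   (desk scale; the `"paper"` preset uses 500).
#' @param seed master seed.
#' @param preset `"desk"` (default) or `"paper"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(prevalence_threshold = 0.5,
                            pglmm = NULL, clr_validation = TRUE,
                            n_pc_axes = 2, surface_forward_threshold = 10,
                            surface_backward_threshold = 0,
                            n_null = 50, seed = 1,
                            preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    pglmm <- pglmm_config(preset = "paper", seed = seed)
    n_null <- 500
  }
  if (is.null(pglmm)) pglmm <- pglmm_config(seed = seed)
  structure(list(prevalence_threshold = prevalence_threshold, pglmm = pglmm,
                 clr_validation = clr_validation, n_pc_axes = n_pc_axes,
                 surface_forward_threshold = surface_forward_threshold,
                 surface_backward_threshold = surface_backward_threshold,
                 n_null = n_null, seed = seed, preset = preset),
            class = "pipeline_config")
}

#' Reconcile a tree and an abundance table
#'
#' Lists species found in only one of the two inputs, the proposed pruning,
#' and per-component prevalence.
#'
#' @param tree a `phylo`.
#' @param table a [toxin_table()] or species x component matrix.
#' @param presence_tol see [prevalence_filter()].
#' @return list with `common`, `in_table_only`, `in_tree_only`,
#'   `prevalence` (computed over the common species).
#' @export
validate_inputs <- function(tree, table, presence_tol = 1e-6) {
  validate_phylogeny(tree)
  v <- as_values(table)
  common <- intersect(tree$tip.label, rownames(v))
  if (!length(common))
    stop("tree and table share no species", call. = FALSE)
  list(common = common,
       in_table_only = setdiff(rownames(v), tree$tip.label),
       in_tree_only = setdiff(tree$tip.label, rownames(v)),
       prevalence = colMeans(v[common, , drop = FALSE] > presence_tol))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full macroevolutionary analysis
#'
#' Executes the pipeline end to end: percent normalisation, prevalence
#' filtering, the Bayesian phylogenetic mixed model (PCOV, lambda, MCMC
#' diagnostics), the clr-transform validation refit, PCA of the PCOV with
#' species scores, the stepwise OU convergence search on the first PC axes
#' with a simulated null and p-value, and per-component ancestral state
#' reconstruction with root-presence calls. Any stage error halts with the
#' stage name; when `output_dir` is given each stage's output is persisted
#' as it completes.
#'
#' @param tree a `phylo` or path to a Newick file.
#' @param table a [toxin_table()] or path to a TSV/CSV table.
#' @param config a [pipeline_config()].
#' @param output_dir optional directory for per-stage TSV/JSON outputs.
#' @return a `pipeline_report` list with every stage's output.
#' @export
run_pipeline <- function(tree, table, config = pipeline_config(),
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(tree)) tree <- read_phylogeny(tree)
  if (is.character(table)) table <- read_toxin_table(table)
  if (!is.null(output_dir) && !dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)

  val <- run_stage("validate", validate_inputs(tree, table))
  if (length(val$in_tree_only)) tree <- prune_to_taxa(tree, val$common)
  v <- as_values(table)[val$common, , drop = FALSE]
  batch <- if (inherits(table, "toxin_table")) table$batch[val$common]
  table <- toxin_table(v, batch)

  table <- run_stage("normalize", percent_normalize(table))
  filtered <- run_stage("prevalence_filter",
                        prevalence_filter(table, config$prevalence_threshold))

  pg_cfg <- config$pglmm
  pg_cfg$seed <- derive_seed(config$seed, 11)
  fit <- run_stage("fit_pglmm", fit_pglmm(filtered, tree, pg_cfg))
  pcov <- run_stage("posterior_pcov", posterior_pcov(fit))
  lambda <- run_stage("lambda_estimates", lambda_estimates(fit))
  diagnostics <- run_stage("diagnostics", {
    lam_draws <- attr(lambda, "draws")
    ess <- apply(lam_draws, 2, effective_sample_size)
    list(ess_lambda = setNames(ess, fit$components),
         mean_ess = mean(ess),
         deviance_autocorr_lag1 = autocorrelation(fit$deviance, 1),
         dic = dic(fit))
  })

  clr_val <- NULL
  if (config$clr_validation) {
    clr_val <- run_stage("clr_validation", {
      clr <- clr_transform(impute_zeros(filtered))
      clr_cfg <- pg_cfg
      clr_cfg$seed <- derive_seed(config$seed, 12)
      clr_fit <- fit_pglmm(clr, tree, clr_cfg, batch = filtered$batch)
      clr_pcov <- posterior_pcov(clr_fit)
      off <- upper.tri(pcov$significant)
      list(pcov = clr_pcov, dic = dic(clr_fit),
           dic_raw = diagnostics$dic,
           mask_agreement = mean(pcov$significant[off] ==
                                 clr_pcov$significant[off]))
    })
  }

  pca <- run_stage("pca", {
    p <- pcov_pca(pcov$mean_G)
    species_scores(fit$Y, p)
  })

  surface <- run_stage("surface", {
    traits <- pca$scores[, seq_len(config$n_pc_axes), drop = FALSE]
    res <- run_surface(traits, tree,
                       forward_threshold = config$surface_forward_threshold,
                       backward_threshold = config$surface_backward_threshold)
    nt <- surface_null_test(res, traits, tree, n_sim = config$n_null,
                            seed = derive_seed(config$seed, 13),
                            forward_threshold = config$surface_forward_threshold,
                            backward_threshold = config$surface_backward_threshold)
    list(result = res, null = nt$null, p_c = round(nt$p_c, 3),
         p_delta_k = round(nt$p_delta_k, 3))
  })

  asr <- run_stage("asr", ml_ancestral_states_all(tree, filtered))
  root_presence <- run_stage("root_presence", root_presence_call(asr))

  report <- structure(list(
    inputs = list(n_species = length(val$common),
                  n_components_input = ncol(v),
                  species = val$common, validation = val),
    config = config,
    retained_components = attr(filtered, "retained"),
    filtered_table = filtered,
    fit = fit, pcov = pcov, lambda = lambda, diagnostics = diagnostics,
    clr_validation = clr_val, pca = pca, surface = surface,
    asr = asr, root_presence = root_presence),
    class = "pipeline_report")

  if (!is.null(output_dir)) persist_report(report, output_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat("  species:", x$inputs$n_species,
      "| components retained:", length(x$retained_components), "of",
      x$inputs$n_components_input, "\n")
  cat("  PC1+PC2 variance:",
      round(100 * sum(x$pca$variance_fractions[1:2]), 1), "%\n")
  s <- x$surface
  cat("  surface: k =", s$result$k, "k' =", s$result$kprime,
      "delta_k =", s$result$delta_k, "c =", s$result$c,
      "p_c =", s$p_c, "\n")
  cat("  root presence:",
      paste(names(x$root_presence)[x$root_presence], collapse = ", "), "\n")
  invisible(x)
}

persist_report <- function(report, dir) {
  j <- function(x, f) jsonlite::write_json(x, file.path(dir, f),
                                           auto_unbox = TRUE, digits = NA,
                                           pretty = TRUE)
  write_toxin_table(report$filtered_table, file.path(dir, "filtered_table.tsv"))
  write_matrix_tsv(report$pcov$mean_G, file.path(dir, "pcov_mean_G.tsv"))
  write_matrix_tsv(report$pcov$mean_R, file.path(dir, "pcov_mean_R.tsv"))
  j(list(significant = report$pcov$significant), "pcov_significance.json")
  write.table(report$lambda, file.path(dir, "lambda.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_pca_tsv(report$pca, file.path(dir, "pca"))
  s <- report$surface
  j(list(k = s$result$k, kprime = s$result$kprime,
         delta_k = s$result$delta_k, c = s$result$c,
         n_convergent_regimes = s$result$n_convergent_regimes,
         p_c = s$p_c, p_delta_k = s$p_delta_k,
         aicc_trace = s$result$history), "surface.json")
  write.table(s$null$stats, file.path(dir, "surface_null.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_asr_tsv(report$asr, file.path(dir, "asr.tsv"))
  j(list(retained_components = report$retained_components,
         diagnostics = report$diagnostics,
         clr_mask_agreement = report$clr_validation$mask_agreement,
         clr_dic = report$clr_validation$dic,
         raw_dic = report$diagnostics$dic,
         root_presence = as.list(report$root_presence),
         seed = report$config$seed,
         preset = report$config$preset), "report.json")
  invisible(dir)
}
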