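#' Default analysis parameters for the pipeline
#'
#' The tunables of the full analysis with their standard values: the
#' 30-colony plate filter, 10,000 K-S permutations, 10,000 null
#' simulations for the tail likelihood-ratio test, 10,000 regression
#' permutations, 100 random tree resolutions and the 42-nt mRNA window.
#' @return named list.
#' @export
pipeline_defaults <- function() {
  list(min_colonies = 30, ks_B = 10000, null_sims = 10000,
       perm_B = 10000, resolutions = 100, window_width = 42,
       include_nonsense = TRUE, drop_minimum = TRUE,
       marker_correct = FALSE, presence_link = "log_w",
       presence_B = 1000)
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates simulate -> fitness -> dfe -> covariates -> regressions ->
#' phylo from a single configuration (an R list, or the path to a YAML or
#' JSON file). The configuration has elements:
#' \describe{
#'   \item{seed}{master seed for all analysis-stage randomness.}
#'   \item{outdir}{output directory.}
#'   \item{simulate}{either `TRUE` / a list of [sim_config()] arguments
#'     (synthetic inputs are generated under `outdir/sim`), or `NULL` with
#'     an `inputs` list of file paths (`competitions`, `mutations`, `gene`,
#'     `reference_genes`, `expression`, `tree`, `tip_states`, optional
#'     `trna`, `marker_control`).}
#'   \item{stages}{character vector of stages to run (default all).}
#'   \item{params}{overrides of [pipeline_defaults()].}
#' }
#' Every enabled stage's inputs are checked before execution starts. A
#' `manifest.json` (package version, config echo, seeds, input hashes) and
#' a `report.json` aggregating the headline results are written to
#' `outdir`; each stage writes its own table alongside. Reruns with the
#' same configuration are bit-identical. A failing stage aborts with the
#' stage named; earlier outputs are retained.
#'
#' @param config list or path to a YAML/JSON run configuration.
#' @return invisibly, the report list.
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir %||% stop("config$outdir is required")
  stages_all <- c("simulate", "fitness", "dfe", "covariates",
                  "regressions", "phylo")
  stages <- config$stages %||% stages_all
  stopifnot(all(stages %in% stages_all))
  params <- utils::modifyList(pipeline_defaults(), config$params %||% list())
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  analysis_seeds <- derive_seeds(seed, 6)
  names(analysis_seeds) <- stages_all
  report <- list()
  log <- list()
  inputs <- config$inputs %||% list()

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      sim_args <- if (isTRUE(config$simulate)) list() else
        (config$simulate %||% list())
      sim_args$seed <- sim_args$seed %||% seed
      cfg <- do.call(sim_config, sim_args)
      simdir <- file.path(outdir, "sim")
      write_simulated_data(cfg, simdir)
      inputs <<- utils::modifyList(list(
        competitions = file.path(simdir, "competitions.csv"),
        marker_control = file.path(simdir, "marker_control.csv"),
        mutations = file.path(simdir, "mutations.csv"),
        gene = file.path(simdir, "gene.fasta"),
        reference_genes = file.path(simdir, "reference_genes.fasta"),
        expression = file.path(simdir, "expression.csv"),
        tree = file.path(simdir, "tree.nwk"),
        tip_states = file.path(simdir, "tip_states.csv"),
        trna = file.path(simdir, "trna_copies.csv")), inputs)
      log$simulate <<- list(config = unclass(cfg))
    })
  }

  needed <- character(0)
  if ("fitness" %in% stages) needed <- c(needed, "competitions", "mutations")
  if ("covariates" %in% stages)
    needed <- c(needed, "gene", "reference_genes", "mutations")
  if ("regressions" %in% stages) needed <- c(needed, "expression")
  if ("phylo" %in% stages) needed <- c(needed, "tree", "tip_states")
  missing_in <- needed[!vapply(needed, function(k)
    !is.null(inputs[[k]]) && file.exists(inputs[[k]]), logical(1))]
  if (length(missing_in) > 0)
    stop("unresolvable inputs for enabled stages: ",
         paste(unique(missing_in), collapse = ", "))

  fitness <- NULL
  if ("fitness" %in% stages) {
    run_stage("fitness", function() {
      counts <- read.csv(inputs$competitions)
      muts <- read.csv(inputs$mutations)
      ctrl <- NULL
      if (!is.null(inputs$marker_control) && file.exists(inputs$marker_control))
        ctrl <- marker_control(read.csv(inputs$marker_control),
                               params$min_colonies)
      ft <- suppressWarnings(estimate_fitness(
        counts, min_colonies = params$min_colonies,
        marker_correction = if (params$marker_correct) ctrl else NULL))
      ft <- merge(as.data.frame(ft), muts[, c("mutation_id", "class")],
                  by = "mutation_id", sort = TRUE)
      write.csv(ft[, c("mutation_id", "class", "w_mean", "sem",
                       "n_replicates")],
                file.path(outdir, "fitness.csv"), row.names = FALSE)
      fitness <<- ft
      log$fitness <<- list(
        n_replicates_read = nrow(counts),
        n_replicates_excluded = sum(ft$n_excluded),
        marker_control = ctrl)
      report$marker_control_w <<- if (is.null(ctrl)) NA else ctrl$w_mean
    })
  } else if (file.exists(file.path(outdir, "fitness.csv"))) {
    fitness <- read.csv(file.path(outdir, "fitness.csv"))
  }

  if ("dfe" %in% stages) {
    run_stage("dfe", function() {
      if (is.null(fitness)) stop("fitness table unavailable")
      dfe <- build_dfe(fitness, include_nonsense = params$include_nonsense)
      ks <- ks_compare(dfe$synonymous$s, dfe$nonsynonymous$s,
                       B = params$ks_B, seed = analysis_seeds[["dfe"]])
      pooled <- fitness[fitness$class %in% c("synonymous", "nonsynonymous") &
                          !is.na(fitness$w_mean), ]
      tail <- suppressMessages(beneficial_tail(
        data.frame(w = pooled$w_mean), drop_minimum = params$drop_minimum))
      tt <- gpd_tail_test(tail$x, n_null_sims = params$null_sims,
                          seed = analysis_seeds[["dfe"]] + 1L)
      write.csv(data.frame(x = tail$x),
                file.path(outdir, "tail_diagnostics.csv"), row.names = FALSE)
      rep_dfe <- list(
        n_synonymous = nrow(dfe$synonymous),
        n_nonsynonymous = nrow(dfe$nonsynonymous),
        n_nonsense = sum(fitness$class == "nonsense", na.rm = TRUE),
        n_beneficial_pooled = tail$n_beneficial,
        n_tail = tail$n_tail,
        ks = unclass(ks)[c("D", "p", "B", "method")],
        tail_test = list(
          tau_exp = tt$exp_fit$tau, tau = tt$free_fit$tau,
          kappa = tt$free_fit$kappa, lr_stat = tt$lr_stat,
          p_value = tt$p_value, p_chisq = tt$p_chisq,
          domain = tt$domain))
      jsonlite::write_json(rep_dfe, file.path(outdir, "dfe_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      report$dfe <<- rep_dfe
    })
  }

  covariates <- NULL
  if ("covariates" %in% stages) {
    run_stage("covariates", function() {
      cds <- read_coding_sequence(inputs$gene)
      muts <- read.csv(inputs$mutations)
      usage <- codon_usage_table(inputs$reference_genes)
      trna <- NULL
      if (!is.null(inputs$trna) && file.exists(inputs$trna))
        trna <- trna_copy_table(read.csv(inputs$trna))
      mfe <- NULL
      if (!is.null(inputs$mfe) && file.exists(inputs$mfe))
        mfe <- read.csv(inputs$mfe)
      cov <- suppressMessages(mutation_covariates(cds, muts, usage, trna, mfe))
      write.csv(cov, file.path(outdir, "covariates.csv"), row.names = FALSE)
      covariates <<- cov
      log$covariates <<- list(n_mutations = nrow(muts),
                              n_covariate_rows = nrow(cov))
      ramp <- ramp_test(cds, usage, B = params$perm_B,
                        seed = analysis_seeds[["covariates"]])
      report$ramp <<- list(
        n_codons_scored = ramp$trend$n,
        trend_slope = unname(ramp$trend$coefficients["index"]),
        trend_adj_r2 = ramp$trend$adj_r_squared,
        trend_p = unname(ramp$trend$p_perm["index"]),
        contrast_p = if (is.null(ramp$contrast)) NA
                     else unname(ramp$contrast$p_perm["early"]))
    })
  }

  if ("regressions" %in% stages) {
    run_stage("regressions", function() {
      if (is.null(fitness)) stop("fitness table unavailable")
      sd_seed <- analysis_seeds[["regressions"]]
      expr <- read.csv(inputs$expression)
      efr <- expression_fitness_regression(fitness, expr,
                                           B = params$perm_B, seed = sd_seed)
      regs <- list(expression_fitness = list(
        n = attr(efr, "n_joined"),
        slope = unname(efr$coefficients["expression"]),
        adj_r2 = efr$adj_r_squared,
        p_perm = unname(efr$p_perm["expression"])))
      if (!is.null(covariates)) {
        d <- merge(fitness, covariates, by = "mutation_id")
        for (v in c("delta_cai", "delta_tai", "distance_from_start_nt")) {
          if (all(is.na(d[[v]]))) next
          pl <- permlm(stats::reformulate(v, "w_mean"), d,
                       B = params$perm_B, seed = sd_seed)
          regs[[paste0("fitness_vs_", v)]] <- list(
            slope = unname(pl$coefficients[v]),
            adj_r2 = pl$adj_r_squared, p_perm = unname(pl$p_perm[v]))
        }
      }
      jsonlite::write_json(regs, file.path(outdir, "regressions.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      report$regressions <<- regs
    })
  }

  if ("phylo" %in% stages) {
    run_stage("phylo", function() {
      if (is.null(fitness)) stop("fitness table unavailable")
      tree <- ape::read.tree(inputs$tree)
      states <- read.csv(inputs$tip_states)
      ss <- suppressMessages(site_summary(
        tree, states, n_resolutions = params$resolutions,
        seed = analysis_seeds[["phylo"]]))
      write.csv(as.data.frame(ss), file.path(outdir, "phylo_presence.csv"),
                row.names = FALSE)
      sense <- fitness[fitness$class %in% c("synonymous", "nonsynonymous"), ]
      pm <- suppressWarnings(presence_model(
        as.data.frame(ss), sense, link = params$presence_link,
        B = params$presence_B, seed = analysis_seeds[["phylo"]] + 1L))
      rep_ph <- list(n = pm$n, slope = pm$slope, p_lrt = pm$p_lrt,
                     p_perm = pm$p_perm, link = pm$link,
                     separation = pm$separation)
      jsonlite::write_json(rep_ph, file.path(outdir, "presence_model.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      report$presence <<- rep_ph
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mutfit")),
    seed = seed, analysis_seeds = as.list(analysis_seeds),
    config = config, params = params,
    input_hashes = lapply(inputs, function(p)
      if (file.exists(p)) unname(tools::md5sum(p)) else NA),
    stage_log = log)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
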