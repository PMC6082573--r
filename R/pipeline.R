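#' Run the full autozygosity pipeline
#'
#' Orchestrates one reproducible run: load (or simulate) genotypes, sample
#' QC, variant QC, optional kinship-based unrelated-subset selection, VIF
#' LD pruning, ROH calling, F statistics, and (when configured) the nested
#' association model sets. Outputs and a JSON manifest (config hash,
#' per-stage dimensions, package version) are written to the output
#' directory; rerunning an identical config reproduces identical outputs.
#'
#' The config is a nested list (or a path to a YAML file with the same
#' structure):
#' \describe{
#'   \item{input}{either `list(bfile = "prefix")` for a PLINK 1 fileset or
#'     `list(simulation = list(...))` with [sim_config()] arguments
#'     (`confounded = TRUE` selects [confounded_cohort()]).}
#'   \item{qc}{[qc_thresholds()] arguments; `kinship = TRUE` enables
#'     unrelated-subset selection at `kinship_max`.}
#'   \item{prune}{`window_snps`, `step`, `vif_max`; `enabled = FALSE`
#'     skips pruning.}
#'   \item{roh}{[roh_params()] arguments plus `denominator_bp` and
#'     `long_threshold_bp`. Simulated inputs default the denominator to
#'     the simulated genome length.}
#'   \item{assoc}{`traits`, `predictor`, `minimal_covariates`,
#'     `sociodemographic_covariates`, `sociodemographic_traits`,
#'     `trait_kinds`, `sets`, `phenotypes` (TSV path; unnecessary for
#'     simulated input). Omit to stop after F statistics.}
#'   \item{out_dir}{output directory (created if needed).}
#'   \item{seed}{run seed; stage seeds are derived deterministically.}
#' }
#'
#' @param config nested list or YAML file path.
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   results (`genotypes`, `segments`, `fstats`, `results`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% abort_autozyg("config$out_dir is required", "autozyg_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L

  # config hash: canonical YAML of the config as given
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    package = "autozyg",
    version = as.character(utils::packageVersion("autozyg")),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    stages = list()
  )
  stage <- "input"
  finish <- function(error = NULL) {
    if (!is.null(error)) manifest$failed_stage <<- stage
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  run <- function() {
    # ---- input ----
    sim <- NULL
    if (!is.null(config$input$simulation)) {
      sim_args <- config$input$simulation
      confounded <- isTRUE(sim_args$confounded)
      sim_args$confounded <- NULL
      sim_args$seed <- sim_args$seed %||% derive_seed(seed, "simulate")
      cfg <- do.call(sim_config, sim_args)
      sim <- if (confounded) confounded_cohort(cfg) else simulate_cohort(cfg)
      g <- sim$genotypes
    } else if (!is.null(config$input$bfile)) {
      g <- read_plink(config$input$bfile)
    } else {
      abort_autozyg("config$input needs `bfile` or `simulation`", "autozyg_config_error")
    }
    manifest$stages$input <<- list(n_individuals = nrow(g$calls), n_variants = ncol(g$calls))

    # ---- QC: samples first, then variants ----
    stage <<- "qc_samples"
    thr_args <- config$qc[intersect(names(config$qc), names(formals(qc_thresholds)))]
    thr <- do.call(qc_thresholds, thr_args %||% list())
    fs <- filter_samples(g, thr)
    g <- fs$genotypes
    manifest$stages$qc_samples <<- list(
      n_removed = sum(fs$report$n_removed), n_individuals = nrow(g$calls)
    )

    stage <<- "qc_variants"
    fv <- filter_variants(g, thr)
    g <- fv$genotypes
    utils::write.table(rbind(fs$report, fv$report), file.path(out_dir, "qc_report.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    manifest$stages$qc_variants <<- list(
      removed = stats::setNames(as.list(fv$report$n_removed), fv$report$rule),
      n_variants = ncol(g$calls)
    )

    # ---- optional kinship-based unrelated selection ----
    if (isTRUE(config$qc$kinship)) {
      stage <<- "kinship"
      k <- compute_kinship(g)
      keep <- select_unrelated(k, thr$kinship_max)
      g <- g[keep, ]
      manifest$stages$kinship <<- list(n_individuals = nrow(g$calls))
    }

    # ---- VIF pruning ----
    if (!isFALSE(config$prune$enabled)) {
      stage <<- "prune"
      pr <- config$prune %||% list()
      keep <- vif_prune(g,
        window_snps = pr$window_snps %||% 50,
        step = pr$step %||% 5,
        vif_max = pr$vif_max %||% 10
      )
      g <- g[, keep]
      manifest$stages$prune <<- list(n_variants = ncol(g$calls))
    }

    # ---- ROH + F statistics ----
    stage <<- "roh"
    roh_cfg <- config$roh %||% list()
    params <- do.call(roh_params, roh_cfg[intersect(names(roh_cfg), names(formals(roh_params)))])
    denom <- roh_cfg$denominator_bp %||%
      (if (!is.null(sim)) sim$config$genome_length_bp else 2.77e9)
    long_thr <- roh_cfg$long_threshold_bp %||% 8.5e6
    segments <- call_roh(g, params)
    write_roh_table(segments, file.path(out_dir, "roh.tsv"))
    manifest$stages$roh <<- list(n_segments = nrow(segments))

    stage <<- "fstats"
    froh <- compute_froh(segments,
      ids = g$samples$iid,
      denominator_bp = denom, long_threshold_bp = long_thr
    )
    fsnp <- compute_fsnp(g)
    fstats <- cbind(froh, f_snp = fsnp$f_snp[match(froh$iid, fsnp$iid)])
    utils::write.table(fstats, file.path(out_dir, "fstats.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    manifest$stages$fstats <<- list(n_individuals = nrow(fstats))

    # ---- association model sets ----
    results <- NULL
    if (!is.null(config$assoc)) {
      stage <<- "assoc"
      ac <- config$assoc
      pheno <- if (!is.null(sim)) {
        sim$phenotypes
      } else if (!is.null(ac$phenotypes)) {
        read_phenotypes(ac$phenotypes)
      } else {
        abort_autozyg("assoc needs phenotypes (path) for non-simulated input", "autozyg_config_error")
      }
      dat <- merge(fstats, pheno, by = "iid")
      kinds <- unlist(ac$trait_kinds) %||% NULL
      results <- run_model_sets(
        dat,
        traits = unlist(ac$traits),
        predictor = unlist(ac$predictor) %||% "f_roh",
        minimal_covariates = unlist(ac$minimal_covariates),
        sociodemographic_covariates = unlist(ac$sociodemographic_covariates) %||% character(0),
        trait_kinds = kinds,
        sociodemographic_traits = unlist(ac$sociodemographic_traits) %||% character(0),
        sets = unlist(ac$sets) %||% 1:3
      )
      utils::write.table(results, file.path(out_dir, "results.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      manifest$stages$assoc <<- list(n_models = nrow(results))
    }
    list(genotypes = g, segments = segments, fstats = fstats, results = results)
  }
  res <- tryCatch(run(), error = function(e) {
    finish(error = e)
    abort_autozyg(
      sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
      "autozyg_pipeline_error"
    )
  })
  finish()
  invisible(c(list(manifest = manifest), res))
}
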