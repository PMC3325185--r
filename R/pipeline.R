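#' End-to-end analysis pipeline
#'
#' Runs an ordered list of named stages (synthetic-data generation, FRAP
#' fitting, recovery reconstruction, well-mixed simulation, intervention
#' screening, spatial simulation) with fail-fast validation: the whole recipe
#' is checked before any stage executes, so an invalid recipe produces no
#' partial outputs. Every artifact is traceable through a JSON run manifest
#' (configuration hash, package version, seeds, per-stage outputs and wall
#' time); the scientific summary is written separately so that deterministic
#' recipes re-run byte-identically.
#'
#' @name workbench
NULL

.pipeline_stages <- c("generate-data", "fit-frap", "reconstruct", "simulate",
                      "intervene", "spatial")

validate_recipe <- function(recipe) {
  if (!is.list(recipe) || is.null(recipe$stages) || !length(recipe$stages))
    stop("recipe must be a list with a non-empty `stages` list")
  for (st in recipe$stages) {
    if (is.null(st$stage))
      stop("every stage needs a `stage` name")
    if (!st$stage %in% .pipeline_stages)
      stop("unknown stage: ", st$stage, " (known: ",
           paste(.pipeline_stages, collapse = ", "), ")")
    if (st$stage == "generate-data" && is.null(st$n_replicates))
      stop("stage generate-data: missing config key `n_replicates`")
    if (st$stage == "intervene" && is.null(st$factors))
      stop("stage intervene: missing config key `factors`")
  }
  invisible(TRUE)
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Run a pipeline recipe
#'
#' @param recipe A list with elements `name`, `seed` (master seed for all
#'   randomness), and `stages` (list of stage specs, each a list with a
#'   `stage` name plus stage-specific keys), or a path to a YAML recipe file.
#' @param out_dir Output directory; created if absent.
#' @return (Invisibly) a list with the manifest and per-stage results;
#'   `manifest.json` and `summary.json` are written into `out_dir`.
#' @export
run_pipeline <- function(recipe, out_dir) {
  if (is.character(recipe)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML recipes require the 'yaml' package")
    recipe <- yaml::read_yaml(recipe)
  }
  validate_recipe(recipe)
  seed <- if (is.null(recipe$seed)) 42L else as.integer(recipe$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(recipe_name = if (is.null(recipe$name)) "unnamed" else recipe$name,
                   config_hash = config_hash(recipe),
                   package_version = as.character(utils::packageVersion("invadosim")),
                   seed = seed, stages = list())
  summary <- list()
  state <- list(traces = NULL, fits = NULL, scenario = invadopodium_scenario())
  t_total <- proc.time()[["elapsed"]]

  for (st in recipe$stages) {
    t0 <- proc.time()[["elapsed"]]
    outputs <- character(0)
    if (st$stage == "generate-data") {
      conds <- if (is.null(st$conditions)) c("control", "bafilomycin") else unlist(st$conditions)
      sd <- if (is.null(st$noise_sd)) 2 else st$noise_sd
      state$traces <- generate_dataset(st$n_replicates, conds,
                                       noise = noise_spec(sd, seed))
      p <- file.path(out_dir, "traces.csv")
      write_frap_csv(state$traces, p)
      outputs <- p
      summary$n_traces <- length(unique(paste(state$traces$condition,
                                              state$traces$replicate_id)))
    } else if (st$stage == "fit-frap") {
      if (is.null(state$traces)) stop("fit-frap requires a generate-data stage first")
      comp <- if (is.null(st$components)) "auto" else st$components
      p <- file.path(out_dir, "fits.json")
      state$fits <- fit_frap_dataset(state$traces, comp, path = p)
      outputs <- p
      for (cond in names(state$fits))
        summary[[paste0("fit_", cond)]] <- list(
          n_components = state$fits[[cond]]$n_components,
          taus_s = state$fits[[cond]]$taus,
          amps_pct = state$fits[[cond]]$amps)
    } else if (st$stage == "reconstruct") {
      if (is.null(state$fits)) stop("reconstruct requires a fit-frap stage first")
      pair <- reconstruct_recovery_pair(state$fits$control,
                                        state$fits$bafilomycin)
      p <- file.path(out_dir, "reconstruction.csv")
      both <- rbind(cbind(pair$control, condition = "control"),
                    cbind(pair$bafilomycin, condition = "bafilomycin"))
      utils::write.csv(both, p, row.names = FALSE)
      outputs <- p
      summary$control_plateau_pct <-
        pair$control$M_total[nrow(pair$control)]
    } else if (st$stage == "simulate") {
      t_end <- if (is.null(st$t_end)) 700 else st$t_end
      res <- run_scenario(state$scenario, t_end = t_end)
      p <- file.path(out_dir, "wellmixed.csv")
      utils::write.csv(data.frame(time_s = res$times,
                                  ecm_remaining = res$ecm_remaining,
                                  deg_rate = deg_rate_series(res)),
                       p, row.names = FALSE)
      outputs <- p
      summary$tau_half_s <- tau_half(res)
      summary$final_ecm_remaining <- res$ecm_remaining[length(res$times)]
    } else if (st$stage == "intervene") {
      modes <- if (is.null(st$modes)) c("turnover", "conc", "both") else unlist(st$modes)
      eff <- efficacy_curve(state$scenario, modes, unlist(st$factors))
      p <- file.path(out_dir, "efficacy.csv")
      utils::write.csv(eff, p, row.names = FALSE)
      outputs <- p
      summary$efficacy <- stats::setNames(
        lapply(seq_len(nrow(eff)), function(i)
          list(mode = eff$mode[i], factor = eff$factor[i],
               efficacy = eff$efficacy[i])), NULL)
    } else if (st$stage == "spatial") {
      grid <- build_grid()
      t_end <- if (is.null(st$t_end)) 400 else st$t_end
      res <- run_spatial(grid, state$scenario, t_end = t_end)
      p <- file.path(out_dir, "spatial.csv")
      utils::write.csv(data.frame(time_s = res$times,
                                  ecm_remaining = res$ecm_remaining),
                       p, row.names = FALSE)
      outputs <- p
      summary$spatial_tau_half_s <- spatial_tau_half(res)
    }
    manifest$stages[[length(manifest$stages) + 1L]] <-
      list(stage = st$stage, outputs = basename(outputs),
           elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
  }
  manifest$wall_time_s <- round(proc.time()[["elapsed"]] - t_total, 3)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, summary = summary))
}
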