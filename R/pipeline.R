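#' Assemble a pipeline run configuration
#'
#' Bundles everything one reproducible end-to-end run needs: either a
#' simulation design (synthetic fields) or a directory of real TIFF fields
#' with a channel-role map, plus segmentation parameters, one gate
#' configuration for the whole run (cutoff constancy), population-model
#' parameters and a global seed.
#'
#' @param outdir Output directory (created if missing).
#' @param design Simulation design for [simulate_experiment()]; `NULL` when
#'   `input_fields` is given.
#' @param input_fields Optional character vector of multi-page TIFF paths of
#'   already-acquired fields (the simulate stage is then skipped).
#' @param segmentation A [segmentation_params()].
#' @param gate A [gate_config()], or `NULL` to derive both cutoffs from the
#'   pooled measurements with [suggest_cutoff()] (logged in the manifest).
#' @param model A [population_model_params()].
#' @param division_times Doubling times (h) for the model sweep stage.
#' @param seed Global integer seed; per-stage seeds are derived from it.
#' @param write_qc Write QC overlay PNGs per field. Default FALSE.
#' @return Object of class `run_config`.
#' @export
run_config <- function(outdir,
                       design = NULL,
                       input_fields = NULL,
                       segmentation = segmentation_params(),
                       gate = NULL,
                       model = population_model_params(),
                       division_times = c(16, 20, 24, 36, 48, 72),
                       seed = 1L,
                       write_qc = FALSE) {
  if (is.null(design) && is.null(input_fields)) {
    stop("run_config needs a simulation design or input_fields")
  }
  structure(list(
    outdir = outdir, design = design, input_fields = input_fields,
    segmentation = segmentation, gate = gate, model = model,
    division_times = division_times, seed = as.integer(seed),
    write_qc = isTRUE(write_qc)
  ), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The file mirrors [run_config()]: top-level keys `outdir`, `design` (a list
#' of entries with `well`, `timepoint`, `condition`, optional `n_fields` and
#' `simulation` overrides), `segmentation`, `gate`, `model`,
#' `division_times`, `seed`, `write_qc`. Unspecified values fall back to the
#' package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  }
  design <- NULL
  if (!is.null(raw$design)) {
    design <- lapply(seq_along(raw$design), function(i) {
      e <- raw$design[[i]]
      sim_args <- e$simulation
      if (is.null(sim_args)) sim_args <- list()
      cfg <- do.call(simulation_config, sim_args)
      list(well = e$well, timepoint = e$timepoint,
           condition = if (is.null(e$condition)) "control" else e$condition,
           n_fields = if (is.null(e$n_fields)) 1L else e$n_fields,
           config = cfg)
    })
  }
  seg <- do.call(segmentation_params,
                 if (is.null(raw$segmentation)) list() else raw$segmentation)
  gate <- if (!is.null(raw$gate)) do.call(gate_config, raw$gate)
  model <- do.call(population_model_params,
                   if (is.null(raw$model)) list() else raw$model)
  run_config(
    outdir = raw$outdir,
    design = design,
    input_fields = raw$input_fields,
    segmentation = seg, gate = gate, model = model,
    division_times = if (is.null(raw$division_times)) {
      c(16, 20, 24, 36, 48, 72)
    } else raw$division_times,
    seed = if (is.null(raw$seed)) 1L else raw$seed,
    write_qc = isTRUE(raw$write_qc)
  )
}

#' Hash of a configuration
#'
#' MD5 of the canonical JSON serialisation (sorted keys, functions and
#' environments excluded): semantically identical configurations hash equal,
#' and any parameter change changes the hash.
#'
#' @param config Any (nested) list-like configuration object.
#' @return Lower-case hex MD5 string.
#' @export
config_hash <- function(config) {
  canonical <- function(x) {
    if (is.list(x)) {
      x <- unclass(x)
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, canonical)
    } else x
  }
  js <- jsonlite::toJSON(canonical(unclass(config)), auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(js), tmp)
  unname(tools::md5sum(tmp))
}

# derive a per-stage seed from the global seed (stable, < 2^31)
stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 1103 + 1299721 * stage_index) %%
               .Machine$integer.max)
}

pipeline_log <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (skipped when `input_fields` is supplied) -> segment ->
#' measure -> gate -> summarize -> stats -> model, writing stable CSV/JSON
#' file contracts under `config$outdir` and a run manifest
#' (`manifest.json`) last. Identical configuration and seed reproduce
#' identical tables. On stage failure the partial manifest is still written
#' and the error names the stage.
#'
#' @param config A [run_config()].
#' @param stop_after Last stage to execute: one of `"simulate"`,
#'   `"segment"`, `"gate"`, `"summarize"`, `"stats"`, `"model"` (default:
#'   run everything).
#' @return The manifest, invisibly (also written to
#'   `<outdir>/manifest.json`).
#' @export
run_pipeline <- function(config,
                         stop_after = c("model", "simulate", "segment",
                                        "gate", "summarize", "stats")) {
  stop_after <- match.arg(stop_after)
  stage_order <- c("simulate", "segment", "gate", "summarize", "stats",
                   "model")
  last_stage <- match(stop_after, stage_order)
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(outdir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  manifest <- list(
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("adipotrace")),
    seed = config$seed,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = list(), outputs = character(0)
  )
  flush_manifest <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  add_output <- function(...) {
    manifest$outputs <<- c(manifest$outputs, c(...))
  }
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      manifest$finished <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
      flush_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    elapsed <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    manifest$stages[[name]] <<- list(status = "ok", elapsed_s = elapsed)
    pipeline_log(name, paste0("done in ", elapsed, " s"))
    res
  }

  finish <- function() {
    manifest$finished <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    flush_manifest()
    invisible(manifest)
  }

  # -- simulate / load fields ------------------------------------------------
  sims <- run_stage("simulate", function() {
    if (!is.null(config$input_fields)) {
      lapply(config$input_fields, function(p) list(field = read_field(p),
                                                   truth = NULL))
    } else {
      design <- lapply(seq_along(config$design), function(i) {
        e <- config$design[[i]]
        e$config$seed <- stage_seed(config$seed, i)
        e
      })
      sims <- simulate_experiment(design)
      for (k in seq_along(sims)) {
        md <- sims[[k]]$field$metadata
        base <- file.path(img_dir, sprintf("field_%s_t%03d_%02d",
                                           md$well, round(md$timepoint),
                                           md$field_id))
        write_field(sims[[k]]$field, paste0(base, ".tif"))
        write_ground_truth(sims[[k]]$truth, paste0(base, "_labels.tif"),
                           paste0(base, "_truth.csv"))
        add_output(paste0(base, ".tif"), paste0(base, "_labels.tif"),
                   paste0(base, "_truth.csv"))
      }
      sims
    }
  })

  if (stop_after == "simulate") return(finish())

  # -- segment + measure -----------------------------------------------------
  records <- run_stage("segment", function() {
    recs <- lapply(seq_along(sims), function(k) {
      field <- sims[[k]]$field
      labels <- segment_nuclei(field$channels$nuclear, config$segmentation)
      if (config$write_qc) {
        qc <- file.path(outdir, sprintf("qc_%02d.png", k))
        write_qc_overlay(field$channels$nuclear, labels, qc)
        add_output(qc)
      }
      measure_nuclei(labels, field)
    })
    out <- do.call(rbind, recs)
    out$nucleus_id <- seq_len(nrow(out))  # unique across fields
    path <- file.path(outdir, "nuclei.csv")
    utils::write.csv(out, path, row.names = FALSE)
    add_output(path)
    out
  })

  if (stop_after == "segment") return(finish())

  # -- gate ------------------------------------------------------------------
  gated <- run_stage("gate", function() {
    gate <- config$gate
    if (is.null(gate)) {
      gate <- gate_config(
        gfp_ratio_cutoff = suggest_cutoff(records$ratio),
        marker_cutoff = suggest_cutoff(records$integrated_marker),
        provenance = "auto_log_valley"
      )
      pipeline_log("gate", sprintf(
        "auto cutoffs: ratio > %.4g, integrated marker > %.4g",
        gate$gfp_ratio_cutoff, gate$marker_cutoff))
    }
    manifest$gate <<- list(gfp_ratio_cutoff = gate$gfp_ratio_cutoff,
                           marker_cutoff = gate$marker_cutoff,
                           provenance = gate$provenance)
    g <- gate_cells(records, gate)
    path <- file.path(outdir, "nuclei_gated.csv")
    utils::write.csv(g, path, row.names = FALSE)
    add_output(path)
    g
  })

  if (stop_after == "gate") return(finish())

  # -- summarize -------------------------------------------------------------
  summaries <- run_stage("summarize", function() {
    s <- summarize_wells(gated)
    path <- file.path(outdir, "well_summaries.csv")
    utils::write.csv(s, path, row.names = FALSE)
    tc <- timecourse_table(s)
    tc_path <- file.path(outdir, "timecourse.csv")
    utils::write.csv(tc, tc_path, row.names = FALSE)
    add_output(path, tc_path)
    s
  })

  if (stop_after == "summarize") return(finish())

  # -- stats -----------------------------------------------------------------
  run_stage("stats", function() {
    key <- interaction(summaries$timepoint, summaries$condition, drop = TRUE)
    tests <- lapply(split(summaries, key), function(g) {
      a <- g$pct_marker_in_gfp_neg[!is.na(g$pct_marker_in_gfp_neg)]
      b <- g$pct_marker_in_gfp_pos[!is.na(g$pct_marker_in_gfp_pos)]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      cbind(data.frame(timepoint = g$timepoint[1],
                       condition = g$condition[1],
                       comparison = "pct_marker: gfp_neg vs gfp_pos"),
            two_sample_t_test(a, b))
    })
    tests <- do.call(rbind, tests)
    path <- file.path(outdir, "stats.csv")
    if (is.null(tests)) {
      tests <- data.frame(note = "no (timepoint, condition) group had >= 2 replicate wells per population")
    }
    utils::write.csv(tests, path, row.names = FALSE)
    add_output(path)
    tests
  })

  if (stop_after == "stats") return(finish())

  # -- model -----------------------------------------------------------------
  run_stage("model", function() {
    tr <- simulate_composition(config$model)
    tr_path <- file.path(outdir, "composition_trajectory.csv")
    utils::write.csv(tr, tr_path, row.names = FALSE)
    f0 <- config$model$other_0 / (config$model$other_0 +
                                    config$model$adipocyte_0)
    sw <- sweep_doubling_times(config$division_times, f0 = f0,
                               survival = config$model$survival,
                               n_days = config$model$n_days,
                               growth = config$model$growth)
    sw_path <- file.path(outdir, "doubling_time_sweep.csv")
    utils::write.csv(sw, sw_path, row.names = FALSE)
    plot_path <- file.path(outdir, "doubling_time_sweep.png")
    grDevices::png(plot_path, width = 700, height = 500)
    graphics::plot(sw$division_time_h, sw$final_pct, type = "b", pch = 19,
                   xlab = "doubling time (h)",
                   ylab = sprintf("%% proliferative lineage at day %d",
                                  config$model$n_days),
                   ylim = c(0, 100),
                   main = sprintf("initial fraction %.2g%%", 100 * f0))
    graphics::abline(h = 100 * f0, lty = 2)
    grDevices::dev.off()
    add_output(tr_path, sw_path, plot_path)
    sw
  })

  finish()
}
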