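# End-to-end pipeline: synthesize -> measure -> persistence -> lineage
# summaries -> simulator comparison, with a run manifest.

#' Default pipeline configuration
#'
#' @param out_dir Output directory for all stages.
#' @param seed Master seed; each stage derives its own child seeds.
#' @param n_cells Number of synthetic cells for the measurement stage.
#' @param n_traces Number of synthetic post-division traces.
#' @param n_founders Founders for the lineage and simulator stages.
#' @param n_portions,band_width,top_k Measurement settings.
#' @param detect_contrast,detect_snr Persistence detection thresholds.
#' @return A named list (class `pipeline_config`).
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_cells = 12L,
                            n_traces = 5L, n_founders = 500L,
                            n_portions = 63L, band_width = 3, top_k = 10L,
                            detect_contrast = 0.2, detect_snr = 2.0) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_cells = as.integer(n_cells),
              n_traces = as.integer(n_traces),
              n_founders = as.integer(n_founders),
              n_portions = as.integer(n_portions),
              band_width = as.numeric(band_width),
              top_k = as.integer(top_k),
              detect_contrast = as.numeric(detect_contrast),
              detect_snr = as.numeric(detect_snr))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of the [pipeline_config()] fields.
#' @param out_dir Output directory (overrides the file if given).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (is.null(y$out_dir)) stop("config must provide `out_dir`")
  do.call(pipeline_config, y)
}

#' Run the full synthetic-data pipeline
#'
#' Chains the package's stages on synthetic data: renders a set of
#' polarized/depolarized cells and measures their POME table; renders
#' post-division profile series and measures persistence; generates a
#' lineage record and summarizes it; and runs the simulator at the
#' division balance estimated from the lineage summary (the observed
#' amplifying fraction among meristemoid divisions). All outputs are
#' written under `config$out_dir` together with a `manifest.json`
#' recording seeds, parameters, and output file hashes. The run is fully
#' deterministic: re-running with the same config reproduces every file
#' byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # stage 1: synthesize and measure a field of cells
  pome <- stage("measure", {
    rows <- list()
    for (i in seq_len(config$n_cells)) {
      polarized <- i %% 2L == 1L
      p <- synth_cell_params(
        amplitude = if (polarized) 60 + 5 * i else 0,
        baseline = 10 + i, sigma = 0.25 + 0.01 * i,
        center = wrap_angle(0.5 * i), noise_sd = 2,
        cell_id = i, seed = config$seed + 100L + i)
      r <- render_cell_image(p)
      tab <- measure_polarity(r$image, r$mask,
                              n_portions = config$n_portions,
                              band_width = config$band_width,
                              top_k = config$top_k, timepoint = 0)
      tab$cell_id <- i
      rows[[i]] <- tab
    }
    do.call(rbind, rows)
  })
  pome_path <- file.path(config$out_dir, "pome_table.csv")
  write_pome_csv(pome, pome_path)
  paths <- c(paths, pome_path)

  # stage 2: persistence from synthetic post-division series
  pers <- stage("persistence", {
    series <- synth_series_params(seed = config$seed + 200L)
    lapply(seq_len(config$n_traces), function(i) {
      cell <- synth_cell_params(noise_sd = 5, cell_id = i,
                                seed = config$seed + 200L + 37L * i)
      ps <- synth_profile_series(series, cell)
      recs <- lapply(ps$profiles, polarity_record)
      tr <- persistence_trace(i, ps$frame_times, recs)
      measure_persistence(tr, config$detect_contrast, config$detect_snr)
    })
  })
  pers_path <- file.path(config$out_dir, "persistence.csv")
  write_persistence_csv(pers, pers_path)
  paths <- c(paths, pers_path)

  # stage 3: lineage record and summary
  summ <- stage("lineage", {
    lp <- synth_lineage_params(n_founders = config$n_founders,
                               p_amp = 0.5, p_spacing = 0.1,
                               max_steps = 8L, seed = config$seed + 300L)
    rec <- generate_lineage(lp)
    lin_path <- file.path(config$out_dir, "lineage.csv")
    write_lineage_csv(rec, lin_path)
    paths <<- c(paths, lin_path)
    summarize_divisions(rec)
  })
  summ_path <- file.path(config$out_dir, "lineage_summary.json")
  jsonlite::write_json(list(counts = as.list(summ$counts),
                            fractions = as.list(round(summ$fractions, 6)),
                            total_divisions = summ$total_divisions,
                            meristemoid_histogram =
                              as.list(summ$meristemoid_histogram),
                            stomatal_index = round(summ$stomatal_index, 6),
                            cell_counts = as.list(summ$cell_counts)),
                       summ_path, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, summ_path)

  # stage 4: simulator at the division balance observed in stage 3
  sim <- stage("simulate", {
    m_divs <- summ$counts[["amplifying"]] + summ$counts[["gmc_scd"]]
    p_amp_hat <- if (m_divs > 0) summ$counts[["amplifying"]] / m_divs else 0.5
    simulate_lineages(sim_params(n_founders = config$n_founders,
                                 p_amp = p_amp_hat,
                                 p_spacing = 0, max_rounds = 8L,
                                 seed = config$seed + 400L),
                      record = FALSE)
  })
  sim_path <- file.path(config$out_dir, "simulation.json")
  jsonlite::write_json(list(p_amp = sim$params$p_amp,
                            stomatal_index = round(sim$stomatal_index, 6),
                            expected_si = round(expected_si(sim$params$p_amp,
                                                            sim$params$max_rounds), 6),
                            total_cells = sim$total_cells,
                            composition = as.list(sim$composition)),
                       sim_path, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, sim_path)

  manifest <- list(package = "stomapolar",
                   version = as.character(utils::packageVersion("stomapolar")),
                   seed = config$seed,
                   config = unclass(config),
                   outputs = as.list(stats::setNames(
                     unname(tools::md5sum(paths)), basename(paths))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
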