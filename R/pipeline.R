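# CSV dialect: UTF-8, header row, one leading format-version comment line.
.cage_version <- "# musselpatch cage-table v1"
.env_version <- "# musselpatch env-series v1"

.numeric_cage_cols <- c("density_treatment", "D0", "D1", "N0", "N1",
                        "duration_days", "total_weight_start_g",
                        "total_weight_end_g", "Temp", "Chl", "Turb")

#' Read and write cage tables
#'
#' The cage-table dialect is a UTF-8 CSV with a header row and a leading
#' format-version comment line. Writing and re-reading a table is a
#' lossless round-trip of all columns. `read_cage_table()` validates the
#' schema (missing required columns are reported together) and reports
#' malformed numeric cells with their line numbers. Clamping of end
#' counts is deliberately not applied at parse time; it belongs to the
#' metrics stage ([derive_survival()]).
#'
#' @param records cage-record data.frame.
#' @param path CSV file path.
#' @return `read_cage_table()`: the records; `write_cage_table()`:
#'   `path`, invisibly.
#' @export
write_cage_table <- function(records, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.cage_version, con)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cage_table
#' @export
read_cage_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  skip <- as.integer(startsWith(lines[1], "#"))
  out <- utils::read.csv(text = lines[(skip + 1):length(lines)],
                         stringsAsFactors = FALSE)
  need <- c("run_id", .numeric_cage_cols)
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("cage table is missing required columns: ",
                         paste(miss, collapse = ", "))
  for (col in intersect(.numeric_cage_cols, names(out))) {
    if (!is.numeric(out[[col]])) {
      vals <- suppressWarnings(as.numeric(out[[col]]))
      bad <- which(is.na(vals) & !is.na(out[[col]]) & out[[col]] != "NA")
      if (length(bad)) stop(sprintf(
        "non-numeric value(s) in column '%s' at line(s) %s of %s", col,
        paste(bad + 1 + skip, collapse = ", "), path))
      out[[col]] <- vals
    }
  }
  out
}

#' Read and write environment series
#'
#' CSV with ISO-8601 UTC timestamps, a header row and a format-version
#' comment line.
#'
#' @param env a `mussel_env` data.frame.
#' @param path CSV file path.
#' @return `read_env_series()`: the series; `write_env_series()`:
#'   `path`, invisibly.
#' @export
write_env_series <- function(env, path) {
  out <- env
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.env_version, con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_env_series
#' @export
read_env_series <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  skip <- as.integer(startsWith(lines[1], "#"))
  out <- utils::read.csv(text = lines[(skip + 1):length(lines)],
                         stringsAsFactors = FALSE)
  out$timestamp <- as.POSIXct(out$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC")
  class(out) <- c("mussel_env", "data.frame")
  out
}

#' Read and write simulation configurations
#'
#' The configuration is one YAML document; [read_config()] validates it
#' on load via [sim_config()].
#'
#' @param config a `sim_config` object.
#' @param path YAML file path.
#' @return `read_config()`: a validated `sim_config`; `write_config()`:
#'   `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$runs <- lapply(as.list(x$runs), function(col)
    if (inherits(col, "Date")) as.character(col) else col)
  # named coefficient vectors must serialize as maps, full precision
  for (nm in c("survival_coeffs", "ci_coeffs", "ptoa_coeffs"))
    x[[nm]] <- as.list(x[[nm]])
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  runs <- as.data.frame(x$runs, stringsAsFactors = FALSE)
  if ("start_date" %in% names(runs)) runs$start_date <- as.Date(runs$start_date)
  sim_config(
    runs = runs,
    densities_kg_m2 = as.numeric(x$densities_kg_m2),
    replicates = x$replicates,
    plot_area_m2 = x$plot_area_m2,
    survival_coeffs = unlist(x$survival_coeffs),
    density_season_coeff = x$density_season_coeff,
    temp_ref_C = x$temp_ref_C,
    intracage_correlation = x$intracage_correlation,
    ci_coeffs = unlist(x$ci_coeffs), ci_log_sd = x$ci_log_sd,
    ptoa_coeffs = unlist(x$ptoa_coeffs), ptoa_log_sd = x$ptoa_log_sd,
    count_error_rate = x$count_error_rate,
    environment = do.call(env_params, x$environment),
    mask = do.call(mask_params, x$mask),
    seed = x$seed)
}

#' MD5 digest of a resolved configuration
#'
#' @param config a `sim_config` object.
#' @return The MD5 hex digest of the canonical YAML serialization.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

.pipeline_plots <- function(path, env, records, slopes_surv, slopes_ci) {
  grDevices::pdf(path, width = 8, height = 6)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
  dayf <- floor(env$day)
  for (ch in c("temperature_C", "chlorophyll_ug_l", "turbidity_FTU")) {
    daily <- tapply(env[[ch]], dayf, mean)
    graphics::plot(as.numeric(names(daily)), daily, type = "l",
                   xlab = "day", ylab = ch)
  }
  graphics::par(op)
  graphics::plot(records$D0, records$p, col = factor(records$run_id),
                 xlab = "starting density (kg m^-2)",
                 ylab = "standardized survival p")
  if ("PtoA" %in% names(records)) {
    m <- tapply(records$PtoA, records$density_treatment, mean)
    s <- tapply(records$PtoA, records$density_treatment, stats::sd)
    x <- as.numeric(names(m))
    graphics::plot(x, m, ylim = range(c(m - s, m + s)), pch = 19,
                   xlab = "starting density (kg m^-2)",
                   ylab = "PtoA (m^-1)")
    graphics::arrows(x, m - s, x, m + s, angle = 90, code = 3, length = 0.03)
  }
  for (sl in list(slopes_surv, slopes_ci)) {
    ok <- is.finite(sl$M)
    if (sum(ok) < 2) next
    idx <- seq_len(nrow(sl))
    graphics::plot(idx[ok], sl$M[ok], pch = 19,
                   ylim = range(c(sl$M[ok] - sl$se_M[ok],
                                  sl$M[ok] + sl$se_M[ok],
                                  sl$threshold[1])),
                   xlab = "run (seasonal order)", ylab = "slope M")
    graphics::arrows(idx[ok], sl$M[ok] - sl$se_M[ok], idx[ok],
                     sl$M[ok] + sl$se_M[ok], angle = 90, code = 3,
                     length = 0.03)
    graphics::abline(h = sl$threshold[1], lty = 2)
  }
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> metrics -> models -> slopes -> report as one
#' reproducible, seeded run: generates the environment series and cage
#' experiment (with condition indices, patch-shape ratios and optional
#' rasterized masks), derives the standardized survival columns, fits
#' the three response models, computes the per-run slope profiles, and
#' writes every stage product plus a run manifest into `out_dir`. One
#' global seed deterministically spawns per-stage child seeds, so
#' identical `(config, seed)` give byte-identical numeric outputs. If a
#' stage fails, the manifest records it and downstream stages are
#' skipped.
#'
#' @param config a [sim_config()] object.
#' @param seed integer global seed (default `config$seed`).
#' @param out_dir output directory (created if needed).
#' @param stages subset of `c("simulate", "metrics", "fit", "slopes",
#'   "report")`; dropping "simulate" re-analyzes the cage table already
#'   present in `out_dir`.
#' @param masks rasterize and measure per-cage cover masks (slower).
#' @param plots write a PDF of diagnostic figures.
#' @return The run manifest (list), invisibly written to
#'   `manifest.json`: config hash, seed, per-stage outputs, package
#'   version, timestamps, and the failed stage if any.
#' @export
run_pipeline <- function(config = sim_config(), seed = config$seed, out_dir,
                         stages = c("simulate", "metrics", "fit", "slopes",
                                    "report"),
                         masks = TRUE, plots = TRUE) {
  validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config_hash = config_hash(config), seed = as.integer(seed),
    software_version = as.character(utils::packageVersion("musselpatch")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    stage_outputs = list(), failed_stage = NULL)
  out <- function(...) file.path(out_dir, ...)
  save_manifest <- function() jsonlite::write_json(
    manifest, out("manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")

  env <- NULL; records <- NULL
  slopes_surv <- NULL; slopes_ci <- NULL
  run_stage <- function(name, body) {
    if (!name %in% stages || !is.null(manifest$failed_stage)) return()
    res <- tryCatch({ body(); NULL }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      warning(sprintf("stage '%s' failed: %s", name, res))
      manifest$failed_stage <<- list(stage = name, message = res)
    }
    save_manifest()
  }

  run_stage("simulate", function() {
    env <<- gen_environment(config, seed = seed + 1L)
    rec <- gen_cage_experiment(config, env, seed = seed + 2L)
    rec <- gen_condition(config, rec, seed = seed + 3L)
    records <<- gen_ptoa(config, rec, seed = seed + 4L)
    write_env_series(env, out("environment.csv"))
    write_cage_table(records, out("cages.csv"))
    manifest$stage_outputs$simulate <<- c(out("environment.csv"),
                                          out("cages.csv"))
  })

  run_stage("metrics", function() {
    if (is.null(records)) records <<- read_cage_table(out("cages.csv"))
    records <<- derive_survival(records)
    if (masks) {
      mdir <- out("masks")
      dir.create(mdir, showWarnings = FALSE)
      mm <- lapply(seq_len(nrow(records)), function(i) {
        mk <- gen_patch_mask(records$density_treatment[i], config$mask,
                             seed = seed + 10000L + i,
                             target_ptoa_m = records$PtoA[i])
        pth <- file.path(mdir, sprintf("mask_run%s_d%02d_r%d.png",
                                       records$run_id[i],
                                       round(records$density_treatment[i]),
                                       records$replicate[i]))
        write_mask(mk, pth, config$mask$scale_mm_per_px)
        pm <- patch_metrics(mk, config$mask$scale_mm_per_px)
        pm$mask_file <- basename(pth)
        pm
      })
      mtab <- do.call(rbind, mm)
      records$ptoa_measured_m <<- mtab$ptoa_m
      utils::write.csv(cbind(records[c("run_id", "replicate",
                                       "density_treatment")], mtab),
                       out("mask_metrics.csv"), row.names = FALSE)
    }
    write_cage_table(records, out("cages_derived.csv"))
    manifest$stage_outputs$metrics <<- out("cages_derived.csv")
  })

  run_stage("fit", function() {
    # always refit from the written table so an analysis-only run is
    # bit-identical to the full run
    records <<- read_cage_table(out("cages_derived.csv"))
    tabs <- list(model1_survival = coef_table(fit_survival_model(records)),
                 model2_ptoa = coef_table(fit_ptoa_model(records)),
                 model3_ci = coef_table(fit_ci_model(records)))
    for (nm in names(tabs))
      utils::write.csv(tabs[[nm]], out(paste0(nm, ".csv")), row.names = FALSE)
    manifest$stage_outputs$fit <<- out(paste0(names(tabs), ".csv"))
  })

  run_stage("slopes", function() {
    if (is.null(records)) records <<- read_cage_table(out("cages_derived.csv"))
    ids <- config$runs$run_id
    slopes_surv <<- do.call(rbind, lapply(ids, function(id)
      survival_slope(records[records$run_id == id, ])))
    slopes_ci <<- do.call(rbind, lapply(ids, function(id)
      ci_slope(records[records$run_id == id, ])))
    prof <- seasonal_profile(slopes_surv, config$runs)
    utils::write.csv(prof$profile, out("slopes_survival.csv"),
                     row.names = FALSE)
    utils::write.csv(slopes_ci, out("slopes_ci.csv"), row.names = FALSE)
    manifest$stage_outputs$slopes <<- c(out("slopes_survival.csv"),
                                        out("slopes_ci.csv"))
    manifest$stage_outputs$concavity <<- prof$concavity
  })

  run_stage("report", function() {
    if (plots) {
      if (is.null(env) && file.exists(out("environment.csv")))
        env <<- read_env_series(out("environment.csv"))
      .pipeline_plots(out("report.pdf"), env, records, slopes_surv,
                      slopes_ci)
      manifest$stage_outputs$report <<- out("report.pdf")
    }
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  save_manifest()
  invisible(manifest)
}
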