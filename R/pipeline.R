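## Pipeline orchestration: a single YAML config drives
## read -> detect -> chains -> lifecycle -> response / spectrum,
## with provenance (config hash, package version) embedded in every output.

cr_default_config <- function() {
  list(
    input = list(path = NULL, format = "auto"),
    hbond = list(r_HO_max = 2.6, r_OO_max = 3.5, angle_min = 140),
    field = list(amplitude = 0, frequency_GHz = 1, axis = c(0, 0, 1),
                 frames_per_cycle = 100),
    analyses = c("census", "lifecycle"),
    temperature = 300,
    seed = 1,
    output_dir = ".",
    log_level = "info"
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML config (or takes a list), fills defaults, normalizes units
#' (GHz to rad/ps happens once, here, via [cr_field()]) and returns either a
#' normalized config or stops with an itemized error list.
#'
#' @param config path to a YAML file, or a named list.
#' @return an object of class `cr_config`: the normalized list with
#'   `criteria` ([hbond_criteria()]), `field_spec` ([cr_field()] or `NULL`
#'   when no response analysis is configured) and `hash` filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  def <- cr_default_config()
  errors <- character(0)
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    errors <- c(errors, paste("unknown config key(s):",
                              paste(unknown, collapse = ", ")))
  merged <- utils::modifyList(def, config[setdiff(names(config), unknown)])
  for (blk in c("input", "hbond", "field")) {
    bad <- setdiff(names(merged[[blk]]), names(def[[blk]]))
    if (length(bad))
      errors <- c(errors, sprintf("unknown key(s) in '%s': %s", blk,
                                  paste(bad, collapse = ", ")))
  }
  hb <- merged$hbond
  for (k in c("r_HO_max", "r_OO_max")) {
    if (!is.numeric(hb[[k]]) || hb[[k]] <= 0)
      errors <- c(errors, sprintf("hbond.%s must be a positive number", k))
  }
  if (!is.numeric(hb$angle_min) || hb$angle_min <= 0 || hb$angle_min > 180)
    errors <- c(errors, "hbond.angle_min must lie in (0, 180]")
  fd <- merged$field
  if (is.character(fd$frequency_GHz)) {
    # accept "0.5 GHz" style values
    m <- regmatches(fd$frequency_GHz,
                    regexec("^\\s*([0-9.eE+-]+)\\s*GHz\\s*$", fd$frequency_GHz))[[1]]
    if (length(m) == 2)
      fd$frequency_GHz <- as.numeric(m[2])
    else
      errors <- c(errors, "field.frequency_GHz must be a number or '<x> GHz'")
    merged$field <- fd
  }
  if (is.numeric(fd$frequency_GHz) && fd$frequency_GHz <= 0)
    errors <- c(errors, "field.frequency_GHz must be positive")
  if (is.numeric(fd$amplitude) && fd$amplitude < 0)
    errors <- c(errors, "field.amplitude must be >= 0")
  bad_an <- setdiff(merged$analyses,
                    c("census", "lifecycle", "response", "spectrum"))
  if (length(bad_an))
    errors <- c(errors, paste("unknown analyses:", paste(bad_an, collapse = ", ")))
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  # canonicalize: drop NULL-valued entries so validation is idempotent
  # (modifyList removes NULLs, so a re-validated config must hash identically)
  merged$input <- merged$input[!vapply(merged$input, is.null, logical(1))]
  merged$criteria <- hbond_criteria(hb$r_HO_max, hb$r_OO_max, hb$angle_min)
  merged$field_spec <- cr_field(fd$amplitude, fd$frequency_GHz,
                                axis = fd$axis,
                                frames_per_cycle = fd$frames_per_cycle)
  merged$hash <- rlang::hash(merged[setdiff(names(merged), "hash")])
  structure(merged, class = "cr_config")
}

write_tsv_with_provenance <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chainrelax %s config %s",
                     as.character(utils::packageVersion("chainrelax")), hash),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes read -> hydrogen-bond detection -> chain partitioning and then
#' the configured analyses in order, writing stage tables (TSV) and a JSON
#' report into the output directory. Outputs are deterministic given the
#' same config and inputs; every file embeds the config hash.
#'
#' @param config a `cr_config` from [validate_config()] (or anything it
#'   accepts).
#' @param trajectory optionally, an already-loaded [cr_trajectory()]
#'   (bypasses `config$input$path`).
#' @return the run report (list), invisibly written as `report.json`.
#' @export
run_pipeline <- function(config, trajectory = NULL) {
  if (inherits(config, "cr_config"))
    config <- unclass(config)[setdiff(names(config),
                                      c("criteria", "field_spec", "hash"))]
  config <- validate_config(config)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  report <- list(package = "chainrelax",
                 version = as.character(utils::packageVersion("chainrelax")),
                 config_hash = config$hash,
                 criteria = unclass(config$criteria),
                 stages = list())
  stage <- function(name, fun) {
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    report$stages[[name]] <<- if (res$ok) "ok" else paste("failed:", res$error)
    if (!res$ok) NULL else res$value
  }

  traj <- if (!is.null(trajectory)) trajectory else
    stage("read", function() {
      if (is.null(config$input$path)) stop("no input path configured")
      read_trajectory(config$input$path, config$input$format,
                      field = config$field_spec)
    })
  if (is.null(traj)) {
    report$stages[["read"]] <- report$stages[["read"]] %||% "failed: no trajectory"
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(report))
  }
  if (length(traj$frames) == 0L) stop("validation error: empty trajectory")

  partitions <- stage("detect", function() {
    lapply(traj$frames, function(f)
      find_chains(detect_hbonds(f, traj$topology, config$criteria)))
  })
  times <- frame_times(traj)

  if ("census" %in% config$analyses && !is.null(partitions)) {
    stage("census", function() {
      cen <- chain_census(partitions, times)
      write_tsv_with_provenance(cen, file.path(out, "census.tsv"), config$hash)
      report$census <<- list(mean_lone_fraction = mean(cen$lone_fraction),
                             mean_n_chains = mean(cen$n_chains))
      cen
    })
  }
  if ("lifecycle" %in% config$analyses && !is.null(partitions)) {
    stage("lifecycle", function() {
      trk <- track_chains(partitions, times)
      ev <- trk$events
      ev_out <- data.frame(time = ev$time, type = ev$type, track = ev$track,
                           molecules = vapply(ev$molecules, paste,
                                              character(1), collapse = ","))
      write_tsv_with_provenance(ev_out, file.path(out, "events.tsv"), config$hash)
      write_tsv_with_provenance(trk$tracks, file.path(out, "tracks.tsv"),
                                config$hash)
      report$lifecycle <<- list(n_tracks = nrow(trk$tracks),
                                events = as.list(table(ev$type)))
      cl <- chain_lifetimes(trk)
      if (sum(!cl$censored) >= 10) {
        fit <- fit_lifetime_distribution(cl$duration, cl$censored)
        report$lifecycle$chain_lifetime_mean_ps <<- fit$mean
        report$lifecycle$chain_lifetime_ci <<- fit$ci
      }
      li <- lone_intervals(partitions, times)
      if (sum(!li$censored) >= 10) {
        fit <- fit_lifetime_distribution(li$duration, li$censored)
        report$lifecycle$lone_lifetime_mean_ps <<- fit$mean
        report$lifecycle$lone_lifetime_ci <<- fit$ci
      }
      trk
    })
  }
  if ("response" %in% config$analyses) {
    stage("response", function() {
      ang <- vapply(traj$frames, function(f)
        mean(bond_angle_to_axis(f, traj$topology, "OH",
                                axis = config$field_spec$axis)), numeric(1))
      n_use <- length(ang) %/% config$field_spec$frames_per_cycle *
        config$field_spec$frames_per_cycle
      ca <- cycle_average(ang[seq_len(n_use)], config$field_spec)
      fit <- fit_sinusoid(ca)
      write_tsv_with_provenance(
        data.frame(phase_time = ca$phase_time, mean_angle = ca$mean, se = ca$se),
        file.path(out, "oh_angle_cycle.tsv"), config$hash)
      report$response <<- list(freq_GHz = config$field_spec$frequency_GHz,
                               A = fit$A, B = fit$B, absA = fit$absA,
                               absB = fit$absB, ci_A = fit$ci_A,
                               ci_B = fit$ci_B, offset = fit$offset)
      fit
    })
  }
  if ("spectrum" %in% config$analyses) {
    stage("spectrum", function() {
      ps <- polarization_series(traj)
      dt <- if (length(times) > 1) times[2] - times[1] else 1
      ac <- polarization_autocorrelation(ps$Pz, dt = dt)
      vol <- prod(traj$frames[[1]]$box)
      sp <- fdt_spectrum(ac, temperature = config$temperature, volume = vol)
      write_tsv_with_provenance(
        data.frame(freq_GHz = sp$freq_GHz, chi_real = sp$chi_real,
                   chi_imag = sp$chi_imag),
        file.path(out, "spectrum.tsv"), config$hash)
      report$spectrum <<- list(chi0 = attr(sp, "chi0"))
      sp
    })
  }
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
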