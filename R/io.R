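#' Read and write the package's CSV formats
#'
#' Plain-CSV round-trips for the tabular interchange formats: agent states
#' (`time_min,agent_id,lineage,colour,rare_mark,site_dv,site_ax,x_um,y_um`,
#' with `x_um = (site_dv - 0.5) * Delta` and `y_um = (site_ax - 0.5) *
#' Delta`), cell tracks (`track_id,time_min,x_um,y_um`), point patterns
#' (`x_um,y_um` plus a sidecar JSON `{x0,y0,x1,y1}` holding the observation
#' window), and event logs.
#'
#' @param snapshots A snapshot tibble from [simulate_colonization()] (columns
#'   `time_min`, `agent_id`, `lineage`, `colour`, `rare_mark`, `site_dv`,
#'   `site_ax`).
#' @param tracks,points,events Tibbles in the corresponding format.
#' @param path Output/input file path (`.csv`).
#' @param lattice_spacing_um Spacing used for the site-to-um conversion.
#' @param window For `write_point_pattern()`: rectangle `c(x0,y0,x1,y1)`
#'   (taken from the pattern's `"window"` attribute when `NULL`).
#' @return Readers return tibbles (point patterns carry a `"window"`
#'   attribute); writers return the path invisibly.
#' @name io_csv
NULL

#' @rdname io_csv
#' @export
write_agent_csv <- function(snapshots, path, lattice_spacing_um = 38) {
  out <- dplyr::mutate(
    snapshots,
    x_um = (.data$site_dv - 0.5) * lattice_spacing_um,
    y_um = (.data$site_ax - 0.5) * lattice_spacing_um
  )
  out <- out[c("time_min", "agent_id", "lineage", "colour", "rare_mark",
               "site_dv", "site_ax", "x_um", "y_um")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io_csv
#' @export
read_agent_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' @rdname io_csv
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(tracks[c("track_id", "time_min", "x_um", "y_um")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io_csv
#' @export
read_tracks_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' @rdname io_csv
#' @export
write_point_pattern <- function(points, path, window = NULL) {
  window <- resolve_window(points, window)
  utils::write.csv(points[c("x_um", "y_um")], path, row.names = FALSE,
                   quote = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(x0 = window[1], y0 = window[2], x1 = window[3], y1 = window[4]),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname io_csv
#' @export
read_point_pattern <- function(path) {
  pts <- tibble::as_tibble(utils::read.csv(path))
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(sidecar)) {
    w <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(pts, "window") <- c(w$x0, w$y0, w$x1, w$y1)
  }
  pts
}

#' @rdname io_csv
#' @export
write_event_csv <- function(events, path) {
  out <- dplyr::mutate(
    events,
    detail = paste0("(", .data$x1, ",", .data$y1, ")->(", .data$x2, ",",
                    .data$y2, ")")
  )
  utils::write.csv(out[c("time_min", "kind", "executed", "agent_id", "detail")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a domain state as a portable greymap (PGM, P2)
#'
#' One pixel per lattice site (rows = dorsoventral, dorsal at the top;
#' columns = axial). Grey levels: empty sites white (255); +1-coloured agents
#' light grey (200); -1-coloured agents black (0); unlabelled agents
#' mid-grey (120); rare-marked agents black (0).
#'
#' @param state A `domain_state`.
#' @param path Output `.pgm` path.
#' @return The path, invisibly.
#' @export
write_pgm <- function(state, path) {
  img <- matrix(255L, state$n_sites_dv, state$n_sites_axial)
  ag <- state$agents
  if (nrow(ag) > 0) {
    ij <- cbind(ag$site_dv, ag$site_ax)
    lv <- ifelse(is.na(ag$colour), 120L, ifelse(ag$colour > 0, 200L, 0L))
    lv[ag$rare_mark == 1L] <- 0L
    img[ij] <- lv
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  apply(img, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

# Greyscale PGM of a numeric matrix scaled to 0..255 (heatmaps).
write_pgm_matrix <- function(mat, path) {
  rng <- range(mat, finite = TRUE)
  scl <- if (diff(rng) > 0) (mat - rng[1]) / diff(rng) else mat * 0
  img <- round(255 * scl)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  apply(img, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

config_defaults <- function() {
  list(
    params = sim_params(),
    scenario = list(name = "wildtype", k = NULL, balanced = TRUE),
    analysis = character(0),
    sweep = NULL,
    replicates = 1L,
    base_seed = 1L
  )
}

#' Load an experiment configuration
#'
#' Reads a YAML configuration whose top-level keys are the simulation
#' parameter names ([sim_params()] fields), an optional `scenario` block
#' (`name`, plus `k`/`balanced` for chimeras), an optional `analysis` list
#' (any of `"stripe"`, `"lineage"`, `"belly_spot"`), an optional `sweep`
#' block (`pm_multipliers`, `tc_hours`, `reps`), `replicates`, and
#' `base_seed`. Missing keys take the wildtype defaults; unknown keys are
#' rejected by name; invalid values raise the corresponding [sim_params()]
#' validation error.
#'
#' @param path Path to a YAML file (an empty file yields the full default
#'   configuration).
#' @return An `experiment_config` list with elements `params`, `scenario`,
#'   `analysis`, `sweep`, `replicates`, `base_seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  param_keys <- setdiff(names(formals(sim_params)), "")
  known <- c(param_keys, "scenario", "analysis", "sweep", "replicates",
             "base_seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- config_defaults()
  pargs <- raw[intersect(names(raw), param_keys)]
  cfg$params <- do.call(sim_params, pargs)
  if (!is.null(raw$scenario)) {
    sc <- raw$scenario
    if (is.character(sc)) sc <- list(name = sc)
    sc$name <- match.arg(sc$name,
                         c("wildtype", "chimera", "rare_clone", "cheeseman"))
    bad <- setdiff(names(sc), c("name", "k", "balanced"))
    if (length(bad) > 0)
      stop("unknown scenario keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    cfg$scenario <- utils::modifyList(cfg$scenario, sc)
  }
  if (!is.null(raw$analysis)) {
    an <- unlist(raw$analysis)
    bad <- setdiff(an, c("stripe", "lineage", "belly_spot"))
    if (length(bad) > 0)
      stop("unknown analysis requests: ", paste(bad, collapse = ", "),
           call. = FALSE)
    cfg$analysis <- an
  }
  if (!is.null(raw$sweep)) {
    sw <- raw$sweep
    bad <- setdiff(names(sw), c("pm_multipliers", "tc_hours", "reps"))
    if (length(bad) > 0)
      stop("unknown sweep keys: ", paste(bad, collapse = ", "), call. = FALSE)
    cfg$sweep <- list(
      pm_multipliers = as.numeric(unlist(sw$pm_multipliers)),
      tc_hours = as.numeric(unlist(sw$tc_hours)),
      reps = if (is.null(sw$reps)) 10L else as.integer(sw$reps)
    )
  }
  if (!is.null(raw$replicates)) {
    cfg$replicates <- as.integer(raw$replicates)
    if (cfg$replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  }
  if (!is.null(raw$base_seed)) cfg$base_seed <- as.integer(raw$base_seed)
  structure(cfg, class = "experiment_config")
}

#' Run a configured experiment and write its result bundle
#'
#' Runs `replicates` seeded realizations of the configured scenario
#' (replicate `r` uses seed `base_seed + r`), writing per-replicate agent
#' snapshot CSVs and PGM renders, any requested analyses (averaged stripe
#' spectrum JSON plus per-replicate clonal-signal CSVs; lineage-dominance
#' JSON; belly-spot JSON), an optional sensitivity-sweep CSV and PGM heatmap,
#' and a `manifest.json` recording parameters, scenario, seeds, package and R
#' versions, and all outputs (relative paths; no timestamps, so identical
#' configurations yield byte-identical manifests).
#'
#' @param config An `experiment_config` from [load_config()].
#' @param output_dir Directory to create/write into.
#' @param record_events Also write per-replicate event-log CSVs.
#' @return The manifest (a list), invisibly.
#' @export
run_experiment <- function(config, output_dir, record_events = FALSE) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(output_dir))
    stop("cannot create output directory: ", output_dir, call. = FALSE)
  params <- config$params
  outputs <- character(0)
  emit <- function(name) {
    outputs <<- c(outputs, name)
    file.path(output_dir, name)
  }
  seeds <- config$base_seed + seq_len(config$replicates)
  signals <- list()
  lineage_rows <- list()
  spot_rows <- list()
  for (r in seq_len(config$replicates)) {
    p <- params
    p$rng_seed <- as.integer(seeds[r])
    sim <- simulate_colonization(
      p, scenario = config$scenario$name,
      chimera_k = if (isTRUE(config$scenario$balanced)) NULL else config$scenario$k,
      record_events = record_events
    )
    tag <- sprintf("rep_%03d", r)
    write_agent_csv(sim$snapshots, emit(paste0(tag, "_agents.csv")),
                    lattice_spacing_um = params$lattice_spacing_um)
    write_pgm(sim$final_state, emit(paste0(tag, "_render.pgm")))
    if (record_events)
      write_event_csv(sim$events, emit(paste0(tag, "_events.csv")))
    if ("stripe" %in% config$analysis) {
      if (config$scenario$name != "chimera")
        stop("stripe analysis requires the chimera scenario", call. = FALSE)
      sig <- clonal_signal(sim$final_state)
      utils::write.csv(
        data.frame(axial_site = sig$site_ax, signal = sig$signal),
        emit(paste0(tag, "_clonal_signal.csv")), row.names = FALSE,
        quote = FALSE
      )
      signals[[r]] <- sig
    }
    if ("lineage" %in% config$analysis) {
      ls <- lineage_stats(sim$final_state, k = min(2L, params$n_founders))
      lineage_rows[[r]] <- list(replicate = r, total = ls$total,
                                top_k = ls$k, top_k_share = ls$top_k_share)
    }
    if ("belly_spot" %in% config$analysis) {
      bs <- belly_spot(sim$final_state,
                       lattice_spacing_um = params$lattice_spacing_um)
      spot_rows[[r]] <- list(replicate = r, present = bs$present,
                             area_sites = bs$area_sites,
                             area_um2 = bs$area_um2)
    }
  }
  if (length(signals) > 0) {
    sp <- stripe_intensity(signals)
    jsonlite::write_json(
      list(stripe_intensity = sp$stripe_intensity,
           dominant_frequency = sp$dominant_frequency,
           n_signals = sp$n_signals, signal_length = sp$signal_length,
           spectrum = sp$spectrum),
      emit("stripe_spectrum.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "columns"
    )
  }
  if (length(lineage_rows) > 0) {
    jsonlite::write_json(
      list(replicates = lineage_rows,
           mean_top_k_share =
             mean(vapply(lineage_rows, `[[`, 1, "top_k_share"))),
      emit("lineage.json"), auto_unbox = TRUE, digits = NA
    )
  }
  if (length(spot_rows) > 0) {
    jsonlite::write_json(
      list(replicates = spot_rows,
           belly_spot_probability =
             mean(vapply(spot_rows, `[[`, TRUE, "present"))),
      emit("belly_spot.json"), auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(config$sweep)) {
    sw <- sensitivity_sweep(
      pm_multipliers = config$sweep$pm_multipliers,
      tc_hours = config$sweep$tc_hours,
      reps = config$sweep$reps, params = params,
      base_seed = config$base_seed
    )
    utils::write.csv(
      data.frame(pm_multiplier = sw$pm_multiplier, Tc_hours = sw$Tc_hours,
                 colonization_probability = sw$colonization_probability,
                 reps = sw$reps),
      emit("sweep.csv"), row.names = FALSE, quote = FALSE
    )
    heat <- matrix(sw$colonization_probability,
                   nrow = length(config$sweep$pm_multipliers))
    write_pgm_matrix(heat, emit("sweep_heatmap.pgm"))
  }
  manifest <- list(
    params = unclass(params)[!vapply(unclass(params), is.null, TRUE)],
    scenario = config$scenario[!vapply(config$scenario, is.null, TRUE)],
    analysis = as.list(config$analysis),
    replicates = config$replicates,
    base_seed = config$base_seed,
    seeds = seeds,
    versions = list(
      melanosim = as.character(utils::packageVersion("melanosim")),
      r = paste(R.version$major, R.version$minor, sep = ".")
    ),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
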