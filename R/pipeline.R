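## End-to-end orchestration: simulate or load matches, preprocess, build the
## state variable, run the return-map segmentation per scene, and estimate
## hierarchical transition statistics per group, with deterministic reports.

#' Pipeline configuration
#'
#' All parameters of an end-to-end run.  Every run's resolved configuration
#' is embedded in the report (and written beside outputs), so results are
#' reproducible from the report alone.
#'
#' @param seed integer master seed (mandatory; every stochastic stage derives
#'   from it).
#' @param simulate `NULL` to analyze `inputs`, or a list of generator
#'   settings; see Details.
#' @param inputs data frame with columns `path` (trajectory CSV), `group`,
#'   optional `match_id`, optional `exclusions` (CSV of `start_s`, `end_s`).
#' @param filter_order,cutoff_hz Butterworth settings (4, 6 Hz).
#' @param tau delay in seconds, or `"auto"` for [select_tau()] (default 0.1).
#' @param weight composite-state weight (default 0.5).
#' @param close_m absolute close-approach scene-cut threshold in meters;
#'   `NULL` uses the `close_quantile` quantile of negative-peak IPD.
#' @param close_quantile default 0.25.
#' @param min_pos_peaks minimal positive peaks per scene (default 4).
#' @param bin_width histogram bin width (default 0.05).
#' @param include_intermittency include peaks of accepted exp/log fits in the
#'   histogram and labeling (default `FALSE`: linear fits only).
#' @param analysis a [retmap_config()].
#' @param out_dir optional output directory.
#' @details `simulate` entries (with defaults):
#'   `n_matches` (3) per group, `scenes_per_match` (6),
#'   `groups` (`c("expert", "intermediate")`),
#'   `n_regimes_range` (1:3) planted regimes per scene,
#'   `classes` (`c("Aa","Ar","Ra","Rr")`) planted class pool,
#'   `noise_sigma` (0.01) observation noise, and the scene-rendering
#'   parameters of [synthetic_spec()] (`oscillation_period`, `sampling_rate`,
#'   `base_m`, `gain_m`, `strike_level`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed, simulate = list(), inputs = NULL,
                            filter_order = 4, cutoff_hz = 6, tau = 0.1,
                            weight = 0.5, close_m = NULL, close_quantile = 0.25,
                            min_pos_peaks = 4, bin_width = 0.05,
                            include_intermittency = FALSE,
                            analysis = retmap_config(min_prominence = 0.012),
                            out_dir = NULL) {
  if (!is_number(seed)) stopf("seed is mandatory")
  if (!is.null(simulate)) {
    defaults <- list(n_matches = 3, scenes_per_match = 6,
                     groups = c("expert", "intermediate"),
                     n_regimes_range = 1:3,
                     classes = c("Aa", "Ar", "Ra", "Rr"),
                     noise_sigma = 0.01, oscillation_period = 2,
                     sampling_rate = 100, base_m = 0.5, gain_m = 2,
                     strike_level = 0.02)
    unknown <- setdiff(names(simulate), names(defaults))
    if (length(unknown)) stopf("unknown simulate settings: %s",
                               paste(unknown, collapse = ", "))
    simulate <- utils::modifyList(defaults, simulate)
  }
  structure(list(seed = as.integer(seed), simulate = simulate, inputs = inputs,
                 filter_order = filter_order, cutoff_hz = cutoff_hz, tau = tau,
                 weight = weight, close_m = close_m,
                 close_quantile = close_quantile,
                 min_pos_peaks = min_pos_peaks, bin_width = bin_width,
                 include_intermittency = include_intermittency,
                 analysis = analysis, out_dir = out_dir),
            class = "pipeline_config")
}

simulate_matches <- function(cfg) {
  sim <- cfg$simulate
  out <- list()
  mseed <- cfg$seed
  for (g in seq_along(sim$groups)) {
    for (m in seq_len(sim$n_matches)) {
      mseed <- (mseed + 7919L) %% .Machine$integer.max
      match_id <- sprintf("%s_%02d", sim$groups[g], m)
      res <- with_seed(mseed, {
        regimes <- list(); scenes <- list()
        for (s in seq_len(sim$scenes_per_match)) {
          nr <- sample(sim$n_regimes_range, 1)
          rg <- random_scene_regimes(nr, classes = sim$classes)
          scenes[[s]] <- length(regimes) + seq_along(rg)
          regimes <- c(regimes, rg)
        }
        spec <- synthetic_spec(
          regimes, scenes = scenes,
          oscillation_period = sim$oscillation_period,
          sampling_rate = sim$sampling_rate,
          noise_sigma = sim$noise_sigma,
          seed = sample.int(.Machine$integer.max - 1L, 1),
          base_m = sim$base_m, gain_m = sim$gain_m,
          strike_level = sim$strike_level)
        generate_match(spec, match_id = match_id, group = sim$groups[g])
      })
      res$spec_seed <- mseed
      out[[match_id]] <- res
    }
  }
  out
}

load_matches <- function(cfg) {
  inp <- cfg$inputs
  if (is.null(inp) || !nrow(inp)) stopf("no inputs configured")
  out <- list()
  for (i in seq_len(nrow(inp))) {
    if (!file.exists(inp$path[i])) stopf("input not found: %s", inp$path[i])
    id <- if ("match_id" %in% names(inp)) inp$match_id[i] else
      sub("\\.csv$", "", basename(inp$path[i]))
    traj <- read_trajectory_csv(inp$path[i], match_id = id, group = inp$group[i])
    excl <- NULL
    if ("exclusions" %in% names(inp) && !is.na(inp$exclusions[i]) &&
        nzchar(inp$exclusions[i])) {
      excl <- read.csv(inp$exclusions[i])
    }
    out[[id]] <- list(traj = traj, truth = NULL, exclusions = excl)
  }
  out
}

## peaks covered by accepted linear (optionally also exp/log) fits, as
## contiguous runs of peak indices within one scene's peak sequence
covered_runs <- function(seg, include_intermittency = FALSE) {
  fits <- Filter(function(f) include_intermittency || f$family == "linear",
                 seg$fits)
  if (!length(fits)) return(list())
  covered <- sort(unique(unlist(lapply(fits, function(f)
    f$start:(f$start + f$length)))))   # map points start..start+L-1 -> peaks
  splits <- cumsum(c(1L, diff(covered) != 1L))
  unname(split(covered, splits))
}

#' Run the full analysis pipeline
#'
#' simulate/load -> low-pass filter -> IPD -> scenes -> state variable ->
#' per-scene return-map segmentation -> per-match F/N labeling -> per-group
#' second-/third-order transitions -> group comparison.  Deterministic given
#' the configuration (including its seed); when `out_dir` is set, the report,
#' the per-fit table and the resolved configuration are written there.
#'
#' @param config a [pipeline_config()].
#' @return a `run_report` list: `config`, `n_scenes`, `fits` (data frame),
#'   `class_by_length` (class x window-length counts),
#'   `functions_per_scene` (distinct accepted fits per analyzed scene),
#'   `thresholds` (per match), `transitions` (per group: order-2/order-3
#'   models), `comparison` (Fisher contrasts, first two groups), `truth`
#'   (per-match ground truth when simulated).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  matches <- if (!is.null(config$simulate)) simulate_matches(config)
             else load_matches(config)

  all_segs <- list()
  match_info <- list()
  for (id in names(matches)) {
    mt <- matches[[id]]
    traj <- lowpass_positions(mt$traj, config$filter_order, config$cutoff_hz)
    ipd <- compute_ipd(traj)
    close_m <- config$close_m
    if (is.null(close_m) && !is.null(config$simulate)) {
      ## simulated strikes have known depth; cut just above it
      close_m <- config$simulate$base_m +
        config$simulate$gain_m * (config$simulate$strike_level + 0.08)
    }
    scenes <- split_scenes(ipd, exclusion_intervals = mt$exclusions,
                           close_m = close_m,
                           close_quantile = config$close_quantile,
                           min_pos_peaks = config$min_pos_peaks)
    tau <- if (identical(config$tau, "auto")) as.numeric(select_tau(ipd))
           else config$tau
    st <- build_state_series(ipd, tau = tau, weight = config$weight)
    dt <- grid_dt(ipd$time)
    segs <- list()
    for (sc in scenes) {
      rng <- sc$start:sc$end
      rng <- rng[st$valid[rng]]
      if (length(rng) < config$analysis$sg_window + 2L) next
      seg <- tryCatch(
        analyze_scene(st$D_norm[rng], config$analysis, dt = dt,
                      amplitude_from = st$S[rng],
                      scene_id = sprintf("%s/%d", id, sc$scene_id)),
        error = function(e) NULL)
      if (!is.null(seg)) segs[[length(segs) + 1L]] <- seg
    }
    all_segs <- c(all_segs, segs)
    match_info[[id]] <- list(segs = segs, group = attr(mt$traj, "group"),
                             tau = tau, n_scenes = length(scenes))
  }

  ## per-match F/N labeling from the histogram of well-fitted peaks
  thresholds <- list()
  match_runs <- list()
  for (id in names(match_info)) {
    mi <- match_info[[id]]
    vals <- unlist(lapply(mi$segs, function(seg) {
      pk <- attr(seg, "peaks")
      unlist(lapply(covered_runs(seg, config$include_intermittency),
                    function(r) pk$amplitude[r]))
    }))
    thr <- tryCatch(as.numeric(find_threshold(
      peak_histogram(vals, config$bin_width))), error = function(e) NA_real_)
    thresholds[[id]] <- thr
    runs <- lapply(mi$segs, function(seg) {
      pk <- attr(seg, "peaks")
      lapply(covered_runs(seg, config$include_intermittency),
             function(r) pk$amplitude[r])
    })
    match_runs[[id]] <- unlist(runs, recursive = FALSE)
  }
  ## pooled fallback for matches whose histogram had no two modes
  pooled_thr <- tryCatch(as.numeric(find_threshold(peak_histogram(
    unlist(match_runs), config$bin_width))), error = function(e) 0.5)
  for (id in names(thresholds)) {
    if (is.na(thresholds[[id]])) thresholds[[id]] <- pooled_thr
  }

  groups <- unique(vapply(match_info, `[[`, "", "group"))
  transitions <- list()
  group_labels <- list()
  for (g in groups) {
    labs <- list()
    for (id in names(match_info)) {
      if (match_info[[id]]$group != g) next
      runs <- match_runs[[id]]
      if (!length(runs)) next
      labs <- c(labs, unclass(label_states(runs, thresholds[[id]])))
    }
    group_labels[[g]] <- labs
    transitions[[g]] <- list(
      second = tryCatch(second_order(labs, group = g), error = function(e) NULL),
      third = tryCatch(third_order(labs, group = g), error = function(e) NULL))
  }
  comparison <- NULL
  if (length(groups) >= 2L) {
    a <- transitions[[groups[1]]]; b <- transitions[[groups[2]]]
    comparison <- list(
      second = if (!is.null(a$second) && !is.null(b$second))
        fisher_compare(a$second, b$second),
      third = if (!is.null(a$third) && !is.null(b$third))
        fisher_compare(a$third, b$third))
  }

  fits <- fits_table(all_segs)
  cbl <- matrix(0L, length(CLASSES), 4,
                dimnames = list(class = CLASSES, length = as.character(3:6)))
  if (nrow(fits)) {
    tab <- table(factor(fits$class, levels = CLASSES),
                 factor(fits$length, levels = 3:6))
    cbl[] <- as.integer(tab)
  }
  report <- list(
    config = config,
    n_scenes = length(all_segs),
    fits = fits,
    class_by_length = cbl,
    functions_per_scene = vapply(all_segs, `[[`, 0L, "n_functions"),
    thresholds = thresholds,
    transitions = transitions,
    comparison = comparison,
    truth = lapply(matches, `[[`, "truth")
  )
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

report_json <- function(report) {
  tm_json <- function(tm) if (is.null(tm)) NULL else list(
    order = tm$order, group = tm$group,
    counts = apply(tm$counts, 1, as.list, simplify = FALSE),
    probs = apply(tm$probs, 1, as.list, simplify = FALSE))
  list(
    seed = report$config$seed,
    n_scenes = report$n_scenes,
    class_by_length = apply(report$class_by_length, 1, as.list,
                            simplify = FALSE),
    class_totals = as.list(rowSums(report$class_by_length)),
    n_attractors = sum(report$class_by_length[c("Aa", "Ar"), ]),
    n_repellers = sum(report$class_by_length[c("Ra", "Rr"), ]),
    n_intermittency = sum(report$class_by_length[c("Exp", "Log"), ]),
    n_fits = nrow(report$fits),
    functions_per_scene = report$functions_per_scene,
    thresholds = report$thresholds,
    transitions = lapply(report$transitions, function(g)
      list(second = tm_json(g$second), third = tm_json(g$third))),
    comparison = if (!is.null(report$comparison)) list(
      second = report$comparison$second, third = report$comparison$third)
  )
}

#' Write a run report
#'
#' Writes `report.json` (counts, transition models, comparisons),
#' `fits.csv` (one row per accepted fit) and `config.json` (the resolved
#' configuration) into `dir`.  Output is byte-identical for identical
#' configurations.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_json(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  write.csv(report$fits, file.path(dir, "fits.csv"), row.names = FALSE)
  cfg <- report$config
  cfg$out_dir <- NULL
  cfg$analysis <- unclass(cfg$analysis)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run report> %d scenes analyzed, %d accepted fits\n",
              x$n_scenes, nrow(x$fits)))
  cat("class totals:\n")
  print(rowSums(x$class_by_length))
  invisible(x)
}

#' Write a canonical fixture suite
#'
#' Generates small canonical inputs: one single-regime scene per dynamical
#' class (peak amplitudes, the rendered continuous scene, and ground truth),
#' one scene switching among three regimes, and a two-group set of synthetic
#' matches as trajectory CSVs.  Byte-identical for identical seeds.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @return named list of written paths, invisibly.
#' @export
make_fixture_suite <- function(seed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  with_seed(seed, {
    for (cl in CLASSES) {
      rg <- random_regime_spec(cl)
      spec <- synthetic_spec(list(rg), seed = seed)
      gp <- generate_peak_sequence(spec)
      base <- file.path(dir, paste0("class_", cl))
      write.csv(data.frame(peak = seq_along(gp$peaks), amplitude = gp$peaks),
                paste0(base, "_peaks.csv"), row.names = FALSE)
      sc <- render_continuous_scene(gp$peaks, spec)
      write.csv(data.frame(time_s = sc$time, S = sc$signal),
                paste0(base, "_scene.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(class = cl, family = rg$family, params = rg$params,
             n_peaks = rg$n_peaks, initial_peak = rg$initial_peak,
             fixed_point = map_fixed_point(rg), peaks = gp$truth$peaks_clean),
        paste0(base, "_truth.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      paths[[paste0("class_", cl)]] <- paste0(base, "_scene.csv")
    }
    ## a scene switching among three regimes with identifiable boundaries
    rg3 <- random_scene_regimes(3)
    spec3 <- synthetic_spec(rg3, seed = seed)
    gp3 <- generate_peak_sequence(spec3)
    sc3 <- render_continuous_scene(gp3$peaks, spec3)
    write.csv(data.frame(time_s = sc3$time, S = sc3$signal),
              file.path(dir, "switch3_scene.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(classes = vapply(rg3, attr, "", "class_label"),
           boundaries = gp3$truth$boundaries, peaks = gp3$truth$peaks_clean),
      file.path(dir, "switch3_truth.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    paths$switch3 <- file.path(dir, "switch3_scene.csv")
    ## two-group match set
    for (g in c("groupA", "groupB")) {
      for (m in 1:2) {
        rg <- c(random_scene_regimes(2), random_scene_regimes(1),
                random_scene_regimes(2))
        scenes <- list(1:2, 3L, 4:5)
        spec <- synthetic_spec(rg, scenes = scenes, noise_sigma = 0.01,
                               seed = seed + 13L * m +
                                 101L * (g == "groupB"))
        mt <- generate_match(spec, match_id = sprintf("%s_m%d", g, m),
                             group = g)
        p <- file.path(dir, sprintf("%s_match%d.csv", g, m))
        write_trajectory_csv(mt$traj, p)
        paths[[sprintf("%s_match%d", g, m)]] <- p
      }
    }
  })
  invisible(paths)
}
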