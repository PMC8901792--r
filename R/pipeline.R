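#' Assemble a pipeline run configuration
#'
#' Defaults follow the standard operating point of the method: 0.01
#' background threshold, LoG radius 5 voxels, energy weight 1/1000, the
#' 4-stage coarse-to-fine schedule with temperatures decaying to 1/30 and
#' step adaptation factor 0.99, 20% initial step, and half-day blending.
#'
#' @param inputs either a list of `bw_volume` objects, or a list with
#'   `synthetic = TRUE` and fields `recorded_ages`, `per_age` (a phantom
#'   series is generated), or a data.frame with `path` and
#'   `recorded_age_days` columns.
#' @param output_dir directory for artifacts.
#' @param threshold,log_radius preprocessing parameters.
#' @param schedule "default", "whole-brain", "reduced", or a list of
#'   `bw_stage` objects.
#' @param lambda deformation-energy weight.
#' @param split whether inputs are whole brains to symmetrize and split
#'   (default FALSE: inputs are already hemisphere frames).
#' @param sigma_days,dt blending parameters.
#' @param distance_resolution_um working resolution of the distance matrix.
#' @param norm,variability_downsample day-to-day variability settings.
#' @param seed master seed; every stage derives its seed from it.
#' @param k CMDS dimensions retained.
#' @return list of class `bw_config`.
#' @export
run_config <- function(inputs, output_dir, threshold = 0.01, log_radius = 5,
                       schedule = "reduced", lambda = 1 / 1000,
                       split = FALSE, sigma_days = 0.5, dt = 0.1,
                       distance_resolution_um = 96, norm = "l2",
                       variability_downsample = 2L, seed = 1L, k = 3L) {
  cfg <- as.list(environment())
  structure(cfg, class = "bw_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with the fields of [run_config()].
#' @return a `bw_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$inputs$paths)) {
    y$inputs <- data.frame(path = unlist(y$inputs$paths),
                           recorded_age_days = unlist(y$inputs$ages))
  }
  do.call(run_config, y)
}

resolve_schedule <- function(schedule) {
  if (is.character(schedule))
    switch(schedule,
           "default" = default_schedule(),
           "whole-brain" = whole_brain_schedule(),
           "reduced" = reduced_schedule(),
           stop("unknown schedule: ", schedule))
  else schedule
}

#' Run the full spatiotemporal registration pipeline
#'
#' preprocess -> (optional symmetrize/split) -> alignment plan -> chained
#' registration -> distance matrix -> CMDS -> adjusted ages -> weighted
#' averages, differentials and variability. Artifacts (CSV tables, grids as
#' JSON, a JSON manifest with parameters, seeds and file checksums) are
#' written under `cfg$output_dir`. A rerun with an identical configuration
#' reproduces identical tables; with `resume = TRUE`, stages whose outputs
#' exist are skipped.
#'
#' @param cfg a `bw_config` (or path to a YAML config).
#' @param resume skip stages whose outputs already exist.
#' @return list: `samples` (registered set), `distances`, `embedding`,
#'   `ages` (a `bw_ages`), `variability` (adjusted/recorded), `manifest`.
#' @export
run_pipeline <- function(cfg, resume = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  schedule <- resolve_schedule(cfg$schedule)
  log_msg <- function(...) message(sprintf(...))

  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  if (resume && file.exists(manifest_path) &&
      file.exists(file.path(cfg$output_dir, "age_table.csv"))) {
    log_msg("resume: artifacts already present in %s", cfg$output_dir)
    return(list(
      ages = read.csv(file.path(cfg$output_dir, "age_table.csv")),
      distances = as.matrix(read.csv(file.path(cfg$output_dir,
                                               "distances.csv"),
                                     row.names = 1)),
      manifest = jsonlite::fromJSON(manifest_path)))
  }

  # ---- inputs ---------------------------------------------------------------
  truth <- NULL
  if (is.list(cfg$inputs) && isTRUE(cfg$inputs$synthetic)) {
    spec <- do.call(phantom_spec, cfg$inputs$spec %||% list())
    ser <- make_series(spec, recorded_ages = cfg$inputs$recorded_ages,
                       per_age = cfg$inputs$per_age %||% 1,
                       age_jitter = cfg$inputs$age_jitter %||% 0.5,
                       seed = cfg$seed)
    raw <- lapply(ser$samples, function(r) r$raw)
    truth <- ser$truth
  } else if (is.data.frame(cfg$inputs)) {
    raw <- lapply(seq_len(nrow(cfg$inputs)), function(i)
      read_volume(cfg$inputs$path[i], sample_id = sprintf("s%02d", i),
                  recorded_age_days = cfg$inputs$recorded_age_days[i],
                  side = "right"))
  } else {
    raw <- cfg$inputs
  }

  # ---- preprocess (and optional split) -------------------------------------
  log_msg("preprocessing %d volumes", length(raw))
  if (isTRUE(cfg$split)) {
    pairs <- lapply(seq_along(raw), function(i)
      symmetrize_and_split(raw[[i]], schedule = schedule,
                           seed = cfg$seed + 1000 + i,
                           threshold = cfg$threshold,
                           log_radius = cfg$log_radius,
                           lambda = cfg$lambda))
    samples <- hemisphere_set(pairs)
  } else {
    filt <- lapply(raw, function(v)
      preprocess_volume(v, cfg$threshold, cfg$log_radius))
    for (i in seq_along(filt)) {
      filt[[i]]$sample_id <- raw[[i]]$sample_id
      filt[[i]]$side <- raw[[i]]$side
      filt[[i]]$recorded_age_days <- raw[[i]]$recorded_age_days
    }
    samples <- hemisphere_set(filt)
  }

  # ---- spatial registration -------------------------------------------------
  plan <- build_alignment_plan(samples, seed = cfg$seed + 1)
  log_msg("registering %d edges", nrow(plan$edges))
  reg <- run_plan(samples, plan, schedule = schedule, lambda = cfg$lambda,
                  seed = cfg$seed + 2)
  for (key in names(reg)) {
    if (!is.null(reg[[key]]$grid))
      grid_to_json(reg[[key]]$grid,
                   file.path(cfg$output_dir,
                             sprintf("grid_%s.json", key)))
  }

  # ---- temporal registration ------------------------------------------------
  D <- pairwise_distances(reg, cfg$distance_resolution_um)
  write.csv(round(D, 12), file.path(cfg$output_dir, "distances.csv"))
  tab <- sample_table(reg)
  emb <- cmds_embed(D, k = cfg$k, ages = tab$recorded_age_days)
  ages <- adjust_ages(emb, tab$recorded_age_days,
                      sample_ids = tab$sample_id, sides = tab$side)
  write_age_table(ages, file.path(cfg$output_dir, "age_table.csv"))

  # ---- rendering ------------------------------------------------------------
  vols <- lapply(reg, function(r) r$registered %||% r$filtered)
  days <- seq(floor(min(tab$recorded_age_days)),
              ceiling(max(tab$recorded_age_days)))
  avg_of <- function(ages_vec) {
    wc <- blend_weights(ages_vec, timeline = days,
                        sigma_days = cfg$sigma_days)
    lapply(days, function(t) average_volume(vols, wc, t))
  }
  avg_adj <- avg_of(ages$table$adjusted_age_days)
  avg_rec <- avg_of(tab$recorded_age_days)
  variability <- c(
    adjusted = day_to_day_variability(avg_adj, cfg$norm,
                                      cfg$variability_downsample),
    recorded = day_to_day_variability(avg_rec, cfg$norm,
                                      cfg$variability_downsample))
  diffs <- lapply(seq_along(days)[-1], function(i)
    differential_volume(avg_adj[[i]], avg_adj[[i - 1]]))
  write.csv(data.frame(setting = names(variability),
                       variability = sprintf("%.12g", variability)),
            file.path(cfg$output_dir, "variability.csv"),
            row.names = FALSE, quote = FALSE)

  # ---- manifest -------------------------------------------------------------
  outputs <- list.files(cfg$output_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("brainwarp")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("inputs", "output_dir"))],
    n_samples = length(reg),
    failures = attr(reg, "failures"),
    checksums = as.list(tools::md5sum(
      outputs[grepl("\\.(csv|json)$", outputs)])))
  manifest_json <- jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                    digits = NA, force = TRUE)
  writeLines(manifest_json, file.path(cfg$output_dir, "manifest.json"))

  list(samples = reg, distances = D, embedding = emb, ages = ages,
       averages = avg_adj, differentials = diffs,
       variability = variability, truth = truth, manifest = manifest)
}
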