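#' Default pipeline configuration
#'
#' A nested list controlling every stage of [run_pipeline()]. Either
#' `dataset` (a dataset-directory path or a `population_dataset`) or
#' `simulator` must be supplied; the remaining entries have working
#' defaults sized for routine use and can be overridden individually (the
#' override list is merged into these defaults).
#'
#' @param dataset path to a dataset directory, or a `population_dataset`.
#' @param simulator list: `model` (`"bump"`, `"linear"` or `"parametric"`),
#'   `n_trials_per_condition`, and an optional `config` /
#'   `ground_truth` object for the chosen generator.
#' @param ... stage overrides: `unmixing` (list: `n_restarts`, `bounds`,
#'   `grid_step`), `decoding` (list: `n_per_condition`, `n_repeats`,
#'   `windows`), `geometry` (list: `n_boot`, `n_null`), `epochs`.
#' @return a `run_config` list.
#' @export
run_config <- function(dataset = NULL, simulator = NULL, ...) {
  cfg <- list(
    dataset = dataset, simulator = simulator,
    epochs = default_epochs(),
    unmixing = list(n_restarts = 100, bounds = c(-0.5, 1.5),
                    grid_step = 0.02),
    decoding = list(n_per_condition = 100, n_repeats = 5,
                    windows = c("delay1", "delay2")),
    geometry = list(n_boot = 200, n_null = 200, n_per_cluster = 100))
  over <- list(...)
  for (nm in names(over))
    cfg[[nm]] <- utils::modifyList(cfg[[nm]] %||% list(), as.list(over[[nm]]))
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with top-level keys matching [run_config()]
#'   arguments (epoch windows under `epochs:` as `[start, end]` pairs).
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ep <- default_epochs()
  if (!is.null(y$epochs)) for (nm in names(y$epochs))
    ep[[nm]] <- as.numeric(y$epochs[[nm]])
  args <- y[setdiff(names(y), "epochs")]
  do.call(run_config, c(args, list(epochs = ep)))
}

substream_seeds <- function(seed, n = 8) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

pipeline_data <- function(config, seed) {
  if (!is.null(config$dataset)) {
    if (inherits(config$dataset, "population_dataset")) return(config$dataset)
    return(read_dataset(config$dataset))
  }
  sim <- config$simulator
  if (is.null(sim)) stop("config must provide a dataset or a simulator")
  switch(sim$model,
    bump = simulate_bump_attractor(
      sim$config %||% attractor_config(),
      sim$n_trials_per_condition %||% 50, seed = seed),
    linear = simulate_linear_model(
      sim$config %||% linear_model_config(),
      sim$n_trials_per_condition %||% 50, seed = seed),
    stop("unknown simulator model: ", sim$model))
}

#' Run the full subspace analysis pipeline
#'
#' Executes the stages in dependency order on one dataset: condition
#' matrices for the two delays, mutual-information mixing fit, unmixed
#' elements and subspaces, within/across-delay decoding in the full space
#' and in both subspaces, subspace geometry (principal angles with random
#' nulls, variance explained, effective dimensionality, loading weights,
#' null-space completeness check), and inter-to-intra cluster ratios.
#' Error-trial decoding is included when the dataset contains error trials.
#' Every random stage draws its own substream from the global seed, so
#' identical `(config, seed)` pairs give identical summaries.
#'
#' @param config a [run_config()] (or YAML path).
#' @param seed global integer seed.
#' @param outdir optional directory: writes `summary.json`, the restart
#'   table, decoding grids and subspace bases as CSV.
#' @return a list with the fitted `solution`, `subspaces`, `decoding`
#'   grids, `geometry` results and a flat numeric `summary`.
#' @export
run_pipeline <- function(config, seed = 1, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  seeds <- substream_seeds(seed)
  data <- pipeline_data(config, seeds[1])
  ep <- config$epochs

  d1bar <- condition_matrix(data, "delay1", epochs = ep)
  d2bar <- condition_matrix(data, "delay2", epochs = ep)
  un <- config$unmixing
  sol <- fit_mixing(d1bar, d2bar, n_restarts = un$n_restarts,
                    bounds = un$bounds, grid_step = un$grid_step,
                    seed = seeds[2])
  el <- unmix_pair(d1bar, d2bar, sol$a, sol$b)
  sub_m <- build_subspace(el$m, label = "memory")
  sub_p <- build_subspace(el$p, label = "preparation")

  # decoding: bin grid restricted to the two delay windows
  dec <- config$decoding
  bins <- sort(unique(unlist(lapply(dec$windows, function(w)
    bins_in_window(data, resolve_window(ep, w))))))
  grids <- list(
    full = cross_temporal_decode(data, NULL, bins = bins,
      n_per_condition = dec$n_per_condition, n_repeats = dec$n_repeats,
      seed = seeds[3], epochs = ep),
    memory = cross_temporal_decode(data, sub_m, bins = bins,
      n_per_condition = dec$n_per_condition, n_repeats = dec$n_repeats,
      seed = seeds[3], epochs = ep),
    preparation = cross_temporal_decode(data, sub_p, bins = bins,
      n_per_condition = dec$n_per_condition, n_repeats = dec$n_repeats,
      seed = seeds[3], epochs = ep))
  wmean <- function(g, w1, w2 = w1) grid_window_mean(g, w1, w2, ep)

  geo <- config$geometry
  angles <- principal_angles(sub_m, sub_p)
  null_ang <- random_subspace_null(nrow(sub_m$basis), sub_p, sub_m$d,
                                   n = geo$n_null, seed = seeds[4])
  # single-trial activity in Delay 2 for geometry summaries
  pp1 <- build_pseudopopulation(data, "delay1", dec$n_per_condition,
                                seed = seeds[5], epochs = ep)
  pp2 <- build_pseudopopulation(data, "delay2", dec$n_per_condition,
                                seed = seeds[5], epochs = ep)
  st <- unmix_single_trials(pp1, pp2, el$m, el$p, sol$a, sol$b)
  proj <- function(mat, sub) crossprod(mat, as_basis(sub))
  iir_m <- inter_intra_ratio(proj(st$train$m2, sub_m), st$labels,
                             n_boot = geo$n_boot,
                             n_per_cluster = geo$n_per_cluster,
                             seed = seeds[6])
  iir_mp <- inter_intra_ratio(proj(pp2$train, sub_m), pp2$labels,
                              n_boot = geo$n_boot,
                              n_per_cluster = geo$n_per_cluster,
                              seed = seeds[6])
  lw <- loading_weights(sub_m, sub_p, n_perm = geo$n_null, seed = seeds[7])
  nullsp <- null_space_projection(list(sub_m, sub_p))
  null_resid <- max(
    sqrt(sum(crossprod(nullsp$basis, unclass(d1bar))^2)) /
      sqrt(sum(unclass(d1bar)^2)),
    sqrt(sum(crossprod(nullsp$basis, unclass(d2bar))^2)) /
      sqrt(sum(unclass(d2bar)^2)))
  eff_dim <- effective_dimensionality(proj(pp2$train, sub_m))
  var_m1 <- variance_explained(t(pp1$train), sub_m)
  var_p1 <- variance_explained(t(pp1$train), sub_p)
  var_m2 <- variance_explained(t(pp2$train), sub_m)
  var_p2 <- variance_explained(t(pp2$train), sub_p)

  summary <- c(
    a = sol$a, b = sol$b, mi_min = sol$mi_min,
    mi_original = sol$mi_original,
    full_delay1 = wmean(grids$full, "delay1"),
    full_delay2 = wmean(grids$full, "delay2"),
    full_delay1_to_delay2 = wmean(grids$full, "delay1", "delay2"),
    memory_delay1 = wmean(grids$memory, "delay1"),
    memory_delay2 = wmean(grids$memory, "delay2"),
    preparation_delay1 = wmean(grids$preparation, "delay1"),
    preparation_delay2 = wmean(grids$preparation, "delay2"),
    chance = 100 / grids$full$n_classes,
    n_angles_below_chance = sum(angles_below_chance(angles, null_ang)),
    leading_angle_deg = angles[1],
    ratio_m = iir_m$ratio, ratio_mp = iir_mp$ratio,
    loading_correlation = lw$correlation,
    n_exclusive = sum(lw$exclusive_memory) + sum(lw$exclusive_preparation),
    effective_dim = eff_dim,
    var_memory_delay1 = var_m1, var_preparation_delay1 = var_p1,
    var_memory_delay2 = var_m2, var_preparation_delay2 = var_p2,
    null_space_residual = null_resid)

  # error trials, when present
  if (any(data$trials$outcome == "error")) {
    can <- tryCatch({
      pe1 <- build_pseudopopulation(data, "delay1", dec$n_per_condition,
                                    seed = seeds[8], outcome = "error",
                                    epochs = ep)
      pe2 <- build_pseudopopulation(data, "delay2", dec$n_per_condition,
                                    seed = seeds[8], outcome = "error",
                                    epochs = ep)
      ste <- unmix_error_trials(pe1, pe2, el$m, el$p, sol$a, sol$b)
      em <- decode_error_trials(
        list(train = proj_t(st$train$m2, sub_m), test = proj_t(st$test$m2, sub_m),
             labels = st$labels),
        list(test = proj_t(ste$test$m2, sub_m), labels = ste$labels), NULL)
      ep_ <- decode_error_trials(
        list(train = proj_t(st$train$p2, sub_p), test = proj_t(st$test$p2, sub_p),
             labels = st$labels),
        list(test = proj_t(ste$test$p2, sub_p), labels = ste$labels), NULL)
      c(memory_error = em$accuracy_error,
        memory_correct_heldout = em$accuracy_correct,
        preparation_error = ep_$accuracy_error,
        preparation_correct_heldout = ep_$accuracy_correct)
    }, error = function(e) NULL)
    if (!is.null(can)) summary <- c(summary, can)
  }

  out <- list(data = data, solution = sol, elements = el,
              subspaces = list(memory = sub_m, preparation = sub_p,
                               null = nullsp),
              decoding = grids,
              geometry = list(angles = angles, angle_null = null_ang,
                              iir_memory = iir_m, iir_memory_plus = iir_mp,
                              loading = lw),
              summary = summary, seed = seed)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(as.list(summary), file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    data.table::fwrite(sol$restarts, file.path(outdir, "restarts.csv"))
    for (nm in names(grids))
      data.table::fwrite(as.data.frame(grids[[nm]]$accuracy),
                         file.path(outdir, paste0("grid_", nm, ".csv")))
    data.table::fwrite(as.data.frame(sub_m$basis),
                       file.path(outdir, "subspace_memory.csv"))
    data.table::fwrite(as.data.frame(sub_p$basis),
                       file.path(outdir, "subspace_preparation.csv"))
  }
  out
}

# neurons x trials -> trials-in-columns projection used by the error-trial
# decoder (which expects neurons x trials input with projection = NULL)
proj_t <- function(mat, sub) t(crossprod(mat, as_basis(sub)))
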