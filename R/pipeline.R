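# Allowed configuration keys, per task type. Unknown keys anywhere in the
# config are rejected before any computation runs.
.task_schema <- list(
  synth_isotherm = c("type", "name", "model", "params", "noise_sd",
                     "n_points", "out_csv"),
  analyze_isotherm = c("type", "input", "path", "smooth_window",
                       "smooth_order", "liftoff_threshold", "plateau_ceiling"),
  synth_mixture = c("type", "name", "excess", "excess_params", "fractions",
                    "pi_max", "dpi", "n_points"),
  mixing_gexc = c("type", "input", "pi_target", "dpi"),
  synth_slab = c("type", "name", "n_atoms", "element", "slab_bounds", "box",
                 "n_frames", "out_xyz"),
  md_density = c("type", "input", "bin_width", "reference")
)

validate_config <- function(config) {
  top_allowed <- c("seed", "output_dir", "tasks")
  unknown <- setdiff(names(config), top_allowed)
  if (length(unknown)) {
    stop_monofilm(sprintf("unknown configuration key(s): %s",
                          paste(unknown, collapse = ", ")),
                  "monofilm_schema_error")
  }
  if (is.null(config$seed) || is.null(config$output_dir) ||
      is.null(config$tasks)) {
    stop_monofilm("config needs keys: seed, output_dir, tasks",
                  "monofilm_schema_error")
  }
  if (!is.list(config$tasks) || !length(config$tasks)) {
    stop_monofilm("tasks must be a non-empty list", "monofilm_schema_error")
  }
  for (i in seq_along(config$tasks)) {
    task <- config$tasks[[i]]
    type <- task$type
    if (is.null(type) || !type %in% names(.task_schema)) {
      stop_monofilm(
        sprintf("task %d: unknown or missing type '%s' (known: %s)", i,
                type %||% "<missing>",
                paste(names(.task_schema), collapse = ", ")),
        "monofilm_schema_error"
      )
    }
    bad <- setdiff(names(task), .task_schema[[type]])
    if (length(bad)) {
      stop_monofilm(sprintf("task %d (%s): unknown key(s): %s", i, type,
                            paste(bad, collapse = ", ")),
                    "monofilm_schema_error")
    }
  }
  invisible(config)
}

#' Run a synthesize-analyze-report pipeline from a configuration
#'
#' Executes the configured task list in order, passing named intermediate
#' datasets between tasks, and writes all results (CSV tables, a JSON
#' report, a parameter log) into `output_dir`. The run is deterministic
#' given the configuration and seed: re-running the same config produces
#' byte-identical outputs.
#'
#' Supported task types: `synth_isotherm`, `analyze_isotherm`,
#' `synth_mixture`, `mixing_gexc`, `synth_slab`, `md_density`; see the
#' bundled demo configuration
#' (`system.file("configs", "demo.yaml", package = "monofilm")`).
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Unknown keys are rejected before any computation.
#' @param output_dir Optional override of the configured output directory.
#' @return Invisibly, the report list (also written as `report.json`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  out_dir <- output_dir %||% config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  datasets <- list()
  report <- list(monofilm_version = as.character(utils::packageVersion("monofilm")),
                 seed = seed, tasks = list())
  log_lines <- c(sprintf("monofilm %s", report$monofilm_version),
                 sprintf("seed: %d", seed))

  get_input <- function(task, i) {
    if (!is.null(task$path)) return(read_isotherm(task$path))
    nm <- task$input
    if (is.null(nm) || is.null(datasets[[nm]])) {
      stop_monofilm(
        sprintf("task %d (%s): input '%s' not produced by an earlier task",
                i, task$type, nm %||% "<missing>"),
        "monofilm_schema_error"
      )
    }
    datasets[[nm]]
  }

  for (i in seq_along(config$tasks)) {
    task <- config$tasks[[i]]
    task_seed <- seed + i  # distinct, reproducible stream per task
    entry <- switch(task$type,
      synth_isotherm = {
        model <- do.call(isotherm_model,
                         c(list(kind = task$model %||% "le-plateau-lc"),
                           task$params %||% list(),
                           list(noise_sd = task$noise_sd %||% 0)))
        gen <- generate_isotherm(model, n_points = task$n_points %||% 200L,
                                 seed = task_seed,
                                 label = task$name %||% "synthetic")
        datasets[[task$name]] <- gen$isotherm
        csv <- file.path(out_dir, task$out_csv %||%
                           paste0(task$name, ".csv"))
        write_isotherm(gen$isotherm, csv)
        list(type = task$type, name = task$name, model = model$kind,
             n_points = length(gen$isotherm$area), file = basename(csv))
      },
      analyze_isotherm = {
        iso <- get_input(task, i)
        w <- task$smooth_window %||% 11L
        o <- task$smooth_order %||% 3L
        feats <- isotherm_features(
          iso, threshold = task$liftoff_threshold %||% 0.5,
          plateau_ceiling = task$plateau_ceiling %||% 10,
          window = w, order = o
        )
        mc <- compressional_modulus(iso, window = w, order = o)
        csv <- file.path(out_dir, paste0(iso$label, "_modulus.csv"))
        write.csv(as.data.frame(mc), csv, row.names = FALSE)
        c(list(type = task$type, input = iso$label, file = basename(csv)),
          unclass(feats))
      },
      synth_mixture = {
        model <- mixture_model(excess = task$excess %||% "zero",
                               excess_params = task$excess_params %||% list())
        gen <- generate_mixture_series(
          model, fractions = unlist(task$fractions %||% c(0.25, 0.5, 0.75)),
          pi_max = task$pi_max %||% 40, seed = task_seed,
          dpi = task$dpi %||% 0.1, n_points = task$n_points %||% 200L
        )
        datasets[[task$name]] <- gen$series
        list(type = task$type, name = task$name, excess = model$excess,
             fractions = gen$series$fractions)
      },
      mixing_gexc = {
        series <- get_input(task, i)
        curve <- excess_gibbs_curve(series, pi_target = task$pi_target %||% 35,
                                    dpi = task$dpi %||% 0.1)
        csv <- file.path(out_dir, paste0(task$input, "_gexc.csv"))
        write.csv(as.data.frame(curve), csv, row.names = FALSE)
        ext <- curve_extremum(curve)
        stoich <- if (!is.null(ext$x2)) {
          stoichiometry_from_fraction(ext$x2)
        }
        list(type = task$type, input = task$input,
             pi_target = curve$pi_target, file = basename(csv),
             extremum = ext,
             stoichiometry = if (!is.null(stoich)) {
               sprintf("%d:%d", stoich[[1L]], stoich[[2L]])
             })
      },
      synth_slab = {
        gen <- generate_slab_configuration(
          n_atoms = task$n_atoms %||% 500L,
          element = task$element %||% "O",
          slab_bounds = unlist(task$slab_bounds %||% c(-10, 10)),
          box = unlist(task$box %||% c(50, 50, 100)),
          n_frames = task$n_frames %||% 10L, seed = task_seed
        )
        datasets[[task$name]] <- gen$frames
        xyz <- file.path(out_dir, task$out_xyz %||%
                           paste0(task$name, ".extxyz"))
        write_frames(gen$frames, xyz, format = "xyz")
        list(type = task$type, name = task$name,
             n_atoms = nrow(gen$frames$atoms),
             n_frames = length(gen$frames$coords), file = basename(xyz))
      },
      md_density = {
        tf <- get_input(task, i)
        prof <- electron_density_profile(
          tf, bin_width = task$bin_width %||% 0.5,
          reference = task$reference %||% "water_com"
        )
        csv <- file.path(out_dir, paste0(task$input, "_density.csv"))
        write.csv(as.data.frame(prof), csv, row.names = FALSE)
        list(type = task$type, input = task$input, file = basename(csv),
             peak_density = max(prof$density),
             electrons_per_frame = prof$electrons_per_frame)
      }
    )
    report$tasks[[i]] <- entry
    log_lines <- c(log_lines,
                   sprintf("task %d: %s %s", i, task$type,
                           paste(names(task)[names(task) != "type"],
                                 vapply(task[names(task) != "type"],
                                        function(v) paste(format(unlist(v)),
                                                          collapse = ","),
                                        character(1L)),
                                 sep = "=", collapse = " ")))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(report)
}
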