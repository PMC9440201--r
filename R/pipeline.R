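# Known configuration keys per stage; unknown keys are rejected.
.config_keys <- list(
  top = c("stages", "seed", "out_dir", "simulate", "fit", "titrate",
          "predict", "cv"),
  simulate = c("pK", "n", "f_acid", "f_base", "pH", "delta", "kappa", "d",
               "noise_sigma", "t_max", "n_points", "pair", "environment",
               "steep_acid_background", "centers_A", "widths_A", "centers_B",
               "widths_B"),
  fit = c("traces", "K", "K_max", "criterion", "band", "n_starts",
          "fit_dims"),
  titrate = c("series", "component_window", "fix_n"),
  predict = c("structure", "pairs", "L", "cone_half_angle", "n_samples",
              "clash_cutoff", "smoothing"),
  cv = c("trajectory", "N_range", "C_range", "split_mode", "sb_donor",
         "sb_acceptor", "sb_cutoff", "window", "restraints", "distances_nm"))

#' Default pipeline configuration
#'
#' A complete, documented configuration for [run_pipeline()]: a
#' simulate -> fit -> titrate round trip on the default two-state
#' equilibrium.
#'
#' @param seed Pipeline seed.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1) {
  list(stages = c("simulate", "fit", "titrate"),
       seed = seed,
       simulate = list(pK = 7.6, n = 1, f_acid = 0.8, f_base = 0.2,
                       pH = c(4, 5, 6, 7, 7.5, 8, 9), delta = 0.3,
                       kappa = 0.2, d = 3, noise_sigma = 0.006,
                       t_max = 3, n_points = 300, pair = "site1-site2"),
       fit = list(K = 2, criterion = "bic", band = "delta", n_starts = 8),
       titrate = list(component_window = NULL, fix_n = NULL))
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path", call. = FALSE)
  unknown <- setdiff(names(config), .config_keys$top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  for (stage in intersect(names(config), names(.config_keys)[-1])) {
    bad <- setdiff(names(config[[stage]]), .config_keys[[stage]])
    if (length(bad))
      stop("unknown key(s) in stage '", stage, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!length(config$stages))
    stop("config selects no stages", call. = FALSE)
  bad_stage <- setdiff(config$stages, c("simulate", "fit", "titrate",
                                        "predict", "cv"))
  if (length(bad_stage))
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "), call. = FALSE)
  config$seed <- config$seed %||% 1
  config
}

#' Run the analysis pipeline end to end
#'
#' Executes the selected stages in order — `simulate` (synthetic two-state
#' DEER dataset), `fit` (global Gaussian analysis, optionally with model
#' selection), `titrate` (population assembly + Hill fit), `predict`
#' (structure-based distance prediction) and `cv` (collective variables /
#' salt bridges / restraint energies) — and returns a manifest recording
#' parameters, seeds and per-stage summaries. Reruns with the same config
#' and inputs reproduce all outputs.
#'
#' @param config Configuration list (see [default_run_config()]) or a path
#'   to a YAML/JSON file. Unknown keys are rejected.
#' @param out_dir Optional output directory; when given, traces,
#'   distributions, fit reports and the manifest are written there.
#' @return List with per-stage results and `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  config <- validate_config(config)
  seed <- config$seed
  out_dir <- out_dir %||% config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  results <- list()
  manifest <- list(package_version = as.character(utils::packageVersion("deerfit")),
                   r_version = R.version.string,
                   seed = seed, stages = config$stages, parameters = config,
                   inputs = list(), stage_log = list())
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  for (stage in config$stages) {
    if (stage == "simulate") {
      results$simulate <- run_stage("simulate", function() {
        sc <- config$simulate %||% list()
        comp_args <- list()
        if (!is.null(sc$centers_A))
          comp_args$state_A <- gaussian_components(sc$centers_A,
                                                   sc$widths_A %||% rep(0.3, length(sc$centers_A)))
        if (!is.null(sc$centers_B))
          comp_args$state_B <- gaussian_components(sc$centers_B,
                                                   sc$widths_B %||% rep(0.3, length(sc$centers_B)))
        sc <- sc[setdiff(names(sc), c("centers_A", "widths_A", "centers_B",
                                      "widths_B"))]
        spec <- do.call(equilibrium_spec, c(sc, comp_args))
        generate_deer_dataset(spec, seed = derive_seed(seed, 1))
      })
      manifest$stage_log$simulate <- list(
        n_traces = length(results$simulate$conditions$traces),
        truth_pK = results$simulate$truth$pK,
        sub_seed = derive_seed(seed, 1))
      if (!is.null(out_dir)) {
        for (i in seq_along(results$simulate$conditions$traces))
          write_trace(results$simulate$conditions$traces[[i]],
                      file.path(out_dir, sprintf("trace_%02d.dat", i)))
        jsonlite::write_json(results$simulate$truth,
                             file.path(out_dir, "truth.json"),
                             auto_unbox = TRUE, digits = NA, force = TRUE)
      }
    } else if (stage == "fit") {
      results$fit <- run_stage("fit", function() {
        fc <- config$fit %||% list()
        conditions <- if (!is.null(fc$traces)) {
          files <- Sys.glob(fc$traces)
          if (!length(files)) stop("no trace files match ", fc$traces)
          for (f in files) manifest$inputs[[f]] <<- unname(tools::md5sum(f))
          condition_set(lapply(files, read_trace))
        } else if (!is.null(results$simulate)) {
          results$simulate$conditions
        } else stop("fit stage needs trace files or a preceding simulate stage")
        if (!is.null(fc$K))
          fit_global(conditions, K = fc$K, n_starts = fc$n_starts %||% 8,
                     seed = derive_seed(seed, 2),
                     fit_dims = isTRUE(fc$fit_dims))
        else
          choose_model(conditions, K_max = fc$K_max %||% 4,
                       criterion = fc$criterion %||% "bic",
                       n_starts = fc$n_starts %||% 8,
                       seed = derive_seed(seed, 2),
                       fit_dims = isTRUE(fc$fit_dims))
      })
      manifest$stage_log$fit <- list(
        K = results$fit$n_components, objective = results$fit$objective,
        centers = results$fit$components$r0, sub_seed = derive_seed(seed, 2))
      if (!is.null(out_dir)) {
        write_fit_report(results$fit, file.path(out_dir, "fit_report.json"))
        for (c in seq_len(nrow(results$fit$populations)))
          write_distribution(fitted_distribution(results$fit, c),
                             file.path(out_dir, sprintf("Pr_%s.dat",
                               rownames(results$fit$populations)[c])))
      }
    } else if (stage == "titrate") {
      results$titrate <- run_stage("titrate", function() {
        tc <- config$titrate %||% list()
        series <- if (!is.null(tc$series)) {
          manifest$inputs[[tc$series]] <<- unname(tools::md5sum(tc$series))
          read_titration_table(tc$series)
        } else if (!is.null(results$fit)) {
          comp <- tc$component_window %||% 1
          titrate_from_fits(results$fit, comp)
        } else stop("titrate stage needs a series file or a preceding fit stage")
        hill_fit(series, fix_n = tc$fix_n)
      })
      manifest$stage_log$titrate <- list(
        pK = results$titrate$pK, n = results$titrate$n,
        pK_2sigma = results$titrate$pK_2sigma,
        direction = results$titrate$direction)
      if (!is.null(results$simulate))
        manifest$stage_log$titrate$truth_pK <- results$simulate$truth$pK
    } else if (stage == "predict") {
      results$predict <- run_stage("predict", function() {
        pc <- config$predict %||% list()
        if (is.null(pc$structure)) stop("predict stage needs a structure path")
        manifest$inputs[[pc$structure]] <<- unname(tools::md5sum(pc$structure))
        st <- read_structure(pc$structure)
        if (is.null(pc$pairs)) stop("predict stage needs pairs")
        pairs <- strsplit(pc$pairs, "-")
        lapply(pairs, function(pr) {
          c1 <- build_label_cloud(st, pr[1], L = pc$L %||% 7,
                                  cone_half_angle = pc$cone_half_angle %||% 90,
                                  n_samples = pc$n_samples %||% 2000,
                                  clash_cutoff = pc$clash_cutoff %||% 2.5,
                                  seed = derive_seed(seed, 31))
          c2 <- build_label_cloud(st, pr[2], L = pc$L %||% 7,
                                  cone_half_angle = pc$cone_half_angle %||% 90,
                                  n_samples = pc$n_samples %||% 2000,
                                  clash_cutoff = pc$clash_cutoff %||% 2.5,
                                  seed = derive_seed(seed, 32))
          predict_distribution(c1, c2, smoothing = pc$smoothing %||% 0.05)
        })
      })
      manifest$stage_log$predict <- list(n_pairs = length(results$predict))
      if (!is.null(out_dir))
        for (i in seq_along(results$predict))
          write_distribution(results$predict[[i]],
                             file.path(out_dir, sprintf("predicted_%02d.dat", i)))
    } else if (stage == "cv") {
      results$cv <- run_stage("cv", function() {
        cc <- config$cv %||% list()
        if (is.null(cc$trajectory)) stop("cv stage needs a trajectory path")
        manifest$inputs[[cc$trajectory]] <<- unname(tools::md5sum(cc$trajectory))
        traj <- read_structure(cc$trajectory)
        out <- list()
        if (!is.null(cc$N_range)) {
          split <- split_domains(traj, cc$N_range, cc$C_range,
                                 mode = cc$split_mode %||% "by-sequence")
          out$angles <- t(vapply(seq_len(traj$n_models), function(m)
            compute_alpha_beta(traj, split, model = m), numeric(2)))
        }
        if (!is.null(cc$sb_donor)) {
          pair <- salt_bridge_pair(cc$sb_donor, cc$sb_acceptor,
                                   cutoff = cc$sb_cutoff %||% 4)
          out$salt_bridge <- salt_bridge_series(traj, pair,
                                                window = cc$window %||% 10)
        }
        if (!is.null(cc$restraints)) {
          rs <- utils::read.table(cc$restraints, comment.char = "#",
                                  col.names = c("pair", "target_nm", "k"))
          out$restraint <- restraint_energy(cc$distances_nm, rs)
        }
        out
      })
      manifest$stage_log$cv <- list(computed = names(results$cv))
    }
  }
  results$manifest <- manifest
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  results
}
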