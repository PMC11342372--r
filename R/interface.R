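#' Default run configuration
#'
#' The documented defaults of every module: fingerprint delta 0.2 A, bin
#' 0.5 A, r_max 8 A; clustering threshold 0.026 with minimum cluster size
#' 20; learning parameters (79, 3, 19, 68) with initial weight 100;
#' surrogate batches of 5 runs x 50 iterations, at most 20 batches,
#' e_min -563 eV, 100 trials; curation method 1 with delta_e 0.3 eV and 20
#' parents.
#'
#' @return nested named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    fingerprint = list(delta = 0.2, bin_width = 0.5, r_max = 8.0,
                       v_uc = 512.0),
    clustering = list(threshold = 0.026, min_size = 20L),
    agent = list(A = 79, B = 3, C = 19, D = 68,
                 initial_weight = 100, weight_floor = 1),
    trial = list(batch_size = 5L, iters_per_run = 50L, max_batches = 20L,
                 e_min = -563.0, n_trials = 100L),
    curation = list(method = 1L, delta_e = 0.3, target_size = 20L),
    ea = list(iters_per_run = 50L, n_selections = 100L,
              min_sep_frac = 0.70, relax_max_steps = 100L,
              force_tol = 0.05, lookalike_threshold = 0.005)
  ), class = "run_config")
}

# per-section validators; each returns an error message or NULL
check_positive <- function(x, key) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    stop("config key '", key, "': must be a positive number (got ",
         deparse(x), ")")
  }
}

#' Load a run configuration from a YAML file
#'
#' Unset keys fall back to [default_config()]; an empty file yields exactly
#' the defaults. Unknown sections or keys, and invalid values, raise a
#' validation error naming the offending key.
#'
#' @param path path to a YAML config file.
#' @return a validated `run_config` list.
#' @export
load_config <- function(path) {
  defaults <- default_config()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  bad_sections <- setdiff(names(user), c(names(defaults)))
  if (length(bad_sections) > 0) {
    stop("unknown config section '", bad_sections[1], "'")
  }
  cfg <- defaults
  for (sec in names(user)) {
    if (sec == "seed") {
      cfg$seed <- as.integer(user$seed)
      next
    }
    bad_keys <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(bad_keys) > 0) {
      stop("unknown config key '", sec, ".", bad_keys[1], "'")
    }
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  with(cfg$fingerprint, {
    check_positive(delta, "fingerprint.delta")
    check_positive(bin_width, "fingerprint.bin_width")
    check_positive(r_max, "fingerprint.r_max")
    check_positive(v_uc, "fingerprint.v_uc")
  })
  check_positive(cfg$clustering$threshold, "clustering.threshold")
  check_positive(cfg$clustering$min_size, "clustering.min_size")
  for (k in c("A", "B", "C", "D")) {
    v <- cfg$agent[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop("config key 'agent.", k, "': must be a non-negative number")
    }
  }
  check_positive(cfg$agent$initial_weight, "agent.initial_weight")
  check_positive(cfg$agent$weight_floor, "agent.weight_floor")
  for (k in c("batch_size", "iters_per_run", "max_batches", "n_trials")) {
    check_positive(cfg$trial[[k]], paste0("trial.", k))
  }
  if (!is.finite(cfg$trial$e_min)) stop("config key 'trial.e_min': must be finite")
  if (!cfg$curation$method %in% 1:3) {
    stop("config key 'curation.method': must be 1, 2 or 3")
  }
  check_positive(cfg$curation$delta_e, "curation.delta_e")
  check_positive(cfg$curation$target_size, "curation.target_size")
  for (k in c("iters_per_run", "n_selections", "min_sep_frac",
              "relax_max_steps", "force_tol")) {
    check_positive(cfg$ea[[k]], paste0("ea.", k))
  }
  cfg
}

# fingerprint_config from a run_config
fp_config_from <- function(cfg) {
  fingerprint_config(delta = cfg$fingerprint$delta,
                     bin_width = cfg$fingerprint$bin_width,
                     r_max = cfg$fingerprint$r_max,
                     v_uc = cfg$fingerprint$v_uc)
}

# minimal --key value / --flag parser for the CLI
parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  out
}

cli_opt <- function(opts, key, default = NULL, as = as.character) {
  if (is.null(opts[[key]])) default else as(opts[[key]])
}

#' Command-line entry point
#'
#' Subcommands:
#' * `fixtures --n N --seed S [--out lib.xyz] [--stoich C9H7N]` - build a
#'   synthetic structure library and write it as multi-frame XYZ.
#' * `cluster --in lib.xyz [--threshold 0.026] [--min-size 20]
#'   [--out assignment.csv]` - fingerprint, cluster and write the
#'   assignment.
#' * `tune --models models.csv --seed S [--stride 20] [--trials 30]
#'   [--emin -563] [--workers 1] [--out grid.csv]` - surrogate grid search,
#'   results sorted by success area.
#' * `simulate --models models.csv --seed S [--params 79,3,19,68]
#'   [--trials 100] [--emin -563] [--out curve.csv]` - surrogate trials for
#'   one parameter combination; writes the cumulative success curve.
#' * `run-ea --in lib.xyz --seed S [--method 1] [--delta-e 0.3]
#'   [--params 79,3,19,68] [--selections 100] [--iters 50]
#'   [--threshold 0.026] [--min-size 20] [--out record.json]` - clustered
#'   EA with the toy calculator.
#'
#' @param args character vector of command-line arguments (the subcommand
#'   followed by options).
#' @return exit status, invisibly (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: clusterEA <command> [options]\n",
    "commands: fixtures | cluster | tune | simulate | run-ea\n")
  if (length(args) < 1 || args[1] %in% c("-h", "--help", "help")) {
    cat(usage)
    return(invisible(if (length(args) < 1) 1L else 0L))
  }
  cmd <- args[1]
  if (!cmd %in% c("fixtures", "cluster", "tune", "simulate", "run-ea")) {
    message("unknown command: ", cmd, "\n", usage)
    return(invisible(1L))
  }
  opts <- parse_cli_args(args[-1])

  parse_stoich <- function(txt) {
    parts <- regmatches(txt, gregexpr("[A-Z][a-z]?[0-9]*", txt))[[1]]
    if (length(parts) == 0) stop("cannot parse stoichiometry: ", txt)
    els <- sub("[0-9]*$", "", parts)
    cnt <- as.integer(sub("^[A-Z][a-z]?", "", parts))
    cnt[is.na(cnt)] <- 1L
    stats::setNames(cnt, els)
  }
  parse_params <- function(txt) {
    v <- as.numeric(strsplit(txt, ",")[[1]])
    if (length(v) != 4) stop("--params must be four comma-separated values")
    learning_params(v[1], v[2], v[3], v[4])
  }

  if (cmd == "fixtures") {
    n <- cli_opt(opts, "n", 40L, as.integer)
    seed <- cli_opt(opts, "seed", NULL, as.integer)
    if (is.null(seed)) stop("fixtures: --seed is required")
    out <- cli_opt(opts, "out", "library.xyz")
    stoich <- parse_stoich(cli_opt(opts, "stoich", "C9H7N"))
    set.seed(seed)
    lib <- build_library(n, stoich)
    write_xyz(lib, out)
    message("wrote ", n, " structures to ", out, " (seed ", seed, ")")
  } else if (cmd == "cluster") {
    path <- cli_opt(opts, "in")
    if (is.null(path)) stop("cluster: --in is required")
    threshold <- cli_opt(opts, "threshold", 0.026, as.numeric)
    min_size <- cli_opt(opts, "min-size", 20L, as.integer)
    out <- cli_opt(opts, "out", "assignment.csv")
    lib <- read_xyz(path)
    a <- cluster_structures(lib, threshold = threshold, min_size = min_size)
    write_assignment(a, out)
    message(length(a$sizes), " clusters (sizes ",
            paste(a$sizes, collapse = ", "), ") written to ", out)
  } else if (cmd == "tune") {
    models_path <- cli_opt(opts, "models")
    models <- if (is.null(models_path)) cluster_models_fixture() else
      read_cluster_models(models_path)
    seed <- cli_opt(opts, "seed", NULL, as.integer)
    if (is.null(seed)) stop("tune: --seed is required")
    stride <- cli_opt(opts, "stride", 20L, as.integer)
    trials <- cli_opt(opts, "trials", 30L, as.integer)
    emin <- cli_opt(opts, "emin", -563.0, as.numeric)
    workers <- cli_opt(opts, "workers", 1L, as.integer)
    out <- cli_opt(opts, "out", "grid.csv")
    cfg <- trial_config(e_min = emin, n_trials = trials)
    res <- grid_search(models, stride = stride, cfg = cfg, seed = seed,
                       workers = workers)
    utils::write.csv(res, out, row.names = FALSE)
    message(nrow(res), " combinations written to ", out, "; best: A=",
            res$A[1], " B=", res$B[1], " C=", res$C[1], " D=", res$D[1],
            " area=", round(res$area[1], 1))
  } else if (cmd == "simulate") {
    models_path <- cli_opt(opts, "models")
    models <- if (is.null(models_path)) cluster_models_fixture() else
      read_cluster_models(models_path)
    seed <- cli_opt(opts, "seed", NULL, as.integer)
    if (is.null(seed)) stop("simulate: --seed is required")
    params <- parse_params(cli_opt(opts, "params", "79,3,19,68"))
    trials <- cli_opt(opts, "trials", 100L, as.integer)
    emin <- cli_opt(opts, "emin", -563.0, as.numeric)
    out <- cli_opt(opts, "out", "curve.csv")
    cfg <- trial_config(e_min = emin, n_trials = trials)
    set.seed(seed)
    results <- lapply(seq_len(cfg$n_trials), function(i)
      run_trial(models, params, cfg))
    curve <- cumulative_success_curve(results, cfg$max_iter)
    xs <- seq(0, cfg$max_iter, by = cfg$iters_per_run)
    utils::write.csv(data.frame(iteration = xs,
                                fraction = success_fraction(curve, xs)),
                     out, row.names = FALSE)
    message("success area ", round(success_area(curve), 1), " over ",
            cfg$n_trials, " trials; curve written to ", out)
  } else if (cmd == "run-ea") {
    path <- cli_opt(opts, "in")
    if (is.null(path)) stop("run-ea: --in is required")
    seed <- cli_opt(opts, "seed", NULL, as.integer)
    if (is.null(seed)) stop("run-ea: --seed is required")
    method <- cli_opt(opts, "method", 1L, as.integer)
    delta_e <- cli_opt(opts, "delta-e", 0.3, as.numeric)
    params <- parse_params(cli_opt(opts, "params", "79,3,19,68"))
    n_sel <- cli_opt(opts, "selections", 100L, as.integer)
    iters <- cli_opt(opts, "iters", 50L, as.integer)
    threshold <- cli_opt(opts, "threshold", 0.026, as.numeric)
    min_size <- cli_opt(opts, "min-size", 20L, as.integer)
    target_size <- cli_opt(opts, "target-size", 20L, as.integer)
    out <- cli_opt(opts, "out", "record.json")
    lib <- read_xyz(path)
    set.seed(seed)
    assignment <- cluster_structures(lib, threshold = threshold,
                                     min_size = min_size)
    clusters <- split_by_cluster(lib, assignment)
    cfg <- ea_config(iters_per_run = iters, n_selections = n_sel)
    rec <- clustered_ea(clusters, params,
                        curation_config(method, delta_e, target_size),
                        toy_calculator(), cfg)
    payload <- list(seed = seed, n_clusters = length(clusters),
                    best_energy = rec$best_energy,
                    success_iteration = rec$success_iteration,
                    log = rec$log)
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows"), out)
    message("best energy ", round(rec$best_energy, 4), " eV after ",
            nrow(rec$log), " selections; record written to ", out)
  }
  invisible(0L)
}
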