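#' Configuration-driven experiments
#'
#' [run_experiment()] ties the modules into reproducible experiment bundles
#' driven by a single config (typically a YAML file; see
#' [load_run_config()]). Four experiment kinds are supported:
#' \describe{
#'   \item{abm-moments}{agent-based run with stationary activity moments
#'     and the slow-manifold theory columns attached.}
#'   \item{ode-portrait}{replicator-like trajectories of A' from a set of
#'     initial conditions.}
#'   \item{phase-diagram}{stability phase diagram of the reasonable
#'     strategy over an (alpha2/alpha1, l) grid.}
#'   \item{ess-report}{ESS verdicts for every strategy of a game, well-mixed
#'     and temporal.}
#' }
#' Outputs are CSV/JSON artifacts plus a manifest (full resolved config,
#' seeds, package version); reloading a manifest reproduces the identical
#' config object.
#'
#' @name experiment
NULL

#' Load and validate a run configuration
#'
#' @param file YAML (or JSON) config path.
#' @return validated config list (class `run_config`).
#' @export
load_run_config <- function(file) {
  cfg <- if (grepl("\\.json$", file)) jsonlite::fromJSON(file,
                                                         simplifyVector = TRUE)
  else yaml::read_yaml(file)
  validate_run_config(cfg)
}

#' @rdname load_run_config
#' @param cfg a config list (already parsed).
#' @export
validate_run_config <- function(cfg) {
  errs <- character()
  kinds <- c("abm-moments", "ode-portrait", "phase-diagram", "ess-report")
  if (is.null(cfg$experiment) || !cfg$experiment %in% kinds)
    errs <- c(errs, paste0("experiment must be one of: ",
                           paste(kinds, collapse = ", ")))
  needs_game <- is.null(cfg$experiment) ||
    cfg$experiment %in% c("abm-moments", "ode-portrait", "ess-report")
  if (needs_game) {
    g <- tryCatch(config_game(cfg), error = function(e) conditionMessage(e))
    if (is.character(g)) errs <- c(errs, paste0("game: ", g))
  }
  if (identical(cfg$experiment, "abm-moments")) {
    d <- tryCatch(activity_dist_from_config(cfg$distribution),
                  error = function(e) conditionMessage(e))
    if (is.character(d)) errs <- c(errs, paste0("distribution: ", d))
    for (fld in c("N", "m", "delta"))
      if (is.null(cfg$net[[fld]]) || cfg$net[[fld]] < 1)
        errs <- c(errs, paste0("net.", fld, " must be a positive integer"))
    if (is.null(cfg$beta) || cfg$beta < 0)
      errs <- c(errs, "beta must be a non-negative real")
  }
  if (identical(cfg$experiment, "phase-diagram")) {
    if (is.null(cfg$alpha_ratio) || is.null(cfg$l))
      errs <- c(errs, "phase-diagram needs alpha_ratio and l grids")
  }
  if (length(errs))
    stop("invalid run config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  class(cfg) <- c("run_config", "list")
  cfg
}

config_game <- function(cfg) {
  g <- cfg$game
  if (is.null(g)) stop("missing 'game' block")
  if (!is.null(g$mug)) return(mug_matrix(g$mug$h, g$mug$l))
  if (!is.null(g$matrix))
    return(payoff_matrix(do.call(rbind, lapply(g$matrix, unlist)),
                         labels = unlist(g$labels)))
  stop("game block needs either 'mug: {h, l}' or 'matrix' rows")
}

config_alphas <- function(cfg, dist = NULL) {
  if (!is.null(cfg$alpha1))
    return(list(alpha1 = cfg$alpha1, alpha2 = cfg$alpha2 %||% 0))
  w <- selection_weights(cfg$beta, cfg$net$m, cfg$net$delta, dist)
  list(alpha1 = w$alpha1, alpha2 = w$alpha2)
}

#' Run a configured experiment
#'
#' @param config a `run_config` (or a path / plain list, which is loaded
#'   and validated first).
#' @param out output directory (created if missing).
#' @param seed master seed; overrides the config's seed if given.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list of produced artifact paths and the main
#'   result object.
#' @export
run_experiment <- function(config, out = tempfile("tegt-run-"), seed = NULL,
                           quiet = FALSE) {
  if (is.character(config)) config <- load_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- seed %||% config$seed %||% 20240529L
  say <- function(...) if (!quiet) message(...)
  artifacts <- list()
  result <- NULL

  if (config$experiment == "ess-report") {
    A <- config_game(config)
    al <- config_alphas(config)
    verdicts <- lapply(seq_len(nrow(A)), function(i) {
      wm <- ess_well_mixed(A, i)
      tn <- ess_temporal(A, al$alpha1, al$alpha2, i)
      list(strategy = rownames(A)[i],
           well_mixed = unname(wm$ess),
           temporal = tn$verdict,
           margins = tn$report$margin)
    })
    result <- verdicts
    path <- file.path(out, "ess-report.json")
    jsonlite::write_json(verdicts, path, auto_unbox = TRUE, digits = NA)
    artifacts$report <- path
    say("ESS report for ", nrow(A), " strategies -> ", path)
  } else if (config$experiment == "phase-diagram") {
    pd <- phase_diagram(unlist(config$alpha_ratio), unlist(config$l),
                        band = config$band %||% 0)
    result <- pd
    path <- file.path(out, "phase-diagram.csv")
    utils::write.csv(pd, path, row.names = FALSE)
    artifacts$grid <- path
    say("phase diagram with ", nrow(pd), " cells -> ", path)
  } else if (config$experiment == "ode-portrait") {
    A <- config_game(config)
    al <- config_alphas(config)
    Ap <- transformed_matrix(A, al$alpha1, al$alpha2)$A_prime
    n <- nrow(A)
    starts <- config$starts
    if (is.null(starts)) {
      set.seed(split_seed(seed, 1L))
      k <- config$n_starts %||% 20L
      starts <- lapply(seq_len(k), function(i) random_simplex(n))
    }
    t_end <- config$t_end %||% 500
    rows <- list()
    for (i in seq_along(starts)) {
      tr <- integrate_trajectory(Ap, unlist(starts[[i]]), t_end,
                                 mutation = config$mutation %||% 0)
      rows[[i]] <- data.frame(start = i, t = tr$times, tr$x)
    }
    traj <- do.call(rbind, rows)
    names(traj) <- c("start", "t", rownames(A))
    result <- traj
    path <- file.path(out, "trajectories.csv")
    utils::write.csv(traj, path, row.names = FALSE)
    artifacts$trajectories <- path
    say(length(starts), " trajectories integrated -> ", path)
  } else {  # abm-moments
    A <- config_game(config)
    d <- activity_dist_from_config(config$distribution)
    k_max <- config$k_max %||% 8L
    res <- run_abm(A, d, N = config$net$N, m = config$net$m,
                   delta = config$net$delta, beta = config$beta,
                   init_freq = unlist(config$init_freq %||%
                                        rep(1 / nrow(A), nrow(A))),
                   steps = config$steps %||% 1000L,
                   record_steps = config$record_steps %||% 250L,
                   k_max = k_max,
                   replicates = config$replicates %||% 1L,
                   seed = seed,
                   freeze_activities = isTRUE(config$freeze_activities))
    st <- apply(res$stationary, c(2, 3), mean)
    xbar <- st[, 1]
    theory <- slow_manifold_moments(xbar / sum(xbar), d, k_max)
    tab <- data.frame(strategy = rep(rownames(A), k_max + 1),
                      k = rep(0:k_max, each = nrow(A)),
                      moment = as.vector(st),
                      theory = as.vector(theory) * sum(xbar))
    result <- list(abm = res, table = tab)
    path <- file.path(out, "moments.csv")
    utils::write.csv(tab, path, row.names = FALSE)
    artifacts$moments <- path
    say("ABM moments (", config$replicates %||% 1L, " replicates) -> ", path)
  }

  manifest <- list(config = unclass(config), seed = seed,
                   package_version = as.character(utils::packageVersion("tegt")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mpath <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  artifacts$manifest <- mpath
  invisible(list(artifacts = artifacts, result = result, out = out))
}

#' Reload the config stored in a run manifest
#'
#' @param path manifest.json written by [run_experiment()].
#' @return the validated `run_config` it was produced from.
#' @export
read_manifest_config <- function(path) {
  man <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  validate_run_config(man$config)
}

random_simplex <- function(n) {
  e <- -log(stats::runif(n))
  e / sum(e)
}
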