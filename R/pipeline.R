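# End-to-end pipeline: synthesize -> extract surfaces -> plan -> optimize ->
# evaluate -> report, with per-case isolation directories and a manifest that
# makes reruns byte-reproducible.

#' Run one planning case (plan, optionally optimize, evaluate)
#'
#' Plans on the case's segmentation environment and evaluates clearance
#' against both the segmentation and the ground-truth environments.
#'
#' @param fixture an `ot_case_fixture` from [make_benchmark()].
#' @param rrt an [rrt_config()] (the fixture's seed is used if `seed` is NULL
#'   in the config call; pass a fully-specified config for reproducibility).
#' @param sco an [sco_config()], or `NULL` to skip optimization.
#' @param ds evaluation discretization, mm.
#' @return list with `plan` (`ot_plan_result`), `opt` (optimizer output or
#'   `NULL`), `case` (one-row evaluation data.frame with pre/post clearance).
#' @export
run_case <- function(fixture, rrt = rrt_config(max_iter = 3000L),
                     sco = sco_config(), ds = 0.1) {
  stopifnot(inherits(fixture, "ot_case_fixture"))
  rrt$seed <- as.integer(fixture$seed)
  pr <- tryCatch(
    plan_trajectory(fixture$env_seg, fixture$start, fixture$goal,
                    fixture$kappa_max, fixture$d_min, rrt),
    otoplan_precondition_error = function(e) {
      structure(list(success = FALSE, trajectory = NULL, iterations = 0L,
                     tree_sizes = c(start = 0L, goal = 0L),
                     cause = conditionMessage(e)),
                class = "ot_plan_result")
    })
  opt <- NULL
  final <- if (pr$success) pr$trajectory else NULL
  pre_min_seg <- if (pr$success) min_distance(pr$trajectory, fixture$env_seg, ds) else NA_real_
  if (pr$success && !is.null(sco)) {
    opt <- optimize_trajectory(pr$trajectory, fixture$env_seg,
                               fixture$kappa_max, fixture$d_min, sco)
    final <- opt$trajectory
  }
  ev <- evaluate_case(final, fixture$env_seg, fixture$env_gt, fixture$d_min,
                      ds = ds, case_id = fixture$case_id)
  ev$scenario <- fixture$scenario
  ev$seed <- fixture$seed
  ev$min_distance_initial <- pre_min_seg
  list(plan = pr, opt = opt, case = ev)
}

canonical_config <- function(cfg) {
  # stable key order so serialized configs (and their hash) are reproducible
  if (is.list(cfg)) {
    nm <- names(cfg)
    if (!is.null(nm) && all(nzchar(nm))) cfg <- cfg[order(nm)]
    cfg <- lapply(cfg, canonical_config)
  }
  cfg
}

# polynomial fingerprint of a character string (manifest config hash)
config_fingerprint <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full preoperative planning pipeline
#'
#' Generates (or loads) the benchmark cases, plans and optimizes every case,
#' evaluates the functional metrics, and writes per-case artifacts plus an
#' aggregate report and an execution manifest.  Reruns from an identical
#' configuration produce identical report JSON.
#'
#' @param config a list (or path to a YAML file) with fields:
#'   `out_dir` (artifact directory, or `NULL` for no artifacts),
#'   `n_cases`, `seed`, `scenarios`, `perturb` (`mode`, `magnitude`),
#'   `rrt` (overrides for [rrt_config()]), `sco` (overrides for
#'   [sco_config()], or `FALSE` to skip optimization), `ds`.
#' @return list with `report` (overall `ot_benchmark_report`),
#'   `per_scenario` (named list of reports), `cases` (per-case data.frame)
#'   and `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(out_dir = NULL, n_cases = 3L, seed = 1L,
                   scenarios = c("Access", "SSC-Access", "RL-Access"),
                   perturb = list(mode = "dilate", magnitude = 1),
                   rrt = list(max_iter = 3000L), sco = list(), ds = 0.1)
  cfg <- modifyList(defaults, config)
  bad <- setdiff(cfg$scenarios, c("Access", "SSC-Access", "RL-Access"))
  if (length(bad)) {
    stop("unknown scenario(s) in config: ", paste(bad, collapse = ", "))
  }
  stopifnot(cfg$n_cases >= 1, cfg$ds > 0)
  rrt <- do.call(rrt_config, cfg$rrt)
  sco <- if (identical(cfg$sco, FALSE)) NULL else do.call(sco_config, cfg$sco)

  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  fixtures <- make_benchmark(cfg$n_cases, seed = cfg$seed,
                             scenarios = cfg$scenarios, perturb = cfg$perturb)
  rows <- list()
  for (i in seq_along(fixtures)) {
    fx <- fixtures[[i]]
    res <- run_case(fx, rrt = rrt, sco = sco, ds = cfg$ds)
    rows[[i]] <- res$case
    if (!is.null(out_dir)) {
      cdir <- file.path(out_dir, fx$case_id)
      dir.create(cdir, showWarnings = FALSE)
      if (res$plan$success) {
        trajectory_to_json(res$plan$trajectory, file.path(cdir, "trajectory_initial.json"))
        if (!is.null(res$opt)) {
          trajectory_to_json(res$opt$trajectory, file.path(cdir, "trajectory_optimized.json"))
          if (nrow(res$opt$log)) {
            write.csv(res$opt$log, file.path(cdir, "sco_iterations.csv"),
                      row.names = FALSE)
          }
        }
        fz <- is_feasible(if (is.null(res$opt)) res$plan$trajectory else res$opt$trajectory,
                          fx$env_seg, fx$kappa_max, fx$d_min, ds = cfg$ds)
        jsonlite::write_json(fz, file.path(cdir, "feasibility.json"),
                             auto_unbox = TRUE, digits = NA)
      } else {
        jsonlite::write_json(list(success = FALSE, cause = res$plan$cause,
                                  iterations = res$plan$iterations,
                                  tree_sizes = as.list(res$plan$tree_sizes)),
                             file.path(cdir, "failure.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }
  cases <- do.call(rbind, rows)
  report <- aggregate_cases(cases)
  per_scenario <- lapply(split(cases, cases$scenario), aggregate_cases)

  if (!is.null(out_dir)) {
    cfg_json <- jsonlite::toJSON(canonical_config(cfg[setdiff(names(cfg), "out_dir")]),
                                 auto_unbox = TRUE, digits = NA)
    manifest <- list(package = "otoplan",
                     version = as.character(utils::packageVersion("otoplan")),
                     seed = cfg$seed, config = canonical_config(
                       cfg[setdiff(names(cfg), "out_dir")]),
                     config_hash = config_fingerprint(as.character(cfg_json)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rep_obj <- list(
      overall = report[c("r_s", "r_d", "r_f", "n_cases", "n_success")],
      per_scenario = lapply(per_scenario, function(r)
        r[c("r_s", "r_d", "r_f", "n_cases", "n_success")]),
      cases = cases)
    jsonlite::write_json(rep_obj, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  list(report = report, per_scenario = per_scenario, cases = cases,
       out_dir = out_dir)
}
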