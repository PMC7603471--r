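# Functional-evaluation metrics: scenario constraint sets, per-case safety
# evaluation against paired (planning, ground-truth) environments, and the
# aggregate success rate r_s, mean minimal distance r_d and failure rate r_f,
# plus Dice / Hausdorff segmentation utilities.

#' Planning scenario constraint sets
#'
#' The three access-canal scenarios and their printed constraints:
#' cochlear implantation (`"Access"`, kappa_max 0.05 / d_min 0.8 mm) and two
#' vestibular schwannoma approaches, through the superior semicircular canal
#' (`"SSC-Access"`, 0.05 / 1.5 mm) and retrolabyrinthine (`"RL-Access"`,
#' 0.05 / 2.0 mm).
#'
#' @param name one of `"Access"`, `"SSC-Access"`, `"RL-Access"`.
#' @return list with `name`, `kappa_max` (1/mm) and `d_min` (mm).
#' @export
scenario_defaults <- function(name) {
  tab <- list(
    "Access"     = list(kappa_max = 0.05, d_min = 0.8),
    "SSC-Access" = list(kappa_max = 0.05, d_min = 1.5),
    "RL-Access"  = list(kappa_max = 0.05, d_min = 2.0)
  )
  if (!name %in% names(tab)) {
    stop(sprintf("unknown scenario '%s'; valid names: %s", name,
                 paste(names(tab), collapse = ", ")))
  }
  c(list(name = name), tab[[name]])
}

#' Full planning scenario (constraints plus endpoint states)
#'
#' @param name scenario name (see [scenario_defaults()]).
#' @param start,goal `ot_state` endpoint configurations.
#' @param kappa_max,d_min optional overrides of the scenario defaults.
#' @export
planning_scenario <- function(name, start, goal, kappa_max = NULL, d_min = NULL) {
  def <- scenario_defaults(name)
  stopifnot(is_ot_state(start), is_ot_state(goal))
  kappa_max <- if (is.null(kappa_max)) def$kappa_max else kappa_max
  d_min <- if (is.null(d_min)) def$d_min else d_min
  stopifnot(kappa_max >= 0, d_min > 0)
  structure(list(name = name, kappa_max = kappa_max, d_min = d_min,
                 start = start, goal = goal),
            class = "ot_scenario")
}

#' Evaluate one planned case against planning and ground-truth surfaces
#'
#' Computes the minimal distance of the trajectory to the surfaces used for
#' planning and to the ground-truth surfaces; the safety is violated when
#' the ground-truth clearance falls below `d_min` (the planned path is too
#' close to the true position of the risk structures).
#'
#' @param traj an `ot_trajectory`, an `ot_plan_result`, or anything else
#'   (treated as a planning failure).
#' @param env_planning environment the trajectory was planned against.
#' @param env_gt ground-truth environment.
#' @param d_min safety distance, mm.
#' @param ds discretization step for the distance evaluation, mm.
#' @param case_id optional case identifier.
#' @return one-row `data.frame` with columns `case_id`, `planned`,
#'   `min_distance_planning`, `min_distance_gt`, `violated`.
#' @export
evaluate_case <- function(traj, env_planning, env_gt, d_min, ds = 0.1,
                          case_id = NA_character_) {
  stopifnot(ds > 0)
  if (inherits(traj, "ot_plan_result")) {
    traj <- if (isTRUE(traj$success)) traj$trajectory else NULL
  }
  if (!inherits(traj, "ot_trajectory")) {
    return(data.frame(case_id = case_id, planned = FALSE,
                      min_distance_planning = NA_real_,
                      min_distance_gt = NA_real_, violated = NA))
  }
  dp <- min_distance(traj, env_planning, ds)
  dg <- min_distance(traj, env_gt, ds)
  data.frame(case_id = case_id, planned = TRUE,
             min_distance_planning = dp, min_distance_gt = dg,
             violated = dg < d_min)
}

#' Aggregate case results into the benchmark metrics
#'
#' The success rate `r_s` is the fraction of cases with a planned
#' trajectory; the mean minimal distance `r_d` averages the clearance on the
#' planning surfaces over successful cases only; the failure rate `r_f` is
#' the fraction of successful cases whose ground-truth clearance violates
#' `d_min`.  With zero successes, `r_d` and `r_f` are undefined and reported
#' as `NA`.
#'
#' @param results `data.frame` of rows from [evaluate_case()].
#' @return an `ot_benchmark_report`: list with `r_s`, `r_d`, `r_f`,
#'   `n_cases`, `n_success`, and the per-case `results`.
#' @export
aggregate_cases <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  n <- nrow(results)
  succ <- results$planned
  ns <- sum(succ)
  r_s <- ns / n
  if (ns == 0) {
    r_d <- NA_real_; r_f <- NA_real_
  } else {
    r_d <- mean(results$min_distance_planning[succ])
    r_f <- sum(results$violated[succ]) / ns
  }
  structure(list(r_s = r_s, r_d = r_d, r_f = r_f, n_cases = n,
                 n_success = ns, results = results),
            class = "ot_benchmark_report")
}

#' @export
print.ot_benchmark_report <- function(x, ...) {
  cat(sprintf("<ot_benchmark_report> %d cases: r_s = %.3f, r_d = %s mm, r_f = %s\n",
              x$n_cases, x$r_s,
              if (is.na(x$r_d)) "NA" else sprintf("%.3f", x$r_d),
              if (is.na(x$r_f)) "NA" else sprintf("%.3f", x$r_f)))
  invisible(x)
}

#' Dice coefficient and Hausdorff distance between two binary masks
#'
#' Dice = 2|A n B| / (|A| + |B|); the Hausdorff distance is the classical
#' (maximum) symmetric Hausdorff distance between the surface voxels of the
#' two masks, in physical millimetres.
#'
#' @param mask_a,mask_b binary 3D arrays on the same grid.
#' @param spacing voxel spacing, mm.
#' @return list with `dice` and `hd` (mm).
#' @export
dice_hausdorff <- function(mask_a, mask_b, spacing = c(1, 1, 1)) {
  mask_a <- as.array(mask_a); mask_b <- as.array(mask_b)
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks must share the same grid")
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  a <- mask_a != 0; b <- mask_b != 0
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) stop("both masks are empty")
  dice <- 2 * sum(a & b) / (na + nb)
  if (na == 0 || nb == 0) return(list(dice = dice, hd = Inf))
  sa <- surface_voxels_cpp(as.integer(a), dim(a))
  sb <- surface_voxels_cpp(as.integer(b), dim(b))
  pa <- sweep(sa - 1, 2, spacing, `*`)
  pb <- sweep(sb - 1, 2, spacing, `*`)
  hd <- hausdorff_points_cpp(pa, pb)
  list(dice = dice, hd = hd)
}
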