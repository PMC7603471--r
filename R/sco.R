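# Sequential convex optimization of spline trajectories.
#
# The decision variables are the interior waypoints (the first and last two
# are fixed, which pins both endpoint positions and directions).  The cost is
# a weighted sum of the squared-length surrogate f_Gamma and per-spline
# clearance terms theta - sd(W_i); constraints keep the clearance above d_min
# and, where a spline exceeds kappa_max, penalise the distance to the
# straightened waypoint targets.  Signed distances are linearized around
# nearest points that stay frozen within each convexification; the convex
# subproblems (quadratic cost + l1 hinge penalties in a trust-region box) are
# solved by ADMM.  The outer scheme is the classic penalty / convexify /
# trust-region triple loop with an l1 exact-penalty merit function.

#' SCO configuration
#'
#' Defaults follow the printed parameter setup where legible: 15 penalty
#' iterations, 50 convexifications, 10 trust-region iterations, trust factors
#' `tau_plus` 1.1 / `tau_minus` 0.9, tolerances `eps_x` = `eps_f` = 1e-4 and
#' `eps_c` = 0.25, penalty scaling `k` = 10.  The remaining cells of the
#' printed table are garbled in the source; `mu0` = 0.5, `s0` = 0.15 mm,
#' `theta` = 1 mm, `alpha_len` = 1 and `alpha_obs` = 10 are reconstructed
#' defaults, all exposed here.
#'
#' @param n_penalty,n_convexify,n_trust iteration caps of the three loops.
#' @param tau_plus,tau_minus trust-region expansion / shrink factors.
#' @param eps_x,eps_f,eps_c convergence margins for the step, the cost and
#'   the constraint violation.
#' @param k penalty scaling factor.
#' @param mu0 initial penalty value.
#' @param s0 initial trust-region half-width, mm.
#' @param theta clearance target, mm (should be well above `d_min` for a
#'   noticeable clearance improvement).
#' @param alpha_len,alpha_obs cost weights of the length surrogate and the
#'   clearance terms.
#' @export
sco_config <- function(n_penalty = 15L, n_convexify = 50L, n_trust = 10L,
                       tau_plus = 1.1, tau_minus = 0.9,
                       eps_x = 1e-4, eps_f = 1e-4, eps_c = 0.25,
                       k = 10, mu0 = 0.5, s0 = 0.15, theta = 1,
                       alpha_len = 1, alpha_obs = 10) {
  stopifnot(n_penalty >= 1, n_convexify >= 1, n_trust >= 1,
            tau_plus > 1, tau_minus < 1, tau_minus > 0,
            eps_x > 0, eps_f > 0, eps_c > 0, k > 1, mu0 > 0, s0 > 0, theta > 0,
            alpha_len >= 0, alpha_obs >= 0)
  structure(list(n_penalty = as.integer(n_penalty),
                 n_convexify = as.integer(n_convexify),
                 n_trust = as.integer(n_trust),
                 tau_plus = tau_plus, tau_minus = tau_minus,
                 eps_x = eps_x, eps_f = eps_f, eps_c = eps_c,
                 k = k, mu0 = mu0, s0 = s0, theta = theta,
                 alpha_len = alpha_len, alpha_obs = alpha_obs),
            class = "ot_sco_config")
}

#' Squared-length cost surrogate of a waypoint sequence
#'
#' Sum over consecutive waypoint pairs of the squared coordinate differences
#' (squared segment lengths, not lengths) -- the smoothness/length surrogate
#' minimised by the optimizer.
#'
#' @param waypoints `n x 3` matrix, `n >= 2`.
#' @export
cost_length <- function(waypoints) {
  W <- as.matrix(waypoints)
  stopifnot(nrow(W) >= 2, ncol(W) == 3)
  sum((W[-1, , drop = FALSE] - W[-nrow(W), , drop = FALSE])^2)
}

#' Per-spline clearance cost terms
#'
#' One term per spline, evaluated at the spline's central (interior)
#' waypoint: `theta - sd(W_i)`.  Negative values mean the clearance already
#' exceeds the target `theta` (no clamping).
#'
#' @param traj an `ot_trajectory`.
#' @param env an `ot_environment`.
#' @param theta clearance target, mm (> 0).
#' @return named numeric vector indexed by interior waypoint.
#' @export
clearance_cost <- function(traj, env, theta) {
  stopifnot(inherits(traj, "ot_trajectory"), theta > 0)
  n <- nrow(traj$waypoints)
  if (n < 3) return(setNames(numeric(0), character(0)))
  interior <- 2:(n - 1)
  sd <- signed_distance_batch(env, traj$waypoints[interior, , drop = FALSE])
  setNames(theta - sd, interior)
}

#' Straightening targets and curvature penalty of a waypoint triple
#'
#' For an interior waypoint `i`, computes the translated waypoint targets
#' \eqn{\bar W_{i-1}, \bar W_i, \bar W_{i+1}} (built from the midpoints
#' \eqn{P_i = (W_{i-1}+W_{i+1})/2} and \eqn{Q_i = (W_i+P_i)/2}) that
#' straighten the local spline, and the penalty
#' \eqn{g_{i,\kappa} = \sum_j \sum_k |W_{i+j,k} - \bar W_{i+j,k}|^2}.
#'
#' @param waypoints `n x 3` matrix.
#' @param i interior waypoint index (`2 <= i <= n - 1`).
#' @return list with `targets` (3 x 3 matrix: rows i-1, i, i+1) and `g`.
#' @export
curvature_smoothing <- function(waypoints, i) {
  W <- as.matrix(waypoints)
  n <- nrow(W)
  if (!(i >= 2 && i <= n - 1)) stop("i must index an interior waypoint")
  P <- (W[i - 1, ] + W[i + 1, ]) / 2
  Q <- (W[i, ] + P) / 2
  tgt <- rbind(Q + (W[i - 1, ] - P),
               (W[i, ] + Q) / 2,
               Q + (W[i + 1, ] - P))
  g <- sum((W[(i - 1):(i + 1), ] - tgt)^2)
  list(targets = tgt, g = g)
}

# --- subproblem construction ----------------------------------------------

# map: waypoint index + coordinate -> position in the free displacement
# vector, or 0 if that waypoint is fixed
free_map <- function(n, free_idx) {
  m <- matrix(0L, n, 3)
  if (length(free_idx)) {
    m[free_idx, ] <- matrix(seq_len(3 * length(free_idx)), ncol = 3, byrow = TRUE)
  }
  m
}

# Assemble the convex quadratic model around the current waypoints.
# anchors: list over interior waypoints with sd / normal (NULL if no env).
build_subproblem <- function(W, free_idx, anchors, active, cfg, kappa_max,
                             d_min, s) {
  n <- nrow(W)
  interior <- if (n >= 3) 2:(n - 1) else integer(0)
  nf <- 3 * length(free_idx)
  fm <- free_map(n, free_idx)
  H0 <- matrix(0, nf, nf); c0 <- numeric(nf); const0 <- 0
  Hk <- matrix(0, nf, nf); ck <- numeric(nf); constk <- 0
  Arows <- list(); bvals <- numeric(0)
  hinge_const <- 0

  add_quad_row <- function(H, c, idxs, coefs, const, weight) {
    # term weight * (const + sum coefs * delta[idxs])^2, idxs may contain 0
    keep <- idxs > 0
    ii <- idxs[keep]; cc <- coefs[keep]
    if (length(ii)) {
      H[ii, ii] <- H[ii, ii] + 2 * weight * outer(cc, cc)
      c[ii] <- c[ii] + 2 * weight * cc * const
    }
    list(H = H, c = c, const = weight * const^2)
  }

  # f_Gamma: squared segment lengths
  for (leg in 1:(n - 1)) {
    for (k3 in 1:3) {
      r <- add_quad_row(H0, c0, c(fm[leg, k3], fm[leg + 1, k3]), c(1, -1),
                        W[leg, k3] - W[leg + 1, k3], cfg$alpha_len)
      H0 <- r$H; c0 <- r$c; const0 <- const0 + r$const
    }
  }
  # clearance cost and hinge constraints
  if (!is.null(anchors)) {
    for (j in seq_along(interior)) {
      i <- interior[j]
      sd0 <- anchors$sd[j]; nrm <- anchors$normal[j, ]
      const0 <- const0 + cfg$alpha_obs * (cfg$theta - sd0)
      bj <- d_min - sd0
      if (fm[i, 1] > 0) {
        c0[fm[i, ]] <- c0[fm[i, ]] - cfg$alpha_obs * nrm
        row <- numeric(nf)
        row[fm[i, ]] <- -nrm
        Arows[[length(Arows) + 1]] <- row
        bvals <- c(bvals, bj)
      } else {
        hinge_const <- hinge_const + max(0, bj)
      }
    }
  }
  # curvature penalties for active splines: g_i = sum over the three
  # straightening rows; closed form g_i = (9/64) |W_{i-1} - 2 W_i + W_{i+1}|^2
  for (i in active) {
    for (k3 in 1:3) {
      idxs <- c(fm[i - 1, k3], fm[i, k3], fm[i + 1, k3])
      const <- W[i - 1, k3] - 2 * W[i, k3] + W[i + 1, k3]
      r <- add_quad_row(Hk, ck, idxs, c(1, -2, 1), const, 9 / 64)
      Hk <- r$H; ck <- r$c; constk <- constk + r$const
    }
  }
  A <- if (length(Arows)) do.call(rbind, Arows) else matrix(0, 0, nf)
  structure(list(
    H0 = H0, c0 = c0, const0 = const0,
    Hk = Hk, ck = ck, constk = constk,
    A = A, b = bvals, hinge_const = hinge_const,
    s = s, free_idx = free_idx, n = n,
    fixed_waypoints = setdiff(seq_len(n), free_idx),
    n_eq = 3 * length(setdiff(seq_len(n), free_idx)),
    active = active, anchors = anchors
  ), class = "ot_convex_subproblem")
}

# model merit value at displacement delta for penalty mu
subproblem_merit <- function(sp, delta, mu) {
  q0 <- 0.5 * sum(delta * ((sp$H0 + mu * sp$Hk) %*% delta)) +
    sum((sp$c0 + mu * sp$ck) * delta)
  hin <- if (nrow(sp$A)) sum(pmax(0, sp$A %*% delta + sp$b)) else 0
  sp$const0 + mu * sp$constk + q0 + mu * (hin + sp$hinge_const)
}

#' Convexify a trajectory around its current waypoints
#'
#' Builds the convex quadratic subproblem of one SCO convexification:
#' the exact quadratic length surrogate plus linearized clearance costs,
#' hinge inequality constraints `d_min - sd <= 0` per spline, quadratic
#' straightening penalties for splines currently exceeding `kappa_max`, and
#' equality constraints fixing the first and last two waypoints.  Signed
#' distances are linearized about anchors (nearest point and normal) frozen
#' at the current waypoints; at zero displacement every linearized quantity
#' equals its true value.
#'
#' @param traj an `ot_trajectory`.
#' @param env an `ot_environment` (or `NULL`).
#' @param cfg an [sco_config()].
#' @param state list with elements `mu` (penalty) and `s` (trust half-width);
#'   defaults to the configuration's initial values.
#' @param d_min safety distance, mm.
#' @return an `ot_convex_subproblem`.
#' @export
convexify <- function(traj, env, cfg, state = NULL, d_min = 0.5) {
  stopifnot(inherits(traj, "ot_trajectory"), inherits(cfg, "ot_sco_config"))
  if (is.null(state)) state <- list(mu = cfg$mu0, s = cfg$s0)
  W <- traj$waypoints
  n <- nrow(W)
  free_idx <- if (n >= 5) 3:(n - 2) else integer(0)
  interior <- if (n >= 3) 2:(n - 1) else integer(0)
  anchors <- NULL
  if (!is.null(env) && length(interior)) {
    q <- signed_distance_query_batch(env, W[interior, , drop = FALSE])
    anchors <- list(sd = q$sd, normal = q$normal, nearest = q$nearest)
  }
  kappas <- corner_curvatures(traj)
  active <- intersect(which(kappas > traj$kappa_max), interior)
  build_subproblem(W, free_idx, anchors, active, cfg, traj$kappa_max, d_min,
                   state$s)
}

#' Solve a convex subproblem (ADMM)
#'
#' Minimises the quadratic model plus `mu` times the l1 hinge penalties
#' inside the trust-region box.  Alternating direction method of multipliers
#' with box projection and hinge proximal steps; iterated to a tight
#' residual, so the result agrees with the exact minimiser to high accuracy.
#'
#' @param sp an `ot_convex_subproblem`.
#' @param mu penalty value.
#' @return displacement vector (length `3 * n_free`), box-feasible.
#' @export
solve_subproblem <- function(sp, mu) {
  nf <- length(sp$c0)
  if (nf == 0) return(numeric(0))
  H <- sp$H0 + mu * sp$Hk
  cc <- sp$c0 + mu * sp$ck
  A <- sp$A; b <- sp$b
  nh <- nrow(A)
  s <- sp$s
  rho <- max(1, mean(abs(diag(H))))
  M <- H + rho * diag(nf)
  if (nh) M <- M + rho * crossprod(A)
  R <- chol(M)
  u <- numeric(nf); p1 <- numeric(nf)
  v <- if (nh) as.numeric(b) else numeric(0)
  p2 <- numeric(nh)
  kappa_prox <- mu / rho
  delta <- numeric(nf)
  for (it in seq_len(20000L)) {
    rhs <- -cc + rho * (u - p1)
    if (nh) rhs <- rhs + rho * as.numeric(crossprod(A, v - b - p2))
    delta_new <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
    Ad <- if (nh) as.numeric(A %*% delta_new + b) else numeric(0)
    u_new <- pmin(pmax(delta_new + p1, -s), s)
    if (nh) {
      w <- Ad + p2
      v_new <- ifelse(w < 0, w, ifelse(w > kappa_prox, w - kappa_prox, 0))
    } else v_new <- v
    p1 <- p1 + delta_new - u_new
    if (nh) p2 <- p2 + Ad - v_new
    prim <- max(abs(delta_new - u_new), if (nh) abs(Ad - v_new) else 0)
    dual <- max(abs(u_new - u), if (nh) abs(v_new - v) else 0)
    chg <- max(abs(delta_new - delta))
    delta <- delta_new; u <- u_new; v <- v_new
    if (prim < 1e-11 && rho * dual < 1e-11 && chg < 1e-12 && it > 5) break
  }
  u
}

# --- the optimizer ---------------------------------------------------------

# true l1 merit at waypoints W (exact signed distances, fixed active set)
true_merit_fn <- function(W, env, cfg, d_min, mu, active) {
  n <- nrow(W)
  interior <- if (n >= 3) 2:(n - 1) else integer(0)
  f <- cfg$alpha_len * cost_length(W)
  viol <- 0
  if (!is.null(env) && length(interior)) {
    sd <- signed_distance_batch(env, W[interior, , drop = FALSE])
    f <- f + cfg$alpha_obs * sum(cfg$theta - sd)
    viol <- viol + sum(pmax(0, d_min - sd))
  }
  for (i in active) viol <- viol + curvature_smoothing(W, i)$g
  list(merit = f + mu * viol, f = f, viol = viol)
}

max_violation <- function(W, env, start, goal, kappa_max, d_min) {
  n <- nrow(W)
  interior <- if (n >= 3) 2:(n - 1) else integer(0)
  v_sd <- 0
  if (!is.null(env) && length(interior)) {
    sd <- signed_distance_batch(env, W[interior, , drop = FALSE])
    v_sd <- max(0, max(d_min - sd))
  }
  traj <- build_trajectory(W, start, goal, kappa_max, clamp = TRUE)
  v_kappa <- max(0, (traj$max_curvature - kappa_max) / kappa_max)
  max(v_sd, v_kappa)
}

#' Optimize a trajectory for length and clearance (SCO)
#'
#' Runs the penalty / convexification / trust-region triple loop on the
#' interior waypoints of an initial trajectory.  The first and last two
#' waypoints are fixed, so the endpoint states of the result are bit-identical
#' to the input.  Terminates on convergence (step below `eps_x`, cost change
#' below `eps_f`, max constraint violation below `eps_c`) or on iteration
#' exhaustion; non-convergence is a reported status, not an error.
#'
#' @param traj initial `ot_trajectory` (typically from [plan_trajectory()]).
#' @param env an `ot_environment` (or `NULL` for free space).
#' @param kappa_max curvature bound, 1/mm.
#' @param d_min safety distance, mm.
#' @param cfg an [sco_config()].
#' @return list with `trajectory` (optimized), `report` (status, final
#'   penalty, violation) and `log` (one row per trust-region iteration:
#'   penalty/convexification/trust indices, mu, s, true cost, merit before
#'   and after, model decrease, acceptance).
#' @export
optimize_trajectory <- function(traj, env, kappa_max, d_min,
                                cfg = sco_config()) {
  stopifnot(inherits(traj, "ot_trajectory"), inherits(cfg, "ot_sco_config"))
  start <- traj$start; goal <- traj$goal
  W <- traj$waypoints
  n <- nrow(W)
  free_idx <- if (n >= 5) 3:(n - 2) else integer(0)
  log_rows <- list()
  if (!length(free_idx)) {
    return(list(trajectory = traj,
                report = list(status = "no-free-waypoints", converged = TRUE,
                              mu = cfg$mu0, violation = 0, f = cost_length(W)),
                log = data.frame()))
  }
  fm <- free_map(n, free_idx)
  apply_delta <- function(W, delta) {
    W2 <- W
    for (j in seq_along(free_idx)) {
      W2[free_idx[j], ] <- W[free_idx[j], ] + delta[(3 * j - 2):(3 * j)]
    }
    W2
  }

  mu <- cfg$mu0
  s <- cfg$s0
  converged <- FALSE
  interior <- 2:(n - 1)
  for (p_it in seq_len(cfg$n_penalty)) {
    f_prev <- NA_real_
    for (c_it in seq_len(cfg$n_convexify)) {
      traj_cur <- build_trajectory(W, start, goal, kappa_max, clamp = TRUE)
      kappas <- corner_curvatures(traj_cur)
      active <- intersect(which(kappas > kappa_max), interior)
      anchors <- NULL
      if (!is.null(env)) {
        q <- signed_distance_query_batch(env, W[interior, , drop = FALSE])
        anchors <- list(sd = q$sd, normal = q$normal, nearest = q$nearest)
      }
      sp <- build_subproblem(W, free_idx, anchors, active, cfg, kappa_max,
                             d_min, s)
      m0 <- true_merit_fn(W, env, cfg, d_min, mu, active)
      accepted <- FALSE
      step_inf <- 0
      for (t_it in seq_len(cfg$n_trust)) {
        sp$s <- s
        delta <- solve_subproblem(sp, mu)
        model_new <- subproblem_merit(sp, delta, mu)
        # model merit at zero displacement equals the true merit at W
        model_dec <- subproblem_merit(sp, numeric(length(delta)), mu) - model_new
        if (model_dec <= 1e-12) break  # model optimal at current point
        Wc <- apply_delta(W, delta)
        mc <- true_merit_fn(Wc, env, cfg, d_min, mu, active)
        ratio <- (m0$merit - mc$merit) / model_dec
        ok <- is.finite(ratio) && ratio > 0.25
        log_rows[[length(log_rows) + 1]] <- data.frame(
          penalty_iter = p_it, convexify_iter = c_it, trust_iter = t_it,
          mu = mu, s = s, f = m0$f, merit_before = m0$merit,
          merit_after = mc$merit, model_decrease = model_dec,
          accepted = ok)
        if (ok) {
          W <- Wc
          step_inf <- max(abs(delta))
          s <- min(s * cfg$tau_plus, 10 * cfg$s0)
          accepted <- TRUE
          break
        } else {
          s <- s * cfg$tau_minus
          if (s < cfg$eps_x) break
        }
      }
      f_cur <- true_merit_fn(W, env, cfg, d_min, mu, active)$f
      if (!accepted) break
      if (step_inf < cfg$eps_x &&
          !is.na(f_prev) && abs(f_prev - f_cur) < cfg$eps_f) break
      f_prev <- f_cur
      if (s < cfg$eps_x) break
    }
    viol <- max_violation(W, env, start, goal, kappa_max, d_min)
    if (viol <= cfg$eps_c) { converged <- TRUE; break }
    mu <- mu * cfg$k
  }
  out_traj <- build_trajectory(W, start, goal, kappa_max, clamp = TRUE)
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else data.frame()
  list(trajectory = out_traj,
       report = list(status = if (converged) "converged" else "iteration-limit",
                     converged = converged, mu = mu,
                     violation = max_violation(W, env, start, goal, kappa_max,
                                               d_min),
                     f = true_merit_fn(W, env, cfg, d_min, mu,
                                       integer(0))$f),
       log = log_df)
}
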