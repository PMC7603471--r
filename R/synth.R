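# Seeded synthetic temporal-bone-like anatomy.
#
# The generator emulates the topology and spatial scale of the nine risk
# structures of the otobasis (sub-millimetre nerve tubes, millimetre-scale
# vessels and canals, a spiral cochlea analogue, three semicircular arcs, an
# ossicle blob cluster) inside a ~48 mm field surrounded by a spherical
# "skull" shell used for start placement.  It mimics scale and topology, NOT
# anatomical shape: it exists so the planning/optimization/evaluation
# pipeline is fully testable without patient data, and must never be
# mistaken for a model of real anatomy.

OT_LABELS <- c(ICA = 1L, JV = 2L, FN = 3L, Coc = 4L, ChT = 5L, Oss = 6L,
               SCC = 7L, IAC = 8L, EAC = 9L, Skull = 10L)

# base structure geometry (mm), designed around a 48 mm cubic field
base_anatomy_structures <- function() {
  # cochlea-analogue spiral around T = (16, 24, 20)
  Tc <- c(16, 24, 20)
  th <- seq(0, 3.5 * pi, length.out = 40)
  rsp <- 2.2 * (1 - 0.8 * th / (3.5 * pi))
  e1 <- c(1, 0, 0); e2 <- c(0, 0.3, 0.954)
  coc_path <- t(Tc + t(outer(rsp * cos(th), e1) + outer(rsp * sin(th), e2)))
  coc_r <- 1.3 - 0.8 * th / (3.5 * pi)
  # three semicircular-canal arcs around S = (11, 20, 28)
  S <- c(11, 20, 28)
  arc <- function(centre, u, v, radius, from, to, n = 36) {
    a <- seq(from, to, length.out = n)
    t(centre + t(outer(radius * cos(a), u) + outer(radius * sin(a), v)))
  }
  scc_paths <- list(
    arc(S + c(0, 0, 0.8), c(1, 0, 0), c(0, 1, 0), 3.2, 0, 4 * pi / 3),
    arc(S + c(0.8, 0, 0), c(0, 1, 0), c(0, 0, 1), 3.2, pi / 3, pi / 3 + 4 * pi / 3),
    arc(S + c(0, 0.8, 0), c(1, 0, 0), c(0, 0, 1), 3.2, 2 * pi / 3, 2 * pi / 3 + 4 * pi / 3)
  )
  list(
    ICA = list(label = OT_LABELS[["ICA"]], type = "tube",
               path = rbind(c(28, 6, 8), c(18, 14, 9), c(10, 22, 10)), radius = 2.0),
    JV  = list(label = OT_LABELS[["JV"]], type = "tube",
               path = rbind(c(28, 42, 8), c(18, 34, 9), c(13, 28, 11)), radius = 2.5,
               bulb = c(13, 28, 11), bulb_radius = 3.0),
    EAC = list(label = OT_LABELS[["EAC"]], type = "tube",
               path = rbind(c(43, 24, 14), c(22, 24, 15)), radius = 2.8),
    IAC = list(label = OT_LABELS[["IAC"]], type = "tube",
               path = rbind(c(10, 14, 22), c(10, 34, 22)), radius = 2.5),
    SCC = list(label = OT_LABELS[["SCC"]], type = "arcs",
               paths = scc_paths, radius = 0.6),
    Coc = list(label = OT_LABELS[["Coc"]], type = "spiral",
               path = coc_path, radii = coc_r, centre = Tc),
    Oss = list(label = OT_LABELS[["Oss"]], type = "spheres",
               centres = rbind(c(22, 28.5, 24), c(23.5, 29.5, 25), c(22.8, 27.8, 23.5)),
               radii = c(1.2, 0.9, 0.7)),
    FN  = list(label = OT_LABELS[["FN"]], type = "tube",
               path = rbind(c(13, 28, 28), c(14.5, 27, 23), c(16, 26.5, 19),
                            c(17.5, 26, 13)), radius = 0.7),
    ChT = list(label = OT_LABELS[["ChT"]], type = "tube",
               path = rbind(c(16, 26.5, 19), c(20, 26.8, 22), c(25, 27, 25.5)),
               radius = 0.45),
    Skull = list(label = OT_LABELS[["Skull"]], type = "shell",
                 centre = c(24, 24, 24), semi = c(22, 22, 22), thickness = 1.2)
  )
}

#' Parameters of the synthetic anatomy generator
#'
#' Defaults emulate the imaging conditions of a temporal-bone CT label
#' volume: anisotropic 0.2 x 0.2 x 0.4 mm spacing over a ~48 mm field.
#' Structure geometry (paths, radii) can be overridden through `structures`.
#'
#' @param dims grid size (voxels).
#' @param spacing voxel spacing, mm.
#' @param origin physical position of voxel (1,1,1), mm.
#' @param seed integer seed for the geometric jitter.
#' @param jitter_global half-range of the rigid whole-anatomy jitter, mm.
#' @param jitter_structure half-range of the per-structure jitter, mm.
#' @param radius_jitter relative half-range of per-structure radius scaling.
#' @param structures structure geometry list (defaults to the built-in
#'   temporal-bone-like layout).
#' @export
anatomy_params <- function(dims = c(240, 240, 120), spacing = c(0.2, 0.2, 0.4),
                           origin = c(0, 0, 0), seed = 1L,
                           jitter_global = 0.8, jitter_structure = 0.5,
                           radius_jitter = 0.08,
                           structures = base_anatomy_structures()) {
  stopifnot(length(dims) == 3, all(dims >= 8), length(spacing) == 3,
            all(spacing > 0), radius_jitter >= 0, radius_jitter < 0.5)
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 origin = as.numeric(origin), seed = as.integer(seed),
                 jitter_global = jitter_global,
                 jitter_structure = jitter_structure,
                 radius_jitter = radius_jitter, structures = structures),
            class = "ot_anatomy_params")
}

# jitter helper: applies the rigid + per-structure offsets and radius scale
jitter_structures <- function(params) {
  st <- params$structures
  g <- runif(3, -params$jitter_global, params$jitter_global)
  for (nm in names(st)) {
    if (nm == "Skull") { st[[nm]]$centre <- st[[nm]]$centre + g; next }
    u <- g + runif(3, -params$jitter_structure, params$jitter_structure)
    rs <- 1 + runif(1, -params$radius_jitter, params$radius_jitter)
    s <- st[[nm]]
    if (!is.null(s[["path"]])) s[["path"]] <- sweep(s[["path"]], 2, u, `+`)
    if (!is.null(s[["paths"]]))
      s[["paths"]] <- lapply(s[["paths"]], function(p) sweep(p, 2, u, `+`))
    if (!is.null(s[["centres"]])) s[["centres"]] <- sweep(s[["centres"]], 2, u, `+`)
    if (!is.null(s[["centre"]])) s[["centre"]] <- s[["centre"]] + u
    if (!is.null(s[["bulb"]])) s[["bulb"]] <- s[["bulb"]] + u
    if (!is.null(s[["radius"]])) s[["radius"]] <- s[["radius"]] * rs
    if (!is.null(s[["radii"]])) s[["radii"]] <- s[["radii"]] * rs
    if (!is.null(s[["bulb_radius"]])) s[["bulb_radius"]] <- s[["bulb_radius"]] * rs
    st[[nm]] <- s
  }
  list(structures = st, global_shift = g)
}

#' Generate a synthetic temporal-bone-like label volume with fiducials
#'
#' Rasterizes the nine risk-structure analogues plus the skull shell into a
#' label volume (rasterization priority: vessels > canals > arcs/cochlea >
#' ossicles > nerves > shell; earlier structures win overlaps, so structures
#' never overlap in the result).  Also returns per-scenario fiducial states:
#' a "round window" goal beside the cochlea analogue, an IAC-adjacent goal,
#' and scenario-specific start states on the skull shell.
#'
#' The generator mimics topology and spatial scale only; it is NOT a model
#' of patient anatomy and must not be used for any clinical purpose.
#'
#' @param params an [anatomy_params()].
#' @return list with `volume` (`ot_label_volume`), `fiducials` (per-scenario
#'   list of `start` / `goal` states) and `jitter` provenance.
#' @export
generate_anatomy <- function(params = anatomy_params()) {
  stopifnot(inherits(params, "ot_anatomy_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(params$seed)
  jit <- jitter_structures(params)
  st <- jit$structures

  dims <- params$dims; spacing <- params$spacing; origin <- params$origin
  lo_phys <- origin - spacing / 2
  hi_phys <- origin + (dims - 0.5) * spacing
  check_inside <- function(pts, r) {
    pts <- matrix(pts, ncol = 3)
    if (any(sweep(pts, 2, lo_phys, `-`) < r - spacing / 2) ||
        any(sweep(pts, 2, hi_phys, `-`) > -(r - spacing / 2))) {
      stop("structure exceeds the volume grid; enlarge dims or shrink the geometry")
    }
  }

  vol <- array(0L, dims)
  order_names <- c("ICA", "JV", "EAC", "IAC", "SCC", "Coc", "Oss", "FN", "ChT",
                   "Skull")
  for (nm in order_names) {
    s <- st[[nm]]
    if (s$type == "tube") {
      check_inside(s$path, s$radius)
      raster_tube_cpp(vol, dims, spacing, origin, s$path,
                      rep(s$radius, nrow(s$path)), s$label)
      if (!is.null(s$bulb)) {
        check_inside(rbind(s$bulb), s$bulb_radius)
        raster_tube_cpp(vol, dims, spacing, origin, rbind(s$bulb),
                        s$bulb_radius, s$label)
      }
    } else if (s$type == "arcs") {
      for (p in s$paths) {
        check_inside(p, s$radius)
        raster_tube_cpp(vol, dims, spacing, origin, p,
                        rep(s$radius, nrow(p)), s$label)
      }
    } else if (s$type == "spiral") {
      check_inside(s$path, max(s$radii))
      raster_tube_cpp(vol, dims, spacing, origin, s$path, s$radii, s$label)
    } else if (s$type == "spheres") {
      check_inside(s$centres, max(s$radii))
      for (j in seq_len(nrow(s$centres))) {
        raster_tube_cpp(vol, dims, spacing, origin, rbind(s$centres[j, ]),
                        s$radii[j], s$label)
      }
    } else if (s$type == "shell") {
      raster_shell_cpp(vol, dims, spacing, origin, s$centre, s$semi,
                       s$thickness, s$label)
    }
  }
  lv <- label_volume(vol, spacing, origin, labels = OT_LABELS)

  # fiducials: starts on the shell mid-surface, goals beside the targets
  shell <- st$Skull
  on_shell <- function(v) shell$centre + shell$semi[1] * vunit(v)
  coc_centre <- st$Coc$centre
  rw_goal <- coc_centre + 5.2 * vunit(c(1, 0.3, 0.7))
  iac_goal <- c(14.5, 31, 18.5) + jit$global_shift
  starts <- list(
    "Access"     = on_shell(c(1, 0, 0.42)),
    "SSC-Access" = on_shell(c(0.25, -0.35, 0.9)),
    "RL-Access"  = on_shell(c(0.8, 0.8, 0.3))
  )
  goals <- list("Access" = rw_goal, "SSC-Access" = iac_goal,
                "RL-Access" = iac_goal)
  fiducials <- lapply(names(starts), function(nm) {
    dirv <- vunit(goals[[nm]] - starts[[nm]])
    list(start = ot_state(starts[[nm]], dirv), goal = ot_state(goals[[nm]], dirv))
  })
  names(fiducials) <- names(starts)
  list(volume = lv, fiducials = fiducials,
       jitter = list(global_shift = jit$global_shift, seed = params$seed))
}

#' Perturb a label volume to emulate automatic-segmentation error
#'
#' Applies a label-wise perturbation with an independent seeded stream per
#' structure, so failure modes can be induced selectively.  Modes:
#' `dilate` / `erode` (morphological, `magnitude` voxels; emulates over- /
#' under-segmentation), `fragment` (cuts `ceiling(magnitude)` random holes
#' per structure; emulates fragmented surfaces), `boundary_noise` (randomly
#' removes surface voxels and adds adjacent background voxels with
#' probability `magnitude`).  Magnitude 0 is the identity.  Grid, spacing
#' and origin are unchanged; overlaps created by dilation resolve in
#' ascending label order.
#'
#' @param lv an `ot_label_volume`.
#' @param mode one of `"dilate"`, `"erode"`, `"fragment"`, `"boundary_noise"`.
#' @param magnitude nonnegative perturbation strength (see modes).
#' @param seed integer seed; per-structure streams use `seed + label`.
#' @param labels which labels to perturb (default: all present except any
#'   named "Skull").
#' @export
perturb_segmentation <- function(lv, mode, magnitude, seed = 1L, labels = NULL) {
  stopifnot(inherits(lv, "ot_label_volume"), magnitude >= 0)
  modes <- c("dilate", "erode", "fragment", "boundary_noise")
  if (!mode %in% modes) {
    stop(sprintf("unknown perturbation mode '%s'; valid modes: %s", mode,
                 paste(modes, collapse = ", ")))
  }
  if (magnitude == 0) return(lv)
  present <- setdiff(sort(unique(as.vector(lv$data))), 0L)
  if (is.null(labels)) {
    skul <- if (!is.null(lv$labels) && "Skull" %in% names(lv$labels))
      lv$labels[["Skull"]] else integer(0)
    labels <- setdiff(present, skul)
  }
  dims <- dim(lv$data)
  out <- lv$data
  out[out %in% labels] <- 0L
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  for (l in sort(as.integer(labels))) {
    set.seed(as.integer(seed) + l)
    m <- as.integer(lv$data == l)
    if (mode %in% c("dilate", "erode")) {
      m <- morph_cpp(m, dims, rep(magnitude, 3), mode == "dilate")
    } else if (mode == "fragment") {
      idx <- which(m == 1L)
      if (length(idx)) {
        ncut <- ceiling(magnitude)
        seeds <- idx[ceiling(runif(ncut) * length(idx))]
        cut <- integer(0)
        ar <- array(m, dims)
        for (sv in seeds) {
          ijk <- arrayInd(sv, dims)
          rr <- 1 + magnitude  # hole radius in voxels
          rng <- lapply(1:3, function(a)
            max(1, ijk[a] - ceiling(rr)):min(dims[a], ijk[a] + ceiling(rr)))
          ar[rng[[1]], rng[[2]], rng[[3]]] <- 0L
        }
        m <- as.integer(ar)
      }
    } else if (mode == "boundary_noise") {
      p <- min(1, magnitude)
      ar <- array(m, dims)
      surf <- surface_voxels_cpp(m, dims)
      if (nrow(surf)) {
        drop <- runif(nrow(surf)) < p
        ar[surf[drop, , drop = FALSE]] <- 0L
        grown <- array(morph_cpp(m, dims, c(1, 1, 1), TRUE), dims)
        band <- which(grown == 1L & array(m, dims) == 0L)
        add <- band[runif(length(band)) < p]
        ar[add] <- 1L
      }
      m <- as.integer(ar)
    }
    sel <- which(m == 1L & out == 0L)
    out[sel] <- l
  }
  label_volume(array(out, dims), lv$spacing, lv$origin, labels = lv$labels)
}

#' Benchmark-resolution anatomy parameters
#'
#' Same 48 mm field as the default generator, rasterized at 0.4 x 0.4 x
#' 0.8 mm so that many-case benchmarks stay fast.  See the methods vignette
#' for the rationale.
#'
#' @param seed integer seed.
#' @param ... passed to [anatomy_params()].
#' @export
benchmark_params <- function(seed = 1L, ...) {
  anatomy_params(dims = c(120, 120, 60), spacing = c(0.4, 0.4, 0.8),
                 seed = seed, ...)
}

#' Generate a seeded benchmark of planning cases
#'
#' Each case carries a ground-truth label volume, a perturbed "automatic
#' segmentation" variant, the extracted obstacle environments for both, the
#' scenario name and its endpoint states.  Every fixture's start and goal
#' are audited to clear the ground-truth obstacles by the scenario's d_min;
#' a case whose audit fails is re-jittered with a derived seed (up to 20
#' attempts) before erroring.
#'
#' @param n_cases number of cases (>= 1).
#' @param seed integer base seed.
#' @param scenarios scenario names cycled over the cases.
#' @param params_fn function(seed) returning [anatomy_params()] for a case
#'   (default [benchmark_params()]).
#' @param perturb list with `mode` and `magnitude` for the paired
#'   "automatic segmentation" volume.
#' @param smooth_iters surface-extraction smoothing iterations.
#' @return list of case fixtures (class `ot_case_fixture`), each with
#'   `case_id`, `scenario`, `kappa_max`, `d_min`, `start`, `goal`,
#'   `volume_gt`, `volume_seg`, `env_gt`, `env_seg`, `seed`.
#' @export
make_benchmark <- function(n_cases, seed = 1L,
                           scenarios = c("Access", "SSC-Access", "RL-Access"),
                           params_fn = benchmark_params,
                           perturb = list(mode = "dilate", magnitude = 1),
                           smooth_iters = 50) {
  stopifnot(n_cases >= 1)
  fixtures <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    scen <- scenario_defaults(scenarios[((i - 1) %% length(scenarios)) + 1])
    fixture <- NULL
    for (attempt in 0:19) {
      case_seed <- as.integer(seed) + (i - 1L) + attempt * 100003L
      an <- generate_anatomy(params_fn(seed = case_seed))
      fid <- an$fiducials[[scen$name]]
      env_gt <- environment_from_labels(an$volume, smooth_iters = smooth_iters)
      sd0 <- signed_distance_batch(env_gt, rbind(fid$start$position,
                                                 fid$goal$position))
      if (all(sd0 >= scen$d_min)) {
        lv_seg <- perturb_segmentation(an$volume, perturb$mode,
                                       perturb$magnitude,
                                       seed = case_seed + 500L)
        env_seg <- environment_from_labels(lv_seg, smooth_iters = smooth_iters)
        fixture <- structure(list(
          case_id = sprintf("case_%03d", i), scenario = scen$name,
          kappa_max = scen$kappa_max, d_min = scen$d_min,
          start = fid$start, goal = fid$goal,
          volume_gt = an$volume, volume_seg = lv_seg,
          env_gt = env_gt, env_seg = env_seg, seed = case_seed),
          class = "ot_case_fixture")
        break
      }
    }
    if (is.null(fixture)) {
      stop(sprintf("could not place collision-free endpoint states for case %d (base seed %d)",
                   i, seed))
    }
    fixtures[[i]] <- fixture
  }
  fixtures
}
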