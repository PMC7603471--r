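# Synthetic anatomy generator and segmentation perturbations.

test_that("generate_anatomy produces nine structures plus shell, deterministically", {
  p <- benchmark_params(seed = 6)
  an <- generate_anatomy(p)
  present <- setdiff(sort(unique(as.vector(an$volume$data))), 0L)
  expect_setequal(present, 1:10)  # nine risk structures + skull shell
  # same seed: voxel-identical; different seed: different
  an2 <- generate_anatomy(benchmark_params(seed = 6))
  expect_identical(an2$volume$data, an$volume$data)
  an3 <- generate_anatomy(benchmark_params(seed = 7))
  expect_false(identical(an3$volume$data, an$volume$data))
  # parameter echo: the nerve radii ordering requested is what is rasterized
  st <- p$structures
  expect_gt(st$FN$radius, st$ChT$radius)
  # fiducials exist for all three scenarios with unit directions
  expect_setequal(names(an$fiducials), c("Access", "SSC-Access", "RL-Access"))
  for (f in an$fiducials) {
    expect_equal(sqrt(sum(f$start$direction^2)), 1, tolerance = 1e-12)
    expect_equal(sqrt(sum(f$goal$direction^2)), 1, tolerance = 1e-12)
  }
  # oversized structures are rejected
  bad <- benchmark_params(seed = 1)
  bad$structures$ICA$radius <- 60
  expect_error(generate_anatomy(bad), "exceeds the volume grid")
})

test_that("perturb_segmentation modes behave per contract", {
  an <- generate_anatomy(benchmark_params(seed = 8))
  lv <- an$volume
  # magnitude 0 is the identity
  expect_identical(perturb_segmentation(lv, "dilate", 0, seed = 1)$data, lv$data)
  expect_error(perturb_segmentation(lv, "sharpen", 1), "unknown perturbation mode")
  # dilation grows every non-touching structure
  lvd <- perturb_segmentation(lv, "dilate", 1, seed = 1)
  for (l in 1:9) {
    expect_gte(sum(lvd$data == l), sum(lv$data == l))
  }
  expect_gt(sum(lvd$data %in% 1:9), sum(lv$data %in% 1:9))
  # erosion shrinks
  lve <- perturb_segmentation(lv, "erode", 1, seed = 1)
  expect_lt(sum(lve$data %in% 1:9), sum(lv$data %in% 1:9))
  # fragmentation never decreases the component count (deletion cannot merge)
  lvf <- perturb_segmentation(lv, "fragment", 2, seed = 3, labels = 2L)
  nc <- function(d, l) length(otoplan:::cc_label_cpp(as.integer(d == l), dim(d))$sizes)
  expect_gte(nc(lvf$data, 2L), nc(lv$data, 2L))
  # determinism
  expect_identical(perturb_segmentation(lv, "boundary_noise", 0.3, seed = 5)$data,
                   perturb_segmentation(lv, "boundary_noise", 0.3, seed = 5)$data)
  # grid/spacing unchanged
  expect_identical(lvd$spacing, lv$spacing)
  expect_identical(dim(lvd$data), dim(lv$data))
})

test_that("Dice to ground truth decreases monotonically with perturbation", {
  mags <- c(0, 1, 2)
  dice_at <- function(mag) {
    mean(vapply(4:5, function(seed) {
      an <- generate_anatomy(benchmark_params(seed = seed))
      lvp <- perturb_segmentation(an$volume, "dilate", mag, seed = seed)
      mean(vapply(c(1L, 2L, 9L), function(l) {
        dice_hausdorff(an$volume$data == l, lvp$data == l, an$volume$spacing)$dice
      }, numeric(1)))
    }, numeric(1)))
  }
  d <- vapply(mags, dice_at, numeric(1))
  expect_equal(d[1], 1)
  expect_true(all(diff(d) < 0))
})

test_that("make_benchmark yields audited, reproducible fixtures", {
  fx <- make_benchmark(3, seed = 11)
  expect_length(fx, 3)
  expect_equal(vapply(fx, `[[`, character(1), "scenario"),
               c("Access", "SSC-Access", "RL-Access"))
  for (f in fx) {
    sd0 <- otoplan:::signed_distance_batch(f$env_gt, rbind(f$start$position,
                                                           f$goal$position))
    expect_true(all(sd0 >= f$d_min))  # start/goal audit
    expect_false(identical(f$volume_seg$data, f$volume_gt$data))
  }
  fx2 <- make_benchmark(3, seed = 11)
  expect_identical(fx$volume_gt, fx2$volume_gt)
  expect_identical(fx[[2]]$start, fx2[[2]]$start)
})

test_that("extracted surfaces of generated structures are watertight", {
  an <- generate_anatomy(benchmark_params(seed = 9))
  for (l in c(1L, 3L, 5L, 7L)) {  # vessel, nerve, thin branch, arcs
    m <- extract_surface(an$volume, l)
    expect_true(is_watertight(m), info = paste("label", l))
  }
})

test_that("planner succeeds on at least 80% of default Access-analog cases", {
  ok <- 0L
  for (seed in 0:9) {
    an <- generate_anatomy(anatomy_params(seed = seed))
    env <- environment_from_labels(an$volume)
    fid <- an$fiducials[["Access"]]
    pr <- tryCatch(
      plan_trajectory(env, fid$start, fid$goal, 0.05, 0.8,
                      rrt_config(max_iter = 3000L, seed = seed)),
      error = function(e) list(success = FALSE))
    ok <- ok + isTRUE(pr$success)
  }
  expect_gte(ok, 8L)
})
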