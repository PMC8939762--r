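test_that("plane grids match a brute-force lattice enumeration", {
  # independent O(N^2) filter: integer (and half-integer) lattice points
  # inside the 4.8 mm circle at 0.3 mm pitch
  brute <- function(off) {
    n <- 0L
    for (i in -20:20) for (j in -20:20) {
      if ((i + off)^2 + (j + off)^2 <= (2.4 / 0.3)^2) n <- n + 1L
    }
    n
  }
  g_cen <- plane_grid(4.8, 0.3, "centered")
  g_half <- plane_grid(4.8, 0.3, "half-offset")
  expect_equal(nrow(g_cen), brute(0))       # 197
  expect_equal(nrow(g_cen), 197L)
  expect_equal(nrow(g_half), brute(0.5))    # 208
  expect_equal(nrow(g_half), 208L)
  # every spot is inside the circle (inclusive)
  expect_true(all(g_cen$x_mm^2 + g_cen$y_mm^2 <= 2.4^2 + 1e-9))
  # row-major sorting
  expect_true(!is.unsorted(g_cen$y_mm))
})

test_that("grid edge cases", {
  expect_equal(nrow(plane_grid(0.3, 0.3, "centered")), 1L)
  expect_warning(g <- plane_grid(0.2, 0.5), "single-spot")
  expect_equal(nrow(g), 1L)
  expect_error(plane_grid(-1, 0.3), "positive")
})

test_that("serpentine route visits each spot once, rows alternating", {
  sq <- expand.grid(x_mm = c(0, 1), y_mm = c(0, 1))
  route <- serpentine_route(sq)
  expect_equal(route_length(route), 3)  # three unit moves
  g <- plane_grid(4.8, 0.3)
  r <- serpentine_route(g)
  expect_equal(nrow(r), nrow(g))
  expect_setequal(paste(r$x_mm, r$y_mm), paste(g$x_mm, g$y_mm))
  # route length matches an explicit pairwise-distance oracle
  oracle <- 0
  for (i in 2:nrow(r)) {
    oracle <- oracle + sqrt((r$x_mm[i] - r$x_mm[i - 1])^2 +
                              (r$y_mm[i] - r$y_mm[i - 1])^2)
  }
  expect_equal(route_length(r), oracle)
  expect_gt(oracle, 61)
  expect_lt(oracle, 67)
  # length is invariant under reversal of the serpentine direction
  rev_r <- r[nrow(r):1, ]
  expect_equal(route_length(rev_r), route_length(r))
})

test_that("plan timing sums dwell, travel and plane moves", {
  two <- manual_plan(data.frame(x_mm = c(0, 0.3), y_mm = c(0, 0)))
  expect_equal(plan_timing(two)$total_s, 2 * 0.4 + 0.3 / 2)  # 0.95 s
  none <- manual_plan(data.frame(x_mm = numeric(0), y_mm = numeric(0)))
  expect_equal(plan_timing(none)$total_s, 0)
  # the reference protocol: declared 204 spots/plane, 6 planes
  plan <- scan_plan(spots_per_plane = 204)
  expect_equal(plan_timing(plan)$total_min, 11.5, tolerance = 0.05)
  # spot count declared does not alter the route geometry
  expect_equal(nrow(plan$spots), 197L)
})

test_that("coverage volumes agree with analytic non-overlapping cylinders", {
  plan <- scan_plan()
  cov <- coverage_stats(plan, focal_diameter_um = 104, voxel_um = 10)
  # 104 um spots on a 300 um lattice never overlap; the voxelised union
  # must match the analytic cylinder sum within lattice quantization
  # (the 52 um disc radius spans only ~5 voxels)
  analytic <- nrow(plan$spots) * spot_volume(104, 0.3) * plan$n_planes
  expect_equal(cov$treated_mm3, analytic, tolerance = 0.03)
  expect_lte(cov$treated_mm3, cov$scanned_mm3)
  expect_gte(cov$treated_fraction, 0)
  expect_lte(cov$scanned_fraction, 1)
  expect_equal(cov$total_mm3, pi * 2.4^2 * 1.5)
  # a 204-spot protocol under the same conventions treats ~11.5% of the
  # treatment cylinder
  expect_equal(204 * spot_volume(104, 0.3) * 6 / cov$total_mm3, 0.115,
               tolerance = 0.01)
  # both fractions grow with the focal diameter
  wider <- coverage_stats(plan, focal_diameter_um = 208, voxel_um = 10)
  expect_gt(wider$treated_fraction, cov$treated_fraction)
  expect_gte(wider$scanned_fraction, cov$scanned_fraction)
})

test_that("single-spot focal volume has the expected magnitude", {
  expect_equal(spot_volume(104, 0.5), pi * 0.052^2 * 0.5)
  expect_equal(spot_volume(104, 0.5), 4.25e-3, tolerance = 0.002)
})

test_that("G-code export and parse are exact inverses", {
  plan <- scan_plan()
  lines <- export_gcode(plan)
  parsed <- parse_gcode(lines)
  expect_equal(parsed$spots$x_mm, round(plan$spots$x_mm, 3))
  expect_equal(parsed$spots$y_mm, round(plan$spots$y_mm, 3))
  expect_equal(parsed$dwell_s, plan$dwell_s)
  expect_equal(parsed$speed_mm_s, plan$speed_mm_s)
  expect_equal(parsed$n_planes, plan$n_planes)
  expect_equal(parsed$z_planes_mm, round(plan$z_planes_mm, 3))
  # one dwell word per spot per plane
  expect_equal(sum(grepl("^G4 ", lines)),
               nrow(plan$spots) * plan$n_planes)
})

test_that("single-spot plan emits exactly one move and one dwell", {
  one <- manual_plan(data.frame(x_mm = 0.5, y_mm = -0.25))
  lines <- export_gcode(one, comment = FALSE)
  expect_equal(sum(grepl("^G1 X", lines)), 1L)
  expect_equal(sum(grepl("^G4 P400$", lines)), 1L)
})

test_that("G-code parser rejects unsupported words with line numbers", {
  expect_error(parse_gcode(c("G21", "G2 X1 Y1 I0 J1")), "line 2")
  expect_error(parse_gcode(c("G1 X1 Q5")), "unsupported axis")
  expect_error(parse_gcode(c("G4")), "without P")
})

test_that("laser offset is a rigid, invertible translation", {
  g <- plane_grid(4.8, 0.3)
  expect_equal(laser_offset_transform(g, c(0, 0)), g)
  shifted <- laser_offset_transform(g, c(1, 2))
  expect_equal(mean(shifted$x_mm) - mean(g$x_mm), 1)
  expect_equal(mean(shifted$y_mm) - mean(g$y_mm), 2)
  expect_equal(laser_offset_transform(shifted, c(-1, -2)), g)
})

test_that("plan JSON and spot CSV round-trip", {
  plan <- scan_plan(spots_per_plane = 204)
  jp <- withr::local_tempfile(fileext = ".json")
  write_plan_json(plan, jp)
  back <- read_plan_json(jp)
  expect_equal(back$spots, plan$spots)
  expect_equal(back$spots_per_plane, 204)
  expect_equal(plan_timing(back), plan_timing(plan))
  cp <- withr::local_tempfile(fileext = ".csv")
  write_spot_csv(plan, cp)
  tab <- read.csv(cp)
  expect_equal(nrow(tab), nrow(plan$spots) * plan$n_planes)
  expect_equal(tab$order, seq_len(nrow(tab)))
})
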