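test_that("planted integer translations between cycles are recovered and removed", {
  sim <- generate_ion_stack(make_disk_scene(seed = 11L, n_cycles = 3L))
  st <- sim$stack
  # roll cycle 2 of every mass by (3, -2): pixel (i, j) moves to (i+3, j-2)
  rolled <- st$counts
  nr <- st$dim_px[1]; nc <- st$dim_px[2]
  roll <- function(m, dr, dc) {
    out <- m
    out[((seq_len(nr) - 1 + dr) %% nr) + 1,
        ((seq_len(nc) - 1 + dc) %% nc) + 1] <- m
    out
  }
  for (m in 1:4)
    rolled[m, 2, , ] <- roll(matrix(st$counts[m, 2, , ], nr, nc), 3, -2)
  shifted <- ion_image_stack(rolled, st$pixel_size_nm, st$dwell_ms)
  al <- align_cycles(shifted)
  expect_equal(unname(al$shifts[2, ]), c(3, -2))
  expect_equal(unname(al$shifts[3, ]), c(0, 0))
  # interior pixels restored exactly after alignment
  interior_r <- 12:(nr - 12); interior_c <- 12:(nc - 12)
  expect_equal(al$stack$counts[3, 2, interior_r, interior_c],
               st$counts[3, 2, interior_r, interior_c])
})

test_that("an already-aligned stack yields zero shifts; noise shifts stay bounded", {
  sim <- generate_ion_stack(make_disk_scene(seed = 12L, n_cycles = 4L))
  al <- align_cycles(sim$stack)
  expect_true(all(al$shifts == 0))

  set.seed(13)
  noise <- array(rpois(4 * 3 * 64 * 64, 2), dim = c(4, 3, 64, 64))
  aln <- align_cycles(ion_image_stack(noise, 78.125, 1), max_shift = 10)
  expect_true(all(abs(aln$shifts) <= 10))
})

test_that("all-zero reference cycles are flagged with zero shift", {
  sim <- generate_ion_stack(make_disk_scene(seed = 14L, n_cycles = 3L))
  counts <- sim$stack$counts
  counts[3, 2, , ] <- 0  # blank the CN14 reference image of cycle 2
  al <- align_cycles(ion_image_stack(counts, 78.125, 1))
  expect_equal(al$flagged, 2L)
  expect_equal(unname(al$shifts[2, ]), c(0L, 0L))
})

test_that("dead-time correction follows the non-paralyzable formula", {
  counts <- array(0, dim = c(4, 1, 2, 2))
  counts[1, 1, 1, 1] <- 1000
  st <- ion_image_stack(counts, dwell_ms = 1)
  # tau = 0 is the identity
  expect_identical(deadtime_correct(st, 0), st)
  cor44 <- deadtime_correct(st, 44)
  expect_equal(unname(cor44$counts[1, 1, 1, 1]), 1000 / (1 - 0.044),
               tolerance = 1e-9)
  expect_equal(unname(cor44$counts[1, 1, 2, 2]), 0)
  # saturation flags the pixel invalid
  counts[1, 1, 1, 2] <- 3e7  # n * tau / dwell > 1 at tau = 44 ns
  sat <- deadtime_correct(ion_image_stack(counts), 44)
  expect_true(is.na(sat$counts[1, 1, 1, 2]))
  expect_equal(attr(sat, "n_saturated"), 1L)
})

test_that("planted disks are segmented with high overlap and size filtering", {
  scene <- make_disk_scene(seed = 21L)
  sim <- generate_ion_stack(scene)
  rois <- segment_particles(sim$stack)
  # 7 planted, 1 below the 0.3 um minimum diameter
  expect_equal(length(rois), 6L)
  for (r in rois) {
    lab_at <- sim$masks[r$pixels]
    planted <- unique(lab_at[lab_at > 0])
    expect_length(planted, 1L)
    expect_gt(jaccard(r$pixels, sim$masks == planted), 0.8)
  }
  # sorted by area descending
  areas <- vapply(rois, function(r) nrow(r$pixels), numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("a blank stack yields no ROIs", {
  st <- ion_image_stack(array(0, dim = c(4, 3, 64, 64)))
  expect_equal(length(segment_particles(st)), 0L)
})

test_that("highly 15N-enriched particles need the CN_total channel", {
  # particle almost all 15N: bright in CN15, nearly dark in CN14
  particles <- data.frame(row = 64, col = 64, diameter_um = 1.2,
                          c_density = 2, n_density = 3,
                          f13C = 0.0111, f15N = 0.98)
  scene <- scene_spec(dim_px = c(128L, 128L), particles = particles,
                      background_c = 0.5, background_n = 0.5,
                      n_cycles = 10L, beam_fwhm_nm = 0, seed = 22L)
  sim <- generate_ion_stack(scene)
  expect_equal(length(segment_particles(sim$stack, channel = "CN14")), 0L)
  got <- segment_particles(sim$stack, channel = "CN_total")
  expect_equal(length(got), 1L)
  expect_gt(jaccard(got[[1]]$pixels, sim$masks == 1), 0.8)
})

test_that("segmentation is translation-equivariant away from borders", {
  base <- data.frame(row = c(40, 70), col = c(40, 80),
                     diameter_um = c(1.0, 1.4), c_density = 5, n_density = 2,
                     f13C = 0.0111, f15N = 0.0037)
  shifted <- transform(base, row = row + 9, col = col - 7)
  r1 <- segment_particles(generate_ion_stack(
    scene_spec(dim_px = c(128L, 128L), particles = base, n_cycles = 8L,
               beam_fwhm_nm = 0, seed = 23L))$stack)
  r2 <- segment_particles(generate_ion_stack(
    scene_spec(dim_px = c(128L, 128L), particles = shifted, n_cycles = 8L,
               beam_fwhm_nm = 0, seed = 23L))$stack)
  expect_equal(length(r1), length(r2))
  for (i in seq_along(r1)) {
    moved <- cbind(r1[[i]]$pixels[, "row"] + 9, r1[[i]]$pixels[, "col"] - 7)
    a <- moved[order(moved[, 1], moved[, 2]), , drop = FALSE]
    b <- r2[[i]]$pixels[order(r2[[i]]$pixels[, 1], r2[[i]]$pixels[, 2]), ,
                        drop = FALSE]
    # same scene realisation shifted: masks agree almost everywhere
    both <- nrow(merge(as.data.frame(a), as.data.frame(unname(b))))
    expect_gt(both / max(nrow(a), nrow(b)), 0.9)
  }
})

test_that("ROI count is monotone non-increasing in the threshold above background", {
  # below the background level everything merges into one giant component,
  # so the meaningful regime starts at the default robust threshold
  sim <- generate_ion_stack(make_disk_scene(seed = 24L))
  img <- channel_sum_image(sim$stack, "CN14")
  thr0 <- median(img) + 5 * mad(img)
  counts <- vapply(seq(thr0, max(img), length.out = 8), function(thr)
    length(segment_particles(sim$stack, threshold = thr,
                             min_diameter_um = 0)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("hotspot finder keeps only the 4-50 um band", {
  # 80 um field of view: 256 px at 312.5 nm
  particles <- data.frame(row = c(60, 128, 200), col = c(60, 128, 200),
                          diameter_um = c(5, 1, 60),
                          c_density = 10, n_density = 10,
                          f13C = 0.0111, f15N = 0.0037)
  scene <- scene_spec(dim_px = c(256L, 256L), pixel_size_nm = 312.5,
                      particles = particles, n_cycles = 5L,
                      beam_fwhm_nm = 0, seed = 25L)
  sim <- generate_ion_stack(scene)
  hs <- find_hotspots(sim$stack)
  expect_equal(length(hs), 1L)
  expect_equal(hs[[1]]$source, "hotspot")
  expect_gt(jaccard(hs[[1]]$pixels, sim$masks == 1), 0.8)
  expect_gt(hs[[1]]$equiv_diameter_um, 4)
  expect_lt(hs[[1]]$equiv_diameter_um, 50)
})

test_that("ratios by cycle: constant counts give SEM 0 and the plain ratio", {
  counts <- array(0, dim = c(4, 5, 16, 16))
  counts[1, , , ] <- 50   # C2
  counts[2, , , ] <- 10   # 13C12C
  counts[3, , , ] <- 200  # CN14
  counts[4, , , ] <- 40   # CN15
  st <- ion_image_stack(counts)
  roi <- manual_roi(cbind(3:6, 3:6), st)
  rec <- roi_isotope_stats(st, roi)
  expect_equal(rec$ratio_mean_c, 10 / 50)
  expect_equal(rec$ratio_sem_c, 0)
  expect_equal(rec$ratio_mean_n, 40 / 200)
  expect_equal(rec$ratio_sem_n, 0)
  expect_equal(rec$n_cycles_used_n, 5L)
  expect_true(rec$usable)
})

test_that("ROI mean 15N recovers planted truth within 3 SEM at high counts", {
  f15 <- 0.30
  particles <- data.frame(row = 32, col = 32, diameter_um = 1.5,
                          c_density = 5, n_density = 50,
                          f13C = 0.0111, f15N = f15)
  scene <- scene_spec(dim_px = c(64L, 64L), particles = particles,
                      background_n = 1e-3, background_c = 0.1,
                      yield_cn = 50, n_cycles = 25L, beam_fwhm_nm = 0,
                      seed = 31L)
  sim <- generate_ion_stack(scene)
  roi <- manual_roi(arrayInd(which(sim$masks == 1), dim(sim$masks)), sim$stack)
  rec <- roi_isotope_stats(sim$stack, roi)
  # per-ROI CN14 counts per cycle ~ area * density * yield * (1-f) >> 1e3
  f_est <- nitrogen_ion_ratio_to_atom_fraction(rec$ratio_mean_n)
  f_lo <- nitrogen_ion_ratio_to_atom_fraction(rec$ratio_mean_n - 3 * rec$ratio_sem_n)
  f_hi <- nitrogen_ion_ratio_to_atom_fraction(rec$ratio_mean_n + 3 * rec$ratio_sem_n)
  expect_gt(f15, f_lo)
  expect_lt(f15, f_hi)
  expect_equal(f_est, f15, tolerance = 0.05)
})

test_that("mean and SEM equal brute-force recomputation from per-cycle ratios", {
  sim <- generate_ion_stack(make_disk_scene(seed = 32L, n_cycles = 12L))
  rois <- segment_particles(sim$stack)
  rec <- roi_isotope_stats(sim$stack, rois[[1]])
  nr <- sim$stack$dim_px[1]
  manual_ratios <- sapply(seq_len(sim$stack$n_cycles), function(j) {
    num <- den <- 0
    for (i in seq_len(nrow(rois[[1]]$pixels))) {
      rr <- rois[[1]]$pixels[i, 1]; cc <- rois[[1]]$pixels[i, 2]
      num <- num + sim$stack$counts[4, j, rr, cc]
      den <- den + sim$stack$counts[3, j, rr, cc]
    }
    num / den
  })
  manual_ratios <- unname(manual_ratios)
  expect_equal(rec$ratios_n_by_cycle, manual_ratios)
  expect_equal(rec$ratio_mean_n, mean(manual_ratios))
  expect_equal(rec$ratio_sem_n,
               sd(manual_ratios) / sqrt(length(manual_ratios)))
})

test_that("zero-denominator cycles are excluded and fully dark ROIs flagged unusable", {
  counts <- array(0, dim = c(4, 4, 16, 16))
  counts[1, , , ] <- 20; counts[2, , , ] <- 2
  counts[3, 1:3, , ] <- 100; counts[4, 1:3, , ] <- 10  # cycle 4 dark in CN
  st <- ion_image_stack(counts)
  roi <- manual_roi(cbind(5:8, 5:8), st)
  rec <- roi_isotope_stats(st, roi)
  expect_equal(rec$n_cycles_used_n, 3L)
  expect_equal(rec$n_cycles_excluded_n, 1L)
  expect_true(rec$usable)

  dark <- array(0, dim = c(4, 4, 16, 16))
  rec2 <- roi_isotope_stats(ion_image_stack(dark), roi)
  expect_false(rec2$usable)
})

test_that("the ratio of a union ROI lies between the two component means", {
  sim <- generate_ion_stack(make_disk_scene(seed = 33L))
  rois <- segment_particles(sim$stack)
  a <- rois[[1]]; b <- rois[[2]]
  u <- manual_roi(rbind(a$pixels, b$pixels), sim$stack, id = "union")
  ra <- roi_isotope_stats(sim$stack, a)$ratio_mean_n
  rb <- roi_isotope_stats(sim$stack, b)$ratio_mean_n
  ru <- roi_isotope_stats(sim$stack, u)$ratio_mean_n
  expect_gte(ru, min(ra, rb) - 1e-12)
  expect_lte(ru, max(ra, rb) + 1e-12)
})

test_that("stacks round-trip through TIFF + JSON sidecar and masks serialize", {
  sim <- generate_ion_stack(make_disk_scene(seed = 34L, dim_px = c(32L, 32L),
                                            n_cycles = 3L,
                                            particles = data.frame(
                                              row = 16, col = 16,
                                              diameter_um = 0.8,
                                              c_density = 5, n_density = 2,
                                              f13C = 0.0111, f15N = 0.0037)))
  tif <- tempfile(fileext = ".tif"); js <- tempfile(fileext = ".json")
  write_ion_stack(sim$stack, tif, js)
  back <- read_ion_stack(tif, js)
  expect_equal(back$counts, sim$stack$counts)
  expect_equal(back$pixel_size_nm, sim$stack$pixel_size_nm)

  rois <- segment_particles(sim$stack, min_diameter_um = 0.2)
  mj <- tempfile(fileext = ".json")
  write_roi_masks_json(rois, mj, sim$stack$dim_px)
  dec <- jsonlite::read_json(mj, simplifyVector = TRUE)
  expect_equal(sum(dec$rois$rle$length[[1]]), nrow(rois[[1]]$pixels))
})
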