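# Candidate detection: component labelling, moments, filters, ROI cuts.

# brute-force second-central-moment oracle for a pixel set
oracle_axes <- function(rows, cols) {
  n <- length(rows)
  if (n == 1) return(c(major = 1, minor = 1))
  mu <- matrix(0, 2, 2)
  rb <- mean(rows); cb <- mean(cols)
  for (i in seq_len(n)) {
    v <- c(rows[i] - rb, cols[i] - cb)
    mu <- mu + tcrossprod(v)
  }
  ev <- sort(eigen(mu / n, symmetric = TRUE)$values, decreasing = TRUE)
  c(major = 4 * sqrt(ev[1]), minor = 4 * sqrt(max(0, ev[2])))
}

lung_box_volume <- function(vals) {
  # a soft-tissue-free synthetic parenchyma: lung background with structures
  arr <- array(-850L, dim = c(40, 40, 5))
  for (p in vals) arr[p$rows, p$cols, p$slices] <- as.integer(p$hu)
  ct_volume(arr, spacing = c(2.5, 1, 1), patient_id = "synthetic-lab")
}

full_mask <- function(volume) array(TRUE, dim = dim(volume$voxels))

test_that("uniform lung below the threshold yields zero components", {
  vol <- lung_box_volume(list())
  comp <- label_candidate_components(vol, full_mask(vol), -750)
  expect_equal(nrow(comp), 0L)
})

test_that("a painted 5x5 square is one component with exact stats", {
  vol <- lung_box_volume(list(list(rows = 11:15, cols = 21:25, slices = 3,
                                   hu = 0)))
  comp <- label_candidate_components(vol, full_mask(vol), -750)
  expect_equal(nrow(comp), 1L)
  expect_equal(comp$slice, 3L)
  expect_equal(comp$area_px, 25L)
  expect_equal(c(comp$row, comp$col), c(13, 23))
  expect_equal(comp$axis_ratio, 1, tolerance = 1e-12)
})

test_that("component moments match a brute-force oracle on random blobs", {
  for (seed in 1:5) {
    pix <- with_seed(seed, {
      n <- sample(2:60, 1)
      start <- c(sample(5:30, 1), sample(5:30, 1))
      ## random connected blob by walking
      pts <- matrix(start, 1, 2)
      while (nrow(pts) < n) {
        from <- pts[sample(nrow(pts), 1), ]
        step <- from + sample(c(-1L, 0L, 1L), 2, replace = TRUE)
        step <- pmin(pmax(step, 2L), 38L)
        pts <- unique(rbind(pts, step))
      }
      pts
    })
    vol <- lung_box_volume(list())
    arr <- vol$voxels
    arr[cbind(pix, 2L)] <- 0L
    vol$voxels <- arr
    comp <- label_candidate_components(vol, full_mask(vol), -750)
    expect_equal(nrow(comp), 1L)
    ax <- oracle_axes(pix[, 1], pix[, 2])
    expect_equal(comp$major, unname(ax["major"]), tolerance = 1e-9)
    expect_equal(comp$minor, unname(ax["minor"]), tolerance = 1e-9)
    expect_equal(comp$area_px, nrow(pix))
  }
})

test_that("small-structure filter is inclusive at the boundary", {
  comp <- data.frame(slice = 1, label = 1:3, area_px = c(1L, 2L, 9L),
                     row = 1, col = 1, major = 1, minor = 1, axis_ratio = 1)
  expect_equal(filter_small_components(comp, 2)$area_px, c(2L, 9L))
  expect_equal(nrow(filter_small_components(comp, 9)), 1L)
  expect_equal(nrow(filter_small_components(comp, 1)), 3L)
})

test_that("elongated structures are deleted; disks and degenerates handled", {
  vol <- lung_box_volume(list(
    list(rows = 20, cols = 5:24, slices = 2, hu = 0)))   # 1 x 20 line
  comp <- label_candidate_components(vol, full_mask(vol), -750)
  expect_equal(comp$axis_ratio, Inf)                     # collinear
  expect_equal(nrow(filter_elongated_components(comp, 3)), 0L)
  ## a disk survives
  m <- matrix(FALSE, 40, 40)
  d <- sqrt((row(m) - 20)^2 + (col(m) - 20)^2)
  pix <- which(d <= 6, arr.ind = TRUE)
  vol2 <- lung_box_volume(list())
  arr <- vol2$voxels; arr[cbind(pix, 2L)] <- 0L; vol2$voxels <- arr
  comp2 <- label_candidate_components(vol2, full_mask(vol2), -750)
  expect_lt(comp2$axis_ratio, 1.1)
  expect_equal(nrow(filter_elongated_components(comp2, 3)), 1L)
})

test_that("a near-in-plane vessel section is deleted as a thin long structure", {
  ## tilt ~80 deg: in-plane axis ratio sec(80) ~ 5.8 > 3
  spec <- phantom_spec(noise_sd = 0, seed = 3, trachea = NULL,
                       vessels = data.frame(radius_mm = 1.5, tilt_deg = 80,
                                            azimuth_deg = 90, x = -19,
                                            y = 0, z = 1.25, hu = 30))
  ph <- generate_phantom(spec)
  seg <- segment_lungs(ph$volume)
  dv <- detection_volume(seg$parenchyma, seg$mask)
  comp <- label_candidate_components(dv$volume, dv$mask, -750)
  mid <- comp[comp$slice == 33 & comp$area_px > 20 & comp$col < 64, ]
  expect_gte(nrow(mid), 1L)
  expect_true(all(mid$axis_ratio > 3))
  expect_equal(nrow(filter_elongated_components(mid, 3)), 0L)
})

test_that("filters commute on any component set", {
  for (seed in 1:3) {
    comp <- with_seed(seed, data.frame(
      slice = 1, label = 1:50,
      area_px = sample(1:40, 50, TRUE), row = 1, col = 1,
      major = runif(50, 1, 10), minor = runif(50, 0.5, 5)))
    comp$axis_ratio <- comp$major / comp$minor
    a <- filter_elongated_components(filter_small_components(comp, 9), 3)
    b <- filter_small_components(filter_elongated_components(comp, 3), 9)
    expect_identical(a, b)
  }
})

test_that("ROI stacks are exact crops with padding and replication", {
  vol <- random_volume(10, dims = c(200, 200, 7))
  ## deep interior: equals a direct sub-grid copy
  roi <- extract_roi_stack(vol, c(4, 100, 90))
  expect_equal(dim(roi$stack), c(64, 64, 3))
  expect_identical(roi$stack[, , 2], vol$voxels[68:131, 58:121, 4])
  expect_identical(roi$stack[, , 1], vol$voxels[68:131, 58:121, 3])
  expect_identical(roi$stack[, , 3], vol$voxels[68:131, 58:121, 5])
  ## centroid pixel sits at patch position 33 (0-based index 32)
  expect_identical(roi$stack[33, 33, 2], vol$voxels[100, 90, 4])
  ## corner: shape preserved, padding with -1024, neighbour replicated
  corner <- extract_roi_stack(vol, c(1, 1, 1))
  expect_equal(dim(corner$stack), c(64, 64, 3))
  expect_true(all(corner$stack[1:10, , ] == -1024L))
  expect_identical(corner$stack[, , 1], corner$stack[, , 2]) # replicated
  ## uniform volume: all three patches identical
  u <- uniform_volume(-500, c(80, 80, 5))
  ur <- extract_roi_stack(u, c(3, 40, 40))
  expect_identical(ur$stack[, , 1], ur$stack[, , 3])
  expect_error(extract_roi_stack(vol, c(9, 10, 10)), "bounds")
})

test_that("detect_candidates finds every nodule >= 4 mm on its central slice", {
  ph <- easy_phantom()
  seg <- easy_segmentation()
  cands <- detect_candidates(seg$parenchyma, seg$mask)
  comp <- attr(cands, "components")
  ann <- ph$annotations
  for (i in seq_len(nrow(ann))) {
    if (ann$diameter_mm[i] < 4) next
    near <- comp[abs(comp$slice - ann$slice[i]) <= 1 &
                   abs(comp$row - ann$row[i]) < 6 &
                   abs(comp$col - ann$col[i]) < 6, ]
    expect_gte(nrow(near), 1L)
  }
})

test_that("candidates >= 5 mm land within the true nodule radius", {
  ph <- easy_phantom()
  seg <- easy_segmentation()
  cands <- detect_candidates(seg$parenchyma, seg$mask)
  comp <- attr(cands, "components")
  sp <- ph$volume$spacing
  ann <- ph$annotations[ph$annotations$diameter_mm >= 5, ]
  for (i in seq_len(nrow(ann))) {
    dz <- (comp$slice - ann$slice[i]) * sp[1]
    dy <- (comp$row - ann$row[i]) * sp[2]
    dx <- (comp$col - ann$col[i]) * sp[3]
    dist <- sqrt(dz^2 + dy^2 + dx^2)
    expect_true(any(dist <= ann$diameter_mm[i] / 2),
                label = paste("recall of", ann$nodule_id[i]))
  }
})

test_that("every candidate centre lies inside the lung mask", {
  seg <- easy_segmentation()
  cands <- detect_candidates(seg$parenchyma, seg$mask)
  for (cd in cands)
    expect_true(seg$mask[cd$center["row"], cd$center["col"],
                         cd$center["slice"]])
})

test_that("candidate detection is deterministic and ordered", {
  seg <- easy_segmentation()
  a <- attr(detect_candidates(seg$parenchyma, seg$mask), "components")
  b <- attr(detect_candidates(seg$parenchyma, seg$mask), "components")
  expect_identical(a, b)
  expect_false(is.unsorted(a$slice))
})

test_that("empty parenchyma yields an empty candidate list", {
  vol <- uniform_volume(-1024, c(70, 70, 4))
  cands <- detect_candidates(vol, array(FALSE, dim = dim(vol$voxels)))
  expect_length(cands, 0L)
})

test_that("candidate_params validates and converts areas", {
  expect_error(candidate_params(roi_size = 32), "fixed at 64")
  expect_error(candidate_params(min_area_px = 0), "min_area_px")
  expect_error(candidate_params(max_axis_ratio = 0.5), "max_axis_ratio")
  expect_equal(area_mm2_to_px(49, c(2.5, 0.7, 0.7)), 100)
})
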