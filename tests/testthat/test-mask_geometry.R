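# small helper: RGB overlay from a grey base with rectangular blobs
blob_overlay <- function(grey, blobs) {
  ov <- array(as.integer(grey), dim = c(nrow(grey), ncol(grey), 3L))
  for (b in blobs) {
    for (ch in 1:3) {
      plane <- ov[, , ch]
      plane[b$rows + 1L, b$cols + 1L] <- b$colour[ch]
      ov[, , ch] <- plane
    }
  }
  ov
}

test_that("mask rules: two pixels minimum, 8-connectivity incl. diagonals", {
  red <- c(255L, 0L, 0L)
  expect_identical(validate_mask(lesion_mask(rbind(c(0, 0), c(1, 1)), red)),
                   character(0))
  expect_match(validate_mask(lesion_mask(rbind(c(5, 5)), red)),
               "minimal size")
  expect_match(validate_mask(lesion_mask(rbind(c(0, 0), c(0, 2)), red)),
               "not 8-connected")
  # grey tones can never be mask colours
  expect_error(lesion_mask(rbind(c(0, 0), c(0, 1)), c(7L, 7L, 7L)), "grey")
})

test_that("colour blobs are extracted one mask per colour, greyscale is ignored", {
  grey <- matrix(80L, 60, 120)
  cols <- list(c(255L, 0L, 0L), c(0L, 255L, 0L), c(0L, 0L, 255L),
               c(255L, 255L, 0L), c(255L, 0L, 255L))
  blobs <- lapply(1:5, function(i) {
    list(rows = 10:14, cols = (i * 20):(i * 20 + 3), colour = cols[[i]])
  })
  ov <- blob_overlay(grey, blobs)
  masks <- extract_masks(ov, grey)
  expect_length(masks, 5L)
  # deterministic ordering by leftmost column
  expect_identical(vapply(masks, function(m) min(m$pixels[, 2L]), 0L),
                   as.integer((1:5) * 20))
  expect_true(all(vapply(masks, function(m) nrow(m$pixels), 0L) == 20L))

  # a purely greyscale overlay has no masks
  expect_length(extract_masks(blob_overlay(grey, list()), grey), 0L)

  # one colour split into two distant blobs violates connectivity
  ov_bad <- blob_overlay(grey, list(
    list(rows = 5:6, cols = 5:6, colour = c(255L, 0L, 0L)),
    list(rows = 40:41, cols = 80:81, colour = c(255L, 0L, 0L))
  ))
  expect_error(extract_masks(ov_bad, grey), "#FF0000")

  # shape mismatch between overlay and base
  expect_error(extract_masks(ov, matrix(0L, 10, 10)), "shape")
})

test_that("touching lesions in different colours are never merged", {
  grey <- matrix(0L, 20, 40)
  ov <- blob_overlay(grey, list(
    list(rows = 5:8, cols = 10:14, colour = c(255L, 0L, 0L)),
    list(rows = 5:8, cols = 15:19, colour = c(0L, 0L, 255L))
  ))
  masks <- extract_masks(ov, grey)
  expect_length(masks, 2L)
  expect_identical(vapply(masks, function(m) colour_hex(m$colour), ""),
                   c("#FF0000", "#0000FF"))
})

test_that("morphometrics follow the closed-form definitions", {
  calib <- scan_calibration(11.27, 3.87)

  block <- lesion_mask(as.matrix(expand.grid(0:2, 10:12)), c(255L, 0L, 0L))
  g <- measure_geometry(block, calib)
  expect_identical(g$area_px, 9L)
  expect_equal(g$area_um2, 9 * 11.27 * 3.87)   # 392.5341
  expect_identical(g$diameter_px, 3L)
  expect_equal(g$diameter_um, 33.81)
  expect_equal(c(g$centroid_row, g$centroid_col), c(1, 11))

  run <- lesion_mask(cbind(7L, 20:24), c(0L, 200L, 50L))
  g <- measure_geometry(run, calib)
  expect_identical(g$diameter_px, 5L)
  expect_equal(g$centroid_row, 7)

  # L-shape: mean over the enumerated coordinates
  lshape <- rbind(cbind(0L, 0:3), cbind(1:4, 0L))
  g <- measure_geometry(lesion_mask(lshape, c(255L, 128L, 0L)), calib)
  expect_identical(g$area_px, 8L)
  expect_equal(c(g$centroid_row, g$centroid_col),
               c(mean(lshape[, 1]), mean(lshape[, 2])))
  expect_equal(c(g$centroid_row, g$centroid_col), c(1.25, 0.75))

  # a vertical pair has lateral diameter 1
  vert <- lesion_mask(rbind(c(0L, 4L), c(1L, 4L)), c(0L, 128L, 255L))
  expect_identical(measure_geometry(vert, calib)$diameter_px, 1L)

  expect_error(measure_geometry(lesion_mask(rbind(c(0, 0), c(5, 5)),
                                            c(255L, 0L, 0L)), calib),
               "invalid mask")
})

test_that("geometry is translation invariant and bounded by the pixel count", {
  calib <- scan_calibration(10.5, 3.9)
  set.seed(42)
  for (k in 1:20) {
    # random connected blob grown from a seed pixel
    px <- rbind(c(50L, 50L))
    for (j in 1:sample(3:40, 1)) {
      base <- px[sample(nrow(px), 1), ]
      cand <- base + sample(c(-1L, 0L, 1L), 2, replace = TRUE)
      px <- unique(rbind(px, pmax(cand, 0L)))
    }
    m <- lesion_mask(px, c(255L, 0L, 0L))
    g <- measure_geometry(m, calib)
    expect_true(g$diameter_px >= 1L && g$diameter_px <= g$area_px)
    expect_true(g$centroid_row >= min(px[, 1]) && g$centroid_row <= max(px[, 1]))
    expect_true(g$centroid_col >= min(px[, 2]) && g$centroid_col <= max(px[, 2]))

    dr <- sample(0:30, 1); dc <- sample(0:30, 1)
    g2 <- measure_geometry(lesion_mask(cbind(px[, 1] + dr, px[, 2] + dc),
                                       c(255L, 0L, 0L)), calib)
    expect_identical(g2$area_px, g$area_px)
    expect_identical(g2$diameter_px, g$diameter_px)
    expect_equal(g2$centroid_row, g$centroid_row + dr)
    expect_equal(g2$centroid_col, g$centroid_col + dc)

    # metric area is locked to the calibration
    expect_equal(g$area_um2 / g$area_px, pixel_area(calib))
  }
})

test_that("rendering then extracting masks is the identity", {
  set.seed(7)
  grey <- matrix(sample(0:255, 100 * 150, replace = TRUE), 100, 150)
  masks <- list(
    lesion_mask(as.matrix(expand.grid(10:15, 20:30)), c(255L, 0L, 0L),
                scan_id = "rt"),
    lesion_mask(as.matrix(expand.grid(50:52, 100:140)), c(0L, 160L, 255L),
                scan_id = "rt"),
    lesion_mask(rbind(c(80L, 5L), c(81L, 6L), c(82L, 7L)), c(30L, 255L, 30L),
                scan_id = "rt")
  )
  ov <- render_masks(grey, masks)
  back <- extract_masks(ov, grey, scan_id = "rt")
  expect_length(back, 3L)
  key <- function(m) colour_hex(m$colour)
  back <- back[order(match(vapply(back, key, ""), vapply(masks, key, "")))]
  for (i in 1:3) {
    expect_identical(back[[i]]$pixels, masks[[i]]$pixels)
  }

  # overlapping masks cannot be rendered
  clash <- list(masks[[1]],
                lesion_mask(as.matrix(expand.grid(12:14, 25:26)),
                            c(0L, 0L, 255L)))
  expect_error(render_masks(grey, clash), "overlap")
})

test_that("run-length JSON serialisation round-trips masks exactly", {
  set.seed(13)
  masks <- list(
    lesion_mask(rbind(cbind(0L, 0:3), cbind(1:4, 0L)), c(255L, 99L, 0L),
                scan_id = "s1", lesion_id = "A"),
    lesion_mask(as.matrix(expand.grid(5:9, 40:44)), c(0L, 70L, 255L),
                scan_id = "s1", lesion_id = "B")
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_masks_json(masks, path)
  back <- read_masks_json(path)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_identical(back[[i]]$pixels, masks[[i]]$pixels)
    expect_identical(back[[i]]$colour, masks[[i]]$colour)
    expect_identical(back[[i]]$lesion_id, masks[[i]]$lesion_id)
  }
})

test_that("geometry tables carry one row per mask with consistent units", {
  calib <- scan_calibration(11.27, 3.87)
  masks <- list(
    lesion_mask(as.matrix(expand.grid(0:1, 0:4)), c(255L, 0L, 0L)),
    lesion_mask(as.matrix(expand.grid(10:12, 20:25)), c(0L, 255L, 0L))
  )
  tab <- geometry_table(masks, calib)
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$area_um2, tab$area_px * pixel_area(calib))
  expect_equal(tab$diameter_um, tab$diameter_px * calib$pixel_width_um)
})
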