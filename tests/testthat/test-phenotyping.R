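test_that("operational lesion typing follows the RPE state with SP-03 precedence", {
  expect_identical(classify_lesion(small_drusen_record()), "DRUSEN")
  expect_identical(classify_lesion(sdd_record()), "SDD")
  # hyper-reflective-only wins although the RPE is bent up
  expect_identical(classify_lesion(hyperreflective_record()),
                   "HYPERREFLECTIVE_ONLY")
  r <- grading_record("s", "L", rpe = "NOT_GRADABLE")
  expect_identical(classify_lesion(r), "UNGRADABLE")
  r <- grading_record("s", "L", rpe = "BENT_DOWN")
  expect_identical(classify_lesion(r), "SDD")
  r <- grading_record("s", "L", rpe = "DISRUPTED")
  expect_identical(classify_lesion(r), "DRUSEN")

  bad <- small_drusen_record()
  bad$brightness <- character(0)
  expect_error(classify_lesion(bad), "invalid record")
})

test_that("every valid record lands in exactly one type", {
  recs <- random_valid_cohort(80, seed = 31)
  types <- vapply(recs, classify_lesion, "")
  expect_true(all(types %in% LESION_TYPES))
  # partition: reclassifying is stable
  expect_identical(vapply(recs, classify_lesion, ""), types)
})

test_that("leading drusen selection picks the maximal cutting area", {
  vol <- data.frame(scan_index = 48L, lesion_id = as.character(1:5),
                    area_um2 = c(2740, 1566, 2001, 7307, 3262))
  sel <- select_leading(vol)
  expect_identical(sel$lesion_id, "4")
  expect_equal(sel$area_um2, 7307)

  single <- data.frame(scan_index = 3L, lesion_id = "only", area_um2 = 12)
  expect_identical(select_leading(single)$lesion_id, "only")

  tie <- data.frame(scan_index = c(7L, 3L), lesion_id = c("a", "b"),
                    area_um2 = c(100, 100))
  expect_identical(select_leading(tie)$scan_index, 3L)

  expect_error(select_leading(vol[0, ]), "no lesions")
})

test_that("leading selection agrees with brute-force enumeration", {
  set.seed(17)
  for (k in 1:25) {
    vol <- data.frame(
      scan_index = sample(1:97, 30, replace = TRUE),
      lesion_id = sprintf("L%02d", sample(1:99, 30)),
      area_um2 = round(rlnorm(30, 8, 1), 1)
    )
    sel <- select_leading(vol)
    expect_equal(sel$area_um2, max(vol$area_um2))
    best <- vol[vol$area_um2 == max(vol$area_um2), ]
    best <- best[order(best$scan_index, best$lesion_id), ][1, ]
    expect_identical(sel$lesion_id, best$lesion_id)
    expect_identical(sel$scan_index, best$scan_index)
  }
})

# the published five-lesion tracking example: baseline and follow-up
# cutting areas (um^2), matched by mask colour
tracking_example <- function() {
  list(
    baseline = data.frame(lesion_id = as.character(1:5),
                          area_um2 = c(2740, 1566, 2001, 7307, 3262)),
    followup = data.frame(lesion_id = as.character(1:5),
                          area_um2 = c(3219, 9917, 2740, 13397, 14093))
  )
}

test_that("tracked pairs carry the area deltas of the five-lesion example", {
  ex <- tracking_example()
  recs <- lapply(1:5, function(i) {
    grading_record("fu", as.character(i), is_followup = TRUE,
                   rpe = "BENT_UP", progression = "GROWTH")
  })
  tp <- track_lesions(ex$baseline, ex$followup, recs)
  expect_identical(nrow(tp), 5L)
  expect_equal(tp$delta_area_um2[match(as.character(1:5), tp$lesion_id)],
               c(479, 8351, 739, 6090, 10831))
  expect_true(all(tp$matched))
  # every pair reads as noticeable growth at the default threshold
  for (i in seq_len(nrow(tp))) {
    chk <- check_progression_consistency(tp[i, ])
    expect_true(chk$consistent)
    expect_identical(chk$expected, "GROWTH")
  }
})

test_that("unmatched lesions get NEW expectation or zero follow-up area", {
  b <- data.frame(lesion_id = c("a", "b"), area_um2 = c(100, 200))
  f <- data.frame(lesion_id = c("a", "c"), area_um2 = c(100, 50))
  recs <- list(
    grading_record("fu", "a", is_followup = TRUE, progression = "STATIONARY"),
    grading_record("fu", "c", is_followup = TRUE, progression = "NEW")
  )
  tp <- track_lesions(b, f, recs)
  expect_identical(sort(tp$lesion_id), c("a", "b", "c"))

  cc <- tp[tp$lesion_id == "c", ]
  expect_equal(cc$baseline_area_um2, 0)
  expect_false(cc$matched)
  expect_true(check_progression_consistency(cc)$consistent)
  expect_identical(check_progression_consistency(cc)$expected, "NEW")

  bb <- tp[tp$lesion_id == "b", ]
  expect_equal(bb$followup_area_um2, 0)
  expect_equal(bb$delta_area_um2, -200)

  # identical scans give zero deltas
  tp0 <- track_lesions(b, b)
  expect_true(all(tp0$delta_area_um2 == 0))

  # growth claimed without a baseline partner is a consistency error
  bad <- list(grading_record("fu", "c", is_followup = TRUE,
                             progression = "GROWTH"))
  expect_error(track_lesions(b, f[f$lesion_id == "c", , drop = FALSE], bad),
               "no baseline partner")
})

test_that("sum of deltas equals total area change (conservation)", {
  set.seed(23)
  for (k in 1:10) {
    ids <- sprintf("L%02d", 1:12)
    b <- data.frame(lesion_id = sample(ids, 8), area_um2 = rlnorm(8, 8, 0.7))
    f <- data.frame(lesion_id = sample(ids, 9), area_um2 = rlnorm(9, 8, 0.7))
    tp <- track_lesions(b, f)
    expect_equal(sum(tp$delta_area_um2), sum(f$area_um2) - sum(b$area_um2))
    m <- tp[tp$matched, ]
    common <- intersect(b$lesion_id, f$lesion_id)
    expect_equal(sum(m$delta_area_um2),
                 sum(f$area_um2[match(common, f$lesion_id)]) -
                   sum(b$area_um2[match(common, b$lesion_id)]))
  }
})

test_that("the advisory progression check flags contradictions only", {
  grown <- list(baseline_area_um2 = 1566, delta_area_um2 = 8351,
                recorded_progression = "GROWTH")
  expect_true(check_progression_consistency(grown, 0.10)$consistent)

  flat <- list(baseline_area_um2 = 1000, delta_area_um2 = 0,
               recorded_progression = "GROWTH")
  chk <- check_progression_consistency(flat)
  expect_false(chk$consistent)
  expect_match(chk$message, "review")

  shrunk <- list(baseline_area_um2 = 1000, delta_area_um2 = -600,
                 recorded_progression = "REMISSION_LAYERS_PRESERVED")
  expect_true(check_progression_consistency(shrunk)$consistent)

  unclear <- list(baseline_area_um2 = 1000, delta_area_um2 = 900,
                  recorded_progression = "UNCLEAR")
  expect_true(check_progression_consistency(unclear)$consistent)

  new_wrong <- list(baseline_area_um2 = 0, delta_area_um2 = 500,
                    recorded_progression = "STATIONARY")
  expect_false(check_progression_consistency(new_wrong)$consistent)
})

test_that("phenotype tables join types with geometry", {
  recs <- list(small_drusen_record(), sdd_record())
  geo <- data.frame(scan_id = c("ex-drusen", "ex-sdd"),
                    lesion_id = c("L1", "L1"),
                    area_um2 = c(1705, 5292), diameter_um = c(150, 300))
  tab <- phenotype_table(recs, geo)
  expect_identical(tab$lesion_type, c("DRUSEN", "SDD"))
  expect_equal(tab$area_um2, c(1705, 5292))
})
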