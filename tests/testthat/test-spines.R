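rules <- spine_rules()

test_that("retention filters apply inclusive physical-unit boundaries", {
  base <- tibble::tibble(length_um = 1, max_width_um = 1, volume_um3 = 0.03,
                         head_diameter_um = 0.2, neck_diameter_um = 0.2)
  probe <- function(field, value) {
    m <- base; m[[field]] <- value
    retention_flags(m, rules)
  }
  expect_false(probe("length_um", 6))            # over-long protrusion
  expect_false(probe("length_um", 5.001))
  expect_true(probe("length_um", 5))             # inclusive maximum
  expect_true(probe("length_um", 0.1))           # inclusive minimum
  expect_false(probe("length_um", 0.099))
  expect_false(probe("volume_um3", 0.019))
  expect_true(probe("volume_um3", 0.020))        # inclusive minimum volume
  expect_true(probe("max_width_um", 3.0))        # inclusive maximal width
  expect_false(probe("max_width_um", 3.1))
})

test_that("classification follows the mushroom -> stubby -> thin rule order", {
  m <- function(head, ratio, vol) {
    list(head_diameter_um = head, neck_diameter_um = head / ratio,
         volume_um3 = vol)
  }
  expect_equal(classify_spine(m(0.4, 1.2, 0.03), rules), "mushroom")
  expect_equal(classify_spine(m(0.3, 1.2, 0.05), rules), "stubby")
  expect_equal(classify_spine(m(0.3, 1.2, 0.03), rules), "thin")
  # mushroom wins over stubby even above the stubby volume cutoff
  expect_equal(classify_spine(m(0.5, 1.5, 0.10), rules), "mushroom")
  # both mushroom conditions are required
  expect_equal(classify_spine(m(0.5, 1.05, 0.03), rules), "thin")
  expect_equal(classify_spine(m(0.34, 3, 0.03), rules), "thin")
  expect_error(
    classify_spine(list(head_diameter_um = 0.4, neck_diameter_um = 0,
                        volume_um3 = 0.03), rules),
    "neck")
})

test_that("classification is a partition of the retained set", {
  tab <- make_protrusion_table(15, rules, seed = 5, n_reject = 5)
  kept <- filter_protrusions(tab, rules)
  cls <- classify_spines(kept, rules)
  expect_true(all(cls %in% c("thin", "stubby", "mushroom")))
  expect_length(cls, nrow(kept))
  census <- spine_density(cls, 30)
  expect_equal(census$counts[["total"]],
               sum(census$counts[c("thin", "stubby", "mushroom")]))
  expect_equal(census$densities[["total"]],
               sum(census$densities[c("thin", "stubby", "mushroom")]))
})

test_that("tightening any retention threshold never increases the retained count", {
  tab <- make_protrusion_table(12, rules, seed = 9, n_reject = 8)
  n0 <- nrow(filter_protrusions(tab, rules))
  tighter <- list(
    spine_rules(min_volume_um3 = 0.03),
    spine_rules(min_length_um = 0.5),
    spine_rules(max_length_um = 1.5),
    spine_rules(max_width_um = 0.5)
  )
  for (r in tighter) expect_lte(nrow(filter_protrusions(tab, r)), n0)
})

test_that("spine densities are counts per micrometre", {
  census <- spine_density(rep("thin", 6), 20)
  expect_equal(census$densities[["total"]], 0.3)
  empty <- spine_density(character(0), 10)
  expect_true(all(empty$densities == 0))
  mixed <- spine_density(rep(c("thin", "stubby", "mushroom"), c(3, 2, 1)), 10)
  expect_equal(unname(mixed$densities[c("thin", "stubby", "mushroom", "total")]),
               c(0.3, 0.2, 0.1, 0.6))
  expect_error(spine_density("thin", 0), "positive")
})

test_that("voxel-count thresholds follow from the physical thresholds", {
  cal <- calibration(0.066, z_step_um = 0.2)
  vv <- voxel_volume_um3(cal)
  expect_equal(vv, 0.066^2 * 0.2)
  # at this voxel size the 0.020/0.040 um^3 contracts correspond to ~23/46
  # voxels; the physical values are authoritative
  expect_equal(ceiling(rules$min_volume_um3 / vv), 23)
  expect_equal(ceiling(rules$stubby_min_volume_um3 / vv), 46)
})

test_that("template geometry is recovered from synthetic spine images", {
  si <- make_spine_image(c("mushroom", "thin"), seed = 2)
  mt <- measure_protrusions(si$mask, si$shaft, si$calibration, si$section_um)
  mush <- mt[1, ]
  expect_gt(mush$head_diameter_um / mush$neck_diameter_um, 1.1)
  expect_gte(mush$head_diameter_um, 0.35)
  peg <- mt[2, ]
  expect_equal(peg$head_diameter_um / peg$neck_diameter_um, 1, tolerance = 0.05)
})

test_that("measure + classify recovers at least 90% of generated classes", {
  classes <- rep(c("thin", "stubby", "mushroom"), times = 7)
  si <- make_spine_image(classes, seed = 14)
  mt <- measure_protrusions(si$mask, si$shaft, si$calibration, si$section_um)
  expect_equal(nrow(mt), length(classes))
  expect_false(any(mt$border))
  kept <- filter_protrusions(mt, rules)
  expect_equal(nrow(kept), length(classes))  # all templates pass retention
  got <- classify_spines(kept, rules)
  expect_gte(mean(got == classes[kept$id]), 0.9)
})

test_that("border-touching protrusions are flagged and excluded from measurement", {
  m <- matrix(FALSE, 20, 30)
  shaft <- matrix(FALSE, 20, 30)
  shaft[15:20, ] <- TRUE
  m[15:20, ] <- TRUE
  m[1:14, 5:7] <- TRUE        # runs off the top border
  m[10:14, 20:22] <- TRUE     # interior protrusion
  mt <- measure_protrusions(m, shaft, calibration(0.02, 0.2))
  expect_equal(sum(mt$border), 1L)
  expect_true(is.na(mt$length_um[mt$border]))
  expect_false(is.na(mt$length_um[!mt$border]))
})
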