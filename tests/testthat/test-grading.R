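test_that("built-in schemes load with the documented index coverage", {
  our <- load_scheme("our_center")
  expect_setequal(names(our$indexes), c("dsc", "cmd", "dv", "mhd", "ahd"))
  expect_setequal(names(load_scheme("velker")$indexes), "dsc")
  expect_setequal(names(load_scheme("ciardo")$indexes), c("dsc", "cmd", "ahd"))
  expect_error(load_scheme("nope"), "unknown scheme")
})

test_that("grade_value reproduces documented level assignments", {
  our <- load_scheme("our_center")
  velker <- load_scheme("velker")
  expect_equal(grade_value(0.96, our$indexes$dsc), 3)
  # a DSC in [0.6, 0.7) splits the schemes: level 1 at our centre, 2 by velker
  expect_equal(grade_value(0.62, our$indexes$dsc), 1)
  expect_equal(grade_value(0.62, velker$indexes$dsc), 2)
  # boundary values take the better level
  expect_equal(grade_value(1.00, our$indexes$cmd), 2)
  expect_equal(grade_value(0.5, our$indexes$cmd), 3)
  expect_equal(grade_value(0.8, our$indexes$dsc), 3)
  expect_equal(grade_value(0.7, our$indexes$dsc), 2)
  expect_equal(grade_value(0.58, our$indexes$ahd), 1)
  # level 4 only at the exact perfect value
  expect_equal(grade_value(1.0, our$indexes$dsc), 4)
  expect_equal(grade_value(0, our$indexes$mhd), 4)
  expect_equal(grade_value(1e-6, our$indexes$mhd), 3)
  # schemes without a perfect level top out at 3
  expect_equal(grade_value(1.0, velker$indexes$dsc), 3)
  expect_error(grade_value(1.3, our$indexes$dsc), "out of range")
  expect_error(grade_value(-0.2, our$indexes$ahd), ">= 0")
})

test_that("grade_value is monotone and the level partition is total", {
  set.seed(5)
  for (nm in c("our_center", "velker", "ciardo")) {
    sch <- load_scheme(nm)
    for (ix in names(sch$indexes)) {
      th <- sch$indexes[[ix]]
      vals <- if (ix == "dsc") sort(runif(50)) else sort(runif(50, 0, 8))
      lv <- vapply(vals, grade_value, integer(1), thresholds = th)
      expect_true(all(lv %in% 1:4))
      # exactly one level per value, monotone in the improvement direction
      if (th$direction == "higher") {
        expect_true(all(diff(lv) >= 0))
      } else {
        expect_true(all(diff(lv) <= 0))
      }
    }
  }
})

test_that("grade_metric_set grades per defined index and omits the rest", {
  m <- thorax_mean_metrics_df()
  rl <- m[m$oar == "R Lung", ]
  expect_equal(unname(grade_metric_set(rl, "our_center")), c(3, 3, 3, 2, 3))
  heart <- m[m$oar == "Heart", ]
  expect_equal(unname(grade_metric_set(heart, "our_center")), c(3, 3, 3, 2, 2))
  perfect <- metric_set(1, 0, 0, 0, 0)
  expect_equal(unname(grade_metric_set(perfect, "our_center")), rep(4L, 5))
  cia <- grade_metric_set(rl, "ciardo")
  expect_setequal(names(cia), c("dsc", "cmd", "ahd"))
  # an index missing from the metrics is an error, not a default
  expect_error(grade_metric_set(list(dsc = 0.9, cmd_cm = 0.1), "our_center"),
               "lack field")
})

test_that("subjective grading follows the three length classes", {
  # long organs: percentage path, boundaries on the better side
  expect_equal(subjective_grade(71, pct_modified = 6), 3)
  expect_equal(subjective_grade(71, pct_modified = 10), 3)
  expect_equal(subjective_grade(319, pct_modified = 14), 2)
  expect_equal(subjective_grade(50, pct_modified = 20), 2)
  expect_equal(subjective_grade(50, pct_modified = 20.5), 1)
  expect_equal(subjective_grade(71, 5), 3)   # 7.04% unrounded
  # short organs: count path
  expect_equal(subjective_grade(9, 7), 1)
  expect_equal(subjective_grade(9, 1), 3)
  expect_equal(subjective_grade(9, 3), 2)
  expect_equal(subjective_grade(10, 4), 1)
  # very short organs
  expect_equal(subjective_grade(2, 1), 3)
  expect_equal(subjective_grade(2, 2), 2)
  # nothing modified is always level 4
  expect_equal(subjective_grade(71, 0), 4)
  expect_equal(subjective_grade(2, 0), 4)
  expect_equal(subjective_grade(500, pct_modified = 0), 4)
  # inconsistent records
  expect_error(subjective_grade(5, 7), "inconsistent-record")
  expect_error(subjective_grade(0, pct_modified = 50), "inconsistent-record")
})

test_that("display percentage rounds half up, grading stays unrounded", {
  expect_equal(pct_modified_display(5, 71), 7)
  expect_equal(pct_modified_display(1, 8), 13)   # 12.5 rounds up
  # 10.4% displays as 10 but still grades by the unrounded value
  expect_equal(pct_modified_display(26, 250), 10)
  expect_equal(subjective_grade(250, 26), 2)  # 10.4% -> level 2
})

test_that("consistency_report tabulates level deltas with percentages", {
  subj <- c(A = 2, B = 3, C = 1)
  obj <- c(A = 3, B = 3, C = 3)
  cr <- consistency_report(subj, obj)
  expect_equal(cr$category, c("one_level_lower", "equal", "other"))
  s <- attr(cr, "summary")
  expect_equal(s$count, c(1L, 1L, 1L))
  expect_equal(s$pct, c(33.3, 33.3, 33.3))
  # identical vectors: all equal
  cr2 <- consistency_report(subj, subj)
  expect_equal(attr(cr2, "summary")$pct, c(0, 100, 0))
  # all subjective 1 vs objective 3: everything lands in "other"
  cr3 <- consistency_report(setNames(rep(1, 13), paste0("o", 1:13)),
                            setNames(rep(3, 13), paste0("o", 1:13)))
  expect_equal(attr(cr3, "summary")$count, c(0L, 0L, 13L))
  expect_error(consistency_report(subj, obj[1:2]), "mismatch")
})

test_that("a custom scheme JSON validates and grades", {
  f <- tempfile(fileext = ".json")
  writeLines('{"name":"custom","indexes":{"dsc":{"direction":"higher","cutpoints":[0.5,0.9]}}}', f)
  sch <- load_scheme(f)
  expect_equal(grade_value(0.95, sch$indexes$dsc), 3)
  writeLines('{"name":"bad","indexes":{"dsc":{"direction":"higher","cutpoints":[0.9,0.5]}}}', f)
  expect_error(load_scheme(f), "increasing")
  writeLines('{"name":"bad2","indexes":{"cmd":{"direction":"higher","cutpoints":[0.2,0.5]}}}', f)
  expect_error(load_scheme(f), "direction")
  unlink(f)
})
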