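test_that("summarize_levels gives exact per-level stats", {
  cases <- data.frame(subjective_level = rep(3, 5),
                      dsc = c(0.93, 0.94, 0.95, 0.97, 0.99))
  s <- summarize_levels(cases)
  expect_equal(nrow(s), 1)
  expect_equal(s$min, 0.93)
  expect_equal(s$max, 0.99)
  expect_equal(s$mean, 0.956)
  # single case: min = max = mean
  one <- summarize_levels(data.frame(subjective_level = 2, dsc = 0.81))
  expect_equal(c(one$min, one$max, one$mean), rep(0.81, 3))
  # grouping by observed level
  mix <- summarize_levels(data.frame(subjective_level = c(1, 1, 3),
                                     dsc = c(0.5, 0.6, 0.9)))
  expect_equal(mix$level, c(1, 3))
  expect_equal(mix$n_cases, c(2, 1))
  expect_error(summarize_levels(data.frame()), "nonempty")
  expect_error(summarize_levels(data.frame(oar = c("a", "b"),
                                           subjective_level = c(1, 1),
                                           dsc = c(0.5, 0.6))), "mixes")
})

test_that("ranges_overlap treats intervals as closed", {
  expect_true(ranges_overlap(c(0.88, 0.95), c(0.95, 1)))  # shared endpoint
  expect_false(ranges_overlap(c(0.5, 0.6), c(0.7, 0.8)))
  expect_true(ranges_overlap(c(0.1, 0.9), c(0.2, 0.3)))   # containment
})

test_that("single-level cohorts yield half-bounded standards on all indexes", {
  # a well-performing organ observed only at level 3
  cases <- data.frame(oar = "RL", subjective_level = 3,
                      dsc = c(0.93, 0.95, 0.99), cmd_cm = c(0.05, 0.26, 0.1),
                      dv_pct = c(2, 14, 7), mhd_cm = c(1.2, 4.27, 2),
                      ahd_cm = c(0.02, 0.19, 0.1))
  fit <- soc_standard(cases, indexes = c("dsc", "cmd_cm", "dv_pct",
                                         "mhd_cm", "ahd_cm"))
  f <- fit$oars$RL
  expect_equal(f$distribution_kind, "single-level")
  expect_equal(f$indexes$dsc$levels[, c("lo", "hi")],
               data.frame(lo = 0.93, hi = 1))
  expect_equal(f$indexes$cmd_cm$levels$lo, 0)
  expect_equal(f$indexes$cmd_cm$levels$hi, 0.26)
  expect_equal(f$indexes$mhd_cm$levels$hi, 4.27)
  # a poor organ observed only at level 1
  bad <- data.frame(oar = "CW", subjective_level = 1,
                    dsc = c(0.6, 0.85), cmd_cm = c(0.28, 1.4))
  fb <- soc_standard(bad, indexes = c("dsc", "cmd_cm"))$oars$CW
  expect_equal(fb$indexes$dsc$levels[, c("lo", "hi")],
               data.frame(lo = 0, hi = 0.85))
  expect_equal(fb$indexes$cmd_cm$levels$lo, 0.28)
  expect_true(is.infinite(fb$indexes$cmd_cm$levels$hi))
  # rendering: half-bounded distance as ">= a", dsc as "a-b"
  tab <- format_standard_table(soc_standard(bad, indexes = c("dsc", "cmd_cm")))
  expect_equal(tab$cmd_cm_L1, ">= 0.28")
  expect_equal(tab$dsc_L1, "0-0.85")
  expect_equal(tab$dsc_L2, "-")
})

test_that("disjoint adjacent levels give range-based standards, overlap gives means", {
  disj <- data.frame(oar = "X",
                     subjective_level = c(2, 2, 3, 3),
                     dsc = c(0.70, 0.78, 0.82, 0.95))
  fd <- soc_standard(disj)$oars$X$indexes$dsc$levels
  expect_equal(fd$mode, c("range", "range"))
  expect_equal(fd$lo, c(0.70, 0.82))   # level 2 not extended to 0
  expect_equal(fd$hi, c(0.78, 1))      # best level extended to the perfect value
  ovl <- data.frame(oar = "X",
                    subjective_level = c(2, 2, 3, 3),
                    dsc = c(0.70, 0.90, 0.85, 0.95))
  fo <- soc_standard(ovl)$oars$X$indexes$dsc$levels
  expect_equal(fo$mode, c("mean", "mean"))
  expect_equal(fo$mean, c(0.80, 0.90))
  # non-monotone means are an explicit "undefined", not a silent standard
  nm <- data.frame(oar = "X",
                   subjective_level = c(2, 2, 3, 3),
                   dsc = c(0.9, 0.95, 0.5, 0.99))
  fn <- soc_standard(nm)$oars$X$indexes$dsc$levels
  expect_true(all(fn$mode == "undefined"))
  expect_equal(soc_standard(nm)$oars$X$distribution_kind, "multi-level")
})

test_that("a mixed standard keeps ranges at one pair and means at another", {
  cases <- data.frame(oar = "T",
                      subjective_level = c(1, 1, 2, 2, 3, 3),
                      dsc = c(0.50, 0.60, 0.70, 0.78, 0.75, 0.95))
  lv <- soc_standard(cases)$oars$T$indexes$dsc$levels
  # pair (1,2) disjoint; pair (2,3) overlaps with monotone means
  expect_equal(lv$mode, c("range", "mean", "mean"))
  pairs <- soc_standard(cases)$oars$T$indexes$dsc$pairs
  expect_equal(pairs$relation, c("disjoint", "overlap_monotone"))
})

test_that("adjacent-level comparison uses only observed levels", {
  cases <- data.frame(oar = "A",
                      subjective_level = c(1, 1, 3, 3),  # level 2 absent
                      dsc = c(0.4, 0.5, 0.9, 0.95))
  lv <- soc_standard(cases)$oars$A$indexes$dsc$levels
  expect_equal(lv$level, c(1, 3))
  expect_equal(lv$mode, c("range", "range"))
  tab <- format_standard_table(soc_standard(cases))
  expect_equal(tab$dsc_L2, "-")
})

test_that("training cases are reassigned their own level by a range-based standard", {
  set.seed(9)
  spec <- data.frame(oar = "L", level = c(1, 2, 3), n = c(30, 30, 30),
                     dsc_lo = c(0.30, 0.62, 0.85),
                     dsc_hi = c(0.55, 0.80, 0.98))
  coh <- simulate_cohort(spec, seed = 11)
  fit <- soc_standard(coh)
  expect_true(all(fit$oars$L$indexes$dsc$levels$mode == "range"))
  pred <- predict(fit, coh)
  expect_equal(pred, as.integer(coh$subjective_level))
})

test_that("gap values grade to the worse level; mean-based uses nearest mean", {
  disj <- data.frame(oar = "X", subjective_level = c(2, 2, 3, 3),
                     dsc = c(0.70, 0.78, 0.82, 0.95))
  fit <- soc_standard(disj)
  expect_equal(predict(fit, data.frame(oar = "X", dsc = 0.80)), 2L)
  expect_equal(predict(fit, data.frame(oar = "X", dsc = 0.99)), 3L)
  expect_equal(predict(fit, data.frame(oar = "X", dsc = 0.10)), 2L)
  expect_equal(predict(fit, data.frame(oar = "Y", dsc = 0.9)), NA_integer_)
  ovl <- data.frame(oar = "X", subjective_level = c(2, 2, 3, 3),
                    dsc = c(0.70, 0.90, 0.85, 0.95))
  fo <- soc_standard(ovl)  # means 0.80 and 0.90
  expect_equal(predict(fo, data.frame(oar = "X", dsc = 0.82)), 2L)
  expect_equal(predict(fo, data.frame(oar = "X", dsc = 0.89)), 3L)
  expect_equal(predict(fo, data.frame(oar = "X", dsc = 0.85)), 3L)  # tie to better
})

test_that("simulated disjoint cohorts recover their interval endpoints", {
  spec <- data.frame(oar = "L", level = c(2, 3), n = c(200, 200),
                     dsc_lo = c(0.60, 0.85), dsc_hi = c(0.75, 0.98))
  coh <- simulate_cohort(spec, seed = 21)
  lv <- soc_standard(coh)$oars$L$indexes$dsc$levels
  expect_equal(lv$mode, c("range", "range"))
  # extreme order statistics sit within ~3/(n+1) interval widths of the truth
  tol2 <- 3 * (0.75 - 0.60) / 201
  tol3 <- 3 * (0.98 - 0.85) / 201
  expect_lt(abs(lv$lo[1] - 0.60), tol2)
  expect_lt(abs(lv$max[1] - 0.75), tol2)
  expect_lt(abs(lv$min[2] - 0.85), tol3)
  expect_equal(lv$hi[2], 1)  # quality side extended to the perfect value
})

test_that("overlapping simulated cohorts recover means within 3 standard errors", {
  spec <- data.frame(oar = "L", level = c(2, 3), n = c(200, 200),
                     dsc_mean = c(0.75, 0.85), dsc_sd = c(0.06, 0.05))
  coh <- simulate_cohort(spec, seed = 22)
  lv <- soc_standard(coh)$oars$L$indexes$dsc$levels
  expect_equal(lv$mode, c("mean", "mean"))
  expect_lt(abs(lv$mean[1] - 0.75), 3 * 0.06 / sqrt(200))
  expect_lt(abs(lv$mean[2] - 0.85), 3 * 0.05 / sqrt(200))
})

test_that("excluded cases are dropped before derivation", {
  cases <- data.frame(oar = "X", subjective_level = c(3, 3, 3),
                      dsc = c(0.93, 0.95, 0.10),
                      exclude = c(0, 0, 1))
  lv <- soc_standard(cases)$oars$X$indexes$dsc$levels
  expect_equal(lv$lo, 0.93)
  expect_equal(lv$n, 2)
})

test_that("standard table orders organs by descending mean of the first index", {
  cases <- rbind(
    data.frame(oar = "B", subjective_level = 3, dsc = c(0.9, 0.92)),
    data.frame(oar = "A", subjective_level = 1, dsc = c(0.5, 0.6)),
    data.frame(oar = "C", subjective_level = 1, dsc = c(0.56, 0.60)))
  tab <- format_standard_table(soc_standard(cases))
  expect_equal(tab$oar, c("B", "C", "A"))
})
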