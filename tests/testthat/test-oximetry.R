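mk_records <- function(po2, depth = 200, class = "capillary",
                       animal = "m1", cohort = "WT", day = 0) {
  data.frame(cohort = cohort, animal_id = animal, vessel_id = paste0("v", seq_along(po2)),
             vessel_class = class, depth_um = depth, day = day,
             po2 = po2, so2 = po2_to_so2(po2), stringsAsFactors = FALSE)
}

test_that("layer summaries compute mean, SE and CV with sample sd", {
  r <- mk_records(c(10, 20))
  s <- layer_summary(r, value = "po2")
  expect_equal(s$mean, 15)
  expect_equal(s$cv, 0.471404520791, tolerance = 1e-10)  # sd 7.0711 / 15
  expect_equal(s$se, s$sd / sqrt(2))
  # identical records: CV = 0, SE = 0
  s0 <- layer_summary(mk_records(rep(42, 8)), value = "po2")
  expect_equal(s0$cv, 0)
  expect_equal(s0$se, 0)
  # CV is scale invariant
  s3 <- layer_summary(mk_records(3 * c(10, 20)), value = "po2")
  expect_equal(s3$cv, s$cv)
  # non-positive mean: undefined CV flagged
  r$po2 <- c(-5, 5)
  expect_warning(sn <- layer_summary(r, value = "po2"), "non-positive")
  expect_true(is.na(sn$cv))
})

test_that("records group into the correct layers", {
  r <- mk_records(c(50, 60, 70, 80, 90), depth = c(50, 100, 200, 300, 400))
  s <- layer_summary(r, value = "po2")
  expect_equal(s$layer, c("I", "II/III", "IV"))
  expect_equal(s$n, c(1, 3, 1))
  expect_equal(sum(s$n), nrow(r))
})

test_that("DOE is the arteriovenous SO2 difference with stated invariances", {
  r <- rbind(mk_records(c(90, 94), class = "arteriole"),
             mk_records(c(60, 64), class = "venule"))
  r$so2 <- r$po2  # use raw values to check the arithmetic: 92 - 62
  d <- compute_doe(r)
  expect_equal(d$sao2, 92)
  expect_equal(d$svo2, 62)
  expect_equal(d$doe, 30)
  # translation invariance
  r2 <- r; r2$so2 <- r2$so2 + 4.5
  expect_equal(compute_doe(r2)$doe, 30)
  # equal means give zero extraction
  r3 <- r; r3$so2 <- 70
  expect_equal(compute_doe(r3)$doe, 0)
  # duplication of the record set leaves DOE unchanged
  expect_equal(compute_doe(rbind(r, r))$doe, 30)
  # a layer missing one class is omitted with a warning
  r4 <- rbind(mk_records(80, class = "arteriole", depth = 50),
              mk_records(c(90, 60), class = c("arteriole", "venule"),
                         depth = 400))
  r4$so2 <- r4$po2
  expect_warning(d4 <- compute_doe(r4), "omitted")
  expect_equal(d4$layer, "IV")
  suppressWarnings(
    expect_error(compute_doe(mk_records(80, class = "arteriole")), "no layer"))
})

test_that("cohort aggregation averages animals, not vessels", {
  r <- rbind(mk_records(rep(40, 10), animal = "m1"),
             mk_records(rep(60, 2), animal = "m2"))
  agg <- cohort_aggregate(r, value = "po2", stat = "mean")
  # unweighted across animals: (40 + 60) / 2 regardless of vessel counts
  expect_equal(agg$mean, 50)
  expect_equal(agg$n_animals, 2)
  # single animal: cohort mean equals the animal's summary
  agg1 <- cohort_aggregate(mk_records(c(30, 50)), value = "po2")
  expect_equal(agg1$mean, 40)
  expect_equal(agg1$se, 0)
})

test_that("longitudinal deltas subtract the day-0 baseline per vessel point", {
  base <- mk_records(c(50, 60), day = 0)
  d7 <- mk_records(c(45, 55), day = 7)
  d7$vessel_id <- base$vessel_id
  r <- rbind(base, d7)
  dl <- so2_deltas(r)
  truth <- mean(po2_to_so2(c(45, 55)) - po2_to_so2(c(50, 60)))
  expect_equal(dl$delta_mean, truth)
  expect_equal(dl$day, 7)
  expect_error(so2_deltas(d7), "baseline")
})
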