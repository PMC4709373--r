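# Dosing calendars, adherence patterns, exposure conversion, CMPL.

test_that("calendar has 250 scheduled doses per year at 5 days/week", {
  expect_equal(scheduledDoses(buildCalendar(5, 1)), 250)
  expect_equal(scheduledDoses(buildCalendar(5, 2)), 500)
  expect_equal(scheduledDoses(buildCalendar(7, 1)), 350)
  cal <- buildCalendar(5, 1)
  expect_true(all(cal@taken))
  # 5 consecutive dosing days then 2 off
  expect_equal(cal@day[1:6], c(1:5, 8))
  expect_error(buildCalendar(0, 1), "1..7")
  expect_error(buildCalendar(5, -1), "> 0")
})

test_that("printed missed-dose grid is reproduced exactly", {
  cal <- buildCalendar(5, 1)
  fractions <- seq(0.1, 0.9, by = 0.1)
  # random pattern and 1-year holidays: 25, 50, ..., 225 per year
  for (f in fractions) {
    expect_equal(missedDoses(applyRandomMissing(cal, f, seed = 3)),
                 round(250 * f))
    expect_equal(missedDoses(applyDrugHolidays(cal, f, "1 year")),
                 round(250 * f))
  }
  # 6-month blocks (125 doses): 25/50/75/100 at the even deciles
  for (f in c(0.2, 0.4, 0.6, 0.8)) {
    perBlock <- missedPerBlock(applyDrugHolidays(cal, f, "6 months"), 125)
    expect_equal(perBlock, rep(as.integer(round(125 * f)), 2))
  }
  # 2-month blocks (50 doses): 5, 10, ..., 45 at every decile
  for (f in fractions) {
    perBlock <- missedPerBlock(applyDrugHolidays(cal, f, "2 months"), 50)
    expect_equal(perBlock, rep(as.integer(round(50 * f)), 5))
  }
  # 1-month blocks (25 doses): 5/10/15/20 at the even deciles
  for (f in c(0.2, 0.4, 0.6, 0.8)) {
    perBlock <- missedPerBlock(applyDrugHolidays(cal, f, "1 month"), 25)
    expect_equal(perBlock, rep(as.integer(round(25 * f)), 10))
  }
})

test_that("random and consecutive patterns miss identical totals", {
  cal <- buildCalendar(5, 1)
  for (f in c(0.2, 0.4, 0.6, 0.8)) {
    nRandom <- missedDoses(applyRandomMissing(cal, f, seed = 11))
    for (st in c("1 year", "6 months", "2 months", "1 month"))
      expect_equal(missedDoses(applyDrugHolidays(cal, f, st)), nRandom)
  }
})

test_that("random missing is seeded, exact and bounded", {
  cal <- buildCalendar(5, 2)
  expect_equal(applyRandomMissing(cal, 0, 1)@taken, cal@taken)
  expect_equal(missedDoses(applyRandomMissing(cal, 1, 1)), 500)
  a <- applyRandomMissing(cal, 0.4, seed = 99)
  b <- applyRandomMissing(cal, 0.4, seed = 99)
  c2 <- applyRandomMissing(cal, 0.4, seed = 100)
  expect_identical(a@taken, b@taken)
  expect_false(identical(a@taken, c2@taken))
  # exactly 100 per year
  expect_equal(missedPerBlock(a, 250), c(100L, 100L))
  expect_error(applyRandomMissing(cal, 1.2, 1), "\\[0, 1\\]")
})

test_that("drug holidays sit at the block start (or end on request)", {
  cal <- buildCalendar(5, 1)
  h <- applyDrugHolidays(cal, 0.4, "1 year")
  expect_equal(h@taken, c(rep(FALSE, 100), rep(TRUE, 150)))
  hEnd <- applyDrugHolidays(cal, 0.4, "1 year", placement = "end")
  expect_equal(hEnd@taken, c(rep(TRUE, 150), rep(FALSE, 100)))
  expect_equal(applyDrugHolidays(cal, 0, "6 months")@taken, cal@taken)
  # 1-month blocks: first 10 of every 25 missed at 40%
  h2 <- applyDrugHolidays(cal, 0.4, "1 month")
  expect_equal(h2@taken[1:25], c(rep(FALSE, 10), rep(TRUE, 15)))
  expect_equal(h2@taken[26:50], c(rep(FALSE, 10), rep(TRUE, 15)))
})

test_that("calendar converts to the documented daily exposure", {
  pk <- pkParameters()
  reg <- infusionRegimen(45, 45)
  cal <- buildCalendar(5, 1)
  tl <- exposureFromCalendar(cal, reg, pk)
  # taken-day level 2025 / (13.857 * 24) = 6.089 mg/L
  expect_equal(max(tl@levels), 6.0893, tolerance = 1e-4)
  # full-adherence weekly mean equals the weekly css average
  dayLevels <- timelineAt(tl, (0:(350 - 1)) * 24)
  expect_equal(mean(dayLevels), cssAv(cssAverage(pk, reg)),
               tolerance = 1e-9)
  # all doses missed: identically zero
  tl0 <- exposureFromCalendar(applyRandomMissing(cal, 1, 1), reg, pk)
  expect_true(all(tl0@levels == 0))
  # time-average proportional to taken count
  cal40 <- applyDrugHolidays(cal, 0.4, "2 months")
  tl40 <- exposureFromCalendar(cal40, reg, pk)
  expect_equal(mean(timelineAt(tl40, (0:349) * 24)),
               0.6 * mean(dayLevels), tolerance = 1e-9)
})

test_that("CMPL counts observations above threshold", {
  expect_equal(deriveCmpl(c(100, 2500, 2400)), 0)
  expect_equal(deriveCmpl(c(rep(1000, 8), 3000, 9000)), 0.2)
  expect_equal(deriveCmpl(rep(5000, 4)), 1)
  expect_error(deriveCmpl(numeric(0)), "observation")
})

test_that("compliance-adjusted exposure follows (1 - CMPL)", {
  expect_equal(complianceAdjustedExposure(4.35, 0), 4.35)
  expect_equal(complianceAdjustedExposure(4.35, 1), 0)
  expect_equal(complianceAdjustedExposure(4.3495, 0.21), 3.436,
               tolerance = 1e-3)
  expect_error(complianceAdjustedExposure(4.35, 1.5), "\\[0, 1\\]")
})
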