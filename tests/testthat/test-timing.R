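test_that("constructed synchronization schemes pass all checks", {
  sch <- build_timing(12, exposure = 25000, display = 10000, refresh = 1000)
  expect_equal(nrow(validate_timing(sch)), 0)
  expect_equal(sch$sequence_length, 12L)
  expect_equal(sum(sch$events$state == "display_normal"), 12)
  expect_equal(sum(sch$events$state == "display_inverted"), 12)
})

test_that("every pattern display is DC balanced with the LED blanked for the inverse", {
  sch <- build_timing(3, exposure = 25000, display = 10000, refresh = 1000)
  ev <- sch$events
  for (p in 0:2) {
    dn <- ev[ev$pattern == p & ev$state == "display_normal", ]
    di <- ev[ev$pattern == p & ev$state == "display_inverted", ]
    led <- ev[ev$pattern == p & ev$state == "on", ]
    expect_equal(dn$duration, di$duration)
    # LED strictly inside the normal display, clear of the inverse
    expect_gte(led$t_start, dn$t_start)
    expect_lte(led$t_start + led$duration, dn$t_start + dn$duration)
    expect_lte(led$t_start + led$duration, di$t_start)
  }
})

test_that("exposures too short for DC balancing are refused with the budget", {
  expect_error(build_timing(3, exposure = 15000, display = 10000,
                            refresh = 1000), "2\\*display \\+ refresh")
  expect_error(build_timing(3, exposure = 25000, display = 10000,
                            refresh = 1000, led_guard = 5000), "guard")
  expect_error(build_timing(3, exposure = 25000.5, display = 10000,
                            refresh = 1000), "integer")
})

test_that("tampered schedules are caught by validation", {
  sch <- build_timing(3, exposure = 25000, display = 10000, refresh = 1000)
  # push an LED pulse into the refresh / inverted-display interval
  bad <- sch
  i <- which(bad$events$state == "on")[1]
  bad$events$t_start[i] <- bad$events$t_start[i] + 5000
  v <- validate_timing(bad)
  expect_true("led_blanking" %in% v$type)
  expect_true("led_containment" %in% v$type)
  # break DC balance
  bad2 <- sch
  j <- which(bad2$events$state == "display_inverted")[1]
  bad2$events$duration[j] <- bad2$events$duration[j] - 100
  expect_true("dc_balance" %in% validate_timing(bad2)$type)
  # drop a pattern entirely
  bad3 <- sch
  bad3$events <- bad3$events[bad3$events$pattern != 1, ]
  expect_true("missing_pattern" %in% validate_timing(bad3)$type)
})

test_that("illumination duty reflects the DC-balancing photon cost", {
  sch <- build_timing(12, exposure = 25000, display = 10000, refresh = 1000,
                      led_guard = 1)
  expect_equal(illumination_duty(sch), (10000 - 2) / 25000)
  expect_lt(illumination_duty(sch), 0.5)   # at least half the light is lost
})

test_that("timing schemes export as a readable event table", {
  sch <- build_timing(2, exposure = 25000, display = 10000, refresh = 1000)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path), add = TRUE)
  write_timing(sch, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(sch$events))
  expect_equal(back$t_start, sch$events$t_start)
})
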