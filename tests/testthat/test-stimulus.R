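test_that("frame onsets reproduce the published timings", {
  # central line at 0, first ISI 30 ms, then 40 ms between pair onsets
  expect_equal(frame_onset(0), 0)
  expect_equal(frame_onset(c(1, 2, 3, 5, 7, 8, 11, 12, 14)),
               c(50, 90, 130, 210, 290, 330, 450, 490, 570))
  # consecutive-onset arithmetic: 40 ms gap, first ISI 30 ms
  n <- 2:30
  expect_equal(frame_onset(n) - frame_onset(n - 1), rep(40, length(n)))
  expect_equal(frame_onset(1) - 20, 30)
  expect_error(frame_onset(-1), "non-negative")
  expect_error(frame_onset(1.5), "integer")
})

test_that("sequences have the published total durations and layout", {
  s18 <- build_sequence(get_condition("V"))
  expect_equal(s18$duration_ms, 750)
  expect_equal(nrow(s18$elements), 1 + 2 * 18)
  s20 <- build_sequence(get_condition("C5 [R1]"))
  expect_equal(s20$duration_ms, 830)
  expect_equal(nrow(s20$elements), 1 + 2 * 20)

  # every element lasts 20 ms; eccentricity grows with |location| while diverging
  expect_true(all(s18$elements$duration_ms == 20))
  right <- s18$elements[s18$elements$location_id > 0, ]
  right <- right[order(right$location_id), ]
  expect_true(all(diff(right$eccentricity_arcmin) > 0))
  # 4 gaps between frames 8 and 12 span the printed 13.3', 8 gaps the
  # printed 26.7' (both printed to one decimal)
  ecc <- function(loc) right$eccentricity_arcmin[right$location_id == loc]
  expect_lt(abs(ecc(12) - ecc(8) - 13.3), 0.05)
  expect_lt(abs(ecc(8) - 26.7), 0.1)
})

test_that("offsets land only on the attended stream at the named frames", {
  spec <- get_condition("V-AV8-PV12 [R2]")
  sq <- build_sequence(spec, attended_stream = "right")
  el <- sq$elements
  expect_equal(el$offset_sign[el$location_id == 0], 1)
  expect_equal(el$offset_sign[el$location_id == 8], -1)
  expect_equal(el$offset_sign[el$location_id == 12], 1)
  expect_true(all(el$offset_sign[el$location_id < 0] == 0))
  expect_true(all(el$offset_sign[!el$location_id %in% c(0, 8, 12)] == 0))
})

test_that("swapping the attended stream mirrors locations but not timing", {
  spec <- get_condition("V-AV8 [R2]")
  r <- build_sequence(spec, attended_stream = "right")$elements
  l <- build_sequence(spec, attended_stream = "left")$elements
  key <- function(e) e[order(e$onset_ms, abs(e$location_id), e$location_id), ]
  r <- key(r); l <- key(l)
  expect_equal(l$onset_ms, r$onset_ms)
  expect_equal(sort(l$location_id), sort(-r$location_id))
  # the offset moves with the attended stream
  expect_equal(l$offset_sign[l$location_id == -8], -1)
  expect_true(all(l$offset_sign[l$location_id == 8] == 0))
})

test_that("element signals are the offset sign over the presentation interval", {
  sq <- build_sequence(get_condition("V-AV8 [R2]"))
  central <- element_signal(sq, 0)
  expect_equal(central, data.frame(t_on = 0, t_off = 20, value = 1))
  av8 <- element_signal(sq, 8)
  expect_equal(av8, data.frame(t_on = 330, t_off = 350, value = -1))
  aligned <- element_signal(sq, 3)
  expect_equal(aligned$value, 0)
  expect_error(element_signal(sq, 99), "no element")

  # signal conservation: total |signal| mass = 20 ms per offset element
  mass <- sum(vapply(unique(sq$elements$location_id), function(loc) {
    s <- element_signal(sq, loc)
    sum(abs(s$value) * (s$t_off - s$t_on))
  }, numeric(1)))
  expect_equal(mass, 20 * 2)
})

test_that("the condition library covers the published conditions and validates", {
  lib <- condition_library()
  expect_true(all(c("V", "AV", "V-AV7", "V-PV11 [R1]", "V-AV8 [R2]",
                    "V-AV12 [R2]", "V-AV8-PV12 [R1]", "V-AV8-PV12 [R2]",
                    "PV8-PV12 [R1]", "PV8-AV12 [R2]", "PV1-AV5 [R1]",
                    "C1 [R1]", "C5 [R2]") %in% names(lib)))
  expect_equal(lib[["V-AV8-PV12 [R1]"]]$offsets,
               c("0" = 1, "8" = -1, "12" = 1))
  expect_equal(lib[["V"]]$offsets, c("0" = 1))
  for (spec in lib) {
    frames <- as.integer(names(spec$offsets))
    expect_true(all(frames >= 0 & frames <= spec$n_pairs))
    expect_true(all(spec$offsets %in% c(-1, 0, 1)))
  }
})

test_that("invalid condition specifications are rejected", {
  expect_error(condition_spec("bad", c("30" = 1), n_pairs = 18), "beyond")
  expect_error(condition_spec("bad", c("0" = 2)), "-1, 0 or \\+1")
  expect_error(condition_spec("bad", c("-1" = 1)), "non-negative")
  expect_error(get_condition("NOPE"), "unknown condition")
})

test_that("a no-offset condition yields identically zero signals", {
  sq <- build_sequence(condition_spec("blank", c("0" = 0)))
  for (loc in unique(sq$elements$location_id))
    expect_true(all(element_signal(sq, loc)$value == 0))
})
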