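test_that("closed-form leaky integration matches the Euler oracle", {
  # single 20-ms pulse, the canonical memory-box input
  sig <- data.frame(t_on = 0, t_off = 20, value = 1)
  expect_equal(integrate_box(sig, tau = 0.3), 0.3 * (1 - exp(-0.02 / 0.3)))
  expect_lt(abs(integrate_box(sig, tau = 0.3) - euler_leaky(sig, 0.3)), 1e-6)

  # random non-overlapping piecewise-constant signals, several taus
  set.seed(41)
  for (rep in 1:4) {
    k <- sample(2:4, 1)
    durs <- sample(5:30, k, replace = TRUE)
    gaps <- sample(5:40, k, replace = TRUE)
    starts <- cumsum(gaps + c(0, durs[-k]))
    sig <- data.frame(t_on = starts, t_off = starts + durs,
                      value = sample(c(-1, 0, 1), k, replace = TRUE))
    tau <- runif(1, 0.1, 0.6)
    expect_lt(abs(integrate_box(sig, tau) - euler_leaky(sig, tau)), 1e-6)
  }
})

test_that("leaky integration limits behave like the ODE", {
  expect_equal(integrate_box(data.frame(t_on = 0, t_off = 50, value = 0), 0.3), 0)
  expect_equal(integrate_box(data.frame(t_on = numeric(0), t_off = numeric(0),
                                        value = numeric(0)), 0.3), 0)
  # saturation at the fixed point s * tau for long constant input
  sat <- integrate_box(data.frame(t_on = 0, t_off = 1e5, value = 1), 0.3)
  expect_equal(sat, 0.3, tolerance = 1e-9)
  expect_error(integrate_box(data.frame(t_on = 0, t_off = 20, value = 1), -1),
               "positive")
  expect_error(
    integrate_box(data.frame(t_on = c(0, 10), t_off = c(20, 30),
                             value = c(1, 1)), 0.3),
    "non-overlapping")
})

test_that("window assignment splits the published onsets correctly", {
  expect_equal(assign_window(330, 425), 1L) # frame 8 integrates with centre
  expect_equal(assign_window(490, 425), 2L) # frame 12 does not
  expect_equal(assign_window(0, 425), 1L)
  expect_equal(assign_window(450, 425), 2L) # frame 11 under a 425-ms window
  expect_equal(assign_window(450, 475), 1L) # ... but inside a 475-ms window
  expect_error(assign_window(-5, 425), ">= 0")
})

test_that("windows partition boxes with no crosstalk", {
  params <- model_params()
  sq <- build_sequence(get_condition("V-AV8-PV12 [R2]"))
  boxes <- memory_boxes(sq, params)
  # each box in exactly one window, consistent with its opening time
  expect_equal(boxes$window_index, assign_window(boxes$t_open, params$T_readout))
  expect_true(all(boxes$t_close == boxes$t_open + 20))
  # evidence in window 2 never leaks into window 1: compare against the
  # same condition with the window-2 offset removed
  sq1 <- build_sequence(get_condition("V-AV8 [R2]"))
  r_full <- window_readout(memory_boxes(sq1, params), 1, params)
  r_with12 <- window_readout(boxes, 1, params)
  expect_identical(r_with12$summed_evidence, r_full$summed_evidence)
})

test_that("within-window opposite offsets cancel exactly", {
  params <- model_params()
  ro <- stage1_readouts(build_sequence(get_condition("V-AV8 [R2]")), params)
  expect_identical(ro$summed_evidence[1], 0)
  # three-offset condition: cancellation in window 1, lone pro in window 2
  ro3 <- stage1_readouts(build_sequence(get_condition("V-AV8-PV12 [R2]")), params)
  expect_identical(ro3$summed_evidence[1], 0)
  expect_equal(ro3$summed_evidence[2], 1)
  # a single vernier reads out as exactly +/-1 under the default scale
  roV <- stage1_readouts(build_sequence(get_condition("V")), params)
  expect_equal(roV$summed_evidence, c(1, 0))
})

test_that("readout is linear and antisymmetric in the offset assignment", {
  params <- model_params()
  ro_of <- function(off) stage1_readouts(
    build_sequence(condition_spec("x", off, n_pairs = 18)), params)$summed_evidence
  a <- c("0" = 1, "3" = 1)
  b <- c("5" = 1, "12" = -1)
  # superposition: disjoint offset sets add
  expect_equal(ro_of(c(a, b)), ro_of(a) + ro_of(b))
  # sign antisymmetry
  expect_equal(ro_of(-c(a, b)), -ro_of(c(a, b)))
})

test_that("empty windows read out zero evidence", {
  params <- model_params()
  boxes <- memory_boxes(build_sequence(get_condition("V")), params)
  expect_equal(window_readout(boxes, 2, params)$summed_evidence, 0)
  expect_equal(window_readout(boxes, 7, params)$summed_evidence, 0)
})
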