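test_that("E* and S follow the ALEX ratio definitions", {
  expect_equal(compute_estar(100, 100), 0.5)
  expect_equal(compute_estar(70, 30), 0.3)
  expect_equal(compute_estar(0, 250), 1.0)
  expect_equal(compute_stoichiometry(50, 50, 100), 0.5)
  expect_equal(compute_stoichiometry(100, 50, 0), 1.0)
  expect_equal(compute_stoichiometry(0, 0, 200), 0.0)
  # zero denominators flagged, not dropped
  e <- compute_estar(c(0, 70), c(0, 30))
  expect_true(is.na(e[1]))
  expect_equal(attr(e, "undefined"), 1L)
  s <- compute_stoichiometry(0, 0, 0)
  expect_true(is.na(s[1]))
})

test_that("E* and S are invariant to intensity scaling", {
  set.seed(71)
  for (i in 1:20) {
    dd <- runif(50, 10, 1000); da <- runif(50, 10, 1000); aa <- runif(50, 10, 1000)
    c_scale <- runif(1, 0.01, 100)
    expect_equal(compute_estar(dd, da), compute_estar(c_scale * dd, c_scale * da),
                 tolerance = 1e-12)
    expect_equal(compute_stoichiometry(dd, da, aa),
                 compute_stoichiometry(c_scale * dd, c_scale * da, c_scale * aa),
                 tolerance = 1e-12)
  }
})

test_that("bleach step detector locates constructed steps", {
  set.seed(81)
  noise <- function(n) rnorm(n, 0, 10)
  one_step <- c(rep(1000, 200), rep(0, 270)) + noise(470)
  expect_equal(detect_bleach_steps(one_step, 5, 0.5), 200)
  expect_length(detect_bleach_steps(rep(1000, 470) + noise(470), 5, 0.5), 0)
  two_step <- c(rep(1000, 100), rep(450, 200), rep(0, 170)) + noise(470)
  expect_equal(detect_bleach_steps(two_step, 5, 0.5), c(100, 300))
  expect_error(detect_bleach_steps(one_step, 0, 0.5), "window")
  expect_error(detect_bleach_steps(one_step, 5, 1.2), "drop_ratio")
})

test_that("blink detector requires a dark interval with recovery", {
  set.seed(82)
  noise <- function(n) rnorm(n, 0, 10)
  blink <- c(rep(1000, 100), rep(0, 20), rep(1000, 100)) + noise(220)
  expect_true(detect_blinking(blink, 5, 0.5))
  bleach <- c(rep(1000, 100), rep(0, 120)) + noise(220)
  expect_false(detect_blinking(bleach, 5, 0.5))
  expect_false(detect_blinking(rep(1000, 220) + noise(220), 5, 0.5))
})

test_that("detectors achieve full recall and precision on annotated fixtures", {
  # step amplitudes are >= 5x the intensity noise SD by construction
  fx_b <- make_fixtures("bleach", seed = 5)
  steps <- detect_bleach_steps(fx_b$traces[[1]]$I_AA)
  expect_equal(steps, fx_b$truth$acceptor_step)
  fx_m <- make_fixtures("multi_bleach", seed = 5)
  dd_sig <- fx_m$traces[[1]]$I_DD + fx_m$traces[[1]]$I_DA
  expect_equal(detect_bleach_steps(dd_sig), fx_m$truth$donor_steps)
  fx_s <- make_fixtures("static", seed = 5)
  expect_length(detect_bleach_steps(fx_s$traces[[1]]$I_AA), 0)
  expect_false(detect_blinking(fx_s$traces[[1]]$I_DD + fx_s$traces[[1]]$I_DA))
  fx_bl <- make_fixtures("blink", seed = 5)
  expect_true(detect_blinking(fx_bl$traces[[1]]$I_DD + fx_bl$traces[[1]]$I_DA))
})

test_that("species classification applies the stoichiometry gates", {
  expect_equal(classify_species(0.3, 0.55, c(0.3, 0.8)), "D-A")
  expect_equal(classify_species(0.3, 0.95, c(0.3, 0.8)), "D-only")
  expect_equal(classify_species(0.3, 0.05, c(0.3, 0.8)), "A-only")
  expect_equal(classify_species(0.3, 0.3, c(0.3, 0.8)), "D-A")  # inclusive bounds
  expect_error(classify_species(0.3, 0.5, c(0.8, 0.3)), "s_bounds")
})

test_that("truncation keeps only frames preceding the bleach", {
  tr <- intensity_trace("x", rep(700, 470), rep(300, 470), rep(500, 470), 0.02)
  expect_length(truncate_at_bleach(tr, 200)$estar, 200)
  expect_length(truncate_at_bleach(tr, NULL)$estar, 470)
  expect_length(truncate_at_bleach(tr, 1)$estar, 1)
  expect_error(truncate_at_bleach(tr, 0), "at least one frame")
})

test_that("trace selection applies the exclusion rules and is deterministic", {
  fx <- list(
    make_fixtures("early_bleach", seed = 9)$traces[[1]],
    make_fixtures("bleach", seed = 9)$traces[[1]],
    make_fixtures("static", seed = 9)$traces[[1]],
    make_fixtures("multi_bleach", seed = 9)$traces[[1]],
    make_fixtures("blink", seed = 9)$traces[[1]]
  )
  sel <- select_traces(fx)
  rep1 <- sel$report
  expect_equal(nrow(rep1), 5)                       # one verdict per input
  expect_equal(sum(rep1$kept) + sum(!rep1$kept), 5)
  expect_equal(rep1$reason[rep1$trace_id == "early1"], "early-bleach")
  expect_equal(rep1$reason[rep1$trace_id == "multi1"], "multi-step-bleach")
  expect_equal(rep1$reason[rep1$trace_id == "blink1"], "blink")
  # single late acceptor bleach: kept, truncated at the step
  expect_true(rep1$kept[rep1$trace_id == "bleach1"])
  expect_equal(rep1$truncate_frame[rep1$trace_id == "bleach1"], 400)
  kept_ids <- vapply(sel$traces, function(t) t$trace_id, character(1))
  expect_equal(length(sel$traces[[which(kept_ids == "bleach1")]]$estar), 400)
  # clean trace kept untruncated
  expect_true(rep1$kept[rep1$trace_id == "static1"])
  expect_equal(rep1$truncate_frame[rep1$trace_id == "static1"], 470)
  # determinism
  expect_identical(select_traces(fx)$report, rep1)
})

test_that("donor-only species are rejected by the S gate", {
  # no acceptor signal at all: S near 1
  donly <- intensity_trace("donly", rnorm(470, 1000, 20), rnorm(470, 30, 20),
                           rnorm(470, 10, 20), 0.02)
  sel <- select_traces(list(donly))
  expect_equal(sel$report$reason, "not-DA-species")
})
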