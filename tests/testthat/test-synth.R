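test_that("schedule satisfies its structural invariants across configurations", {
  for (cfg in list(list(seed = 1, p = 0.05, n = 200),
                   list(seed = 2, p = 0.2, n = 120),
                   list(seed = 3, p = 0, n = 80))) {
    sch <- generate_schedule(omission_prob = cfg$p, n_trials = cfg$n, seed = cfg$seed)
    expect_equal(diff(sch$onset_s), rep(0.75, nrow(sch) - 1), tolerance = 1e-12)
    # every omitted slot flanked by presented slots with the same image
    om <- which(sch$omitted)
    expect_true(all(om > 1 & om < nrow(sch)))
    expect_true(all(!sch$omitted[om - 1] & !sch$omitted[om + 1]))
    expect_true(all(sch$image_id[om - 1] == sch$image_id[om] &
                      sch$image_id[om + 1] == sch$image_id[om]))
    # one image per trial, consecutive trials differ
    per_trial <- tapply(sch$image_id, sch$trial_index, unique)
    expect_true(all(lengths(per_trial) == 1))
    expect_true(all(diff(unlist(per_trial)) != 0))
    # trial lengths within the truncated support
    expect_true(all(table(sch$trial_index) >= 5 & table(sch$trial_index) <= 11))
    if (cfg$p == 0) expect_equal(sum(sch$omitted), 0)
  }
})

test_that("schedules are deterministic in the seed and reject bad configs", {
  a <- generate_schedule(n_trials = 60, seed = 7)
  b <- generate_schedule(n_trials = 60, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_schedule(n_trials = 60, seed = 8)))
  expect_error(generate_schedule(omission_prob = 1), "omission_prob")
  expect_error(generate_schedule(repeats_min = 9, repeats_max = 7), "repeats_min")
})

test_that("trial lengths follow the truncated geometric distribution", {
  sch <- generate_schedule(n_trials = 10000, seed = 5)
  lens <- as.integer(table(sch$trial_index))
  support <- 5:11
  pmf <- 0.3 * 0.7^(support - 5)
  pmf <- pmf / sum(pmf)
  obs <- tabulate(lens, nbins = 11)[support]
  gof <- suppressWarnings(stats::chisq.test(obs, p = pmf))
  expect_gt(gof$p.value, 0.001)
})

test_that("unmodulated units are Poisson: count matches rate and Fano is near 1", {
  sch <- generate_schedule(n_trials = 200, seed = 9)
  mx <- mix_of("unmodulated", 4)
  mx$baseline_rate <- 5
  us <- generate_units(sch, mix = mx, rate_jitter_sd = 0, seed = 10)
  t_end <- max(sch$onset_s) + 0.75
  for (sp in us$spikes) {
    n <- length(sp)
    expect_lt(abs(n - 5 * t_end), 4 * sqrt(5 * t_end))
    expect_true(!is.unsorted(sp) && all(sp >= 0))
    # Fano factor of per-cycle counts
    cyc <- count_in_windows(sp, sch$onset_s, 0.75)
    fano <- stats::var(cyc) / mean(cyc)
    expect_lt(abs(fano - 1), 4 * sqrt(2 / length(cyc)))
  }
})

test_that("a template with zero rate yields zero spikes", {
  sch <- generate_schedule(n_trials = 30, seed = 1)
  mx <- mix_of("unmodulated", 2)
  mx$baseline_rate <- 0
  mx$amplitude <- 0
  us <- generate_units(sch, mix = mx, rate_jitter_sd = 0, seed = 2)
  expect_true(all(lengths(us$spikes) == 0))
})

test_that("ramp-to-onset units peak in the bin containing the stimulus onset", {
  sch <- generate_schedule(n_trials = 250, seed = 12, omission_prob = 0)
  us <- generate_units(sch, mix = mix_of("ramp_off", 6), seed = 13)
  onsets <- sch$onset_s[-1]
  merged <- sort(unlist(us$spikes))
  p <- compute_psth(merged, onsets, window = c(-0.25, 0.25), bin_s = 0.05)
  # template maximum sits immediately before/at stimulus onset
  peak_time <- p$time[which.max(p$rate)]
  expect_lt(abs(peak_time), 0.08)
})

test_that("STIM-OFF archetypes carry no image tuning while STIM-ON do", {
  sch <- generate_schedule(n_trials = 400, seed = 21)
  mx <- rbind(mix_of("sustained_on", 8), mix_of("step_off_on", 8))
  us <- generate_units(sch, mix = mx, tuning_gain_sd = 0.6, seed = 22)
  stim <- sch[!sch$omitted, ]
  img_var <- vapply(us$spikes, function(sp) {
    ev <- count_in_windows(sp, stim$onset_s, 0.25) / 0.25
    means <- tapply(ev, stim$image_id, mean)
    stats::var(means) / mean(ev)^2
  }, 0)
  on_var <- img_var[us$archetype == "sustained_on"]
  off_var <- img_var[us$archetype == "step_off_on"]
  expect_gt(median(on_var), 3 * median(off_var))
})

test_that("behaviour traces show a lagged omission slowdown and unit-median pupil", {
  sch <- generate_schedule(n_trials = 250, seed = 31)
  tr <- generate_behavior(sch, seed = 32)
  expect_equal(median(tr$pupil_diameter), 1)
  expect_equal(diff(range(diff(tr$time_s))), 0, tolerance = 1e-9)
  eta <- event_triggered_average(tr, event_onsets(sch), window = c(-0.5, 2))
  tmin <- eta$lag_s[which.min(eta$value)]
  # speed minimum after the post-omission image onset (one cycle = 0.75 s)
  expect_gt(tmin, 0.75)
  # depth 0 leaves the omission-triggered average flat within noise
  tr0 <- generate_behavior(sch, slowdown_depth = 0, seed = 33)
  eta0 <- event_triggered_average(tr0, event_onsets(sch), window = c(-0.5, 2))
  expect_lt(diff(range(eta0$value)), 3)
})
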