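test_that("PSTH recovers a homogeneous rate within Poisson error", {
  t_end <- 2000
  sp <- poisson_train(5, t_end, seed = 1)
  ev <- seq(10, t_end - 10, length.out = 1000)
  p <- compute_psth(sp, ev)
  se <- sqrt(5 / (0.01 * length(ev)))
  expect_true(all(abs(p$rate - 5) < 4 * se))
  expect_equal(mean(p$zrate), 0, tolerance = 1e-10)
  expect_equal(sd(p$zrate), 1, tolerance = 1e-10)
})

test_that("PSTH handles delta trains, empty trains and zero events", {
  ev <- seq(5, 50, by = 5)
  p <- compute_psth(ev, ev, window = c(-0.1, 0.1), bin_s = 0.01)
  expect_equal(p$rate[p$time > 0 & p$time < 0.01], 100)
  expect_equal(sum(p$rate), 100)
  p0 <- compute_psth(numeric(0), ev)
  expect_true(all(p0$rate == 0))
  expect_true(attr(p0, "zero_variance"))
  expect_error(compute_psth(1:10, numeric(0)), "non-empty")
})

test_that("PSTH is linear: merged trains give summed rates exactly", {
  sp1 <- poisson_train(4, 300, seed = 2)
  sp2 <- poisson_train(7, 300, seed = 3)
  ev <- seq(5, 295, by = 1.5)
  pm <- compute_psth(sort(c(sp1, sp2)), ev)
  expect_equal(pm$rate, compute_psth(sp1, ev)$rate + compute_psth(sp2, ev)$rate,
               tolerance = 1e-12)
})

test_that("hippocampal step units score up, sustained units score down", {
  sus_mix <- mix_of("sustained_on", 10)
  sus_mix$baseline_rate <- 8
  sus_mix$amplitude <- 20   # strong responder: clear persistence tail in the gray
  sess <- make_session(seed = 41, n_trials = 700,
                       mix = rbind(mix_of("hippocampal_step", 10), sus_mix))
  mod <- omission_modulation(sess$units, sess$schedule)
  arch <- sess$units$archetype[match(mod$unit_id, sess$units$unit_id)]
  hpc <- mod$sign_class[arch == "hippocampal_step"]
  sus <- mod$sign_class[arch == "sustained_on"]
  expect_gte(mean(hpc == "up"), 0.9)
  expect_true(all(mod$delta_z[arch == "hippocampal_step"] > 0))
  expect_gte(mean(sus == "down"), 0.5)
  expect_true(all(sus != "up"))
  # step responders ramp within the omission window in the z-scored sense
  expect_true(all(is.finite(mod$RI[arch == "hippocampal_step"]) |
                    mod$flag[arch == "hippocampal_step"] == "ri_undefined"))
})

test_that("ramping index follows its closed form and flags non-positive args", {
  tm <- seq(0.005, 0.245, by = 0.01)
  ramp <- function(r_early, r_late) {
    c(rep(r_early, 10), seq(r_early, r_late, length.out = 5), rep(r_late, 10))
  }
  expect_equal(ramping_index(ramp(1, 3), tm)$RI, 1)
  expect_equal(ramping_index(ramp(0.5, 1.5), tm)$RI, 0)
  flat <- ramping_index(rep(2, 25), tm)
  expect_true(is.nan(flat$RI))
  expect_identical(flat$flag, "ri_undefined")
  expect_error(ramping_index(rep(1, 5), seq(0, 0.05, length.out = 5)), "200 ms")
})

test_that("stimulus and omission modulation are inversely related across units", {
  sess <- make_session(seed = 51, n_trials = 250)
  mod <- omission_modulation(sess$units, sess$schedule)
  stim_on <- event_onsets(sess$schedule, omitted = FALSE)
  stim_z <- vapply(sess$units$spikes, function(sp) {
    p <- compute_psth(sp, stim_on)
    mean(p$zrate[p$time >= 0 & p$time < 0.25])
  }, 0)
  expect_lt(cor(stim_z, mod$delta_z), -0.3)
})

test_that("omission specificity is null for image-agnostic omission branches", {
  sch <- generate_schedule(n_trials = 400, seed = 61)
  stim <- sch[!sch$omitted, ]
  om <- sch[sch$omitted, ]
  # planted tuned units: strong response to image 0, image-independent omission
  make_tuned <- function(seed, om_pref_rate = 12) {
    withr::with_seed(seed, {
      rate_stim <- ifelse(stim$image_id == 0, 35, 5)
      sp1 <- unlist(lapply(seq_len(nrow(stim)), function(i) {
        stim$onset_s[i] + sort(runif(rpois(1, rate_stim[i] * 0.25), 0, 0.25))
      }))
      rate_om <- ifelse(om$image_id == 0, om_pref_rate, 12)
      sp2 <- unlist(lapply(seq_len(nrow(om)), function(i) {
        om$onset_s[i] + sort(runif(rpois(1, rate_om[i] * 0.25), 0, 0.25))
      }))
      sort(c(sp1, sp2))
    })
  }
  units <- dplyr::bind_rows(lapply(1:40, function(i) {
    unit_row(make_tuned(1000 + i), unit_id = sprintf("t%02d", i))
  }))
  spec <- omission_specificity(units, sch)
  expect_gte(mean(spec$tuned), 0.9)
  tuned <- spec[spec$tuned & !is.na(spec$significant), ]
  expect_lte(mean(tuned$significant), 0.2)  # near the nominal type-I level

  # a unit whose omission rate doubles only for its preferred image
  inj <- unit_row(make_tuned(999, om_pref_rate = 30))
  res <- omission_specificity(inj, sch)
  expect_true(res$tuned)
  expect_identical(res$preferred_image, 0L)
  expect_true(res$significant)
})

test_that("specificity is flagged undefined with too few preferred omissions", {
  sch <- generate_schedule(n_trials = 12, seed = 64)
  units <- generate_units(sch, mix = mix_of("sustained_on", 1),
                          tuning_gain_sd = 2, seed = 65)
  res <- omission_specificity(units, sch)
  expect_true(res$flag %in% c("not_tuned", "too_few_omissions"))
})
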