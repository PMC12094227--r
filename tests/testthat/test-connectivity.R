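test_that("cross-correlograms count pairs by lag with exact identities", {
  pre <- seq(1, 60, by = 0.5)
  cc <- compute_ccg(pre, pre + 0.0016, bin_s = 0.0004, window_s = 0.01)
  expect_equal(cc$count[abs(cc$lag_s - 0.0016) < 1e-9], length(pre))
  expect_equal(sum(cc$count), length(pre))
  # mirror identity
  a <- poisson_train(10, 120, seed = 1)
  b <- poisson_train(12, 120, seed = 2)
  ab <- compute_ccg(a, b)
  ba <- compute_ccg(b, a)
  expect_equal(ab$count, rev(ba$count))
  expect_error(compute_ccg(numeric(0), b), "non-empty")
})

test_that("independent Poisson trains give the closed-form expected CCG level", {
  r1 <- 8; r2 <- 10; t_end <- 400
  a <- poisson_train(r1, t_end, seed = 3)
  b <- poisson_train(r2, t_end, seed = 4)
  cc <- compute_ccg(a, b, bin_s = 0.0004, window_s = 0.02)
  expected <- r1 * r2 * t_end * 0.0004
  expect_lt(abs(mean(cc$count) - expected), 4 * sqrt(expected / nrow(cc)))
})

test_that("interval jitter preserves per-interval spike counts exactly", {
  sp <- poisson_train(20, 50, seed = 5)
  js <- withr::with_seed(6, jitter_spikes(sp, interval_s = 0.005))
  expect_equal(length(js), length(sp))
  expect_equal(floor(sort(sp) / 0.005), floor(js / 0.005))
})

plant_synapse <- function(seed, rate_pre = 5, rate_post = 5, t_end = 600,
                          p_trans = 0.1, lag = 0.0015, jit = 2e-4) {
  withr::with_seed(seed, {
    pre <- sort(runif(rpois(1, rate_pre * t_end), 0, t_end))
    n_ev <- rbinom(1, length(pre), p_trans)
    evoked <- sample(pre, n_ev) + lag + runif(n_ev, -jit, jit)
    post <- sort(c(runif(rpois(1, rate_post * t_end), 0, t_end), evoked))
    list(pre = pre, post = post)
  })
}

test_that("planted excitatory synapses are detected at the right lag", {
  hits <- vapply(1:10, function(i) {
    tr <- plant_synapse(100 + i)
    d <- detect_monosynaptic(tr$pre, tr$post, n_surrogates = 120, seed = i)
    d$sign == "excitatory" && abs(d$peak_lag_ms - 1.5) < 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  tr <- plant_synapse(200)
  d <- detect_monosynaptic(tr$pre, tr$post, n_surrogates = 120, seed = 1)
  expect_gt(d$strength, 0.05)  # ~0.1 excess spikes per presynaptic spike
})

test_that("planted inhibitory coupling is detected as a trough", {
  hits <- vapply(1:6, function(i) {
    tr <- withr::with_seed(300 + i, {
      pre <- sort(runif(rpois(1, 8 * 600), 0, 600))
      post <- sort(runif(rpois(1, 25 * 600), 0, 600))
      # suppress post spikes within 0.8-3.8 ms after each pre spike
      idx <- findInterval(post, pre)
      rel <- ifelse(idx > 0, post - pre[pmax(idx, 1)], Inf)
      drop <- rel > 8e-4 & rel < 3.8e-3 & runif(length(post)) < 0.85
      list(pre = pre, post = post[!drop])
    })
    d <- detect_monosynaptic(tr$pre, tr$post, n_surrogates = 120, seed = i)
    d$sign == "inhibitory"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("detection is calibrated on independent trains and symmetric in jitter target", {
  n_pairs <- 60
  res <- vapply(1:n_pairs, function(i) {
    a <- poisson_train(6, 300, seed = 400 + i)
    b <- poisson_train(6, 300, seed = 800 + i)
    detect_monosynaptic(a, b, n_surrogates = 100, seed = i)$sign != "none"
  }, logical(1))
  # family alpha = 0.05: false-positive count within binomial range
  expect_lte(sum(res), qbinom(0.995, n_pairs, 0.05) + 1)
})

test_that("graph summaries conserve edge totals and recover planted topology", {
  # planted topology: within-cluster edges only
  units <- dplyr::bind_rows(lapply(1:6, function(i) {
    tr <- plant_synapse(500 + i, t_end = 400, p_trans = 0.15)
    dplyr::bind_rows(
      unit_row(tr$pre, sprintf("pre%d", i), area = sprintf("A%d", (i - 1) %/% 3)),
      unit_row(tr$post, sprintf("post%d", i), area = sprintf("A%d", (i - 1) %/% 3))
    )
  }))
  graph <- infer_connectivity(units, within_area = FALSE, seed = 1,
                              n_surrogates = 100)
  asg <- tibble::tibble(
    unit_id = units$unit_id,
    cluster = rep(1:6, each = 2),
    semantic_label = NA_character_, class = NA_character_
  )
  model <- structure(list(assignments = asg, k = 6L), class = "omi_clusters")
  s <- connectivity_summary(graph, model)
  expect_equal(sum(s$fractions$mean_divergence * 2),
               sum(s$fractions$mean_convergence * 2))
  exc <- s$probability$excitatory
  expect_gt(mean(diag(exc), na.rm = TRUE), mean(exc[row(exc) != col(exc)], na.rm = TRUE))
  # every planted pre->post synapse is recovered as an excitatory edge
  found <- vapply(1:6, function(i) {
    any(graph$edges$pre == sprintf("pre%d", i) &
          graph$edges$post == sprintf("post%d", i) &
          graph$edges$sign == "excitatory")
  }, logical(1))
  expect_gte(mean(found), 5 / 6)
})
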