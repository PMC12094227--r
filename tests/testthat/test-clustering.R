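# Adjusted Rand index (independent check of partition agreement).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  s_ij <- sum_comb(tab); s_a <- sum_comb(rowSums(tab)); s_b <- sum_comb(colSums(tab))
  expected <- s_a * s_b / choose(n, 2)
  (s_ij - expected) / ((s_a + s_b) / 2 - expected)
}

sess_cl <- make_session(seed = 71, n_trials = 250,
                        mix = default_unit_mix(n_per = 20, n_hpc = 0))
vis_cl <- sess_cl$units[sess_cl$units$area == "VISp", ]
rm_cl <- build_response_matrix(vis_cl, sess_cl$schedule)

test_that("response correlations are 1 for clones, -1 for sign flips, block-structured", {
  u <- vis_cl[1:2, ]
  u$spikes[[2]] <- u$spikes[[1]]
  rm2 <- build_response_matrix(u, sess_cl$schedule)
  expect_equal(rm2$corr[1, 2], 1, tolerance = 1e-12)
  expect_equal(cor(rm_cl$features[1, ], -rm_cl$features[1, ]), -1)
  # within-archetype correlations exceed between-archetype ones
  arch <- vis_cl$archetype[match(rm_cl$unit_id, vis_cl$unit_id)]
  same <- outer(arch, arch, "==")
  diag(same) <- NA
  expect_gt(mean(rm_cl$corr[which(same)]), mean(rm_cl$corr[which(!same)]) + 0.3)
})

test_that("dispersion decreases in k and selection is deterministic", {
  ks <- choose_k(rm_cl, k_grid = 2:8, seed = 3)
  expect_true(all(diff(ks$table$W_k) <= 1e-9))
  ks2 <- choose_k(rm_cl, k_grid = 2:8, seed = 3)
  expect_identical(ks$table, ks2$table)
  expect_identical(glance(ks), glance(ks2))
  expect_true(ks$k_opt %in% 2:8)
})

test_that("clustering recovers archetypes and is stable across seeds", {
  cl <- cluster_units(rm_cl, k = 5, seed = 4)
  arch <- vis_cl$archetype[match(cl$assignments$unit_id, vis_cl$unit_id)]
  expect_gte(mean(arch == cl$assignments$semantic_label), 0.95)
  expect_identical(sort(unique(cl$assignments$class)), c("STIM_OFF", "STIM_ON"))
  off <- cl$assignments$class[arch %in% c("step_off_on", "ramp_off")]
  expect_gte(mean(off == "STIM_OFF"), 0.9)
  cl2 <- cluster_units(rm_cl, k = 5, seed = 5)
  expect_gt(ari(cl$assignments$cluster, cl2$assignments$cluster), 0.9)
})

test_that("partitions survive duplication of every unit", {
  dup <- dplyr::bind_rows(vis_cl, dplyr::mutate(vis_cl, unit_id = paste0(unit_id, "_b")))
  rmd <- build_response_matrix(dup, sess_cl$schedule)
  cld <- cluster_units(rmd, k = 5, seed = 6)
  a <- cld$assignments$cluster[match(vis_cl$unit_id, cld$assignments$unit_id)]
  b <- cld$assignments$cluster[match(paste0(vis_cl$unit_id, "_b"), cld$assignments$unit_id)]
  expect_gte(mean(a == b), 0.95)
})

test_that("STIM-OFF generated units fire more during stimulus-free epochs", {
  # generator-consistency: OFF archetypes are built with higher baselines
  base <- tapply(vis_cl$baseline_rate, vis_cl$archetype, median)
  expect_gt(min(base[c("step_off_on", "ramp_off")]),
            max(base[c("transient_on", "sustained_on", "ramp_to_offset")]))
})

test_that("cluster composition fractions are normalised per stratum", {
  cl <- cluster_units(rm_cl, k = 5, seed = 4)
  comp <- cluster_composition(cl, vis_cl, by = "layer")
  sums <- comp |>
    dplyr::group_by(layer) |>
    dplyr::summarise(s = sum(fraction))
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-12)
  # 50/50 planted mix
  half <- make_session(seed = 81, n_trials = 150,
                       mix = rbind(mix_of("transient_on", 15), mix_of("ramp_off", 15)))
  rmh <- build_response_matrix(half$units, half$schedule)
  clh <- cluster_units(rmh, k = 2, seed = 7,
                       label_archetypes = c("transient_on", "ramp_off"))
  comph <- cluster_composition(clh, half$units, by = "area")
  expect_equal(sort(comph$fraction), c(0.5, 0.5), tolerance = 0.15)
})

test_that("elapsed time in the omission is decodable from ramping clusters only", {
  sess <- make_session(seed = 91, n_trials = 400,
                       mix = rbind(mix_of("ramp_off", 12), mix_of("sustained_on", 12)))
  rmx <- build_response_matrix(sess$units, sess$schedule)
  cl <- cluster_units(rmx, k = 2, seed = 8,
                      label_archetypes = c("ramp_off", "sustained_on"))
  dec <- decode_time_bin(sess$units, sess$schedule, cl)
  mae <- tapply(dec$mae, dec$semantic_label, mean)
  expect_lt(mae[["ramp_off"]], mae[["sustained_on"]])

  # noiseless linear readout: counts equal to the bin index decode exactly
  om <- event_onsets(sess$schedule)
  lin_spikes <- sort(unlist(lapply(om, function(o) {
    unlist(lapply(1:5, function(b) o + (b - 1) * 0.05 + seq_len(b) * 0.004))
  })))
  ulin <- unit_row(lin_spikes)
  rml <- list(unit_id = "u1")
  mdl <- structure(list(assignments = tibble::tibble(
    unit_id = "u1", cluster = 1L, semantic_label = "ramp_off", class = "STIM_OFF"
  ), k = 1L), class = "omi_clusters")
  dl <- decode_time_bin(ulin, sess$schedule, mdl)
  expect_lt(mean(dl$mae), 0.05)
})

test_that("label-shuffled activity decodes elapsed time at chance", {
  mx <- mix_of("ramp_off", 30)
  mx$amplitude <- 32
  sess <- make_session(seed = 95, n_trials = 300, mix = mx)
  rmx <- build_response_matrix(sess$units, sess$schedule)
  cl <- cluster_units(rmx, k = 2, seed = 9,
                      label_archetypes = c("ramp_off", "sustained_on"))
  dec <- decode_time_bin(sess$units, sess$schedule, cl)
  perm <- decode_time_bin(sess$units, sess$schedule, cl, permute_labels = TRUE,
                          seed = 11)
  # uniform guessing over 5 bins has MAE 1.2 around the mean bin
  expect_lt(abs(mean(perm$mae) - 1.2), 0.15)
  expect_lt(mean(dec$mae), mean(perm$mae) - 0.1)
})
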