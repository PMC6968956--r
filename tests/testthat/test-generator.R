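# Synthetic SEP study generator: determinism, effect calibration and
# confinement, artifact attrition.

test_that("a default study has the configured number of participants and trials", {
  cfg <- small_gen_config(seed = 5)
  study <- simulate_study(cfg)
  expect_length(study, 4)
  expect_identical(names(study), sprintf("P%02d", 1:4))
  for (es in study) {
    expect_equal(dim(es$data)[1], 12)
    expect_equal(sum(es$condition == "Hand"), 6)
    expect_equal(sum(es$condition == "Surface"), 6)
    expect_true(all(table(es$hand, es$condition) == 3))  # balanced hands
  }
  full <- sep_gen_config(seed = 1)
  expect_equal(full$n_participants, 15L)
})

test_that("regeneration with an identical seed is bit-exact; participants differ", {
  cfg <- small_gen_config(seed = 17)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
  expect_false(identical(s1$P01$data, s1$P02$data))
  # determinism keyed on participant id, not list position
  solo <- simulate_epochs(cfg, "P02")
  expect_identical(solo$data, s1$P02$data)
})

test_that("zero effect and zero noise yield the bare template and a null contrast", {
  cfg <- small_gen_config(noise_sd = 0, attrition_rate = 0,
                          effect_contra = NULL, effect_ipsi = NULL,
                          seed = 2)
  es <- simulate_epochs(cfg, "P01")
  tmpl <- vicarsep:::gen_template(cfg) * cfg$peak_amplitude_uv
  on_analysis <- es$channels %in% six_channels()
  for (t in c(1, 5, 12)) {
    for (c in which(on_analysis)) {
      expect_equal(es$data[t, c, ], tmpl)
    }
    for (c in which(!on_analysis)) {
      expect_equal(es$data[t, c, ], rep(0, length(tmpl)))
    }
  }
  pp <- preprocess_epochs(es)
  hand <- average_sep(pp, "Hand", "Contralateral")
  surf <- average_sep(pp, "Surface", "Contralateral")
  expect_equal(hand$values, surf$values, tolerance = 1e-12)
})

test_that("noise-free condition means reproduce the configured targets after preprocessing", {
  cfg <- sep_gen_config(n_participants = 2, noise_sd = 0,
                        attrition_rate = 0, effect_sd_ratio = 0, seed = 1)
  pp <- preprocess_epochs(simulate_epochs(cfg, "P01"))
  targets <- list(
    list("Hand", "Contralateral", cfg$effect_contra$window, 3.06),
    list("Surface", "Contralateral", cfg$effect_contra$window, 5.80),
    list("Hand", "Ipsilateral", cfg$effect_ipsi$window, 0.94),
    list("Surface", "Ipsilateral", cfg$effect_ipsi$window, -1.07))
  for (tg in targets) {
    w <- average_sep(pp, tg[[1]], tg[[2]])
    expect_equal(window_mean_amplitude(w, tg[[3]]), tg[[4]],
                 tolerance = 1e-9)
  }
  # grand SEP peak sits near the configured latency
  peak_t <- w$time_ms[which.max(average_sep(pp, "Surface",
                                            "Contralateral")$values)]
  expect_gt(peak_t, 110)
  expect_lt(peak_t, 150)
})

test_that("injected effects are confined to their windows in the raw trials", {
  cfg <- sep_gen_config(n_participants = 2, noise_sd = 0,
                        attrition_rate = 0, effect_sd_ratio = 0, seed = 1)
  es <- simulate_epochs(cfg, "P01")
  iL_hand <- which(es$hand == "Left" & es$condition == "Hand")[1]
  iL_surf <- which(es$hand == "Left" & es$condition == "Surface")[1]
  dif <- es$data[iL_hand, , ] - es$data[iL_surf, , ]
  in_c <- es$time_ms >= 92 & es$time_ms <= 184
  in_i <- es$time_ms >= 66 & es$time_ms <= 166
  contra_ch <- es$channels %in% analysis_electrodes()$right
  ipsi_ch <- es$channels %in% analysis_electrodes()$left
  expect_true(all(dif[contra_ch, !in_c] == 0))
  expect_true(all(dif[ipsi_ch, !in_i] == 0))
  expect_true(all(dif[!contra_ch & !ipsi_ch, ] == 0))
  expect_true(all(abs(dif[contra_ch, in_c]) > 0))
})

test_that("artifact attrition leaves about 18 retained trials per condition", {
  cfg <- sep_gen_config(seed = 23)
  study <- simulate_study(cfg)
  retained <- sapply(study, function(es)
    attr(reject_artifacts(lowpass_filter(es)), "retained"))
  expect_gt(mean(retained), 16)
  expect_lt(mean(retained), 20)
  # ground-truth contaminated trials are the ones flagged
  es <- lowpass_filter(study[[1]])
  flagged <- reject_artifacts(es)$is_artifact
  expect_identical(flagged, attr(study[[1]], "contaminated"))
})

test_that("the contralateral difference recovers the group effect within Monte Carlo error", {
  cfg <- sep_gen_config(seed = 31)
  dm <- sep_diff_matrices(simulate_study(cfg))
  # truth: Hand - Surface = 3.06 - 5.80 = -2.74 uV over 92-184 ms
  expect_lt(abs(window_mean_amplitude(dm$contra, c(92, 184)) - (-2.74)),
            1.2)
  expect_lt(abs(window_mean_amplitude(dm$ipsi, c(66, 166)) - 2.01), 1.2)
})

test_that("invalid generator parameters are rejected", {
  expect_error(sep_gen_config(rho = 1), class = "vicarsep_invalid_parameter")
  expect_error(sep_gen_config(epoch_window = c(100, 700)),
               class = "vicarsep_invalid_parameter")
  expect_error(sep_gen_config(n_participants = 1),
               class = "vicarsep_invalid_parameter")
  expect_error(sep_gen_config(effect_contra = list(hand_mean = 1,
                                                   surface_mean = 2,
                                                   window = c(600, 800))),
               class = "vicarsep_invalid_parameter")
  expect_error(sep_gen_config(effect_contra = NULL),
               class = "vicarsep_invalid_parameter")
})
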