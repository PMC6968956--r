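# Preprocessing chain: defining identities, idempotence, cluster selection
# and laterality pooling.

test_that("baseline correction zeroes the baseline window and is idempotent", {
  es <- make_noise_epochset(4, sd = 3)
  bc <- baseline_correct(es)
  idx <- which(bc$time_ms >= -100 & bc$time_ms <= 0)
  bl <- rowMeans(bc$data[, , idx, drop = FALSE], dims = 2)
  expect_lt(max(abs(bl)), 1e-9)
  expect_equal(baseline_correct(bc)$data, bc$data, tolerance = 1e-12)
})

test_that("baseline correction removes any constant trial offset", {
  es <- make_noise_epochset(5)
  shifted <- es
  shifted$data[2, , ] <- shifted$data[2, , ] + 7
  expect_equal(baseline_correct(shifted)$data, baseline_correct(es)$data,
               tolerance = 1e-12)
  bad <- preproc_config(baseline_window = c(-500, 0))
  expect_error(baseline_correct(es, bad),
               class = "vicarsep_invalid_parameter")
})

test_that("average reference zeroes the per-sample channel mean and is idempotent", {
  es <- make_noise_epochset(6, sd = 2)
  rr <- rereference_average(es)
  expect_identical(rr$reference, "average")
  chm <- colMeans(aperm(rr$data, c(2, 1, 3)))
  expect_lt(max(abs(chm)), 1e-9)
  expect_equal(rereference_average(rr)$data, rr$data, tolerance = 1e-12)
})

test_that("average reference has the two-channel closed form and needs >= 2 channels", {
  a <- sin(seq_len(20))
  b <- cos(seq_len(20))
  x <- array(0, c(1, 2, 20))
  x[1, 1, ] <- a
  x[1, 2, ] <- b
  rr <- rereference_average(x)
  expect_equal(rr[1, 1, ], (a - b) / 2)
  expect_equal(rr[1, 2, ], (b - a) / 2)
  expect_error(rereference_average(x[, 1, , drop = FALSE]),
               class = "vicarsep_invalid_state")
})

test_that("baseline correction and average referencing commute", {
  es <- make_noise_epochset(7, sd = 4)
  ab <- rereference_average(baseline_correct(es))
  ba <- baseline_correct(rereference_average(es))
  expect_equal(ab$data, ba$data, tolerance = 1e-9)
})

test_that("artifact rejection flags exactly the trials exceeding the criterion", {
  es <- make_epochset(n_trials = 4)
  expect_equal(sum(reject_artifacts(es)$is_artifact), 0)
  es$data[3, 2, 100] <- 500
  rej <- reject_artifacts(es)
  expect_identical(which(rej$is_artifact), 3L)
  expect_equal(attr(rej, "retained")[["Hand"]], 1)
  # all trials of one condition rejected -> participant flagged unusable
  es$data[1, 1, 50] <- 400
  expect_warning(rej2 <- reject_artifacts(es), "unusable")
  expect_true(attr(rej2, "unusable"))
})

test_that("averaging selects the cluster contralateral to the stimulated hand", {
  es <- make_epochset(n_trials = 2, condition = c("Hand", "Hand"),
                      hand = c("Left", "Left"))
  right_ch <- es$channels %in% analysis_electrodes()$right
  es$data[, right_ch, ] <- 7
  es$data[, !right_ch, ] <- -1
  contra <- average_sep(es, "Hand", "Contralateral")
  ipsi <- average_sep(es, "Hand", "Ipsilateral")
  expect_true(all(contra$values == 7))   # left hand -> right hemisphere
  expect_true(all(ipsi$values == -1))
  expect_equal(contra$n_trials_included, 2)
})

test_that("a single retained trial's SEP equals that trial's cluster mean", {
  es <- make_noise_epochset(9, n_trials = 2,
                            condition = c("Surface", "Hand"),
                            hand = c("Right", "Left"))
  w <- average_sep(es, "Surface", "Contralateral")
  chidx <- match(analysis_electrodes()$left, es$channels)
  expect_equal(w$values, colMeans(es$data[1, chidx, ]))
  expect_equal(w$n_trials_included, 1)
  es$is_artifact[1] <- TRUE
  expect_error(average_sep(es, "Surface", "Contralateral"),
               class = "vicarsep_missing_data")
})

test_that("laterality pooling is symmetric under a left-right relabelling", {
  es <- make_noise_epochset(10, n_trials = 6)
  mirrored <- es
  mirrored$hand <- ifelse(es$hand == "Left", "Right", "Left")
  el <- analysis_electrodes()
  swap <- es$channels
  swap[match(el$left, es$channels)] <- el$right
  swap[match(el$right, es$channels)] <- el$left
  mirrored$channels <- swap
  for (k in c("Hand", "Surface")) {
    for (lat in c("Contralateral", "Ipsilateral")) {
      expect_equal(average_sep(mirrored, k, lat)$values,
                   average_sep(es, k, lat)$values)
    }
  }
})

test_that("difference matrices have the right shape, zero rows for equal conditions", {
  mk_wave <- function(pid, k, values) {
    structure(list(values = values, time_ms = seq(-100, 700, by = 2),
                   participant_id = pid, condition = k,
                   laterality = "Contralateral", n_trials_included = 5),
              class = "sep_waveform")
  }
  base <- sin(seq(-100, 700, by = 2) / 50)
  seps <- list()
  for (p in sprintf("S%02d", 1:15)) {
    seps[[length(seps) + 1]] <- mk_wave(p, "Hand", base)
    seps[[length(seps) + 1]] <- mk_wave(p, "Surface", base)
  }
  dm <- build_diff_matrix(seps, "Contralateral")
  expect_equal(dim(dm), c(15L, 101L))        # 0-200 ms inclusive at 2 ms
  expect_true(all(dm == 0))
  expect_equal(attr(dm, "time_ms"), seq(0, 200, by = 2))
  # a participant missing one condition is dropped with a warning
  expect_warning(dm2 <- build_diff_matrix(seps[-2], "Contralateral"),
                 "lacks a condition")
  expect_equal(nrow(dm2), 14)
})

test_that("interaction matrix is the row-wise double difference", {
  m <- with_seed(3, matrix(stats::rnorm(5 * 101), 5, 101))
  rownames(m) <- sprintf("S%02d", 1:5)
  tm <- seq(0, 200, by = 2)
  contra <- vicarsep:::new_diffmat(m, tm, "Contralateral")
  ipsi <- vicarsep:::new_diffmat(m, tm, "Ipsilateral")
  inter <- build_interaction_matrix(contra, ipsi)
  expect_true(all(inter == 0))
  expect_identical(attr(inter, "laterality"), "interaction")
  one <- vicarsep:::new_diffmat(m[1, , drop = FALSE], tm, "Ipsilateral")
  expect_error(build_interaction_matrix(contra, one),
               class = "vicarsep_invalid_input")
  # one participant is a valid (degenerate) construction
  onec <- vicarsep:::new_diffmat(m[1, , drop = FALSE], tm, "Contralateral")
  expect_equal(nrow(build_interaction_matrix(onec,
                                             vicarsep:::new_diffmat(
                                               m[1, , drop = FALSE] * 0,
                                               tm, "Ipsilateral"))), 1)
})

test_that("window means handle constants, zeros and empty windows", {
  tm <- seq(0, 200, by = 2)
  z <- vicarsep:::new_diffmat(matrix(0, 3, 101), tm, "Contralateral")
  expect_equal(window_mean_amplitude(z, c(50, 150)), 0)
  k <- vicarsep:::new_diffmat(matrix(2.5, 3, 101), tm, "Contralateral")
  expect_equal(window_mean_amplitude(k, c(0, 200)), 2.5)
  expect_error(window_mean_amplitude(k, c(300, 400)),
               class = "vicarsep_invalid_parameter")
  expect_error(window_mean_amplitude(k, c(100, 50)),
               class = "vicarsep_invalid_parameter")
})
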