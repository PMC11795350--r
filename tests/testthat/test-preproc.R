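test_that("segmentation tiles the recording and skips late events", {
  cont <- matrix(rnorm(30 * 512), 30, 512)
  rownames(cont) <- as.character(montage_1020())
  seg <- segment_epochs(cont, c(1, 257))
  expect_equal(dim(seg$data), c(2, 30, 256))
  recon <- cbind(seg$data[1, , ], seg$data[2, , ])
  expect_equal(unname(recon), unname(cont))

  expect_warning(seg2 <- segment_epochs(cont, c(1, 300)), "skipped")
  expect_equal(dim(seg2$data)[1], 1)

  long <- matrix(0.6 * sin(2 * pi * 10 * (0:(40 * 256 - 1)) / 256), 30,
                 40 * 256, byrow = TRUE)
  seg3 <- segment_epochs(long, seq(1, by = 256, length.out = 38))
  expect_equal(dim(seg3$data), c(38, 30, 256))
})

test_that("each rejection criterion fires on its designed fixture and only there", {
  base <- clean_epochs(n_ep = 5, amp = 20, f = 10)
  res <- reject_epochs(base)
  expect_equal(sum(res$log$per_epoch$kept), 5)
  expect_equal(unname(res$log$summary), c(0L, 0L, 0L, 0L))

  # (a) amplitude: 100 uV deflection in epoch 3 only
  amp <- inject_artifacts(base, "amplitude", 3, magnitude = 100, seed = 1)
  ra <- reject_epochs(amp)
  expect_identical(which(!ra$log$per_epoch$kept), 3L)
  expect_true("a" %in% ra$log$violations$criterion)

  # (b) voltage step in uV/ms: at 256 Hz a step large enough to violate
  # 50 uV/ms would also violate (a) and (c); a 2000-Hz fixture isolates it
  # (per-sample limit 25 uV there)
  n <- 1024
  t <- (0:(n - 1)) / 2000
  sig <- 5 * sin(2 * pi * 20 * t)
  datb <- array(0, dim = c(2, 30, n))
  for (e in 1:2) for (ch in 1:30) datb[e, ch, ] <- sig
  datb[2, 7, 500:n] <- datb[2, 7, 500:n] + 35
  epb <- epoch_array(datb, srate = 2000)
  rb <- reject_epochs(epb)
  expect_identical(which(!rb$log$per_epoch$kept), 2L)
  expect_identical(unique(rb$log$violations$criterion), "b")

  # (c) slow drift: 120 uV ramp over 400 ms stays under the +-70 uV and
  # step limits but exceeds 50 uV within a 200-ms window
  datc <- base$data
  ramp <- seq(-60, 60, length.out = 103)
  datc[4, 12, 77:179] <- datc[4, 12, 77:179] * 0.05 + ramp
  epc <- epoch_array(datc, subject_id = "C", condition = "shape")
  rc <- reject_epochs(epc)
  expect_identical(which(!rc$log$per_epoch$kept), 4L)
  expect_identical(unique(rc$log$violations$criterion), "c")

  # (d) flatline: an all-zeros epoch has activity 0 < 0.5 uV
  datd <- base$data
  datd[2, , ] <- 0
  epd <- epoch_array(datd, subject_id = "D", condition = "shape")
  rd <- reject_epochs(epd)
  expect_identical(which(!rd$log$per_epoch$kept), 2L)
  expect_identical(unique(rd$log$violations$criterion), "d")

  flat <- inject_artifacts(base, "flatline", 5, magnitude = 0.4, seed = 3)
  rf <- reject_epochs(flat)
  expect_identical(which(!rf$log$per_epoch$kept), 5L)
  expect_true("d" %in% rf$log$violations$criterion)
})

test_that("rejection is idempotent, monotone in its thresholds and conserving", {
  base <- clean_epochs(n_ep = 8, amp = 20)
  bad <- inject_artifacts(base, "amplitude", c(2, 6), magnitude = 90, seed = 1)
  bad <- inject_artifacts(bad, "flatline", 4, magnitude = 0.3, seed = 2)
  res <- reject_epochs(bad)
  expect_equal(n_epochs(res$epochs) + sum(!res$log$per_epoch$kept), 8)

  # idempotence: the survivors pass unchanged
  res2 <- reject_epochs(res$epochs)
  expect_identical(res2$epochs$data, res$epochs$data)
  expect_true(all(res2$log$per_epoch$kept))

  # loosening any single criterion never rejects more epochs
  n_rej <- sum(!res$log$per_epoch$kept)
  loosen <- list(
    rejection_criteria(max_abs_amplitude = 200),
    rejection_criteria(max_step = 500),
    rejection_criteria(max_diff_200ms = 500),
    rejection_criteria(min_activity_100ms = 0.01)
  )
  for (cr in loosen) {
    expect_lte(sum(!reject_epochs(bad, cr)$log$per_epoch$kept), n_rej)
  }

  # all epochs rejected is an explicit error naming the recording
  allbad <- epoch_array(array(0, dim = c(3, 30, 256)), subject_id = "S099",
                        condition = "binding")
  expect_error(reject_epochs(allbad), "S099")
})
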