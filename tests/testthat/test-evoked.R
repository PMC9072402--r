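test_that("epoch containers enforce the half-open window convention", {
  # [-0.2, 1.8) s at 250 Hz -> 500 samples
  data <- array(0, c(3, 4, 500))
  ep <- epoch_set(data, rate = 250, window = c(-0.2, 1.8))
  expect_equal(dim(ep$data)[3], 500)
  expect_equal(epoch_times(ep)[1], -0.2)
  expect_error(epoch_set(array(0, c(3, 4, 501)), 250, c(-0.2, 1.8)),
               "samples")
})

test_that("continuous recordings are cut into fixed-length epochs", {
  set.seed(1)
  rec <- matrix(rnorm(2 * 2000), 2)
  ep <- epoch_continuous(rec, onsets = c(2, 4), window = c(-0.2, 1.8),
                         rate = 250)
  expect_equal(dim(ep$data), c(2, 2, 500))
  i0 <- round((2 - 0.2) * 250) + 1
  expect_equal(ep$data[1, 1, ], rec[1, i0:(i0 + 499)])
  empty <- epoch_continuous(rec, numeric(0))
  expect_equal(dim(empty$data)[1], 0)
  expect_error(epoch_continuous(rec, onsets = 0.1), "trial")
  expect_error(epoch_continuous(rec, onsets = 7.9), "trial")
})

test_that("peak-to-peak rejection flags exactly the contaminated trials", {
  data <- array(0, c(4, 3, 100))
  ep <- epoch_set(data, 250, c(-0.2, 0.2))
  expect_true(all(reject_peak_to_peak(ep, 2e-11)))
  data[2, 1, 50] <- 3e-11                     # spike above threshold
  data[3, 2, 10] <- 0.9e-11                   # below threshold
  ep2 <- epoch_set(data, 250, c(-0.2, 0.2))
  expect_equal(reject_peak_to_peak(ep2, 2e-11), c(TRUE, FALSE, TRUE, TRUE))
  # brute-force oracle on random data
  set.seed(2)
  data3 <- array(rnorm(5 * 3 * 50, sd = 1e-11), c(5, 3, 50))
  ep3 <- epoch_set(data3, 250, c(0, 0.2))
  thr <- 4e-11
  oracle <- sapply(1:5, function(r) {
    all(apply(data3[r, , ], 1, function(v) diff(range(v))) <= thr)
  })
  expect_equal(reject_peak_to_peak(ep3, thr), oracle)
})

test_that("sensor triplets merge into the configured weighted sum", {
  x <- matrix(rnorm(9 * 10), 9)
  grouping <- rep(1:3, each = 3)
  merged <- merge_sensor_triplets(x, grouping)
  oracle <- rbind(colSums(x[1:3, ]), colSums(x[4:6, ]), colSums(x[7:9, ]))
  expect_equal(merged, oracle)
  # identical channels with mean weights return the member
  trip <- x[c(1, 1, 1), ]
  expect_equal(merge_sensor_triplets(trip, c(1, 1, 1),
                                     weights = rep(1 / 3, 3)),
               x[1, , drop = FALSE])
  # 306 -> 102
  big <- matrix(0, 306, 5)
  expect_equal(nrow(merge_sensor_triplets(big, rep(1:102, each = 3))), 102)
  expect_error(merge_sensor_triplets(x, rep(1:2, c(4, 5))), "triplet")
})

test_that("unisensory removal is exact ordinary least squares", {
  set.seed(3)
  aud <- structure(list(data = matrix(rnorm(3 * 200), 3), n_trials = 10,
                        rate = 250, window = c(0, 0.8),
                        sensor_names = paste0("S", 1:3)), class = "evoked")
  vis <- aud
  vis$data <- matrix(rnorm(3 * 200), 3)
  task <- aud
  task$data <- 0.5 * aud$data + 2 * vis$data
  res <- remove_unisensory(task, aud, vis)
  expect_equal(res$weights$beta_a, rep(0.5, 3), tolerance = 1e-10)
  expect_equal(res$weights$beta_v, rep(2, 3), tolerance = 1e-10)
  expect_lt(max(abs(res$residual$data)), 1e-12)
  # orthogonal unit-norm regressors: weights equal inner products
  qa <- qr.Q(qr(cbind(rnorm(100), rnorm(100))))
  aud2 <- structure(list(data = matrix(qa[, 1], 1), n_trials = 1, rate = 250,
                         window = c(0, 0.4), sensor_names = "S1"),
                    class = "evoked")
  vis2 <- aud2
  vis2$data <- matrix(qa[, 2], 1)
  y <- rnorm(100)
  task2 <- aud2
  task2$data <- matrix(y, 1)
  res2 <- remove_unisensory(task2, aud2, vis2)
  expect_equal(res2$weights$beta_a, sum(qa[, 1] * y), tolerance = 1e-10)
  expect_equal(res2$weights$beta_v, sum(qa[, 2] * y), tolerance = 1e-10)
  # collinear localizers raise a conditioning warning
  expect_warning(remove_unisensory(task, aud, aud), "collinear")
})

test_that("unisensory removal is idempotent", {
  set.seed(4)
  mk <- function(m) structure(list(data = m, n_trials = 5, rate = 250,
                                   window = c(0, 0.4),
                                   sensor_names = paste0("S", 1:2)),
                              class = "evoked")
  aud <- mk(matrix(rnorm(2 * 100), 2))
  vis <- mk(matrix(rnorm(2 * 100), 2))
  task <- mk(1.2 * aud$data - 0.7 * vis$data + matrix(rnorm(200, sd = 3), 2))
  first <- remove_unisensory(task, aud, vis)
  second <- remove_unisensory(first$residual, aud, vis)
  expect_lt(max(abs(second$weights$beta_a)), 1e-10)
  expect_lt(max(abs(second$weights$beta_v)), 1e-10)
  expect_equal(second$residual$data, first$residual$data, tolerance = 1e-10)
})

test_that("synthetic round trip recovers the unisensory weights", {
  stim <- packaged_stimulus_set()
  truth <- ground_truth(n_participants = 2, snr = 5, seed = 9)
  design <- make_design(2, reps = 20, blocks = 1, localizer_blocks = 2,
                        seed = 9)
  layout <- make_layout(12, 4)
  ep <- simulate_epochs(truth, design, stim, layout, seed = 9,
                        orthogonalize_multisensory = TRUE)
  tr <- attr(ep, "truth")
  labels <- sapply(stim, `[[`, "label")
  ev <- function(task, s) {
    average_evoked(ep, ep$trial_meta$task == task &
                     ep$trial_meta$stimulus == s)
  }
  cj <- lapply(labels, function(s) ev("causality", s))
  aud <- lapply(labels, function(s) ev("localizer_A", s))
  vis <- lapply(labels, function(s) ev("localizer_V", s))
  out <- remove_unisensory(cj, aud, vis)
  rel_a <- abs(out$weights$beta_a - tr$unisensory$beta_a) /
    tr$unisensory$beta_a
  rel_v <- abs(out$weights$beta_v - tr$unisensory$beta_v) /
    tr$unisensory$beta_v
  expect_lt(max(rel_a), 0.05)
  expect_lt(max(rel_v), 0.05)
  # the residual tracks the multisensory component better than either
  # unisensory trace
  tm <- attr(ep, "templates")
  for (n in 1:3) {
    resid <- unlist(lapply(seq_along(labels), function(i) {
      out$residual[[i]]$data[n, ]
    }))
    multi <- unlist(lapply(labels, function(s) {
      attr(tm[[paste(1, s, "task", sep = "|")]], "multi")[n, ]
    }))
    aud_tr <- unlist(lapply(labels, function(s) {
      tm[[paste(1, s, "A", sep = "|")]][n, ]
    }))
    vis_tr <- unlist(lapply(labels, function(s) {
      tm[[paste(1, s, "V", sep = "|")]][n, ]
    }))
    expect_gt(abs(cor(resid, multi)), abs(cor(resid, aud_tr)))
    expect_gt(abs(cor(resid, multi)), abs(cor(resid, vis_tr)))
  }
})

test_that("cluster RMS is the root mean square over the mask", {
  m <- matrix(7, 4, 5)
  mask <- matrix(FALSE, 4, 5)
  mask[2, 2:3] <- TRUE
  expect_equal(cluster_rms(m, mask), 7)
  m2 <- matrix(0, 1, 2)
  m2[1, ] <- c(3, -4)
  expect_equal(cluster_rms(m2, matrix(TRUE, 1, 2)), sqrt(12.5))
  expect_equal(round(cluster_rms(m2, matrix(TRUE, 1, 2)), 4), 3.5355)
  ones <- matrix(1, 3, 3)
  expect_equal(cluster_rms(ones, matrix(TRUE, 3, 3)), 1)
  expect_error(cluster_rms(m, matrix(FALSE, 4, 5)), "empty")
  # per-trial RMS on an epoch set equals the direct computation
  set.seed(5)
  data <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  ep <- epoch_set(data, 250, c(0, 0.02))
  mask2 <- matrix(runif(20) > 0.5, 4, 5)
  rms <- cluster_rms(ep, mask2)
  expect_equal(rms[2], sqrt(mean(data[2, , ][mask2]^2)))
})

test_that("evoked-on-summary regression recovers a built-in slope", {
  set.seed(6)
  P <- 10
  z <- rep(zscore_pop(rnorm(6)), P)
  participant <- rep(1:P, each = 6)
  b <- rnorm(P, 0, 0.3)
  df <- data.frame(
    rms = 2 + 1.5 * z + b[participant] + rnorm(6 * P, sd = 0.3),
    z = z, task = "causality", participant = participant)
  df2 <- df
  df2$task <- "temporal_order"
  df2$rms <- 2 + 0 * z + b[participant] + rnorm(6 * P, sd = 0.3)
  res <- regress_evoked_on_mcd(rbind(df, df2))
  expect_equal(res$per_task$causality$slope, 1.5, tolerance = 0.2)
  expect_lt(res$per_task$causality$p, 0.001)
  expect_gt(res$per_task$temporal_order$p, 0.01)
  expect_lt(res$interaction_p, 0.01)
  # noiseless linear toy: exact slope
  df3 <- data.frame(rms = 3 * rep(zscore_pop(1:6), 4), z = rep(zscore_pop(1:6), 4),
                    task = rep(c("causality", "temporal_order"), each = 12),
                    participant = rep(rep(1:2, each = 6), 2))
  res3 <- suppressWarnings(suppressMessages(regress_evoked_on_mcd(df3)))
  expect_equal(res3$per_task$causality$slope, 3, tolerance = 1e-6)
})

test_that("zero-effect evoked regressions stay at the nominal false-positive rate", {
  set.seed(7)
  n_runs <- 60
  hits <- 0
  for (i in seq_len(n_runs)) {
    z <- rep(zscore_pop(rnorm(6)), 8)
    participant <- rep(1:8, each = 6)
    df <- data.frame(rms = rnorm(48), z = z, task = "causality",
                     participant = participant)
    df2 <- df
    df2$task <- "temporal_order"
    df2$rms <- rnorm(48)
    res <- suppressWarnings(suppressMessages(
      regress_evoked_on_mcd(rbind(df, df2))))
    if (res$per_task$causality$p < 0.05) hits <- hits + 1
  }
  expect_lte(hits, ceiling(0.15 * n_runs))   # 5% nominal, generous MC slack
})

test_that("single-trial brain-behavior model selection finds a built-in interaction", {
  set.seed(8)
  P <- 8
  n_pp <- 60
  b <- rnorm(P, 0, 0.3)
  mk <- function(task, slope) {
    rms <- rnorm(P * n_pp)
    participant <- rep(1:P, each = n_pp)
    eta <- slope * rms + b[participant]
    data.frame(response = rbinom(P * n_pp, 1, plogis(eta)), rms = rms,
               task = task, participant = participant)
  }
  df <- rbind(mk("causality", 1.5), mk("temporal_order", 0))
  res <- single_trial_brain_behavior(df)
  expect_equal(res$selected, "activity_x_task")
  expect_lt(res$per_task$causality$p, 0.01)
  expect_gt(res$per_task$temporal_order$p, 0.05)
  expect_false(res$separation)
  # null data: the plain activity model stays competitive
  df0 <- rbind(mk("causality", 0), mk("temporal_order", 0))
  res0 <- single_trial_brain_behavior(df0)
  expect_true(res0$selected %in% c("activity", "activity_plus_task"))
  # deterministic threshold responses are flagged as separation
  dfs <- rbind(mk("causality", 0), mk("temporal_order", 0))
  dfs$response <- as.integer(dfs$rms > 0)
  ress <- suppressWarnings(suppressMessages(single_trial_brain_behavior(dfs)))
  expect_true(ress$separation)
})

test_that("band-limited signals pass through the band-pass decimator", {
  t <- seq(0, 2, by = 1 / 250)[-1]
  x <- sin(2 * pi * 10 * t)                  # 10 Hz, inside 1-40 Hz band
  y <- bandpass_decimate(x, rate = 250, l_freq = 1, h_freq = 40)
  keep <- 100:400                            # avoid filter edge effects
  expect_equal(y[keep], x[keep], tolerance = 0.02)
  expect_error(bandpass_decimate(x, 250, out_rate = 100), "divide")
})
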