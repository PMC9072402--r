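test_that("lagged designs are exact shifted copies with zero padding", {
  set.seed(1)
  x <- rnorm(50)
  D0 <- lagged_design(x, 0L)
  expect_equal(as.numeric(D0), x)
  lags <- 0:4
  D <- lagged_design(x, lags)
  for (j in seq_along(lags)) {
    l <- lags[j]
    oracle <- c(rep(0, l), x[seq_len(50 - l)])    # manual shift
    expect_equal(D[, j], oracle)
  }
  # negative (acausal) lags shift the other way
  Dn <- lagged_design(x, -2L)
  expect_equal(as.numeric(Dn), c(x[3:50], 0, 0))
  # 4 components x L lags -> 4L columns
  X <- matrix(rnorm(200), 50, 4)
  expect_equal(ncol(lagged_design(X, 0:9)), 40)
  lw <- lag_window(0, 0.5, 250)
  expect_length(lw$lags, 126)
})

test_that("ridge solutions match the normal-equations oracle", {
  set.seed(2)
  X <- matrix(rnorm(200 * 6), 200)
  Y <- matrix(rnorm(200 * 2), 200)
  m0 <- fit_trf(X, Y, lambda = 0)
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  oracle <- solve(crossprod(Xc), crossprod(Xc, Yc))
  expect_equal(m0$flat_weights, t(oracle), tolerance = 1e-8)
  # explicit ridge algebra
  lam <- 3.7
  mr <- fit_trf(X, Y, lambda = lam)
  oracler <- solve(crossprod(Xc) + diag(lam, 6), crossprod(Xc, Yc))
  expect_equal(mr$flat_weights, t(oracler), tolerance = 1e-8)
  # very large penalty shrinks the weights toward zero
  mbig <- fit_trf(X, Y, lambda = 1e9)
  expect_lt(max(abs(mbig$flat_weights)), 1e-5)
  # singular design with no penalty is rejected
  Xs <- cbind(X[, 1], X[, 1], X[, 2])
  expect_error(fit_trf(Xs, Y, lambda = 0), "singular")
})

test_that("noise-free kernels are recovered to within 1 percent", {
  fx <- random_trf_entries(n_entries = 4, n_t = 400, snr = Inf, seed = 3)
  D <- do.call(rbind, lapply(fx$entries, function(e) {
    lagged_design(e$components, fx$lags)
  }))
  Y <- do.call(rbind, lapply(fx$entries, function(e) e$response))
  m <- fit_trf(D, Y, lambda = 1e-8, component_names = c("c1", "c2"),
               lags = fx$lags)
  expect_equal(m$weights, fx$w_true, tolerance = 0.01, ignore_attr = TRUE)
})

test_that("kernel recovery degrades monotonically with noise and stays high at SNR 5", {
  cors <- sapply(c(Inf, 5, 1), function(snr) {
    fx <- random_trf_entries(n_entries = 6, n_t = 400, snr = snr, seed = 4)
    D <- do.call(rbind, lapply(fx$entries, function(e) {
      lagged_design(e$components, fx$lags)
    }))
    Y <- do.call(rbind, lapply(fx$entries, function(e) e$response))
    m <- fit_trf(D, Y, lambda = 1, component_names = c("c1", "c2"),
                 lags = fx$lags)
    cor(as.vector(m$weights), as.vector(fx$w_true))
  })
  expect_true(all(diff(cors) < 0))
  expect_gt(cors[2], 0.9)                  # SNR 5
})

test_that("cross-validation scores approach 1 on clean data and 0 on noise", {
  fx <- random_trf_entries(n_entries = 6, n_t = 300, snr = Inf, seed = 5)
  sc <- trf_crossval(fx$entries, lags = fx$lags, lambda = 1e-6,
                     contributions = FALSE)
  expect_equal(sc$n_folds, 6)
  expect_gt(min(sc$rho), 0.98)
  # fold bookkeeping mirrors the participant x stimulus count
  fx78 <- random_trf_entries(n_entries = 78, n_t = 60, n_sensors = 1,
                             n_lags = 3, seed = 6)
  sc78 <- trf_crossval(fx78$entries, lags = fx78$lags, lambda = 1,
                       contributions = FALSE)
  expect_equal(sc78$n_folds, 78)
  # pure-noise targets score near zero
  fx0 <- random_trf_entries(n_entries = 8, n_t = 300, snr = Inf, seed = 7)
  for (i in seq_along(fx0$entries)) {
    set.seed(100 + i)
    fx0$entries[[i]]$response[] <- rnorm(length(fx0$entries[[i]]$response))
  }
  sc0 <- trf_crossval(fx0$entries, lags = fx0$lags, lambda = 1,
                      contributions = FALSE)
  expect_lt(max(abs(sc0$rho)), 0.05)
})

test_that("nested penalty selection picks a sensible lambda", {
  fx <- random_trf_entries(n_entries = 6, n_t = 250, snr = 2, seed = 8)
  sc <- trf_crossval(fx$entries, lags = fx$lags,
                     lambda = 10^seq(-2, 4, by = 1), contributions = FALSE)
  expect_true(all(sc$lambda_used %in% 10^seq(-2, 4, by = 1)))
  fixed_small <- trf_crossval(fx$entries, lags = fx$lags, lambda = 1e-2,
                              contributions = FALSE)
  expect_gte(mean(sc$rho), mean(fixed_small$rho) - 0.02)
})

test_that("held-out component attribution is specific to the driving component", {
  stim <- packaged_stimulus_set()[1:4]
  design <- make_design(2, reps = 3, blocks = 1, localizer_blocks = 1,
                        stimuli = sapply(stim, `[[`, "label"), seed = 2)
  lay2 <- make_layout(2, 2)
  nl <- 25
  t_ax <- (0:(nl - 1)) / 250
  ok <- 0
  n_seeds <- 10
  for (seed in seq_len(n_seeds)) {
    truth <- ground_truth(n_participants = 2, snr = 5, seed = seed)
    trf0 <- array(0, c(2, 4, nl))
    trf0[1, 3, ] <- exp(-t_ax / 0.1) * sin(2 * pi * 5 * t_ax)  # corr-driven
    trf0[2, 4, ] <- exp(-t_ax / 0.1) * sin(2 * pi * 7 * t_ax)  # lag-driven
    truth$trf_true <- trf0
    truth$unisensory <- data.frame(beta_a = c(0, 0), beta_v = c(0, 0))
    truth$topography <- data.frame(topo_a = c(0.01, 0.01),
                                   topo_v = c(0.01, 0.01))
    ep <- simulate_epochs(truth, design, stim, lay2, n_lags = nl,
                          seed = seed)
    entries <- trf_entries(ep, stim, truth$mcd_params)
    sc <- trf_crossval(entries, lags = lag_window(0, (nl - 1) / 250, 250),
                       lambda = 1)
    within1 <- sc$component_rho[1, "corr"]
    cross1 <- sc$component_rho[1, "lag"]
    within2 <- sc$component_rho[2, "lag"]
    cross2 <- sc$component_rho[2, "corr"]
    if (within1 > cross1 && within2 > cross2) ok <- ok + 1
  }
  expect_equal(ok, n_seeds)
})

test_that("attribution conventions: zero weights score zero, single component equals full", {
  fx <- random_trf_entries(n_entries = 3, n_t = 200, n_comp = 2, snr = Inf,
                           seed = 9)
  D <- do.call(rbind, lapply(fx$entries[1:2], function(e) {
    lagged_design(e$components, fx$lags)
  }))
  Y <- do.call(rbind, lapply(fx$entries[1:2], function(e) e$response))
  m <- fit_trf(D, Y, lambda = 1e-6, component_names = c("c1", "c2"),
               lags = fx$lags)
  held_D <- lagged_design(fx$entries[[3]]$components, fx$lags)
  held_Y <- fx$entries[[3]]$response
  # all-zero weights for one component -> rho 0 with a flag
  mz <- m
  mz$flat_weights[, 1:length(fx$lags$lags)] <- 0
  rho_z <- component_contribution(mz, held_D, held_Y, 1)
  expect_true(all(rho_z == 0))
  expect_true(all(attr(rho_z, "constant")))
  # a single-component model's contribution equals its full score
  fx1 <- random_trf_entries(n_entries = 3, n_t = 200, n_comp = 1,
                            snr = Inf, seed = 10)
  D1 <- do.call(rbind, lapply(fx1$entries[1:2], function(e) {
    lagged_design(e$components, fx1$lags)
  }))
  Y1 <- do.call(rbind, lapply(fx1$entries[1:2], function(e) e$response))
  m1 <- fit_trf(D1, Y1, lambda = 1e-6, component_names = "c1",
                lags = fx1$lags)
  hd <- lagged_design(fx1$entries[[3]]$components, fx1$lags)
  hy <- fx1$entries[[3]]$response
  full <- sapply(seq_len(ncol(hy)), function(s) {
    cor(predict(m1, hd)[, s], hy[, s])
  })
  expect_equal(as.numeric(component_contribution(m1, hd, hy, 1)), full,
               tolerance = 1e-10)
})

test_that("detector components are collinear enough that attribution overlaps", {
  # the lag unit tracks the filtered visual input almost perfectly on
  # these stimuli; attribution across those two components must overlap
  stim <- packaged_stimulus_set()[1:3]
  truth <- ground_truth(n_participants = 1, seed = 2)
  pr <- truth$mcd_params[1, ]
  comp <- mcdmeg:::.component_traces(
    stim[[1]], mcd_params(pr$tau_a, pr$tau_v, pr$tau_av), 250,
    c(-0.2, 1.8) + first_onset(stim[[1]]))
  expect_gt(abs(cor(comp[, "mcd_v"], comp[, "lag"])), 0.9)
  design <- make_design(1, reps = 2, blocks = 1, localizer_blocks = 1,
                        stimuli = sapply(stim, `[[`, "label"), seed = 3)
  lay <- make_layout(2, 2)
  nl <- 20
  truth$trf_true <- array(0, c(2, 4, nl))
  truth$trf_true[1, 2, ] <- exp(-(0:(nl - 1)) / 5)   # driven by mcd_v only
  truth$unisensory <- data.frame(beta_a = c(0, 0), beta_v = c(0, 0))
  truth$topography <- data.frame(topo_a = c(0.01, 0.01),
                                 topo_v = c(0.01, 0.01))
  ep <- simulate_epochs(truth, design, stim, lay, n_lags = nl, seed = 3)
  entries <- trf_entries(ep, stim, truth$mcd_params)
  sc <- trf_crossval(entries, lags = lag_window(0, (nl - 1) / 250, 250),
                     lambda = 1)
  # collinear components inherit part of the score even though only the
  # visual unit drives the sensor; an independent predictor would stay
  # near zero (see the pure-noise check above)
  expect_gt(sc$component_rho[1, "mcd_v"], 0.9)
  expect_gt(abs(sc$component_rho[1, "lag"]), 0.1)
  expect_gt(abs(sc$component_rho[1, "corr"]), 0.1)
})

test_that("windowed scores split the epoch correctly", {
  fx <- random_trf_entries(n_entries = 5, n_t = 500, snr = 10, seed = 11)
  # treat rows as a [-0.2, 1.8) epoch at 250 Hz
  ws <- windowed_scores(fx$entries,
                        windows = list(early = c(0, 0.5),
                                       late = c(0.5, 1.0)),
                        epoch_window = c(-0.2, 1.8), rate = 250,
                        lags = fx$lags, lambda = 1)
  # stationary process: early and late scores agree within MC error
  expect_equal(mean(ws$early$rho), mean(ws$late$rho), tolerance = 0.1)
  # the full window reproduces the unsplit score
  full <- windowed_scores(fx$entries,
                          windows = list(all = c(-0.2, 1.8)),
                          epoch_window = c(-0.2, 1.8), rate = 250,
                          lags = fx$lags, lambda = 1)
  plain <- trf_crossval(fx$entries, lags = fx$lags, lambda = 1,
                        contributions = FALSE)
  expect_equal(full$all$rho, plain$rho, tolerance = 1e-10)
  expect_error(windowed_scores(fx$entries,
                               windows = list(bad = c(1.9, 2.5)),
                               epoch_window = c(-0.2, 1.8), rate = 250,
                               lags = fx$lags), "window")
})
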