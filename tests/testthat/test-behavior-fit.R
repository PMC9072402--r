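test_that("flat model with no random effect reduces to coin-flip likelihood", {
  set.seed(1)
  z <- zscore_pop(rnorm(6))
  names(z) <- paste0("s", 1:6)
  tr <- cells_to_trials(matrix(5, 2, 6), matrix(10, 2, 6), names(z))
  expect_equal(nll_mixed_logistic(0, 0, 0, tr, z), nrow(tr) * log(2),
               tolerance = 1e-12)
})

test_that("marginal likelihood matches quadrature oracles", {
  set.seed(2)
  z <- zscore_pop(rnorm(6))
  names(z) <- paste0("s", 1:6)
  k <- matrix(rbinom(12, 20, 0.5), 2, 6)
  n <- matrix(20, 2, 6)
  tr <- cells_to_trials(k, n, names(z))
  for (sg in c(0.2, 0.5)) {
    mine <- nll_mixed_logistic(0.4, 1.1, sg, tr, z, nodes = 40)
    oracle <- gh40_nll(0.4, 1.1, sg, k, n, unname(z))
    expect_equal(mine, oracle, tolerance = 1e-6)
  }
  # dense numerical integration as ground truth at larger sigma, where
  # the non-adaptive oracle itself loses accuracy
  truth <- -sum(sapply(1:2, function(p) {
    f <- function(b) sapply(b, function(bb) {
      eta <- 0.4 + 1.1 * z + bb
      exp(sum(k[p, ] * plogis(eta, log.p = TRUE) +
                (n[p, ] - k[p, ]) * plogis(-eta, log.p = TRUE))) *
        dnorm(bb, 0, 1.2)
    })
    log(integrate(f, -Inf, Inf, rel.tol = 1e-12)$value)
  }))
  expect_equal(nll_mixed_logistic(0.4, 1.1, 1.2, tr, z), truth,
               tolerance = 1e-4)
})

test_that("likelihood vanishes for separable data as the slope grows", {
  z <- c(s1 = -1, s2 = 1)
  tr <- cells_to_trials(matrix(c(0, 0, 20, 20), 2, 2),
                        matrix(20, 2, 2), names(z))
  nll <- sapply(c(1, 3, 8, 20), function(b1) {
    nll_mixed_logistic(0, b1, 0, tr, z)
  })
  expect_true(all(diff(nll) < 0))
  expect_lt(nll[4], 1e-3)
})

test_that("errors are raised for malformed trial tables", {
  z <- c(a = -1, b = 1)
  bad <- data.frame(participant = 1, stimulus = "c", response = 1)
  expect_error(nll_mixed_logistic(0, 1, 0.5, bad, z), "stimulus")
  nonbin <- data.frame(participant = 1, stimulus = "a", response = 2)
  expect_error(nll_mixed_logistic(0, 1, 0.5, nonbin, z), "binary")
  zna <- c(a = NaN, b = 1)
  ok <- data.frame(participant = 1, stimulus = "a", response = 1)
  expect_error(nll_mixed_logistic(0, 1, 0.5, ok, zna), "a")
})

test_that("the cell-level ML fit agrees with the mixed-model oracle", {
  set.seed(5)
  z <- zscore_pop(rnorm(6))
  P <- 8
  b <- rnorm(P, 0, 0.6)
  pi <- plogis(outer(b, 0.3 + 1.4 * z, `+`))
  k <- matrix(rbinom(P * 6, 40, pi), P, 6)
  cells <- list(k = k, n = matrix(40, P, 6), z = z, participants = 1:P)
  mine <- mcdmeg:::.fit_cell_logistic(cells, hessian = TRUE)
  df <- data.frame(k = as.vector(k), n = 40,
                   z = rep(z, each = P), p = factor(rep(1:P, 6)))
  or <- lme4::glmer(cbind(k, n - k) ~ z + (1 | p), data = df,
                    family = binomial, nAGQ = 15)
  expect_equal(mine$beta0, unname(lme4::fixef(or)[1]), tolerance = 1e-3)
  expect_equal(mine$beta1, unname(lme4::fixef(or)[2]), tolerance = 1e-3)
  expect_equal(mine$sigma, sqrt(unname(unlist(lme4::VarCorr(or)))),
               tolerance = 0.02, ignore_attr = TRUE)
  # absolute likelihoods are checked against dense numerical integration
  # (lme4's binomial logLik carries a different additive constant)
  truth_nll <- -sum(sapply(seq_len(P), function(p) {
    f <- function(bb) sapply(bb, function(x) {
      eta <- mine$beta0 + mine$beta1 * z + x
      exp(sum(k[p, ] * plogis(eta, log.p = TRUE) +
                (40 - k[p, ]) * plogis(-eta, log.p = TRUE))) *
        dnorm(x, 0, mine$sigma)
    })
    log(integrate(f, -4 * mine$sigma - 3, 4 * mine$sigma + 3,
                  rel.tol = 1e-12)$value)
  }))
  expect_equal(mine$nll, truth_nll, tolerance = 1e-4)
  expect_equal(mine$se[2], summary(or)$coefficients["z", "Std. Error"],
               tolerance = 0.05)
})

test_that("joint fit recovers generative time constants across observer groups", {
  # two 20-observer groups with time constants drawn from the fitted
  # per-participant ranges; the z-scored summaries leave a shallow
  # common-scale ridge in the likelihood, so recovery is assessed as a
  # median relative error over the recovered constants
  stim <- packaged_stimulus_set()
  errs <- NULL
  for (seed in c(17, 42)) {
    tab <- mcd_fitted_params()
    extra <- transform(tab[1:7, ], participant = 14:20)
    tab <- rbind(tab, extra)
    set.seed(seed)
    tv <- runif(1, 103, 152)
    ta <- runif(1, 50, 110)
    tab$tau_v <- tv
    tab$tau_a <- ta
    tab$tau_av <- runif(1, 372, 1147)
    truth <- ground_truth(n_participants = 20, mcd_params = tab, seed = seed)
    design <- make_design(20, reps = 25, blocks = 3, localizer_blocks = 1,
                          seed = seed)
    trials <- simulate_observer(truth, design, stim, seed = seed)
    tt <- trials[trials$task %in% c("causality", "temporal_order"), ]
    fit <- fit_mcd_behavior(tt, stim, n_restarts = 2, seed = seed,
                            control = list(n_particles = 8L,
                                           swarm_iters = 10L,
                                           refine_maxit = 120L))
    errs <- rbind(errs, c(abs(fit$mcd_params$tau_v - tv) / tv,
                          abs(fit$mcd_params$tau_a - ta) / ta))
    expect_gt(fit$link$beta1[fit$link$task == "causality"], 0)
    expect_gt(fit$link$beta1[fit$link$task == "temporal_order"], 0)
    expect_true(all(fit$r2$r2 >= 0 & fit$r2$r2 <= 1))
    expect_equal(-fit$loglik, min(fit$nll_by_restart))
  }
  expect_lt(median(errs), 0.15)
  expect_lt(max(errs), 0.25)
})

test_that("the joint fit is deterministic under a fixed seed", {
  stim <- packaged_stimulus_set()
  truth <- ground_truth(n_participants = 3, seed = 21)
  design <- make_design(3, reps = 10, blocks = 1, localizer_blocks = 0,
                        seed = 21)
  trials <- simulate_observer(truth, design, stim, seed = 21)
  tt <- trials[trials$task %in% c("causality", "temporal_order"), ]
  ctl <- list(n_particles = 5L, swarm_iters = 5L, refine_maxit = 50L)
  fit <- fit_mcd_behavior(tt, stim, n_restarts = 1, seed = 99, control = ctl)
  fit2 <- fit_mcd_behavior(tt, stim, n_restarts = 1, seed = 99, control = ctl)
  expect_identical(fit$mcd_params, fit2$mcd_params)
  expect_identical(fit$link, fit2$link)
  expect_identical(fit$loglik, fit2$loglik)
  expect_error(fit_mcd_behavior(tt[tt$task == "causality", ], stim,
                                n_restarts = 1, seed = 1), "both tasks")
})

test_that("pseudo R2 is the squared correlation of per-stimulus proportions", {
  stim_labels <- paste0("s", 1:6)
  sm <- data.frame(label = stim_labels,
                   corr_avg = 1:6, lag_avg = 6:1,
                   corr_z = zscore_pop(1:6), lag_z = zscore_pop(6:1))
  fit <- structure(list(
    mcd_params = mcd_params(80, 120, 600),
    link = data.frame(task = c("causality", "temporal_order"),
                      beta0 = c(0, 0), beta1 = c(1.5, 1), sigma = c(0, 0)),
    random_intercepts = list(causality = c(`1` = 0),
                             temporal_order = c(`1` = 0)),
    summaries = sm), class = "behavior_fit")
  # observed proportions equal to predictions -> r2 = 1
  pred <- plogis(1.5 * sm$corr_z)
  k <- round(pred * 1000)
  tr_c <- cells_to_trials(matrix(k, 1), matrix(1000, 1, 6), stim_labels)
  tr_c$task <- "causality"
  pred_t <- plogis(1 * sm$lag_z)
  tr_t <- cells_to_trials(matrix(round(pred_t * 1000), 1),
                          matrix(1000, 1, 6), stim_labels)
  tr_t$task <- "temporal_order"
  r2 <- pseudo_r2(fit, rbind(tr_c, tr_t))
  expect_gt(min(r2$r2), 0.999)
  # hand-computed toy value
  obs <- c(0.1, 0.4, 0.3, 0.8, 0.6, 0.9)
  tr_c2 <- cells_to_trials(matrix(round(obs * 100), 1),
                           matrix(100, 1, 6), stim_labels)
  tr_c2$task <- "causality"
  tr_t2 <- tr_t
  r2b <- pseudo_r2(fit, rbind(tr_c2, tr_t2))
  expect_equal(r2b$r2[r2b$task == "causality"],
               cor(round(obs * 100) / 100, plogis(1.5 * sm$corr_z))^2,
               tolerance = 1e-12)
})

test_that("task goodness-of-fit comparison is a textbook paired t-test", {
  expect_equal(compare_task_fit(c(.5, .6, .7), c(.5, .6, .7)),
               list(t = 0, df = 2, p = 1, mean_diff = 0, degenerate = TRUE))
  set.seed(9)
  a <- runif(13, 0.6, 0.95)
  b <- runif(13, 0.5, 0.9)
  res <- compare_task_fit(a, b)
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(13))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$df, 12)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 12), tolerance = 1e-12)
  const <- compare_task_fit(b + 0.05, b)
  expect_true(const$degenerate)
  expect_error(compare_task_fit(a, b[1:5]), "paired")
})

test_that("Monte-Carlo power is calibrated at zero effect and saturates at large effects", {
  null <- power_mc(0, n_participants = 5, trials_per_cell = 20,
                   n_sim = 250, seed = 31)
  expect_lt(null$power, 12)          # ~alpha = 5% type-I rate
  expect_gt(null$power, 0.5)
  big <- power_mc(6, n_participants = 6, trials_per_cell = 30,
                  n_sim = 60, seed = 32)
  expect_equal(big$power, 100)
  expect_true(all(big$ci >= 0 & big$ci <= 100))
  expect_error(power_mc(1, n_sim = 10), "at least 50")
})

test_that("the judgment-correlation regression recovers a built-in coupling", {
  set.seed(41)
  P <- 10
  b <- rnorm(P, 0, 0.05)
  df <- expand.grid(participant = 1:P, stimulus = paste0("s", 1:6))
  p_cj <- runif(nrow(df), 0.1, 0.9)
  mk_trials <- function(p_resp, task) {
    out <- NULL
    for (i in seq_len(nrow(df))) {
      k <- rbinom(1, 50, p_resp[i])
      out <- rbind(out, data.frame(
        participant = df$participant[i], task = task,
        stimulus = df$stimulus[i],
        response = c(rep(1, k), rep(0, 50 - k))))
    }
    out
  }
  # coupled: TOJ proportions track CJ proportions with slope ~0.6
  p_toj <- pmin(pmax(0.2 + 0.6 * p_cj + b[df$participant], 0.02), 0.98)
  trials <- rbind(mk_trials(p_cj, "causality"),
                  mk_trials(p_toj, "temporal_order"))
  res <- cj_toj_correlation(trials)
  expect_equal(res$beta, 0.6, tolerance = 0.15)
  expect_lt(res$p, 0.001)
  # decoupled: slope indistinguishable from zero
  trials0 <- rbind(mk_trials(p_cj, "causality"),
                   mk_trials(runif(nrow(df), 0.1, 0.9), "temporal_order"))
  res0 <- cj_toj_correlation(trials0)
  expect_gt(res0$p, 0.01)
})
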