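#' @importFrom stats plogis dnorm optim pnorm qt sd cor
NULL

# --- marginal likelihood machinery -----------------------------------------

# Aggregate one task's binary trials into per (participant, stimulus)
# binomial cells.  z is the per-stimulus predictor (z-scored detector
# summary), matched by stimulus label.
.aggregate_cells <- function(trials, predictor) {
  stopifnot(all(c("participant", "stimulus", "response") %in% names(trials)))
  if (!all(trials$response %in% c(0, 1))) {
    stop("responses must be binary 0/1", call. = FALSE)
  }
  parts <- sort(unique(trials$participant))
  stims <- names(predictor)
  if (is.null(stims)) stop("predictor must be named by stimulus", call. = FALSE)
  miss <- setdiff(unique(as.character(trials$stimulus)), stims)
  if (length(miss)) {
    stop("no predictor value for stimulus: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(predictor)) {
    stop("NaN/NA predictor for stimulus: ",
         paste(stims[is.na(predictor)], collapse = ", "), call. = FALSE)
  }
  p_i <- match(trials$participant, parts)
  s_i <- match(as.character(trials$stimulus), stims)
  k <- matrix(0, length(parts), length(stims))
  n <- matrix(0, length(parts), length(stims))
  for (r in seq_len(nrow(trials))) {
    k[p_i[r], s_i[r]] <- k[p_i[r], s_i[r]] + trials$response[r]
    n[p_i[r], s_i[r]] <- n[p_i[r], s_i[r]] + 1
  }
  list(k = k, n = n, z = as.numeric(predictor), participants = parts)
}

# binomial log-likelihood per participant at random intercept b (vector
# over participants): l_p(b_p) = sum_s k log pi + (n - k) log(1 - pi)
.cell_loglik <- function(b, beta0, beta1, cells) {
  eta <- outer(b, beta0 + beta1 * cells$z, `+`)
  # stable log pi, log(1 - pi)
  rowSums(cells$k * stats::plogis(eta, log.p = TRUE) +
            (cells$n - cells$k) * stats::plogis(-eta, log.p = TRUE))
}

# posterior mode and curvature of the random intercept, Newton iterations
# vectorized over participants; b0 warm-starts the search
.intercept_mode <- function(beta0, beta1, sigma, cells, iter = 12L,
                            b0 = NULL) {
  b <- if (is.null(b0)) numeric(nrow(cells$k)) else b0
  for (i in seq_len(iter)) {
    eta <- outer(b, beta0 + beta1 * cells$z, `+`)
    pi <- stats::plogis(eta)
    g <- rowSums(cells$k - cells$n * pi) - b / sigma^2
    h <- -rowSums(cells$n * pi * (1 - pi)) - 1 / sigma^2
    step <- g / h
    b <- b - pmax(pmin(step, 2), -2)  # damped for separation-prone cells
    if (max(abs(step)) < 1e-10) break
  }
  eta <- outer(b, beta0 + beta1 * cells$z, `+`)
  pi <- stats::plogis(eta)
  list(b = b, h = -rowSums(cells$n * pi * (1 - pi)) - 1 / sigma^2)
}

# marginal negative log-likelihood with Gaussian random intercepts
# integrated out by adaptive Gauss-Hermite quadrature (mode-centred,
# curvature-scaled nodes)
.agq_nll <- function(beta0, beta1, sigma, cells, nodes = 15L, warm = NULL) {
  if (!all(is.finite(c(beta0, beta1, sigma))) || sigma < 0) return(Inf)
  if (sigma < 1e-8) {
    return(-sum(.cell_loglik(numeric(nrow(cells$k)), beta0, beta1, cells)))
  }
  gh <- .gh_cache(nodes)
  md <- .intercept_mode(beta0, beta1, sigma, cells,
                        b0 = if (!is.null(warm)) warm$b else NULL)
  if (!is.null(warm)) warm$b <- md$b
  s_hat <- 1 / sqrt(-md$h)
  P <- length(md$b)
  # all nodes at once: rows index (participant, node) pairs
  B <- outer(s_hat * sqrt(2), gh$x) + md$b         # P x J
  eta <- matrix(rep(beta0 + beta1 * cells$z, each = P * nodes),
                P * nodes) + as.vector(B)           # (P*J) x S
  K <- cells$k[rep(seq_len(P), nodes), , drop = FALSE]
  N <- cells$n[rep(seq_len(P), nodes), , drop = FALSE]
  lp <- rowSums(K * stats::plogis(eta, log.p = TRUE) +
                  (N - K) * stats::plogis(-eta, log.p = TRUE))
  logt <- matrix(lp, P, nodes) +
    matrix(log(gh$w) + gh$x^2, P, nodes, byrow = TRUE) +
    stats::dnorm(B, 0, sigma, log = TRUE)
  m <- apply(logt, 1, max)
  ll <- log(sqrt(2) * s_hat) + m + log(rowSums(exp(logt - m)))
  -sum(ll)
}

# memoized Gauss-Hermite nodes/weights
.gh_env <- new.env(parent = emptyenv())
.gh_cache <- function(nodes) {
  key <- as.character(nodes)
  if (is.null(.gh_env[[key]])) .gh_env[[key]] <- pracma::gaussHermite(nodes)
  .gh_env[[key]]
}

#' Marginal negative log-likelihood of a mixed logistic psychometric model
#'
#' Computes the negative marginal log-likelihood of binary responses under
#' a logistic model `logit P(response = 1) = beta0 + beta1 * z(stimulus) +
#' b(participant)`, with Gaussian participant random intercepts
#' `b ~ N(0, sigma^2)` integrated out by adaptive Gauss-Hermite quadrature.
#'
#' @param beta0,beta1 intercept and slope of the logistic link.
#' @param sigma standard deviation of the participant random intercepts
#'   (0 collapses to an ordinary logistic likelihood).
#' @param trials data.frame with columns `participant`, `stimulus`,
#'   `response` (0/1) for one task.
#' @param predictor named numeric vector: z-scored detector summary per
#'   stimulus label.
#' @param nodes quadrature nodes (default 15).
#' @return negative log-likelihood (finite for finite parameters).
#' @examples
#' tr <- data.frame(participant = 1, stimulus = rep(c("a", "b"), each = 2),
#'                  response = c(0, 1, 1, 0))
#' nll_mixed_logistic(0, 0, 0, tr, c(a = -1, b = 1))  # 4 * log(2)
#' @export
nll_mixed_logistic <- function(beta0, beta1, sigma, trials, predictor,
                               nodes = 15L) {
  cells <- .aggregate_cells(trials, predictor)
  .agq_nll(beta0, beta1, sigma, cells, nodes = nodes)
}

# ML fit of (beta0, beta1, log sigma) on binomial cells; Nelder-Mead with a
# moment-based warm start, optional Wald covariance from the numeric Hessian
.fit_cell_logistic <- function(cells, start = NULL, nodes = 15L,
                               hessian = FALSE, maxit = 250L) {
  if (is.null(start)) {
    # moment start: pooled logistic regression ignoring the random effect,
    # sigma from the spread of per-participant mean logits
    p_cell <- (cells$k + 0.5) / (cells$n + 1)
    p_hat <- pmin(pmax(colSums(cells$k) / pmax(colSums(cells$n), 1),
                       0.02), 0.98)
    co <- stats::coef(stats::lm(stats::qlogis(p_hat) ~ cells$z))
    dev_p <- rowMeans(stats::qlogis(p_cell)) - mean(stats::qlogis(p_cell))
    s0 <- min(max(stats::sd(dev_p), 0.1), 2)
    start <- c(co[1], co[2], log(s0))
  }
  warm <- new.env(parent = emptyenv())
  fn <- function(par) .agq_nll(par[1], par[2], exp(par[3]), cells,
                               nodes = nodes, warm = warm)
  fit <- stats::optim(start, fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8))
  out <- list(beta0 = unname(fit$par[1]), beta1 = unname(fit$par[2]),
              sigma = unname(exp(fit$par[3])), nll = fit$value,
              convergence = fit$convergence, par = unname(fit$par))
  if (hessian) {
    # Hessian in (beta0, beta1, log sigma) space: sigma can sit near its
    # boundary and the slope SE is invariant to the reparametrization
    H <- stats::optimHess(fit$par, fn)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) < 0)) {
      # fall back to the fixed-effect block with log sigma held fixed
      Hb <- H[1:2, 1:2]
      V <- matrix(NA_real_, 3, 3)
      Vb <- tryCatch(solve(Hb), error = function(e) matrix(NA_real_, 2, 2))
      V[1:2, 1:2] <- Vb
    }
    out$se <- unname(sqrt(pmax(diag(V)[1:2], 0)))
    out$z_slope <- out$beta1 / out$se[2]
    out$p_slope <- 2 * stats::pnorm(-abs(out$z_slope))
  }
  out
}

# --- joint detector + link fit ---------------------------------------------

.split_tasks <- function(trials) {
  tasks <- c("causality", "temporal_order")
  if (!all(tasks %in% unique(trials$task))) {
    stop("both tasks (causality, temporal_order) must be present: the ",
         "detector time constants are fitted jointly", call. = FALSE)
  }
  lapply(stats::setNames(tasks, tasks), function(tk) {
    trials[trials$task == tk, , drop = FALSE]
  })
}

# per-task predictor at candidate time constants: corr_z drives causality,
# lag_z drives temporal order
.task_predictors <- function(stimuli, params, rate, window) {
  sm <- mcd_stimulus_summaries(stimuli, params, rate = rate, window = window)
  list(causality = stats::setNames(sm$corr_z, sm$label),
       temporal_order = stats::setNames(sm$lag_z, sm$label),
       summaries = sm)
}

# basic global-best particle swarm on a box; deterministic given the RNG
# state on entry
.pso <- function(fn, lower, upper, n_particles = 10L, iters = 20L,
                 inertia = 0.72, c1 = 1.5, c2 = 1.5) {
  d <- length(lower)
  X <- sapply(seq_len(d), function(j) stats::runif(n_particles, lower[j],
                                                   upper[j]))
  V <- sapply(seq_len(d), function(j) {
    stats::runif(n_particles, -1, 1) * (upper[j] - lower[j]) / 4
  })
  f <- apply(X, 1, fn)
  Pb <- X
  fPb <- f
  g <- which.min(f)
  gx <- X[g, ]
  gf <- f[g]
  for (it in seq_len(iters)) {
    r1 <- matrix(stats::runif(n_particles * d), n_particles, d)
    r2 <- matrix(stats::runif(n_particles * d), n_particles, d)
    V <- inertia * V + c1 * r1 * (Pb - X) +
      c2 * r2 * matrix(gx, n_particles, d, byrow = TRUE) - c2 * r2 * X
    X <- X + V
    X <- pmin(pmax(X, matrix(lower, n_particles, d, byrow = TRUE)),
              matrix(upper, n_particles, d, byrow = TRUE))
    f <- apply(X, 1, fn)
    upd <- f < fPb
    Pb[upd, ] <- X[upd, , drop = FALSE]
    fPb[upd] <- f[upd]
    g <- which.min(fPb)
    if (fPb[g] < gf) {
      gf <- fPb[g]
      gx <- Pb[g, ]
    }
  }
  list(par = gx, value = gf)
}

#' Jointly fit detector time constants and task-specific logistic links
#'
#' Maximum-likelihood fit of the seven fixed parameters of the behavioral
#' model: the three detector time constants (shared across tasks) and an
#' intercept and slope of the logistic link per task (causality judgments
#' driven by the z-scored correlation output, temporal-order judgments by
#' the z-scored lag output), with Gaussian participant random intercepts
#' whose standard deviations are estimated as per-task nuisance
#' parameters.  The optimizer is a particle swarm over the (log) time
#' constants with the link parameters profiled out at each evaluation,
#' followed by Nelder-Mead refinement of the full joint vector; the whole
#' procedure is restarted `n_restarts` times and the best fit kept.
#'
#' @param trials trial table with columns `participant`, `task`
#'   (`causality` / `temporal_order`), `stimulus`, `response` (0/1).
#' @param stimuli list of `event_sequence`s; labels must match
#'   `trials$stimulus`.
#' @param n_restarts number of independent swarm restarts (best kept).
#' @param seed RNG seed; the fit is deterministic given it.
#' @param rate detector simulation rate (Hz).
#' @param window averaging window (s).
#' @param tau_bounds search bounds for all three time constants (ms).
#' @param control list: `n_particles`, `swarm_iters`, `refine_maxit`,
#'   `nodes` (quadrature nodes).
#' @return An object of class `behavior_fit`: `mcd_params`, per-task
#'   `link` data.frame (beta0, beta1, sigma), random-intercept modes,
#'   `loglik`, per-restart NLLs, per-participant-by-task `r2`, and the
#'   fitted stimulus summaries.
#' @export
fit_mcd_behavior <- function(trials, stimuli, n_restarts = 10, seed = 1,
                             rate = 1000, window = 3,
                             tau_bounds = c(10, 2000), control = list()) {
  ctl <- utils::modifyList(list(n_particles = 10L, swarm_iters = 20L,
                                refine_maxit = 200L, nodes = 15L), control)
  by_task <- .split_tasks(trials)
  cells <- list()
  # cells are predictor-independent; only z changes with the taus
  prep <- .task_predictors(stimuli, mcd_default_params(), rate, window)
  for (tk in names(by_task)) {
    cells[[tk]] <- .aggregate_cells(by_task[[tk]], prep[[tk]])
  }
  warm <- list(causality = NULL, temporal_order = NULL)
  objective <- function(log_tau) {
    params <- mcd_params(exp(log_tau[1]), exp(log_tau[2]), exp(log_tau[3]))
    pred <- .task_predictors(stimuli, params, rate, window)
    total <- 0
    fits <- list()
    for (tk in names(cells)) {
      cl <- cells[[tk]]
      cl$z <- as.numeric(pred[[tk]])  # same stimulus order as aggregation
      ft <- .fit_cell_logistic(cl, start = warm[[tk]], nodes = ctl$nodes,
                               maxit = 250L)
      warm[[tk]] <<- ft$par
      fits[[tk]] <- ft
      total <- total + ft$nll
    }
    attr(total, "fits") <- fits
    total
  }
  lb <- log(rep(tau_bounds[1], 3))
  ub <- log(rep(tau_bounds[2], 3))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  best <- NULL
  restart_nll <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, "behavior_fit") + r)
    warm <- list(causality = NULL, temporal_order = NULL)
    sw <- .pso(function(p) as.numeric(objective(p)), lb, ub,
               n_particles = ctl$n_particles, iters = ctl$swarm_iters)
    # joint refinement: log taus + (beta0, beta1, log sigma) per task
    obj_at <- objective(sw$par)
    fits <- attr(obj_at, "fits")
    full0 <- c(sw$par, fits$causality$par, fits$temporal_order$par)
    joint <- function(par) {
      if (any(par[1:3] < lb) || any(par[1:3] > ub)) return(Inf)
      params <- mcd_params(exp(par[1]), exp(par[2]), exp(par[3]))
      pred <- .task_predictors(stimuli, params, rate, window)
      cl1 <- cells$causality
      cl1$z <- as.numeric(pred$causality)
      cl2 <- cells$temporal_order
      cl2$z <- as.numeric(pred$temporal_order)
      .agq_nll(par[4], par[5], exp(par[6]), cl1, nodes = ctl$nodes) +
        .agq_nll(par[7], par[8], exp(par[9]), cl2, nodes = ctl$nodes)
    }
    ref <- stats::optim(full0, joint, method = "Nelder-Mead",
                        control = list(maxit = ctl$refine_maxit,
                                       reltol = 1e-8))
    restart_nll[r] <- ref$value
    if (is.null(best) || ref$value < best$value) best <- ref
  }
  par <- best$par
  params <- mcd_params(exp(par[1]), exp(par[2]), exp(par[3]))
  pred <- .task_predictors(stimuli, params, rate, window)
  link <- data.frame(
    task = c("causality", "temporal_order"),
    beta0 = c(par[4], par[7]), beta1 = c(par[5], par[8]),
    sigma = c(exp(par[6]), exp(par[9]))
  )
  ranef <- list()
  for (i in 1:2) {
    tk <- link$task[i]
    cl <- cells[[tk]]
    cl$z <- as.numeric(pred[[tk]])
    md <- .intercept_mode(link$beta0[i], link$beta1[i],
                          max(link$sigma[i], 1e-6), cl)
    ranef[[tk]] <- stats::setNames(md$b, cl$participants)
  }
  fit <- structure(list(
    mcd_params = params, link = link, random_intercepts = ranef,
    loglik = -best$value, nll_by_restart = restart_nll,
    n_restarts_used = n_restarts, summaries = pred$summaries,
    seed = seed
  ), class = "behavior_fit")
  fit$r2 <- pseudo_r2(fit, trials)
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.behavior_fit <- function(x, ...) {
  cat("<behavior_fit>\n")
  cat(sprintf("  tau_A = %.1f ms, tau_V = %.1f ms, tau_AV = %.1f ms\n",
              x$mcd_params$tau_a, x$mcd_params$tau_v, x$mcd_params$tau_av))
  for (i in seq_len(nrow(x$link))) {
    cat(sprintf("  %s: beta0 = %.3f, beta1 = %.3f, sigma = %.3f\n",
                x$link$task[i], x$link$beta0[i], x$link$beta1[i],
                x$link$sigma[i]))
  }
  cat(sprintf("  logLik = %.3f (best of %d restarts)\n", x$loglik,
              x$n_restarts_used))
  invisible(x)
}

#' Per-participant goodness of fit of the behavioral model
#'
#' Squared Pearson correlation between predicted and observed per-stimulus
#' response proportions, computed separately for each participant and
#' task.  Predictions use the fixed effects plus the participant's
#' random-intercept mode.
#'
#' @param fit a `behavior_fit`.
#' @param trials the trial table the model was fitted to.
#' @return data.frame with columns `participant`, `task`, `r2` (`NA` with a
#'   warning when the observed proportions have zero variance).
#' @export
pseudo_r2 <- function(fit, trials) {
  stopifnot(inherits(fit, "behavior_fit"))
  by_task <- .split_tasks(trials)
  sm <- fit$summaries
  out <- NULL
  for (i in seq_len(nrow(fit$link))) {
    tk <- fit$link$task[i]
    zcol <- if (tk == "causality") "corr_z" else "lag_z"
    pred_z <- stats::setNames(sm[[zcol]], sm$label)
    cl <- .aggregate_cells(by_task[[tk]], pred_z)
    b <- fit$random_intercepts[[tk]][as.character(cl$participants)]
    for (p in seq_along(cl$participants)) {
      obs <- cl$k[p, ] / cl$n[p, ]
      prd <- stats::plogis(fit$link$beta0[i] + b[p] +
                             fit$link$beta1[i] * cl$z)
      keep <- cl$n[p, ] > 0
      r2 <- if (stats::sd(obs[keep]) == 0) {
        warning("zero variance in observed proportions for participant ",
                cl$participants[p], " (", tk, "); r2 undefined")
        NA_real_
      } else {
        stats::cor(obs[keep], prd[keep])^2
      }
      out <- rbind(out, data.frame(participant = cl$participants[p],
                                   task = tk, r2 = r2))
    }
  }
  out
}

#' Paired comparison of goodness of fit across tasks
#'
#' Paired t-test on per-participant R-squared values between the two
#' tasks.
#'
#' @param r2_causality,r2_temporal per-participant R-squared vectors,
#'   paired by participant.
#' @return list with `t`, `df`, `p`, `mean_diff`, and `degenerate` flag
#'   (zero-variance differences).
#' @export
compare_task_fit <- function(r2_causality, r2_temporal) {
  if (length(r2_causality) != length(r2_temporal)) {
    stop("R-squared vectors must be paired by participant", call. = FALSE)
  }
  d <- r2_causality - r2_temporal
  n <- length(d)
  if (stats::sd(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = n - 1, p = if (mean(d) == 0) 1 else 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(r2_causality, r2_temporal, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Monte-Carlo observational power analysis
#'
#' Simulates datasets of the study design (participants x stimuli x
#' trials, logistic responses driven by a z-scored detector summary with
#' Gaussian participant random intercepts), refits the mixed logistic
#' model to each, and estimates power as the fraction of simulations in
#' which the Wald test on the fixed slope is significant.  The confidence
#' interval on power is the exact Clopper-Pearson binomial interval.
#'
#' @param beta true fixed-effect slope (e.g. 1.80 for causality, 1.02 for
#'   temporal order).
#' @param n_participants number of participants (study: 13).
#' @param trials_per_cell trials per participant-stimulus cell (study: 75).
#' @param predictor z-scored per-stimulus predictor values; defaults to
#'   the packaged six-stimulus correlation z-scores.
#' @param beta0 true intercept.
#' @param sigma_b random-intercept standard deviation.
#' @param n_sim number of simulated datasets (>= 50).
#' @param alpha significance level of the two-sided Wald test.
#' @param seed RNG seed.
#' @return list with `power` (%), `ci` (95% CI in %), `n_significant`,
#'   `n_sim`.
#' @export
power_mc <- function(beta, n_participants = 13, trials_per_cell = 75,
                     predictor = NULL, beta0 = 0, sigma_b = 0.5,
                     n_sim = 500, alpha = 0.05, seed = 1) {
  if (n_sim < 50) stop("n_sim must be at least 50", call. = FALSE)
  if (is.null(predictor)) {
    sm <- mcd_stimulus_summaries(packaged_stimulus_set())
    predictor <- sm$corr_z
  }
  S <- length(predictor)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "power"))
  sig <- logical(n_sim)
  cells <- list(k = matrix(0, n_participants, S),
                n = matrix(trials_per_cell, n_participants, S),
                z = as.numeric(predictor),
                participants = seq_len(n_participants))
  for (s in seq_len(n_sim)) {
    b <- stats::rnorm(n_participants, 0, sigma_b)
    pi <- stats::plogis(outer(b, beta0 + beta * cells$z, `+`))
    cells$k <- matrix(stats::rbinom(n_participants * S, trials_per_cell, pi),
                      n_participants, S)
    ft <- tryCatch(
      .fit_cell_logistic(cells, hessian = TRUE),
      error = function(e) NULL
    )
    sig[s] <- !is.null(ft) && is.finite(ft$p_slope) && ft$p_slope < alpha
  }
  n_sig <- sum(sig)
  ci <- stats::binom.test(n_sig, n_sim)$conf.int
  list(power = 100 * n_sig / n_sim, ci = 100 * as.numeric(ci),
       n_significant = n_sig, n_sim = n_sim)
}

#' Correlation between causality and temporal-order judgments
#'
#' Regresses per-participant-per-stimulus temporal-order response
#' proportions on the matching causality proportions with a participant
#' random intercept, quantifying how far the two judgments covary across
#' stimuli (the stimulus set is designed to keep this weak).  Computing
#' the relation on proportions rather than trials is an interpretation;
#' see the methods vignette.
#'
#' @param trials trial table containing both tasks.
#' @return list with `beta` (slope), `se`, `p` (Satterthwaite), and the
#'   underlying proportion table.
#' @export
cj_toj_correlation <- function(trials) {
  by_task <- .split_tasks(trials)
  prop <- function(tab) {
    agg <- stats::aggregate(response ~ participant + stimulus, tab, mean)
    agg
  }
  cj <- prop(by_task$causality)
  toj <- prop(by_task$temporal_order)
  names(cj)[3] <- "p_cj"
  names(toj)[3] <- "p_toj"
  df <- merge(cj, toj, by = c("participant", "stimulus"))
  m <- lmerTest::lmer(p_toj ~ p_cj + (1 | participant), data = df,
                      REML = FALSE)
  cs <- summary(m)$coefficients
  list(beta = cs["p_cj", "Estimate"], se = cs["p_cj", "Std. Error"],
       p = cs["p_cj", "Pr(>|t|)"], proportions = df)
}

#' Serialize a behavior fit to JSON
#'
#' @param fit a `behavior_fit`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_behavior_fit <- function(fit, path) {
  stopifnot(inherits(fit, "behavior_fit"))
  obj <- list(
    mcd_params = unclass(fit$mcd_params), link = fit$link,
    random_intercepts = lapply(fit$random_intercepts, as.list),
    loglik = fit$loglik, nll_by_restart = fit$nll_by_restart,
    n_restarts_used = fit$n_restarts_used, seed = fit$seed,
    summaries = fit$summaries, r2 = fit$r2
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
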