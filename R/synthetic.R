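#' Ground truth for synthetic data generation
#'
#' Bundles everything needed to generate behavioral and neural datasets
#' with known structure: per-participant detector time constants
#' (defaulting to the fitted study values), per-task logistic link
#' parameters, true temporal response functions per sensor and detector
#' component, per-sensor unisensory mixing weights, and the noise model.
#'
#' @param n_participants number of participants.
#' @param mcd_params data.frame with columns `participant`, `tau_a`,
#'   `tau_v`, `tau_av` (ms); defaults to the first `n_participants` rows of
#'   [mcd_fitted_params()].
#' @param link data.frame with columns `task`, `beta0`, `beta1`; defaults
#'   to the study effect sizes (slope 1.80 on the correlation z-score for
#'   causality, 1.02 on the lag z-score for temporal order, intercepts 0).
#' @param sigma_b random-intercept standard deviation.
#' @param trf_true sensor x component x lag array of true response
#'   functions; defaults to damped-oscillation kernels built by
#'   [damped_oscillation_trf()] when epochs are simulated.
#' @param unisensory data.frame with per-sensor attenuation weights
#'   `beta_a`, `beta_v` applied to the unisensory responses in the task
#'   context; defaults are drawn when epochs are simulated.
#' @param topography data.frame with per-sensor unisensory response
#'   amplitudes `topo_a`, `topo_v` (shared between localizer and task
#'   blocks); defaults are drawn when epochs are simulated.
#' @param snr signal-to-noise variance ratio of simulated epochs.
#' @param noise `"white"` or `"pink"` (1/f) sensor noise.
#' @param seed base seed; all generation derives from it.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(n_participants = 13, mcd_params = NULL, link = NULL,
                         sigma_b = 0.5, trf_true = NULL, unisensory = NULL,
                         topography = NULL, snr = 5,
                         noise = c("white", "pink"), seed = 1) {
  noise <- match.arg(noise)
  if (is.null(mcd_params)) {
    mcd_params <- utils::head(mcd_fitted_params(), n_participants)
    if (n_participants > 13) {
      extra <- mcd_fitted_params()[rep(1:13, length.out = n_participants - 13), ]
      extra$participant <- 14:n_participants
      mcd_params <- rbind(mcd_params, extra)
    }
  }
  if (is.null(link)) {
    link <- data.frame(task = c("causality", "temporal_order"),
                       beta0 = c(0, 0), beta1 = c(1.80, 1.02))
  }
  structure(list(n_participants = n_participants, mcd_params = mcd_params,
                 link = link, sigma_b = sigma_b, trf_true = trf_true,
                 unisensory = unisensory, topography = topography, snr = snr,
                 noise = noise, seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth: %d participants, SNR %g, %s noise, seed %d>\n",
              x$n_participants, x$snr, x$noise, x$seed))
  invisible(x)
}

#' Serialize / restore a ground truth as JSON
#' @param truth a `ground_truth`.
#' @param path JSON path.
#' @return `path` / the restored object.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- unclass(truth)
  if (!is.null(obj$trf_true)) {
    obj$trf_dim <- dim(obj$trf_true)
    obj$trf_true <- as.numeric(obj$trf_true)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$trf_true)) {
    obj$trf_true <- array(obj$trf_true, dim = obj$trf_dim)
    obj$trf_dim <- NULL
  }
  obj$mcd_params <- as.data.frame(obj$mcd_params)
  obj$link <- as.data.frame(obj$link)
  class(obj) <- "ground_truth"
  obj
}

# shuffle with bounded run length: no stimulus more than max_run times in
# a row, by resampling offending tails
.constrained_order <- function(items, max_run = 3L, max_tries = 200L) {
  for (tr in seq_len(max_tries)) {
    x <- sample(items)
    r <- rle(x)
    if (max(r$lengths) <= max_run) return(x)
  }
  stop("could not satisfy the run-length constraint", call. = FALSE)
}

#' Build the factorial trial design
#'
#' Generates the full trial listing of the study design: per participant,
#' `blocks` blocks of `reps` repetitions of each stimulus for each of the
#' two tasks, plus `localizer_blocks` passive blocks per modality with
#' `reps` repetitions of each stimulus.  Within every block the stimulus
#' order is pseudo-random with no stimulus occurring more than `max_run`
#' times consecutively.  With the defaults this yields
#' 2 x 3 x 25 x 6 + 2 x 25 x 2 x 6 = 1500 trials per participant and 75
#' presentations of each stimulus per task.
#'
#' @param n_participants participants (study: 13).
#' @param reps repetitions of each stimulus per block (study: 25).
#' @param blocks task blocks per task (study: 3).
#' @param localizer_blocks passive blocks per modality (study: 2).
#' @param stimuli stimulus labels or a count (study: 6).
#' @param max_run maximum consecutive repeats of one stimulus.
#' @param seed RNG seed.
#' @return data.frame with columns `participant`, `task`, `block`,
#'   `stimulus`, `trial` (index within participant); responses unset.
#' @export
make_design <- function(n_participants = 13, reps = 25, blocks = 3,
                        localizer_blocks = 2, stimuli = 6, max_run = 3L,
                        seed = 1) {
  if (length(stimuli) == 1L && is.numeric(stimuli)) {
    stimuli <- sprintf("seq-%02d", seq_len(stimuli))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "design"))
  rows <- list()
  for (p in seq_len(n_participants)) {
    ptrials <- list()
    for (task in c("causality", "temporal_order")) {
      for (b in seq_len(blocks)) {
        ord <- .constrained_order(rep(stimuli, reps), max_run)
        ptrials[[length(ptrials) + 1L]] <-
          data.frame(participant = p, task = task,
                     block = paste0(substr(task, 1, 1), b), stimulus = ord)
      }
    }
    for (mod in c("A", "V")) {
      for (b in seq_len(localizer_blocks)) {
        ord <- .constrained_order(rep(stimuli, reps), max_run)
        ptrials[[length(ptrials) + 1L]] <-
          data.frame(participant = p, task = paste0("localizer_", mod),
                     block = paste0("loc", mod, b), stimulus = ord)
      }
    }
    tab <- do.call(rbind, ptrials)
    tab$trial <- seq_len(nrow(tab))
    rows[[p]] <- tab
  }
  do.call(rbind, rows)
}

#' Simulate behavioral responses of model observers
#'
#' Draws Bernoulli responses for the task trials of a design from the
#' generative model `logit P(1) = beta0_task + beta1_task * z + b_p`, where
#' `z` is the participant-specific z-scored detector summary of the
#' stimulus (correlation for causality, lag for temporal order) and `b_p`
#' the participant's Gaussian random intercept.  Localizer trials get `NA`
#' responses.
#'
#' @param truth a `ground_truth`.
#' @param design trial design from [make_design()].
#' @param stimuli list of `event_sequence`s whose labels match the design.
#' @param rate detector simulation rate (Hz).
#' @param seed RNG seed (defaults to the truth's).
#' @return the design with a `response` column (coded 1 for "same cause" /
#'   "visual first").
#' @export
simulate_observer <- function(truth, design, stimuli, rate = 1000,
                              seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "observer"))
  parts <- sort(unique(design$participant))
  b <- stats::rnorm(length(parts), 0, truth$sigma_b)
  names(b) <- parts
  # participant-specific summaries (time constants differ per observer)
  zmap <- list()
  for (p in parts) {
    pr <- truth$mcd_params[truth$mcd_params$participant == p, ]
    sm <- mcd_stimulus_summaries(
      stimuli, mcd_params(pr$tau_a, pr$tau_v, pr$tau_av), rate = rate)
    zmap[[as.character(p)]] <- list(
      causality = stats::setNames(sm$corr_z, sm$label),
      temporal_order = stats::setNames(sm$lag_z, sm$label))
  }
  link <- truth$link
  design$response <- NA_real_
  for (tk in c("causality", "temporal_order")) {
    li <- link[link$task == tk, ]
    sel <- which(design$task == tk)
    z <- vapply(sel, function(i) {
      zmap[[as.character(design$participant[i])]][[tk]][[
        as.character(design$stimulus[i])]]
    }, 0)
    eta <- li$beta0 + li$beta1 * z + b[as.character(design$participant[sel])]
    design$response[sel] <- stats::rbinom(length(sel), 1, stats::plogis(eta))
  }
  design
}

#' Planar sensor layout with 8-neighborhood adjacency
#'
#' Places `n_sensors` on a near-square planar grid and connects each
#' sensor to its (up to 8) touching neighbors.  Used as the synthetic
#' stand-in for a real sensor array geometry.
#'
#' @param n_sensors sensor count (default 102, the virtual-magnetometer
#'   count of the study recordings).
#' @param ncol grid columns; rows are `ceiling(n_sensors / ncol)`.
#' @return list with `positions` (data.frame `sensor`, `x`, `y`) and
#'   `adjacency` (symmetric logical matrix, zero diagonal).
#' @export
make_layout <- function(n_sensors = 102, ncol = ceiling(sqrt(n_sensors))) {
  nrow <- ceiling(n_sensors / ncol)
  idx <- seq_len(n_sensors) - 1L
  x <- idx %% ncol
  y <- idx %/% ncol
  names <- sprintf("S%03d", seq_len(n_sensors))
  adj <- matrix(FALSE, n_sensors, n_sensors, dimnames = list(names, names))
  for (i in seq_len(n_sensors)) {
    near <- which(abs(x - x[i]) <= 1 & abs(y - y[i]) <= 1)
    near <- setdiff(near, i)
    adj[i, near] <- TRUE
  }
  list(positions = data.frame(sensor = names, x = x, y = y),
       adjacency = adj)
}

#' Damped-oscillation response function bank
#'
#' Builds a sensor x component x lag array of ground-truth temporal
#' response functions, each a damped oscillation
#' `a * exp(-t / decay) * sin(2 pi f t)` with per-sensor random amplitude,
#' frequency and decay.  Sensors listed in `silent` get all-zero filters
#' for a component, letting attribution tests target specific sensors.
#'
#' @param n_sensors,n_components,n_lags array dimensions.
#' @param rate sampling rate (Hz) of the lag axis.
#' @param amplitude peak scale.
#' @param silent optional list mapping component index to sensor indices
#'   whose filter for that component is zero.
#' @return numeric array `sensor x component x lag`.
#' @export
damped_oscillation_trf <- function(n_sensors, n_components, n_lags,
                                   rate = 250, amplitude = 1,
                                   silent = NULL) {
  t <- (seq_len(n_lags) - 1) / rate
  out <- array(0, dim = c(n_sensors, n_components, n_lags))
  for (n in seq_len(n_sensors)) {
    for (i in seq_len(n_components)) {
      a <- amplitude * stats::runif(1, 0.5, 1.5)
      f <- stats::runif(1, 2, 8)
      decay <- stats::runif(1, 0.05, 0.2)
      out[n, i, ] <- a * exp(-t / decay) * sin(2 * pi * f * t)
    }
  }
  if (!is.null(silent)) {
    for (i in names(silent)) out[silent[[i]], as.integer(i), ] <- 0
  }
  out
}

# detector component traces (MCD_A, MCD_V, CORR, LAG) for one stimulus on
# the epoch grid [window[1], window[2]) at `rate`; t = 0 is the first event
.component_traces <- function(seq, params, rate, window) {
  enc <- encode_events(seq, rate = rate,
                       horizon = max(seq$duration, window[2]) + 0.5)
  resp <- mcd_respond(enc$s_a, enc$s_v, params)
  n <- round((window[2] - window[1]) * rate)
  i0 <- round(window[1] * rate)  # relative to t = 0
  idx <- i0 + seq_len(n)
  pick <- function(tr) {
    out <- numeric(n)
    ok <- idx >= 1 & idx <= length(tr)
    out[ok] <- tr[idx[ok]]
    out
  }
  cbind(mcd_a = pick(resp$mcd_a), mcd_v = pick(resp$mcd_v),
        corr = pick(resp$corr), lag = pick(resp$lag))
}

# unisensory evoked template: event train convolved with a fixed
# damped-oscillation evoked kernel
.unisensory_trace <- function(onsets, rate, window, f = 10, decay = 0.08) {
  n <- round((window[2] - window[1]) * rate)
  t_axis <- window[1] + (seq_len(n) - 1) / rate
  out <- numeric(n)
  kl <- round(0.4 * rate)
  kt <- (seq_len(kl) - 1) / rate
  kern <- exp(-kt / decay) * sin(2 * pi * f * kt)
  for (o in onsets) {
    i <- round((o - window[1]) * rate) + 1L
    j <- min(i + kl - 1L, n)
    if (j >= 1 && i <= n) {
      a <- max(i, 1L)
      out[a:j] <- out[a:j] + kern[seq_len(j - a + 1L) + (a - i)]
    }
  }
  out
}

#' Simulate multichannel epoched recordings
#'
#' Generates an `epoch_set` for the task and localizer trials of a design.
#' Localizer epochs carry the unisensory evoked response
#' `topo(n) * uni(t)` plus noise; task epochs carry the sum of the true
#' response functions convolved with the stimulus's detector component
#' time courses, the attenuation-weighted unisensory responses
#' `beta_A(n) topo_a(n) aud(t) + beta_V(n) topo_v(n) vis(t)`, and noise
#' scaled to the requested signal-to-noise variance ratio, so that the
#' unisensory-removal regression of task on localizer evoked responses
#' recovers `beta_A(n)`, `beta_V(n)`.  Amplitudes are on a tesla-like
#' 1e-13 scale.
#'
#' @param truth a `ground_truth`; its `trf_true` and `unisensory` slots are
#'   filled with defaults (and returned in the attribute `"truth"`) when
#'   unset.
#' @param design trial design (see [make_design()]); may be a subset.
#' @param stimuli list of `event_sequence`s.
#' @param layout sensor layout from [make_layout()].
#' @param rate epoch sampling rate (Hz).
#' @param window epoch window (s), half-open.
#' @param n_lags true response-function length (samples).
#' @param scale physical amplitude scale applied to all signals.
#' @param multi_gain power of the multisensory component relative to the
#'   unisensory part (1 = equal average power); applied by rescaling the
#'   auto-generated response-function bank, so the stored ground truth
#'   stays consistent with the data.  User-supplied `trf_true` banks are
#'   used as given.
#' @param orthogonalize_multisensory project the multisensory component
#'   out of the span of the unisensory traces per sensor and stimulus, so
#'   that the separability assumption of the removal regression holds
#'   exactly; the default leaves the natural temporal overlap in place.
#' @param seed RNG seed (defaults to the truth's).
#' @return An `epoch_set`; attribute `"truth"` carries the completed
#'   ground truth (with the realized `trf_true`, unisensory weights and
#'   topography).
#' @export
simulate_epochs <- function(truth, design, stimuli, layout = make_layout(12),
                            rate = 250, window = c(-0.2, 1.8), n_lags = 50,
                            scale = 1e-13, multi_gain = 1,
                            orthogonalize_multisensory = FALSE,
                            seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "epochs"))
  n_sensors <- nrow(layout$positions)
  auto_trf <- is.null(truth$trf_true)
  if (auto_trf) {
    truth$trf_true <- damped_oscillation_trf(n_sensors, 4, n_lags, rate)
  }
  if (is.null(truth$unisensory)) {
    truth$unisensory <- data.frame(beta_a = stats::runif(n_sensors, 0.3, 1.2),
                                   beta_v = stats::runif(n_sensors, 0.3, 1.2))
  }
  if (is.null(truth$topography)) {
    truth$topography <- data.frame(topo_a = stats::runif(n_sensors, 0.5, 2),
                                   topo_v = stats::runif(n_sensors, 0.5, 2))
  }
  n_t <- round((window[2] - window[1]) * rate)
  labels <- vapply(stimuli, `[[`, "", "label")
  parts <- sort(unique(design$participant))
  # deterministic part per participant x stimulus x condition-type
  templates <- list()
  for (p in parts) {
    pr <- truth$mcd_params[truth$mcd_params$participant == p, ]
    par_p <- mcd_params(pr$tau_a, pr$tau_v, pr$tau_av)
    for (s in seq_along(stimuli)) {
      sq <- stimuli[[s]]
      t0 <- first_onset(sq)
      comp <- .component_traces(sq, par_p, rate, window + t0)
      # standardize components so each contributes comparable variance
      # (note: the `scale` argument shadows base::scale here)
      comp <- apply(comp, 2, function(v) {
        s <- stats::sd(v)
        if (s == 0) numeric(length(v)) else (v - mean(v)) / s
      })
      aud <- .unisensory_trace(sq$auditory_onsets - t0, rate, window)
      vis <- .unisensory_trace(sq$visual_onsets - t0, rate, window)
      multi <- matrix(0, n_sensors, n_t)
      for (i in 1:4) {
        ci <- comp[, i]
        for (n in seq_len(n_sensors)) {
          w <- truth$trf_true[n, i, ]
          if (any(w != 0)) {
            y <- stats::filter(ci, w, method = "convolution", sides = 1)
            y <- as.numeric(y)
            y[is.na(y)] <- 0
            multi[n, ] <- multi[n, ] + y
          }
        }
      }
      loc_a <- outer(truth$topography$topo_a, aud)
      loc_v <- outer(truth$topography$topo_v, vis)
      if (orthogonalize_multisensory) {
        for (n in seq_len(n_sensors)) {
          X <- cbind(loc_a[n, ], loc_v[n, ])
          if (any(X != 0)) {
            multi[n, ] <- multi[n, ] - X %*% qr.solve(X, multi[n, ])
          }
        }
      }
      uni <- truth$unisensory$beta_a * loc_a + truth$unisensory$beta_v * loc_v
      key <- function(type) paste(p, labels[s], type, sep = "|")
      task_tpl <- multi + uni
      attr(task_tpl, "multi") <- multi
      attr(task_tpl, "uni") <- uni
      templates[[key("task")]] <- task_tpl
      templates[[key("A")]] <- loc_a
      templates[[key("V")]] <- loc_v
    }
  }
  if (auto_trf) {
    # balance the multisensory power against the unisensory part so both
    # survive at the same noise level
    task_keys <- grep("\\|task$", names(templates), value = TRUE)
    v_multi <- mean(vapply(task_keys, function(k) {
      mean(attr(templates[[k]], "multi")^2)
    }, 0))
    v_uni <- mean(vapply(task_keys, function(k) {
      mean(attr(templates[[k]], "uni")^2)
    }, 0))
    if (v_multi > 0) {
      g <- sqrt(multi_gain * max(v_uni, 1e-12) / v_multi)
      truth$trf_true <- truth$trf_true * g
      for (k in task_keys) {
        m <- attr(templates[[k]], "multi") * g
        u <- attr(templates[[k]], "uni")
        new <- m + u
        attr(new, "multi") <- m
        attr(new, "uni") <- u
        templates[[k]] <- new
      }
    }
  }
  type_of <- function(task) switch(task, localizer_A = "A",
                                   localizer_V = "V", "task")
  # trial-weighted mean signal power, so the realized epoch-set
  # signal-to-noise variance ratio matches the requested one
  trial_keys <- vapply(seq_len(nrow(design)), function(r) {
    paste(design$participant[r], design$stimulus[r],
          type_of(design$task[r]), sep = "|")
  }, "")
  sig_var <- mean(vapply(trial_keys, function(k) mean(templates[[k]]^2), 0))
  noise_sd <- sqrt(sig_var / truth$snr)
  n_trials <- nrow(design)
  data <- array(0, dim = c(n_trials, n_sensors, n_t))
  for (r in seq_len(n_trials)) {
    key <- paste(design$participant[r], design$stimulus[r],
                 type_of(design$task[r]), sep = "|")
    noise <- matrix(stats::rnorm(n_sensors * n_t, 0, noise_sd),
                    n_sensors, n_t)
    if (truth$noise == "pink") {
      noise <- t(apply(noise, 1, .pink_filter))
      noise <- noise * noise_sd / stats::sd(noise)
    }
    data[r, , ] <- (templates[[key]] + noise) * scale
  }
  ep <- epoch_set(data, rate = rate, window = window, trial_meta = design,
                  sensor_names = layout$positions$sensor)
  attr(ep, "truth") <- truth
  attr(ep, "templates") <- templates
  attr(ep, "scale") <- scale
  ep
}

# crude 1/f shaping by cumulative-sum leaky integration
.pink_filter <- function(x) {
  y <- stats::filter(x, 0.95, method = "recursive")
  as.numeric(y)
}
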