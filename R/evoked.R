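#' Epoched multichannel recordings
#'
#' Container for trials x sensors x time sample arrays with sampling
#' metadata, trial metadata aligned to the behavioral trial table, and a
#' kept-trial mask.
#'
#' @param data numeric array `trials x sensors x time` (tesla).
#' @param rate sampling rate (Hz).
#' @param window epoch window `c(t_min, t_max)` in seconds, half-open:
#'   sample count must equal `round(diff(window) * rate)`.
#' @param trial_meta data.frame with one row per trial (or `NULL`).
#' @param sensor_names character vector, one per sensor.
#' @param kept logical mask of retained trials.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, rate, window = c(-0.2, 1.8), trial_meta = NULL,
                      sensor_names = NULL, kept = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  n_t <- round((window[2] - window[1]) * rate)
  if (dim(data)[3] != n_t) {
    stop(sprintf(
      "window [%g, %g) at %g Hz implies %d samples; data has %d",
      window[1], window[2], rate, n_t, dim(data)[3]), call. = FALSE)
  }
  if (!is.null(trial_meta) && nrow(trial_meta) != dim(data)[1]) {
    stop("trial metadata rows must match the trial dimension", call. = FALSE)
  }
  if (is.null(sensor_names)) {
    sensor_names <- sprintf("S%03d", seq_len(dim(data)[2]))
  }
  if (is.null(kept)) kept <- rep(TRUE, dim(data)[1])
  structure(list(data = data, rate = rate, window = window,
                 trial_meta = trial_meta, sensor_names = sensor_names,
                 kept = kept),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set: %d trials (%d kept) x %d sensors x %d samples, [%g, %g) s at %g Hz>\n",
    d[1], sum(x$kept), d[2], d[3], x$window[1], x$window[2], x$rate))
  invisible(x)
}

#' Epoch time axis
#' @param epochs an `epoch_set`.
#' @return numeric vector of sample times (s) relative to stimulus onset.
#' @export
epoch_times <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  epochs$window[1] + (seq_len(dim(epochs$data)[3]) - 1) / epochs$rate
}

#' Cut fixed-length epochs out of a continuous recording
#'
#' Extracts a half-open window around each event onset from a continuous
#' sensors x time recording.  Every epoch has
#' `round(diff(window) * rate)` samples.
#'
#' @param recording numeric matrix `sensors x time`.
#' @param onsets event onset times (s) relative to the recording start.
#' @param window epoch window (s) around each onset.
#' @param rate sampling rate (Hz) of the recording.
#' @param trial_meta optional per-event metadata.
#' @return An `epoch_set`.  Events whose window is not fully covered raise
#'   an error listing the offending trials.
#' @export
epoch_continuous <- function(recording, onsets, window = c(-0.2, 1.8),
                             rate = 250, trial_meta = NULL) {
  stopifnot(is.matrix(recording))
  if (!length(onsets)) {
    return(epoch_set(array(0, c(0, nrow(recording),
                                round(diff(window) * rate))),
                     rate = rate, window = window, trial_meta = trial_meta))
  }
  n_t <- round(diff(window) * rate)
  i0 <- round((onsets + window[1]) * rate) + 1L
  bad <- which(i0 < 1L | (i0 + n_t - 1L) > ncol(recording))
  if (length(bad)) {
    stop("window not covered by the recording for trial(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  data <- array(0, c(length(onsets), nrow(recording), n_t))
  for (r in seq_along(onsets)) {
    data[r, , ] <- recording[, i0[r]:(i0[r] + n_t - 1L)]
  }
  epoch_set(data, rate = rate, window = window, trial_meta = trial_meta,
            sensor_names = rownames(recording))
}

#' Peak-to-peak artifact rejection
#'
#' A trial is kept iff its maximum peak-to-peak amplitude over all sensors
#' does not exceed the threshold (study threshold for magnetometer-type
#' channels: 2e-11 T).
#'
#' @param epochs an `epoch_set`.
#' @param threshold peak-to-peak threshold, same units as the data.
#' @return logical kept mask (also stored in the returned attribute-free
#'   vector; assign it to `epochs$kept` to apply).
#' @export
reject_peak_to_peak <- function(epochs, threshold = 2e-11) {
  stopifnot(inherits(epochs, "epoch_set"), threshold > 0)
  n_trials <- dim(epochs$data)[1]
  vapply(seq_len(n_trials), function(r) {
    m <- matrix(epochs$data[r, , ], nrow = dim(epochs$data)[2])
    ptp <- apply(m, 1, function(v) max(v) - min(v))
    max(ptp) <= threshold
  }, TRUE)
}

#' Merge sensor triplets into virtual channels
#'
#' Combines each triplet of physical channels (e.g. two planar
#' gradiometers plus one magnetometer) into a single virtual channel by a
#' weighted sum, reducing a 306-channel array to 102 virtual sensors.
#' The physically informed field transformation used on real recordings
#' requires proprietary sensor geometry and is out of scope; synthetic
#' data are generated directly at the virtual-channel level.
#'
#' @param data numeric matrix `sensors x time` (or array
#'   `trials x sensors x time`).
#' @param grouping integer vector assigning each input sensor to an output
#'   channel; every output must receive exactly three inputs.
#' @param weights length-3 weights applied within each triplet in input
#'   order (default unit weights).
#' @return merged matrix/array with `max(grouping)` channels.
#' @export
merge_sensor_triplets <- function(data, grouping, weights = c(1, 1, 1)) {
  counts <- table(grouping)
  if (any(counts != 3L)) {
    stop("grouping must partition the sensors into complete triplets",
         call. = FALSE)
  }
  n_out <- length(counts)
  merge_mat <- matrix(0, n_out, length(grouping))
  for (g in seq_len(n_out)) {
    members <- which(grouping == as.integer(names(counts))[g])
    merge_mat[g, members] <- weights
  }
  if (is.matrix(data)) {
    merge_mat %*% data
  } else {
    stopifnot(length(dim(data)) == 3L)
    out <- array(0, c(dim(data)[1], n_out, dim(data)[3]))
    for (r in seq_len(dim(data)[1])) {
      out[r, , ] <- merge_mat %*% data[r, , ]
    }
    out
  }
}

#' Average kept trials into an evoked response
#'
#' @param epochs an `epoch_set`.
#' @param select optional logical/integer trial selection (combined with
#'   the kept mask).
#' @return list of class `evoked`: `data` (sensors x time), `n_trials`,
#'   `rate`, `window`, `sensor_names`.
#' @export
average_evoked <- function(epochs, select = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- which(epochs$kept)
  if (!is.null(select)) {
    sel <- if (is.logical(select)) which(select) else select
    idx <- intersect(idx, sel)
  }
  if (!length(idx)) stop("no kept trials to average", call. = FALSE)
  data <- apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
  structure(list(data = data, n_trials = length(idx), rate = epochs$rate,
                 window = epochs$window, sensor_names = epochs$sensor_names),
            class = "evoked")
}

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf("<evoked: %d sensors x %d samples, average of %d trials>\n",
              nrow(x$data), ncol(x$data), x$n_trials))
  invisible(x)
}

#' Remove unisensory evoked components from a multisensory response
#'
#' Per sensor, regresses the task-evoked trace (pooled across all time
#' points and all stimuli) on the auditory-only and visual-only localizer
#' traces by ordinary least squares (no intercept), and subtracts the
#' fitted weighted sum:
#' `residual(n, t) = task(n, t) - beta_A(n) aud(n, t) - beta_V(n) vis(n, t)`.
#'
#' @param task_evoked,aud_evoked,vis_evoked `evoked` objects (or lists of
#'   per-stimulus `evoked` objects) on identical grids.
#' @return list with `residual` (same shape as the task input), `weights`
#'   (data.frame `sensor`, `beta_a`, `beta_v`, `kappa` condition number).
#'   A warning is raised for ill-conditioned (near-collinear) localizer
#'   traces.
#' @export
remove_unisensory <- function(task_evoked, aud_evoked, vis_evoked) {
  as_list <- function(x) if (inherits(x, "evoked")) list(x) else x
  task <- as_list(task_evoked)
  aud <- as_list(aud_evoked)
  vis <- as_list(vis_evoked)
  if (length(unique(c(length(task), length(aud), length(vis)))) != 1L) {
    stop("task and localizer inputs must cover the same stimuli",
         call. = FALSE)
  }
  dims <- lapply(c(task, aud, vis), function(e) dim(e$data))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("all evoked inputs must share the same sensors x time grid",
         call. = FALSE)
  }
  n_sensors <- nrow(task[[1]]$data)
  beta <- matrix(NA_real_, n_sensors, 2)
  kappa <- numeric(n_sensors)
  resid <- lapply(task, function(e) e)
  for (n in seq_len(n_sensors)) {
    y <- unlist(lapply(task, function(e) e$data[n, ]))
    xa <- unlist(lapply(aud, function(e) e$data[n, ]))
    xv <- unlist(lapply(vis, function(e) e$data[n, ]))
    X <- cbind(xa, xv)
    kappa[n] <- kappa(X, exact = TRUE)
    b <- tryCatch(qr.solve(X, y), error = function(e) c(0, 0))
    beta[n, ] <- b
  }
  if (any(!is.finite(kappa)) || any(kappa > 1e8)) {
    warning("near-collinear localizer traces for sensor(s): ",
            paste(which(!is.finite(kappa) | kappa > 1e8), collapse = ", "),
            "; weights are unstable")
  }
  for (s in seq_along(resid)) {
    resid[[s]]$data <- task[[s]]$data - beta[, 1] * aud[[s]]$data -
      beta[, 2] * vis[[s]]$data
  }
  if (inherits(task_evoked, "evoked")) resid <- resid[[1]]
  list(residual = resid,
       weights = data.frame(sensor = task[[1]]$sensor_names %||%
                              seq_len(n_sensors),
                            beta_a = beta[, 1], beta_v = beta[, 2],
                            kappa = kappa))
}

#' Root-mean-square amplitude over a sensor-time cluster
#'
#' @param x an `evoked` object, a sensors x time matrix, or an `epoch_set`
#'   (in which case one RMS per kept trial is returned).
#' @param mask logical sensors x time matrix marking the cluster.
#' @return scalar RMS, or a per-trial vector for an `epoch_set`.
#' @export
cluster_rms <- function(x, mask) {
  if (!any(mask)) stop("empty cluster mask", call. = FALSE)
  if (inherits(x, "epoch_set")) {
    idx <- which(x$kept)
    return(vapply(idx, function(r) {
      m <- x$data[r, , , drop = TRUE]
      sqrt(mean(m[mask]^2))
    }, 0))
  }
  m <- if (inherits(x, "evoked")) x$data else x
  stopifnot(identical(dim(m), dim(mask)))
  sqrt(mean(m[mask]^2))
}

#' Mixed regression of cluster activity on detector summaries
#'
#' Fits a linear mixed model of per-stimulus cluster RMS on a z-scored
#' detector summary with a participant random intercept, separately
#' testing the task interaction:
#' `rms ~ z * task + (1 | participant)`.
#'
#' @param df data.frame with columns `rms`, `z`, `task`, `participant`.
#' @return list with per-task `slope` and Satterthwaite `p`, plus
#'   `interaction_p`.
#' @export
regress_evoked_on_mcd <- function(df) {
  stopifnot(all(c("rms", "z", "task", "participant") %in% names(df)))
  df$task <- factor(df$task)
  full <- lmerTest::lmer(rms ~ z * task + (1 | participant), data = df,
                         REML = FALSE)
  co <- summary(full)$coefficients
  inter_row <- grep(":", rownames(co))
  out <- list(interaction_p = if (length(inter_row)) co[inter_row, "Pr(>|t|)"]
              else NA_real_)
  per_task <- lapply(levels(df$task), function(tk) {
    sub <- df[df$task == tk, ]
    m <- lmerTest::lmer(rms ~ z + (1 | participant), data = sub, REML = FALSE)
    cs <- summary(m)$coefficients
    list(slope = cs["z", "Estimate"], p = cs["z", "Pr(>|t|)"])
  })
  names(per_task) <- levels(df$task)
  out$per_task <- per_task
  out
}

#' Single-trial regression of responses on cluster activity
#'
#' Fits nested mixed logistic models of the single-trial response on the
#' cluster RMS -- activity only, activity plus task, and activity by task
#' interaction, all with a participant random intercept -- and selects by
#' sequential likelihood-ratio tests with an AIC tie-break.  Simple
#' per-task effects are reported for the selected model.  Complete
#' separation (fitted probabilities collapsing to 0/1) is detected and
#' flagged.
#'
#' @param df data.frame with columns `response` (0/1), `rms`, `task`,
#'   `participant`.
#' @return list with `selected` model name, `lrt` table, `coefficients` of
#'   the selected model, per-task simple effects, and `separation` flag.
#' @export
single_trial_brain_behavior <- function(df) {
  stopifnot(all(c("response", "rms", "task", "participant") %in% names(df)))
  df$task <- factor(df$task)
  df$rms_s <- as.numeric(scale(df$rms))  # scale for optimizer stability
  ctrl <- lme4::glmerControl(check.conv.singular = "ignore",
                             calc.derivs = FALSE)
  # screen for (near-)complete separation with a cheap fixed-effects fit:
  # the mixed fits diverge on such data
  screen <- suppressWarnings(stats::glm(response ~ rms_s * task, data = df,
                                        family = stats::binomial()))
  p_scr <- stats::fitted(screen)
  separated <- mean(p_scr < 1e-6 | p_scr > 1 - 1e-6) > 0.5 ||
    any(abs(stats::coef(screen)) > 15, na.rm = TRUE)
  fit_safe <- function(formula, data, fixed_formula) {
    tryCatch(
      lme4::glmer(formula, data = data, family = stats::binomial(),
                  control = ctrl),
      error = function(e) {
        tryCatch(
          lme4::glmer(formula, data = data, family = stats::binomial(),
                      control = ctrl, nAGQ = 0),
          error = function(e2) {
            separated <<- TRUE
            suppressWarnings(stats::glm(fixed_formula, data = data,
                                        family = stats::binomial()))
          })
      })
  }
  m1 <- fit_safe(response ~ rms_s + (1 | participant), df,
                 response ~ rms_s)
  m2 <- fit_safe(response ~ rms_s + task + (1 | participant), df,
                 response ~ rms_s + task)
  m3 <- fit_safe(response ~ rms_s * task + (1 | participant), df,
                 response ~ rms_s * task)
  mixed <- inherits(m1, "glmerMod") && inherits(m2, "glmerMod") &&
    inherits(m3, "glmerMod")
  if (!mixed) {
    # uniform fixed-effects comparison when any mixed fit diverged
    m1 <- suppressWarnings(stats::glm(response ~ rms_s, data = df,
                                      family = stats::binomial()))
    m2 <- suppressWarnings(stats::glm(response ~ rms_s + task, data = df,
                                      family = stats::binomial()))
    m3 <- suppressWarnings(stats::glm(response ~ rms_s * task, data = df,
                                      family = stats::binomial()))
    an <- stats::anova(m1, m2, m3, test = "Chisq")
    p12 <- an$`Pr(>Chi)`[2]
    p23 <- an$`Pr(>Chi)`[3]
  } else {
    an <- stats::anova(m1, m2, m3)
    p12 <- an$`Pr(>Chisq)`[2]
    p23 <- an$`Pr(>Chisq)`[3]
  }
  selected <- if (!is.na(p23) && p23 < 0.05) "activity_x_task"
  else if (!is.na(p12) && p12 < 0.05) "activity_plus_task"
  else "activity"
  # AIC tie-break between adjacent candidates
  aics <- c(activity = stats::AIC(m1), activity_plus_task = stats::AIC(m2),
            activity_x_task = stats::AIC(m3))
  if (abs(diff(range(aics))) < 2) selected <- names(which.min(aics))
  model <- switch(selected, activity = m1, activity_plus_task = m2,
                  activity_x_task = m3)
  coefs <- if (mixed) lme4::fixef(model) else stats::coef(model)
  fitted_p <- stats::fitted(model)
  separation <- separated ||
    mean(fitted_p < 1e-6 | fitted_p > 1 - 1e-6) > 0.5 ||
    any(abs(coefs) > 15, na.rm = TRUE)
  simple <- lapply(levels(df$task), function(tk) {
    sub <- df[df$task == tk, ]
    m <- fit_safe(response ~ rms_s + (1 | participant), sub,
                  response ~ rms_s)
    cs <- summary(m)$coefficients
    pcol <- intersect(c("Pr(>|z|)", "Pr(>|t|)"), colnames(cs))[1]
    list(slope = cs["rms_s", "Estimate"], p = cs["rms_s", pcol])
  })
  names(simple) <- levels(df$task)
  inter <- summary(m3)$coefficients
  inter_row <- grep(":", rownames(inter))
  pcol3 <- intersect(c("Pr(>|z|)", "Pr(>|t|)"), colnames(inter))[1]
  list(selected = selected, lrt = an,
       coefficients = coefs,
       interaction = list(estimate = inter[inter_row, "Estimate"],
                          p = inter[inter_row, pcol3]),
       per_task = simple, separation = separation)
}

#' Zero-phase band-pass filter and decimation
#'
#' Forward-backward Butterworth band-pass followed by decimation to a
#' target rate.  Synthetic data are generated band-limited at the target
#' rate, so on them this is effectively a pass-through; the operation
#' exists for continuous recordings sampled faster than the analysis
#' rate.
#'
#' @param x numeric vector or sensors x time matrix.
#' @param rate input sampling rate (Hz).
#' @param l_freq,h_freq band edges (Hz).
#' @param out_rate output rate; must divide `rate`.
#' @param order filter order.
#' @return filtered, decimated signal (same shape family as input).
#' @export
bandpass_decimate <- function(x, rate, l_freq = 1, h_freq = 40,
                              out_rate = rate, order = 4) {
  if (rate %% out_rate != 0) {
    stop("out_rate must divide the input rate", call. = FALSE)
  }
  bf <- signal::butter(order, c(l_freq, h_freq) / (rate / 2), type = "pass")
  dec <- rate / out_rate
  apply_one <- function(v) {
    y <- signal::filtfilt(bf, v)
    y[seq(1, length(y), by = dec)]
  }
  if (is.matrix(x)) t(apply(x, 1, apply_one)) else apply_one(x)
}
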