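#' Lag window of a temporal response function
#'
#' @param t_min,t_max lag range (s), `t_min < t_max`; causal filters use
#'   non-negative lags.
#' @param rate sampling rate (Hz).
#' @return An object of class `lag_window` with the integer lag axis.
#' @export
lag_window <- function(t_min = 0, t_max = 0.5, rate = 250) {
  if (!(t_min < t_max)) stop("t_min must be below t_max", call. = FALSE)
  lags <- round(t_min * rate):round(t_max * rate)
  structure(list(t_min = t_min, t_max = t_max, rate = rate, lags = lags),
            class = "lag_window")
}

#' @export
print.lag_window <- function(x, ...) {
  cat(sprintf("<lag_window: [%g, %g] s at %g Hz, %d lags>\n",
              x$t_min, x$t_max, x$rate, length(x$lags)))
  invisible(x)
}

#' Time-lagged design matrix
#'
#' Stacks time-lagged copies of each predictor time course, zero-padded at
#' the edges, so that a linear model on the design implements a
#' finite-impulse-response convolution.  Columns are ordered component by
#' component, lag by lag within component.
#'
#' @param components numeric matrix `time x components` (a vector is taken
#'   as one component).
#' @param lags a `lag_window` or an integer vector of sample lags.
#' @return numeric matrix `time x (components * lags)` with column names
#'   `<component>.lag<k>`.
#' @export
lagged_design <- function(components, lags) {
  if (inherits(lags, "lag_window")) lags <- lags$lags
  if (is.vector(components)) components <- matrix(components, ncol = 1)
  n_t <- nrow(components)
  n_c <- ncol(components)
  cn <- colnames(components)
  if (is.null(cn)) cn <- paste0("c", seq_len(n_c))
  out <- matrix(0, n_t, n_c * length(lags))
  nm <- character(n_c * length(lags))
  col <- 0L
  for (i in seq_len(n_c)) {
    for (l in lags) {
      col <- col + 1L
      if (l >= 0) {
        if (l < n_t) out[(l + 1):n_t, col] <- components[1:(n_t - l), i]
      } else {
        if (-l < n_t) out[1:(n_t + l), col] <- components[(1 - l):n_t, i]
      }
      nm[col] <- sprintf("%s.lag%d", cn[i], l)
    }
  }
  colnames(out) <- nm
  out
}

#' Fit temporal response functions by ridge regression
#'
#' Solves the penalized least squares problem
#' `min ||Y - X W||^2 + lambda ||W||^2` per sensor, where `X` is a lagged
#' component design and `Y` the sensor time series.  Columns of `X` and
#' `Y` are centered internally; with `lambda = 0` the solution equals
#' ordinary least squares and a singular design raises a conditioning
#' error.
#'
#' @param design numeric matrix `time x (components * lags)`, typically
#'   from [lagged_design()].
#' @param response numeric matrix `time x sensors` (a vector is one
#'   sensor).
#' @param lambda ridge penalty (>= 0).
#' @param component_names,lags optional metadata stored in the model.
#' @return An object of class `trf_model`: `weights`
#'   (sensor x component x lag array when metadata are given, otherwise
#'   sensor x predictor matrix), `lambda`, centering statistics.
#' @export
fit_trf <- function(design, response, lambda = 0, component_names = NULL,
                    lags = NULL) {
  if (is.vector(response)) response <- matrix(response, ncol = 1)
  stopifnot(nrow(design) == nrow(response))
  mu_x <- colMeans(design)
  mu_y <- colMeans(response)
  Xc <- sweep(design, 2, mu_x)
  Yc <- sweep(response, 2, mu_y)
  G <- crossprod(Xc)
  if (lambda == 0) {
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < max(ev) * 1e-10) {
      stop("singular design with lambda = 0; add a ridge penalty",
           call. = FALSE)
    }
  }
  W <- solve(G + diag(lambda, ncol(design)), crossprod(Xc, Yc))
  weights <- t(W)  # sensors x predictors, (component, lag) column order
  if (!is.null(component_names) && !is.null(lags)) {
    if (inherits(lags, "lag_window")) lags <- lags$lags
    weights <- aperm(array(t(W), dim = c(ncol(response), length(lags),
                                         length(component_names))),
                     c(1, 3, 2))  # -> sensor x component x lag
    dimnames(weights) <- list(NULL, component_names, NULL)
  }
  structure(list(weights = weights, flat_weights = t(W), lambda = lambda,
                 mu_x = mu_x, mu_y = mu_y,
                 component_names = component_names, lags = lags),
            class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf("<trf_model: %d sensors x %d predictors, lambda = %g>\n",
              nrow(x$flat_weights), ncol(x$flat_weights), x$lambda))
  invisible(x)
}

#' Predict sensor time series from a fitted TRF
#'
#' @param object a `trf_model`.
#' @param design lagged design matrix on the same predictor layout.
#' @param components optional subset of predictor columns to use (all
#'   others treated as zero), given as a column index vector.
#' @param ... unused.
#' @return predicted matrix `time x sensors`.
#' @export
predict.trf_model <- function(object, design, components = NULL, ...) {
  W <- object$flat_weights
  Xc <- sweep(design, 2, object$mu_x)
  if (!is.null(components)) {
    keep <- matrix(0, nrow(W), ncol(W))
    keep[, components] <- W[, components]
    W <- keep
  }
  sweep(Xc %*% t(W), 2, object$mu_y, `+`)
}

# per-entry sufficient statistics for fast leave-one-out ridge
.trf_stats <- function(entries, lags) {
  lapply(entries, function(e) {
    D <- lagged_design(e$components, lags)
    list(D = D, Y = e$response, G = crossprod(D),
         XtY = crossprod(D, e$response), sx = colSums(D),
         sy = colSums(e$response), n = nrow(D),
         participant = e$participant, stimulus = e$stimulus)
  })
}

# ridge solve on centered totals assembled from sufficient statistics
.ridge_from_stats <- function(G, XtY, sx, sy, n, lambda) {
  Gc <- G - tcrossprod(sx) / n
  XtYc <- XtY - tcrossprod(sx, sy) / n
  solve(Gc + diag(lambda, nrow(Gc)), XtYc)
}

#' Cross-validated encoding scores of model-based TRFs
#'
#' Leave-one-(participant, stimulus)-out cross-validation of ridge TRFs:
#' for each fold, response functions are fitted on all remaining entries,
#' the held-out sensor time series are predicted, and performance is the
#' per-sensor Pearson correlation between prediction and recording,
#' averaged over folds (the study design gives 13 x 6 = 78 folds).  The
#' per-component contribution uses the same held-out predictions with all
#' other components' weights set to zero.
#'
#' @param entries list of folds; each element a list with `participant`,
#'   `stimulus`, `components` (time x components matrix) and `response`
#'   (time x sensors matrix).
#' @param lags a `lag_window` (or integer sample lags).
#' @param lambda ridge penalty: a single value, or a vector to be selected
#'   by nested cross-validation (held-in entries split by stimulus) on
#'   each training fold.
#' @param contributions compute per-component held-out scores.
#' @return An object of class `encoding_score`: `rho` (sensors, fold
#'   average), `rho_by_fold`, `component_rho` (sensors x components, when
#'   requested), `lambda_used` per fold, `n_folds`, `constant_flags`.
#' @export
trf_crossval <- function(entries, lags = lag_window(0, 0.5, 250),
                         lambda = 1, contributions = TRUE) {
  stopifnot(length(entries) >= 2L)
  stats_list <- .trf_stats(entries, lags)
  n_fold <- length(stats_list)
  p <- ncol(stats_list[[1]]$G)
  n_sensors <- ncol(stats_list[[1]]$Y)
  comp_names <- colnames(entries[[1]]$components)
  if (is.null(comp_names)) {
    comp_names <- paste0("c", seq_len(ncol(entries[[1]]$components)))
  }
  n_comp <- length(comp_names)
  lag_vec <- if (inherits(lags, "lag_window")) lags$lags else lags
  n_lag <- length(lag_vec)
  tot <- list(G = Reduce(`+`, lapply(stats_list, `[[`, "G")),
              XtY = Reduce(`+`, lapply(stats_list, `[[`, "XtY")),
              sx = Reduce(`+`, lapply(stats_list, `[[`, "sx")),
              sy = Reduce(`+`, lapply(stats_list, `[[`, "sy")),
              n = sum(vapply(stats_list, `[[`, 0, "n")))
  rho_by_fold <- matrix(NA_real_, n_fold, n_sensors)
  comp_rho <- array(NA_real_, c(n_fold, n_sensors, n_comp))
  lambda_used <- numeric(n_fold)
  constant <- FALSE
  for (f in seq_len(n_fold)) {
    st <- stats_list[[f]]
    G <- tot$G - st$G
    XtY <- tot$XtY - st$XtY
    sx <- tot$sx - st$sx
    sy <- tot$sy - st$sy
    n <- tot$n - st$n
    lam <- if (length(lambda) == 1L) lambda else {
      .select_lambda(stats_list[-f], lambda)
    }
    lambda_used[f] <- lam
    W <- .ridge_from_stats(G, XtY, sx, sy, n, lam)
    mu_x <- sx / n
    mu_y <- sy / n
    Dc <- sweep(st$D, 2, mu_x)
    pred <- sweep(Dc %*% W, 2, mu_y, `+`)
    for (s in seq_len(n_sensors)) {
      r <- .safe_cor(pred[, s], st$Y[, s])
      if (isTRUE(attr(r, "constant"))) constant <- TRUE
      rho_by_fold[f, s] <- as.numeric(r)
    }
    if (contributions) {
      for (ci in seq_len(n_comp)) {
        cols <- ((ci - 1) * n_lag + 1):(ci * n_lag)
        Wi <- matrix(0, p, n_sensors)
        Wi[cols, ] <- W[cols, ]
        pred_i <- Dc %*% Wi
        for (s in seq_len(n_sensors)) {
          r <- .safe_cor(pred_i[, s], st$Y[, s])
          if (isTRUE(attr(r, "constant"))) constant <- TRUE
          comp_rho[f, s, ci] <- as.numeric(r)
        }
      }
    }
  }
  structure(list(
    rho = colMeans(rho_by_fold), rho_by_fold = rho_by_fold,
    component_rho = if (contributions) {
      m <- apply(comp_rho, c(2, 3), mean)
      colnames(m) <- comp_names
      m
    } else NULL,
    component_rho_by_fold = if (contributions) comp_rho else NULL,
    lambda_used = lambda_used, n_folds = n_fold,
    component_names = comp_names, constant_flag = constant
  ), class = "encoding_score")
}

#' @export
print.encoding_score <- function(x, ...) {
  cat(sprintf("<encoding_score: %d folds, mean rho %.3f (range %.3f..%.3f)>\n",
              x$n_folds, mean(x$rho), min(x$rho), max(x$rho)))
  invisible(x)
}

# inner lambda selection: split the training entries by stimulus and pick
# the penalty with the best mean held-out correlation
.select_lambda <- function(train_stats, grid) {
  stims <- vapply(train_stats, function(s) as.character(s$stimulus), "")
  groups <- split(seq_along(train_stats), stims)
  if (length(groups) < 2L) groups <- split(seq_along(train_stats),
                                           seq_along(train_stats))
  tot <- list(G = Reduce(`+`, lapply(train_stats, `[[`, "G")),
              XtY = Reduce(`+`, lapply(train_stats, `[[`, "XtY")),
              sx = Reduce(`+`, lapply(train_stats, `[[`, "sx")),
              sy = Reduce(`+`, lapply(train_stats, `[[`, "sy")),
              n = sum(vapply(train_stats, `[[`, 0, "n")))
  score <- vapply(grid, function(lam) {
    acc <- 0
    cnt <- 0
    for (g in groups) {
      G <- tot$G; XtY <- tot$XtY; sx <- tot$sx; sy <- tot$sy; n <- tot$n
      for (i in g) {
        G <- G - train_stats[[i]]$G
        XtY <- XtY - train_stats[[i]]$XtY
        sx <- sx - train_stats[[i]]$sx
        sy <- sy - train_stats[[i]]$sy
        n <- n - train_stats[[i]]$n
      }
      W <- .ridge_from_stats(G, XtY, sx, sy, n, lam)
      for (i in g) {
        st <- train_stats[[i]]
        pred <- sweep(sweep(st$D, 2, sx / n) %*% W, 2, sy / n, `+`)
        for (s in seq_len(ncol(st$Y))) {
          r <- .safe_cor(pred[, s], st$Y[, s])
          acc <- acc + as.numeric(r)
          cnt <- cnt + 1
        }
      }
    }
    acc / cnt
  }, 0)
  grid[which.max(score)]
}

#' Encoding scores within sub-windows of the epoch
#'
#' Recomputes held-out correlations separately inside time sub-windows
#' (e.g. an early 0-500 ms and a late 500-1000 ms part) while the TRF fit
#' itself uses the full window.
#'
#' @param entries as in [trf_crossval()].
#' @param windows named list of `c(start, end)` second pairs, interpreted
#'   on the epoch time axis.
#' @param epoch_window epoch window (s) of the response rows.
#' @param rate sampling rate (Hz).
#' @inheritParams trf_crossval
#' @return named list of `encoding_score` objects, one per window.
#' @export
windowed_scores <- function(entries, windows = list(early = c(0, 0.5),
                                                    late = c(0.5, 1.0)),
                            epoch_window = c(-0.2, 1.8), rate = 250,
                            lags = lag_window(0, 0.5, rate), lambda = 1) {
  n_t <- nrow(entries[[1]]$response)
  out <- list()
  for (wn in names(windows)) {
    w <- windows[[wn]]
    i0 <- round((w[1] - epoch_window[1]) * rate) + 1L
    i1 <- round((w[2] - epoch_window[1]) * rate)
    if (i0 > i1 || i0 < 1L || i1 > n_t) {
      stop("empty or out-of-range scoring window: ", wn, call. = FALSE)
    }
    out[[wn]] <- .windowed_crossval(entries, lags, lambda, i0:i1)
  }
  out
}

# full-window fit, sub-window scoring
.windowed_crossval <- function(entries, lags, lambda, score_idx) {
  stats_list <- .trf_stats(entries, lags)
  tot <- list(G = Reduce(`+`, lapply(stats_list, `[[`, "G")),
              XtY = Reduce(`+`, lapply(stats_list, `[[`, "XtY")),
              sx = Reduce(`+`, lapply(stats_list, `[[`, "sx")),
              sy = Reduce(`+`, lapply(stats_list, `[[`, "sy")),
              n = sum(vapply(stats_list, `[[`, 0, "n")))
  n_fold <- length(stats_list)
  n_sensors <- ncol(stats_list[[1]]$Y)
  rho_by_fold <- matrix(NA_real_, n_fold, n_sensors)
  for (f in seq_len(n_fold)) {
    st <- stats_list[[f]]
    G <- tot$G - st$G
    XtY <- tot$XtY - st$XtY
    sx <- tot$sx - st$sx
    sy <- tot$sy - st$sy
    n <- tot$n - st$n
    lam <- if (length(lambda) == 1L) lambda else
      .select_lambda(stats_list[-f], lambda)
    W <- .ridge_from_stats(G, XtY, sx, sy, n, lam)
    pred <- sweep(sweep(st$D, 2, sx / n) %*% W, 2, sy / n, `+`)
    for (s in seq_len(n_sensors)) {
      rho_by_fold[f, s] <- as.numeric(.safe_cor(pred[score_idx, s],
                                                st$Y[score_idx, s]))
    }
  }
  structure(list(rho = colMeans(rho_by_fold), rho_by_fold = rho_by_fold,
                 component_rho = NULL, lambda_used = NA_real_,
                 n_folds = n_fold, constant_flag = FALSE),
            class = "encoding_score")
}

#' Held-out contribution of a single component
#'
#' Predicts held-out data using only one component's weights of a fitted
#' TRF model and correlates the prediction with the recording per sensor;
#' a constant prediction (all-zero weights) scores 0 by convention, with
#' a flag.
#'
#' @param model a `trf_model` from [fit_trf()] with component metadata.
#' @param design held-out lagged design matrix.
#' @param response held-out time x sensors matrix.
#' @param component component index.
#' @return numeric vector of per-sensor correlations; attribute
#'   `constant` marks sensors with constant predictions.
#' @export
component_contribution <- function(model, design, response, component) {
  stopifnot(inherits(model, "trf_model"))
  n_lag <- length(model$lags %||% stop("model lacks lag metadata"))
  cols <- ((component - 1) * n_lag + 1):(component * n_lag)
  pred <- predict(model, design, components = cols)
  flags <- logical(ncol(response))
  rho <- vapply(seq_len(ncol(response)), function(s) {
    r <- .safe_cor(pred[, s], response[, s])
    flags[s] <<- isTRUE(attr(r, "constant"))
    as.numeric(r)
  }, 0)
  structure(rho, constant = flags)
}
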