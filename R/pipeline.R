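#' Pipeline configuration
#'
#' Validated bag of settings for [run_pipeline()].  All stage parameters
#' default to desk-scale values so the full pipeline runs in minutes;
#' study-scale settings (pool of 1e6 candidates, 13 participants, 102
#' sensors, 10000 permutations) are reached by overriding the same knobs.
#'
#' @param seed single top-level seed; every stage derives its own stream
#'   from it (see [derive_seed()]).
#' @param n_pool candidate pool size for stimulus design.
#' @param k stimuli to select.
#' @param rho_max selection decorrelation bound.
#' @param n_participants,reps,blocks simulated design size.
#' @param n_sensors,grid_ncol sensor layout.
#' @param epoch_rate epoch sampling rate (Hz).
#' @param snr epoch signal-to-noise variance ratio.
#' @param n_perm cluster permutations.
#' @param cluster_threshold cluster-forming |t|.
#' @param trf_lags lag window (s) as `c(t_min, t_max)`.
#' @param trf_lambda ridge penalty (scalar or grid for nested selection).
#' @param fit_restarts behavioral fit restarts.
#' @param stimulus_subset optional character vector of stimulus labels to
#'   restrict the TRF stage to (e.g. an ambiguous-stimulus subset).
#' @param fit_behavior run the (slow) joint behavioral fit stage.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_pool = 2000, k = 6, rho_max = 0.2,
                            n_participants = 3, reps = 5, blocks = 1,
                            n_sensors = 12, grid_ncol = 4, epoch_rate = 250,
                            snr = 5, n_perm = 200, cluster_threshold = 2.6,
                            trf_lags = c(0, 0.2), trf_lambda = 1,
                            fit_restarts = 2, stimulus_subset = NULL,
                            fit_behavior = FALSE) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_pool >= cfg$k, cfg$k >= 3, cfg$rho_max > 0,
            cfg$n_participants >= 2, cfg$n_sensors >= 4,
            cfg$trf_lags[1] < cfg$trf_lags[2], cfg$n_perm >= 10)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes every stage in order on synthetic data: stimulus design
#' (pool, scoring, constrained selection), trial design and model-observer
#' simulation, optional joint behavioral fit, epoch simulation, artifact
#' rejection and evoked averaging, unisensory removal, task-contrast
#' cluster permutation statistics, and cross-validated TRF encoding with
#' per-component attribution.  Every artifact is written under `out_dir`
#' together with a manifest holding the exact configuration and seed.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory.
#' @return list of stage results, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  # --- stimulus design -----------------------------------------------------
  pool <- sample_sequence_pool(config$n_pool,
                               seed = derive_seed(config$seed, "stimuli"))
  pool <- score_pool(pool)
  set <- select_stimulus_set(pool, k = config$k, rho_max = config$rho_max,
                             seed = derive_seed(config$seed, "stimuli"))
  write_stimulus_set(set, file.path(out_dir, "stimuli"),
                     extra = list(seed = config$seed,
                                  n_pool = config$n_pool))
  res$stimuli <- set

  # --- behavior ------------------------------------------------------------
  truth <- ground_truth(n_participants = config$n_participants,
                        snr = config$snr, seed = config$seed)
  design <- make_design(n_participants = config$n_participants,
                        reps = config$reps, blocks = config$blocks,
                        localizer_blocks = 1,
                        stimuli = vapply(set$sequences, `[[`, "", "label"),
                        seed = config$seed)
  trials <- simulate_observer(truth, design, set$sequences,
                              seed = config$seed)
  write_trial_table(trials, file.path(out_dir, "trials.csv"))
  res$trials <- trials
  if (config$fit_behavior) {
    task_trials <- trials[trials$task %in% c("causality", "temporal_order"), ]
    fit <- fit_mcd_behavior(task_trials, set$sequences,
                            n_restarts = config$fit_restarts,
                            seed = config$seed,
                            control = list(n_particles = 6L,
                                           swarm_iters = 8L,
                                           refine_maxit = 80L))
    write_behavior_fit(fit, file.path(out_dir, "behavior_fit.json"))
    res$behavior_fit <- fit
  }

  # --- epochs and evoked ---------------------------------------------------
  layout <- make_layout(config$n_sensors, config$grid_ncol)
  write_adjacency(layout$adjacency, file.path(out_dir, "adjacency.csv"))
  epochs <- simulate_epochs(truth, trials, set$sequences, layout,
                            rate = config$epoch_rate, seed = config$seed)
  epochs$kept <- reject_peak_to_peak(epochs, threshold = 1)  # synthetic scale
  truth <- attr(epochs, "truth")
  labels <- vapply(set$sequences, `[[`, "", "label")
  ev_for <- function(task, stim) {
    average_evoked(epochs, epochs$trial_meta$task == task &
                     epochs$trial_meta$stimulus == stim)
  }
  cj <- lapply(labels, function(s) ev_for("causality", s))
  toj <- lapply(labels, function(s) ev_for("temporal_order", s))
  aud <- lapply(labels, function(s) ev_for("localizer_A", s))
  vis <- lapply(labels, function(s) ev_for("localizer_V", s))
  rm_cj <- remove_unisensory(cj, aud, vis)
  rm_toj <- remove_unisensory(toj, aud, vis)
  jsonlite::write_json(rm_cj$weights, file.path(out_dir, "weights.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  res$unisensory_weights <- rm_cj$weights

  # --- task contrast cluster statistics ------------------------------------
  # pairs = participant x stimulus residual evoked per task
  parts <- sort(unique(trials$participant))
  n_t <- dim(epochs$data)[3]
  mk_pairs <- function(task) {
    arr <- array(0, c(length(parts) * length(labels), config$n_sensors, n_t))
    i <- 0
    for (p in parts) for (s in labels) {
      i <- i + 1
      sel <- epochs$trial_meta$task == task &
        epochs$trial_meta$stimulus == s & epochs$trial_meta$participant == p
      arr[i, , ] <- average_evoked(epochs, sel)$data
    }
    arr
  }
  pairs_cj <- mk_pairs("causality")
  pairs_toj <- mk_pairs("temporal_order")
  perm <- permutation_p(pairs_cj - pairs_toj,
                        threshold = config$cluster_threshold,
                        adjacency = layout$adjacency, n_perm = config$n_perm,
                        seed = config$seed)
  write_clusters(perm, file.path(out_dir, "clusters.json"))
  res$clusters <- perm

  # --- TRF encoding --------------------------------------------------------
  trf_labels <- if (is.null(config$stimulus_subset)) labels else
    intersect(labels, config$stimulus_subset)
  entries <- trf_entries(epochs, set$sequences[labels %in% trf_labels],
                         truth$mcd_params)
  lw <- lag_window(config$trf_lags[1], config$trf_lags[2],
                   config$epoch_rate)
  score <- trf_crossval(entries, lags = lw, lambda = config$trf_lambda)
  res$trf <- score
  jsonlite::write_json(
    list(rho = score$rho, component_rho = score$component_rho,
         n_folds = score$n_folds, stimuli = trf_labels),
    file.path(out_dir, "trf_scores.json"), auto_unbox = TRUE, digits = NA)

  manifest <- list(config = unclass(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("mcdmeg")),
                   created = "run_pipeline")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Build TRF cross-validation entries from an epoch set
#'
#' Averages task epochs per (participant, stimulus) and pairs each average
#' with the detector component time courses of that stimulus under the
#' participant's time constants, producing the fold list consumed by
#' [trf_crossval()].
#'
#' @param epochs an `epoch_set` whose metadata include `participant`,
#'   `task`, `stimulus`.
#' @param stimuli list of `event_sequence`s.
#' @param params_table data.frame of per-participant time constants
#'   (`participant`, `tau_a`, `tau_v`, `tau_av`).
#' @param tasks tasks whose trials enter the average.
#' @return list of entries (`participant`, `stimulus`, `components`,
#'   `response`).
#' @export
trf_entries <- function(epochs, stimuli, params_table,
                        tasks = c("causality", "temporal_order")) {
  stopifnot(inherits(epochs, "epoch_set"), !is.null(epochs$trial_meta))
  labels <- vapply(stimuli, `[[`, "", "label")
  parts <- sort(unique(epochs$trial_meta$participant))
  entries <- list()
  for (p in parts) {
    pr <- params_table[params_table$participant == p, ]
    par_p <- mcd_params(pr$tau_a, pr$tau_v, pr$tau_av)
    for (si in seq_along(stimuli)) {
      sel <- epochs$trial_meta$participant == p &
        epochs$trial_meta$stimulus == labels[si] &
        epochs$trial_meta$task %in% tasks
      if (!any(sel & epochs$kept)) next
      ev <- average_evoked(epochs, sel)
      t0 <- first_onset(stimuli[[si]])
      comp <- .component_traces(stimuli[[si]], par_p, epochs$rate,
                                epochs$window + t0)
      comp <- apply(comp, 2, function(v) {
        s <- stats::sd(v)
        if (s == 0) numeric(length(v)) else (v - mean(v)) / s
      })
      colnames(comp) <- c("mcd_a", "mcd_v", "corr", "lag")
      entries[[length(entries) + 1L]] <- list(
        participant = p, stimulus = labels[si], components = comp,
        response = t(ev$data))
    }
  }
  entries
}
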