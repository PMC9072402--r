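# shared fixtures and independent oracles used across test files

toy_sequences <- function(n = 4, seed = 101, n_events = 5, duration = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    event_sequence(sort(runif(n_events, 0, duration - 0.01)),
                   sort(runif(n_events, 0, duration - 0.01)),
                   duration = duration, label = sprintf("toy-%02d", i))
  })
}

# recursive flood fill over supra-threshold samples: the independent
# clustering oracle (sensor adjacency at equal times + consecutive times
# on the same sensor)
floodfill_clusters <- function(tmap, threshold, adjacency) {
  supra <- abs(tmap) > threshold
  visited <- matrix(FALSE, nrow(tmap), ncol(tmap))
  out <- list()
  for (s in seq_len(nrow(tmap))) for (t in seq_len(ncol(tmap))) {
    if (!supra[s, t] || visited[s, t]) next
    pol <- sign(tmap[s, t])
    stack <- list(c(s, t))
    members <- NULL
    visited[s, t] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      members <- rbind(members, cur)
      cs <- cur[1]; ct <- cur[2]
      cand <- NULL
      if (ct > 1) cand <- rbind(cand, c(cs, ct - 1))
      if (ct < ncol(tmap)) cand <- rbind(cand, c(cs, ct + 1))
      for (ns in which(adjacency[cs, ])) cand <- rbind(cand, c(ns, ct))
      for (r in seq_len(NROW(cand))) {
        ns <- cand[r, 1]; nt <- cand[r, 2]
        same_sensor <- ns == cs
        if (!same_sensor && nt != ct) next
        if (supra[ns, nt] && !visited[ns, nt] &&
            sign(tmap[ns, nt]) == pol) {
          visited[ns, nt] <- TRUE
          stack[[length(stack) + 1]] <- c(ns, nt)
        }
      }
    }
    out[[length(out) + 1]] <- list(
      mass = sum(tmap[members]), size = nrow(members), polarity = pol)
  }
  out
}

# marginal NLL by non-adaptive 40-node Gauss-Hermite: the quadrature oracle
gh40_nll <- function(beta0, beta1, sigma, k, n, z) {
  gh <- pracma::gaussHermite(40)
  -sum(sapply(seq_len(nrow(k)), function(p) {
    vals <- sapply(seq_len(40), function(j) {
      b <- sqrt(2) * sigma * gh$x[j]
      eta <- beta0 + beta1 * z + b
      gh$w[j] / sqrt(pi) *
        exp(sum(k[p, ] * plogis(eta, log.p = TRUE) +
                  (n[p, ] - k[p, ]) * plogis(-eta, log.p = TRUE)))
    })
    log(sum(vals))
  }))
}

# trial table expansion of binomial cell counts
cells_to_trials <- function(k, n, stim_labels) {
  out <- NULL
  for (p in seq_len(nrow(k))) for (s in seq_len(ncol(k))) {
    out <- rbind(out, data.frame(
      participant = p, stimulus = stim_labels[s],
      response = c(rep(1, k[p, s]), rep(0, n[p, s] - k[p, s]))))
  }
  out
}

# well-conditioned synthetic TRF entries: white-noise components convolved
# with known kernels, used where weight recovery must be identifiable
random_trf_entries <- function(n_entries = 6, n_t = 300, n_comp = 2,
                               n_sensors = 2, n_lags = 8, snr = Inf,
                               seed = 1) {
  set.seed(seed)
  w_true <- array(rnorm(n_sensors * n_comp * n_lags, sd = 0.5),
                  dim = c(n_sensors, n_comp, n_lags))
  entries <- lapply(seq_len(n_entries), function(e) {
    comp <- matrix(rnorm(n_t * n_comp), n_t, n_comp)
    colnames(comp) <- paste0("c", seq_len(n_comp))
    Y <- sapply(seq_len(n_sensors), function(s) {
      y <- numeric(n_t)
      for (i in seq_len(n_comp)) {
        # direct causal convolution with zero initial history
        for (t in seq_len(n_t)) {
          l_max <- min(n_lags, t)
          y[t] <- y[t] + sum(w_true[s, i, seq_len(l_max)] *
                               comp[t - seq_len(l_max) + 1, i])
        }
      }
      if (is.finite(snr)) y <- y + rnorm(n_t, sd = sd(y) / sqrt(snr))
      y
    })
    list(participant = (e - 1) %/% 3 + 1, stimulus = paste0("s", (e - 1) %% 3),
         components = comp, response = Y)
  })
  list(entries = entries, w_true = w_true,
       lags = lag_window(0, (n_lags - 1) / 250, 250))
}
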