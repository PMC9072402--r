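#' Elementwise paired t-map over sensor-time arrays
#'
#' Computes the paired t statistic at every sensor-time sample between two
#' conditions measured on the same pairs (participant x stimulus), as used
#' for the task contrast: with 13 participants and 6 sequences the test
#' has 77 degrees of freedom.
#'
#' @param cond_a,cond_b numeric arrays `pairs x sensors x time` (matching
#'   dimensions).
#' @return list with `t` (sensors x time matrix), `df`, and `diff_mean`.
#' @export
paired_tmap <- function(cond_a, cond_b) {
  stopifnot(identical(dim(cond_a), dim(cond_b)), length(dim(cond_a)) == 3L)
  d <- cond_a - cond_b
  n <- dim(d)[1]
  if (n < 2) stop("need at least two pairs", call. = FALSE)
  dm <- apply(d, c(2, 3), mean)
  ds <- apply(d, c(2, 3), stats::sd)
  tmap <- dm / (ds / sqrt(n))
  tmap[ds == 0 & dm == 0] <- 0
  list(t = tmap, df = n - 1, diff_mean = dm)
}

#' Cluster-forming threshold from the t distribution
#'
#' Two-sided critical t value at level `p` for the given degrees of
#' freedom; at p = 0.01 and df = 77 this rounds to 2.6, the study's
#' cluster-forming threshold.
#'
#' @param p two-sided alpha level.
#' @param df degrees of freedom.
#' @return critical |t|.
#' @export
cluster_threshold <- function(p = 0.01, df = 77) {
  stats::qt(1 - p / 2, df)
}

#' Group supra-threshold samples into spatio-temporal clusters
#'
#' Connected components of the samples whose |t| exceeds the threshold,
#' split by sign.  Two samples are connected when they are on the same
#' sensor at consecutive time points, or on adjacent sensors at the same
#' time point (or, optionally, at consecutive time points on adjacent
#' sensors is NOT connected: connectivity is sensor-adjacency x same time
#' plus same sensor x adjacent time).
#'
#' @param tmap sensors x time t-statistic matrix.
#' @param threshold cluster-forming |t| threshold (study: 2.6).
#' @param adjacency symmetric logical sensor adjacency matrix; `NULL`
#'   treats every sensor as isolated (temporal clustering only).
#' @param temporal connect consecutive time samples on the same sensor.
#' @return list of clusters, each with `members` (matrix of sensor/time
#'   indices), `mass` (sum of member t values), `polarity` (+1/-1).
#'   Ordered by decreasing |mass|.
#' @export
form_clusters <- function(tmap, threshold = 2.6, adjacency = NULL,
                          temporal = TRUE) {
  stopifnot(is.matrix(tmap))
  n_s <- nrow(tmap)
  n_t <- ncol(tmap)
  if (is.null(adjacency)) adjacency <- matrix(FALSE, n_s, n_s)
  out <- list()
  for (pol in c(1, -1)) {
    supra <- which(pol * tmap > threshold)
    if (!length(supra)) next
    sens <- (supra - 1L) %% n_s + 1L
    time <- (supra - 1L) %/% n_s + 1L
    id <- seq_along(supra)
    # edges among supra-threshold samples
    edges <- NULL
    pos <- matrix(NA_integer_, n_s, n_t)
    pos[cbind(sens, time)] <- id
    if (temporal && n_t > 1) {
      nxt <- pos[cbind(sens, pmin(time + 1L, n_t))]
      ok <- !is.na(nxt) & time < n_t
      edges <- rbind(edges, cbind(id[ok], nxt[ok]))
    }
    nbrs <- which(adjacency, arr.ind = TRUE)
    if (nrow(nbrs)) {
      for (tt in unique(time)) {
        here <- pos[, tt]
        a <- here[nbrs[, 1]]
        b <- here[nbrs[, 2]]
        ok <- !is.na(a) & !is.na(b)
        if (any(ok)) edges <- rbind(edges, cbind(a[ok], b[ok]))
      }
    }
    g <- igraph::graph_from_edgelist(
      if (is.null(edges)) matrix(integer(0), 0, 2) else edges,
      directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(id) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership[seq_along(id)]
    for (cid in unique(comp)) {
      m <- which(comp == cid)
      out[[length(out) + 1L]] <- list(
        members = cbind(sensor = sens[m], time = time[m]),
        mass = sum(tmap[cbind(sens[m], time[m])]),
        polarity = pol)
    }
  }
  out[order(-abs(vapply(out, `[[`, 0, "mass")))]
}

# max cluster-mass magnitude of a t map (both polarities)
.max_cluster_mass <- function(tmap, threshold, adjacency, temporal = TRUE) {
  cl <- form_clusters(tmap, threshold, adjacency, temporal)
  if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, 0, "mass")))
}

#' Cluster-corrected p-values by sign-flip permutation
#'
#' Builds the null distribution of the maximum cluster mass by randomly
#' flipping the sign of each pair's condition difference (equivalent to
#' shuffling the task labels within pairs), re-forming clusters on every
#' permutation, and compares each observed cluster's |mass| to that null.
#' Monte-Carlo p-values use the add-one estimator
#' `p = (1 + #{null >= observed}) / (1 + n_perm)`; when `2^pairs` does not
#' exceed `n_perm` the enumeration is exhaustive and
#' `p = #{null >= observed} / 2^pairs` (the identity flip included).
#'
#' @param diffs numeric array `pairs x sensors x time` of paired
#'   condition differences.
#' @param threshold cluster-forming |t| threshold.
#' @param adjacency sensor adjacency matrix.
#' @param n_perm number of permutations (study: 10000).
#' @param seed RNG seed.
#' @param temporal connect consecutive time samples.
#' @return list with `clusters` (each with `p` added), `null_max` (the
#'   permutation distribution), `method` (`"exhaustive"` or
#'   `"montecarlo"`), `df`.
#' @export
permutation_p <- function(diffs, threshold = 2.6, adjacency = NULL,
                          n_perm = 10000, seed = 1, temporal = TRUE) {
  stopifnot(length(dim(diffs)) == 3L)
  n <- dim(diffs)[1]
  zeros <- array(0, dim(diffs))
  obs <- paired_tmap(diffs, zeros)
  clusters <- form_clusters(obs$t, threshold, adjacency, temporal)
  exhaustive <- 2^n <= n_perm
  tstat_for <- function(signs) {
    flipped <- sweep(diffs, 1, signs, `*`)
    paired_tmap(flipped, zeros)$t
  }
  if (exhaustive) {
    signs_mat <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    null_max <- apply(signs_mat, 1, function(sg) {
      .max_cluster_mass(tstat_for(sg), threshold, adjacency, temporal)
    })
    p_of <- function(mass) mean(null_max >= abs(mass))
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(seed, "clusters"))
    null_max <- vapply(seq_len(n_perm), function(i) {
      sg <- sample(c(-1, 1), n, replace = TRUE)
      .max_cluster_mass(tstat_for(sg), threshold, adjacency, temporal)
    }, 0)
    p_of <- function(mass) (1 + sum(null_max >= abs(mass))) / (1 + n_perm)
  }
  for (i in seq_along(clusters)) clusters[[i]]$p <- p_of(clusters[[i]]$mass)
  list(clusters = clusters, null_max = null_max,
       method = if (exhaustive) "exhaustive" else "montecarlo", df = n - 1)
}

#' Spatial cluster correction of per-sensor score maps
#'
#' One-sample t-test of per-participant sensor scores (e.g. encoding
#' correlations) against zero, clustered over sensor adjacency only, with
#' a sign-flip permutation null of the maximum cluster mass
#' (study settings: threshold 2.6, 10000 permutations).
#'
#' @param scores numeric matrix `participants x sensors`.
#' @param adjacency sensor adjacency matrix.
#' @param threshold cluster-forming |t| threshold.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return as [permutation_p()], with cluster members being sensor indices.
#' @export
spatial_cluster_correct <- function(scores, adjacency, threshold = 2.6,
                                    n_perm = 10000, seed = 1) {
  stopifnot(is.matrix(scores))
  # sensors x time with a single time sample; temporal adjacency is moot
  diffs <- array(scores, dim = c(nrow(scores), ncol(scores), 1L))
  res <- permutation_p(diffs, threshold = threshold, adjacency = adjacency,
                       n_perm = n_perm, seed = seed, temporal = FALSE)
  res$clusters <- lapply(res$clusters, function(cl) {
    cl$members <- cl$members[, "sensor"]
    cl
  })
  res
}

#' Write cluster results to JSON
#'
#' @param result output of [permutation_p()] or
#'   [spatial_cluster_correct()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(result, path) {
  obj <- list(method = result$method, df = result$df,
              clusters = lapply(result$clusters, function(cl) {
                list(members = apply(as.matrix(cl$members), 1, as.list),
                     mass = cl$mass, polarity = cl$polarity, p = cl$p)
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
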