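# save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Derive per-stage seeds from one top-level seed
#'
#' All randomness in the pipeline flows from a single integer seed; each
#' stage gets a fixed, documented offset so reruns are reproducible and
#' stages never share a stream.  Derived seeds stay below 2^31.
#'
#' @param seed top-level integer seed.
#' @param stage stage name.
#' @return integer seed for the stage.
#' @export
derive_seed <- function(seed, stage) {
  offsets <- c(stimuli = 101L, design = 211L, observer = 307L,
               behavior_fit = 401L, power = 503L, epochs = 601L,
               clusters = 701L, trf = 809L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage, call. = FALSE)
  (as.integer(seed) %% 20000000L) * 100L + offsets[[stage]]
}

# Pearson correlation that returns 0 (with attribute flag) when either
# argument is constant; used for cross-validated encoding scores where a
# constant prediction is defined to have zero score
.safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    structure(0, constant = TRUE)
  } else {
    stats::cor(x, y)
  }
}
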