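# Myogenic/neurogenic classification from spatial focality.
#
# A muscle generator projects onto one or two electrodes over the active
# muscle, so its mixing ("inverse weight") column is spatially focal; a
# cortical generator volume-conducts smoothly across the scalp. Focality is
# the maximum per-electrode z-score of the component's mixing column.

#' Z-score component topographies across electrodes
#'
#' Each component's mixing column is independently z-scored across electrodes
#' (subtract the column mean, divide by the column SD). The population-SD
#' convention (divide by n, not n-1) is used, fixed for reproducibility.
#' A zero-variance column maps to all zeros.
#'
#' @param mixing Channels x components mixing matrix (>= 2 channels).
#' @return Matrix of the same shape, in SD units per column.
#' @export
normalize_topography <- function(mixing) {
  A <- as.matrix(mixing)
  if (nrow(A) < 2) stop("need >= 2 channels to z-score a topography")
  apply(A, 2, function(col) {
    mu <- mean(col)
    s <- sqrt(mean((col - mu)^2))
    if (s == 0) rep(0, length(col)) else (col - mu) / s
  })
}

#' Classify components as myogenic or neurogenic by focality
#'
#' A component is focal when the magnitude of its z-scored topography exceeds
#' `threshold_sd` (inclusive) in at least one electrode; the absolute value
#' makes the decision invariant to the sign indeterminacy of ICA mixing
#' columns. Two decision modes:
#' * `per_component` (default): each component is tested independently;
#'   a non-focal component is never pruned.
#' * `variance_prefix`: myogenic components are assumed to carry more
#'   variance than neurogenic ones, so the boundary between the last myogenic
#'   and first neurogenic component is drawn after the **last** focal
#'   component in explained-variance order, and everything before it is
#'   labeled myogenic too.
#'
#' @param z Z-scored topography matrix from [normalize_topography()], columns
#'   ordered by explained variance descending.
#' @param threshold_sd Focality threshold in SD units (default 2).
#' @param mode `"per_component"` or `"variance_prefix"`.
#' @param trial_index Optional trial number recorded in the labels.
#' @return A data frame with one row per component: `trial_index`,
#'   `component_index`, `focality`, `klass` (`"myogenic"`/`"neurogenic"`),
#'   `rule`.
#' @export
classify_components <- function(z, threshold_sd = 2,
                                mode = c("per_component", "variance_prefix"),
                                trial_index = NA_integer_) {
  mode <- match.arg(mode)
  z <- as.matrix(z)
  focality <- apply(abs(z), 2, max)
  focal <- focality >= threshold_sd
  if (mode == "per_component") {
    myo <- focal
  } else {
    last <- if (any(focal)) max(which(focal)) else 0L
    myo <- seq_along(focality) <= last
  }
  data.frame(
    trial_index = trial_index,
    component_index = seq_along(focality),
    focality = as.numeric(focality),
    klass = ifelse(myo, "myogenic", "neurogenic"),
    rule = mode,
    stringsAsFactors = FALSE
  )
}

#' Back-project a trial keeping only neurogenic components
#'
#' `cleaned = mixing[, neurogenic] %*% sources[neurogenic, ]`, plus the
#' channel means removed during decomposition (restored only when at least
#' one component survives; pruning everything returns exact zeros). The shape
#' equals the trial data; channels excluded from ICA are handled at
#' reconstitution, not here.
#'
#' @param decomp A `trial_decomposition`.
#' @param labels Data frame from [classify_components()] covering every
#'   component of the trial.
#' @return Channels x samples cleaned matrix.
#' @export
prune_backproject <- function(decomp, labels) {
  stopifnot(inherits(decomp, "trial_decomposition"))
  if (nrow(labels) != decomp$n_components) {
    stop("labels cover ", nrow(labels), " components but the trial has ",
         decomp$n_components)
  }
  keep <- which(labels$klass == "neurogenic")
  n <- ncol(decomp$sources)
  nch <- nrow(decomp$mixing)
  if (length(keep) == 0) {
    out <- matrix(0, nch, n)
  } else {
    out <- decomp$mixing[, keep, drop = FALSE] %*%
      decomp$sources[keep, , drop = FALSE] + decomp$channel_means
  }
  rownames(out) <- decomp$channels
  out
}
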