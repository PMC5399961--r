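# Trial segmentation and Infomax ICA.
#
# Each >16 Hz trial is mean-centered, whitened by principal components
# (dropping directions below a variance floor), rotated by natural-gradient
# Infomax (C++ core), and the components are re-ordered by the fraction of
# trial variance their back-projection explains.

#' Segment a recording into consecutive trials
#'
#' Spans are consecutive, non-overlapping, 0-based half-open intervals of
#' `round(trial_s * fs)` samples. A final remainder shorter than half a trial
#' is merged into the last full trial; a remainder of half a trial or more is
#' kept as its own (short) trial. A recording shorter than one trial yields a
#' single span.
#'
#' @param rec An [eeg_recording()].
#' @param trial_s Trial length in seconds, default 120 (24,000 samples at the
#'   clinical 200 Hz rate).
#' @return List of spans, each `list(start, end)` (0-based half-open).
#' @export
segment_trials <- function(rec, trial_s = 120) {
  n <- n_samples(rec)
  if (n < 1) stop("empty recording")
  T <- round(trial_s * rec$fs_hz)
  if (n <= T) return(list(list(start = 0L, end = n)))
  k <- n %/% T
  rem <- n - k * T
  starts <- (seq_len(k) - 1L) * T
  ends <- starts + T
  if (rem > 0) {
    if (rem < T / 2) {
      ends[k] <- n                       # merge short remainder into last trial
    } else {
      starts <- c(starts, k * T); ends <- c(ends, n)
    }
  }
  mapply(function(s, e) list(start = as.integer(s), end = as.integer(e)),
         starts, ends, SIMPLIFY = FALSE)
}

#' Infomax ICA of one trial
#'
#' Natural-gradient Infomax with the logistic nonlinearity (extended Infomax,
#' with a kurtosis-sign switch for sub-Gaussian sources, via
#' `extended = TRUE`). The trial is mean-centered, whitened by principal
#' components retaining directions above `var_floor` of total variance, and
#' rotated with an annealing learning-rate schedule until the weight-change
#' norm drops below `tol` or `max_iter` passes elapse. Deterministic given
#' `seed`. Components are sorted by explained variance, descending; the
#' mixing ("inverse weight") matrix is the pseudoinverse of the unmixing
#' matrix and gives each component's scalp topography.
#'
#' @param trial_data Channels x samples numeric matrix (rownames = labels).
#' @param seed Integer seed for the per-pass sample permutations (default 0).
#' @param tol Convergence tolerance on the weight-change norm (default 1e-6).
#' @param max_iter Maximum training passes (default 512).
#' @param extended Use extended Infomax (default `FALSE`, the classic runica
#'   default).
#' @param var_floor Relative variance floor below which principal components
#'   are dropped before rotation (default 1e-9); protects against the
#'   near-singular trials that channel exclusion and filtering can create.
#' @param lrate Initial learning rate; default `0.00065 / log(k)` for `k`
#'   retained components (the classic heuristic).
#' @return A `trial_decomposition`: `unmixing` (components x channels),
#'   `mixing` (channels x components), `sources` (components x samples, of the
#'   centered data), `explained_var` (descending), `channel_means`,
#'   `channels`, `converged`, `iterations`, `seed`.
#' @export
infomax_ica <- function(trial_data, seed = 0, tol = 1e-6, max_iter = 512,
                        extended = FALSE, var_floor = 1e-9, lrate = NULL) {
  X <- as.matrix(trial_data)
  storage.mode(X) <- "double"
  nch <- nrow(X); n <- ncol(X)
  if (n < 20 * nch^2) {
    warning("trial has ", n, " samples for ", nch, " channels; fewer than the ",
            "recommended 20*channels^2 = ", 20 * nch^2,
            " -- decomposition may be unstable")
  }
  means <- rowMeans(X)
  Xc <- X - means
  total_var <- sum(Xc^2) / n
  if (total_var == 0) stop("trial has zero variance; nothing to decompose")

  C <- tcrossprod(Xc) / n
  eig <- eigen(C, symmetric = TRUE)
  keep <- eig$values > var_floor * sum(eig$values)
  if (!any(keep)) stop("no principal component above the variance floor")
  if (!all(keep)) {
    warning("data are rank deficient: dropped ", sum(!keep),
            " near-null principal direction(s) (collinear or excluded channels)")
  }
  d <- eig$values[keep]
  V <- eig$vectors[, keep, drop = FALSE]
  k <- length(d)
  sphere <- diag(1 / sqrt(d), k) %*% t(V)
  Xw <- sphere %*% Xc

  if (is.null(lrate)) lrate <- 0.00065 / max(log(k), 1)
  block <- as.integer(ceiling(min(5 * log(n), 0.3 * n)))
  res <- .infomax_core(Xw, block, lrate, tol, as.integer(max_iter),
                       as.integer(seed), isTRUE(extended))
  if (!res$converged) {
    warning("Infomax did not reach tolerance ", tol, " in ", res$iterations,
            " passes; proceeding with converged = FALSE")
  }

  unmixing <- res$W %*% sphere              # k x nch
  mixing <- pracma::pinv(unmixing)          # nch x k
  sources <- unmixing %*% Xc                # k x n

  ev <- colSums(mixing^2) * rowSums(sources^2) / n / total_var
  ord <- order(ev, decreasing = TRUE)
  labs <- rownames(X)
  if (is.null(labs)) labs <- paste0("CH", seq_len(nch))

  structure(list(
    unmixing = unmixing[ord, , drop = FALSE],
    mixing = mixing[, ord, drop = FALSE],
    sources = sources[ord, , drop = FALSE],
    explained_var = ev[ord],
    channel_means = means,
    channels = labs,
    n_components = k,
    converged = res$converged,
    iterations = res$iterations,
    seed = seed,
    extended = isTRUE(extended)
  ), class = "trial_decomposition")
}

#' @export
print.trial_decomposition <- function(x, ...) {
  cat(sprintf(
    "<trial_decomposition> %d components from %d channels; %s in %d passes\n",
    x$n_components, length(x$channels),
    if (x$converged) "converged" else "NOT converged", x$iterations))
  cat("  explained variance:",
      paste(sprintf("%.3f", utils::head(x$explained_var, 6)), collapse = " "),
      if (x$n_components > 6) "..." else "", "\n")
  invisible(x)
}

#' Per-component explained-variance fractions
#'
#' Fraction i is the variance of component i's back-projection
#' `mixing[, i] %o% sources[i, ]`, summed over channels, divided by the total
#' (centered) trial variance. The fractions define the component ordering.
#'
#' @param decomp A `trial_decomposition`.
#' @param trial_data The trial the decomposition was fit to.
#' @return Numeric vector of fractions, in the decomposition's component order.
#' @export
explained_variance <- function(decomp, trial_data) {
  X <- as.matrix(trial_data)
  Xc <- X - rowMeans(X)
  n <- ncol(Xc)
  total <- sum(Xc^2) / n
  colSums(decomp$mixing^2) * rowSums(decomp$sources^2) / n / total
}

#' Amari divergence between an estimated unmixing and a true mixing
#'
#' Permutation- and scale-invariant score of ICA recovery: 0 when
#' `unmixing %*% mixing_true` is a scaled permutation of the identity, larger
#' as the product spreads off that structure. Normalized to \[0, 1\].
#'
#' @param unmixing Estimated unmixing matrix W (k x k).
#' @param mixing_true True mixing matrix A (k x k).
#' @return Nonnegative scalar.
#' @export
amari_index <- function(unmixing, mixing_true) {
  P <- abs(unmixing %*% mixing_true)
  k <- nrow(P)
  rows <- sum(rowSums(P / apply(P, 1, max)) - 1)
  cols <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1)
  (rows + cols) / (2 * k * (k - 1))
}
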