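# Data features: region-by-time containers, eigenvariate extraction,
# cross-spectral density estimation (multivariate autoregressive model by
# default, Welch periodogram as a cross-check), functional connectivity.

#' Region-by-time BOLD container
#'
#' @param Y Numeric matrix, regions x volumes.
#' @param TR Repetition time (s).
#' @param labels Optional region labels.
#' @return Object of class `dcm_timeseries`.
#' @export
timeseries_data <- function(Y, TR, labels = NULL) {
  if (!is.matrix(Y) || anyNA(Y))
    stop("Y must be a numeric matrix with no missing values", call. = FALSE)
  if (!is.numeric(TR) || length(TR) != 1L || TR <= 0)
    stop("TR must be a single positive number of seconds", call. = FALSE)
  if (ncol(Y) <= nrow(Y))
    warning("fewer volumes than regions; spectral estimates will be poor")
  labels <- labels %||% rownames(Y) %||% paste0("R", seq_len(nrow(Y)))
  dimnames(Y) <- NULL
  structure(list(Y = Y, TR = TR, labels = labels),
            class = "dcm_timeseries")
}

#' Principal eigenvariate of a voxel-by-time matrix
#'
#' Summarizes an ROI by the first principal component time course of its
#' (row-centered) voxel matrix, scaled by the leading singular value over
#' the square root of the voxel count, with the sign fixed so that the mean
#' voxel loading is positive (sign consistency matters when averaging over
#' subjects).
#'
#' @param voxels Numeric matrix, voxels x time.
#' @return Numeric time series of length `ncol(voxels)`.
#' @export
extract_eigenvariate <- function(voxels) {
  if (!is.matrix(voxels) || ncol(voxels) < 2L)
    stop("voxels must be a v x t matrix with t >= 2", call. = FALSE)
  X <- voxels - rowMeans(voxels)
  if (max(abs(X)) == 0)
    stop("constant (zero-variance) voxel matrix", call. = FALSE)
  sv <- svd(X, nu = 1, nv = 1)
  sgn <- sign(mean(sv$u[, 1]))
  if (sgn == 0) sgn <- 1
  sgn * sv$d[1] * sv$v[, 1] / sqrt(nrow(voxels))
}

# Remove per-region mean and linear trend (and optionally frequencies below
# `highpass_hz` via a discrete-cosine projection).
.detrend <- function(Y, TR, highpass_hz = NULL) {
  t_n <- ncol(Y)
  X <- cbind(1, seq_len(t_n))
  if (!is.null(highpass_hz)) {
    k_max <- floor(2 * t_n * TR * highpass_hz)
    if (k_max >= 1) {
      tt <- seq_len(t_n) - 0.5
      dct <- sapply(seq_len(k_max), function(k) cos(pi * k * tt / t_n))
      X <- cbind(X, dct)
    }
  }
  resid <- t(stats::lm.fit(X, t(Y))$residuals)
  matrix(resid, nrow(Y), t_n)
}

# Least-squares fit of a multivariate autoregressive model of given order.
.fit_mar <- function(Y, order) {
  n <- nrow(Y); t_n <- ncol(Y)
  rows <- t_n - order
  X <- matrix(0, rows, n * order)
  for (k in seq_len(order))
    X[, (k - 1) * n + seq_len(n)] <- t(Y[, (order - k) + seq_len(rows),
                                         drop = FALSE])
  Z <- t(Y[, order + seq_len(rows), drop = FALSE])
  B <- qr.solve(X, Z)                         # (n*order) x n
  E <- Z - X %*% B
  Sigma <- crossprod(E) / (rows - n * order)
  A_k <- lapply(seq_len(order), function(k)
    t(B[(k - 1) * n + seq_len(n), , drop = FALSE]))
  list(A = A_k, Sigma = Sigma)
}

# Welch cross-spectral estimate averaged onto a target grid: Hann-windowed
# 50%-overlap segments; periodogram bins are band-averaged within the cell
# around each grid frequency.
.welch_csd <- function(Y, dt, freq_hz, n_seg = NULL) {
  n <- nrow(Y); t_n <- ncol(Y)
  n_seg <- min(n_seg %||% min(1024L, 2^floor(log2(t_n / 4))), t_n)
  if (n_seg < 8) stop("series too short for Welch estimation", call. = FALSE)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_seg) / (n_seg + 1))
  U <- mean(w^2)
  step <- n_seg %/% 2
  starts <- seq(1L, t_n - n_seg + 1L, by = step)
  f_bins <- (seq_len(n_seg %/% 2)) / (n_seg * dt)
  acc <- array(0i, c(n, n, length(f_bins)))
  for (s in starts) {
    seg <- Y[, s + seq_len(n_seg) - 1L, drop = FALSE]
    seg <- seg - rowMeans(seg)
    Xf <- t(apply(seg * rep(w, each = n), 1, fft))
    if (n == 1L) Xf <- matrix(Xf, 1L)
    Xf <- Xf[, 1L + seq_along(f_bins), drop = FALSE]
    for (kf in seq_along(f_bins))
      acc[, , kf] <- acc[, , kf] +
        (Xf[, kf] %*% Conj(t(Xf[, kf]))) * dt / (n_seg * U)
  }
  acc <- acc / length(starts)
  # band-average onto the requested grid (outer edges half a cell wide, so
  # out-of-band periodogram bins never leak into the end cells)
  mids <- (freq_hz[-1] + freq_hz[-length(freq_hz)]) / 2
  dg <- if (length(freq_hz) > 1) diff(freq_hz[1:2]) else freq_hz[1]
  edges <- c(freq_hz[1] - dg / 2, mids, freq_hz[length(freq_hz)] + dg / 2)
  G <- array(0i, c(n, n, length(freq_hz)))
  for (kg in seq_along(freq_hz)) {
    sel <- which(f_bins > edges[kg] & f_bins <= edges[kg + 1])
    if (!length(sel)) sel <- which.min(abs(f_bins - freq_hz[kg]))
    G[, , kg] <- apply(acc[, , sel, drop = FALSE], c(1, 2), mean)
  }
  G
}

#' Estimate complex cross spectra from time series
#'
#' Default estimator: fit a multivariate autoregressive (MAR) model of the
#' given order by least squares and evaluate its implied spectral density
#' \eqn{S(f) = \Delta t\, H(f)\, \Sigma\, H(f)^\dagger} with
#' \eqn{H(f) = (I - \sum_k A_k e^{-2\pi i f k \Delta t})^{-1}} on the
#' requested grid -- smooth parametric spectra suited to short fMRI series.
#' A Welch periodogram (`method = "welch"`) is provided as a nonparametric
#' cross-check.  Series are mean/trend-removed first (plus an optional
#' high-pass).
#'
#' @param ts A [timeseries_data()] object.
#' @param freq_hz Target frequency grid (Hz).
#' @param order MAR order (default 8).
#' @param method `"mar"` or `"welch"`.
#' @param highpass_hz Optional high-pass cutoff applied during detrending.
#' @param n_seg Welch segment length (default: power of two near a quarter
#'   of the series, capped at 1024); longer segments resolve lower
#'   frequencies at the cost of fewer averages.
#' @return A `dcm_csd` of kind `"observed"` (Hermitian by construction,
#'   non-negative auto-spectra).
#' @export
estimate_csd <- function(ts, freq_hz, order = 8, method = c("mar", "welch"),
                         highpass_hz = NULL, n_seg = NULL) {
  stopifnot(inherits(ts, "dcm_timeseries"))
  method <- match.arg(method)
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  if (ncol(ts$Y) < 4 * order)
    stop("series too short for MAR order ", order, call. = FALSE)
  Y <- .detrend(ts$Y, ts$TR, highpass_hz)
  dt <- ts$TR
  n <- nrow(Y)
  if (method == "welch") {
    G <- .welch_csd(Y, dt, freq_hz, n_seg)
  } else {
    fit <- .fit_mar(Y, order)
    G <- array(0i, c(n, n, length(freq_hz)))
    for (kf in seq_along(freq_hz)) {
      z <- exp(-2i * pi * freq_hz[kf] * seq_len(order) * dt)
      Aw <- diag(1 + 0i, n)
      for (k in seq_len(order)) Aw <- Aw - fit$A[[k]] * z[k]
      H <- solve(Aw)
      Gk <- dt * H %*% fit$Sigma %*% Conj(t(H))
      G[, , kf] <- (Gk + Conj(t(Gk))) / 2
    }
  }
  for (kf in seq_along(freq_hz)) {
    Gk <- (G[, , kf] + Conj(t(G[, , kf]))) / 2
    diag(Gk) <- pmax(Re(diag(Gk)), 0)
    G[, , kf] <- Gk
  }
  new_csd(G, freq_hz, "observed", labels = ts$labels)
}

#' Functional connectivity matrix
#'
#' Pearson correlations between regional time series: symmetric, unit
#' diagonal, entries in `[-1, 1]`.  Undirected by construction -- the
#' comparator (and source of prior modes) for directed effective
#' connectivity.
#'
#' @param ts A [timeseries_data()] object with at least 3 volumes.
#' @return `n` x `n` correlation matrix.
#' @export
functional_connectivity <- function(ts) {
  stopifnot(inherits(ts, "dcm_timeseries"))
  if (ncol(ts$Y) < 3) stop("need at least 3 volumes", call. = FALSE)
  v <- apply(ts$Y, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance region: ", ts$labels[which(v == 0)[1]],
         call. = FALSE)
  FC <- stats::cor(t(ts$Y))
  dimnames(FC) <- list(ts$labels, ts$labels)
  diag(FC) <- 1
  FC
}

#' Read / write region-by-time series as TSV/CSV
#'
#' One header row of region names, one row per volume.  `TR` is taken from
#' the `tr` argument or from a JSON sidecar (`<path>.json` with field
#' `RepetitionTime`).
#'
#' @param path File path (`.tsv` or `.csv`).
#' @param tr Repetition time in seconds (overrides any sidecar).
#' @return A [timeseries_data()] object.
#' @export
read_timeseries <- function(path, tr = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE)
  if (is.null(tr)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar))
      tr <- jsonlite::read_json(sidecar)$RepetitionTime
  }
  if (is.null(tr))
    stop("TR not supplied and no sidecar found for ", path, call. = FALSE)
  timeseries_data(t(as.matrix(df)), TR = tr, labels = colnames(df))
}

#' @rdname read_timeseries
#' @param ts A [timeseries_data()] object.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "dcm_timeseries"))
  df <- as.data.frame(t(ts$Y))
  colnames(df) <- ts$labels
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(RepetitionTime = ts$TR),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
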