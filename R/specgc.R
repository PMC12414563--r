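#' Frequency grid for spectral connectivity
#'
#' Regular grid from DC to Nyquist inclusive. At the default acquisition
#' settings (500 Hz sampling, 0.1 Hz resolution) this yields 2501 samples.
#'
#' @param fs sampling rate (Hz).
#' @param freq_resolution grid step (Hz).
#' @return numeric vector of frequencies in `[0, fs/2]`.
#' @export
gc_freq_grid <- function(fs, freq_resolution = 0.1) {
  stopifnot(fs > 0, freq_resolution > 0, freq_resolution <= fs / 2)
  seq(0, fs / 2, by = freq_resolution)
}

#' Canonical EEG frequency bands
#'
#' theta 4-8, alpha 8-12, beta 14-30, gamma 30-40 Hz. Band edges are
#' inclusive at both ends, so 8 Hz contributes to both theta and alpha and
#' 30 Hz to both beta and gamma; 12-14 Hz belongs to no band.
#'
#' @return named list of `c(lo, hi)` pairs (Hz).
#' @export
default_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 12), beta = c(14, 30), gamma = c(30, 40))
}

# Internal Gram-matrix engine for least-squares VAR fitting.
# X: samples x regions matrix (centered by caller); returns cross-moment
# blocks from which any sub-model (bivariate or univariate, order p) can be
# solved without touching the raw data again. Column order of Z: lag 1 for
# all regions, then lag 2, ...
ar_gram <- function(X, p) {
  T <- nrow(X)
  R <- ncol(X)
  if (T <= 10 * p) stop("series too short: need more than 10 * p samples")
  Emb <- stats::embed(X, p + 1L)
  Y <- Emb[, seq_len(R), drop = FALSE]
  Z <- Emb[, -seq_len(R), drop = FALSE]
  list(G = crossprod(Z), C = crossprod(Z, Y), YY = crossprod(Y),
       n_eff = T - p, R = R, p = p)
}

# Solve the bivariate VAR(p) for region pair (i, j) from precomputed Gram
# blocks; also returns the univariate reduced-model residual variances.
pair_model_from_gram <- function(gram, i, j, fs, labels = NULL) {
  p <- gram$p; R <- gram$R
  idx <- as.vector(vapply(seq_len(p) - 1L, function(k) k * R + c(i, j),
                          numeric(2)))
  Gs <- gram$G[idx, idx, drop = FALSE]
  Cs <- gram$C[idx, c(i, j), drop = FALSE]
  B <- tryCatch(solve(Gs, Cs), error = function(e) {
    stop("degenerate input for pair (", i, ",", j,
         "): rank-deficient regressor matrix (constant series?)")
  })
  sigma <- (gram$YY[c(i, j), c(i, j)] - crossprod(B, Cs)) / gram$n_eff
  sigma <- (sigma + t(sigma)) / 2
  coeff <- array(0, dim = c(2, 2, p))
  for (k in seq_len(p)) {
    # B rows for lag k are the (i, j) regressors; columns are the targets.
    # coeff[target, source, k] convention.
    coeff[, , k] <- t(B[(k - 1L) * 2L + 1:2, , drop = FALSE])
  }
  red <- vapply(c(i, j), function(r) {
    idu <- (seq_len(p) - 1L) * R + r
    Gu <- gram$G[idu, idu, drop = FALSE]
    Cu <- gram$C[idu, r, drop = FALSE]
    Bu <- tryCatch(solve(Gu, Cu), error = function(e) {
      stop("degenerate input for region ", r, ": constant series")
    })
    drop(gram$YY[r, r] - crossprod(Bu, Cu)) / gram$n_eff
  }, numeric(1))
  structure(list(order = p, coeff = coeff, noise_cov = sigma, fs = fs,
                 pair = c(i, j),
                 pair_labels = if (is.null(labels)) NULL else labels[c(i, j)],
                 reduced_var = stats::setNames(red, c("i", "j")),
                 n_eff = gram$n_eff),
            class = "bivar_var")
}

#' Fit a bivariate VAR model to two regional time series
#'
#' Ordinary least squares on lagged regressors: the coefficients minimise the
#' one-step prediction error over samples `p+1 .. T`, and the residual
#' covariance uses denominator `T - p`. Series are mean-centered before
#' fitting. The univariate reduced models (each series on its own past
#' alone), needed for time-domain Granger causality, are fitted from the
#' same cross-moments and exposed as `reduced_var`.
#'
#' @param x_i,x_j numeric series of equal length `T > 10 p`.
#' @param p model order (the analysis default downstream is 30).
#' @param fs sampling rate (Hz), carried into spectral computations.
#' @return object of class `bivar_var` with fields `order`, `coeff`
#'   (2 x 2 x p, `coeff[target, source, lag]`), `noise_cov`, `reduced_var`.
#' @export
fit_var <- function(x_i, x_j, p, fs = 500) {
  stopifnot(length(x_i) == length(x_j), p >= 1)
  X <- cbind(x_i - mean(x_i), x_j - mean(x_j))
  gram <- ar_gram(X, p)
  pair_model_from_gram(gram, 1L, 2L, fs = fs)
}

#' @export
print.bivar_var <- function(x, ...) {
  cat("bivariate VAR(", x$order, "), fs = ", x$fs, " Hz, pair (",
      x$pair[1], ",", x$pair[2], ")\n", sep = "")
  cat("  innovation covariance:\n")
  print(x$noise_cov)
  invisible(x)
}

# Vectorised 2x2 transfer/spectral/GC machinery shared by the estimator and
# the analytic oracle. coeff: 2 x 2 x p (target, source, lag); sigma: 2 x 2.
# Returns per-frequency S11, S22 (real), H entries (complex), and the two
# Geweke GC spectra. freq in Hz.
geweke_pair_spectrum <- function(coeff, sigma, fs, freq, eps = 1e-12) {
  p <- dim(coeff)[3]
  W <- exp(-2i * pi * outer(freq, seq_len(p)) / fs)   # F x p
  a11 <- 1 - as.vector(W %*% coeff[1, 1, ])
  a12 <-   - as.vector(W %*% coeff[1, 2, ])
  a21 <-   - as.vector(W %*% coeff[2, 1, ])
  a22 <- 1 - as.vector(W %*% coeff[2, 2, ])
  det <- a11 * a22 - a12 * a21
  bad <- Mod(det) < 1e-300
  if (any(bad)) {
    stop("characteristic matrix not invertible at f = ",
         paste(freq[which(bad)[seq_len(min(3, sum(bad)))]], collapse = ", "),
         " Hz")
  }
  H11 <- a22 / det; H12 <- -a12 / det
  H21 <- -a21 / det; H22 <- a11 / det
  s11 <- sigma[1, 1]; s22 <- sigma[2, 2]; s12 <- sigma[1, 2]
  S11 <- Re(H11 * Conj(H11)) * s11 + 2 * Re(H11 * Conj(H12)) * s12 +
    Re(H12 * Conj(H12)) * s22
  S22 <- Re(H21 * Conj(H21)) * s11 + 2 * Re(H21 * Conj(H22)) * s12 +
    Re(H22 * Conj(H22)) * s22
  # Geweke: causal power of 1 -> 2 is (s11 - s12^2/s22) |H21|^2; the
  # remainder |H22 + (s12/s22) H21|^2 s22 is the intrinsic part of S22.
  caus12 <- (s11 - s12^2 / s22) * Re(H21 * Conj(H21))
  caus21 <- (s22 - s12^2 / s11) * Re(H12 * Conj(H12))
  den12 <- S22 - caus12
  den21 <- S11 - caus21
  clamp12 <- den12 <= eps * S22
  clamp21 <- den21 <= eps * S11
  den12[clamp12] <- eps * S22[clamp12]
  den21[clamp21] <- eps * S11[clamp21]
  gc12 <- log(S22 / den12)
  gc21 <- log(S11 / den21)
  neg12 <- gc12 < 0; neg21 <- gc21 < 0
  gc12[neg12] <- 0; gc21[neg21] <- 0
  list(freq = freq, S11 = S11, S22 = S22,
       H11 = H11, H12 = H12, H21 = H21, H22 = H22,
       gc12 = gc12, gc21 = gc21,
       n_clamped = sum(clamp12) + sum(clamp21) + sum(neg12) + sum(neg21))
}

#' Transfer function and spectral matrix of a bivariate VAR model
#'
#' `H(f) = (I - sum_k A_k e^{-i 2 pi f k / fs})^{-1}` and
#' `S(f) = H(f) Sigma H(f)*`.
#'
#' @param model a `bivar_var` from [fit_var()].
#' @param freq_grid frequencies (Hz), within `[0, fs/2]`.
#' @return list of class `spectral_factors`: `freq_grid`, `H` (complex array
#'   `2 x 2 x F`), `S` (complex array `2 x 2 x F`).
#' @export
spectral_factors <- function(model, freq_grid) {
  stopifnot(inherits(model, "bivar_var"),
            all(freq_grid >= 0), all(freq_grid <= model$fs / 2))
  gp <- geweke_pair_spectrum(model$coeff, model$noise_cov, model$fs, freq_grid)
  nf <- length(freq_grid)
  H <- array(0i, dim = c(2, 2, nf))
  H[1, 1, ] <- gp$H11; H[1, 2, ] <- gp$H12
  H[2, 1, ] <- gp$H21; H[2, 2, ] <- gp$H22
  s <- model$noise_cov
  S <- array(0i, dim = c(2, 2, nf))
  S[1, 1, ] <- gp$S11
  S[2, 2, ] <- gp$S22
  S12 <- gp$H11 * Conj(gp$H21) * s[1, 1] + gp$H11 * Conj(gp$H22) * s[1, 2] +
    gp$H12 * Conj(gp$H21) * s[1, 2] + gp$H12 * Conj(gp$H22) * s[2, 2]
  S[1, 2, ] <- S12
  S[2, 1, ] <- Conj(S12)
  structure(list(freq_grid = freq_grid, H = H, S = S),
            class = "spectral_factors")
}

#' Spectral Granger causality for both directions of a fitted pair
#'
#' Geweke's frequency-domain measure: the power spectrum of the target is
#' partitioned into an intrinsic part and a causal part predicted by the
#' source, and GC(f) is the log ratio of total to intrinsic power,
#' `GC_{i->j}(f) = ln( S_jj / (S_jj - (Sigma_ii - Sigma_ij^2/Sigma_jj)
#' |H_ji(f)|^2) )`. Values are clamped at 0 against round-off; clamp events
#' are counted in the result.
#'
#' @inheritParams spectral_factors
#' @return list of class `gc_spectrum_pair` with `freq_grid`, `gc_ij`,
#'   `gc_ji` (non-negative, nats), `pair`, `n_clamped`.
#' @export
spectral_gc_pair <- function(model, freq_grid) {
  stopifnot(inherits(model, "bivar_var"),
            all(freq_grid >= 0), all(freq_grid <= model$fs / 2))
  gp <- geweke_pair_spectrum(model$coeff, model$noise_cov, model$fs, freq_grid)
  structure(list(freq_grid = freq_grid, gc_ij = gp$gc12, gc_ji = gp$gc21,
                 pair = model$pair, n_clamped = gp$n_clamped),
            class = "gc_spectrum_pair")
}

#' Time-domain Granger causality of a fitted pair
#'
#' `ln(sigma^2_reduced / sigma^2_full)` for each direction, where the
#' reduced variance comes from the univariate fit on the target's own past
#' and the full variance is the corresponding diagonal element of the
#' bivariate innovation covariance. The instantaneous (contemporaneous)
#' causality `ln(Sigma_ii Sigma_jj / det Sigma)` is also returned; when it
#' is small the spectral measure integrates to the time-domain measure.
#'
#' @param model a `bivar_var`.
#' @return named list `gc_ij`, `gc_ji`, `instantaneous`.
#' @export
time_domain_gc <- function(model) {
  s <- model$noise_cov
  list(gc_ij = log(model$reduced_var[["j"]] / s[2, 2]),
       gc_ji = log(model$reduced_var[["i"]] / s[1, 1]),
       instantaneous = log(s[1, 1] * s[2, 2] / det(s)))
}

#' All-pairs spectral connectivity for one subject
#'
#' Fits one bivariate VAR per unordered region pair (both directions come
#' from the same fit) and evaluates the Geweke spectral GC on the full
#' DC-to-Nyquist grid. All pairs share one precomputed Gram matrix of
#' lagged cross-moments, so the cost per pair is a small linear solve.
#' Pairs whose fit fails (degenerate series) are recorded as missing (`NA`
#' across frequencies), not as zero.
#'
#' @param subject a `ts_set`.
#' @param p AR model order (default 30).
#' @param freq_resolution grid step (Hz, default 0.1).
#' @return object of class `spectral_connectivity`: `subject_id`,
#'   `gc` (R x R x F array, zero diagonal), `freq_grid`, `roi_labels`,
#'   `n_clamped`, `failed_pairs`.
#' @export
connectivity_matrices <- function(subject, p = 30L, freq_resolution = 0.1) {
  stopifnot(inherits(subject, "ts_set"))
  X <- t(subject$data)
  R <- ncol(X)
  if (R < 2) stop("need at least 2 regions")
  if (any(!is.finite(X))) stop("non-finite values in time series")
  X <- scale(X, center = TRUE, scale = FALSE)
  freq <- gc_freq_grid(subject$fs, freq_resolution)
  gram <- ar_gram(X, p)
  gc <- array(0, dim = c(R, R, length(freq)),
              dimnames = list(subject$roi_labels, subject$roi_labels, NULL))
  n_clamped <- 0L
  failed <- list()
  for (i in seq_len(R - 1L)) {
    for (j in (i + 1L):R) {
      res <- tryCatch({
        m <- pair_model_from_gram(gram, i, j, fs = subject$fs,
                                  labels = subject$roi_labels)
        geweke_pair_spectrum(m$coeff, m$noise_cov, m$fs, freq)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        gc[i, j, ] <- NA_real_
        gc[j, i, ] <- NA_real_
        failed[[length(failed) + 1L]] <-
          list(pair = c(i, j), message = conditionMessage(res))
      } else {
        gc[i, j, ] <- res$gc12
        gc[j, i, ] <- res$gc21
        n_clamped <- n_clamped + res$n_clamped
      }
    }
  }
  structure(list(subject_id = subject$subject_id, gc = gc, freq_grid = freq,
                 roi_labels = subject$roi_labels, n_clamped = n_clamped,
                 failed_pairs = failed),
            class = "spectral_connectivity")
}

#' @export
print.spectral_connectivity <- function(x, ...) {
  d <- dim(x$gc)
  cat("spectral_connectivity '", x$subject_id, "': ", d[1], " x ", d[2],
      " x ", d[3], " (regions x regions x frequencies)\n", sep = "")
  if (length(x$failed_pairs)) {
    cat("  failed pairs: ", length(x$failed_pairs), "\n", sep = "")
  }
  invisible(x)
}

#' Average a spectral connectivity tensor into frequency bands
#'
#' Arithmetic mean of `GC_{i->j}(f)` over grid points with
#' `lo <= f <= hi` (both ends inclusive).
#'
#' @param conn a `spectral_connectivity`.
#' @param bands named list of `c(lo, hi)` (Hz); default [default_bands()].
#' @return object of class `band_connectivity`: `subject_id`, `bands`
#'   (named list of R x R adjacency matrices), `band_defs`, `roi_labels`.
#' @export
band_average <- function(conn, bands = default_bands()) {
  stopifnot(inherits(conn, "spectral_connectivity"))
  freq <- conn$freq_grid
  tol <- 1e-9
  mats <- lapply(bands, function(b) {
    stopifnot(length(b) == 2, b[1] <= b[2], b[2] <= max(freq) + tol)
    sel <- which(freq >= b[1] - tol & freq <= b[2] + tol)
    if (!length(sel)) {
      stop("band [", b[1], ", ", b[2], "] Hz contains no grid point")
    }
    A <- apply(conn$gc[, , sel, drop = FALSE], c(1, 2), mean)
    diag(A) <- 0
    A
  })
  structure(list(subject_id = conn$subject_id, bands = mats,
                 band_defs = bands, roi_labels = conn$roi_labels),
            class = "band_connectivity")
}
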