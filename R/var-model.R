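#' Ground-truth vector-autoregressive model specifications
#'
#' A `var_model_spec` holds the complete generative description of a
#' stationary VAR(p) process used to emulate source-level resting-state
#' activity: the lag coefficient matrices, the innovation covariance, the
#' sampling rate, and the list of band-specific directed couplings that were
#' planted in it. Because the coefficients are known exactly, spectral
#' Granger causality can be computed analytically from the spec
#' (see [analytic_spectral_gc()]) and used as an oracle for the estimator.
#'
#' @name var_model_spec
#' @seealso [make_var_model()], [simulate_var()], [analytic_spectral_gc()]
NULL

#' Companion matrix of a VAR(p) coefficient array
#'
#' @param coeff numeric array `R x R x p`; `coeff[,,k]` is the lag-k
#'   coefficient matrix (row = target, column = source).
#' @return the `Rp x Rp` companion matrix.
#' @keywords internal
companion_matrix <- function(coeff) {
  R <- dim(coeff)[1]
  p <- dim(coeff)[3]
  M <- matrix(0, R * p, R * p)
  for (k in seq_len(p)) {
    M[seq_len(R), (k - 1L) * R + seq_len(R)] <- coeff[, , k]
  }
  if (p > 1) {
    M[R + seq_len(R * (p - 1L)), seq_len(R * (p - 1L))] <-
      diag(R * (p - 1L))
  }
  M
}

#' Spectral radius of the companion matrix (stationarity check)
#'
#' @param coeff VAR coefficient array `R x R x p`.
#' @return largest eigenvalue modulus of the companion matrix; the process
#'   is (covariance) stationary iff this is `< 1`.
#' @export
var_spectral_radius <- function(coeff) {
  max(Mod(eigen(companion_matrix(coeff), only.values = TRUE)$values))
}

#' Default band-specific coupling targets for a synthetic cohort
#'
#' Encodes the canonical resting-state motif the simulator emulates:
#' top-down (frontal to posterior) coupling carried by slow rhythms
#' (theta, alpha) and bottom-up (posterior to frontal) coupling carried by
#' fast rhythms (beta, gamma). Source regions are split round-robin among
#' the slow bands (frontal) and fast bands (posterior), so each source
#' carries exactly one rhythm: a damped cortical oscillator at the band's
#' center frequency. Each source then drives every region of the opposite
#' cluster plus the later-indexed sources of its own band (feed-forward
#' within-cluster coupling, so band difference networks contain closed
#' triangles rather than a purely bipartite pattern -- without them,
#' neighbourhood-based segregation measures would be degenerately zero on
#' the sparse group difference network). Within-band coupling is kept
#' acyclic: a feedback loop between two resonators at the same frequency
#' is amplified by both resonances and destabilises the process at gains
#' that are otherwise physiological.
#'
#' @param frontal integer indices of frontal source regions.
#' @param posterior integer indices of posterior regions.
#' @param strength coupling strength expressed as a fraction of the source
#'   oscillator's resonance amplification: the lag-1 cross coefficient is
#'   `strength * (1 - r)` with pole radius `r = exp(-pi * bw / fs)`, so the
#'   effective drive at the source's resonance (where `|H|` is about
#'   `1 / (1 - r)`) is `strength` regardless of band or sampling rate.
#'   The default produces spectral GC peaks of a few tenths of a nat at
#'   the planted frequency, in the range seen for strongly coupled cortical
#'   region pairs, while keeping multi-loop motifs stationary from the
#'   6-region toy scale up to the 68-region atlas at 500 Hz.
#' @param fs sampling rate (Hz) the model will be built at; needed to
#'   convert `strength` into a lag-1 coefficient.
#' @param slow_bands,fast_bands band names for the top-down and bottom-up
#'   motifs; restrict these to plant couplings in fewer bands.
#' @return data frame with columns `source`, `target`, `f0` (center
#'   frequency, Hz), `bw` (-3 dB bandwidth, Hz), `gain`, `band`.
#' @export
default_band_targets <- function(frontal, posterior, strength = 0.8,
                                 fs = 500,
                                 slow_bands = c("theta", "alpha"),
                                 fast_bands = c("beta", "gamma")) {
  band_f0 <- c(theta = 6, alpha = 10, beta = 22, gamma = 35)
  band_bw <- c(theta = 3, alpha = 3, beta = 6, gamma = 5)
  stopifnot(all(c(slow_bands, fast_bands) %in% names(band_f0)))
  rows <- list()
  add_motif <- function(sources, targets, bands) {
    src_band <- bands[1L + (seq_along(sources) - 1L) %% length(bands)]
    for (s in seq_along(sources)) {
      b <- src_band[s]
      gain <- strength * (1 - exp(-pi * band_bw[[b]] / fs))
      peers <- sources[src_band == b & seq_along(sources) > s]
      for (tg in c(targets, peers)) {
        rows[[length(rows) + 1L]] <<- data.frame(
          source = sources[s], target = tg,
          f0 = band_f0[[b]], bw = band_bw[[b]], gain = gain, band = b
        )
      }
    }
  }
  add_motif(frontal, posterior, slow_bands)
  add_motif(posterior, frontal, fast_bands)
  out <- do.call(rbind, rows)
  # normalise each edge by its target's in-degree, keeping every region's
  # total incoming coupling budget fixed as the network grows (the directed
  # analogue of synaptic scaling); without it, dense motifs lose
  # stationarity at per-edge gains that are harmless in a sparse network
  indeg <- table(out$target)
  out$gain <- out$gain / as.numeric(indeg[as.character(out$target)])
  out
}

#' Construct a stationary VAR model with band-specific directed coupling
#'
#' Each source region listed in `band_targets` receives a damped-oscillator
#' pole pair at its center frequency: with pole radius
#' `r = exp(-pi * bw / fs)` and angle `2*pi*f0/fs`, the lag-1/lag-2 self
#' coefficients are `2 r cos(theta)` and `-r^2`, which places the -3 dB
#' width of the spectral resonance at approximately `bw`. Directed influence
#' is a lag-1 cross coefficient `gain * group_effect` from source to target.
#' Regions that source no oscillator get a mild AR(1) self term drawn
#' uniformly from `base_range` (seeded, so the spec is reproducible).
#'
#' @param n_rois number of regions (>= 2).
#' @param band_targets data frame as returned by [default_band_targets()],
#'   or `NULL` for fully independent channels.
#' @param group_effect multiplicative attenuation in `[0, 1]` applied to all
#'   coupling gains; `1` is the full-gain (low-schizotypy-like) model.
#' @param seed integer seed controlling the baseline AR(1) draws.
#' @param fs sampling rate (Hz).
#' @param order model order (>= 2 when oscillators are present).
#' @param noise_sd innovation standard deviation (shared by all regions;
#'   the innovation covariance is diagonal so connectivity differences are
#'   never confounded with instantaneous correlation).
#' @param base_range range of the uniform draw for non-oscillator AR(1)
#'   self coefficients.
#' @return object of class `var_model_spec`.
#' @export
make_var_model <- function(n_rois, band_targets = NULL, group_effect = 1,
                           seed = 1L, fs = 500, order = 3L,
                           noise_sd = 1, base_range = c(0.3, 0.6)) {
  stopifnot(n_rois >= 2, order >= 2, group_effect >= 0, group_effect <= 1)
  if (!is.null(band_targets) && nrow(band_targets) > 0) {
    stopifnot(all(band_targets$f0 < fs / 2), all(band_targets$bw > 0),
              all(is.finite(band_targets$gain)),
              all(band_targets$source >= 1), all(band_targets$source <= n_rois),
              all(band_targets$target >= 1), all(band_targets$target <= n_rois),
              all(band_targets$source != band_targets$target))
  }
  coeff <- array(0, dim = c(n_rois, n_rois, order))
  set.seed(as.integer(seed))
  base_a <- stats::runif(n_rois, base_range[1], base_range[2])
  sources <- if (is.null(band_targets)) integer(0) else unique(band_targets$source)
  for (s in sources) {
    if (length(unique(band_targets$f0[band_targets$source == s])) > 1) {
      stop("source region ", s, " is assigned more than one oscillator ",
           "frequency; give each source a single band")
    }
  }
  for (i in seq_len(n_rois)) {
    if (i %in% sources) {
      tgt <- band_targets[match(i, band_targets$source), ]
      r <- exp(-pi * tgt$bw / fs)
      th <- 2 * pi * tgt$f0 / fs
      coeff[i, i, 1] <- 2 * r * cos(th)
      coeff[i, i, 2] <- -r^2
    } else {
      coeff[i, i, 1] <- base_a[i]
    }
  }
  if (!is.null(band_targets)) {
    for (k in seq_len(nrow(band_targets))) {
      coeff[band_targets$target[k], band_targets$source[k], 1] <-
        coeff[band_targets$target[k], band_targets$source[k], 1] +
        band_targets$gain[k] * group_effect
    }
  }
  rho <- var_spectral_radius(coeff)
  if (rho >= 1) {
    stop("constructed model is non-stationary (companion spectral radius ",
         format(rho, digits = 4), " >= 1); reduce coupling gains")
  }
  structure(list(
    n_rois = as.integer(n_rois),
    order = as.integer(order),
    coeff = coeff,
    noise_cov = diag(noise_sd^2, n_rois),
    fs = fs,
    band_targets = band_targets,
    spectral_radius = rho
  ), class = "var_model_spec")
}

#' @export
print.var_model_spec <- function(x, ...) {
  cat("VAR(", x$order, ") model: ", x$n_rois, " regions, fs = ", x$fs,
      " Hz, companion spectral radius = ", format(x$spectral_radius, digits = 4),
      "\n", sep = "")
  nt <- if (is.null(x$band_targets)) 0L else nrow(x$band_targets)
  cat("  band-specific directed couplings: ", nt, "\n", sep = "")
  invisible(x)
}

#' Simulate a regional time-series set from a VAR model
#'
#' Draws Gaussian innovations, iterates the VAR recursion and discards a
#' burn-in segment so the emitted samples come from the stationary
#' distribution. With the same `(model, n_samples, seed)` the output is
#' bitwise reproducible.
#'
#' @param model a [var_model_spec].
#' @param n_samples number of retained samples (must exceed `10 * order`).
#' @param seed integer seed for the innovation draws.
#' @param subject_id label stored with the output.
#' @param burn_in transient samples discarded before recording (>= 1000).
#' @param roi_labels optional label vector (default `ROI01`, `ROI02`, ...).
#' @return object of class `ts_set` with fields `subject_id`, `fs`,
#'   `data` (regions x samples matrix) and `roi_labels`.
#' @export
simulate_var <- function(model, n_samples, seed = 1L,
                         subject_id = "sim", burn_in = 1000L,
                         roi_labels = NULL) {
  stopifnot(inherits(model, "var_model_spec"))
  if (model$spectral_radius >= 1) stop("refusing to simulate a non-stationary model")
  if (n_samples <= 10 * model$order) {
    stop("n_samples must exceed 10 * model order (", 10 * model$order, ")")
  }
  burn_in <- max(as.integer(burn_in), 1000L)
  R <- model$n_rois
  p <- model$order
  ntot <- n_samples + burn_in
  set.seed(as.integer(seed))
  innov <- matrix(stats::rnorm(R * ntot), nrow = R)
  L <- t(chol(model$noise_cov))
  innov <- L %*% innov
  x <- matrix(0, R, ntot)
  A <- lapply(seq_len(p), function(k) model$coeff[, , k])
  for (t in (p + 1L):ntot) {
    acc <- innov[, t]
    for (k in seq_len(p)) acc <- acc + A[[k]] %*% x[, t - k]
    x[, t] <- acc
  }
  data <- x[, (burn_in + 1L):ntot, drop = FALSE]
  if (is.null(roi_labels)) roi_labels <- sprintf("ROI%02d", seq_len(R))
  rownames(data) <- roi_labels
  structure(list(subject_id = subject_id, fs = model$fs,
                 data = data, roi_labels = roi_labels),
            class = "ts_set")
}

#' @export
print.ts_set <- function(x, ...) {
  cat("ts_set '", x$subject_id, "': ", nrow(x$data), " regions x ",
      ncol(x$data), " samples @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Exact autocovariance sequence of a stationary VAR model
#'
#' Solves the companion-form discrete Lyapunov equation
#' `P = A P A' + Q` by doubling iteration and propagates the Yule-Walker
#' recursion to the requested maximum lag.
#'
#' @param model a [var_model_spec].
#' @param max_lag highest lag h for which Gamma(h) is returned.
#' @return list of `max_lag + 1` matrices, `[[h + 1]]` = Gamma(h) =
#'   E[x_t x_{t-h}'].
#' @keywords internal
var_autocov <- function(model, max_lag) {
  R <- model$n_rois
  p <- model$order
  A <- companion_matrix(model$coeff)
  Q <- matrix(0, R * p, R * p)
  Q[seq_len(R), seq_len(R)] <- model$noise_cov
  # doubling iteration: P_{k+1} = P_k + A_k P_k A_k', A_{k+1} = A_k^2
  P <- Q
  Ak <- A
  for (it in 1:60) {
    incr <- Ak %*% P %*% t(Ak)
    P <- P + incr
    if (max(abs(incr)) < 1e-14 * max(abs(P))) break
    Ak <- Ak %*% Ak
  }
  P <- (P + t(P)) / 2
  gam <- vector("list", max_lag + 1L)
  # companion stationary covariance holds Gamma(j-i) in block (i, j)
  for (h in 0:min(max_lag, p - 1L)) {
    gam[[h + 1L]] <- P[seq_len(R), h * R + seq_len(R), drop = FALSE]
  }
  if (max_lag >= p) {
    for (h in p:max_lag) {
      acc <- matrix(0, R, R)
      for (k in seq_len(p)) acc <- acc + model$coeff[, , k] %*% gam[[h - k + 1L]]
      gam[[h + 1L]] <- acc
    }
  }
  gam
}

#' Yule-Walker AR fit from an exact autocovariance sequence
#'
#' Solves the multivariate Yule-Walker equations
#' `Gamma(m) = sum_k B_k Gamma(m-k)` for `m = 1..q` given exact
#' autocovariances, returning AR coefficients and innovation covariance of
#' the best order-q linear predictor. Used to obtain the (VARMA) marginal
#' process of a region pair as a high-order AR model.
#'
#' @param gam list of autocovariance matrices Gamma(0..q).
#' @param q AR order.
#' @return list with `coeff` (`d x d x q` array) and `sigma` (`d x d`).
#' @keywords internal
yule_walker_ar <- function(gam, q) {
  d <- nrow(gam[[1]])
  G <- function(h) if (h >= 0) gam[[h + 1L]] else t(gam[[-h + 1L]])
  Tmat <- matrix(0, d * q, d * q)
  for (k in seq_len(q)) {
    for (m in seq_len(q)) {
      Tmat[(k - 1L) * d + seq_len(d), (m - 1L) * d + seq_len(d)] <- G(m - k)
    }
  }
  Grow <- do.call(cbind, lapply(seq_len(q), G))        # [Gamma(1) ... Gamma(q)]
  B <- Grow %*% solve(Tmat)                            # d x dq
  coeff <- array(0, dim = c(d, d, q))
  sigma <- gam[[1]]
  for (k in seq_len(q)) {
    Bk <- B[, (k - 1L) * d + seq_len(d), drop = FALSE]
    coeff[, , k] <- Bk
    sigma <- sigma - Bk %*% t(gam[[k + 1L]])
  }
  list(coeff = coeff, sigma = (sigma + t(sigma)) / 2)
}
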