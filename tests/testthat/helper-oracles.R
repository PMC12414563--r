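# Independent brute-force oracles and small fixture generators.

# Shortest directed path length from i to j by exhaustive enumeration of
# all simple paths (lengths L_ij = 1/A_ij). Independent of any graph
# library; only feasible for small n.
brute_shortest <- function(A, i, j) {
  n <- nrow(A)
  best <- Inf
  visit <- function(node, dist, seen) {
    if (dist >= best) return(invisible(NULL))
    if (node == j) {
      best <<- dist
      return(invisible(NULL))
    }
    for (nxt in seq_len(n)) {
      if (!seen[nxt] && A[node, nxt] > 0) {
        seen[nxt] <- TRUE
        visit(nxt, dist + 1 / A[node, nxt], seen)
        seen[nxt] <- FALSE
      }
    }
  }
  seen <- rep(FALSE, n)
  seen[i] <- TRUE
  visit(i, 0, seen)
  best
}

brute_global_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        d <- brute_shortest(A, i, j)
        if (is.finite(d) && d > 0) acc <- acc + 1 / d
      }
    }
  }
  acc / (n * (n - 1))
}

brute_local_efficiency <- function(A) {
  n <- nrow(A)
  eff <- vapply(seq_len(n), function(i) {
    nbrs <- setdiff(which(A[i, ] > 0 | A[, i] > 0), i)
    if (length(nbrs) < 2) return(0)
    brute_global_efficiency(A[nbrs, nbrs, drop = FALSE])
  }, numeric(1))
  mean(eff)
}

# Random weighted digraph with edge probability p_edge.
random_digraph <- function(n, p_edge = 0.4) {
  A <- matrix(stats::runif(n * n, 0.1, 2) *
                (stats::runif(n * n) < p_edge), n, n)
  diag(A) <- 0
  A
}

# Random stable bivariate VAR spec with diagonal innovation covariance:
# coefficient matrices are redrawn until the companion spectral radius is
# comfortably below 1 and (by default) each channel's own-lag polynomial
# is itself stable. The latter keeps the intrinsic spectral factor
# minimum-phase, which is the condition under which the spectral GC
# integrates exactly to the time-domain measure.
random_stable_bivar <- function(order = 2, max_radius = 0.9,
                                min_phase = TRUE) {
  repeat {
    coeff <- array(stats::rnorm(4 * order, sd = 0.4), dim = c(2, 2, order))
    rho <- var_spectral_radius(coeff)
    if (rho >= max_radius || rho == 0) next
    if (min_phase &&
        !all(vapply(1:2, function(c) {
          all(Mod(polyroot(c(1, -coeff[c, c, ]))) > 1)
        }, logical(1)))) next
    break
  }
  coeff
}

# Wrap a coefficient array into a var_model_spec without the constructor's
# oscillator scaffolding (for tests that need arbitrary coefficients).
as_var_spec <- function(coeff, noise_cov = NULL, fs = 250) {
  R <- dim(coeff)[1]
  if (is.null(noise_cov)) noise_cov <- diag(R)
  structure(list(n_rois = R, order = dim(coeff)[3], coeff = coeff,
                 noise_cov = noise_cov, fs = fs, band_targets = NULL,
                 spectral_radius = var_spectral_radius(coeff)),
            class = "var_model_spec")
}
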