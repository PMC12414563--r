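# Shared two-sample permutation machinery.
#
# X: subjects x variables matrix; grp1 logical vector marking group 1.
# Pooled-variance Student t per variable; one shared sequence of label
# shuffles applied to every variable (each variable's null uses only its
# own statistic, so sharing shuffles is valid and fully vectorised).
# p = (1 + #{|t_perm| >= |t_obs|}) / (n_perm + 1).
perm_t_test <- function(X, grp1, n_perm, seed, welch = FALSE) {
  stopifnot(is.matrix(X), length(grp1) == nrow(X), n_perm >= 1)
  n <- nrow(X)
  n1 <- sum(grp1)
  n2 <- n - n1
  stopifnot(n1 >= 2, n2 >= 2)
  Xsq <- X^2
  Stot <- colSums(X)
  SStot <- colSums(Xsq)
  tstat_from_ind <- function(P) {
    # P: draws x subjects 0/1 indicator of group 1
    S1 <- P %*% X
    SS1 <- P %*% Xsq
    S2 <- rep(1, nrow(P)) %*% t(Stot) - S1
    SS2 <- rep(1, nrow(P)) %*% t(SStot) - SS1
    m1 <- S1 / n1
    m2 <- S2 / n2
    v1 <- (SS1 - S1^2 / n1)
    v2 <- (SS2 - S2^2 / n2)
    if (welch) {
      se2 <- v1 / (n1 - 1) / n1 + v2 / (n2 - 1) / n2
    } else {
      sp2 <- (v1 + v2) / (n1 + n2 - 2)
      se2 <- sp2 * (1 / n1 + 1 / n2)
    }
    list(t = (m1 - m2) / sqrt(se2), se2 = se2)
  }
  obs <- tstat_from_ind(matrix(as.numeric(grp1), nrow = 1))
  t_obs <- drop(obs$t)
  # zero pooled variance up to round-off relative to the variable's scale
  vtot <- SStot - Stot^2 / n
  degenerate <- !is.finite(t_obs) | drop(obs$se2) <= 0 |
    vtot <= 1e-10 * pmax(SStot, .Machine$double.xmin)
  t_obs[degenerate] <- 0
  set.seed(as.integer(seed))
  exceed <- numeric(ncol(X))
  done <- 0L
  chunk <- 500L  # bound the n_perm x n_vars working set
  while (done < n_perm) {
    nb <- min(chunk, n_perm - done)
    P <- matrix(0, nb, n)
    for (b in seq_len(nb)) {
      P[b, sample.int(n, n1)] <- 1
    }
    t_perm <- tstat_from_ind(P)$t
    t_perm[!is.finite(t_perm)] <- 0
    exceed <- exceed + colSums(abs(t_perm) >= rep(abs(t_obs), each = nb))
    done <- done + nb
  }
  p <- (1 + exceed) / (n_perm + 1)
  p[degenerate] <- 1
  list(t_obs = t_obs, p = p, degenerate = degenerate,
       n1 = n1, n2 = n2, n_perm = n_perm, seed = as.integer(seed))
}

#' Edgewise two-sample permutation t-tests between groups
#'
#' For every directed edge, a two-tailed nonparametric permutation test of
#' the group difference in band connectivity: the observed statistic is the
#' pooled-variance Student t, and its null distribution comes from random
#' relabelings of subjects into groups (one shared shuffle sequence for all
#' edges). Diagonal entries and zero-variance edges are degenerate and get
#' `t = 0`, `p = 1`.
#'
#' @param low,high lists of R x R band adjacency matrices (one per subject).
#' @param n_perm number of permutations (the analysis default is 5000).
#' @param seed integer seed for the shuffle sequence.
#' @param welch use Welch's unequal-variance t instead of pooled (default
#'   pooled, matching near-equal group sizes).
#' @return object of class `edge_stats`: `t_obs`, `p_perm` (R x R
#'   matrices), `n_perm`, `seed`, `band` (filled by callers).
#' @export
edge_permutation_test <- function(low, high, n_perm = 5000L, seed = 1L,
                                  welch = FALSE) {
  stopifnot(length(low) >= 1, length(high) >= 1)
  dims <- dim(low[[1]])
  stopifnot(dims[1] == dims[2])
  ok <- vapply(c(low, high), function(A) identical(dim(A), dims), logical(1))
  if (!all(ok)) stop("matrices are not conformable")
  R <- dims[1]
  X <- t(vapply(c(low, high), as.vector, numeric(R * R)))
  grp1 <- rep(c(TRUE, FALSE), c(length(low), length(high)))
  res <- perm_t_test(X, grp1, n_perm = n_perm, seed = seed, welch = welch)
  t_obs <- matrix(res$t_obs, R, R, dimnames = dimnames(low[[1]]))
  p <- matrix(res$p, R, R, dimnames = dimnames(low[[1]]))
  diag(t_obs) <- 0
  diag(p) <- 1
  structure(list(t_obs = t_obs, p_perm = p, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), n_low = length(low),
                 n_high = length(high), band = NA_character_),
            class = "edge_stats")
}

#' Sparsify subject matrices by the group-contrast edge mask
#'
#' Retains only edges whose permutation p-value is below `alpha`
#' (uncorrected), setting all other entries of every subject's matrix to
#' exactly zero. The mask is shared by all subjects. With
#' `bypass = TRUE` the inputs are returned unchanged (the complete,
#' non-thresholded variant of the analysis) and the mask keeps every
#' off-diagonal edge.
#'
#' @param subjects list of R x R band adjacency matrices.
#' @param stats an `edge_stats` for the same cohort and band.
#' @param alpha retention threshold in (0, 1), default 0.05.
#' @param bypass disable sparsification.
#' @return object of class `sparse_band_connectivity`: `matrices` (list),
#'   `mask` (logical R x R), `retained` (edge count), `alpha`, `bypass`.
#' @export
apply_sparsity_mask <- function(subjects, stats, alpha = 0.05,
                                bypass = FALSE) {
  stopifnot(inherits(stats, "edge_stats"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  R <- nrow(stats$p_perm)
  stopifnot(all(vapply(subjects, function(A) all(dim(A) == R), logical(1))))
  if (bypass) {
    mask <- matrix(TRUE, R, R, dimnames = dimnames(stats$p_perm))
    diag(mask) <- FALSE
    out <- subjects
  } else {
    mask <- stats$p_perm < alpha
    diag(mask) <- FALSE
    out <- lapply(subjects, function(A) {
      A[!mask] <- 0
      A
    })
  }
  structure(list(matrices = out, mask = mask, retained = sum(mask),
                 alpha = alpha, bypass = bypass),
            class = "sparse_band_connectivity")
}
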