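#' Analytic spectral Granger causality from true VAR coefficients
#'
#' Computes, with no estimation step, the Geweke spectral GC of every
#' ordered region pair of a known stationary VAR model. For a 2-region
#' model the bivariate process is the model itself and the result is exact.
#' For larger models the marginal process of each pair is a VARMA; it is
#' represented by its exact autocovariance sequence (companion-form
#' Lyapunov solution) and reduced to a high-order bivariate AR model via
#' the Yule-Walker equations, after which the same Geweke formula applies.
#' Pairs with no direct or indirect influence have exactly zero
#' cross-autocovariance and therefore exactly zero GC.
#'
#' @param model a [var_model_spec].
#' @param freq_grid frequencies (Hz) within `[0, fs/2]`.
#' @param marginal_order AR order used for the pairwise marginal
#'   representation when `n_rois > 2`; the truncation error decays with the
#'   model's companion spectral radius to this power.
#' @return object of class `gc_oracle`: `gc` (R x R x F array, zero
#'   diagonal), `freq_grid`.
#' @export
analytic_spectral_gc <- function(model, freq_grid, marginal_order = 200L) {
  stopifnot(inherits(model, "var_model_spec"),
            all(freq_grid >= 0), all(freq_grid <= model$fs / 2))
  if (model$spectral_radius >= 1) stop("model is not stationary")
  R <- model$n_rois
  nf <- length(freq_grid)
  gc <- array(0, dim = c(R, R, nf))
  if (R == 2) {
    gp <- geweke_pair_spectrum(model$coeff, model$noise_cov, model$fs,
                               freq_grid)
    gc[1, 2, ] <- gp$gc12
    gc[2, 1, ] <- gp$gc21
  } else {
    q <- as.integer(marginal_order)
    gam <- var_autocov(model, q)
    for (i in seq_len(R - 1L)) {
      for (j in (i + 1L):R) {
        sub <- lapply(gam, function(g) g[c(i, j), c(i, j), drop = FALSE])
        # independent pairs short-circuit to exact zero
        cross <- max(vapply(sub, function(g) max(abs(g[1, 2]), abs(g[2, 1])),
                            numeric(1)))
        if (cross == 0) next
        yw <- yule_walker_ar(sub, q)
        gp <- geweke_pair_spectrum(yw$coeff, yw$sigma, model$fs, freq_grid)
        gc[i, j, ] <- gp$gc12
        gc[j, i, ] <- gp$gc21
      }
    }
  }
  structure(list(gc = gc, freq_grid = freq_grid), class = "gc_oracle")
}

#' Analytic time-domain Granger causality of a 2-region VAR model
#'
#' `ln(sigma^2_reduced / sigma^2_full)` per direction, where the reduced
#' innovation variance of each channel's univariate marginal is obtained by
#' Yule-Walker on the exact autocovariance sequence.
#'
#' @param model a 2-region [var_model_spec].
#' @param marginal_order univariate AR truncation order.
#' @return named list `gc_12`, `gc_21`.
#' @export
analytic_time_gc <- function(model, marginal_order = 200L) {
  stopifnot(inherits(model, "var_model_spec"), model$n_rois == 2)
  q <- as.integer(marginal_order)
  gam <- var_autocov(model, q)
  red <- vapply(1:2, function(r) {
    sub <- lapply(gam, function(g) g[r, r, drop = FALSE])
    yule_walker_ar(sub, q)$sigma[1, 1]
  }, numeric(1))
  list(gc_12 = log(red[2] / model$noise_cov[2, 2]),
       gc_21 = log(red[1] / model$noise_cov[1, 1]))
}

#' Synthetic atlas/partition table for an n-region cohort
#'
#' Assigns the first `n_frontal` regions to the frontal cluster, the last
#' `n_posterior` to the posterior cluster, and the remainder to the
#' excluded temporo-central cluster, mimicking the three-way anatomical
#' categorisation used for the directional indices.
#'
#' @param n_rois total regions.
#' @param n_frontal,n_posterior cluster sizes.
#' @return data frame with columns `roi`, `label`, `hemisphere`, `lobe`,
#'   `cluster`.
#' @export
synthetic_atlas <- function(n_rois,
                            n_frontal = max(2L, round(0.4 * n_rois)),
                            n_posterior = max(2L, round(0.3 * n_rois))) {
  stopifnot(n_frontal + n_posterior <= n_rois)
  cluster <- rep("temporocentral", n_rois)
  cluster[seq_len(n_frontal)] <- "frontal"
  cluster[n_rois - seq_len(n_posterior) + 1L] <- "posterior"
  labels <- sprintf("ROI%02d", seq_len(n_rois))
  data.frame(roi = labels, label = labels,
             hemisphere = NA_character_, lobe = NA_character_,
             cluster = cluster)
}

#' Default group effect profile
#'
#' Multiplicative attenuation of the coupling gains in the high-schizotypy
#' group, per band. The default attenuates all four planted couplings by
#' 30%, i.e. slow-band top-down and fast-band bottom-up influence are all
#' weaker in the high group while the innovation covariance (hence channel
#' power at the sources' own rhythm) is shared between groups.
#'
#' @param attenuation multiplier in `[0, 1]` applied to the named bands.
#' @param bands character vector of band names to attenuate.
#' @return named numeric vector over theta/alpha/beta/gamma.
#' @export
default_effect_profile <- function(attenuation = 0.7,
                                   bands = c("theta", "alpha", "beta",
                                             "gamma")) {
  prof <- c(theta = 1, alpha = 1, beta = 1, gamma = 1)
  prof[bands] <- attenuation
  prof
}

#' Generate a two-group synthetic cohort
#'
#' Low-group subjects are drawn from the full-gain VAR model; high-group
#' subjects from a model whose coupling gains are attenuated per band
#' according to `effect_profile`. All subjects share the sampling rate,
#' region labels and innovation covariance; each has an independent seeded
#' noise realisation.
#'
#' @param n_low,n_high group sizes (>= 2).
#' @param n_rois number of regions.
#' @param fs sampling rate (Hz).
#' @param duration_s recording duration (s); `fs * duration_s` samples per
#'   subject.
#' @param effect_profile named band -> multiplier vector, see
#'   [default_effect_profile()].
#' @param band_targets coupling table; default [default_band_targets()] on
#'   the synthetic atlas clusters.
#' @param atlas partition table; default [synthetic_atlas()].
#' @param strength coupling strength passed to [default_band_targets()].
#' @param order true generative VAR order (deliberately much smaller than
#'   the analysis order).
#' @param seed integer master seed; subject seeds are derived from it.
#' @return object of class `gc_cohort`: `subjects` (list of `ts_set`),
#'   `groups` (factor low/high), `fs`, `roi_labels`, `atlas`,
#'   `models` (list with the true low/high [var_model_spec]s).
#' @export
generate_cohort <- function(n_low = 54L, n_high = 55L, n_rois = 68L,
                            fs = 500, duration_s = 120,
                            effect_profile = default_effect_profile(),
                            band_targets = NULL, atlas = NULL,
                            strength = 0.8, order = 3L, seed = 1L) {
  stopifnot(n_low >= 2, n_high >= 2)
  n_samples <- round(fs * duration_s)
  if (n_samples <= 10 * order) {
    stop("duration too short: fs * duration_s must exceed 10 * order")
  }
  if (is.null(atlas)) atlas <- synthetic_atlas(n_rois)
  stopifnot(nrow(atlas) == n_rois)
  if (is.null(band_targets)) {
    band_targets <- default_band_targets(
      frontal = which(atlas$cluster == "frontal"),
      posterior = which(atlas$cluster == "posterior"),
      strength = strength, fs = fs
    )
  }
  high_targets <- band_targets
  if (!is.null(high_targets$band)) {
    mult <- effect_profile[high_targets$band]
    mult[is.na(mult)] <- 1
    high_targets$gain <- high_targets$gain * as.numeric(mult)
  }
  model_low <- make_var_model(n_rois, band_targets, group_effect = 1,
                              seed = seed, fs = fs, order = order)
  model_high <- make_var_model(n_rois, high_targets, group_effect = 1,
                               seed = seed, fs = fs, order = order)
  set.seed(as.integer(seed))
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_low + n_high)
  groups <- factor(rep(c("low", "high"), c(n_low, n_high)),
                   levels = c("low", "high"))
  subjects <- vector("list", n_low + n_high)
  for (s in seq_along(subjects)) {
    mdl <- if (groups[s] == "low") model_low else model_high
    subjects[[s]] <- simulate_var(
      mdl, n_samples, seed = subj_seeds[s],
      subject_id = sprintf("sub-%03d", s),
      roi_labels = atlas$label
    )
  }
  structure(list(subjects = subjects, groups = groups, fs = fs,
                 roi_labels = atlas$label, atlas = atlas,
                 models = list(low = model_low, high = model_high),
                 seed = as.integer(seed)),
            class = "gc_cohort")
}

#' @export
print.gc_cohort <- function(x, ...) {
  cat("gc_cohort: ", length(x$subjects), " subjects (",
      sum(x$groups == "low"), " low / ", sum(x$groups == "high"),
      " high), ", length(x$roi_labels), " regions @ ", x$fs, " Hz\n",
      sep = "")
  invisible(x)
}

#' Scaled-down demonstration cohort
#'
#' The desk-scale study conditions used throughout the package's worked
#' examples and recovery checks: 25 + 25 subjects, 10 regions (4 frontal,
#' 3 posterior, 3 excluded), 30 s recordings at 250 Hz, with theta
#' top-down and gamma bottom-up coupling attenuated by 30% in the high
#' group. Alpha- and beta-band effects then arise indirectly, from the
#' spectral tails of the theta and gamma oscillators, mirroring the
#' qualitative pattern of slow-band top-down and fast-band bottom-up
#' group differences.
#'
#' @param seed integer master seed.
#' @param n_low,n_high group sizes.
#' @param attenuation high-group coupling multiplier (default 0.7).
#' @return a `gc_cohort`.
#' @export
demo_cohort <- function(seed = 1L, n_low = 25L, n_high = 25L,
                        attenuation = 0.7) {
  atlas <- synthetic_atlas(10L)
  bt <- default_band_targets(which(atlas$cluster == "frontal"),
                             which(atlas$cluster == "posterior"),
                             fs = 250,
                             slow_bands = "theta", fast_bands = "gamma")
  generate_cohort(n_low = n_low, n_high = n_high, n_rois = 10L, fs = 250,
                  duration_s = 30, band_targets = bt, atlas = atlas,
                  effect_profile = default_effect_profile(
                    attenuation, c("theta", "gamma")),
                  seed = seed)
}

#' Write a cohort to disk as TSV time series plus manifest
#'
#' Each subject becomes `<id>.tsv` (header = region labels, rows = time
#' samples); `manifest.csv` lists subject_id, group, fs and relative path;
#' `atlas.tsv` carries the partition; `model_spec.json` serialises the true
#' generative models for oracle tests.
#'
#' @param cohort a `gc_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(cohort$subjects))
  for (s in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[s]]
    paths[s] <- paste0(sub$subject_id, ".tsv")
    df <- as.data.frame(t(sub$data))
    names(df) <- sub$roi_labels
    utils::write.table(df, file.path(dir, paths[s]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest <- data.frame(
    subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
    group = as.character(cohort$groups),
    fs = cohort$fs,
    path = paths
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.table(cohort$atlas, file.path(dir, "atlas.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ser <- function(m) list(n_rois = m$n_rois, order = m$order,
                          coeff = m$coeff, noise_cov = m$noise_cov,
                          fs = m$fs)
  jsonlite::write_json(lapply(cohort$models, ser),
                       file.path(dir, "model_spec.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()] (or any conforming layout)
#'
#' @param dir directory holding `manifest.csv`, per-subject TSVs and
#'   optionally `atlas.tsv`.
#' @return a `gc_cohort` (without true models unless the sidecar exists).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "group", "fs", "path") %in% names(manifest)))
  fs <- unique(manifest$fs)
  if (length(fs) != 1) stop("all subjects must share one sampling rate")
  subjects <- lapply(seq_len(nrow(manifest)), function(s) {
    df <- utils::read.delim(file.path(dir, manifest$path[s]),
                            check.names = FALSE)
    data <- t(as.matrix(df))
    if (any(!is.finite(data))) {
      stop("non-finite values in ", manifest$path[s])
    }
    structure(list(subject_id = manifest$subject_id[s], fs = fs,
                   data = data, roi_labels = rownames(data)),
              class = "ts_set")
  })
  labels <- subjects[[1]]$roi_labels
  if (!all(vapply(subjects, function(s) identical(s$roi_labels, labels),
                  logical(1)))) {
    stop("all subjects must share the same region labels")
  }
  atlas_path <- file.path(dir, "atlas.tsv")
  atlas <- if (file.exists(atlas_path)) {
    utils::read.delim(atlas_path, stringsAsFactors = FALSE)
  } else NULL
  structure(list(subjects = subjects,
                 groups = factor(manifest$group, levels = c("low", "high")),
                 fs = fs, roi_labels = labels, atlas = atlas,
                 models = NULL, seed = NA_integer_),
            class = "gc_cohort")
}
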