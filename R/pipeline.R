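#' Pipeline run configuration
#'
#' Assembles all tunable parameters with defaults matching the reference
#' acquisition/analysis settings: 500 Hz sampling, AR order 30, 0.1 Hz
#' spectral resolution, the four canonical bands, 5000 permutations, and
#' edgewise retention threshold 0.05.
#'
#' @param fs sampling rate (Hz).
#' @param ar_order analysis AR model order.
#' @param freq_resolution spectral grid step (Hz).
#' @param bands named list of band edges (Hz).
#' @param n_perm permutations for edge and node tests.
#' @param edge_alpha uncorrected edge retention threshold.
#' @param node_alpha Bonferroni-corrected node significance level.
#' @param sparsify apply the group-contrast sparsity mask (`FALSE`
#'   reproduces the complete, non-thresholded variant).
#' @param seed master seed for permutation draws.
#' @return list of class `run_config`.
#' @export
run_config <- function(fs = 500, ar_order = 30L, freq_resolution = 0.1,
                       bands = default_bands(), n_perm = 5000L,
                       edge_alpha = 0.05, node_alpha = 0.05,
                       sparsify = TRUE, seed = 1L) {
  stopifnot(fs > 0, ar_order >= 1, freq_resolution > 0,
            n_perm >= 1, edge_alpha > 0, edge_alpha < 1)
  structure(list(fs = fs, ar_order = as.integer(ar_order),
                 freq_resolution = freq_resolution, bands = bands,
                 n_perm = as.integer(n_perm), edge_alpha = edge_alpha,
                 node_alpha = node_alpha, sparsify = isTRUE(sparsify),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Band connectivity for every subject of a cohort
#'
#' @param cohort a `gc_cohort`.
#' @param config a [run_config] (its `fs` must match the cohort's).
#' @return list: `band_mats` (band -> list of R x R adjacencies),
#'   `n_clamped`, `failed_pairs`.
#' @export
cohort_band_connectivity <- function(cohort, config) {
  stopifnot(inherits(cohort, "gc_cohort"))
  n_clamped <- 0L
  failed <- 0L
  per_subject <- lapply(cohort$subjects, function(sub) {
    conn <- connectivity_matrices(sub, p = config$ar_order,
                                  freq_resolution = config$freq_resolution)
    n_clamped <<- n_clamped + conn$n_clamped
    failed <<- failed + length(conn$failed_pairs)
    band_average(conn, config$bands)
  })
  bands <- names(config$bands)
  band_mats <- lapply(bands, function(b) {
    lapply(per_subject, function(bc) bc$bands[[b]])
  })
  names(band_mats) <- bands
  list(band_mats = band_mats, n_clamped = n_clamped,
       failed_pairs = failed)
}

#' Run the full resting-state connectivity analysis
#'
#' Orchestrates, per frequency band: spectral GC estimation and band
#' averaging for every subject, group-contrast edgewise permutation
#' sparsification, global/local efficiency and degree centralities, node
#' significance, directional fronto-posterior indices, and group-level
#' statistics (omnibus mixed models plus Bonferroni-corrected planned
#' contrasts). Deterministic given `config$seed`.
#'
#' @param cohort a `gc_cohort` (simulated or read from disk).
#' @param config a [run_config].
#' @param part a [roi_partition]; defaults to the cohort atlas when
#'   present, else the packaged 68-region table.
#' @param out_dir optional directory; when given, tidy CSV/TSV outputs and
#'   a JSON run report are written there.
#' @return list of class `gc_run`: `band_mats` (sparse), `edge_stats`,
#'   `masks`, `global_metrics` (tidy df), `centralities`,
#'   `node_sig`, `dir_indices` (tidy df), `stats`, `report`.
#' @export
run_pipeline <- function(cohort, config = run_config(), part = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(cohort, "gc_cohort"))
  if (!isTRUE(all.equal(cohort$fs, config$fs))) {
    stop("config fs (", config$fs, ") does not match cohort fs (",
         cohort$fs, ")")
  }
  if (is.null(part)) {
    part <- if (!is.null(cohort$atlas)) partition_rois(cohort$atlas)
            else partition_rois()
  }
  subject_ids <- vapply(cohort$subjects, `[[`, "", "subject_id")
  groups <- cohort$groups
  is_low <- groups == "low"

  conn <- cohort_band_connectivity(cohort, config)
  bands <- names(config$bands)

  edge_stats <- list()
  masks <- list()
  sparse_mats <- list()
  for (b in bands) {
    mats <- conn$band_mats[[b]]
    es <- edge_permutation_test(mats[is_low], mats[!is_low],
                                n_perm = config$n_perm, seed = config$seed)
    es$band <- b
    sp <- apply_sparsity_mask(mats, es, alpha = config$edge_alpha,
                              bypass = !config$sparsify)
    edge_stats[[b]] <- es
    masks[[b]] <- sp$mask
    sparse_mats[[b]] <- sp$matrices
  }

  gm <- global_metrics_table(sparse_mats, subject_ids, groups)

  cent <- lapply(bands, function(b) {
    lapply(sparse_mats[[b]], degree_centralities)
  })
  names(cent) <- bands
  node_sig <- lapply(bands, function(b) {
    list(outdegree = node_significance(cent[[b]][is_low], cent[[b]][!is_low],
                                       "outdegree", n_perm = config$n_perm,
                                       seed = config$seed,
                                       alpha = config$node_alpha),
         indegree = node_significance(cent[[b]][is_low], cent[[b]][!is_low],
                                      "indegree", n_perm = config$n_perm,
                                      seed = config$seed,
                                      alpha = config$node_alpha))
  })
  names(node_sig) <- bands

  di <- directional_indices_table(sparse_mats, node_sig, part,
                                  subject_ids, groups)

  stats_out <- pipeline_stats(gm, di, bands)

  report <- list(
    parameters = unclass(config),
    n_subjects = length(subject_ids),
    n_low = sum(is_low), n_high = sum(!is_low),
    n_rois = length(cohort$roi_labels),
    clamp_events = conn$n_clamped,
    fit_failures = conn$failed_pairs,
    mask_density = vapply(masks, mean, numeric(1)),
    retained_edges = vapply(masks, sum, numeric(1))
  )

  run <- structure(list(band_mats = sparse_mats, edge_stats = edge_stats,
                        masks = masks, global_metrics = gm,
                        centralities = cent, node_sig = node_sig,
                        dir_indices = di, stats = stats_out,
                        partition = part, report = report),
                   class = "gc_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Group-level inference tables: omnibus mixed models plus planned
# contrasts (family = 4 bands for GE/LE; 8 band x direction cells for the
# combined directional indices).
pipeline_stats <- function(gm, di, bands) {
  contrast_rows <- function(values, measure) {
    do.call(rbind, lapply(names(values), function(key) {
      v <- values[[key]]
      res <- tryCatch(
        planned_contrast(v$low, v$high, family_size = v$family),
        error = function(e) NULL
      )
      if (is.null(res)) return(NULL)
      data.frame(measure = measure, cell = key, t = res$t, df = res$df,
                 p_raw = res$p_raw, p_bonferroni = res$p_bonferroni,
                 mean_low = res$mean_low, mean_high = res$mean_high,
                 n_dropped = res$n_dropped)
    }))
  }
  ge_vals <- lapply(bands, function(b) {
    list(low = gm$GE[gm$band == b & gm$group == "low"],
         high = gm$GE[gm$band == b & gm$group == "high"],
         family = length(bands))
  })
  names(ge_vals) <- bands
  le_vals <- lapply(bands, function(b) {
    list(low = gm$LE[gm$band == b & gm$group == "low"],
         high = gm$LE[gm$band == b & gm$group == "high"],
         family = length(bands))
  })
  names(le_vals) <- bands
  ci_vals <- list()
  for (b in bands) {
    for (d in c("fp", "pf")) {
      col <- paste0("CI_", d)
      sel <- di$band == b
      ci_vals[[paste(b, d, sep = ".")]] <- list(
        low = di[[col]][sel & di$group == "low"],
        high = di[[col]][sel & di$group == "high"],
        family = 2L * length(bands)
      )
    }
  }
  contrasts <- rbind(contrast_rows(ge_vals, "GE"),
                     contrast_rows(le_vals, "LE"),
                     contrast_rows(ci_vals, "CI"))

  gm_long <- data.frame(subject = gm$subject_id, group = gm$group,
                        band = gm$band, value = gm$GE)
  le_long <- data.frame(subject = gm$subject_id, group = gm$group,
                        band = gm$band, value = gm$LE)
  di_long <- rbind(
    data.frame(subject = di$subject_id, group = di$group, band = di$band,
               direction = "fp", value = di$CI_fp),
    data.frame(subject = di$subject_id, group = di$group, band = di$band,
               direction = "pf", value = di$CI_pf)
  )
  safe_omnibus <- function(d) {
    tryCatch(suppressWarnings(omnibus_model(d)), error = function(e) NULL)
  }
  list(contrasts = contrasts,
       omnibus = list(GE = safe_omnibus(gm_long),
                      LE = safe_omnibus(le_long),
                      CI = safe_omnibus(di_long)))
}

#' @export
print.gc_run <- function(x, ...) {
  cat("gc_run: ", x$report$n_subjects, " subjects, ", x$report$n_rois,
      " regions, bands: ", paste(names(x$band_mats), collapse = ", "),
      "\n", sep = "")
  cat("  retained edges per band: ",
      paste(sprintf("%s=%d", names(x$report$retained_edges),
                    x$report$retained_edges), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Write pipeline outputs as plain-text tables plus a JSON report
#'
#' Emits per-band sparse adjacency TSVs for each subject, per-band edge
#' statistics TSVs (t, p, mask), tidy CSVs of global metrics, centralities
#' and directional indices, a contrasts CSV, and `report.json`.
#'
#' @param run a `gc_run`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  stopifnot(inherits(run, "gc_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mat_dir <- file.path(out_dir, "matrices")
  dir.create(mat_dir, showWarnings = FALSE)
  gm <- run$global_metrics
  subject_ids <- unique(gm$subject_id)
  for (b in names(run$band_mats)) {
    es <- run$edge_stats[[b]]
    utils::write.table(es$t_obs, file.path(out_dir, paste0("edge_t_", b, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(es$p_perm, file.path(out_dir, paste0("edge_p_", b, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(run$masks[[b]] * 1L,
                       file.path(out_dir, paste0("edge_mask_", b, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
    for (s in seq_along(run$band_mats[[b]])) {
      utils::write.table(
        run$band_mats[[b]][[s]],
        file.path(mat_dir, sprintf("%s_%s.tsv", subject_ids[s], b)),
        sep = "\t", quote = FALSE, col.names = NA
      )
    }
  }
  utils::write.csv(gm, file.path(out_dir, "global_metrics.csv"),
                   row.names = FALSE)
  cent_rows <- do.call(rbind, lapply(names(run$centralities), function(b) {
    do.call(rbind, lapply(seq_along(run$centralities[[b]]), function(s) {
      ct <- run$centralities[[b]][[s]]
      data.frame(subject_id = subject_ids[s],
                 group = gm$group[match(subject_ids[s], gm$subject_id)],
                 band = b, roi = names(ct$outdegree),
                 outdegree = unname(ct$outdegree),
                 indegree = unname(ct$indegree))
    }))
  }))
  utils::write.csv(cent_rows, file.path(out_dir, "centralities.csv"),
                   row.names = FALSE)
  utils::write.csv(run$dir_indices, file.path(out_dir, "dir_indices.csv"),
                   row.names = FALSE)
  utils::write.csv(run$stats$contrasts, file.path(out_dir, "contrasts.csv"),
                   row.names = FALSE)
  omni <- lapply(run$stats$omnibus, function(o) if (is.null(o)) NULL else o$table)
  jsonlite::write_json(list(report = run$report, omnibus = omni),
                       file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
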