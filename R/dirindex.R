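#' Load the packaged 68-region cortical partition table
#'
#' Desikan-Killiany atlas labels (34 per hemisphere, suffixed `_L` / `_R`)
#' categorised into frontal, posterior (parieto-occipital) and excluded
#' temporo-central clusters. The frontal cluster holds the 11 bilateral
#' frontal labels (22 regions); the posterior cluster is a reconstruction
#' of 9 bilateral parieto-occipital labels (18 regions) chosen from the
#' atlas's parietal and occipital rows excluding insula, isthmus cingulate
#' and postcentral. The table is plain TSV and can be edited or replaced
#' by the user to change cluster membership.
#'
#' @param path optional path to an alternative partition TSV with columns
#'   `roi`, `label`, `hemisphere`, `lobe`, `cluster`.
#' @return data frame with those columns.
#' @export
load_roi_partition <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dk68_partition.tsv", package = "gcnet")
  }
  atlas <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("roi", "label", "cluster")
  if (!all(need %in% names(atlas))) {
    stop("partition table must have columns: ", paste(need, collapse = ", "))
  }
  atlas
}

#' Partition region labels into frontal / posterior / excluded clusters
#'
#' @param atlas partition table with columns `label` and `cluster`
#'   (values `frontal`, `posterior`, anything else = excluded).
#' @return object of class `roi_partition`: `frontal`, `posterior`,
#'   `excluded` (label vectors) and counts `n_f`, `n_p`.
#' @export
partition_rois <- function(atlas = load_roi_partition()) {
  if (anyDuplicated(atlas$label)) stop("duplicate region labels in atlas")
  if (any(is.na(atlas$cluster) | atlas$cluster == "")) {
    stop("every region must be assigned to exactly one cluster")
  }
  frontal <- atlas$label[atlas$cluster == "frontal"]
  posterior <- atlas$label[atlas$cluster == "posterior"]
  excluded <- setdiff(atlas$label, c(frontal, posterior))
  structure(list(frontal = frontal, posterior = posterior,
                 excluded = excluded,
                 n_f = length(frontal), n_p = length(posterior)),
            class = "roi_partition")
}

#' @export
print.roi_partition <- function(x, ...) {
  cat("roi_partition: ", x$n_f, " frontal, ", x$n_p, " posterior, ",
      length(x$excluded), " excluded (temporo-central)\n", sep = "")
  invisible(x)
}

#' Directional fronto-posterior connectivity index for one subject
#'
#' Averages the connectivity of a significance-restricted subnetwork.
#' With `degree_kind = "out"` and `direction = "fp"`, the subnetwork
#' W_out_fp holds the connections exiting the significant frontal regions
#' (by Outdegree) towards all posterior regions, and
#' `OutFP = sum(W_out_fp) / (N_p * N_fo)`. The other three combinations
#' are analogous: OutPF sums significant posterior sources into all frontal
#' targets (/ N_f * N_po); InFP sums all frontal sources into significant
#' posterior targets (by Indegree; / N_pi * N_f); InPF sums all posterior
#' sources into significant frontal targets (/ N_fi * N_p). When the
#' relevant significant set is empty the index is undefined (`NA`), never
#' silently zero.
#'
#' @param A band adjacency matrix with row/column names = region labels.
#' @param sig a [node_significance] computed for the matching band and
#'   metric (`out` requires Outdegree significance, `in` Indegree).
#' @param part a [roi_partition].
#' @param degree_kind `"out"` or `"in"`.
#' @param direction `"fp"` (fronto-posterior) or `"pf"`.
#' @return list: `value` (scalar or NA), `n_sig`, `size` (subnetwork size,
#'   0 when undefined).
#' @export
directional_index <- function(A, sig, part,
                              degree_kind = c("out", "in"),
                              direction = c("fp", "pf")) {
  degree_kind <- match.arg(degree_kind)
  direction <- match.arg(direction)
  stopifnot(inherits(sig, "node_significance"),
            inherits(part, "roi_partition"))
  expected_metric <- if (degree_kind == "out") "outdegree" else "indegree"
  if (!identical(sig$metric, expected_metric)) {
    stop("significance metric mismatch: need ", expected_metric,
         " significance for degree_kind = '", degree_kind, "'")
  }
  labels <- rownames(A)
  if (is.null(labels) || !identical(labels, colnames(A))) {
    stop("adjacency must carry matching row/column region labels")
  }
  frontal <- intersect(labels, part$frontal)
  posterior <- intersect(labels, part$posterior)
  sig_set <- sig$significant_nodes
  if (degree_kind == "out" && direction == "fp") {
    src <- intersect(sig_set, frontal); tgt <- posterior
  } else if (degree_kind == "out" && direction == "pf") {
    src <- intersect(sig_set, posterior); tgt <- frontal
  } else if (degree_kind == "in" && direction == "fp") {
    src <- frontal; tgt <- intersect(sig_set, posterior)
  } else {
    src <- posterior; tgt <- intersect(sig_set, frontal)
  }
  n_sig <- if (degree_kind == "out") length(src) else length(tgt)
  if (n_sig == 0) {
    return(list(value = NA_real_, n_sig = 0L, size = 0L))
  }
  size <- length(src) * length(tgt)
  list(value = sum(A[src, tgt, drop = FALSE]) / size,
       n_sig = n_sig, size = size)
}

#' Combine Outdegree- and Indegree-based indices into one per direction
#'
#' The combined index CI is the mean of the defined components; if exactly
#' one is defined, CI equals that component; if both are undefined, CI is
#' undefined (`NA`).
#'
#' @param out_idx,in_idx scalars (possibly `NA`) for the same subject,
#'   band and direction.
#' @return scalar or `NA`.
#' @export
combine_indices <- function(out_idx, in_idx) {
  vals <- c(out_idx, in_idx)
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Tidy directional-index table for a cohort
#'
#' Computes OutFP/OutPF/InFP/InPF and the combined CI_fp/CI_pf for every
#' subject and band, given per-band sparse matrices and per-band node
#' significance for both centrality metrics.
#'
#' @param matrices named list band -> list of per-subject adjacencies
#'   (with region-label dimnames).
#' @param sig named list band -> list with elements `outdegree` and
#'   `indegree`, each a [node_significance].
#' @param part a [roi_partition].
#' @param subject_ids,groups per-subject metadata.
#' @return data frame (subject_id, group, band, OutFP, OutPF, InFP, InPF,
#'   CI_fp, CI_pf, and the four subnetwork sizes).
#' @export
directional_indices_table <- function(matrices, sig, part, subject_ids,
                                      groups) {
  rows <- lapply(names(matrices), function(band) {
    mats <- matrices[[band]]
    so <- sig[[band]]$outdegree
    si <- sig[[band]]$indegree
    per <- lapply(mats, function(A) {
      ofp <- directional_index(A, so, part, "out", "fp")
      opf <- directional_index(A, so, part, "out", "pf")
      ifp <- directional_index(A, si, part, "in", "fp")
      ipf <- directional_index(A, si, part, "in", "pf")
      data.frame(OutFP = ofp$value, OutPF = opf$value,
                 InFP = ifp$value, InPF = ipf$value,
                 CI_fp = combine_indices(ofp$value, ifp$value),
                 CI_pf = combine_indices(opf$value, ipf$value),
                 size_out_fp = ofp$size, size_out_pf = opf$size,
                 size_in_fp = ifp$size, size_in_pf = ipf$size)
    })
    cbind(data.frame(subject_id = subject_ids,
                     group = as.character(groups), band = band),
          do.call(rbind, per))
  })
  do.call(rbind, rows)
}
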