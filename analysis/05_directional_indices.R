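#!/usr/bin/env Rscript

# Stage 5: directional fronto-posterior connectivity indices.
#
# Using the significant-node sets from stage 4 and the cohort partition,
# computes OutFP/OutPF/InFP/InPF and the combined CI_fp/CI_pf per subject
# and band. Undefined indices (empty significant set) propagate as
# missing values. Writes results/dir_indices.csv.

suppressPackageStartupMessages(library(gcnet))

coh <- read_cohort("results/cohort")
ids <- vapply(coh$subjects, `[[`, "", "subject_id")
is_low <- coh$groups == "low"
bands <- names(default_bands())
part <- partition_rois(coh$atlas)

read_sparse <- function(id, b) {
  as.matrix(utils::read.delim(
    file.path("results/sparse", sprintf("%s_%s.tsv", id, b)),
    row.names = 1, check.names = FALSE))
}
mats <- lapply(bands, function(b) lapply(ids, read_sparse, b = b))
names(mats) <- bands

sig <- lapply(bands, function(b) {
  cents <- lapply(mats[[b]], degree_centralities)
  list(outdegree = node_significance(cents[is_low], cents[!is_low],
                                     "outdegree", n_perm = 1000, seed = 1L),
       indegree = node_significance(cents[is_low], cents[!is_low],
                                    "indegree", n_perm = 1000, seed = 1L))
})
names(sig) <- bands

di <- directional_indices_table(mats, sig, part, ids, coh$groups)
utils::write.csv(di, "results/dir_indices.csv", row.names = FALSE)

agg <- stats::aggregate(cbind(CI_fp, CI_pf) ~ band + group, di, mean,
                        na.action = stats::na.pass, na.rm = TRUE)
print(agg)
cat("Undefined CI_fp:", sum(is.na(di$CI_fp)),
    "| undefined CI_pf:", sum(is.na(di$CI_pf)), "of", nrow(di), "rows\n")
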