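#!/usr/bin/env Rscript

# Stage 3: group-contrast sparsification.
#
# Per band, a two-tailed permutation t-test (1000 label shuffles) on every
# directed edge; edges with uncorrected p < .05 are retained, all others
# set to zero in every subject's matrix. Writes edge t/p/mask TSVs and the
# sparse subject matrices under results/sparse/.

suppressPackageStartupMessages(library(gcnet))

coh <- read_cohort("results/cohort")
ids <- vapply(coh$subjects, `[[`, "", "subject_id")
is_low <- coh$groups == "low"
bands <- names(default_bands())

read_band <- function(id, b) {
  as.matrix(utils::read.delim(
    file.path("results/connectivity", sprintf("%s_%s.tsv", id, b)),
    row.names = 1, check.names = FALSE))
}

out_dir <- "results/sparse"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
for (b in bands) {
  mats <- lapply(ids, read_band, b = b)
  es <- edge_permutation_test(mats[is_low], mats[!is_low],
                              n_perm = 1000, seed = 1L)
  sp <- apply_sparsity_mask(mats, es, alpha = 0.05)
  utils::write.table(es$t_obs, file.path(out_dir, paste0("edge_t_", b, ".tsv")),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(es$p_perm, file.path(out_dir, paste0("edge_p_", b, ".tsv")),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(sp$mask * 1L,
                     file.path(out_dir, paste0("edge_mask_", b, ".tsv")),
                     sep = "\t", quote = FALSE, col.names = NA)
  for (s in seq_along(ids)) {
    utils::write.table(sp$matrices[[s]],
                       file.path(out_dir, sprintf("%s_%s.tsv", ids[s], b)),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  cat(sprintf("%-6s retained %d of %d directed edges\n", b, sp$retained,
              nrow(es$p_perm) * (nrow(es$p_perm) - 1)))
}
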