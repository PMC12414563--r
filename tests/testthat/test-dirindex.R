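fake_sig <- function(nodes, metric) {
  structure(list(significant_nodes = nodes, metric = metric,
                 alpha = 0.05, p_raw = NULL, p_bonferroni = NULL,
                 t_obs = NULL, n_perm = 0L, seed = 0L),
            class = "node_significance")
}

test_that("packaged partition reproduces the printed cluster sizes", {
  atlas <- load_roi_partition()
  expect_equal(nrow(atlas), 68)
  part <- partition_rois(atlas)
  expect_equal(part$n_f, 22)
  expect_equal(part$n_p, 18)
  expect_length(part$excluded, 28)
  expect_length(intersect(part$frontal, part$posterior), 0)
  # bilateral structure: every base label appears once per hemisphere
  expect_equal(sum(endsWith(part$frontal, "_L")), 11)
  expect_equal(sum(endsWith(part$posterior, "_R")), 9)
})

test_that("partition validation rejects unassigned or duplicate labels", {
  atlas <- load_roi_partition()
  bad <- atlas
  bad$cluster[3] <- ""
  expect_error(partition_rois(bad), "exactly one cluster")
  dup <- rbind(atlas, atlas[1, ])
  expect_error(partition_rois(dup), "duplicate")
})

test_that("uniform-weight matrices give index = w for any significant set", {
  part <- structure(list(frontal = c("F1", "F2"), posterior = c("P1", "P2", "P3"),
                         excluded = "T1", n_f = 2L, n_p = 3L),
                    class = "roi_partition")
  labels <- c("F1", "F2", "P1", "P2", "P3", "T1")
  w <- 0.37
  A <- matrix(w, 6, 6, dimnames = list(labels, labels))
  diag(A) <- 0
  for (sig_set in list("F1", c("F1", "F2"))) {
    out <- directional_index(A, fake_sig(sig_set, "outdegree"), part,
                             "out", "fp")
    expect_equal(out$value, w)
    expect_equal(out$size, 3L * length(sig_set))
  }
  expect_equal(directional_index(A, fake_sig(c("P2", "P3"), "outdegree"),
                                 part, "out", "pf")$value, w)
  expect_equal(directional_index(A, fake_sig("P1", "indegree"), part,
                                 "in", "fp")$value, w)
  expect_equal(directional_index(A, fake_sig("F2", "indegree"), part,
                                 "in", "pf")$value, w)
})

test_that("hand-computed 4-node toy matches the subnetwork average", {
  part <- structure(list(frontal = c("F1", "F2"), posterior = c("P1", "P2"),
                         excluded = character(0), n_f = 2L, n_p = 2L),
                    class = "roi_partition")
  labels <- c("F1", "F2", "P1", "P2")
  A <- matrix(0, 4, 4, dimnames = list(labels, labels))
  A["F1", "P1"] <- 0.02; A["F1", "P2"] <- 0.04
  A["F2", "P1"] <- 0.10; A["F2", "P2"] <- 0.20
  A["P1", "F1"] <- 0.08; A["P2", "F2"] <- 0.16
  # only F1 significant by outdegree: OutFP = (0.02 + 0.04) / (2 * 1)
  res <- directional_index(A, fake_sig("F1", "outdegree"), part, "out", "fp")
  expect_equal(res$value, 0.03)
  expect_equal(res$size, 2L)
  # only P2 significant by indegree: InFP = (0.04 + 0.20) / (1 * 2)
  res2 <- directional_index(A, fake_sig("P2", "indegree"), part, "in", "fp")
  expect_equal(res2$value, 0.12)
})

test_that("empty significant sets propagate as undefined, never zero", {
  part <- structure(list(frontal = "F1", posterior = "P1",
                         excluded = character(0), n_f = 1L, n_p = 1L),
                    class = "roi_partition")
  A <- matrix(0.5, 2, 2, dimnames = list(c("F1", "P1"), c("F1", "P1")))
  diag(A) <- 0
  res <- directional_index(A, fake_sig(character(0), "outdegree"),
                           part, "out", "pf")
  expect_true(is.na(res$value))
  expect_equal(res$size, 0L)
})

test_that("metric/degree-kind mismatches are refused", {
  part <- structure(list(frontal = "F1", posterior = "P1",
                         excluded = character(0), n_f = 1L, n_p = 1L),
                    class = "roi_partition")
  A <- matrix(0.5, 2, 2, dimnames = list(c("F1", "P1"), c("F1", "P1")))
  diag(A) <- 0
  expect_error(directional_index(A, fake_sig("F1", "indegree"), part,
                                 "out", "fp"), "mismatch")
})

test_that("combined index averages the defined components", {
  expect_equal(combine_indices(0.010, 0.006), 0.008)
  expect_equal(combine_indices(NA_real_, 0.004), 0.004)
  expect_equal(combine_indices(0.004, NA_real_), 0.004)
  expect_true(is.na(combine_indices(NA_real_, NA_real_)))
})

test_that("the tidy cohort table carries sizes and missingness through", {
  part <- structure(list(frontal = c("F1", "F2"), posterior = c("P1", "P2"),
                         excluded = character(0), n_f = 2L, n_p = 2L),
                    class = "roi_partition")
  labels <- c("F1", "F2", "P1", "P2")
  A <- matrix(0.1, 4, 4, dimnames = list(labels, labels))
  diag(A) <- 0
  mats <- list(x = list(A, 2 * A))
  sig <- list(x = list(
    outdegree = fake_sig("F1", "outdegree"),
    indegree = fake_sig(character(0), "indegree")
  ))
  tab <- directional_indices_table(mats, sig, part, c("s1", "s2"),
                                   c("low", "high"))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$OutFP, c(0.1, 0.2))
  expect_true(all(is.na(tab$InFP)))
  expect_true(all(is.na(tab$InPF)))
  expect_equal(tab$CI_fp, tab$OutFP)      # single defined component
  expect_true(all(is.na(tab$CI_pf)))      # OutPF needs sig posterior
  expect_equal(tab$size_out_fp, c(2L, 2L))
})
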