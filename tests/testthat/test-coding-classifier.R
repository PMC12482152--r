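classifier_fixture <- function(seed = 101, n_coding = 10, n_rrna = 5,
                               n_trna = 0, queries = NULL) {
  ids <- c(sprintf("cds%02d", seq_len(n_coding)),
           if (n_rrna) sprintf("rrna%02d", seq_len(n_rrna)),
           if (n_trna) sprintf("trna%02d", seq_len(n_trna)))
  cls <- rep(c("coding", "rrna", "trna"), c(n_coding, n_rrna, n_trna))
  profs <- rep(c("coding_peak", "rrna_like", "trna_like"),
               c(n_coding, n_rrna, n_trna))
  totals <- rep(1000, length(ids))
  if (!is.null(queries)) {
    ids <- c(ids, queries$gene_id)
    cls <- c(cls, rep("srna", nrow(queries)))
    profs <- c(profs, queries$profile_class)
    totals <- c(totals, queries$total)
  }
  hist <- draw_profiles(ids, profs, totals, seed = seed)
  list(hist = hist,
       classes = tibble::tibble(gene_id = ids, class = cls))
}

test_that("profile building converts to percentages and excludes low reads", {
  hist <- make_histogram(c("ok", "low", "cds1", "rrna1"),
                         list(c(`27` = 2, `25` = 1),
                              c(`27` = 64),
                              c(`27` = 800, `26` = 200),
                              c(`36` = 500)))
  classes <- tibble::tibble(gene_id = c("ok", "low", "cds1", "rrna1"),
                            class = c("srna", "srna", "coding", "rrna"))
  prof <- build_profile_matrix(hist, classes, min_reads = 65)
  expect_true(prof$excluded[prof$gene_id == "low"])
  # percentages are computed even for excluded profiles
  row_ok <- prof[prof$gene_id == "ok", as.character(15:45)]
  expect_equal(unname(unlist(row_ok[c("25", "27")])), c(100 / 3, 200 / 3),
               tolerance = 1e-9)
  expect_equal(sum(unlist(row_ok)), 100, tolerance = 1e-6)
  # the pooled CDS profile is always appended
  expect_true("pooled_cds" %in% prof$reference_class)
  pooled <- prof[prof$reference_class == "pooled_cds", ]
  expect_equal(pooled$total_reads, 1000)
  expect_error(build_profile_matrix(
    hist, dplyr::mutate(classes, class = "srna")), "coding reference")
})

test_that("a 64-read profile is excluded at the 65-read threshold", {
  fx <- classifier_fixture(queries = tibble::tibble(
    gene_id = c("at64", "at65"), profile_class = "coding_peak",
    total = c(64, 65)))
  prof <- build_profile_matrix(fx$hist, fx$classes, min_reads = 65)
  expect_true(prof$excluded[prof$gene_id == "at64"])
  expect_false(prof$excluded[prof$gene_id == "at65"])
})

test_that("k-selection finds the constructed separation", {
  fx <- classifier_fixture(n_coding = 10, n_rrna = 5)
  prof <- build_profile_matrix(fx$hist, fx$classes, min_reads = 65)
  cl <- cluster_profiles(prof)
  expect_true(cl$separation_achieved)
  expect_equal(cl$k, 2)
  # a distinct tRNA group may need one more cut but never mixes rRNA in
  fx3 <- classifier_fixture(n_coding = 10, n_rrna = 5, n_trna = 3)
  prof3 <- build_profile_matrix(fx3$hist, fx3$classes, min_reads = 65)
  cl3 <- cluster_profiles(prof3)
  expect_true(cl3$separation_achieved)
  expect_lte(cl3$k, 3)
})

test_that("identical-profile degenerate input is flagged unseparable", {
  hist <- make_histogram(c("cds1", "rrna1"),
                         list(c(`27` = 100), c(`27` = 100)))
  classes <- tibble::tibble(gene_id = c("cds1", "rrna1"),
                            class = c("coding", "rrna"))
  prof <- build_profile_matrix(hist, classes, min_reads = 10)
  cl <- cluster_profiles(prof)
  expect_false(cl$separation_achieved)
  expect_error(classify_srnas(cl, prof), "refusing")
})

test_that("planted sRNA labels are recovered and schema matches Yes/No/NA", {
  fx <- classifier_fixture(queries = tibble::tibble(
    gene_id = c("s_coding", "s_rrna", "s_low"),
    profile_class = c("coding_peak", "rrna_like", "coding_peak"),
    total = c(1000, 1000, 20)))
  prof <- build_profile_matrix(fx$hist, fx$classes, min_reads = 65)
  cl <- cluster_profiles(prof)
  calls <- classify_srnas(cl, prof, condition = "control")
  got <- setNames(calls$call, calls$gene_id)
  expect_equal(got[["s_coding"]], "coding_like")
  expect_equal(got[["s_rrna"]], "not_coding_like")
  expect_equal(got[["s_low"]], "insufficient_reads")
  expect_true(is.na(calls$cluster[calls$gene_id == "s_low"]))
  expect_equal(unique(calls$condition), "control")
})

test_that("calls are invariant to input row order", {
  fx <- classifier_fixture(queries = tibble::tibble(
    gene_id = sprintf("q%02d", 1:6),
    profile_class = rep(c("coding_peak", "rrna_like"), 3),
    total = c(120, 300, 800, 90, 2000, 75)))
  run <- function(hist) {
    prof <- build_profile_matrix(hist, fx$classes, min_reads = 65)
    cl <- cluster_profiles(prof)
    calls <- classify_srnas(cl, prof)
    calls[order(calls$gene_id), c("gene_id", "call")]
  }
  set.seed(2)
  shuffled <- fx$hist[sample.int(nrow(fx$hist)), ]
  expect_equal(run(fx$hist), run(shuffled))
})

test_that("threshold calibration excludes the misleading low-count positive", {
  # positives at 30 / 80 / 200 reads; the 30-read one carries a noncoding-
  # looking profile, so thresholds <= 30 fail and the first candidate in
  # (30, 80] wins
  fx <- classifier_fixture(queries = tibble::tibble(
    gene_id = c("pos_low", "pos_mid", "pos_high", "other"),
    profile_class = c("rrna_like", "coding_peak", "coding_peak",
                      "rrna_like"),
    total = c(30, 80, 200, 500)))
  positives <- c("pos_low", "pos_mid", "pos_high")
  t_sel <- calibrate_min_count(fx$hist, fx$classes, positives,
                               candidate_thresholds = c(25, 50, 100))
  expect_equal(t_sel, 50L)
  # when every surviving positive classifies correctly the smallest wins
  fx2 <- classifier_fixture(queries = tibble::tibble(
    gene_id = positives, profile_class = "coding_peak",
    total = c(110, 300, 900)))
  expect_equal(calibrate_min_count(fx2$hist, fx2$classes, positives,
                                   c(25, 50, 100)), 25L)
  expect_error(calibrate_min_count(fx$hist, fx$classes, "pos_low",
                                   c(100, 200)), "below every candidate")
})

test_that("raising min_reads only removes profiles, keeping survivor calls", {
  fx <- classifier_fixture(n_coding = 12, n_rrna = 5, queries = tibble::tibble(
    gene_id = sprintf("q%02d", 1:10),
    profile_class = rep(c("coding_peak", "rrna_like"), each = 5),
    total = round(seq(80, 1500, length.out = 10))))
  calls_at <- function(mr) {
    prof <- build_profile_matrix(fx$hist, fx$classes, min_reads = mr)
    calls <- classify_srnas(cluster_profiles(prof), prof)
    setNames(calls$call, calls$gene_id)
  }
  lo <- calls_at(65)
  hi <- calls_at(500)
  survivors <- names(hi)[hi != "insufficient_reads"]
  agree <- mean(lo[survivors] == hi[survivors])
  expect_gte(agree, 0.95)
})
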