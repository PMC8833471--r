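test_that("RPKM and TPM normalization match closed forms", {
  cnt <- matrix(c(10L, 10L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  em <- normalize_counts(cnt, c(g1 = 1000, g2 = 2000), c(s1 = "a"))
  expect_equal(unname(em$tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  # RPKM = count * 1e9 / (length * total)
  expect_equal(unname(em$rpkm[, 1]), c(10 * 1e9 / (1000 * 20),
                                       10 * 1e9 / (2000 * 20)))

  # single expressed gene is the whole transcriptome
  cnt1 <- matrix(7L, 1, 1, dimnames = list("g1", "s1"))
  em1 <- normalize_counts(cnt1, c(g1 = 500), c(s1 = "a"))
  expect_equal(unname(em1$tpm[1, 1]), 1e6)

  # equal counts, equal lengths split evenly
  cnt2 <- matrix(c(5L, 5L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  em2 <- normalize_counts(cnt2, c(g1 = 800, g2 = 800), c(s1 = "a"))
  expect_equal(unname(em2$tpm[, 1]), c(5e5, 5e5))

  expect_error(normalize_counts(
    matrix(0L, 1, 1, dimnames = list("g1", "bad_sample")),
    c(g1 = 100), c(bad_sample = "a")), "bad_sample")
  expect_error(normalize_counts(cnt, c(g1 = 0, g2 = 100), c(s1 = "a")),
               "> 0")
})

test_that("TPM sums to one million per sample on random matrices", {
  for (seed in 1:3) {
    sim <- simulate_counts(expression_sim_config(n_genes = 300, seed = seed,
                                                 pathway_plan = NULL))
    sums <- colSums(sim$expression$tpm)
    expect_true(all(abs(sums - 1e6) < 1e-3))
  }
})

test_that("expression floor is inclusive at the threshold", {
  # craft counts so gene means land exactly at / around 2 RPKM
  # RPKM = c * 1e9 / (1000 * total); choose total = 1e6 so RPKM = c
  cnt <- matrix(c(2L, 1L, 999997L, 3L, 0L, 999997L), ncol = 2,
                dimnames = list(c("gA", "gB", "gBig"), c("s1", "s2")))
  em <- make_em(cnt, conditions = c(s1 = "x", s2 = "x"))
  expect_equal(unname(rowMeans(em$rpkm)[c("gA", "gB")]), c(2.5, 0.5))
  expressed <- expression_floor(em, 2)
  expect_true("gA" %in% expressed)    # mean 2.5 >= 2
  expect_false("gB" %in% expressed)   # mean 0.5
  # boundary: a gene at exactly the threshold is included
  cnt2 <- matrix(c(2L, 999998L), ncol = 1,
                 dimnames = list(c("gA", "gBig"), "s1"))
  em2 <- make_em(cnt2, conditions = c(s1 = "x"))
  expect_true("gA" %in% expression_floor(em2, 2))
  # threshold zero keeps everything, including all-zero genes
  cnt3 <- rbind(cnt, gZero = c(0L, 0L))
  em3 <- make_em(cnt3, conditions = c(s1 = "x", s2 = "x"))
  expect_equal(sort(expression_floor(em3, 0)), sort(rownames(cnt3)))
  expect_false("gZero" %in% expression_floor(em3, 0.001))
})

test_that("three-criterion DE filter applies thresholds as stated", {
  sim <- simulate_counts(expression_sim_config(
    n_genes = 500, conditions = c(case = 6L, control = 6L),
    n_planted = 50, planted_fc = 6, planted_direction = "both",
    pathway_plan = NULL, seed = 5))
  de <- suppressWarnings(
    differential_expression(sim$expression, "case", "control"))
  hi <- pmax(de$mean_a, de$mean_b)
  expect_equal(de$pass,
               hi > 2 & de$fold_change >= 1.5 & de$q < 0.05)
  expect_true(all(de$q >= de$p))
  expect_true(all(de$fold_change >= 1))
  expect_equal(de$direction, ifelse(de$mean_a >= de$mean_b, "up", "down"))
  # q-values equal the BH oracle applied to the reported p-values
  expect_equal(de$q, bh_enum(de$p), tolerance = 1e-12)
  # planted genes dominate the calls
  expect_gt(mean(sim$truth$planted$gene %in% de$gene[de$pass]), 0.8)
  expect_error(differential_expression(sim$expression, "case", "absent"),
               "two samples")
})

test_that("each DE criterion excludes genes on its own", {
  # 12 samples, two conditions; big filler gene keeps totals equal so
  # RPKM == count for length-1000 genes under total 1e6
  n <- 6L
  filler <- function(x) 1000000L - x
  mk <- function(case_counts, ctrl_counts) {
    cnt <- rbind(gTest = c(case_counts, ctrl_counts),
                 gBig = filler(c(case_counts, ctrl_counts)))
    colnames(cnt) <- paste0("s", 1:12)
    make_em(cnt, conditions = stats::setNames(rep(c("case", "ctrl"),
                                                  each = n),
                                              colnames(cnt)))
  }
  run <- function(em) {
    suppressWarnings(differential_expression(em, "case", "ctrl",
                                             genes = "gTest"))
  }
  # means 10 vs 1: passes everything
  de <- run(mk(rep(10L, n), rep(1L, n)))
  expect_true(de$pass); expect_equal(de$fold_change, 10)
  # max mean below the floor criterion fails regardless of significance
  de2 <- run(mk(rep(2L, n), rep(1L, n)))
  expect_equal(de2$fold_change, 2)
  expect_false(de2$pass)  # max mean 2 is not > 2
  # fold change below 1.5 fails
  de3 <- run(mk(rep(30L, n), rep(25L, n)))
  expect_false(de3$pass); expect_lt(de3$fold_change, 1.5)
  # zero smaller mean yields infinite fold change, which passes the FC rule
  de4 <- run(mk(rep(10L, n), rep(0L, n)))
  expect_equal(de4$fold_change, Inf)
  expect_true(de4$pass)
})

test_that("lowering any DE threshold never shrinks the pass set", {
  sim <- simulate_counts(expression_sim_config(
    n_genes = 400, conditions = c(case = 5L, control = 5L),
    n_planted = 60, planted_fc = 3, pathway_plan = NULL, seed = 8))
  base <- suppressWarnings(differential_expression(
    sim$expression, "case", "control"))
  for (looser in list(list(max_mean = 1), list(fc = 1.2), list(q = 0.1))) {
    de2 <- suppressWarnings(do.call(differential_expression,
      c(list(sim$expression, "case", "control"), looser)))
    expect_true(all(base$gene[base$pass] %in% de2$gene[de2$pass]),
                label = paste("loosening", names(looser)))
  }
})

test_that("baseline subtraction does set algebra and bookkeeping", {
  r <- subtract_baseline(paste0("g", 1:5), c("g2", "g4"))
  expect_equal(r$remaining, c("g1", "g3", "g5"))
  expect_equal(unlist(r[-1], use.names = FALSE), c(5, 2, 2, 3))
  expect_equal(subtract_baseline(c("a", "b"), character(0))$remaining,
               c("a", "b"))
  expect_equal(subtract_baseline(c("a", "b"), c("a", "b"))$n_remaining, 0)
  # arithmetic identity on random sets
  set.seed(21)
  for (i in 1:20) {
    a <- sample(paste0("g", 1:50), sample(0:30, 1))
    b <- sample(paste0("g", 1:50), sample(0:30, 1))
    r <- subtract_baseline(a, b)
    expect_equal(r$n_remaining + r$n_intersection, r$n_exposed)
  }
})

test_that("PCA QC flags a planted outlier and orders variance", {
  set.seed(17)
  n_genes <- 200
  profile <- stats::rlnorm(n_genes, log(50), 1.5)
  counts <- sapply(1:12, function(i) {
    stats::rpois(n_genes, profile)
  })
  # one sample's expression permuted across genes: same library, wrong genes
  counts[, 12] <- counts[sample(n_genes), 12]
  dimnames(counts) <- list(paste0("g", 1:n_genes), paste0("s", 1:12))
  storage.mode(counts) <- "integer"
  em <- make_em(counts,
                conditions = stats::setNames(rep("grp", 12),
                                             colnames(counts)))
  qc <- pca_qc(em, k = 3, floor_rpkm = 0)
  expect_true(qc$outlier[["s12"]])
  expect_equal(sum(qc$outlier), 1)
  expect_true(all(diff(qc$variance_explained) <= 1e-12))
  expect_lte(sum(qc$variance_explained), 1 + 1e-12)
  # duplicated profiles land on identical coordinates
  counts2 <- counts[, c(1, 1, 2, 3), drop = FALSE]
  colnames(counts2) <- paste0("t", 1:4)
  em2 <- make_em(counts2, conditions = stats::setNames(rep("grp", 4),
                                                       colnames(counts2)))
  qc2 <- pca_qc(em2, k = 2, floor_rpkm = 0)
  expect_equal(qc2$coords["t1", ], qc2$coords["t2", ], tolerance = 1e-9)
  expect_error(pca_qc(em2, k = 4), "smaller")
})

test_that("count-matrix dialect round-trips through disk", {
  sim <- simulate_counts(expression_sim_config(n_genes = 100, seed = 3,
                                               pathway_plan = NULL))
  td <- withr::local_tempdir()
  write_count_matrix(sim$expression, file.path(td, "counts.tsv"))
  em2 <- read_count_matrix(file.path(td, "counts.tsv"),
                           sim$expression$conditions)
  expect_equal(unname(em2$counts), unname(sim$expression$counts))
  expect_equal(em2$rpkm, sim$expression$rpkm, tolerance = 1e-12)
})
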