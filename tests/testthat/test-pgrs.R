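test_that("additive score matches the log-odds closed form", {
  gm <- make_gm(list(s1 = c(2, 1, 0), s2 = c(0, 0, 0), s3 = c(1, 1, 1)),
                ors = c(2.0, 0.5, 3.0),
                groups = c(s1 = "case", s2 = "case", s3 = "control"))
  tab <- compute_pgrs(gm)
  expect_equal(tab$score[tab$sample_id == "s1"], log(2), tolerance = 1e-12)
  expect_equal(tab$score[tab$sample_id == "s2"], 0)
  expect_equal(tab$score[tab$sample_id == "s3"],
               log(2) + log(0.5) + log(3), tolerance = 1e-12)
  expect_true(all(tab$n_loci_used == 3))

  # unit odds ratios carry no information regardless of dosage
  gm1 <- make_gm(list(s1 = c(2, 1, 0)), ors = c(1, 1, 1), c(s1 = "case"))
  expect_equal(compute_pgrs(gm1)$score, 0)
})

test_that("scoring is additive over a split locus panel", {
  sim <- simulate_genotypes(genotype_sim_config(
    groups = c(case = 25L, control = 25L), missing_rate = 0, seed = 11))
  gm <- sim$genotypes
  w <- stats::setNames(gm$loci$or, gm$loci$snp_id)
  full <- compute_pgrs(gm, weights = w)$score
  half1 <- compute_pgrs(gm, weights = w[1:15])$score
  half2 <- compute_pgrs(gm, weights = w[16:30])$score
  expect_equal(half1 + half2, full, tolerance = 1e-12)
})

test_that("missing-dosage policies behave as documented", {
  dos <- rbind(s1 = c(2, NA), s2 = c(0, 1), s3 = c(2, 1))
  gm <- make_gm(list(s1 = dos[1, ], s2 = dos[2, ], s3 = dos[3, ]),
                ors = c(2, 3),
                groups = c(s1 = "g", s2 = "g", s3 = "g"))
  # impute: NA -> 2 * freq among non-missing = 2 * (0.5) = 1
  imp <- compute_pgrs(gm, missing_policy = "impute")
  expect_equal(imp$score[1], 2 * log(2) + 1 * log(3), tolerance = 1e-12)
  expect_equal(imp$n_imputed, c(1L, 0L, 0L))
  # omit_locus: missing locus contributes nothing
  ol <- compute_pgrs(gm, missing_policy = "omit_locus")
  expect_equal(ol$score[1], 2 * log(2))
  # omit_sample: the incomplete sample is dropped
  os <- compute_pgrs(gm, missing_policy = "omit_sample")
  expect_equal(os$sample_id, c("s2", "s3"))

  expect_error(compute_pgrs(gm, weights = c(rs1 = -1)), "> 0")
  expect_error(compute_pgrs(gm, weights = c(rs9 = 2)), "absent")
})

test_that("in-sample allele ORs match 2x2 closed forms", {
  # cases: 5 samples of dosage 2 -> a = 10, b = 0 (zero cell)
  # controls: 10 samples summing to 5 -> c = 5, d = 15
  cases <- stats::setNames(rep(2, 5), paste0("ca", 1:5))
  ctrls <- stats::setNames(c(2, 2, 1, rep(0, 7)), paste0("co", 1:10))
  gm <- make_gm(as.list(c(cases, ctrls)), ors = 1.5,
                groups = c(stats::setNames(rep("case", 5), names(cases)),
                           stats::setNames(rep("control", 10), names(ctrls))))
  est <- estimate_insample_ors(gm, "case", "control")
  expect_equal(unlist(est[1, c("a", "b", "c", "d")], use.names = FALSE),
               c(10, 0, 5, 15))
  expect_true(est$zero_cell_corrected)
  expect_equal(est$or, (10.5 * 15.5) / (0.5 * 5.5), tolerance = 1e-12)

  # a=10, b=10, c=5, d=15 -> OR 3.0 on the uncorrected table
  cases2 <- stats::setNames(rep(1, 10), paste0("ca", 1:10))
  gm2 <- make_gm(as.list(c(cases2, ctrls)), ors = 1.5,
                 groups = c(stats::setNames(rep("case", 10), names(cases2)),
                            stats::setNames(rep("control", 10),
                                            names(ctrls))))
  est2 <- estimate_insample_ors(gm2, "case", "control")
  expect_false(est2$zero_cell_corrected)
  expect_equal(est2$or, 3.0, tolerance = 1e-12)
  expect_equal(est2$p,
               stats::fisher.test(matrix(c(10, 10, 5, 15), 2,
                                         byrow = TRUE))$p.value)

  # equal allele frequencies -> OR exactly 1
  gm3 <- make_gm(list(a1 = 1, a2 = 1, b1 = 1, b2 = 1), ors = 1.5,
                 groups = c(a1 = "case", a2 = "case",
                            b1 = "control", b2 = "control"))
  expect_equal(estimate_insample_ors(gm3, "case", "control")$or, 1.0)

  expect_error(estimate_insample_ors(gm3, "case", "nope"), "nope")
})

test_that("group comparison reports omnibus, pairwise U and method flags", {
  scores <- data.frame(group = rep(c("a", "b"), each = 3),
                       score = c(1, 2, 3, 4, 5, 6))
  cmp <- compare_groups(scores, c("a", "b"))
  expect_equal(cmp$pairwise$U, 0)
  expect_equal(cmp$pairwise$p, 0.1, tolerance = 1e-12)
  expect_equal(cmp$pairwise$method, "exact")

  # identical tied groups: no evidence, tie-corrected approximation
  scores2 <- data.frame(group = rep(c("a", "b"), each = 3),
                        score = c(1, 2, 3, 1, 2, 3))
  cmp2 <- compare_groups(scores2, c("a", "b"))
  expect_equal(cmp2$pairwise$method, "normal_approx_tie_corrected")
  expect_gt(cmp2$pairwise$p, 0.9)
  expect_equal(cmp2$pairwise$U, 4.5)

  # three groups: omnibus KW plus all three pairs exactly once
  scores3 <- data.frame(group = rep(c("a", "b", "c"), each = 4),
                        score = c(rnorm(8), rnorm(4, 5)))
  cmp3 <- compare_groups(scores3, c("a", "b", "c"))
  expect_equal(nrow(cmp3$pairwise), 3)
  expect_equal(cmp3$omnibus$p,
               stats::kruskal.test(scores3$score,
                                   factor(scores3$group))$p.value)
  expect_error(compare_groups(scores3, c("a", "zz")), "zz")
  expect_error(compare_groups(scores3, "a"), "two groups")

  # optional Bonferroni never lowers a p-value
  cmp4 <- compare_groups(scores3, c("a", "b", "c"), adjust = "bonferroni")
  expect_true(all(cmp4$pairwise$p_adjusted >= cmp4$pairwise$p))
})

test_that("small-sample pairwise p equals brute-force enumeration", {
  set.seed(301)
  for (n in 1:4) {
    for (m in seq_len(8 - n)) {
      if (m < 1) next
      vals <- sample(seq_len(100), n + m)  # distinct values, no ties
      scores <- data.frame(group = rep(c("a", "b"), c(n, m)),
                           score = vals)
      cmp <- compare_groups(scores, c("a", "b"))
      expect_equal(cmp$pairwise$method, "exact")
      expect_equal(cmp$pairwise$p,
                   mw_enum_p(vals[seq_len(n)], vals[n + seq_len(m)]),
                   tolerance = 1e-12,
                   label = sprintf("p for n=%d m=%d", n, m))
      expect_equal(cmp$pairwise$U, mw_u(vals[seq_len(n)], vals[n + seq_len(m)]))
    }
  }
})

test_that("omnibus test is calibrated on null scores", {
  set.seed(99)
  n_rep <- 1000
  pvals <- replicate(n_rep, {
    scores <- data.frame(group = rep(c("a", "b", "c"), each = 15),
                         score = rnorm(45))
    stats::kruskal.test(scores$score, factor(scores$group))$p.value
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.02)
  # p-values roughly uniform: mean near 0.5
  expect_lt(abs(mean(pvals) - 0.5), 0.05)
})

test_that("score and comparison writers produce readable files", {
  gm <- make_gm(list(s1 = c(1, 1), s2 = c(0, 2)), ors = c(1.2, 1.4),
                groups = c(s1 = "case", s2 = "control"))
  tab <- compute_pgrs(gm)
  td <- withr::local_tempdir()
  write_pgrs_table(tab, file.path(td, "scores.tsv"))
  back <- utils::read.delim(file.path(td, "scores.tsv"))
  expect_equal(back$score, tab$score)
  cmp <- compare_groups(rbind(tab, transform(tab, score = score + 1,
                                             sample_id = paste0(sample_id, "b"))),
                        c("case", "control"))
  write_comparison_json(cmp, file.path(td, "cmp.json"))
  parsed <- jsonlite::read_json(file.path(td, "cmp.json"))
  expect_equal(parsed$omnibus$p, cmp$omnibus$p, tolerance = 1e-9)
})
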