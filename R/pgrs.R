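#' Compute additive polygenic risk scores
#'
#' Scores every sample as the weighted sum of its risk-allele dosages,
#' `score = sum_j ln(OR_j) * dosage_j`, the additive log-odds model used for
#' polygenic risk scoring over a curated locus panel. Weights are odds ratios
#' per risk allele; an OR below 1 (protective risk-labelled allele) enters as
#' a negative weight.
#'
#' @param gm A [genotype_matrix()].
#' @param weights Named numeric vector of odds ratios per snp id. Default:
#'   the `or` column of `gm$loci` (literature weights). All weighted snp ids
#'   must be present in the matrix and all ORs must be positive.
#' @param or_source Label recorded per row, conventionally `"literature"` or
#'   `"in_sample"`.
#' @param missing_policy How missing dosages enter the score:
#'   `"impute"` (default) substitutes `2 * f`, with `f` the risk-allele
#'   frequency among non-missing samples of the whole cohort, keeping scores
#'   comparable across samples with different missingness; `"omit_locus"`
#'   drops the missing locus from that sample's sum; `"omit_sample"` drops
#'   samples with any missing dosage.
#' @return A `data.frame` with columns `sample_id`, `group`, `score`,
#'   `or_source`, `n_loci_used`, `n_imputed`.
#' @examples
#' loci <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
#'                    risk_allele = c("A", "C", "G"),
#'                    other_allele = c("G", "T", "A"),
#'                    or = c(2.0, 0.5, 3.0),
#'                    phenotype = "BE", source = NA)
#' d <- matrix(c(2, 1, 0), 1, 3, dimnames = list("s1", loci$snp_id))
#' gm <- genotype_matrix(d, loci, c(s1 = "EA/BE"))
#' compute_pgrs(gm)$score  # 2*ln(2) + ln(0.5) = ln(2)
#' @export
compute_pgrs <- function(gm, weights = NULL, or_source = "literature",
                         missing_policy = c("impute", "omit_locus",
                                            "omit_sample")) {
  missing_policy <- match.arg(missing_policy)
  if (is.null(weights)) {
    weights <- stats::setNames(gm$loci$or, gm$loci$snp_id)
  }
  absent <- setdiff(names(weights), colnames(gm$dosage))
  if (length(absent)) {
    stop("weighted loci absent from genotype matrix: ",
         paste(absent, collapse = ", "))
  }
  if (!length(weights)) stop("empty locus set: nothing to score")
  if (any(weights <= 0)) {
    stop("odds ratios must be > 0; offending: ",
         paste(names(weights)[weights <= 0], collapse = ", "))
  }
  dos <- gm$dosage[, names(weights), drop = FALSE]
  w <- log(weights)
  n_imputed <- rowSums(is.na(dos))
  if (missing_policy == "impute") {
    for (j in seq_len(ncol(dos))) {
      nas <- is.na(dos[, j])
      if (any(nas)) {
        f <- mean(dos[!nas, j]) / 2
        if (is.nan(f)) stop("locus ", colnames(dos)[j],
                            " has no non-missing genotypes to impute from")
        dos[nas, j] <- 2 * f
      }
    }
  } else if (missing_policy == "omit_locus") {
    dos[is.na(dos)] <- 0
  } else {
    keep <- n_imputed == 0
    dos <- dos[keep, , drop = FALSE]
    n_imputed <- n_imputed[keep]
    if (!nrow(dos)) stop("no samples without missing dosages")
  }
  score <- as.numeric(dos %*% w)
  data.frame(sample_id = rownames(dos),
             group = unname(gm$groups[rownames(dos)]),
             score = score,
             or_source = or_source,
             n_loci_used = length(w),
             n_imputed = if (missing_policy == "impute") as.integer(n_imputed)
                         else 0L,
             stringsAsFactors = FALSE)
}

#' Per-SNP case/control allele association and in-sample odds ratios
#'
#' For each locus, cross-tabulates risk versus other allele counts (two per
#' non-missing diploid sample) in a case group against a control group, and
#' reports the allele-count odds ratio `OR = (a*d)/(b*c)` with a two-sided
#' Fisher's exact p-value. Tables with a zero cell get the Haldane-Anscombe
#' +0.5 correction on all four cells for the point estimate only (flagged);
#' the Fisher p is always computed on the raw counts.
#'
#' @param gm A [genotype_matrix()].
#' @param case_group,control_group Group labels present in `gm$groups`.
#' @return A `data.frame` with one row per locus: `snp_id`, the 2x2 counts
#'   `a` (case risk), `b` (case other), `c` (control risk), `d` (control
#'   other), `or`, `p`, `zero_cell_corrected`. `or` is `NA` (with a warning)
#'   when a group has no non-missing genotypes at the locus.
#' @export
estimate_insample_ors <- function(gm, case_group, control_group) {
  for (g in c(case_group, control_group)) {
    if (!g %in% gm$groups) stop("group not present in cohort: ", g)
  }
  case <- gm$dosage[gm$groups == case_group, , drop = FALSE]
  ctrl <- gm$dosage[gm$groups == control_group, , drop = FALSE]
  n <- ncol(gm$dosage)
  out <- data.frame(snp_id = colnames(gm$dosage),
                    a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
                    or = NA_real_, p = NA_real_,
                    zero_cell_corrected = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    x <- case[, j]; y <- ctrl[, j]
    nx <- sum(!is.na(x)); ny <- sum(!is.na(y))
    if (nx == 0 || ny == 0) {
      warning("no non-missing genotypes at ", out$snp_id[j],
              " in one group; OR undefined")
      next
    }
    a <- sum(x, na.rm = TRUE); b <- 2 * nx - a
    c_ <- sum(y, na.rm = TRUE); d <- 2 * ny - c_
    out[j, c("a", "b", "c", "d")] <- c(a, b, c_, d)
    if (any(c(a, b, c_, d) == 0)) {
      out$or[j] <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
      out$zero_cell_corrected[j] <- TRUE
    } else {
      out$or[j] <- (a * d) / (b * c_)
    }
    out$p[j] <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2,
                                          byrow = TRUE))$p.value
  }
  out
}

#' Compare score distributions across groups
#'
#' Omnibus Kruskal-Wallis test across all requested groups plus all pairwise
#' two-sided Mann-Whitney (Wilcoxon rank-sum) tests. Pairwise p-values are
#' exact (full enumeration) when both group sizes are at most 10 and the
#' pooled values have no ties, and otherwise use the normal approximation
#' with tie correction; the method used is recorded per pair. Pairwise
#' p-values are unadjusted by default, matching the convention of reporting
#' raw pairwise p alongside the omnibus test.
#'
#' @param scores A score `data.frame` from [compute_pgrs()] (needs columns
#'   `group` and `score`).
#' @param groups Character vector of group labels to compare (at least two).
#'   Samples in other groups are ignored.
#' @param adjust `"none"` (default) or `"bonferroni"` for the pairwise
#'   p-values.
#' @return A list with `omnibus` (`statistic`, `df`, `p`) and `pairwise`
#'   (a `data.frame`: `group_a`, `group_b`, `n_a`, `n_b`, `U`, `p`,
#'   `method`).
#' @export
compare_groups <- function(scores, groups = unique(scores$group),
                           adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (length(groups) < 2) stop("need at least two groups to compare")
  absent <- setdiff(groups, scores$group)
  if (length(absent)) {
    stop("group(s) absent from score table: ", paste(absent, collapse = ", "))
  }
  sub <- scores[scores$group %in% groups, ]
  kw <- stats::kruskal.test(sub$score, factor(sub$group, levels = groups))
  pairs <- utils::combn(groups, 2)
  pw <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                   n_a = NA_integer_, n_b = NA_integer_,
                   U = NA_real_, p = NA_real_, method = NA_character_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    x <- sub$score[sub$group == pairs[1, i]]
    y <- sub$score[sub$group == pairs[2, i]]
    exact <- length(x) <= 10 && length(y) <= 10 &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                         correct = !exact))
    pw$n_a[i] <- length(x); pw$n_b[i] <- length(y)
    pw$U[i] <- unname(wt$statistic)
    pw$p[i] <- wt$p.value
    pw$method[i] <- if (exact) "exact" else "normal_approx_tie_corrected"
  }
  if (adjust == "bonferroni") {
    pw$p_adjusted <- pmin(1, pw$p * nrow(pw))
  }
  list(omnibus = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter),
                      p = kw$p.value),
       pairwise = pw)
}

#' Write a score table / comparison report
#'
#' @param scores Score `data.frame` from [compute_pgrs()].
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_pgrs_table <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pgrs_table
#' @param comparison Result of [compare_groups()].
#' @export
write_comparison_json <- function(comparison, path) {
  jsonlite::write_json(comparison, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
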