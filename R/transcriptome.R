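#' Normalize a gene-level count matrix to RPKM and TPM
#'
#' RPKM (reads per kilobase per million mapped reads) is
#' `count * 1e9 / (length * total_counts)` per sample; TPM (transcripts per
#' million) rescales per-kilobase rates so each sample sums to one million.
#' RPKM is the unit used by the expression floor and the
#' differential-expression filter; the TPM layer is carried for reporting.
#'
#' @param counts Non-negative integer matrix, genes in rows (named), samples
#'   in columns (named).
#' @param gene_lengths Named numeric vector of gene lengths in bases,
#'   covering every row of `counts`; all lengths must be positive.
#' @param conditions Named character vector mapping every sample to a
#'   condition label.
#' @return An object of class `expression_matrix`: a list with `counts`,
#'   `rpkm`, `tpm`, `gene_lengths`, `conditions`.
#' @examples
#' cnt <- matrix(c(10L, 10L), 2, 1,
#'               dimnames = list(c("g1", "g2"), "s1"))
#' em <- normalize_counts(cnt, c(g1 = 1000, g2 = 2000), c(s1 = "a"))
#' em$tpm  # 666666.67 and 333333.33
#' @export
normalize_counts <- function(counts, gene_lengths, conditions) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene row names and sample column names")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  gl <- gene_lengths[rownames(counts)]
  if (anyNA(gl)) {
    stop("gene lengths missing for: ",
         paste(utils::head(rownames(counts)[is.na(gl)], 5), collapse = ", "))
  }
  if (any(gl <= 0)) stop("gene lengths must be > 0")
  miss <- setdiff(colnames(counts), names(conditions))
  if (length(miss)) {
    stop("samples without a condition label: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  totals <- colSums(counts)
  zero <- colnames(counts)[totals == 0]
  if (length(zero)) {
    stop("sample(s) with zero total counts: ", paste(zero, collapse = ", "))
  }
  rpkm <- sweep(counts / gl, 2, totals, "/") * 1e9
  rate <- counts / gl
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  structure(list(counts = counts, rpkm = rpkm, tpm = tpm,
                 gene_lengths = stats::setNames(as.numeric(gl),
                                                rownames(counts)),
                 conditions = conditions[colnames(counts)]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  cat("conditions:", paste(sprintf("%s (n=%d)", names(table(x$conditions)),
                                   as.integer(table(x$conditions))),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Expression floor: genes considered expressed
#'
#' Returns the genes whose mean RPKM across all samples is at least
#' `threshold` (inclusive, default 2 RPKM); only these are carried into
#' differential-expression testing and PCA.
#'
#' @param em An [normalize_counts()] `expression_matrix`.
#' @param threshold Minimum mean RPKM, inclusive.
#' @return Character vector of gene ids.
#' @export
expression_floor <- function(em, threshold = 2) {
  stopifnot(inherits(em, "expression_matrix"))
  rownames(em$rpkm)[rowMeans(em$rpkm) >= threshold]
}

# Vectorized two-sided Welch t-test across matrix rows.
row_welch <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate zero-variance rows: constant within both groups
  zero <- se2 == 0
  p[zero & ma == mb] <- 1    # identical everywhere: no evidence
  p[zero & ma != mb] <- 0    # perfectly separated groups
  p
}

#' Threshold-based differential expression between two conditions
#'
#' Per-gene two-sided test on `log2(RPKM + 1)` (Welch's unequal-variance t by
#' default, Wilcoxon rank-sum as an alternative), Benjamini-Hochberg FDR
#' across the tested genes, and a three-criterion pass rule: a gene is called
#' differentially expressed iff the larger group mean exceeds
#' `max_mean` (strict, default 2 RPKM), the symmetric fold change
#' (larger mean over smaller mean, on the untransformed RPKM scale) is at
#' least `fc` (default 1.5), and the BH q-value is below `q` (default 0.05).
#' Genes whose smaller mean is zero get infinite fold change (passing the
#' fold-change criterion) rather than a pseudocount-distorted ratio.
#'
#' @param em An `expression_matrix`.
#' @param group_a,group_b Condition labels; direction `up` means higher mean
#'   in `group_a`. Both conditions need at least two samples.
#' @param genes Genes to test; default the [expression_floor()] genes at
#'   `floor_rpkm`.
#' @param test `"welch"` or `"wilcoxon"`.
#' @param max_mean,fc,q The three pass thresholds.
#' @param floor_rpkm Expression floor applied when `genes` is `NULL`.
#' @return A `data.frame` per gene: `gene`, `mean_a`, `mean_b` (RPKM),
#'   `fold_change`, `direction`, `p`, `q`, `pass`.
#' @export
differential_expression <- function(em, group_a, group_b, genes = NULL,
                                    test = c("welch", "wilcoxon"),
                                    max_mean = 2, fc = 1.5, q = 0.05,
                                    floor_rpkm = 2) {
  stopifnot(inherits(em, "expression_matrix"))
  test <- match.arg(test)
  sa <- names(em$conditions)[em$conditions == group_a]
  sb <- names(em$conditions)[em$conditions == group_b]
  if (length(sa) < 2 || length(sb) < 2) {
    stop("both conditions need at least two samples (",
         group_a, ": ", length(sa), ", ", group_b, ": ", length(sb), ")")
  }
  if (is.null(genes)) genes <- expression_floor(em, floor_rpkm)
  if (!length(genes)) stop("no genes pass the expression floor")
  xa <- em$rpkm[genes, sa, drop = FALSE]
  xb <- em$rpkm[genes, sb, drop = FALSE]
  la <- log2(xa + 1); lb <- log2(xb + 1)
  p <- if (test == "welch") {
    row_welch(la, lb)
  } else {
    vapply(seq_along(genes), function(i) {
      suppressWarnings(stats::wilcox.test(la[i, ], lb[i, ])$p.value)
    }, numeric(1))
  }
  qv <- stats::p.adjust(p, method = "BH")
  mean_a <- rowMeans(xa); mean_b <- rowMeans(xb)
  lo <- pmin(mean_a, mean_b); hi <- pmax(mean_a, mean_b)
  fold <- ifelse(lo == 0, Inf, hi / lo)
  if (any(lo == 0 & hi > 0)) {
    warning(sum(lo == 0 & hi > 0),
            " gene(s) with a zero smaller mean: fold change set to Inf")
  }
  fold[lo == 0 & hi == 0] <- 1  # flat zero gene: no change
  res <- data.frame(gene = genes,
                    mean_a = unname(mean_a), mean_b = unname(mean_b),
                    fold_change = unname(fold),
                    direction = ifelse(mean_a >= mean_b, "up", "down"),
                    p = p, q = qv,
                    pass = hi > max_mean & fold >= fc & qv < q,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Exposure-minus-baseline gene-set subtraction
#'
#' Removes from an exposure-response gene list the genes that were already
#' differentially expressed without the exposure, leaving the genes whose
#' response is attributable to the exposure itself.
#'
#' @param de_exposed,de_baseline Character vectors of gene ids.
#' @return A list: `remaining` (exposed minus baseline, in `de_exposed`
#'   order), and counts `n_exposed`, `n_baseline`, `n_intersection`,
#'   `n_remaining`.
#' @export
subtract_baseline <- function(de_exposed, de_baseline) {
  de_exposed <- unique(de_exposed); de_baseline <- unique(de_baseline)
  remaining <- setdiff(de_exposed, de_baseline)
  list(remaining = remaining,
       n_exposed = length(de_exposed),
       n_baseline = length(de_baseline),
       n_intersection = length(intersect(de_exposed, de_baseline)),
       n_remaining = length(remaining))
}

#' PCA-based sample quality control
#'
#' Principal components of `log2(RPKM + 1)` over the floor-passing genes
#' (gene-centered), with an outlier flag per sample: a sample is flagged when
#' its Euclidean distance from its condition centroid in the first `k`
#' components exceeds `median + mad_mult * MAD` of all within-condition
#' distances. Flagged samples are reported, never dropped; exclusion is an
#' explicit downstream decision.
#'
#' @param em An `expression_matrix`.
#' @param k Number of components to keep (must be < number of samples).
#' @param genes Genes to use; default the floor-passing genes.
#' @param mad_mult Multiplier on the MAD for the outlier rule.
#' @param floor_rpkm Expression floor applied when `genes` is `NULL`.
#' @return A list: `coords` (samples x k), `variance_explained` (length k,
#'   non-increasing), `centroid_distance`, `outlier` (named logical),
#'   `threshold`.
#' @export
pca_qc <- function(em, k = 3, genes = NULL, mad_mult = 3, floor_rpkm = 2) {
  stopifnot(inherits(em, "expression_matrix"))
  n <- ncol(em$rpkm)
  if (n < 3) stop("need at least 3 samples for PCA QC")
  if (k >= n) stop("k must be smaller than the number of samples (", n, ")")
  if (is.null(genes)) genes <- expression_floor(em, floor_rpkm)
  x <- t(log2(em$rpkm[genes, , drop = FALSE] + 1))   # samples x genes
  x <- sweep(x, 2, colMeans(x))
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- pc$x[, seq_len(k), drop = FALSE]
  cond <- em$conditions[rownames(coords)]
  dist_c <- numeric(n); names(dist_c) <- rownames(coords)
  for (g in unique(cond)) {
    idx <- which(cond == g)
    centroid <- colMeans(coords[idx, , drop = FALSE])
    dist_c[idx] <- sqrt(rowSums(sweep(coords[idx, , drop = FALSE], 2,
                                      centroid)^2))
  }
  thr <- stats::median(dist_c) + mad_mult * stats::mad(dist_c)
  list(coords = coords,
       variance_explained = ve[seq_len(k)],
       centroid_distance = dist_c,
       outlier = dist_c > thr,
       threshold = thr)
}

#' Write a differential-expression table
#' @param de `data.frame` from [differential_expression()].
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix with gene lengths
#'
#' Tab-delimited interchange: columns `gene_id`, `gene_length`, then one
#' column per sample of raw counts.
#'
#' @param path Count table path.
#' @param conditions Named character vector sample -> condition.
#' @return An `expression_matrix`.
#' @export
read_count_matrix <- function(path, conditions) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  if (!all(c("gene_id", "gene_length") %in% names(tab))) {
    stop("count table must have gene_id and gene_length columns")
  }
  counts <- as.matrix(tab[, setdiff(names(tab), c("gene_id", "gene_length")),
                          drop = FALSE])
  rownames(counts) <- tab$gene_id
  storage.mode(counts) <- "integer"
  normalize_counts(counts, stats::setNames(tab$gene_length, tab$gene_id),
                   conditions)
}

#' Write a count matrix with gene lengths
#' @param em An `expression_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(em, path) {
  df <- data.frame(gene_id = rownames(em$counts),
                   gene_length = em$gene_lengths[rownames(em$counts)],
                   em$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
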