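# Independent brute-force oracles, kept separate from the implementation
# routes they check (stats::wilcox.test, stats::p.adjust, stats::phyper).

# Two-sided Mann-Whitney p by full enumeration of all C(n+m, n) label
# assignments; assumes distinct pooled values. The null distribution of U is
# symmetric, so the two-sided p is the fraction of assignments at least as
# far from the mean U as observed.
mw_enum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  u_all <- apply(combs, 2, function(idx) sum(r[idx])) - n * (n + 1) / 2
  mu <- n * m / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}

# Mann-Whitney U for the first sample (for checking reported statistics).
mw_u <- function(x, y) {
  sum(rank(c(x, y))[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# Benjamini-Hochberg by the textbook recipe: sort p ascending, q at rank i is
# the running minimum of p_j * m / j taken from the largest rank down.
bh_enum <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(1, q_sorted)
  q
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# draws of size k from a universe of size n_univ with the first m elements
# as successes: P(overlap >= k_obs).
hyper_enum_p <- function(n_univ, m, k, k_obs) {
  combs <- utils::combn(n_univ, k)
  cnt <- colSums(combs <= m)
  mean(cnt >= k_obs)
}

# Small genotype_matrix builder for hand-specified dosages.
make_gm <- function(dosage_by_sample, ors, groups) {
  dos <- do.call(rbind, dosage_by_sample)
  n_loci <- ncol(dos)
  pairs <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"), ncol = 2,
                  byrow = TRUE)
  idx <- rep_len(seq_len(nrow(pairs)), n_loci)
  loci <- data.frame(snp_id = paste0("rs", seq_len(n_loci)),
                     risk_allele = pairs[idx, 1],
                     other_allele = pairs[idx, 2],
                     or = ors, phenotype = "BE", source = "test",
                     stringsAsFactors = FALSE)
  colnames(dos) <- loci$snp_id
  rownames(dos) <- names(dosage_by_sample)
  genotype_matrix(dos, loci, groups)
}

# Expression matrix from explicit per-condition RPKM-determining counts.
make_em <- function(counts, lengths = NULL, conditions) {
  if (is.null(lengths)) {
    lengths <- stats::setNames(rep(1000, nrow(counts)), rownames(counts))
  }
  normalize_counts(counts, lengths, conditions)
}

# Minimal single-sample VCF writer for fixtures built in code.
write_test_vcf <- function(path, records, samples) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(records, function(r) {
    paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", "PASS", ".", "GT",
            r$gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}
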