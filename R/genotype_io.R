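VALID_NUCS <- c("A", "C", "G", "T")
NUC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Read a literature risk-locus table
#'
#' Reads a tab-delimited table of risk SNPs derived from the GWAS literature:
#' one row per locus with its rsID, risk allele, other allele, published odds
#' ratio and phenotype annotation. The odds ratio is stored with respect to
#' the declared risk allele; an OR below 1 encodes a protective risk-labelled
#' allele and is kept as-is (no re-polarization).
#'
#' @param path Path to a tab-delimited file with header columns
#'   `snp_id`, `risk_allele`, `other_allele`, `or` and optionally
#'   `phenotype` (one of `BE`, `EAC`, `ESCC`, `combined`) and `source`.
#' @return A `data.frame` with columns `snp_id`, `risk_allele`,
#'   `other_allele`, `or`, `phenotype`, `source`, in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("snp_id\trisk_allele\tother_allele\tor\tphenotype\tsource",
#'              "rs9257809\tA\tG\t1.21\tBE\tgwas1",
#'              "rs3072\tG\tC\t0.88\tcombined\tgwas2"), tf)
#' read_risk_table(tf)
#' @export
read_risk_table <- function(path) {
  if (!file.exists(path)) {
    stop("risk table not found: ", path)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE, strip.white = TRUE)
  required <- c("snp_id", "risk_allele", "other_allele", "or")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("risk table ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"phenotype" %in% names(tab)) tab$phenotype <- "combined"
  if (!"source" %in% names(tab)) tab$source <- NA_character_
  or <- suppressWarnings(as.numeric(tab$or))
  for (i in seq_len(nrow(tab))) {
    line_no <- i + 1L  # header is line 1
    if (is.na(tab$snp_id[i]) || !nzchar(tab$snp_id[i])) {
      stop("risk table line ", line_no, ": empty snp_id")
    }
    if (is.na(or[i])) {
      stop("risk table line ", line_no, " (", tab$snp_id[i],
           "): odds ratio not parseable: '", tab$or[i], "'")
    }
    if (or[i] <= 0) {
      stop("risk table line ", line_no, " (", tab$snp_id[i],
           "): odds ratio must be > 0, got ", or[i])
    }
    a <- toupper(tab$risk_allele[i]); b <- toupper(tab$other_allele[i])
    if (!a %in% VALID_NUCS || !b %in% VALID_NUCS) {
      stop("risk table line ", line_no, " (", tab$snp_id[i],
           "): alleles must be single nucleotides in A/C/G/T")
    }
    if (a == b) {
      stop("risk table line ", line_no, " (", tab$snp_id[i],
           "): risk and other allele are identical")
    }
  }
  dup <- tab$snp_id[duplicated(tab$snp_id)]
  if (length(dup)) {
    stop("duplicate snp_id in risk table: ", paste(unique(dup), collapse = ", "))
  }
  out <- data.frame(snp_id = tab$snp_id,
                    risk_allele = toupper(tab$risk_allele),
                    other_allele = toupper(tab$other_allele),
                    or = or,
                    phenotype = tab$phenotype,
                    source = tab$source,
                    stringsAsFactors = FALSE)
  out
}

#' Write a risk-locus table
#'
#' Inverse of [read_risk_table()]; writing then re-reading reproduces the
#' table exactly.
#'
#' @param risk A risk-locus `data.frame` as returned by [read_risk_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_risk_table <- function(risk, path) {
  utils::write.table(risk, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a genotype matrix of risk-allele dosages
#'
#' Bundles a sample-by-locus dosage matrix (counts of the risk allele, 0/1/2
#' or `NA` for missing) with its risk-locus table and a sample-to-group map.
#'
#' @param dosage Numeric matrix, samples in rows, loci in columns; values in
#'   `{0, 1, 2, NA}`. Row names are sample ids, column names snp ids.
#' @param loci Risk-locus `data.frame` ([read_risk_table()]) whose `snp_id`
#'   matches `colnames(dosage)` one-to-one, in order.
#' @param groups Named character vector mapping every sample id to a group
#'   label (e.g. `EA/BE`, `EA-only`, `BE-only`, `control`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, loci, groups) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    stop("dosage values must be 0, 1, 2 or NA")
  }
  if (is.null(rownames(dosage))) stop("dosage must have sample-id row names")
  if (!identical(colnames(dosage), loci$snp_id)) {
    stop("dosage column names must match loci snp_id in order")
  }
  missing_grp <- setdiff(rownames(dosage), names(groups))
  if (length(missing_grp)) {
    stop("samples without a group label: ",
         paste(utils::head(missing_grp, 5), collapse = ", "))
  }
  structure(list(dosage = dosage, loci = loci,
                 groups = groups[rownames(dosage)]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "loci\n")
  cat("groups:", paste(sprintf("%s (n=%d)", names(table(x$groups)),
                               as.integer(table(x$groups))), collapse = ", "),
      "\n")
  cat("missing dosages:", sum(is.na(x$dosage)), "\n")
  invisible(x)
}

#' Harmonize one VCF record against a risk locus
#'
#' Decides how a biallelic VCF REF/ALT pair maps onto a risk locus's
#' risk/other allele pair. Outcomes:
#' \describe{
#'   \item{matched_as_is}{risk allele is ALT, other allele is REF.}
#'   \item{allele_swapped}{risk allele is REF (dosage becomes `2 - ALT count`).}
#'   \item{strand_flipped}{the reverse-complemented locus alleles match
#'     REF/ALT (genotyped on the opposite strand).}
#'   \item{ambiguous_dropped}{REF/ALT is a palindromic pair (A/T or C/G) whose
#'     strand cannot be resolved; dropped unless `allow_ambiguous = TRUE`.}
#'   \item{not_found}{the allele pairs are incompatible.}
#' }
#'
#' @param vcf_ref,vcf_alt Single-nucleotide REF and ALT alleles.
#' @param locus One-row risk-locus `data.frame` (or list) with
#'   `risk_allele` and `other_allele`.
#' @param allow_ambiguous Keep palindromic (A/T, C/G) pairs, matching alleles
#'   by identity without strand checks. Default `FALSE`: such loci cannot be
#'   strand-resolved without frequency heuristics and are dropped.
#' @return A list with `outcome` (one of the labels above) and
#'   `risk_is_alt` (`TRUE` when the risk allele counts with ALT, `FALSE` when
#'   with REF, `NA` otherwise).
#' @export
harmonize_locus <- function(vcf_ref, vcf_alt, locus, allow_ambiguous = FALSE) {
  vcf_ref <- toupper(vcf_ref); vcf_alt <- toupper(vcf_alt)
  risk <- toupper(locus$risk_allele); other <- toupper(locus$other_allele)
  for (a in c(vcf_ref, vcf_alt, risk, other)) {
    if (!a %in% VALID_NUCS) stop("non-ACGT allele: '", a, "'")
  }
  res <- function(outcome, risk_is_alt = NA) {
    list(outcome = outcome, risk_is_alt = risk_is_alt)
  }
  palindromic <- vcf_ref == NUC_COMPLEMENT[vcf_alt]
  if (palindromic && !allow_ambiguous) return(res("ambiguous_dropped"))
  if (setequal(c(vcf_ref, vcf_alt), c(risk, other))) {
    if (risk == vcf_alt) return(res("matched_as_is", TRUE))
    return(res("allele_swapped", FALSE))
  }
  if (!palindromic &&
      setequal(c(vcf_ref, vcf_alt),
               unname(NUC_COMPLEMENT[c(risk, other)]))) {
    if (NUC_COMPLEMENT[[risk]] == vcf_alt) return(res("strand_flipped", TRUE))
    return(res("strand_flipped", FALSE))
  }
  res("not_found")
}

#' Read cohort genotypes from a VCF into risk-allele dosages
#'
#' Extracts GT genotypes for the risk-locus panel from a VCF (v4.x), matching
#' records by rsID first and by `chrom:pos` second, harmonizes each record's
#' REF/ALT orientation against the declared risk/other alleles
#' ([harmonize_locus()]), and counts risk alleles per sample. Multiallelic
#' records and loci absent from the VCF are reported as `not_found` and
#' excluded from the matrix with a warning.
#'
#' @param path Path to a VCF file with a GT FORMAT field.
#' @param loci Risk-locus `data.frame` ([read_risk_table()]).
#' @param groups Named character vector sample id -> group label
#'   ([read_group_map()]).
#' @param allow_ambiguous Passed to [harmonize_locus()].
#' @return A list with `genotypes` (a [genotype_matrix()] restricted to
#'   successfully harmonized loci) and `report` (a `data.frame` with one row
#'   per input locus: `snp_id`, `outcome`, `n_missing`).
#' @export
read_genotypes_vcf <- function(path, loci, groups, allow_ambiguous = FALSE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  ids <- fix[, "ID"]
  keys <- paste0(fix[, "CHROM"], ":", fix[, "POS"])

  outcome <- character(nrow(loci))
  n_missing <- integer(nrow(loci))
  dosage <- matrix(NA_real_, nrow = length(samples), ncol = nrow(loci),
                   dimnames = list(samples, loci$snp_id))
  for (j in seq_len(nrow(loci))) {
    hit <- which(ids == loci$snp_id[j])
    if (!length(hit) && "pos" %in% names(loci)) {
      hit <- which(keys == paste0(loci$chrom[j], ":", loci$pos[j]))
      if (length(hit)) {
        warning("locus ", loci$snp_id[j], " matched by position, not rsID")
      }
    }
    if (!length(hit)) {
      outcome[j] <- "not_found"
      next
    }
    hit <- hit[1]
    alt <- fix[hit, "ALT"]
    if (grepl(",", alt) || nchar(fix[hit, "REF"]) != 1L || nchar(alt) != 1L) {
      outcome[j] <- "not_found"  # multiallelic / non-SNV records are skipped
      next
    }
    h <- harmonize_locus(fix[hit, "REF"], alt, loci[j, ],
                         allow_ambiguous = allow_ambiguous)
    outcome[j] <- h$outcome
    if (is.na(h$risk_is_alt)) next
    alt_count <- gt_to_alt_count(gt[hit, ])
    dosage[, j] <- if (h$risk_is_alt) alt_count else 2 - alt_count
    n_missing[j] <- sum(is.na(alt_count))
  }
  report <- data.frame(snp_id = loci$snp_id, outcome = outcome,
                       n_missing = n_missing, stringsAsFactors = FALSE)
  keep <- outcome %in% c("matched_as_is", "allele_swapped", "strand_flipped")
  dropped <- loci$snp_id[!keep]
  if (length(dropped)) {
    warning("excluded from scoring (", paste(report$outcome[!keep],
            collapse = ", "), "): ", paste(dropped, collapse = ", "))
  }
  gm <- genotype_matrix(dosage[, keep, drop = FALSE],
                        loci[keep, , drop = FALSE], groups)
  list(genotypes = gm, report = report)
}

# "0/1", "0|1", "./." -> count of ALT alleles (NA for missing)
gt_to_alt_count <- function(gt) {
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) != 2L || any(a == ".") || any(is.na(a))) return(NA_real_)
    sum(a != "0")
  }, numeric(1))
}

#' Read a sample-to-group map
#'
#' @param path Two-column tab-delimited file (`sample_id`, `group`), with or
#'   without a header line named exactly that.
#' @return Named character vector: group label per sample id.
#' @export
read_group_map <- function(path) {
  if (!file.exists(path)) stop("group map not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character", strip.white = TRUE)
  if (ncol(tab) < 2) stop("group map must have two columns: sample_id, group")
  if (identical(tolower(tab[1, 1]), "sample_id")) tab <- tab[-1, , drop = FALSE]
  if (anyDuplicated(tab[[1]])) {
    stop("duplicate sample ids in group map: ",
         paste(unique(tab[[1]][duplicated(tab[[1]])]), collapse = ", "))
  }
  stats::setNames(tab[[2]], tab[[1]])
}

#' Write / read the tabular dosage dialect
#'
#' Tab-delimited matrix interchange: first column `sample_id`, one column per
#' snp id, cells in `{0, 1, 2, NA}`. The locus table and group map travel as
#' side files, so a written [genotype_matrix()] round-trips exactly.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path for the dosage table.
#' @return `path`, invisibly.
#' @export
write_dosages <- function(gm, path) {
  df <- data.frame(sample_id = rownames(gm$dosage), gm$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosages
#' @param loci Risk-locus table matching the dosage columns.
#' @param groups Named character vector sample id -> group.
#' @export
read_dosages <- function(path, loci, groups) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  dosage <- as.matrix(tab[, -1, drop = FALSE])
  rownames(dosage) <- tab$sample_id
  genotype_matrix(dosage, loci, groups)
}

#' Write a group map
#' @param groups Named character vector sample id -> group.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_map <- function(groups, path) {
  utils::write.table(data.frame(sample_id = names(groups),
                                group = unname(groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
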