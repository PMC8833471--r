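# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# Allele-count odds ratio implied by two risk-allele frequencies.
implied_allele_or <- function(f_a, f_b) {
  (f_a * (1 - f_b)) / ((1 - f_a) * f_b)
}

# Risk-allele frequency reached by applying an allele OR to baseline odds.
or_to_freq <- function(f_baseline, or) {
  odds <- or * f_baseline / (1 - f_baseline)
  odds / (1 + odds)
}

#' Configuration for the genotype cohort simulator
#'
#' Defaults emulate a four-group Barrett's-esophagus case-control cohort:
#' EA/BE patients (n = 19), EA-only patients (n = 44), BE-only patients
#' (n = 10) and unaffected controls (n = 730), genotyped at a panel of 30
#' independent literature risk SNPs. Control risk-allele frequencies span
#' 0.2-0.5 (common GWAS lead-SNP range) and published ORs span 1.1-1.6,
#' typical of BE/EAC susceptibility loci. The EA/BE group's frequencies are
#' elevated by applying each locus's published OR to the control allele
#' odds, so the case group carries a genuinely higher polygenic burden; the
#' other groups sit at control frequencies.
#'
#' @param groups Named integer vector: group label -> sample count.
#' @param freqs Numeric matrix, loci x groups (colnames = group labels),
#'   of per-group risk-allele frequencies in `[0, 1]`.
#' @param risk Risk-locus `data.frame` (see [read_risk_table()]) with one
#'   row per row of `freqs`.
#' @param missing_rate Probability a genotype is masked to missing.
#' @param seed Integer seed; the simulator is a pure function of the config.
#' @return A list of class `genotype_sim_config`.
#' @export
genotype_sim_config <- function(groups = c("EA/BE" = 19L, "EA-only" = 44L,
                                           "BE-only" = 10L, control = 730L),
                                freqs = NULL, risk = NULL,
                                missing_rate = 0.01, seed = 1L) {
  if (any(groups < 1)) stop("group sizes must be >= 1")
  if (is.null(risk)) {
    n_loci <- 30L
    pairs <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"), ncol = 2,
                    byrow = TRUE)
    idx <- rep_len(seq_len(nrow(pairs)), n_loci)
    risk <- data.frame(snp_id = sprintf("rs%06d", seq_len(n_loci) * 37 + 100),
                       risk_allele = pairs[idx, 1],
                       other_allele = pairs[idx, 2],
                       or = seq(1.1, 1.6, length.out = n_loci),
                       phenotype = "BE", source = "synthetic",
                       stringsAsFactors = FALSE)
  }
  if (is.null(freqs)) {
    f0 <- rep_len(seq(0.2, 0.5, length.out = 10), nrow(risk))
    freqs <- sapply(names(groups), function(g) {
      if (g == "EA/BE") or_to_freq(f0, risk$or) else f0
    })
    rownames(freqs) <- risk$snp_id
  }
  if (nrow(freqs) != nrow(risk)) stop("freqs rows must match risk loci")
  if (!identical(sort(colnames(freqs)), sort(names(groups)))) {
    stop("freqs columns must match group labels")
  }
  if (any(freqs < 0 | freqs > 1)) stop("frequencies must be in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  structure(list(groups = groups, freqs = freqs, risk = risk,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "genotype_sim_config")
}

#' Simulate a genotyped case-control cohort under Hardy-Weinberg
#'
#' Draws each sample's risk-allele dosage at each locus as
#' `Binomial(2, f_group,locus)` (Hardy-Weinberg genotype frequencies, loci
#' independent, no linkage disequilibrium), then masks genotypes to missing
#' at the configured rate. The truth record carries the generating
#' frequencies and the implied allele-count OR between any two groups,
#' `OR = f_a (1 - f_b) / ((1 - f_a) f_b)`.
#'
#' @param config A [genotype_sim_config()].
#' @return A list: `genotypes` (a [genotype_matrix()]) and `truth`
#'   (`freqs`, `risk`, and `implied_or(snp_id, group_a, group_b)`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "genotype_sim_config"))
  groups <- config$groups
  n_total <- sum(groups)
  group_of <- rep(names(groups), groups)
  sample_ids <- sprintf("S%04d", seq_len(n_total))
  names(group_of) <- sample_ids
  freqs <- config$freqs
  dosage <- with_seed(config$seed, {
    d <- matrix(NA_real_, nrow = n_total, ncol = nrow(freqs),
                dimnames = list(sample_ids, rownames(freqs)))
    for (g in names(groups)) {
      idx <- which(group_of == g)
      for (j in seq_len(nrow(freqs))) {
        d[idx, j] <- stats::rbinom(length(idx), 2, freqs[j, g])
      }
    }
    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(length(d)) < config$missing_rate,
                     nrow = nrow(d))
      d[mask] <- NA_real_
    }
    d
  })
  truth <- list(
    freqs = freqs,
    risk = config$risk,
    implied_or = function(snp_id, group_a, group_b) {
      implied_allele_or(freqs[snp_id, group_a], freqs[snp_id, group_b])
    })
  list(genotypes = genotype_matrix(dosage, config$risk, group_of),
       truth = truth)
}

#' Configuration for the count-matrix simulator
#'
#' Defaults emulate a small paired acid-exposure fibroblast experiment:
#' two conditions of three samples each, 2000 genes with log-normal baseline
#' means around 100 counts and negative-binomial noise. The NB
#' parametrization is `variance = mu + dispersion * mu^2` (i.e.
#' `size = 1/dispersion` in [stats::rnbinom()]); `dispersion -> 0` approaches
#' Poisson. Planted effects multiply (or divide, for `direction = "down"`)
#' the first-named condition's mean by the fold change. The pathway plan
#' builds a gene-set collection in which `n_enriched` sets draw a fraction
#' `de_fraction` of their members from the planted genes, yielding known
#' ground-truth enriched pathways.
#'
#' @param n_genes Number of genes.
#' @param conditions Named integer vector: condition label -> sample count.
#'   The first-named condition receives the planted effects.
#' @param baseline_mean Median baseline NB mean in counts.
#' @param mean_sdlog Log-normal spread of per-gene baseline means.
#' @param dispersion NB dispersion (`variance = mu + dispersion * mu^2`);
#'   must be positive (use a tiny value for near-Poisson counts).
#' @param n_planted Number of genes given a planted effect.
#' @param planted_genes Optional explicit character vector of planted gene
#'   ids (`g00001` style); overrides the random choice of `n_planted` genes.
#' @param planted_fc Fold change for planted genes (>= 1).
#' @param planted_direction `"up"`, `"down"` or `"both"` (alternating).
#' @param pathway_plan `NULL`, or a list with `n_sets`, `set_size`,
#'   `n_enriched`, `de_fraction`.
#' @param length_range Gene-length range in bases (uniform integer draw).
#' @param seed Integer seed.
#' @return A list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 2000L,
                                  conditions = c(exposed = 3L, baseline = 3L),
                                  baseline_mean = 100,
                                  mean_sdlog = 1,
                                  dispersion = 0.1,
                                  n_planted = 100L,
                                  planted_genes = NULL,
                                  planted_fc = 4,
                                  planted_direction = "both",
                                  pathway_plan = list(n_sets = 20L,
                                                      set_size = 50L,
                                                      n_enriched = 5L,
                                                      de_fraction = 0.5),
                                  length_range = c(200L, 10000L),
                                  seed = 1L) {
  if (dispersion <= 0) stop("dispersion must be positive")
  if (planted_fc < 1) stop("planted fold change must be >= 1")
  if (any(conditions < 1)) stop("condition sizes must be >= 1")
  if (!is.null(planted_genes)) n_planted <- length(planted_genes)
  if (n_planted > n_genes) stop("more planted genes than genes")
  structure(list(n_genes = as.integer(n_genes), conditions = conditions,
                 baseline_mean = baseline_mean, mean_sdlog = mean_sdlog,
                 dispersion = dispersion, n_planted = as.integer(n_planted),
                 planted_genes = planted_genes,
                 planted_fc = planted_fc,
                 planted_direction = planted_direction,
                 pathway_plan = pathway_plan,
                 length_range = length_range, seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Simulate a gene-level count matrix with planted effects
#'
#' Negative-binomial counts with condition-specific means: planted genes
#' have their mean in the first-named condition multiplied by the planted
#' fold change (up) or divided by it (down). Pure function of the config
#' (same config, same matrix).
#'
#' @param config An [expression_sim_config()].
#' @return A list: `expression` (an `expression_matrix`), `truth` (a list
#'   with `planted` — `data.frame(gene, fc, direction)` —, `collection` (a
#'   [gene_set_collection()] or `NULL`), `enriched_pathways`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  n <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))
  cond_of <- rep(names(config$conditions), config$conditions)
  sample_ids <- sprintf("%s_%d", cond_of, unlist(lapply(config$conditions,
                                                        seq_len)))
  names(cond_of) <- sample_ids
  effect_cond <- names(config$conditions)[1]

  out <- with_seed(config$seed, {
    lengths <- sample(seq(config$length_range[1], config$length_range[2]),
                      n, replace = TRUE)
    base_mu <- stats::rlnorm(n, meanlog = log(config$baseline_mean),
                             sdlog = config$mean_sdlog)
    planted_idx <- if (is.null(config$planted_genes)) {
      sort(sample.int(n, config$n_planted))
    } else {
      idx <- match(config$planted_genes, gene_ids)
      if (anyNA(idx)) stop("planted gene id(s) outside the gene universe")
      sort(idx)
    }
    direction <- switch(config$planted_direction,
                        up = rep("up", config$n_planted),
                        down = rep("down", config$n_planted),
                        both = rep_len(c("up", "down"), config$n_planted))
    mu <- matrix(base_mu, nrow = n, ncol = length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
    eff_cols <- which(cond_of == effect_cond)
    mult <- ifelse(direction == "up", config$planted_fc,
                   1 / config$planted_fc)
    mu[planted_idx, eff_cols] <- mu[planted_idx, eff_cols] * mult
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / config$dispersion),
                     nrow = n, dimnames = dimnames(mu))
    collection <- NULL
    enriched <- character(0)
    if (!is.null(config$pathway_plan)) {
      pp <- config$pathway_plan
      planted_genes <- gene_ids[planted_idx]
      other_genes <- setdiff(gene_ids, planted_genes)
      sets <- list()
      for (s in seq_len(pp$n_sets)) {
        nm <- sprintf("PW%02d", s)
        if (s <= pp$n_enriched) {
          n_de <- round(pp$de_fraction * pp$set_size)
          sets[[nm]] <- c(sample(planted_genes, min(n_de,
                                                    length(planted_genes))),
                          sample(other_genes, pp$set_size - min(n_de,
                                 length(planted_genes))))
          enriched <- c(enriched, nm)
        } else {
          sets[[nm]] <- sample(other_genes, pp$set_size)
        }
      }
      collection <- gene_set_collection(sets, gene_ids)
    }
    list(counts = counts, lengths = lengths, planted_idx = planted_idx,
         direction = direction, collection = collection, enriched = enriched)
  })

  em <- normalize_counts(out$counts,
                         stats::setNames(out$lengths, gene_ids), cond_of)
  truth <- list(planted = data.frame(gene = gene_ids[out$planted_idx],
                                     fc = rep(config$planted_fc,
                                              length(out$planted_idx)),
                                     direction = out$direction,
                                     stringsAsFactors = FALSE),
                effect_condition = effect_cond,
                collection = out$collection,
                enriched_pathways = out$enriched)
  list(expression = em, truth = truth)
}
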