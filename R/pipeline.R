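#' Default pipeline thresholds
#'
#' The reproduce-by-default thresholds used across the pipeline: expression
#' floor 2 RPKM (inclusive), maximum group mean > 2 RPKM (strict), fold
#' change >= 1.5, BH q < 0.05, enrichment p < 0.05 and |direction z| >= 2.
#' All are overridable per call.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(floor_rpkm = 2, max_mean = 2, fc = 1.5, q = 0.05,
       enrich_p = 0.05, enrich_z = 2)
}

#' One-shot end-to-end demo on simulated data
#'
#' Runs the whole pipeline on synthetic data with known ground truth:
#' simulates a four-group genotyped cohort, scores it with literature and
#' in-sample odds-ratio weights, compares score distributions across groups,
#' simulates an acid-exposure and a no-exposure count experiment, applies
#' the three-criterion differential-expression filter to both, subtracts the
#' baseline gene set from the exposure gene set, scores pathway
#' over-representation for both experiments and reports their overlap and
#' shared genes. Every output is written to `out_dir`; with the same `seed`
#' and config two runs produce byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving all randomness.
#' @param genotype_config Optional [genotype_sim_config()]; default uses the
#'   study-scale cohort (19/44/10/730) with `seed`.
#' @param exposed_config,baseline_config Optional [expression_sim_config()]s
#'   for the exposure and no-exposure experiments; defaults plant 100 and 40
#'   effect genes respectively (derived seeds `seed + 1`, `seed + 2`).
#' @param thresholds Named list as [default_thresholds()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the main in-memory results (`scores`,
#'   `comparisons`, `insample_ors`, `de`, `subtraction`, `enrichment`,
#'   `overlap`, `shared_genes`) and `files` (all written paths).
#' @export
run_demo <- function(out_dir, seed = 1L,
                     genotype_config = NULL,
                     exposed_config = NULL, baseline_config = NULL,
                     thresholds = default_thresholds(),
                     quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  out <- function(f) file.path(out_dir, f)
  seed <- as.integer(seed)

  if (is.null(genotype_config)) genotype_config <- genotype_sim_config(seed = seed)
  if (is.null(exposed_config)) {
    exposed_config <- expression_sim_config(
      conditions = c(EA_acid = 6L, control_acid = 6L),
      n_planted = 100L, planted_direction = "up", seed = seed + 1L)
  }

  say("simulating genotype cohort")
  gsim <- simulate_genotypes(genotype_config)
  gm <- gsim$genotypes
  write_risk_table(gm$loci, out("risk_table.tsv"))
  write_dosages(gm, out("dosages.tsv"))
  write_group_map(gm$groups, out("groups.tsv"))

  say("scoring with literature OR weights")
  scores_lit <- compute_pgrs(gm, or_source = "literature")
  write_pgrs_table(scores_lit, out("pgrs_literature.tsv"))

  say("estimating in-sample ORs and rescoring")
  ors <- estimate_insample_ors(gm, case_group = names(genotype_config$groups)[1],
                               control_group = "control")
  utils::write.table(ors, out("insample_ors.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  w_ins <- stats::setNames(ors$or, ors$snp_id)
  w_ins <- w_ins[!is.na(w_ins)]
  scores_ins <- compute_pgrs(gm, weights = w_ins, or_source = "in_sample")
  write_pgrs_table(scores_ins, out("pgrs_in_sample.tsv"))

  say("comparing score distributions across groups")
  cmp_lit <- compare_groups(scores_lit, names(genotype_config$groups))
  cmp_ins <- compare_groups(scores_ins, names(genotype_config$groups))
  write_comparison_json(cmp_lit, out("comparison_literature.json"))
  write_comparison_json(cmp_ins, out("comparison_in_sample.json"))

  say("simulating exposure and baseline count experiments")
  esim <- simulate_counts(exposed_config)
  if (is.null(baseline_config)) {
    # patient-intrinsic genes: DE with and without the exposure, so the
    # baseline subtraction and the cross-experiment overlap are exercised
    intrinsic <- esim$truth$planted$gene[seq_len(
      min(30L, nrow(esim$truth$planted)))]
    extra <- setdiff(sprintf("g%05d", seq_len(exposed_config$n_genes)),
                     esim$truth$planted$gene)
    baseline_config <- expression_sim_config(
      n_genes = exposed_config$n_genes,
      conditions = c(EA_medium = 6L, control_medium = 6L),
      planted_genes = c(intrinsic, extra[seq_len(10L)]),
      planted_direction = "up",
      pathway_plan = NULL, seed = seed + 2L)
  }
  bsim <- simulate_counts(baseline_config)
  write_count_matrix(esim$expression, out("counts_exposed.tsv"))
  write_count_matrix(bsim$expression, out("counts_baseline.tsv"))

  say("differential expression (three-criterion filter)")
  th <- thresholds
  de_args <- list(max_mean = th$max_mean, fc = th$fc, q = th$q,
                  floor_rpkm = th$floor_rpkm)
  de_exp <- do.call(differential_expression,
                    c(list(esim$expression,
                           names(exposed_config$conditions)[1],
                           names(exposed_config$conditions)[2]), de_args))
  de_base <- do.call(differential_expression,
                     c(list(bsim$expression,
                            names(baseline_config$conditions)[1],
                            names(baseline_config$conditions)[2]), de_args))
  write_de_table(de_exp, out("de_exposed.tsv"))
  write_de_table(de_base, out("de_baseline.tsv"))

  say("subtracting baseline-responsive genes")
  sub <- subtract_baseline(de_exp$gene[de_exp$pass],
                           de_base$gene[de_base$pass])
  jsonlite::write_json(sub, out("subtraction.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  say("pathway over-representation and overlap")
  collection <- esim$truth$collection
  write_gmt(collection$sets, out("pathways.gmt"))
  dir_exp <- stats::setNames(de_exp$direction, de_exp$gene)
  dir_base <- stats::setNames(de_base$direction, de_base$gene)
  enr_exp <- apply_significance(
    suppressWarnings(overrepresentation(de_exp$gene[de_exp$pass], collection,
                                        dir_exp)),
    p_cut = th$enrich_p, z_cut = th$enrich_z)
  enr_base <- apply_significance(
    suppressWarnings(overrepresentation(de_base$gene[de_base$pass],
                                        collection, dir_base)),
    p_cut = th$enrich_p, z_cut = th$enrich_z)
  write_enrichment_table(enr_exp, out("enrichment_exposed.tsv"))
  write_enrichment_table(enr_base, out("enrichment_baseline.tsv"))
  tables <- list(exposed = enr_exp, baseline = enr_base)
  ovl <- overlap_experiments(tables, c("exposed", "baseline"))
  write_enrichment_table(ovl$wide, out("overlap_wide.tsv"))
  jsonlite::write_json(list(pair = ovl$pair, overlap = ovl$overlap,
                            n_overlap = ovl$n_overlap),
                       out("overlap.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  shared <- shared_gene_report(
    list(exposed = de_exp$gene[de_exp$pass],
         baseline = de_base$gene[de_base$pass]),
    ovl$overlap, collection)
  jsonlite::write_json(shared, out("shared_genes.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  run_log <- list(seed = seed, thresholds = th,
                  genotype_groups = as.list(genotype_config$groups),
                  n_loci = nrow(genotype_config$risk),
                  exposed_conditions = as.list(exposed_config$conditions),
                  baseline_conditions = as.list(baseline_config$conditions),
                  package_version = as.character(utils::packageVersion("pgrspipe")))
  jsonlite::write_json(run_log, out("run_log.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    scores = list(literature = scores_lit, in_sample = scores_ins),
    comparisons = list(literature = cmp_lit, in_sample = cmp_ins),
    insample_ors = ors,
    de = list(exposed = de_exp, baseline = de_base),
    subtraction = sub,
    enrichment = tables,
    overlap = ovl,
    shared_genes = shared,
    files = list.files(out_dir, full.names = TRUE)))
}
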