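#' Read gene sets from a GMT file
#'
#' GMT: tab-delimited, one set per line (`name`, `description`, member genes).
#'
#' @param path GMT file path.
#' @return Named list of character vectors (set name -> member gene ids).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(ln, 1, 40))
    }
    sets[[parts[1]]] <- unique(parts[-(1:2)])
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field per set (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Bundle gene sets with a gene universe
#'
#' @param sets Named list of character vectors; every set must be non-empty.
#'   Members outside the universe are kept here and intersected at scoring
#'   time.
#' @param universe Character vector: all genes eligible for selection
#'   (typically the expressed genes).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be a non-empty named list")
  }
  if (any(!lengths(sets))) {
    stop("empty gene set(s): ",
         paste(names(sets)[!lengths(sets)], collapse = ", "))
  }
  if (!length(universe)) stop("empty universe")
  structure(list(sets = sets, universe = unique(universe)),
            class = "gene_set_collection")
}

#' Gene-set over-representation with a directional z-score
#'
#' For each gene set, the upper-tail hypergeometric probability of drawing at
#' least the observed overlap when `|de_genes|` genes are drawn from the
#' universe without replacement (the classical one-sided Fisher / ORA test),
#' plus a simple directional score over the set's differential genes,
#' `z = (n_up - n_down) / sqrt(n_up + n_down)`, undefined (`NA`) when the
#' overlap is zero or directions are not supplied. This directional z is a
#' deliberately simple, fully documented score; it follows the sign
#' convention of activation z-scores (positive = predominantly up) but is
#' not numerically comparable to scores from knowledge-base-driven tools.
#'
#' @param de_genes Character vector of differential gene ids. Genes outside
#'   the collection's universe are dropped with a warning.
#' @param collection A [gene_set_collection()].
#' @param directions Optional named character vector (`"up"`/`"down"`) per DE
#'   gene, e.g. from [differential_expression()]'s `direction` column.
#' @return A `data.frame` per set: `pathway`, `set_size` (within the
#'   universe), `overlap`, `n_up`, `n_down`, `p`, `neg_log10_p`,
#'   `direction_z`, `significant` (initialized `NA`; set by
#'   [apply_significance()]).
#' @examples
#' gsc <- gene_set_collection(list(S = paste0("g", 1:5)), paste0("g", 1:10))
#' overrepresentation(paste0("g", 1:5), gsc)$p  # 1/choose(10, 5)
#' @export
overrepresentation <- function(de_genes, collection, directions = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  de_genes <- unique(de_genes)
  if (!length(de_genes)) stop("empty differential gene list")
  outside <- setdiff(de_genes, collection$universe)
  if (length(outside)) {
    warning(length(outside), " differential gene(s) outside the universe ",
            "dropped from over-representation")
    de_genes <- intersect(de_genes, collection$universe)
    if (!length(de_genes)) stop("no differential genes left in the universe")
  }
  n_univ <- length(collection$universe)
  n_de <- length(de_genes)
  out <- data.frame(pathway = names(collection$sets),
                    set_size = NA_integer_, overlap = NA_integer_,
                    n_up = NA_integer_, n_down = NA_integer_,
                    p = NA_real_, neg_log10_p = NA_real_,
                    direction_z = NA_real_, significant = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_along(collection$sets)) {
    set_u <- intersect(collection$sets[[i]], collection$universe)
    m <- length(set_u)
    hits <- intersect(de_genes, set_u)
    k <- length(hits)
    out$set_size[i] <- m
    out$overlap[i] <- k
    # P(X >= k), X ~ Hypergeometric(universe, set as successes, |DE| draws)
    out$p[i] <- stats::phyper(k - 1, m, n_univ - m, n_de, lower.tail = FALSE)
    out$neg_log10_p[i] <- -log10(out$p[i])
    if (!is.null(directions) && k > 0) {
      dirs <- directions[hits]
      n_up <- sum(dirs == "up", na.rm = TRUE)
      n_down <- sum(dirs == "down", na.rm = TRUE)
      out$n_up[i] <- n_up; out$n_down[i] <- n_down
      if (n_up + n_down > 0) {
        out$direction_z[i] <- (n_up - n_down) / sqrt(n_up + n_down)
      }
    }
  }
  out
}

#' Apply the significance convention to an enrichment table
#'
#' A pathway is significant when `p < p_cut` and `|direction_z| >= z_cut`.
#' Pathways whose directional z is undefined (no directional information, as
#' in knowledge-base reports printing N/A) are evaluated in p-only mode and
#' annotated as such.
#'
#' @param table `data.frame` from [overrepresentation()].
#' @param p_cut P-value cutoff (exclusive), default 0.05.
#' @param z_cut Absolute directional-z cutoff (inclusive), default 2.
#' @param mode `"strict"` (p and z) or `"p_only"` (ignore z for all rows).
#' @return The table with `significant` filled and a `significance_mode`
#'   column (`"p_and_z"` or `"p_only"` per row).
#' @export
apply_significance <- function(table, p_cut = 0.05, z_cut = 2,
                               mode = c("strict", "p_only")) {
  mode <- match.arg(mode)
  z_undefined <- is.na(table$direction_z)
  p_ok <- table$p < p_cut
  if (mode == "p_only") {
    table$significant <- p_ok
    table$significance_mode <- "p_only"
  } else {
    table$significant <- ifelse(z_undefined, p_ok,
                                p_ok & abs(table$direction_z) >= z_cut)
    table$significance_mode <- ifelse(z_undefined, "p_only", "p_and_z")
  }
  table
}

#' Cross-experiment pathway-overlap table
#'
#' Builds a wide pathway-by-experiment table of all pathways significant in
#' at least one experiment, with `(neg_log10_p, direction_z)` per cell and
#' `NA` cells where a pathway was absent from an experiment's results, and
#' reports the intersection of significant pathways for a designated pair of
#' experiments. Symmetric in the pair and idempotent on identical inputs.
#'
#' @param tables Named list of enrichment tables, each already passed through
#'   [apply_significance()].
#' @param pair Character vector of two experiment names to intersect.
#' @return A list: `wide` (`data.frame` with per-experiment
#'   `<exp>.neg_log10_p`, `<exp>.direction_z`, `<exp>.significant` columns),
#'   `overlap` (pathways significant in both designated experiments) and
#'   `n_overlap`.
#' @export
overlap_experiments <- function(tables, pair) {
  if (length(tables) < 2) stop("need at least two experiments")
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("tables must be a named list of enrichment tables")
  }
  if (length(pair) != 2) stop("pair must name exactly two experiments")
  unknown <- setdiff(pair, names(tables))
  if (length(unknown)) {
    stop("unknown experiment name(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(tables)) {
    if (!"significant" %in% names(tables[[nm]]) ||
        anyNA(tables[[nm]]$significant)) {
      stop("experiment '", nm, "': run apply_significance() first")
    }
  }
  sig_sets <- lapply(tables, function(t) t$pathway[t$significant])
  all_paths <- sort(unique(unlist(sig_sets)))
  wide <- data.frame(pathway = all_paths, stringsAsFactors = FALSE)
  for (nm in names(tables)) {
    t <- tables[[nm]]
    idx <- match(all_paths, t$pathway)
    wide[[paste0(nm, ".neg_log10_p")]] <- t$neg_log10_p[idx]
    wide[[paste0(nm, ".direction_z")]] <- t$direction_z[idx]
    wide[[paste0(nm, ".significant")]] <- t$significant[idx]
  }
  overlap <- sort(intersect(sig_sets[[pair[1]]], sig_sets[[pair[2]]]))
  list(wide = wide, pair = pair, overlap = overlap,
       n_overlap = length(overlap))
}

#' Genes differentially expressed in both experiments, per overlap pathway
#'
#' For each pathway in an overlap list, the genes that are differentially
#' expressed in both experiments and belong to that pathway, plus the union
#' count across pathways (each gene counted once).
#'
#' @param de_lists Named list (experiment -> character vector of DE gene
#'   ids); must contain at least the two experiments behind the overlap.
#' @param pathways Character vector of overlap pathway names.
#' @param collection A [gene_set_collection()] defining pathway membership.
#' @return A list: `per_pathway` (named list of character vectors),
#'   `union_genes`, `n_union`.
#' @export
shared_gene_report <- function(de_lists, pathways, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(de_lists) < 2) stop("need DE lists from at least two experiments")
  shared_de <- Reduce(intersect, de_lists)
  per_pathway <- lapply(pathways, function(p) {
    if (!p %in% names(collection$sets)) {
      stop("pathway not in collection: ", p)
    }
    sort(intersect(shared_de, collection$sets[[p]]))
  })
  names(per_pathway) <- pathways
  union_genes <- sort(unique(unlist(per_pathway)))
  list(per_pathway = per_pathway, union_genes = union_genes,
       n_union = length(union_genes))
}

#' Write enrichment / overlap tables
#' @param table Enrichment `data.frame`, or the `wide` element of
#'   [overlap_experiments()].
#' @param path Output path (tab-delimited; `NA` cells written as `NA`).
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
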