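# End-to-end orchestration: file IO, pipeline configuration, clustering,
# and the run-all driver that writes every analysis artifact as TSV.

#' Write / read a probe-level intensity TSV
#'
#' Long-by-replicate layout: columns `probe_id`, `gene_id`, `replicate`,
#' then one column per sample.
#'
#' @param pm A [probe_matrix()].
#' @param path File path.
#' @return `path` invisibly (write); a [probe_matrix()] without class
#'   labels attached requires the annotation table (read).
#' @export
write_probe_tsv <- function(pm, path) {
  stopifnot(inherits(pm, "probe_matrix"))
  d <- dim(pm$intensities)
  rows <- do.call(rbind, lapply(seq_len(d[2]), function(r) {
    data.frame(probe_id = dimnames(pm$intensities)[[1]],
               gene_id = unname(pm$probe_gene),
               replicate = r,
               pm$intensities[, r, ],
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$probe_id, rows$replicate, method = "radix"), ]
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_probe_tsv
#' @param annotation Data.frame with columns `sample_id`, `class` (and
#'   optionally `cohort`), or path to such a TSV.
#' @export
read_probe_tsv <- function(path, annotation) {
  if (is.character(annotation))
    annotation <- utils::read.delim(annotation, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "class") %in% names(annotation)))
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("probe_id", "gene_id", "replicate") %in% names(tab)))
  samples <- setdiff(names(tab), c("probe_id", "gene_id", "replicate"))
  probes <- unique(tab$probe_id)
  reps <- sort(unique(tab$replicate))
  ints <- array(NA_real_, dim = c(length(probes), length(reps), length(samples)),
                dimnames = list(probes, NULL, samples))
  for (r in seq_along(reps)) {
    sub <- tab[tab$replicate == reps[r], ]
    sub <- sub[match(probes, sub$probe_id), ]
    ints[, r, ] <- as.matrix(sub[, samples])
  }
  if (anyNA(ints)) stop("incomplete probe/replicate grid in ", path)
  probe_gene <- stats::setNames(tab$gene_id[match(probes, tab$probe_id)], probes)
  classes <- stats::setNames(annotation$class, annotation$sample_id)
  probe_matrix(ints, probe_gene, classes)
}

#' Write / read a feature-by-sample matrix TSV
#'
#' @param mat Numeric matrix with row and column names.
#' @param path File path.
#' @param id_col Name of the id column (default `"feature_id"`).
#' @return `path` invisibly (write); a numeric matrix (read).
#' @export
write_matrix_tsv <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Pipeline configuration
#'
#' Bundles the inputs and the analysis parameters of one end-to-end run.
#' Either file paths (`probe_file`, `annotation_file`, `pathway_file`) or
#' an in-memory `sim_study` (`study`) may be supplied.
#'
#' @param probe_file,annotation_file,pathway_file Input paths (see
#'   [write_probe_tsv()], [write_pathway_db()]).
#' @param study Alternatively, a `sim_study` object.
#' @param out_dir Output directory.
#' @param control_class Label of the control (normal) class.
#' @param pseudocount CNR pseudocount (default 1).
#' @param log_base PAS logarithm base (default 10).
#' @param fraction Top fraction selected per comparison (default 0.10).
#' @param group_size_factors Estimate size factors per sample class
#'   (default TRUE) or globally.
#' @param quantile Apply quantile normalization (default TRUE).
#' @param round Floor aggregated expression to integers (default TRUE).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            probe_file = NULL, annotation_file = NULL,
                            pathway_file = NULL, study = NULL,
                            control_class = "Normal", pseudocount = 1,
                            log_base = 10, fraction = 0.10,
                            group_size_factors = TRUE, quantile = TRUE,
                            round = TRUE) {
  stopifnot(fraction > 0, fraction <= 1, pseudocount >= 0, log_base > 0)
  if (is.null(study)) {
    for (f in c(probe_file, annotation_file, pathway_file))
      if (!file.exists(f)) stop("input file not found: ", f)
  } else stopifnot(inherits(study, "sim_study"))
  structure(list(out_dir = out_dir, probe_file = probe_file,
                 annotation_file = annotation_file,
                 pathway_file = pathway_file, study = study,
                 control_class = control_class, pseudocount = pseudocount,
                 log_base = log_base, fraction = fraction,
                 group_size_factors = group_size_factors,
                 quantile = quantile, round = round),
            class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Probe aggregation, per-class size-factor normalization, quantile
#' normalization, restriction to the pathway database's gene space, CNR
#' against the control class, PAS scoring, constant-feature removal,
#' AUC-ranked marker tables for every pairwise comparison (and the triple
#' comparison when exactly three classes are present) at both the gene
#' (log10 CNR) and pathway (PAS2) level, and complete-linkage clustering
#' of samples on PAS2. All artifacts are written as TSV under `out_dir`
#' together with a parameter log; outputs are byte-identical across
#' re-runs with identical inputs.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the normalized expression, `cnr`, `pas`
#'   (filtered), the marker tables (`markers`, named by comparison and
#'   level), and the clustering.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  if (!is.null(cfg$study)) {
    pm <- cfg$study$probe_matrix
    db <- cfg$study$pathway_db
  } else {
    pm <- with_stage("read", read_probe_tsv(cfg$probe_file, cfg$annotation_file))
    db <- with_stage("read", read_pathway_db(cfg$pathway_file))
  }
  classes <- pm$sample_class
  note("control_class=", cfg$control_class,
       " pseudocount=", cfg$pseudocount, " log_base=", cfg$log_base,
       " fraction=", cfg$fraction,
       " group_size_factors=", cfg$group_size_factors,
       " quantile=", cfg$quantile, " round=", cfg$round)
  if (!cfg$control_class %in% classes)
    stop("control class '", cfg$control_class, "' absent from annotation")

  expr <- with_stage("aggregate", aggregate_probes(pm, round = cfg$round))
  expr <- with_stage("size_factors", size_factor_normalize(
    expr, classes = if (cfg$group_size_factors) classes else NULL))
  note("size_factors=", paste(sprintf("%s:%.4f", names(attr(expr, "size_factors")),
                                      attr(expr, "size_factors")), collapse = " "))
  if (cfg$quantile)
    expr <- with_stage("quantile", quantile_normalize(expr))
  expr <- with_stage("harmonize", harmonize_gene_space(expr, db = db))
  note("genes_missing_from_design=", length(attr(expr, "missing_genes")))

  ctrl_ids <- names(classes)[classes == cfg$control_class]
  cnr <- with_stage("cnr", compute_cnr(expr, ctrl_ids,
                                       pseudocount = cfg$pseudocount))
  pas <- with_stage("pas", compute_pas(cnr, db, log_base = cfg$log_base))
  pas <- with_stage("filter", suppressMessages(filter_constant_features(pas)))
  note("constant_pathways_removed=", length(attr(pas, "removed")))
  logcnr <- log(cnr, base = cfg$log_base)
  genes_var <- with_stage("filter", suppressMessages(
    filter_constant_features(logcnr)))
  note("constant_genes_removed=", length(attr(genes_var, "removed")))

  write_matrix_tsv(expr, file.path(cfg$out_dir, "expression_normalized.tsv"),
                   "gene_id")
  write_matrix_tsv(cnr, file.path(cfg$out_dir, "cnr.tsv"), "gene_id")
  write_matrix_tsv(pas$pas2, file.path(cfg$out_dir, "pas2.tsv"), "pathway")

  labs <- unique(unname(classes))
  cases <- setdiff(labs, cfg$control_class)
  comparisons <- c(lapply(cases, function(cl) c(cl, cfg$control_class)),
                   if (length(cases) >= 2)
                     utils::combn(cases, 2, simplify = FALSE))
  markers <- list()
  feature_sets <- list(pathway = pas$pas2, gene = genes_var)
  for (cmp in comparisons) {
    for (lev in names(feature_sets)) {
      res <- with_stage("markers", select_top_fraction(
        pairwise_markers(feature_sets[[lev]], classes, cmp[1], cmp[2],
                         level = lev), cfg$fraction))
      key <- paste0(cmp[1], "_vs_", cmp[2], ".", lev)
      markers[[key]] <- res
      utils::write.table(res, file.path(cfg$out_dir,
                                        paste0("markers_", key, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         fileEncoding = "UTF-8")
    }
  }
  if (length(labs) == 3L) {
    for (lev in names(feature_sets)) {
      res <- with_stage("markers", select_top_fraction(
        multiclass_markers(feature_sets[[lev]], classes, level = lev),
        cfg$fraction))
      key <- paste0(paste(labs, collapse = "_vs_"), ".", lev)
      markers[[key]] <- res
      utils::write.table(res, file.path(cfg$out_dir,
                                        paste0("markers_", key, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         fileEncoding = "UTF-8")
    }
  }
  note("comparisons=", paste(names(markers), collapse = " "))

  clust <- if (ncol(pas$pas2) >= 2L)
    with_stage("cluster", hierarchical_cluster(pas$pas2)) else NULL
  if (!is.null(clust)) {
    writeLines(clust$order, file.path(cfg$out_dir, "cluster_leaf_order.txt"))
    write_matrix_tsv(pas$pas2[, clust$order, drop = FALSE],
                     file.path(cfg$out_dir, "pas2_clustered.tsv"), "pathway")
  }
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(list(expression = expr, cnr = cnr, pas = pas,
                 markers = markers, clustering = clust))
}

#' Complete-linkage hierarchical clustering of samples
#'
#' Agglomerative clustering of the samples (columns) with Euclidean
#' distance and complete linkage, as used for expression heatmaps. The
#' merge tree and leaf order come from [stats::hclust()], whose ordering
#' is deterministic for a given input.
#'
#' @param mat Numeric matrix, features x samples (>= 2 samples, no
#'   missing values).
#' @return List with `hclust` (the merge tree) and `order` (sample ids in
#'   leaf order).
#' @export
hierarchical_cluster <- function(mat) {
  stopifnot(is.matrix(mat), !anyNA(mat))
  if (ncol(mat) < 2L) stop("clustering needs at least 2 samples")
  hc <- stats::hclust(stats::dist(t(mat), method = "euclidean"),
                      method = "complete")
  list(hclust = hc, order = colnames(mat)[hc$order])
}

#' Compare the selected markers of two pipeline runs
#'
#' Builds pathway-level marker lists from the selected records of a
#' comparison present in both runs and matches them (see
#' [match_markers()]).
#'
#' @param run_a,run_b Return values of [run_pipeline()].
#' @param comparison Marker-table key, e.g. `"AML_vs_Normal.pathway"`.
#' @param cohorts Length-2 labels for the two runs.
#' @return A `match_report`.
#' @export
compare_cohorts <- function(run_a, run_b, comparison,
                            cohorts = c("cohortA", "cohortB")) {
  for (r in list(run_a, run_b))
    if (is.null(r$markers[[comparison]]))
      stop("comparison not found in run: ", comparison)
  lev <- run_a$markers[[comparison]]$level[1]
  match_markers(
    as_marker_list(run_a$markers[[comparison]], cohort = cohorts[1], level = lev),
    as_marker_list(run_b$markers[[comparison]], cohort = cohorts[2], level = lev))
}
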