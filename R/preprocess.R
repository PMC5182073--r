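# Probe-level to gene-level preprocessing: geometric replicate/probe
# averaging, median-of-ratios size factors, quantile normalization, and
# restriction to an array design's gene space.

geom_mean <- function(x) exp(mean(log(x)))  # log(0) = -Inf => 0, by convention

#' Construct a probe-level intensity matrix
#'
#' @param intensities Non-negative numeric 3-d array, probes x replicates x
#'   samples, with probe and sample dimnames.
#' @param probe_gene Character vector mapping probe id -> gene symbol,
#'   named by probe id; must cover every probe.
#' @param sample_class Character vector of class labels (e.g. Normal/AML/ALL)
#'   named by sample id; must cover every sample.
#' @return A `probe_matrix` object.
#' @export
probe_matrix <- function(intensities, probe_gene, sample_class) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3L)
  if (any(intensities < 0)) stop("probe intensities must be >= 0")
  probes <- dimnames(intensities)[[1]]
  samples <- dimnames(intensities)[[3]]
  if (is.null(probes) || is.null(samples))
    stop("intensities needs probe and sample dimnames")
  if (!all(probes %in% names(probe_gene)))
    stop("probe_gene must map every probe to exactly one gene")
  if (!all(samples %in% names(sample_class)))
    stop("sample_class must label every sample")
  structure(list(intensities = intensities,
                 probe_gene = probe_gene[probes],
                 sample_class = sample_class[samples]),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("probe_matrix: %d probes x %d replicates x %d samples (%d genes)\n",
              d[1], d[2], d[3], length(unique(x$probe_gene))))
  cat("classes:", paste(sprintf("%s=%d", names(table(x$sample_class)),
                                table(x$sample_class)), collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate replicate probes into a gene-level expression matrix
#'
#' Replicate signals of each probe are geometrically averaged; where a gene
#' has several probes, the probe values are geometrically averaged in turn.
#' The result is rounded down to integer values (the integer scale expected
#' by the size-factor step) unless `round = FALSE`. A probe with any
#' zero replicate contributes a geometric mean of 0.
#'
#' @param pm A [probe_matrix()].
#' @param round Floor the aggregated values to integers (default TRUE).
#' @return Numeric matrix, genes x samples (gene order = first appearance in
#'   the probe map).
#' @export
aggregate_probes <- function(pm, round = TRUE) {
  stopifnot(inherits(pm, "probe_matrix"))
  ints <- pm$intensities
  # replicate-level geometric mean: probes x samples
  probe_vals <- exp(apply(log(ints), c(1, 3), mean))
  if (any(probe_vals == 0))
    message(sum(probe_vals == 0), " probe/sample value(s) are 0 ",
            "(zero replicate present)")
  gene_order <- unique(unname(pm$probe_gene))
  logs <- log(probe_vals)
  agg <- rowsum(logs, group = pm$probe_gene, reorder = FALSE)
  counts <- as.vector(table(factor(pm$probe_gene, levels = rownames(agg))))
  vals <- exp(agg / counts)
  vals <- vals[gene_order, , drop = FALSE]
  if (round) vals <- floor(vals)
  vals
}

#' Median-of-ratios size-factor normalization
#'
#' Classical median-of-ratios scaling: the reference is the per-gene
#' geometric mean across a group's samples (genes with any zero value in
#' the group are excluded from the reference); each sample's size factor is
#' the median over included genes of value/reference. Factors within a
#' group are rescaled so their geometric mean is 1 (a singleton group gets
#' factor 1), which preserves the group's overall scale; values are divided
#' by the factor. With `classes` supplied, factors are estimated within
#' each sample class independently ("with respect to the sample type");
#' otherwise globally.
#'
#' @param mat Numeric matrix, genes x samples, non-negative.
#' @param classes Optional class label per sample (named by sample id, or
#'   positional). When given, per-class factor estimation is used.
#' @return The normalized matrix, with attribute `"size_factors"` (named by
#'   sample).
#' @export
size_factor_normalize <- function(mat, classes = NULL) {
  stopifnot(is.matrix(mat), all(mat >= 0))
  groups <- if (is.null(classes)) rep("all", ncol(mat))
            else align_classes(classes, colnames(mat))
  sf <- rep(NA_real_, ncol(mat))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) == 1L) { sf[idx] <- 1; next }
    sub <- mat[, idx, drop = FALSE]
    ok <- rowSums(sub == 0) == 0L
    if (!any(ok)) stop("no reference genes (all genes have a zero) in group '",
                       g, "'")
    ref <- exp(rowMeans(log(sub[ok, , drop = FALSE])))
    f <- apply(sub[ok, , drop = FALSE] / ref, 2, stats::median)
    f <- f / exp(mean(log(f)))
    sf[idx] <- f
  }
  out <- sweep(mat, 2, sf, "/")
  names(sf) <- colnames(mat)
  attr(out, "size_factors") <- sf
  out
}

#' Quantile normalization
#'
#' Classical quantile normalization: within each sample the value of rank
#' *r* is replaced by the mean across samples of the *r*-th order
#' statistics; tied values receive the mean of the reference values over
#' the rank positions the tie group occupies. Afterwards every sample holds
#' the same multiset of values.
#'
#' @param mat Numeric matrix, features x samples, no missing values.
#' @return The quantile-normalized matrix.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat), !anyNA(mat))
  if (ncol(mat) <= 1L) return(mat)
  ref <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    y <- numeric(length(x))
    y[order(x)] <- ref
    out[, j] <- stats::ave(y, factor(x), FUN = mean)
  }
  out
}

#' Restrict an expression matrix to an array design's gene space
#'
#' @param mat Numeric matrix, genes x samples.
#' @param design_genes Character vector of design gene symbols; the output
#'   keeps their order.
#' @param db Optional [pathway_db()]; when given and `design_genes` is
#'   missing, its gene universe is used as the design.
#' @return The matrix restricted to design genes present in `mat`, with
#'   attribute `"missing_genes"` (design genes absent from the matrix).
#' @export
harmonize_gene_space <- function(mat, design_genes = NULL, db = NULL) {
  stopifnot(is.matrix(mat))
  if (is.null(design_genes)) {
    if (is.null(db)) stop("supply design_genes or a pathway database")
    design_genes <- gene_universe(db)
  }
  stopifnot(length(design_genes) >= 1L)
  keep <- design_genes[design_genes %in% rownames(mat)]
  if (!length(keep))
    stop("no design genes found in the expression matrix")
  missing <- setdiff(design_genes, rownames(mat))
  if (length(missing))
    message(length(missing), " design gene(s) missing from the matrix")
  out <- mat[keep, , drop = FALSE]
  attr(out, "missing_genes") <- missing
  out
}

# Align a (possibly named) class-label vector with a set of sample ids.
align_classes <- function(classes, sample_ids) {
  if (!is.null(names(classes))) {
    if (!all(sample_ids %in% names(classes)))
      stop("class labels missing for sample(s): ",
           paste(setdiff(sample_ids, names(classes)), collapse = ", "))
    unname(classes[sample_ids])
  } else {
    if (length(classes) != length(sample_ids))
      stop("classes must be named by sample id or match the sample count")
    unname(classes)
  }
}
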