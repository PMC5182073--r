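# AUC-based biomarker ranking: oriented Mann-Whitney AUC per feature,
# pairwise and triple-comparison scoring, top-fraction selection.

#' Oriented ROC AUC of a single feature
#'
#' The raw AUC is the Mann-Whitney probability that a case value exceeds a
#' control value, with ties counted half:
#' `[#(case > control) + 0.5 * #(case == control)] / (n_case * n_control)`,
#' computed via midranks. The oriented AUC folds it into \[0.5, 1\]
#' (`max(raw, 1 - raw)`); `direction` is `"up"` when the case class tends
#' to larger values (raw >= 0.5), `"down"` otherwise.
#'
#' @param case_values,control_values Non-empty numeric vectors.
#' @return List with `auc` (oriented), `raw`, and `direction`.
#' @export
compute_auc <- function(case_values, control_values) {
  n1 <- length(case_values); n2 <- length(control_values)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  r <- rank(c(case_values, control_values))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  raw <- u / (n1 * n2)
  list(auc = max(raw, 1 - raw), raw = raw,
       direction = if (raw >= 0.5) "up" else "down")
}

#' Rank features by oriented AUC for one two-class comparison
#'
#' One record per feature: oriented AUC, direction, and the case/control
#' group means. Records are sorted by oriented AUC descending with ties
#' broken by feature id ascending (byte order), so rankings are fully
#' reproducible.
#'
#' @param features Numeric matrix, features x samples.
#' @param classes Class label per sample (named by sample id, or aligned
#'   with the columns).
#' @param case,control Class labels to compare.
#' @param level Feature level annotation, `"pathway"` or `"gene"`.
#' @return A `comparison_result`: data.frame with columns `feature_id`,
#'   `level`, `comparison`, `auc`, `direction`, `mean_case`,
#'   `mean_control`, carrying attribute `"comparison"`.
#' @export
pairwise_markers <- function(features, classes, case, control,
                             level = c("pathway", "gene")) {
  stopifnot(is.matrix(features), nrow(features) >= 1L)
  level <- match.arg(level)
  cl <- align_classes(classes, colnames(features))
  for (lab in c(case, control))
    if (!lab %in% cl) stop("unknown class label: ", lab)
  ci <- which(cl == case); ki <- which(cl == control)
  recs <- apply(features, 1, function(v) {
    a <- compute_auc(v[ci], v[ki])
    c(a$auc, a$raw, mean(v[ci]), mean(v[ki]))
  })
  res <- data.frame(
    feature_id = rownames(features),
    level = level,
    comparison = paste0(case, "_vs_", control),
    auc = recs[1, ],
    direction = ifelse(recs[2, ] >= 0.5, "up", "down"),
    mean_case = recs[3, ],
    mean_control = recs[4, ],
    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(-res$auc, res$feature_id, method = "radix"), ]
  rownames(res) <- NULL
  attr(res, "comparison") <- paste0(case, "_vs_", control)
  class(res) <- c("comparison_result", "data.frame")
  res
}

#' Rank features by averaged AUC over a three-class comparison
#'
#' For each feature the three pairwise oriented AUCs (class1 vs class2,
#' class1 vs class3, class2 vs class3) are computed and their arithmetic
#' mean used as the feature's overall separation score. Sorting and
#' tie-breaking follow [pairwise_markers()].
#'
#' @inheritParams pairwise_markers
#' @return A `comparison_result` with the averaged score in `auc`, the
#'   three pairwise oriented AUCs in `auc_<a>_vs_<b>` columns, and per-class
#'   mean columns.
#' @export
multiclass_markers <- function(features, classes, level = c("pathway", "gene")) {
  stopifnot(is.matrix(features))
  level <- match.arg(level)
  cl <- align_classes(classes, colnames(features))
  labs <- unique(cl)
  if (length(labs) != 3L)
    stop("triple comparison needs exactly three classes, got ", length(labs))
  prs <- utils::combn(labs, 2, simplify = FALSE)
  idx <- lapply(labs, function(l) which(cl == l))
  names(idx) <- labs
  aucs <- sapply(prs, function(p)
    apply(features, 1, function(v) compute_auc(v[idx[[p[1]]]], v[idx[[p[2]]]])$auc))
  if (nrow(features) == 1L) aucs <- matrix(aucs, nrow = 1)
  colnames(aucs) <- vapply(prs, function(p) paste0("auc_", p[1], "_vs_", p[2]),
                           character(1))
  means <- sapply(labs, function(l) rowMeans(features[, idx[[l]], drop = FALSE]))
  if (nrow(features) == 1L) means <- matrix(means, nrow = 1)
  colnames(means) <- paste0("mean_", labs)
  res <- data.frame(
    feature_id = rownames(features),
    level = level,
    comparison = paste(labs, collapse = "_vs_"),
    auc = rowMeans(aucs),
    aucs, means,
    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(-res$auc, res$feature_id, method = "radix"), ]
  rownames(res) <- NULL
  attr(res, "comparison") <- paste(labs, collapse = "_vs_")
  class(res) <- c("comparison_result", "data.frame")
  res
}

#' Select the top fraction of ranked markers
#'
#' Marks the best `ceiling(fraction * n)` records of an already-ranked
#' comparison as selected ("approximately 10% best separators" with the
#' default fraction) and records the cutoff AUC, i.e. the lowest selected
#' score. Ties spanning the boundary are resolved by the ranking's
#' deterministic feature-id order, leaving the count unchanged.
#'
#' @param result A `comparison_result` from [pairwise_markers()] or
#'   [multiclass_markers()].
#' @param fraction Fraction of features to keep, in (0, 1\]; default 0.10.
#' @return The result with a logical `selected` column and attributes
#'   `"cutoff_auc"` and `"fraction"`.
#' @export
select_top_fraction <- function(result, fraction = 0.10) {
  stopifnot(inherits(result, "comparison_result"), nrow(result) >= 1L,
            fraction > 0, fraction <= 1)
  k <- ceiling(fraction * nrow(result))
  result$selected <- seq_len(nrow(result)) <= k
  attr(result, "cutoff_auc") <- result$auc[k]
  attr(result, "fraction") <- fraction
  result
}
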