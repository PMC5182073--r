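# Cancer-to-normal ratios (CNR) and pathway activation strength (PAS).

#' Cancer-to-normal expression ratios
#'
#' For each gene, the control mean is the average expression over the
#' control samples; the CNR of gene *g* in sample *s* is
#' `(value(g,s) + pseudocount) / (control_mean(g) + pseudocount)`.
#' Control samples may themselves be scored, each against the full control
#' mean; by default every sample in the matrix is scored.
#'
#' @param mat Numeric matrix, genes x samples, non-negative.
#' @param control_ids Sample ids forming the control (normal) cohort.
#' @param pseudocount Non-negative value added to numerator and denominator;
#'   must be > 0 if any zeros are present. Default 1 (integer-scale
#'   normalized expression).
#' @param samples Samples to score; defaults to all columns.
#' @param control_average `"arithmetic"` (default) or `"geometric"` control
#'   averaging.
#' @return Positive matrix, genes x scored samples, with attributes
#'   `"control_ids"` and `"pseudocount"`.
#' @export
compute_cnr <- function(mat, control_ids, pseudocount = 1,
                        samples = colnames(mat),
                        control_average = c("arithmetic", "geometric")) {
  stopifnot(is.matrix(mat), length(control_ids) >= 1L, pseudocount >= 0)
  control_average <- match.arg(control_average)
  if (!all(control_ids %in% colnames(mat)))
    stop("control sample(s) not in matrix: ",
         paste(setdiff(control_ids, colnames(mat)), collapse = ", "))
  if (!all(samples %in% colnames(mat)))
    stop("sample(s) not in matrix: ",
         paste(setdiff(samples, colnames(mat)), collapse = ", "))
  if (pseudocount == 0 && any(mat[, samples] == 0))
    stop("zero expression values present; use a pseudocount > 0")
  ctrl <- mat[, control_ids, drop = FALSE]
  cmean <- if (control_average == "arithmetic") rowMeans(ctrl)
           else exp(rowMeans(log(ctrl)))
  denom <- cmean + pseudocount
  if (any(denom == 0))
    stop("control mean + pseudocount is 0 for gene(s): ",
         paste(rownames(mat)[denom == 0], collapse = ", "))
  cnr <- (mat[, samples, drop = FALSE] + pseudocount) / denom
  attr(cnr, "control_ids") <- control_ids
  attr(cnr, "pseudocount") <- pseudocount
  cnr
}

#' Pathway activation strength scores
#'
#' For a pathway *p* and sample *s*, the raw score is
#' `sum over member genes n of ARR(n,p) * log10(CNR(n,s))`; the normalized
#' score PAS2 divides by the number of member genes, so a positive PAS2
#' indicates pathway activation relative to the controls and a negative
#' one its repression. By default the denominator is the *effective* gene
#' count (member genes actually measured in the CNR matrix), which keeps
#' scores comparable across platforms that miss different genes; the
#' nominal pathway size can be used instead. Pathways with no measured
#' genes are dropped with a warning.
#'
#' @param cnr Positive matrix, genes x samples (see [compute_cnr()]).
#' @param db A [pathway_db()].
#' @param log_base Base of the logarithm (default 10).
#' @param denominator `"effective"` (default) or `"nominal"` gene count.
#' @return A `pas_result`: list with `raw` and `pas2` matrices
#'   (pathways x samples), `effective_n`, and `nominal_n`.
#' @export
compute_pas <- function(cnr, db, log_base = 10,
                        denominator = c("effective", "nominal")) {
  stopifnot(is.matrix(cnr), inherits(db, "pathway_db"))
  denominator <- match.arg(denominator)
  if (any(cnr <= 0)) stop("CNR values must be > 0")
  logc <- log(cnr, base = log_base)
  measured <- rownames(cnr)
  rows <- lapply(db, function(p) {
    g <- intersect(names(p$arr), measured)
    raw <- if (length(g))
      as.vector(p$arr[g] %*% logc[g, , drop = FALSE]) else rep(NA_real_, ncol(cnr))
    list(raw = raw, eff = length(g), nom = length(p$arr))
  })
  eff <- vapply(rows, `[[`, integer(1), "eff")
  if (any(eff == 0L)) {
    warning(sum(eff == 0L), " pathway(s) with no measured genes dropped: ",
            paste(utils::head(names(rows)[eff == 0L], 5), collapse = ", "))
    rows <- rows[eff > 0L]
    eff <- eff[eff > 0L]
  }
  if (!length(rows)) stop("no pathway has measured genes")
  raw <- do.call(rbind, lapply(rows, `[[`, "raw"))
  dimnames(raw) <- list(names(rows), colnames(cnr))
  nom <- vapply(rows, `[[`, integer(1), "nom")
  den <- if (denominator == "effective") eff else nom
  pas2 <- raw / den
  structure(list(raw = raw, pas2 = pas2, effective_n = eff, nominal_n = nom),
            class = "pas_result")
}

#' @export
print.pas_result <- function(x, ...) {
  cat(sprintf("pas_result: %d pathways x %d samples (PAS2 range %.3g..%.3g)\n",
              nrow(x$pas2), ncol(x$pas2), min(x$pas2), max(x$pas2)))
  invisible(x)
}

#' Remove features that are constant across all samples
#'
#' Features (rows) whose values are exactly identical in every sample carry
#' no class information and are removed before biomarker ranking.
#'
#' @param x Feature matrix (features x samples) or a `pas_result`.
#' @param ... Unused.
#' @return Same type as `x`, with constant rows removed and attribute
#'   `"removed"` listing them (for a `pas_result`, the attribute sits on
#'   the object).
#' @export
filter_constant_features <- function(x, ...) UseMethod("filter_constant_features")

#' @rdname filter_constant_features
#' @export
filter_constant_features.matrix <- function(x, ...) {
  stopifnot(ncol(x) >= 1L)
  variable <- apply(x, 1, function(r) any(r != r[1]))
  if (!any(variable)) stop("no variable features")
  removed <- rownames(x)[!variable]
  if (length(removed))
    message(length(removed), " constant feature(s) removed")
  out <- x[variable, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' @rdname filter_constant_features
#' @export
filter_constant_features.pas_result <- function(x, ...) {
  variable <- apply(x$pas2, 1, function(r) any(r != r[1]))
  if (!any(variable)) stop("no variable features")
  removed <- rownames(x$pas2)[!variable]
  if (length(removed))
    message(length(removed), " constant pathway(s) removed")
  out <- structure(list(raw = x$raw[variable, , drop = FALSE],
                        pas2 = x$pas2[variable, , drop = FALSE],
                        effective_n = x$effective_n[variable],
                        nominal_n = x$nominal_n[variable]),
                   class = "pas_result")
  attr(out, "removed") <- removed
  out
}
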