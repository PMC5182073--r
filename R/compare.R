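# Cross-cohort concordance of selected marker lists: complete/incomplete x
# concordant/discordant match taxonomy.

#' Construct a marker list for cohort comparison
#'
#' @param feature_id Character vector of unique feature ids (pathway or
#'   gene names).
#' @param direction `"up"`/`"down"` per feature.
#' @param cohort Cohort label (e.g. "pediatric", "adult").
#' @param level `"pathway"` or `"gene"`.
#' @return A `marker_list` data.frame with attributes `cohort` and `level`.
#' @export
marker_list <- function(feature_id, direction, cohort = "",
                        level = c("pathway", "gene")) {
  level <- match.arg(level)
  stopifnot(length(feature_id) == length(direction),
            all(direction %in% c("up", "down")))
  if (anyDuplicated(feature_id))
    stop("duplicate feature id(s) in marker list")
  out <- data.frame(feature_id = as.character(feature_id),
                    direction = as.character(direction),
                    stringsAsFactors = FALSE)
  attr(out, "cohort") <- cohort
  attr(out, "level") <- level
  class(out) <- c("marker_list", "data.frame")
  out
}

#' Marker list from the selected records of a ranked comparison
#'
#' @param result A `comparison_result` with a `selected` column (see
#'   [select_top_fraction()]).
#' @param cohort Cohort label.
#' @param level Feature level; defaults to the records' own level.
#' @return A [marker_list()].
#' @export
as_marker_list <- function(result, cohort = "", level = NULL) {
  stopifnot(inherits(result, "comparison_result"))
  if (is.null(result$selected))
    stop("run select_top_fraction() first")
  sel <- result[result$selected, ]
  if (is.null(level)) level <- sel$level[1]
  if (is.null(sel$direction))
    stop("triple-comparison results carry no direction; ",
         "build the marker list from a pairwise comparison")
  marker_list(sel$feature_id, sel$direction, cohort = cohort, level = level)
}

#' Match two cohorts' marker lists
#'
#' A *complete* match is an identical feature id in both lists, *concordant*
#' when the directions agree and *discordant* otherwise. For pathway-level
#' lists only, an *incomplete* match pairs features that share a root
#' pathway name (see [parse_branch_name()]) but are different branches;
#' every cross-pair under a shared root is classified independently by
#' direction agreement. Features taking part in a complete match are
#' excluded from incomplete matching; features in neither kind of match are
#' reported unmatched.
#'
#' @param a,b [marker_list()] objects at the same level.
#' @return A `match_report`: list with `pairs` (data.frame: `category`,
#'   `root`, `feature_a`, `direction_a`, `feature_b`, `direction_b`),
#'   `unmatched_a`, `unmatched_b`, `level`, `cohorts`.
#' @export
match_markers <- function(a, b) {
  stopifnot(inherits(a, "marker_list"), inherits(b, "marker_list"))
  if (!identical(attr(a, "level"), attr(b, "level")))
    stop("marker lists are at different levels (",
         attr(a, "level"), " vs ", attr(b, "level"), ")")
  level <- attr(a, "level")
  dir_a <- stats::setNames(a$direction, a$feature_id)
  dir_b <- stats::setNames(b$direction, b$feature_id)

  complete <- sort(intersect(a$feature_id, b$feature_id))
  pairs <- data.frame(category = character(0), root = character(0),
                      feature_a = character(0), direction_a = character(0),
                      feature_b = character(0), direction_b = character(0),
                      stringsAsFactors = FALSE)
  if (length(complete)) {
    conc <- dir_a[complete] == dir_b[complete]
    pairs <- rbind(pairs, data.frame(
      category = ifelse(conc, "complete_concordant", "complete_discordant"),
      root = parse_branch_name(complete)$root,
      feature_a = complete, direction_a = unname(dir_a[complete]),
      feature_b = complete, direction_b = unname(dir_b[complete]),
      stringsAsFactors = FALSE))
  }

  rem_a <- setdiff(a$feature_id, complete)
  rem_b <- setdiff(b$feature_id, complete)
  contrib_a <- character(0); contrib_b <- character(0)
  if (level == "pathway" && length(rem_a) && length(rem_b)) {
    root_a <- stats::setNames(parse_branch_name(rem_a)$root, rem_a)
    root_b <- stats::setNames(parse_branch_name(rem_b)$root, rem_b)
    for (r in sort(intersect(root_a, root_b))) {
      fa <- sort(names(root_a)[root_a == r])
      fb <- sort(names(root_b)[root_b == r])
      grid <- expand.grid(feature_a = fa, feature_b = fb,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      conc <- dir_a[grid$feature_a] == dir_b[grid$feature_b]
      pairs <- rbind(pairs, data.frame(
        category = ifelse(conc, "incomplete_concordant",
                          "incomplete_discordant"),
        root = r,
        feature_a = grid$feature_a, direction_a = unname(dir_a[grid$feature_a]),
        feature_b = grid$feature_b, direction_b = unname(dir_b[grid$feature_b]),
        stringsAsFactors = FALSE))
      contrib_a <- c(contrib_a, fa)
      contrib_b <- c(contrib_b, fb)
    }
  }
  structure(list(
    pairs = pairs,
    unmatched_a = setdiff(rem_a, contrib_a),
    unmatched_b = setdiff(rem_b, contrib_b),
    level = level,
    cohorts = c(a = attr(a, "cohort"), b = attr(b, "cohort"))),
    class = "match_report")
}

match_categories <- c("complete_concordant", "complete_discordant",
                      "incomplete_concordant", "incomplete_discordant")

#' Summarize a match report
#'
#' @param report A `match_report` from [match_markers()].
#' @return Data.frame with one row per match category: `category`,
#'   `n_pairs`, `features` (semicolon-separated `a ~ b` pairs), plus
#'   unmatched counts as two extra rows.
#' @export
summarize_matches <- function(report) {
  stopifnot(inherits(report, "match_report"))
  p <- report$pairs
  rows <- lapply(match_categories, function(cat) {
    sub <- p[p$category == cat, , drop = FALSE]
    feats <- if (nrow(sub)) {
      paste(ifelse(sub$feature_a == sub$feature_b, sub$feature_a,
                   paste(sub$feature_a, "~", sub$feature_b)), collapse = "; ")
    } else ""
    data.frame(category = cat, n_pairs = nrow(sub), features = feats,
               stringsAsFactors = FALSE)
  })
  rbind(do.call(rbind, rows),
        data.frame(category = c("unmatched_a", "unmatched_b"),
                   n_pairs = c(length(report$unmatched_a),
                               length(report$unmatched_b)),
                   features = c(paste(report$unmatched_a, collapse = "; "),
                                paste(report$unmatched_b, collapse = "; ")),
                   stringsAsFactors = FALSE))
}

#' @export
print.match_report <- function(x, ...) {
  s <- summarize_matches(x)
  cat(sprintf("match_report (%s level): %s vs %s\n", x$level,
              x$cohorts["a"], x$cohorts["b"]))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-22s %3d  %s\n", s$category[i], s$n_pairs[i],
                substr(s$features[i], 1, 60)))
  invisible(x)
}

#' Write a match report as TSV
#'
#' @param report A `match_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_match_report <- function(report, path) {
  p <- report$pairs
  extra <- data.frame(
    category = c(rep("unmatched_a", length(report$unmatched_a)),
                 rep("unmatched_b", length(report$unmatched_b))),
    root = parse_branch_name(c(report$unmatched_a, report$unmatched_b))$root,
    feature_a = c(report$unmatched_a, rep(NA, length(report$unmatched_b))),
    direction_a = NA,
    feature_b = c(rep(NA, length(report$unmatched_a)), report$unmatched_b),
    direction_b = NA, stringsAsFactors = FALSE)
  if (!length(report$unmatched_a) && !length(report$unmatched_b))
    extra <- extra[0, , drop = FALSE]
  utils::write.table(rbind(p, extra), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
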