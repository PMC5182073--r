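# Pathway definitions with per-gene activator/repressor role (ARR) weights.

#' Admissible activator/repressor role weights
#'
#' The role of a gene product inside a pathway is encoded by a discrete
#' weight: +1 for an activator, -1 for a repressor, +0.5 / -0.5 for
#' intermediate activator/repressor roles and 0 for an unknown role.
#'
#' @return Numeric vector of the five admissible ARR values.
#' @export
arr_values <- function() c(-1, -0.5, 0, 0.5, 1)

#' Construct a single pathway
#'
#' @param name Pathway name; a trailing parenthesized suffix is interpreted
#'   as a branch label (see [parse_branch_name()]).
#' @param arr Named numeric vector of ARR weights, named by gene symbol.
#' @param description Free-text description.
#' @return A `pathway` object (list with `name`, `description`, `arr`).
#' @export
pathway <- function(name, arr, description = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(arr) < 1L) stop("pathway '", name, "': needs at least one gene")
  genes <- trimws(names(arr))
  if (is.null(names(arr)) || any(!nzchar(genes)))
    stop("pathway '", name, "': every ARR weight must be named by a gene")
  if (anyDuplicated(genes))
    stop("pathway '", name, "': duplicate gene(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (!all(arr %in% arr_values()))
    stop("pathway '", name, "': ARR weight outside {-1,-0.5,0,0.5,1}")
  names(arr) <- genes
  structure(list(name = name, description = description, arr = arr),
            class = "pathway")
}

#' Construct a pathway database
#'
#' @param pathways List of [pathway()] objects with unique names.
#' @return A `pathway_db` object: a named list of pathways, in input order.
#' @export
pathway_db <- function(pathways) {
  stopifnot(is.list(pathways), length(pathways) >= 1L)
  nm <- vapply(pathways, function(p) p$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate pathway name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(pathways) <- nm
  structure(pathways, class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  sizes <- vapply(x, function(p) length(p$arr), integer(1))
  cat(sprintf("pathway_db: %d pathways, %d genes (sizes %d-%d)\n",
              length(x), length(gene_universe(x)), min(sizes), max(sizes)))
  invisible(x)
}

#' Names of the pathways in a database
#' @param db A `pathway_db`.
#' @return Character vector of pathway names, in database order.
#' @export
pathway_names <- function(db) {
  stopifnot(inherits(db, "pathway_db"))
  names(db)
}

#' Union of all gene symbols used by a pathway database
#' @param db A `pathway_db`.
#' @return Character vector of unique gene symbols.
#' @export
gene_universe <- function(db) {
  stopifnot(inherits(db, "pathway_db"))
  unique(unlist(lapply(db, function(p) names(p$arr)), use.names = FALSE))
}

#' Read a pathway database from an extended GMT file
#'
#' The extended GMT (".gmtx") dialect is a superset of GMT: one pathway per
#' tab-separated line, fields `name`, `description`, then one `GENE|ARR`
#' token per member gene with ARR in \{-1, -0.5, 0, 0.5, 1\}. Plain GMT
#' tokens without `|ARR` are accepted with ARR defaulting to +1 (a message
#' reports how many were defaulted).
#'
#' @param path Path to the file.
#' @return A validated [pathway_db()]; input order preserved.
#' @export
read_pathway_db <- function(path) {
  if (!file.exists(path)) stop("pathway database file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty pathway database: ", path)
  n_default <- 0L
  pws <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    f <- trimws(f)
    if (length(f) < 3L)
      stop(sprintf("line %d: expected name, description and >=1 gene token", i))
    toks <- f[-(1:2)]
    toks <- toks[nzchar(toks)]
    if (!length(toks))
      stop(sprintf("line %d: no gene tokens", i))
    has_w <- grepl("|", toks, fixed = TRUE)
    gene <- ifelse(has_w, sub("\\|[^|]*$", "", toks), toks)
    wtok <- ifelse(has_w, sub("^.*\\|", "", toks), "1")
    arr <- suppressWarnings(as.numeric(wtok))
    bad <- is.na(arr) | !(arr %in% arr_values())
    if (any(bad))
      stop(sprintf("line %d: unparsable ARR token '%s' (must be one of %s)",
                   i, wtok[which(bad)[1]],
                   paste(arr_values(), collapse = ", ")))
    n_default <- n_default + sum(!has_w)
    if (any(!nzchar(trimws(gene))))
      stop(sprintf("line %d: empty gene symbol", i))
    if (anyDuplicated(trimws(gene)))
      stop(sprintf("line %d: duplicate gene '%s' within pathway '%s'",
                   i, trimws(gene)[duplicated(trimws(gene))][1], f[1]))
    names(arr) <- gene
    pws[[i]] <- pathway(f[1], arr, description = f[2])
  }
  nm <- vapply(pws, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    d <- which(duplicated(nm))[1]
    stop(sprintf("line %d: duplicate pathway name '%s'", d, nm[d]))
  }
  if (n_default > 0L)
    message(n_default, " gene token(s) without |ARR weight; defaulted to +1")
  pathway_db(pws)
}

#' Write a pathway database to an extended GMT file
#'
#' @param db A `pathway_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathway_db <- function(db, path) {
  stopifnot(inherits(db, "pathway_db"))
  lines <- vapply(db, function(p) {
    paste(c(p$name, p$description,
            paste0(names(p$arr), "|", as.character(p$arr))),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Split a pathway name into root and branch
#'
#' Pathway branches are named by a final parenthesized suffix, e.g.
#' `"ATM Pathway (Apoptosis)"` has root `"ATM Pathway"` and branch
#' `"Apoptosis"`. Only the final trailing parenthetical is treated as the
#' branch; earlier parentheses stay in the root. A name whose trailing
#' parentheses are unbalanced is kept whole as the root (with a warning).
#'
#' @param name Character vector of pathway names.
#' @return A data.frame with columns `name`, `root`, `branch` (branch is
#'   `""` when there is no trailing parenthetical).
#' @export
parse_branch_name <- function(name) {
  stopifnot(is.character(name), all(nzchar(name)))
  one <- function(x) {
    x <- trimws(x)
    nc <- nchar(x)
    if (substring(x, nc, nc) != ")") return(c(x, ""))
    depth <- 0L
    for (j in nc:1) {
      ch <- substring(x, j, j)
      if (ch == ")") depth <- depth + 1L
      else if (ch == "(") {
        depth <- depth - 1L
        if (depth == 0L) {
          root <- trimws(substring(x, 1, j - 1L))
          if (!nzchar(root)) return(c(x, ""))  # pure parenthetical: keep whole
          return(c(root, substring(x, j + 1L, nc - 1L)))
        }
      }
    }
    warning("unbalanced parentheses in pathway name: ", x)
    c(x, "")
  }
  m <- vapply(name, one, character(2))
  data.frame(name = name, root = m[1, ], branch = m[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}
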