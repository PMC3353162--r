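## Per-taxon extinction probabilities, including mapping from IUCN Red
## List categories and data-deficient imputation policies.

.IUCN_CATEGORIES <- c("CR", "EN", "VU", "NT", "LC")

#' Construct an extinction-probability map
#'
#' A named vector of probabilities of extinction in `[0, 1]`, one per
#' taxon, with per-taxon provenance recorded (`"direct"`,
#' `"category-mapped"` or `"data-deficient-imputed"`).
#'
#' @param p named numeric vector of probabilities in `[0, 1]`.
#' @param provenance character vector (length 1 or `length(p)`).
#' @param value_set_name name of the category value set used, or
#'   `"custom"`.
#' @return an object of class `extinction_map`.
#' @export
extinction_map <- function(p, provenance = "direct",
                           value_set_name = "custom") {
  if (!is.numeric(p) || is.null(names(p)) || any(!nzchar(names(p))))
    pd_stop("extinction_map() needs a numeric vector named by taxon")
  names(p) <- trimws(names(p))
  if (anyDuplicated(names(p)))
    pd_stop("duplicate taxa in extinction map")
  if (anyNA(p) || any(p < 0 | p > 1))
    pd_stop("extinction probabilities must lie in [0, 1]")
  provenance <- rep_len(provenance, length(p))
  structure(p, class = "extinction_map", provenance = provenance,
            value_set_name = value_set_name)
}

#' @export
print.extinction_map <- function(x, ...) {
  cat(sprintf("Extinction map over %d taxa (value set: %s)\n", length(x),
              attr(x, "value_set_name")))
  print(utils::head(setNames(as.numeric(x), names(x))))
  if (length(x) > 6L) cat("...\n")
  invisible(x)
}

#' Taxa with positive extinction probability
#'
#' The positive-probability subset of an extinction map (the complement of
#' the taxa routed through the zero-probability HED coefficients).
#'
#' @param p an `extinction_map` or named probability vector.
#' @return character vector of taxon labels.
#' @export
positive_taxa <- function(p) {
  names(p)[as.numeric(p) > 0]
}

#' Built-in IUCN category-to-probability value sets
#'
#' Two published assignments of indicative extinction probabilities to the
#' five IUCN Red List threat categories: `"isaac"` (CR 0.4, EN 0.2, VU 0.1,
#' NT 0.05, LC 0.025 — a doubling of risk per rank) and `"iucn100"`
#' (CR 0.999, EN 0.667, VU 0.1, NT 0.01, LC 0.0001).
#'
#' @param name `"isaac"` or `"iucn100"`.
#' @return a `category_value_set`.
#' @export
builtin_value_set <- function(name) {
  sets <- list(
    isaac = c(CR = 0.4, EN = 0.2, VU = 0.1, NT = 0.05, LC = 0.025),
    iucn100 = c(CR = 0.999, EN = 0.667, VU = 0.1, NT = 0.01, LC = 0.0001))
  if (!is.character(name) || length(name) != 1L || !name %in% names(sets))
    pd_stop(paste0("unknown value set '", paste(name, collapse = ","),
                   "'; valid names: ", paste(names(sets), collapse = ", ")))
  category_value_set(sets[[name]], name = name)
}

#' Construct a category value set
#'
#' @param values named numeric vector over exactly `CR, EN, VU, NT, LC`,
#'   strictly decreasing from CR to LC, all in `(0, 1]`.
#' @param name a label for the set.
#' @return a `category_value_set` (list with `name` and `values`).
#' @export
category_value_set <- function(values, name = "custom") {
  if (!setequal(names(values), .IUCN_CATEGORIES))
    pd_stop(paste0("value set must cover exactly the categories ",
                   paste(.IUCN_CATEGORIES, collapse = ", ")))
  values <- values[.IUCN_CATEGORIES]
  if (any(values <= 0 | values > 1))
    pd_stop("category values must lie in (0, 1]")
  if (any(diff(values) >= 0))
    pd_stop("category values must strictly decrease from CR to LC")
  structure(list(name = name, values = values), class = "category_value_set")
}

#' @export
print.category_value_set <- function(x, ...) {
  cat(sprintf("Category value set '%s':\n", x$name))
  print(x$values)
  invisible(x)
}

#' Map IUCN categories to extinction probabilities
#'
#' Taxa with one of the five indicative categories (CR, EN, VU, NT, LC,
#' case-insensitive) are mapped through the value set.  Data-deficient
#' (DD) taxa are handled by policy:
#' \describe{
#'   \item{`"weighted_mean"`}{the mean of the mapped values of all non-DD
#'     taxa (equivalently the category values weighted by their counts);}
#'   \item{`"as_category:C"`}{the value of category `C`, e.g.
#'     `"as_category:NT"`;}
#'   \item{`"fixed:v"`}{a fixed probability `v`, e.g. `"fixed:0.07"`.}
#' }
#' Extinct and extinct-in-the-wild codes (EX, EW) are rejected: prune those
#' tips from the tree instead of scoring them.
#'
#' @param status named character vector (taxon -> category code) or a data
#'   frame with columns `taxon` and `category`.
#' @param value_set a `category_value_set` (default the `"isaac"` set).
#' @param dd_policy policy string, see Details.
#' @return an [extinction_map()].
#' @examples
#' map_categories(c(a = "CR", b = "LC", c = "DD"), builtin_value_set("isaac"))
#' @export
map_categories <- function(status, value_set = builtin_value_set("isaac"),
                           dd_policy = "weighted_mean") {
  if (is.data.frame(status)) {
    if (!all(c("taxon", "category") %in% names(status)))
      pd_stop("status data frame needs columns 'taxon' and 'category'")
    status <- setNames(as.character(status$category),
                       as.character(status$taxon))
  }
  if (is.null(names(status)) || any(!nzchar(names(status))))
    pd_stop("status must be named by taxon")
  if (!inherits(value_set, "category_value_set"))
    pd_stop("value_set must be a category_value_set")
  taxa <- trimws(names(status))
  cats <- toupper(trimws(unname(status)))
  if (any(cats %in% c("EX", "EW"))) {
    bad <- taxa[cats %in% c("EX", "EW")]
    pd_stop(paste0("extinct categories cannot be scored; prune these tips ",
                   "from the tree: ", paste(bad, collapse = ", ")))
  }
  unknown <- !(cats %in% c(.IUCN_CATEGORIES, "DD"))
  if (any(unknown))
    pd_stop(paste0("unknown IUCN category code(s): ",
                   paste0(taxa[unknown], " ('", status[unknown], "')",
                          collapse = ", ")))
  p <- numeric(length(taxa))
  dd <- cats == "DD"
  p[!dd] <- unname(value_set$values[cats[!dd]])
  prov <- rep("category-mapped", length(taxa))
  if (any(dd)) {
    p[dd] <- .dd_value(dd_policy, value_set, p[!dd])
    prov[dd] <- "data-deficient-imputed"
  }
  extinction_map(setNames(p, taxa), provenance = prov,
                 value_set_name = value_set$name)
}

.dd_value <- function(dd_policy, value_set, mapped_values) {
  if (!is.character(dd_policy) || length(dd_policy) != 1L)
    pd_stop("dd_policy must be a single string")
  if (dd_policy == "weighted_mean") {
    if (!length(mapped_values))
      pd_stop("weighted_mean imputation needs at least one non-DD taxon")
    return(mean(mapped_values))
  }
  if (startsWith(dd_policy, "as_category:")) {
    cat <- toupper(sub("^as_category:", "", dd_policy))
    if (!cat %in% .IUCN_CATEGORIES)
      pd_stop(paste0("as_category policy needs one of ",
                     paste(.IUCN_CATEGORIES, collapse = ", ")))
    return(unname(value_set$values[cat]))
  }
  if (startsWith(dd_policy, "fixed:")) {
    v <- suppressWarnings(as.numeric(sub("^fixed:", "", dd_policy)))
    if (is.na(v) || v < 0 || v > 1)
      pd_stop("fixed policy needs a probability in [0,1], e.g. 'fixed:0.07'")
    return(v)
  }
  pd_stop(paste0("unknown dd_policy '", dd_policy, "'; use 'weighted_mean', ",
                 "'as_category:<C>' or 'fixed:<v>'"))
}

#' Read a taxon status / probability table
#'
#' Two-column delimited text (tab or comma, auto-detected) with a header:
#' column `taxon` plus either `category` (IUCN codes) or `p` (direct
#' probabilities).  Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return a data frame with columns `taxon` and `category` or `p`.
#' @export
read_status_table <- function(path) {
  if (!file.exists(path))
    pd_stop(paste0("status file not found: ", path))
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(trimws(first), "#") & nzchar(trimws(first))]
  if (!length(first)) pd_stop(paste0("status file is empty: ", path))
  sep <- if (grepl("\t", first[1L])) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE, quote = "\"",
                           strip.white = TRUE)
  if (!"taxon" %in% names(tab) || !any(c("category", "p") %in% names(tab)))
    pd_stop("status table needs columns 'taxon' and 'category' (or 'p')")
  tab
}

#' Build an extinction map from a status file
#'
#' Convenience wrapper over [read_status_table()]: a `p` column is taken as
#' direct probabilities; a `category` column is mapped through the value
#' set with the given data-deficient policy.
#'
#' @inheritParams map_categories
#' @param path file path of the status table.
#' @return an [extinction_map()].
#' @export
extinction_map_from_file <- function(path,
                                     value_set = builtin_value_set("isaac"),
                                     dd_policy = "weighted_mean") {
  tab <- read_status_table(path)
  if ("p" %in% names(tab)) {
    return(extinction_map(setNames(as.numeric(tab$p),
                                   as.character(tab$taxon))))
  }
  map_categories(tab, value_set = value_set, dd_policy = dd_policy)
}

#' Combine score tables from several runs
#'
#' Per-taxon arithmetic mean of the numeric columns of several score tables
#' over identical taxon sets — e.g. to combine a run that treats
#' data-deficient taxa as near threatened with one that treats them as
#' vulnerable.  The component tables are retained in the `"components"`
#' attribute.
#'
#' @param tables a list of `score_table` data frames.
#' @return a `score_table` with the shared columns averaged.
#' @export
combine_runs <- function(tables) {
  if (!is.list(tables) || !length(tables) ||
      !all(vapply(tables, is.data.frame, logical(1))))
    pd_stop("combine_runs() expects a non-empty list of score tables")
  ref <- tables[[1L]]
  for (i in seq_along(tables)[-1L]) {
    if (!identical(tables[[i]]$taxon, ref$taxon))
      pd_stop(sprintf("table %d has a different taxon set/order", i))
  }
  cols <- Reduce(intersect, lapply(tables, names))
  num <- cols[vapply(ref[cols], is.numeric, logical(1))]
  out <- ref[c("taxon", num)]
  for (cl in num) {
    out[[cl]] <- Reduce(`+`, lapply(tables, function(tt) tt[[cl]])) /
      length(tables)
  }
  class(out) <- c("score_table", "data.frame")
  attr(out, "components") <- tables
  out
}
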