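#' Per-category cell counts and proportions of a merge result
#'
#' For each output category `t`, `count(t)` is the number of merged-output
#' nuclei of that category and `proportion(t) = count(t) / sum(count)`. All
#' assignable schema categories are included, zero counts with proportion 0.
#' An empty merge result yields total 0 with proportions flagged undefined
#' (`NA`, with an `undefined` attribute) rather than silent `NaN`s.
#'
#' @param result A `merge_result` (or a data frame with a `type` column).
#' @param schema A `type_schema` providing the category universe; defaults
#'   to [default_type_schema()].
#' @return An object of class `proportion_table`: data frame with columns
#'   `category`, `count`, `proportion`; attributes `total` and `undefined`.
#' @export
compute_proportions <- function(result, schema = default_type_schema()) {
  types <- if (inherits(result, "merge_result")) result$nuclei$type
           else result$type
  categories <- schema_categories(schema)
  extra <- setdiff(unique(types), categories)
  categories <- c(categories, extra)  # tolerate ad-hoc categories
  counts <- as.integer(table(factor(types, levels = categories)))
  total <- sum(counts)
  prop <- if (total > 0L) counts / total else rep(NA_real_, length(counts))
  tab <- data.frame(category = categories, count = counts, proportion = prop,
                    stringsAsFactors = FALSE)
  structure(tab, total = total, undefined = total == 0L,
            class = c("proportion_table", "data.frame"))
}

#' @export
print.proportion_table <- function(x, ...) {
  cat("<proportion_table> total = ", attr(x, "total"), " nuclei\n", sep = "")
  if (isTRUE(attr(x, "undefined"))) {
    cat("  proportions undefined (no nuclei)\n")
  }
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Aggregate a proportion table to top-level categories
#'
#' Re-expresses counts and proportions at each category's match level (its
#' depth-1 ancestor: epithelial, inflammatory, connective, dead under the
#' default schema), which puts tables from models with different
#' specificities on a common footing for comparison.
#'
#' @param table A `proportion_table`.
#' @param schema The `type_schema` the table was computed under.
#' @return A `proportion_table` over the depth-1 categories.
#' @export
aggregate_proportions <- function(table, schema = default_type_schema()) {
  lev <- vapply(table$category, function(nd) {
    if (nd %in% names(schema$parent)) depth1_ancestor(nd, schema$parent)
    else nd
  }, "")
  top <- unique(vapply(schema_categories(schema), function(nd)
    depth1_ancestor(nd, schema$parent), ""))
  counts <- vapply(top, function(tp) sum(table$count[lev == tp]), 0L)
  total <- sum(counts)
  prop <- if (total > 0L) counts / total else rep(NA_real_, length(counts))
  out <- data.frame(category = top, count = as.integer(counts),
                    proportion = prop, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(out, total = total, undefined = total == 0L,
            class = c("proportion_table", "data.frame"))
}

#' Total-variation distance between two proportion tables
#'
#' `0.5 * sum_t |p(t) - q(t)|` over the union of categories; a standard
#' summary of how far one cell-type composition is from another.
#'
#' @param p,q `proportion_table`s (or data frames with `category` and
#'   `proportion`).
#' @return Numeric in \[0, 1\].
#' @export
tv_distance <- function(p, q) {
  cats <- union(p$category, q$category)
  pv <- p$proportion[match(cats, p$category)]
  qv <- q$proportion[match(cats, q$category)]
  pv[is.na(pv)] <- 0
  qv[is.na(qv)] <- 0
  0.5 * sum(abs(pv - qv))
}
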