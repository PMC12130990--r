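# CSV dialect for all reports: comma-separated, UTF-8, header row, quoting
# only where needed (base write.csv/read.csv conventions).

#' Write the merge report
#'
#' Detail CSV with one row per output nucleus (`output_id`, `provenance`,
#' `category`, `source_m1`, `source_m2`, `x`, `y`, `prob`, `distance` for
#' paired rows, `equivocal`), plus a per-category summary CSV counting
#' outputs by provenance (merged / conflict / unmatched per source model),
#' written next to it.
#'
#' @param result A `merge_result`.
#' @param path Detail CSV path.
#' @param summary_path Summary CSV path; default replaces `.csv` with
#'   `_summary.csv`.
#' @return Invisibly, a manifest list with both paths and row counts.
#' @export
write_merge_report <- function(result, path,
                               summary_path = default_summary_path(path)) {
  stopifnot(inherits(result, "merge_result"))
  nuc <- result$nuclei
  detail <- data.frame(output_id = nuc$id, provenance = nuc$provenance,
                       category = nuc$type, source_m1 = nuc$source_m1,
                       source_m2 = nuc$source_m2, x = nuc$x, y = nuc$y,
                       prob = nuc$prob, distance = nuc$distance,
                       equivocal = nuc$equivocal, stringsAsFactors = FALSE)
  utils::write.csv(detail, path, row.names = FALSE, na = "")
  prov_levels <- c("merged", "conflict_m1", "conflict_m2",
                   "unmatched_m1", "unmatched_m2")
  cats <- sort(unique(nuc$type))
  tab <- table(factor(nuc$type, levels = cats),
               factor(nuc$provenance, levels = prov_levels))
  summary_df <- data.frame(category = cats,
                           as.data.frame.matrix(tab, row.names = NULL),
                           stringsAsFactors = FALSE)
  names(summary_df) <- c("category", prov_levels)
  summary_df$total <- as.integer(rowSums(tab))
  utils::write.csv(summary_df, summary_path, row.names = FALSE)
  invisible(list(detail = path, summary = summary_path,
                 n_detail = nrow(detail), n_categories = nrow(summary_df)))
}

default_summary_path <- function(path) {
  if (grepl("\\.csv$", path)) sub("\\.csv$", "_summary.csv", path)
  else paste0(path, "_summary.csv")
}

#' Write the equivocal-nuclei report
#'
#' One row per equivocal conflict -- overlapping nuclei typed differently by
#' the two models, both with probability strictly above the equivocal
#' threshold: centroid, both raw labels, both probabilities, the winning
#' model and label, and the pair distance. Intended as a decision-support
#' worklist for manual review.
#'
#' @param result A `merge_result`.
#' @param path Output CSV path.
#' @return Invisibly, a manifest list with the path and row count.
#' @export
write_equivocal_report <- function(result, path) {
  stopifnot(inherits(result, "merge_result"))
  utils::write.csv(result$equivocal, path, row.names = FALSE)
  invisible(list(path = path, n_rows = nrow(result$equivocal)))
}

#' Write a proportions CSV
#'
#' Columns `category`, `count`, `proportion` (9 decimal places), followed by
#' a `TOTAL` row carrying the overall nucleus count. With `percent = TRUE`
#' proportions are written as percentages (x100).
#'
#' @param table A `proportion_table`.
#' @param path Output CSV path.
#' @param percent Write proportions x100. Default `FALSE`.
#' @return Invisibly, a manifest list with the path and row count.
#' @export
write_proportions_csv <- function(table, path, percent = FALSE) {
  stopifnot(inherits(table, "proportion_table"))
  total <- attr(table, "total")
  scale <- if (percent) 100 else 1
  prop_chr <- ifelse(is.na(table$proportion), "",
                     sprintf("%.9f", table$proportion * scale))
  out <- data.frame(category = c(table$category, "TOTAL"),
                    count = c(table$count, total),
                    proportion = c(prop_chr,
                                   if (total > 0) sprintf("%.9f", 1 * scale)
                                   else ""),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(list(path = path, n_rows = nrow(out)))
}

#' Read back a proportions CSV
#'
#' Round-trip companion of [write_proportions_csv()].
#'
#' @param path CSV path.
#' @param percent Was the file written with `percent = TRUE`?
#' @return A `proportion_table`.
#' @export
read_proportions_csv <- function(path, percent = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  total_row <- df$category == "TOTAL"
  total <- if (any(total_row)) df$count[total_row][1] else sum(df$count)
  df <- df[!total_row, , drop = FALSE]
  scale <- if (percent) 100 else 1
  prop <- suppressWarnings(as.numeric(df$proportion)) / scale
  out <- data.frame(category = df$category, count = as.integer(df$count),
                    proportion = prop, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(out, total = as.integer(total), undefined = total == 0L,
            class = c("proportion_table", "data.frame"))
}
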