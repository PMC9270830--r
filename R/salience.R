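#' Per-citation salience score
#'
#' The contribution of a single citation to Smith's salience index: an item
#' recalled at position `rank` in a list of `list_length` items scores
#' `(L - r + 1) / L`, so the first-recalled item scores 1 and the last `1/L`.
#'
#' @param rank Recall position(s), 1-based.
#' @param list_length Length(s) of the containing list.
#' @return Numeric score(s) in `(0, 1]`.
#' @examples
#' informant_item_score(1, 5)  # 1.0
#' informant_item_score(5, 5)  # 0.2
#' @export
informant_item_score <- function(rank, list_length) {
  if (any(rank < 1) || any(rank > list_length))
    stop("rank must satisfy 1 <= rank <= list_length")
  (list_length - rank + 1) / list_length
}

#' Smith's cultural salience index
#'
#' For each item i, salience is the mean over all N lists of the per-citation
#' score [informant_item_score()], counting 0 for lists that do not cite the
#' item: `S_i = (1/N) * sum_j (L_j - r_ij + 1)/L_j`. Items that are both
#' frequently cited and recalled early score highest. Each (informant, group)
#' pair counts as one list; to analyse groups separately, subset first (see
#' [split_groups()]).
#'
#' @param x A [as_freelist()] object.
#' @return A data frame of class `"salience_table"` sorted by decreasing
#'   salience (ties broken by higher frequency, then item name), with columns
#'   `rank` (salience rank, 1 = most salient), `item`, `frequency` (number of
#'   lists citing the item) and `salience`. The [freelist_summary()] of the
#'   source data is attached as attribute `"summary"`.
#' @export
compute_salience <- function(x) {
  x <- as_freelist(x)
  if (nrow(x) == 0L) stop("empty dataset: no citations to score")
  key <- paste(x$informant, x$group, sep = "\r")
  L <- stats::ave(x$rank, key, FUN = length)
  score <- (L - x$rank + 1) / L
  n <- length(unique(key))
  agg <- rowsum(score, x$item)
  items <- rownames(agg)
  freq <- as.integer(rowsum(rep(1L, nrow(x)), x$item))
  sal <- as.vector(agg) / n
  ord <- order(-sal, -freq, items, method = "radix")
  out <- data.frame(rank = seq_along(ord), item = items[ord],
                    frequency = freq[ord], salience = sal[ord],
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- freelist_summary(x)
  class(out) <- c("salience_table", "data.frame")
  out
}

#' Write a salience table to TSV
#'
#' Columns `rank,item,frequency,salience,p_value,label` (the last three only
#' if present), numeric columns in 6-decimal fixed format.
#'
#' @param table A `salience_table`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_salience_table <- function(table, file) {
  out <- as.data.frame(table)
  for (col in intersect(c("salience", "p_value"), names(out)))
    out[[col]] <- sprintf("%.6f", out[[col]])
  utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(file)
}

#' Extract the structural-core item names from a classified table
#'
#' @param table A `salience_table` labelled by [classify_core()].
#' @return Character vector of core items in salience order.
#' @export
core_items <- function(table) {
  if (is.null(table$label)) stop("table has no core/satellite labels")
  table$item[table$label == "core"]
}
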