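#' Validate and construct a free-list dataset
#'
#' A free list records, for one informant, the items (here: medicinal plants)
#' recalled in answer to a single open prompt, in order of recall. A free-list
#' dataset is a long-format table with one row per citation and columns
#' `informant`, `group`, `rank`, `item`. `rank` is 1-based recall order:
#' within each (informant, group) list the ranks must be exactly `1..L` with
#' no gaps or duplicates, and an item may be cited at most once per list.
#' The same informant id may appear in several groups (e.g. the same person
#' interviewed in two periods); each (informant, group) pair is one list.
#'
#' @param x A data frame with columns `informant`, `group`, `rank`, `item`
#'   (extra columns are dropped).
#' @return The validated data frame with class `"freelist"`, rows ordered by
#'   group, informant and rank.
#' @examples
#' fl <- as_freelist(data.frame(
#'   informant = c("i1", "i1", "i2"), group = "g",
#'   rank = c(1, 2, 1), item = c("ameixa", "hortelã", "hortelã")))
#' freelist_summary(fl)
#' @export
as_freelist <- function(x) {
  if (inherits(x, "freelist")) return(x)
  if (!is.data.frame(x)) stop("`x` must be a data frame")
  need <- c("informant", "group", "rank", "item")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  x <- as.data.frame(x)[need]
  if (nrow(x) == 0L) stop("free-list dataset is empty")
  x$informant <- as.character(x$informant)
  x$group <- as.character(x$group)
  x$item <- as.character(x$item)
  if (any(is.na(x$informant)) || any(is.na(x$group)) || any(is.na(x$item)) ||
      any(!nzchar(x$item)))
    stop("informant, group and item must be non-missing")
  rk <- x$rank
  if (any(is.na(rk)) || any(rk < 1) || any(rk != round(rk)))
    stop("ranks must be positive integers")
  x$rank <- as.integer(rk)

  key <- paste(x$informant, x$group, sep = "\r")
  for (k in unique(key)) {
    rows <- x[key == k, ]
    who <- sprintf("informant '%s' (group '%s')", rows$informant[1], rows$group[1])
    dup <- rows$item[duplicated(rows$item)]
    if (length(dup))
      stop("duplicate item for ", who, ": ", paste(unique(dup), collapse = ", "))
    L <- nrow(rows)
    missing_ranks <- setdiff(seq_len(max(rows$rank)), rows$rank)
    if (length(missing_ranks) || max(rows$rank) != L)
      stop("rank gap for ", who, ": ranks must be 1..", L,
           if (length(missing_ranks))
             paste0(", missing ", paste(missing_ranks, collapse = ", ")))
  }
  x <- x[order(x$group, x$informant, x$rank, method = "radix"), ]
  rownames(x) <- NULL
  class(x) <- c("freelist", "data.frame")
  x
}

#' Read free-list interview data from a delimited text file
#'
#' Reads the canonical long format (`informant,group,rank,item`, header
#' required; a `column_map` can rename nonstandard headers) or a wide format
#' with one row per informant (`informant`, optionally `group`, then one
#' column per recall position, left to right; empty cells end the list).
#'
#' @param file Path to a UTF-8 CSV file (or a connection).
#' @param column_map Optional named character vector mapping the standard
#'   names to the file's headers, e.g. `c(informant = "ID", item = "plant")`.
#' @param format `"long"` (default) or `"wide"`.
#' @param group For wide files without a group column, the group label to
#'   assign to every list (default `"all"`).
#' @return A [as_freelist()] object.
#' @export
read_freelists <- function(file, column_map = NULL, format = c("long", "wide"),
                           group = "all") {
  format <- match.arg(format)
  x <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE,
                       fileEncoding = "UTF-8")
  if (nrow(x) == 0L) stop("empty file: no free-list records in ", file)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      j <- match(column_map[[std]], names(x))
      if (is.na(j)) stop("column '", column_map[[std]], "' not found")
      names(x)[j] <- std
    }
  }
  if (format == "wide") {
    if (!"informant" %in% names(x)) stop("wide format needs an 'informant' column")
    has_group <- "group" %in% names(x)
    item_cols <- setdiff(names(x), c("informant", "group"))
    if (!length(item_cols)) stop("wide format has no item columns")
    recs <- lapply(seq_len(nrow(x)), function(i) {
      items <- as.character(unlist(x[i, item_cols], use.names = FALSE))
      items <- items[!is.na(items) & nzchar(trimws(items))]
      if (!length(items)) return(NULL)
      data.frame(informant = x$informant[i],
                 group = if (has_group) x$group[i] else group,
                 rank = seq_along(items), item = items,
                 stringsAsFactors = FALSE)
    })
    x <- do.call(rbind, recs)
    if (is.null(x)) stop("empty file: all lists are empty")
  }
  as_freelist(x)
}

#' Write a free-list dataset to CSV
#'
#' @param x A [as_freelist()] object.
#' @param file Output path; written as UTF-8 CSV with header
#'   `informant,group,rank,item`.
#' @return `file`, invisibly.
#' @export
write_freelists <- function(x, file) {
  x <- as_freelist(x)
  utils::write.csv(as.data.frame(x)[c("informant", "group", "rank", "item")],
                   file, row.names = FALSE, fileEncoding = "UTF-8", quote = TRUE)
  invisible(file)
}

# lower-case, trim, collapse internal whitespace; diacritics untouched
.canon_name <- function(s) {
  s <- tolower(trimws(s))
  gsub("[[:space:]]+", " ", s)
}

#' Canonicalize item names and merge synonyms
#'
#' Item names are lower-cased, trimmed and internal whitespace collapsed
#' (diacritics preserved); an optional synonym map then merges spelling
#' variants. If merging creates a duplicate within a list, the earliest rank
#' is kept and later ranks are renumbered so each list stays `1..L`.
#'
#' @param x A [as_freelist()] object.
#' @param synonym_map Optional two-column data frame `variant,canonical`
#'   (or a named character vector `variant = canonical`). Chains are resolved
#'   transitively; a cycle is an error.
#' @return A canonicalized `freelist`.
#' @export
canonicalize_items <- function(x, synonym_map = NULL) {
  x <- as_freelist(x)
  x$item <- .canon_name(x$item)
  if (!is.null(synonym_map)) {
    if (is.data.frame(synonym_map)) {
      map <- stats::setNames(.canon_name(synonym_map[[2]]),
                             .canon_name(synonym_map[[1]]))
    } else {
      map <- stats::setNames(.canon_name(synonym_map), .canon_name(names(synonym_map)))
    }
    resolve <- function(nm) {
      seen <- character()
      while (nm %in% names(map)) {
        if (nm %in% seen) stop("synonym cycle involving '", nm, "'")
        seen <- c(seen, nm)
        nm <- map[[nm]]
      }
      nm
    }
    for (nm in names(map)) resolve(nm)  # reject cyclic maps up front
    x$item <- vapply(x$item, resolve, character(1), USE.NAMES = FALSE)
  }
  # merging may create within-list duplicates: keep earliest rank, renumber
  key <- paste(x$informant, x$group, sep = "\r")
  keep <- !duplicated(cbind(key, x$item))
  x <- x[keep, ]
  x$rank <- stats::ave(x$rank, key[keep], FUN = function(r) rank(r))
  x$rank <- as.integer(x$rank)
  as_freelist(as.data.frame(x))
}

#' Summarize a free-list dataset
#'
#' The three quantities that parameterize the null scenario for the salience
#' threshold: the number of lists N, the item-pool size M (distinct names),
#' and the list lengths (whose mean is the average citations per informant).
#'
#' @param x A [as_freelist()] object.
#' @return An object of class `"freelist_summary"`: a list with
#'   `n_informants`, `n_items`, `list_lengths` (integer vector, one per list)
#'   and `mean_list_length`.
#' @export
freelist_summary <- function(x) {
  x <- as_freelist(x)
  key <- paste(x$informant, x$group, sep = "\r")
  lens <- as.integer(table(key))
  structure(list(n_informants = length(lens),
                 n_items = length(unique(x$item)),
                 list_lengths = sort(lens),
                 mean_list_length = mean(lens)),
            class = "freelist_summary")
}

#' @export
print.freelist_summary <- function(x, ...) {
  cat("Free-list summary: N =", x$n_informants, "lists, M =", x$n_items,
      "distinct items, mean list length", round(x$mean_list_length, 2), "\n")
  invisible(x)
}

#' Split a free-list dataset by group label
#'
#' @param x A [as_freelist()] object.
#' @return A named list of single-group `freelist` objects.
#' @export
split_groups <- function(x) {
  x <- as_freelist(x)
  lapply(split(as.data.frame(x), x$group), as_freelist)
}
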