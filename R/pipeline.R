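#' End-to-end structural-core comparison of two groups
#'
#' Runs the whole analysis chain on a two-group free-list dataset:
#' canonicalize names, compute Smith's salience per group, apply the
#' null-model salience threshold, classify each group's structural core,
#' build the presence/absence matrix over the union of the two cores, and
#' test compositional similarity with Jaccard + PERMANOVA + dispersion
#' homogeneity + PCoA. Stage seeds (null model per group, permutation
#' tests) are derived deterministically from `seed`, so the full report is
#' reproducible from inputs + seed.
#'
#' @param x A [as_freelist()] object with exactly two groups (or a path to a
#'   long-format CSV, see [read_freelists()]).
#' @param alpha Decision level of the salience threshold.
#' @param n_null Null-model runs per group (default 1000).
#' @param n_permutations Label permutations for PERMANOVA and the
#'   dispersion test (default 999).
#' @param seed Master seed.
#' @param length_model See [null_model_config()].
#' @param synonym_map Optional synonym map for [canonicalize_items()].
#' @param out_dir Optional directory; if given, [write_report()] is called.
#' @param verbose If `TRUE`, log each stage with row/item counts.
#' @return A list of class `"core_comparison"`: per-group classified
#'   salience tables (`salience`), `core_sizes`, `core_union`, the
#'   composition `matrix` (with `dropped_rows`), `permanova`, `dispersion`,
#'   `pcoa`, and `config` (echo of all settings plus package version).
#' @export
run_comparison <- function(x, alpha = 0.05, n_null = 1000,
                           n_permutations = 999, seed = 1,
                           length_model = "resample_observed",
                           synonym_map = NULL, out_dir = NULL,
                           verbose = FALSE) {
  if (is.character(x) && length(x) == 1L) x <- read_freelists(x)
  x <- canonicalize_items(x, synonym_map)
  say <- function(...) if (verbose) message("[ethnocore] ", ...)
  grps <- split_groups(x)
  if (length(grps) != 2L)
    stop("two groups required, found ", length(grps), ": ",
         paste(names(grps), collapse = ", "))
  say("read ", nrow(x), " citations in ", length(grps), " groups")

  salience <- vector("list", 2L)
  names(salience) <- names(grps)
  for (g in 1:2) {
    cfg <- null_model_config(n_runs = n_null, alpha = alpha,
                             seed = .substream_seed(seed, 10000 + g),
                             length_model = length_model)
    salience[[g]] <- salience_threshold(grps[[g]], cfg)
    say("group '", names(grps)[g], "': ",
        attr(salience[[g]], "summary")$n_informants, " lists, ",
        nrow(salience[[g]]), " items, core size ",
        attr(salience[[g]], "core_size"))
  }
  cores <- lapply(salience, core_items)
  core_union <- c(cores[[1]], setdiff(cores[[2]], cores[[1]]))
  if (length(core_union) == 0L)
    stop("no columns to compare: both structural cores are empty")

  m <- core_matrix(x, core_union)
  say("composition matrix: ", nrow(m), " rows x ", ncol(m), " core plants (",
      length(attr(m, "dropped_rows")), " rows dropped)")
  d <- jaccard_distances(m)
  pm <- permanova(d, attr(m, "groups"), n_permutations,
                  seed = .substream_seed(seed, 20001))
  disp <- beta_dispersion(d, attr(m, "groups"), n_permutations,
                          seed = .substream_seed(seed, 20002))
  pc <- pcoa(d)
  say("PERMANOVA pseudo-F = ", round(pm$pseudo_f, 3), ", p = ", pm$p_perm)

  report <- structure(list(
    salience = salience,
    core_sizes = vapply(salience, attr, integer(1), which = "core_size"),
    core_union = core_union,
    matrix = m,
    dropped_rows = attr(m, "dropped_rows"),
    permanova = pm, dispersion = disp, pcoa = pc,
    config = list(alpha = alpha, n_null = n_null,
                  n_permutations = n_permutations, seed = seed,
                  length_model = length_model,
                  version = as.character(utils::packageVersion("ethnocore")))),
    class = "core_comparison")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Comparison stages only, from a pre-built presence/absence matrix
#'
#' Entry point for matrices built elsewhere (e.g. deposited supplementary
#' data): skips the salience stages and runs Jaccard, PERMANOVA, the
#' dispersion test and PCoA. All-zero rows are dropped first (idempotent if
#' the matrix already excludes them).
#'
#' @param m A binary matrix with rownames, or a path to a CSV read by
#'   [read_core_matrix()].
#' @param groups Group labels aligned to rows; defaults to the matrix's
#'   `groups` attribute, else the suffix after the last `:` in rownames.
#' @inheritParams run_comparison
#' @return A `"core_comparison"` report (salience fields `NULL`).
#' @export
run_matrix_comparison <- function(m, groups = NULL, n_permutations = 999,
                                  seed = 1, out_dir = NULL) {
  if (is.character(m) && length(m) == 1L) m <- read_core_matrix(m)
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1))) stop("non-binary cells in composition matrix")
  if (is.null(groups)) groups <- attr(m, "groups")
  if (is.null(groups)) {
    if (is.null(rownames(m)) || !all(grepl(":", rownames(m))))
      stop("supply `groups` or rownames of the form informant:group")
    groups <- sub("^.*:", "", rownames(m))
  }
  keep <- rowSums(m) > 0
  dropped <- rownames(m)[!keep]
  m2 <- m[keep, , drop = FALSE]
  groups <- factor(groups[keep])
  attr(m2, "groups") <- groups
  attr(m2, "dropped_rows") <- dropped
  d <- jaccard_distances(m2)
  pm <- permanova(d, groups, n_permutations, seed = .substream_seed(seed, 20001))
  disp <- beta_dispersion(d, groups, n_permutations,
                          seed = .substream_seed(seed, 20002))
  pc <- pcoa(d)
  report <- structure(list(
    salience = NULL, core_sizes = NULL, core_union = colnames(m2),
    matrix = m2, dropped_rows = dropped,
    permanova = pm, dispersion = disp, pcoa = pc,
    config = list(n_permutations = n_permutations, seed = seed,
                  version = as.character(utils::packageVersion("ethnocore")))),
    class = "core_comparison")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Read a presence/absence composition matrix from CSV
#'
#' Expected dialect: header row, first column `row_id` (typically
#' `informant:group`), remaining columns plant names, cells 0/1. A column
#' named `group` (if present) is split off as the group labels.
#'
#' @param file Path to the CSV file.
#' @return An integer matrix with a `groups` attribute when recoverable.
#' @export
read_core_matrix <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE,
                       fileEncoding = "UTF-8")
  if (ncol(x) < 2L) stop("matrix CSV needs a row_id column and plant columns")
  rid <- as.character(x[[1]])
  x <- x[-1]
  grp <- NULL
  if ("group" %in% names(x)) {
    grp <- as.character(x[["group"]])
    x <- x[setdiff(names(x), "group")]
  }
  m <- as.matrix(x)
  if (!all(m %in% c(0, 1))) stop("non-binary cells in composition matrix")
  storage.mode(m) <- "integer"
  rownames(m) <- rid
  if (is.null(grp) && all(grepl(":", rid))) grp <- sub("^.*:", "", rid)
  if (!is.null(grp)) attr(m, "groups") <- factor(grp)
  m
}

#' Write a composition matrix to CSV
#'
#' @param m A matrix from [core_matrix()] or [read_core_matrix()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_core_matrix <- function(m, file) {
  out <- data.frame(row_id = rownames(m), as.data.frame(unclass(m)),
                    check.names = FALSE)
  utils::write.csv(out, file, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(file)
}

#' @export
print.core_comparison <- function(x, ...) {
  cat("Structural-core comparison\n")
  if (!is.null(x$core_sizes)) {
    for (g in names(x$core_sizes))
      cat(sprintf("  core size (%s): %d\n", g, x$core_sizes[[g]]))
  }
  cat(sprintf("  core union: %d plants; %d retained rows (%d dropped)\n",
              length(x$core_union), nrow(x$matrix), length(x$dropped_rows)))
  print(x$permanova)
  print(x$dispersion)
  invisible(x)
}

.report_list <- function(report) {
  pm <- report$permanova
  out <- list(
    core_sizes = as.list(report$core_sizes),
    core_union = report$core_union,
    n_rows = nrow(report$matrix),
    dropped_rows = report$dropped_rows,
    permanova = pm[c("df_between", "df_within", "ss_between", "ss_within",
                     "ss_total", "ms_between", "ms_within", "pseudo_f",
                     "r_squared", "p_perm", "n_permutations", "exact",
                     "seed")],
    dispersion = list(group_means = as.list(report$dispersion$group_means),
                      f = report$dispersion$f,
                      p_perm = report$dispersion$p_perm),
    pcoa = list(eigenvalues = report$pcoa$eigenvalues,
                prop_explained = report$pcoa$prop_explained),
    config = report$config)
  if (!is.null(report$salience)) {
    out$salience <- lapply(report$salience, function(tab)
      as.data.frame(tab)[c("rank", "item", "frequency", "salience",
                           "p_value", "side", "label")])
  }
  out
}

#' Write a comparison report to disk
#'
#' Writes `report.json` (all statistics, full precision), `report.md`
#' (human-readable tables) and `ordination.svg` into `dir`. Output is
#' deterministic: the same report yields byte-identical files.
#'
#' @param report A `"core_comparison"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- jsonlite::toJSON(.report_list(report), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, null = "null")
  writeLines(json, file.path(dir, "report.json"), useBytes = TRUE)

  pm <- report$permanova
  md <- c("# Structural-core comparison report", "",
          if (!is.null(report$core_sizes))
            c(sprintf("- Core size (%s): %d", names(report$core_sizes),
                      report$core_sizes), ""),
          sprintf("- Core union: %d plants; %d rows retained, %d dropped",
                  length(report$core_union), nrow(report$matrix),
                  length(report$dropped_rows)), "",
          "## PERMANOVA", "",
          "| | Df | SumOfSqs | MeanSqs | pseudo-F | R2 | p |",
          "|---|---|---|---|---|---|---|",
          sprintf("| Groups | %d | %.5f | %.5f | %.4f | %.5f | %.4g |",
                  pm$df_between, pm$ss_between, pm$ms_between, pm$pseudo_f,
                  pm$r_squared, pm$p_perm),
          sprintf("| Residuals | %d | %.5f | %.5f | | %.5f | |",
                  pm$df_within, pm$ss_within, pm$ms_within,
                  1 - pm$r_squared),
          sprintf("| Total | %d | %.5f | | | 1 | |",
                  pm$df_between + pm$df_within, pm$ss_total), "",
          "## Dispersion homogeneity", "",
          sprintf("- Group mean distances to centroid: %s",
                  paste(sprintf("%s = %.4f", names(report$dispersion$group_means),
                                report$dispersion$group_means),
                        collapse = ", ")),
          sprintf("- F = %.4f, permutation p = %.4g", report$dispersion$f,
                  report$dispersion$p_perm))
  writeLines(md, file.path(dir, "report.md"), useBytes = TRUE)

  if (ncol(report$pcoa$coordinates) >= 2)
    plot_ordination(report$pcoa, attr(report$matrix, "groups"),
                    file = file.path(dir, "ordination.svg"))
  invisible(dir)
}
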