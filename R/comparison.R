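#' Binary core-plant composition matrix
#'
#' Builds the participants x core-plants presence/absence matrix used to
#' compare structural-core composition between groups: one row per
#' (informant, group) list, one column per plant of the supplied core union,
#' cell 1 if that list cites the plant. Rows citing none of the core plants
#' are removed (Jaccard dissimilarity is undefined between empty sets) and
#' reported in the `dropped_rows` attribute.
#'
#' @param x A [as_freelist()] object holding all compared groups.
#' @param core_union Ordered character vector of core plant names (typically
#'   the union of the groups' structural cores).
#' @return An integer 0/1 matrix with rownames `informant:group`, and
#'   attributes `groups` (factor aligned to rows) and `dropped_rows`
#'   (character vector of removed row ids).
#' @export
core_matrix <- function(x, core_union) {
  x <- as_freelist(x)
  core_union <- unique(as.character(core_union))
  if (length(core_union) == 0L || !any(nzchar(core_union)))
    stop("empty core: no plants to compare")
  ids <- unique(data.frame(informant = x$informant, group = x$group,
                           stringsAsFactors = FALSE))
  rid <- paste(ids$informant, ids$group, sep = ":")
  m <- matrix(0L, nrow = nrow(ids), ncol = length(core_union),
              dimnames = list(rid, core_union))
  hit <- x$item %in% core_union
  if (any(hit)) {
    ri <- match(paste(x$informant[hit], x$group[hit], sep = ":"), rid)
    ci <- match(x$item[hit], core_union)
    m[cbind(ri, ci)] <- 1L
  }
  keep <- rowSums(m) > 0
  dropped <- rid[!keep]
  m <- m[keep, , drop = FALSE]
  grp <- factor(ids$group[keep])
  if (nrow(m) < 2L || any(table(grp) < 2L))
    stop("need at least 2 non-empty rows per group after dropping ",
         "informants citing no core plant")
  attr(m, "groups") <- grp
  attr(m, "dropped_rows") <- dropped
  m
}

#' Jaccard dissimilarities between presence/absence rows
#'
#' Binary Jaccard dissimilarity `(b + c) / (a + b + c)` for every pair of
#' rows, where `a` counts shared presences and `b`, `c` the presences unique
#' to each row. Computed with [vegan::vegdist()] (`method = "jaccard",
#' binary = TRUE`).
#'
#' @param m A binary matrix with no all-zero rows (see [core_matrix()]).
#' @return A [stats::dist] object with values in `[0, 1]`.
#' @export
jaccard_distances <- function(m) {
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1))) stop("matrix must be binary 0/1")
  if (any(rowSums(m) == 0))
    stop("all-zero row(s): drop informants citing no core plant first")
  d <- vegan::vegdist(m, method = "jaccard", binary = TRUE)
  if (!is.null(attr(m, "groups"))) attr(d, "groups") <- attr(m, "groups")
  d
}

.check_dist_groups <- function(d, groups) {
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-8))
    stop("distance matrix must be square and symmetric")
  groups <- factor(groups)
  if (length(groups) != nrow(dm))
    stop("length of group labels (", length(groups),
         ") does not match distance matrix size (", nrow(dm), ")")
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 rows")
  list(dm = dm, groups = groups)
}

# F statistic from squared distances and integer group codes
.permanova_f <- function(D2, codes, nlev, df1, df2, ss_total) {
  within <- 0
  for (g in seq_len(nlev)) {
    i <- which(codes == g)
    within <- within + sum(D2[i, i]) / (2 * length(i))
  }
  between <- ss_total - within
  (between / df1) / (within / df2)
}

# all distinct permutations of a label vector (as integer codes)
.multiset_permutations <- function(codes) {
  rec <- function(remaining) {
    if (length(remaining) == 1L) return(list(remaining))
    out <- list()
    for (v in unique(remaining)) {
      rest <- remaining[-match(v, remaining)]
      for (tail in rec(rest)) out[[length(out) + 1L]] <- c(v, tail)
    }
    out
  }
  rec(sort(codes))
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the total sum of squared inter-point dissimilarities into
#' between- and within-group components:
#' `SS_total = (1/n) * sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) * sum_{i<j in g} d_ij^2`,
#' `SS_between = SS_total - SS_within`, with
#' `pseudo-F = (SS_between/(a-1)) / (SS_within/(n-a))` and
#' `R^2 = SS_between/SS_total` for `a` groups. Significance is assessed by
#' permuting group labels: `p = (1 + #{F* >= F}) / (1 + n_permutations)`.
#' When the number of distinct relabelings does not exceed
#' `n_permutations`, all of them are enumerated and the exact permutation
#' p-value is reported instead.
#'
#' @param d A [stats::dist] or square symmetric dissimilarity matrix.
#' @param groups Group labels aligned to the rows of `d` (at least 2 groups,
#'   each with at least 2 rows). Defaults to the `groups` attribute of `d`'s
#'   source matrix if present.
#' @param n_permutations Number of random label permutations (default 999,
#'   so the smallest reportable non-exact p is 0.001).
#' @param seed Integer seed for the permutation stream.
#' @return A list of class `"permanova"` with the decomposition
#'   (`df_between`, `df_within`, `ss_between`, `ss_within`, `ss_total`,
#'   `ms_between`, `ms_within`, `pseudo_f`, `r_squared`), `p_perm`,
#'   `n_permutations` actually used, `exact` (logical: exhaustive
#'   enumeration), and `seed`.
#' @export
permanova <- function(d, groups = attr(d, "groups"), n_permutations = 999,
                      seed = 1) {
  ck <- .check_dist_groups(d, groups)
  dm <- ck$dm
  groups <- ck$groups
  n <- nrow(dm)
  a <- nlevels(groups)
  D2 <- dm^2
  ss_total <- sum(D2) / (2 * n)
  df1 <- a - 1L
  df2 <- n - a
  codes <- as.integer(groups)
  within <- 0
  for (g in seq_len(a)) {
    i <- which(codes == g)
    within <- within + sum(D2[i, i]) / (2 * length(i))
  }
  between <- ss_total - within
  f_obs <- (between / df1) / (within / df2)

  counts <- tabulate(codes)
  n_distinct <- round(exp(lfactorial(n) - sum(lfactorial(counts))))
  if (is.finite(n_distinct) && n_distinct <= n_permutations) {
    perms <- .multiset_permutations(codes)
    f_perm <- vapply(perms, function(p)
      .permanova_f(D2, p, a, df1, df2, ss_total), numeric(1))
    p_perm <- mean(f_perm >= f_obs - 1e-12)
    n_used <- length(perms)
    exact <- TRUE
  } else {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      f_b <- .permanova_f(D2, sample(codes), a, df1, df2, ss_total)
      if (f_b >= f_obs - 1e-12) hits <- hits + 1L
    }
    p_perm <- (1 + hits) / (1 + n_permutations)
    n_used <- n_permutations
    exact <- FALSE
  }
  structure(list(df_between = df1, df_within = df2,
                 ss_between = between, ss_within = within, ss_total = ss_total,
                 ms_between = between / df1, ms_within = within / df2,
                 pseudo_f = f_obs, r_squared = between / ss_total,
                 p_perm = p_perm, n_permutations = n_used, exact = exact,
                 seed = seed, groups = groups),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  tab <- data.frame(
    Df = c(x$df_between, x$df_within, x$df_between + x$df_within),
    SumOfSqs = c(x$ss_between, x$ss_within, x$ss_total),
    MeanSqs = c(x$ms_between, x$ms_within, NA),
    pseudo.F = c(x$pseudo_f, NA, NA),
    R2 = c(x$r_squared, 1 - x$r_squared, 1),
    p.value = c(x$p_perm, NA, NA),
    row.names = c("Groups", "Residuals", "Total"))
  cat("PERMANOVA (one factor,",
      if (x$exact) "exact," else "permutation,",
      x$n_permutations, "relabelings)\n")
  printed <- format(round(tab, 5))
  printed[as.matrix(is.na(tab))] <- ""
  print(printed)
  invisible(x)
}

# Gower-centered eigendecomposition of a distance matrix
.gower_eigen <- function(dm) {
  A <- -0.5 * dm^2
  rm <- rowMeans(A)
  G <- A - outer(rm, rep(1, ncol(A))) - outer(rep(1, nrow(A)), colMeans(A)) +
    mean(A)
  eigen((G + t(G)) / 2, symmetric = TRUE)
}

#' Homogeneity of multivariate dispersions
#'
#' Tests whether groups differ in their spread around their own centroids
#' (the multivariate analogue of Levene's test; differences in dispersion
#' can masquerade as location effects in PERMANOVA). Rows are embedded by
#' principal coordinates keeping all axes; each row's dispersion is its
#' distance to its group centroid, corrected for non-Euclidean input:
#' `z_i = sqrt(max(0, d+_i^2 - d-_i^2))` where `d+` and `d-` are distances
#' to the centroid on positive- and negative-eigenvalue axes. A one-way
#' ANOVA F on the `z_i` is assessed by permuting group labels.
#'
#' @inheritParams permanova
#' @return A list of class `"dispersion"` with `distances` (per-row `z_i`),
#'   `group_means`, `f`, `p_perm`, `n_permutations`, `seed`, `groups`.
#' @export
beta_dispersion <- function(d, groups = attr(d, "groups"),
                            n_permutations = 999, seed = 1) {
  ck <- .check_dist_groups(d, groups)
  dm <- ck$dm
  groups <- ck$groups
  n <- nrow(dm)
  e <- .gower_eigen(dm)
  tol <- max(abs(e$values)) * 1e-8
  pos <- e$values > tol
  neg <- e$values < -tol
  cp <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  cn <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-e$values[neg]), sum(neg))
  z <- numeric(n)
  for (lev in levels(groups)) {
    i <- which(groups == lev)
    centp <- colMeans(cp[i, , drop = FALSE])
    centn <- colMeans(cn[i, , drop = FALSE])
    d2p <- rowSums(sweep(cp[i, , drop = FALSE], 2, centp)^2)
    d2n <- rowSums(sweep(cn[i, , drop = FALSE], 2, centn)^2)
    z[i] <- sqrt(pmax(0, d2p - d2n))
  }
  anova_f <- function(z, g) {
    gm <- tapply(z, g, mean)
    ng <- tabulate(as.integer(g))
    ssb <- sum(ng * (gm - mean(z))^2)
    ssw <- sum((z - gm[as.integer(g)])^2)
    df1 <- nlevels(g) - 1L
    df2 <- length(z) - nlevels(g)
    if (ssw <= .Machine$double.eps * max(1, ssb)) {
      if (ssb <= .Machine$double.eps) return(0)
      return(Inf)
    }
    (ssb / df1) / (ssw / df2)
  }
  f_obs <- anova_f(z, groups)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_permutations)) {
    if (anova_f(z, groups[sample.int(n)]) >= f_obs - 1e-12) hits <- hits + 1L
  }
  structure(list(distances = stats::setNames(z, rownames(dm)),
                 group_means = tapply(z, groups, mean),
                 f = f_obs, p_perm = (1 + hits) / (1 + n_permutations),
                 n_permutations = n_permutations, seed = seed,
                 groups = groups),
            class = "dispersion")
}

#' @export
print.dispersion <- function(x, ...) {
  cat("Homogeneity of multivariate dispersions\n")
  cat("Group mean distances to centroid:\n")
  print(round(x$group_means, 4))
  cat(sprintf("F = %.4f, permutation p = %.4g (%d permutations)\n",
              x$f, x$p_perm, x$n_permutations))
  invisible(x)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-0.5 * D^2` (Gower centering) and eigendecomposes it.
#' Coordinates are returned for positive-eigenvalue axes only (eigenvectors
#' scaled by the square roots of their eigenvalues); negative eigenvalues —
#' which arise for non-Euclidean dissimilarities such as Jaccard — are
#' reported but excluded from the coordinates, and the proportion explained
#' is computed over the positive eigenvalues.
#'
#' @param d A [stats::dist] or square symmetric dissimilarity matrix.
#' @return A list of class `"pcoa"` with `coordinates` (rows x positive
#'   axes), `eigenvalues` (all, decreasing) and `prop_explained` (per
#'   positive axis).
#' @export
pcoa <- function(d) {
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-8))
    stop("distance matrix must be square and symmetric")
  e <- .gower_eigen(dm)
  tol <- max(abs(e$values)) * 1e-8
  pos <- e$values > tol
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = e$values,
                 prop_explained = e$values[pos] / sum(e$values[pos])),
            class = "pcoa")
}

#' Ordination scatter plot of the first two principal coordinates
#'
#' Plots axes 1-2 of a [pcoa()] result, coloured by group, with the
#' percentage of (positive-eigenvalue) variation on the axis labels. With
#' fewer than two positive axes a 1-D strip plot is drawn with a warning.
#'
#' @param pc A [pcoa()] result.
#' @param groups Group labels aligned to the embedded rows.
#' @param file Optional output path ending in `.svg` or `.png`; if `NULL`
#'   (default) the current graphics device is used.
#' @param palette Colours, one per group level.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_ordination <- function(pc, groups, file = NULL,
                            palette = c("#1b9e77", "#d95f02", "#7570b3",
                                        "#e7298a"), ...) {
  groups <- factor(groups)
  co <- pc$coordinates
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           svg = grDevices::svg(file, width = 6, height = 5),
           png = grDevices::png(file, width = 720, height = 600, res = 120),
           stop("unsupported plot format: ", ext))
    on.exit(grDevices::dev.off())
  }
  cols <- rep_len(palette, nlevels(groups))
  if (ncol(co) >= 2) {
    pct <- 100 * pc$prop_explained
    graphics::plot(co[, 1], co[, 2], col = cols[as.integer(groups)],
                   pch = as.integer(groups),
                   xlab = sprintf("PCoA 1 (%.1f%%)", pct[1]),
                   ylab = sprintf("PCoA 2 (%.1f%%)", pct[2]), ...)
    graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  } else {
    warning("fewer than 2 positive axes; drawing 1-D strip plot")
    graphics::stripchart(co[, 1] ~ groups, vertical = FALSE, method = "jitter",
                         col = cols, pch = seq_len(nlevels(groups)),
                         xlab = "PCoA 1", ...)
  }
  graphics::legend("topright", legend = levels(groups), col = cols,
                   pch = seq_len(nlevels(groups)), bty = "n")
  invisible(file)
}
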