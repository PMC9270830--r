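#' Configuration of the null-model salience threshold
#'
#' The salience threshold compares the observed salience ranking against
#' salience rankings computed on simulated free-list datasets drawn from a
#' null scenario matched to the field data: the same number of lists N, the
#' same item-pool size M, and the same average citations per list. Under the
#' null, every item is exchangeable: each list is a uniform random sample of
#' distinct items in uniform random order.
#'
#' @param n_runs Number of simulated null datasets (default 1000).
#' @param alpha Decision level for the core/satellite split (default 0.05).
#' @param seed Integer seed; per-run substreams are derived deterministically
#'   from it, so results do not depend on how runs are scheduled.
#' @param length_model How simulated list lengths are drawn:
#'   `"resample_observed"` (default) resamples the observed length multiset
#'   with replacement (preserving its mean and spread), `"fixed_mean"` gives
#'   every list the rounded observed mean length, `"poisson_mean"` draws
#'   Poisson lengths with the observed mean (clamped to `[1, M]`). All models
#'   cap lengths at M since items within a list are distinct.
#' @param correct_p If `TRUE`, report add-one corrected tail proportions
#'   `(b + 1)/(B + 1)` instead of raw `b/B`; default `FALSE`, so a value
#'   outside the whole null range reports p = 0.
#' @return A list of class `"null_model_config"`.
#' @export
null_model_config <- function(n_runs = 1000, alpha = 0.05, seed = 1,
                              length_model = c("resample_observed",
                                               "fixed_mean", "poisson_mean"),
                              correct_p = FALSE) {
  length_model <- match.arg(length_model)
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(n_runs = as.integer(n_runs), alpha = alpha,
                 seed = as.integer(seed), length_model = length_model,
                 correct_p = isTRUE(correct_p)),
            class = "null_model_config")
}

# deterministic 31-bit substream seed for run k of a master seed
.substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + as.numeric(k) * 104729) %%
               2147483647)
}

.length_sampler <- function(summary, length_model) {
  m <- summary$n_items
  switch(length_model,
    resample_observed = {
      pool <- pmin(summary$list_lengths, m)
      function(n) sample(pool, n, replace = TRUE)
    },
    fixed_mean = {
      len <- max(1L, round(summary$mean_list_length))
      if (len > m) stop("fixed mean list length ", len,
                        " exceeds item-pool size ", m)
      function(n) rep(len, n)
    },
    poisson_mean = {
      function(n) pmax(1L, pmin(m, stats::rpois(n, summary$mean_list_length)))
    })
}

# one null run: sorted (decreasing) salience vector of length M
.null_salience_run <- function(n_inf, m_items, draw_lengths) {
  len <- draw_lengths(n_inf)
  items <- unlist(lapply(len, function(l) sample.int(m_items, l)),
                  use.names = FALSE)
  score <- unlist(lapply(len, function(l) (l:1) / l), use.names = FALSE)
  sal <- numeric(m_items)
  agg <- rowsum(score, items)
  sal[as.integer(rownames(agg))] <- agg
  sort(sal, decreasing = TRUE) / n_inf
}

#' Simulate one free-list dataset from the null scenario
#'
#' Draws N lists matched to an observed [freelist_summary()]: list lengths
#' per `length_model`, items sampled uniformly without replacement from an
#' abstract pool of M labels, recall order uniform.
#'
#' @param summary A [freelist_summary()] of the observed data.
#' @param length_model See [null_model_config()].
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @param group_label Group label for the simulated lists.
#' @return A [as_freelist()] object with items `item001..itemM`.
#' @export
simulate_null_dataset <- function(summary, length_model = "resample_observed",
                                  seed = NULL, group_label = "null") {
  if (!inherits(summary, "freelist_summary")) stop("need a freelist_summary")
  if (!is.null(seed)) set.seed(seed)
  draw <- .length_sampler(summary, length_model)
  n <- summary$n_informants
  m <- summary$n_items
  len <- draw(n)
  labels <- sprintf("item%03d", seq_len(m))
  recs <- lapply(seq_len(n), function(j) {
    items <- labels[sample.int(m, len[j])]
    data.frame(informant = sprintf("sim%03d", j), group = group_label,
               rank = seq_along(items), item = items, stringsAsFactors = FALSE)
  })
  as_freelist(do.call(rbind, recs))
}

#' Null distribution of rank-ordered salience values
#'
#' Runs the null scenario `n_runs` times; in each run items' saliences are
#' sorted in decreasing order and the value at each salience rank
#' `k = 1..M` is recorded (ranks beyond a run's realized item count
#' contribute 0). The per-rank collections are the reference distribution
#' the observed ranking is tested against.
#'
#' @param summary A [freelist_summary()] of the observed data.
#' @param config A [null_model_config()].
#' @return An object of class `"null_salience_distribution"`: a list with
#'   `values` (M x n_runs matrix, row k = rank-k null saliences), `mean`
#'   (per-rank mean), `n_runs`, `summary` and `config`.
#' @export
null_salience_distribution <- function(summary, config = null_model_config()) {
  if (!inherits(summary, "freelist_summary")) stop("need a freelist_summary")
  if (!inherits(config, "null_model_config")) stop("need a null_model_config")
  n <- summary$n_informants
  m <- summary$n_items
  draw <- .length_sampler(summary, config$length_model)
  vals <- matrix(0, nrow = m, ncol = config$n_runs)
  for (b in seq_len(config$n_runs)) {
    set.seed(.substream_seed(config$seed, b))
    vals[, b] <- .null_salience_run(n, m, draw)
  }
  structure(list(values = vals, mean = rowMeans(vals), n_runs = config$n_runs,
                 summary = summary, config = config),
            class = "null_salience_distribution")
}

#' Rank-matched null-model p-values for an observed salience table
#'
#' Each observed salience `s_k` (at salience rank k) is compared with the
#' null values at the same rank: with upper tail `u = #{null >= s_k}/B` and
#' lower tail `l = #{null <= s_k}/B` (ties count in both tails), the reported
#' p-value is `min(u, l)`, and the item's `side` is `"prominent"` when `s_k`
#' exceeds the rank-k null mean, `"non-prominent"` otherwise. Down a typical
#' observed ranking the p-values are U-shaped: small at the salient head
#' (above the null), near 0.5 mid-list, and small again in the sparse tail
#' (below the null).
#'
#' @param observed A `salience_table` from [compute_salience()].
#' @param null A [null_salience_distribution()] built from the same
#'   [freelist_summary()].
#' @return The observed table with `p_value` and `side` columns added.
#' @export
salience_pvalues <- function(observed, null) {
  if (!inherits(null, "null_salience_distribution"))
    stop("need a null_salience_distribution")
  m <- nrow(observed)
  if (m != nrow(null$values))
    stop("rank mismatch: observed table has ", m,
         " items but the null distribution has ", nrow(null$values), " ranks")
  B <- ncol(null$values)
  correct <- isTRUE(null$config$correct_p)
  s <- observed$salience
  p <- numeric(m)
  side <- character(m)
  for (k in seq_len(m)) {
    u <- sum(null$values[k, ] >= s[k])
    l <- sum(null$values[k, ] <= s[k])
    b <- min(u, l)
    p[k] <- if (correct) (b + 1) / (B + 1) else b / B
    side[k] <- if (s[k] > null$mean[k]) "prominent" else "non-prominent"
  }
  observed$p_value <- p
  observed$side <- side
  observed
}

#' Split a salience ranking into structural core and satellites
#'
#' The structural core is the maximal prefix of the salience-ranked list
#' whose entries are all significantly *prominent*: p-value below `alpha`
#' and salience above the rank-matched null mean. The first entry failing
#' either condition ends the core; it and everything below it are satellites
#' (low-tail significance further down the list does not reopen the core).
#' Tables that carry only a `p_value` column (e.g. transcribed published
#' rankings) are classified on the p-value criterion alone.
#'
#' @param table A salience table with a `p_value` column, sorted by salience
#'   rank; a `side` column, if present, is honoured as described.
#' @param alpha Decision level in (0, 1), default 0.05.
#' @return The table with a `label` column (`"core"`/`"satellite"`) and the
#'   core size attached as attribute `"core_size"`.
#' @export
classify_core <- function(table, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.null(table$p_value)) stop("table has no p_value column; run salience_pvalues() first")
  if (is.unsorted(table$rank)) stop("table must be sorted by salience rank")
  ok <- table$p_value < alpha
  if (!is.null(table$side)) ok <- ok & table$side == "prominent"
  core_n <- if (all(ok)) length(ok) else which(!ok)[1] - 1L
  table$label <- rep("satellite", nrow(table))
  if (core_n > 0) table$label[seq_len(core_n)] <- "core"
  attr(table, "core_size") <- as.integer(core_n)
  table
}

#' Full salience-threshold analysis of one group
#'
#' Convenience wrapper: [compute_salience()], [null_salience_distribution()],
#' [salience_pvalues()] and [classify_core()] in sequence.
#'
#' @param x A single-group [as_freelist()] object.
#' @param config A [null_model_config()].
#' @return A classified `salience_table` (see [classify_core()]), with the
#'   null distribution attached as attribute `"null"`.
#' @export
salience_threshold <- function(x, config = null_model_config()) {
  tab <- compute_salience(x)
  nd <- null_salience_distribution(attr(tab, "summary"), config)
  tab <- classify_core(salience_pvalues(tab, nd), config$alpha)
  attr(tab, "null") <- nd
  tab
}
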