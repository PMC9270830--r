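#' Configuration for the synthetic free-list generator
#'
#' The generator emulates the statistical structure the salience threshold
#' is designed to detect: a planted core of items that are cited more often
#' (`p_core` vs `p_sat`) and recalled earlier (`recall_bias`) than the
#' satellite items. Each informant cites each item independently with its
#' citation probability; the recall order of the cited items is drawn by a
#' Plackett-Luce scheme in which core items carry weight `exp(recall_bias)`
#' and satellites weight 1, so `recall_bias = 0` gives uniform order.
#'
#' @param n_informants Number of informants N.
#' @param n_items Item-pool size M.
#' @param k_core Planted core size (`<= n_items`).
#' @param p_core,p_sat Per-informant citation probabilities of core and
#'   satellite items (`p_core >= p_sat`).
#' @param recall_bias Strength (>= 0) of core items' tendency to be recalled
#'   first.
#' @param min_list_length Minimum list length; an informant's citations are
#'   redrawn (up to 1000 attempts) until at least this many items are cited.
#' @param seed Integer seed.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_informants = 60, n_items = 50, k_core = 8,
                             p_core = 0.8, p_sat = 0.1, recall_bias = 2,
                             min_list_length = 1, seed = 1) {
  if (k_core > n_items) stop("k_core must not exceed n_items")
  if (p_core < p_sat) stop("p_core must be >= p_sat")
  if (min(p_core, p_sat) < 0 || max(p_core, p_sat) > 1)
    stop("citation probabilities must be in [0, 1]")
  if (recall_bias < 0) stop("recall_bias must be >= 0")
  if (min_list_length < 1) stop("min_list_length must be >= 1")
  structure(list(n_informants = as.integer(n_informants),
                 n_items = as.integer(n_items), k_core = as.integer(k_core),
                 p_core = p_core, p_sat = p_sat, recall_bias = recall_bias,
                 min_list_length = as.integer(min_list_length),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.item_labels <- function(m) sprintf("item%03d", seq_len(m))

# core-set-aware generator shared by the one- and two-group entry points;
# assumes the RNG state has been set by the caller
.generate_group <- function(config, core_idx, group_label) {
  m <- config$n_items
  labels <- .item_labels(m)
  p <- rep(config$p_sat, m)
  p[core_idx] <- config$p_core
  w <- rep(1, m)
  w[core_idx] <- exp(config$recall_bias)
  recs <- vector("list", config$n_informants)
  for (j in seq_len(config$n_informants)) {
    cited <- integer(0)
    for (try in seq_len(1000)) {
      cited <- which(stats::runif(m) < p)
      if (length(cited) >= config$min_list_length) break
    }
    if (length(cited) < config$min_list_length)
      stop("could not reach min_list_length = ", config$min_list_length,
           " in 1000 attempts; citation probabilities are too small")
    ord <- if (length(cited) == 1L) cited else sample(cited, prob = w[cited])
    recs[[j]] <- data.frame(informant = sprintf("%s_inf%03d", group_label, j),
                            group = group_label, rank = seq_along(ord),
                            item = labels[ord], stringsAsFactors = FALSE)
  }
  out <- as_freelist(do.call(rbind, recs))
  attr(out, "core_items") <- labels[core_idx]
  out
}

#' Generate one synthetic free-list dataset with a planted core
#'
#' @param config A [synthetic_config()].
#' @param group_label Group label assigned to all lists.
#' @return A [as_freelist()] object; the planted core item names are
#'   attached as attribute `"core_items"` and the configuration as
#'   `"config"`.
#' @export
simulate_freelists <- function(config = synthetic_config(),
                               group_label = "group1") {
  set.seed(config$seed)
  out <- .generate_group(config, seq_len(config$k_core), group_label)
  attr(out, "config") <- config
  out
}

#' Configuration for a two-group synthetic contrast
#'
#' @param base A [synthetic_config()] shared by both groups (its
#'   `n_informants` is overridden by `group_sizes`).
#' @param core_overlap Fraction in `[0, 1]` of planted core items shared
#'   between the two groups' cores; `round(core_overlap * k_core)` items are
#'   shared, the remainder of group 2's core is drawn disjointly from the
#'   satellite pool.
#' @param group_sizes Integer pair of informant counts.
#' @return A list of class `"two_group_config"`.
#' @export
two_group_config <- function(base = synthetic_config(), core_overlap = 1,
                             group_sizes = c(50, 50)) {
  if (core_overlap < 0 || core_overlap > 1)
    stop("core_overlap must be in [0, 1]")
  if (length(group_sizes) != 2L || any(group_sizes < 1))
    stop("group_sizes must be two positive integers")
  shared <- round(core_overlap * base$k_core)
  if (2 * base$k_core - shared > base$n_items)
    stop("item pool too small for two cores with this overlap")
  structure(list(base = base, core_overlap = core_overlap,
                 n_shared = as.integer(shared),
                 group_sizes = as.integer(group_sizes)),
            class = "two_group_config")
}

#' Generate two synthetic groups with controlled core overlap
#'
#' Group 1's core is items `1..k`; group 2 keeps the first
#' `round(core_overlap * k)` of them and replaces the rest with items drawn
#' from outside group 1's core, so both groups share one item pool but their
#' planted cores overlap exactly as configured.
#'
#' @param config A [two_group_config()].
#' @param group_labels Labels for the two groups.
#' @return A single [as_freelist()] object holding both groups, with
#'   attributes `core_items` (named list per group) and `config`.
#' @export
simulate_two_groups <- function(config = two_group_config(),
                                group_labels = c("group1", "group2")) {
  base <- config$base
  k <- base$k_core
  core1 <- seq_len(k)
  core2 <- c(seq_len(config$n_shared),
             k + seq_len(k - config$n_shared))
  set.seed(base$seed)
  cfg1 <- base; cfg1$n_informants <- config$group_sizes[1]
  cfg2 <- base; cfg2$n_informants <- config$group_sizes[2]
  g1 <- .generate_group(cfg1, core1, group_labels[1])
  g2 <- .generate_group(cfg2, core2, group_labels[2])
  out <- as_freelist(rbind(as.data.frame(g1), as.data.frame(g2)))
  cores <- list(attr(g1, "core_items"), attr(g2, "core_items"))
  names(cores) <- group_labels
  attr(out, "core_items") <- cores
  attr(out, "config") <- config
  out
}
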