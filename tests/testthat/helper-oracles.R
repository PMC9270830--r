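# Hand-rolled oracles and fixture builders, kept deliberately naive and
# independent of the package's vectorized implementations.

make_summary <- function(n, m, lengths) {
  structure(list(n_informants = as.integer(n), n_items = as.integer(m),
                 list_lengths = as.integer(lengths),
                 mean_list_length = mean(lengths)),
            class = "freelist_summary")
}

# double-loop Smith's salience: for every list and every cited item
oracle_salience <- function(fl) {
  fl <- as.data.frame(fl)
  key <- paste(fl$informant, fl$group, sep = "\r")
  keys <- unique(key)
  items <- sort(unique(fl$item))
  sal <- stats::setNames(numeric(length(items)), items)
  frq <- stats::setNames(integer(length(items)), items)
  for (k in keys) {
    rows <- fl[key == k, ]
    L <- nrow(rows)
    for (i in seq_len(L)) {
      it <- rows$item[i]
      sal[it] <- sal[it] + (L - rows$rank[i] + 1) / L
      frq[it] <- frq[it] + 1L
    }
  }
  list(salience = sal / length(keys), frequency = frq)
}

random_freelist <- function(n_inf = 10, m_items = 12, seed = 1,
                            max_len = 8, group = "g") {
  set.seed(seed)
  items <- sprintf("p%02d", seq_len(m_items))
  recs <- lapply(seq_len(n_inf), function(j) {
    L <- sample.int(min(m_items, max_len), 1)
    data.frame(informant = sprintf("inf%02d", j), group = group,
               rank = seq_len(L), item = sample(items, L),
               stringsAsFactors = FALSE)
  })
  as_freelist(do.call(rbind, recs))
}

# pairwise binary Jaccard by explicit a/b/c counting
oracle_jaccard <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- sum(m[i, ] == 1 & m[j, ] == 1)
    b <- sum(m[i, ] == 1 & m[j, ] == 0)
    cc <- sum(m[i, ] == 0 & m[j, ] == 1)
    d[i, j] <- if (a + b + cc == 0) 0 else (b + cc) / (a + b + cc)
  }
  d
}

# PERMANOVA decomposition via Gower centering and hat-matrix traces
# (McArdle-Anderson route), independent of the pairwise-sum formulas
oracle_permanova_gower <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  A <- -0.5 * dm^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C
  X <- stats::model.matrix(~ factor(groups))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  ss_between <- sum(diag(H %*% G))
  ss_total <- sum(diag(G))
  list(ss_total = ss_total, ss_between = ss_between,
       ss_within = ss_total - ss_between)
}

# exact permutation p by enumerating ALL n! index permutations
oracle_exact_permanova_p <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  g <- factor(groups)
  a <- nlevels(g)
  fstat <- function(codes) {
    D2 <- dm^2
    ss_total <- sum(D2) / (2 * n)
    within <- 0
    for (lev in seq_len(a)) {
      i <- which(codes == lev)
      within <- within + sum(D2[i, i]) / (2 * length(i))
    }
    ((ss_total - within) / (a - 1)) / (within / (n - a))
  }
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  codes <- as.integer(g)
  f_obs <- fstat(codes)
  f_all <- vapply(perms(seq_len(n)), function(ix) fstat(codes[ix]), numeric(1))
  mean(f_all >= f_obs - 1e-12)
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f, useBytes = TRUE)
  f
}
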