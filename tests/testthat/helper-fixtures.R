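# Shared fixtures and independent oracles for the test suite.

# a tiny hand-sized collection on the full seven-variable catalog
toy_collection <- function() {
  skeletal_collection(
    individual_id = c("a", "b", "c", "d"),
    population = "PT", sex = "M",
    age = c(22, 23, 41, 43),
    stages = data.frame(v1 = c(0L, 0L, 1L, 1L),
                        v2 = c(1L, 1L, 3L, 3L),
                        v3 = c(0L, NA, 2L, 2L),
                        v4 = c(0L, 0L, 2L, 2L),
                        v5 = c(0L, 0L, 0L, 1L),
                        v6 = c(0L, 0L, 1L, 2L),
                        v7 = c(0L, 0L, 2L, 2L))
  )
}

# random small reference setting for the brute-force oracle checks
random_small_setting <- function(seed) {
  set.seed(seed)
  n_classes <- sample(2:4, 1)
  n_vars <- sample(1:3, 1)
  ks <- sample(2:4, n_vars, replace = TRUE)
  catalog <- variable_catalog(stats::setNames(
    lapply(ks, function(k) c(0, k - 1)),
    paste0("v", seq_len(n_vars))))
  grid <- age_class_grid(15, 15 + 5 * n_classes - 1)
  n <- sample(5:40, 1)
  ages <- sample(15:(15 + 5 * n_classes - 1), n, replace = TRUE)
  stages <- as.data.frame(lapply(seq_len(n_vars), function(j) {
    s <- sample(0:(ks[j] - 1), n, replace = TRUE)
    s[stats::runif(n) < 0.15] <- NA_integer_
    s
  }))
  names(stages) <- names(catalog)
  records <- skeletal_collection(
    individual_id = paste0("r", seq_len(n)), population = "X", sex = "M",
    age = ages, stages = stages, catalog = catalog)
  profile <- stats::setNames(lapply(seq_len(n_vars), function(j) {
    if (stats::runif(1) < 0.2 && n_vars > 1) NA_integer_
    else sample(0:(ks[j] - 1), 1)
  }), names(catalog))
  if (all(is.na(unlist(profile)))) profile[[1]] <- 0L
  list(records = records, grid = grid, catalog = catalog, profile = profile)
}

# brute-force posterior: joint P(class) * prod P(stage | class) computed
# directly from the records, independent of the reference_table machinery
oracle_posterior <- function(records, grid, catalog, profile) {
  k <- nrow(grid)
  cls <- age_class_index(records$age, grid)
  mass <- numeric(k)
  for (c in seq_len(k)) {
    in_c <- cls == c
    m <- sum(in_c) / nrow(records)
    for (v in names(catalog)) {
      s <- profile[[v]]
      if (is.na(s)) next
      scored <- in_c & !is.na(records[[v]])
      m <- m * if (sum(scored) == 0) 0 else {
        sum(records[[v]][scored] == s) / sum(scored)
      }
    }
    mass[c] <- m
  }
  if (sum(mass) == 0) return(NULL)
  mass / sum(mass)
}

# full enumeration of the Wilcoxon signed-rank two-sided p over all 2^n
# sign assignments (zero differences already removed by the caller)
enumerate_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  grids <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  ws <- apply(grids, 1, function(pos) sum(r[unlist(pos)]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# full enumeration of the Mann-Whitney two-sided p over all choose(N, na)
# assignments of the pooled values to group a
enumerate_mann_whitney_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    aa <- pooled[idx]; bb <- pooled[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }
  u_obs <- u_of(seq_len(na))
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}
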