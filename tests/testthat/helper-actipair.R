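# shared fixtures, all built in code

t0 <- as.POSIXct("2013-04-01 00:00:00", tz = "UTC")

make_series <- function(values, unit = "counts", start = t0,
                        device = "dev") {
  epoch_series(values, start = start, unit = unit, device = device)
}

# noise-free, offset-free, gap-free study configuration; the only
# nonwear is the shared overnight block
noiseless_config <- function(n = 5, days = 3, seed = 7, ...) {
  cohort_config(n_participants = n, protocol_days = days,
                offset_range = c(0L, 0L),
                night_minutes_sd = 0,
                phone_nonwear_per_day = 0, ref_nonwear_per_day = 0,
                phone_gap_per_day = 0, ref_gap_per_day = 0,
                phone_noise = list(mult = 0, add = 0),
                ref_noise = list(mult = 0, add = 0),
                seed = seed, ...)
}

# independent arithmetic oracles, written from the defining formulas
# with explicit sums (no calls into the package)

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
}

oracle_adj_r2 <- function(x, y) {
  n <- length(x)
  r2 <- oracle_pearson(x, y)^2
  1 - (1 - r2) * (n - 1) / (n - 2)
}

oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# average ranks by explicit sorting, then Pearson of the ranks
oracle_rank <- function(v) {
  o <- order(v)
  r <- numeric(length(v))
  i <- 1
  while (i <= length(v)) {
    j <- i
    while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_rank(x), oracle_rank(y))
}

# tie-corrected Kruskal-Wallis H over a list of groups
oracle_kruskal_h <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- oracle_rank(x)
  idx <- rep(seq_along(groups), vapply(groups, length, 1L))
  H <- 12 / (N * (N + 1)) *
    sum(vapply(seq_along(groups), function(j)
      sum(r[idx == j])^2 / sum(idx == j), 1)) - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}
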