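# Independent oracles used to cross-check the implementation. These are
# deliberately naive (normal equations, double loops) and share no code
# with the package internals.

# Simple-regression estimates from the normal equations (X'X)^-1 X'y,
# with classical se, R^2 and two-tailed p for the slope.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  xtx_inv <- solve(t(X) %*% X)
  b <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% b
  n <- length(y)
  sigma2 <- sum(res^2) / (n - 2)
  se <- unname(sqrt(diag(xtx_inv) * sigma2))
  tval <- b[2] / se[2]
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = b[1], slope = b[2], se_slope = se[2],
       r2 = 1 - sum(res^2) / ss_tot,
       p_slope = 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE))
}

# Per-tile (ptree, mean LST) by an explicit double loop over tiles and
# pixels; mirrors the aggregation contract including the validity
# threshold and edge-tile discard.
brute_aggregate <- function(lst, cover, w, min_valid_fraction = 0.5) {
  nr <- nrow(lst) %/% w
  nc <- ncol(lst) %/% w
  rows <- list()
  unit_id <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      unit_id <- unit_id + 1L
      ri <- ((i - 1) * w + 1):(i * w)
      cj <- ((j - 1) * w + 1):(j * w)
      l <- lst[ri, cj]; c <- cover[ri, cj]
      ok <- !is.na(l) & !is.na(c)
      if (sum(ok) == 0 || sum(ok) / (w * w) < min_valid_fraction) next
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = unit_id, ptree_pct = 100 * mean(c[ok]),
        lst_mean_c = mean(l[ok]), n_valid_px = sum(ok))
    }
  }
  do.call(rbind, rows)
}

# Per-base-cell cover fraction by explicit counting over fine pixels.
brute_coarsen <- function(binary, ratio) {
  nr <- nrow(binary) / ratio
  nc <- ncol(binary) / ratio
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      blk <- binary[((i - 1) * ratio + 1):(i * ratio),
                    ((j - 1) * ratio + 1):(j * ratio)]
      ok <- !is.na(blk)
      if (sum(ok) >= length(blk) / 2) out[i, j] <- mean(blk[ok])
    }
  }
  out
}

# Pearson r, two-tailed t-transform p, and OLS slope from raw formulas.
cor_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE),
       slope = r * sd(y) / sd(x))
}

# Shared small fixture: a seeded raster pair plus its coarse ladder.
make_test_pair <- function(seed = 1, n = 60, neighborhood_effect = 5,
                           noise_sd = 0.5, ...) {
  simulate_raster_pair(raster_sim_config(
    n_rows = n, n_cols = n, neighborhood_effect = neighborhood_effect,
    noise_sd = noise_sd, seed = seed, ...))
}
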