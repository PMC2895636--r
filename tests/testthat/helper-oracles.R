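# Independent brute-force oracles for the correlation statistics, kept
# deliberately naive (explicit loops, no shared code with the package).

oracle_chi2 <- function(counts) {
  n <- sum(counts)
  r <- rowSums(counts)
  cc <- colSums(counts)
  acc <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      if (r[i] > 0 && cc[j] > 0) {
        e <- r[i] * cc[j] / n
        acc <- acc + (counts[i, j] - e)^2 / e
      }
    }
  }
  acc
}

# midranks computed from first principles, then the Pearson product-moment
# formula applied to the ranks
oracle_spearman <- function(x, y) {
  midrank <- function(z) {
    vapply(z, function(zi) sum(z < zi) + (sum(z == zi) + 1) / 2, numeric(1))
  }
  rx <- midrank(x)
  ry <- midrank(y)
  n <- length(x)
  sxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
  sxx <- sum((rx - mean(rx))^2)
  syy <- sum((ry - mean(ry))^2)
  sxy / sqrt(sxx * syy)
}

# random non-negative count matrix with occasional empty rows/columns
random_histogram <- function(L = 6, lambda = 4) {
  m <- matrix(rpois(L * L, lambda), L, L)
  if (runif(1) < 0.2) m[sample.int(L, 1), ] <- 0
  if (runif(1) < 0.2) m[, sample.int(L, 1)] <- 0
  if (sum(m) == 0) m[1, 1] <- 1
  m
}

# small synthetic population tibble on an L-level grid
random_population <- function(n, L = 6, conds = c("a", "b")) {
  out <- tibble::tibble(model_id = seq_len(n))
  for (nm in conds) {
    out[[paste0("lvl_", nm)]] <- sample.int(L, n, replace = TRUE)
  }
  out
}

toy_grid <- function(L = 6, conds = c("a", "b")) {
  conductance_grid(setNames(lapply(conds, function(x) seq(0, 1, length.out = L)),
                            conds))
}

# hand-built piecewise-linear trace from knots, sampled at dt
knot_trace <- function(kt, kv, dt = 1, duration = max(kt)) {
  tt <- seq(0, duration, by = dt)
  tibble::tibble(time = tt, v = approx(kt, kv, xout = tt, rule = 2)$y)
}

zero_gbar <- function(kin) setNames(rep(0, length(kin$channels)), names(kin$channels))
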