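test_that("2-D histograms count grid cells exactly", {
  g <- toy_grid(3)
  pop <- tibble::tibble(lvl_a = c(1L, 2L, 3L, 3L), lvl_b = c(1L, 2L, 3L, 1L))
  h <- histogram2d(pop, c("a", "b"), g)
  expect_equal(sum(h), 4)
  expect_equal(unname(unclass(h)[cbind(pop$lvl_a, pop$lvl_b)]),
               c(1L, 1L, 1L, 1L))
  # swapped pair order transposes the counts
  h2 <- histogram2d(pop, c("b", "a"), g)
  expect_equal(unclass(h2), t(unclass(h)), ignore_attr = TRUE)
  expect_error(histogram2d(pop, c("a", "z"), g), "unknown conductance")
  # against a brute-force double loop
  set.seed(2)
  popr <- random_population(300, L = 4)
  g4 <- toy_grid(4)
  hr <- unclass(histogram2d(popr, c("a", "b"), g4))
  brute <- matrix(0L, 4, 4)
  for (r in seq_len(nrow(popr))) {
    brute[popr$lvl_a[r], popr$lvl_b[r]] <- brute[popr$lvl_a[r], popr$lvl_b[r]] + 1L
  }
  expect_equal(hr, brute, ignore_attr = TRUE)
})

test_that("chi-squared matches the brute-force oracle and known values", {
  # uniform table: observed equals expected everywhere
  expect_equal(chi2_independence(matrix(5, 6, 6)), 0)
  # perfect diagonal, 10 models per cell (N = 60): direct evaluation
  d <- diag(10, 6)
  expect_equal(chi2_independence(d), oracle_chi2(d))
  expect_equal(chi2_independence(d), 300, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:100) {
    m <- random_histogram()
    expect_equal(chi2_independence(m), oracle_chi2(m), tolerance = 1e-12)
  }
  expect_error(chi2_independence(matrix(0, 6, 6)), "empty")
})

test_that("chi-squared invariances hold", {
  set.seed(4)
  m <- random_histogram()
  expect_equal(chi2_independence(m[sample(6), sample(6)]),
               chi2_independence(m), tolerance = 1e-9)
  expect_equal(chi2_independence(t(m)), chi2_independence(m),
               tolerance = 1e-9)
  # raw statistic scales linearly in the counts (deliberate N-dependence)
  expect_equal(chi2_independence(3 * m), 3 * chi2_independence(m),
               tolerance = 1e-9)
  # product-form counts are exactly independent
  prod_m <- outer(c(2, 0, 3, 1, 4, 2), c(1, 5, 0, 2, 2, 2))
  expect_equal(chi2_independence(prod_m), 0, tolerance = 1e-9)
})

test_that("Spearman rho uses midranks and matches the oracle", {
  g <- toy_grid(6)
  diag_pop <- tibble::tibble(lvl_a = rep(1:6, 3), lvl_b = rep(1:6, 3))
  expect_equal(spearman_rho(diag_pop, c("a", "b")), 1)
  anti <- tibble::tibble(lvl_a = 1:6, lvl_b = 6:1)
  expect_equal(spearman_rho(anti, c("a", "b")), -1)
  set.seed(5)
  pop <- random_population(200)
  expect_equal(spearman_rho(pop, c("a", "b")),
               oracle_spearman(pop$lvl_a, pop$lvl_b), tolerance = 1e-12)
  # rho flips sign when one axis's level order is reversed
  flipped <- pop
  flipped$lvl_b <- 7L - flipped$lvl_b
  expect_equal(spearman_rho(flipped, c("a", "b")),
               -spearman_rho(pop, c("a", "b")), tolerance = 1e-12)
  # constant margin: undefined
  const <- tibble::tibble(lvl_a = rep(2L, 10), lvl_b = 1:10)
  expect_true(is.na(spearman_rho(const, c("a", "b"))))
})

test_that("independence and difference matrices satisfy their identities", {
  prod_m <- outer(c(2, 1, 3, 1, 4, 2), c(1, 5, 1, 2, 2, 2))
  id <- independence_difference(prod_m)
  expect_equal(sum(id$expected), sum(prod_m), tolerance = 1e-9)
  expect_true(all(abs(id$difference) < 1e-9))
  # perfect diagonal: positive on the diagonal, negative off it
  d <- independence_difference(diag(10, 6))
  expect_true(all(diag(d$difference) > 0))
  off <- d$difference[row(d$difference) != col(d$difference)]
  expect_true(all(off < 0))
  expect_equal(sum(d$difference), 0, tolerance = 1e-9)
})

test_that("scan produces all 28 pairs with deterministic order and flags", {
  pl <- data.frame(type = "b", cond_a = "CaS", cond_b = "KCa",
                   sign = 1, width = 2, adherence = 0.9)
  db <- make_planted_db(20000, type_weights = c(b = 1), planted = pl,
                        seed = 7)
  sc <- scan_correlations(db, population = "b")
  expect_s3_class(sc, "correlation_scan")
  expect_equal(nrow(sc), 28)
  expect_equal(nrow(conductance_pairs()), 28)
  hit <- sc[sc$is_correlation, ]
  expect_equal(nrow(hit), 1)
  expect_equal(paste(hit$cond_a, hit$cond_b), "CaS KCa")
  expect_gt(hit$chi2, 500)
  expect_gt(abs(hit$rho), 0.2)
  # strictness: flags mirror the strict inequalities
  expect_equal(sc$is_correlation, sc$passes_chi2 & sc$passes_rho)
  # re-scan identical
  sc2 <- scan_correlations(db, population = "b")
  expect_equal(as.data.frame(sc2), as.data.frame(sc))
})

test_that("small populations are scanned with a low-N warning", {
  db <- make_planted_db(200, seed = 9)
  expect_warning(scan_correlations(db), "little information")
  expect_error(scan_correlations(db[0, ]), "empty population")
})

test_that("edge-concentration heuristic flags zero-dominated histograms", {
  m <- matrix(0L, 6, 6)
  m[1, ] <- 30L
  m[, 1] <- 30L
  m[3, 3] <- 20L
  expect_true(flag_edge_concentration(m, 0.5))
  expect_false(flag_edge_concentration(matrix(5, 6, 6), 0.5))
})

test_that("tidy and glance summarise a scan", {
  pl <- data.frame(type = "b", cond_a = c("CaS", "Na"), cond_b = c("KCa", "Kd"),
                   sign = c(1, -1), width = c(1, 1), adherence = c(1, 1))
  db <- make_planted_db(10000, type_weights = c(b = 1), planted = pl,
                        seed = 13)
  sc <- scan_correlations(db, population = "b")
  td <- tidy(sc)
  expect_s3_class(td, "tbl_df")
  gl <- glance(sc)
  expect_equal(gl$n_tests, 28)
  expect_equal(gl$n_correlations, gl$n_positive + gl$n_negative)
  expect_gte(gl$n_calcium, 1)
  sm <- correlation_sign_matrix(sc)
  expect_equal(nrow(sm), 28)
  expect_true("b" %in% names(sm))
  expect_setequal(setdiff(unique(sm$b), ""), c("+", "-"))
})
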