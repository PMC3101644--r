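test_that("error_rates matches the bipartition definitions", {
  t0 <- unroot_tree(read_newick("((a,b),(c,(d,e)));"))
  expect_equal(error_rates(t0, t0), c(fn = 0, fp = 0, rf = 0))
  star <- star_tree(letters[1:5])
  expect_equal(error_rates(star, t0), c(fn = 1, fp = 0, rf = 0.5))
  # one NNI apart on 5 leaves: both bipartitions differ in one of two edges
  tb <- unroot_tree(read_newick("((a,c),(b,(d,e)));"))
  expect_equal(error_rates(tb, t0), c(fn = 0.5, fp = 0.5, rf = 0.5))
  expect_error(error_rates(star_tree(letters[2:6]), t0), "differ")
})

test_that("rates are symmetric for binary pairs and stay in [0,1]", {
  for (s in 1:10) {
    tA <- rand_topo(9, 1100 + s); tB <- rand_topo(9, 1200 + s)
    tB <- ape::keep.tip(tB, tA$tip.label)
    ab <- error_rates(tA, tB); ba <- error_rates(tB, tA)
    expect_equal(ab[["fn"]], ba[["fp"]])
    expect_equal(ab[["rf"]], ba[["rf"]])
    expect_true(all(ab >= 0 & ab <= 1))
    expect_equal(ab[["rf"]], (ab[["fn"]] + ab[["fp"]]) / 2)
  }
})

test_that("sum_distance reduces to single-tree rates and honours flags", {
  t0 <- rand_topo(8, 55)
  tb <- rand_topo(8, 56); tb <- ape::keep.tip(tb, t0$tip.label)
  expect_equal(sum_distance(tb, list(t0), "fn"),
               error_rates(tb, t0)[["fn"]])
  # perfect supertree on true restrictions
  profile <- lapply(list(1:6, 3:8), function(i)
    restrict(t0, sort(t0$tip.label)[i]))
  expect_equal(sum_distance(t0, profile, "fn"), 0)
  expect_equal(sum_distance(t0, profile, "rf"), 0)
  expect_error(sum_distance(restrict(t0, sort(t0$tip.label)[1:5]),
                            profile, "fn"), "not in the supertree")
  # mean-of-ratios differs in general but agrees on zeros
  expect_equal(sum_distance(t0, profile, "fn", "mean-of-ratios"), 0)
})

test_that("spearman_rho matches the closed form and flags degeneracy", {
  expect_equal(spearman_rho(1:4, 1:4), 1)
  expect_equal(spearman_rho(1:4, 4:1), -1)
  expect_equal(spearman_rho(1:3, c(2, 1, 3)), 0.5)
  for (s in 1:10) {
    x <- with_seed(s, sample(1:5)); y <- with_seed(s + 50, sample(1:5))
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y))
  }
  d <- spearman_rho(c(1, 1, 1), 1:3)
  expect_true(is.na(d))
  expect_true(attr(d, "degenerate"))
  expect_error(spearman_rho(1:3, 1:4), "length")
  expect_error(spearman_rho(1, 1), "2 observations")
})

test_that("run_experiment produces a complete, reproducible table", {
  cond <- model_condition(12, 1.0, "mixed", replicates = 2,
                          estimator = "true", sites = 50)
  res <- run_experiment(cond, c("gmrp", "qmc-all"), seed = 4)
  expect_equal(nrow(res), 4)          # 2 replicates x 2 methods
  expect_true(all(!res$failed))
  expect_true(all(res$fn >= 0 & res$fn <= 1))
  res2 <- run_experiment(cond, c("gmrp", "qmc-all"), seed = 4)
  expect_identical(as.data.frame(res), as.data.frame(res2))
  expect_error(run_experiment(cond, "no-such-method", seed = 1), "unknown")
  s <- attr(res, "summary")
  expect_equal(nrow(s), 2)
  expect_equal(s$mean_fn,
               vapply(split(res$fn, res$method)[unique(s$method)],
                      mean, numeric(1)), ignore_attr = TRUE)
})

test_that("failed replicates are excluded from summaries", {
  tab <- data.frame(
    condition = "c1", density = 0.5, profile_type = "mixed",
    replicate = rep(1:3, each = 2),
    method = rep(c("m1", "m2"), 3),
    fn = c(0.1, 0.2, 0.5, NA, 0.3, 0.4),
    fp = 0.1, rf = 0.1, sum_fn = 0.1, sum_fp = 0.1, sum_rf = 0.1,
    failed = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  s <- summarize_experiment(tab)
  expect_equal(s$n_replicates, c(2, 2))
  expect_equal(s$mean_fn[s$method == "m1"], mean(c(0.1, 0.3)))
  expect_equal(s$mean_fn[s$method == "m2"], mean(c(0.2, 0.4)))
})

test_that("correlation_study matches hand-computed rhos", {
  mk <- function(rep, m, fn, sum_fn)
    data.frame(condition = "c", density = 0.5, profile_type = "mixed",
               replicate = rep, method = m, fn = fn, fp = fn, rf = fn,
               sum_fn = sum_fn, sum_fp = sum_fn, sum_rf = sum_fn,
               failed = FALSE)
  # replicate 1: identical rank order (rho 1); replicate 2: one swap
  tab <- rbind(mk(1, "m1", 0.1, 0.2), mk(1, "m2", 0.2, 0.3),
               mk(1, "m3", 0.3, 0.4),
               mk(2, "m1", 0.1, 0.3), mk(2, "m2", 0.2, 0.2),
               mk(2, "m3", 0.3, 0.4))
  cs <- correlation_study(tab)
  cell <- cs[cs$criterion == "sum_fn" & cs$error == "fn", ]
  expect_equal(cell$mean_rho, mean(c(1, 0.5)))
  expect_equal(cell$min_rho, 0.5)
  expect_equal(cell$max_rho, 1)
  expect_equal(cell$n_replicates, 2)
  # identical outputs across methods: degenerate, flagged, empty cell
  tied <- rbind(mk(1, "m1", 0.1, 0.2), mk(1, "m2", 0.1, 0.2))
  ct <- correlation_study(tied)
  expect_true(all(is.na(ct$mean_rho)))
  expect_true(all(ct$n_degenerate == 1))
  expect_error(correlation_study(tab[tab$method == "m1", ]), "2 methods")
})

test_that("degrading a tree by NNI moves trends FN upward", {
  mean_fn <- matrix(0, nrow = 10, ncol = 21)
  for (s in 1:10) {
    t0 <- rand_topo(20, 1300 + s)
    cur <- t0
    for (k in 1:20) {
      cur <- with_seed(s * 100 + k, phangorn::rNNI(cur, 1))
      mean_fn[s, k + 1] <- error_rates(cur, t0)[["fn"]]
    }
  }
  avg <- colMeans(mean_fn)
  expect_equal(avg[1], 0)
  expect_gt(avg[21], avg[2])
  expect_gt(spearman_rho(seq_along(avg), avg), 0.8)
})

test_that("results CSVs round trip", {
  tab <- data.frame(condition = "c1", density = 0.2, profile_type = "mixed",
                    replicate = 1L, method = "gmrp", fn = 0.25, fp = 0,
                    rf = 0.125, sum_fn = 0.1, sum_fp = 0.1, sum_rf = 0.1,
                    failed = FALSE)
  f <- tempfile(fileext = ".csv")
  write_results_csv(tab, f)
  back <- read_results_csv(f)
  expect_equal(back, tab)
  expect_error(read_results_csv(tempfile()), "no such file")
})
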