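mk_9x9 <- function(obs_a, obs_b) {
  # one feature observed in obs_a/9 samples of A and obs_b/9 of B
  m <- matrix(1, 18, 2)
  m[seq_len(9 - obs_a), 1] <- NA
  m[9 + seq_len(9 - obs_b), 1] <- NA
  toy_table(m, groups = rep(c("A", "B"), each = 9))
}

test_that("the 80% presence rule is applied group-wise", {
  # 8/9 in one group is enough (8/9 = 0.889 >= 0.8)
  kept <- presence_filter(mk_9x9(8, 0))
  expect_equal(length(feature_positions(kept)), 2)
  # 7/9 in both groups is not (7/9 = 0.778 < 0.8)
  dropped <- presence_filter(mk_9x9(7, 7))
  expect_equal(length(feature_positions(dropped)), 1)
  # the stricter both-groups reading
  expect_equal(length(feature_positions(
    presence_filter(mk_9x9(8, 0), rule = "all_groups"))), 1)
  expect_equal(length(feature_positions(
    presence_filter(mk_9x9(9, 8), rule = "all_groups"))), 2)
  # min_frac = 0 keeps everything
  expect_equal(length(feature_positions(presence_filter(mk_9x9(1, 0),
                                                        min_frac = 0))), 2)
  expect_error(presence_filter(mk_9x9(8, 8), min_frac = 1.2), "\\[0, 1\\]")
})

test_that("internal-standard scaling divides by the reference feature", {
  m <- matrix(c(2, 4, 6,
                1, 2, 3,
                2, 2, 2), nrow = 3)
  tab <- toy_table(m, positions = c(3.0, 5.0, 6.0))
  out <- scale_to_reference_feature(tab, ref_position = 6.0)
  mo <- ft_values(out)
  expect_equal(unname(mo[, 3]), c(1, 1, 1))           # reference column is 1
  expect_equal(unname(mo[1, ]), c(2, 1, 2) / 2)       # sample divided by its MA
  bad <- toy_table(matrix(c(1, 1, 0, 1, 1, 1), nrow = 3),
                   positions = c(6.0, 3.0))
  expect_error(scale_to_reference_feature(bad), "s03")
  far <- toy_table(m, positions = c(3.0, 5.0, 7.0))
  expect_error(scale_to_reference_feature(far, ref_position = 6.0),
               "no feature within")
})

test_that("PQN matches a brute-force median-of-quotients oracle", {
  # identical samples: factors 1, unchanged
  same <- toy_table(matrix(rep(c(1, 2, 3, 4), 3), 3, byrow = TRUE))
  out <- pqn_normalize(same)
  expect_equal(unname(pqn_factors(out)), rep(1, 3))
  expect_equal(ft_values(out), ft_values(same))
  # one sample multiplied by 3 gets factor 3 and rejoins the others
  m <- matrix(rep(c(1, 2, 3, 4), 4), 4, byrow = TRUE)
  m[2, ] <- 3 * m[2, ]
  t3 <- pqn_normalize(toy_table(m))
  expect_equal(unname(pqn_factors(t3)[2]), 3)
  expect_equal(unname(ft_values(t3)[2, ]), c(1, 2, 3, 4))
  # 3 x 4 with one missing cell vs an exhaustive hand computation
  m4 <- matrix(c(1.0, 2.0, 0.5, 4.0,
                 2.0, 4.4, 1.0, 8.4,
                 1.1, NA,  0.6, 4.4), 3, 4, byrow = TRUE)
  oracle_factors <- sapply(1:3, function(i) {
    ref <- sapply(1:4, function(j) median(m4[, j], na.rm = TRUE))
    median(m4[i, ] / ref, na.rm = TRUE)
  })
  out4 <- pqn_normalize(toy_table(m4))
  expect_equal(unname(pqn_factors(out4)), oracle_factors)
  expect_true(is.na(ft_values(out4)[3, 2]))    # missing stays missing
})

test_that("PQN is idempotent on dilution-structured data", {
  # PQN models per-sample dilution: samples are multiples of a common
  # profile; once those multipliers are divided out, a second pass must
  # find nothing left to correct
  set.seed(12)
  profile <- rlnorm(10)
  dilution <- rlnorm(6, sd = 0.5)
  m <- outer(dilution, profile)
  m[2, 5] <- NA
  out <- pqn_normalize(toy_table(m))
  again <- pqn_normalize(out)
  expect_equal(unname(pqn_factors(again)), rep(1, 6), tolerance = 1e-9)
})

test_that("KNN imputation uses nearest features and sensible fallbacks", {
  # complete table passes through unchanged
  full <- toy_table(matrix(1:12, 4, 3))
  expect_equal(ft_values(knn_impute(full)), ft_values(full))
  # an exact duplicate feature (distance 0) donates its value at k = 1
  m <- cbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, NA, 5),
             c = c(9, 7, 2, 1, 3))
  tab <- toy_table(m)
  imp <- ft_values(knn_impute(tab, k = 1))
  expect_equal(unname(imp[4, 2]), 4)
  # fewer than k observed neighbours: feature mean fallback
  imp10 <- ft_values(knn_impute(tab, k = 10))
  expect_equal(unname(imp10[4, 2]), mean(c(1, 2, 3, 5)))
  # degenerate inputs
  allna <- toy_table(cbind(c(1, 2, 3), c(NA, NA, NA)))
  expect_error(knn_impute(allna), "entirely missing")
})

test_that("glog identities and monotonicity hold", {
  x <- c(0.1, 1, 7)
  expect_equal(glog_transform(x, 0), log(2 * x))
  expect_equal(glog_transform(0, 2.5), log(2.5) / 2)
  grid <- seq(-2, 5, length.out = 100)
  for (lam in c(0.1, 1, 10))
    expect_true(all(diff(glog_transform(grid, lam)) > 0))
  expect_error(glog_transform(-1, 0), "positive|non-negative")
})

test_that("lambda calibration agrees with an exhaustive grid search", {
  # two-component error model: additive sd a, multiplicative sd b
  set.seed(33)
  n_rep <- 8; p <- 40
  mu <- rlnorm(p, meanlog = 2, sdlog = 1.5)
  a <- 0.5; b <- 0.15
  m <- t(replicate(n_rep, mu * exp(rnorm(p, sd = b)) + rnorm(p, sd = a)))
  tab <- toy_table(m, groups = rep("REP", n_rep))
  lam <- estimate_glog_lambda(tab, "REP")
  # independent oracle: 200 log-spaced lambdas
  lgrid <- 10^seq(-6, 10, length.out = 200)
  obj <- sapply(lgrid, function(l) plasmanmr:::glog_heterogeneity(m, l))
  lam_grid <- lgrid[which.min(obj)]
  expect_lt(abs(log10(as.numeric(lam)) - log10(lam_grid)), 1)
  # the chosen lambda beats both endpoints of the search range
  expect_lte(attr(lam, "objective"),
             plasmanmr:::glog_heterogeneity(m, 1e-12 * median(m)^2))
  expect_lte(attr(lam, "objective"),
             plasmanmr:::glog_heterogeneity(m, 1e12 * median(m)^2))
  # invariance to feature order
  perm <- sample(p)
  lam_p <- estimate_glog_lambda(toy_table(m[, perm],
                                          groups = rep("REP", n_rep)), "REP")
  expect_equal(log(as.numeric(lam_p)), log(as.numeric(lam)), tolerance = 1e-3)
  # constant replicate block returns the lower bound with a warning
  const <- toy_table(matrix(5, 4, 3), groups = rep("REP", 4))
  expect_warning(l0 <- estimate_glog_lambda(const, "REP"), "constant")
  expect_equal(as.numeric(l0), 1e-12 * 25)
})

test_that("the conditioning chain enforces its stage order", {
  set.seed(2)
  m <- matrix(rlnorm(40), 4, 10)
  tab <- toy_table(m, groups = rep(c("A", "B"), each = 2),
                   positions = c(6.0, seq(1, 5, length.out = 9)))
  norm <- pqn_normalize(tab)
  expect_error(presence_filter(norm), "chain order")
  ok <- tab |> presence_filter() |> scale_to_reference_feature() |>
    pqn_normalize() |> knn_impute()
  expect_equal(attr(ok, "steps"),
               c("presence_filter", "scale_to_reference", "pqn", "knn_impute"))
})

test_that("feature tables round-trip through delimited text", {
  m <- matrix(c(1.5, NA, 2.25, 3, 4, 5), 2, 3)
  tab <- toy_table(m, groups = c("A", "B"), positions = c(1.1, 2.2, 3.3))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, f)
  back <- read_feature_table(f)
  expect_equal(ft_values(back), ft_values(tab))
  expect_equal(back$group, tab$group)
  expect_equal(unname(feature_positions(back)), c(1.1, 2.2, 3.3))
})
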