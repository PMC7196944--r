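test_that("PCA reproduces a direct eigen-decomposition", {
  # data on one line: first component explains everything
  t_ <- seq(-2, 2, length.out = 7)
  line <- outer(t_, c(1, 2, -1)) + matrix(rep(c(5, 5, 5), each = 7), 7)
  p1 <- pca(toy_table(line), 1)
  expect_equal(p1$explained_variance_ratio[1], 1)
  # full-rank reconstruction
  set.seed(8)
  X <- matrix(rnorm(30), 6, 5)
  pf <- pca(toy_table(X), 5)
  Xc <- sweep(X, 2, colMeans(X))
  recon <- as.matrix(pf$scores[paste0("PC", 1:5)]) %*% t(pf$loadings)
  expect_equal(unname(recon), unname(Xc), tolerance = 1e-8)
  # explained variances equal covariance eigenvalues on a 6 x 5 table
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(unname(pf$explained_variance), ev[1:5], tolerance = 1e-8)
  expect_error(pca(toy_table(X), 6), "exceed")
})

test_that("PLS-DA extracts the informative direction", {
  d <- separable_xy(n_per = 12, p = 8, delta = 5, noise = 1, seed = 19)
  fit <- plsda_fit(d$X, d$y, A = 1)
  # first weight vector within 5 degrees of the class-mean difference
  diff_dir <- colMeans(d$X[d$y == "B", ]) - colMeans(d$X[d$y == "A", ])
  cosang <- abs(sum(fit$W[, 1] * diff_dir)) /
    sqrt(sum(diff_dir^2))              # ||w|| = 1
  expect_gt(cosang, cos(5 * pi / 180))
  # duplicated feature columns get equal weights
  Xdup <- cbind(d$X[, 1], d$X[, 1], d$X[, 2])
  fd <- plsda_fit(Xdup, d$y, A = 1)
  expect_equal(fd$W[1, 1], fd$W[2, 1])
  # full-rank fit deflates X to numerical zero
  small <- separable_xy(n_per = 3, p = 4, seed = 5)
  fs <- suppressWarnings(plsda_fit(small$X, small$y, A = 10))
  Xc <- scale(small$X, center = TRUE, scale = FALSE)
  resid <- Xc - fs$Tt %*% t(fs$P)
  expect_lt(max(abs(resid)), 1e-8)
  expect_error(plsda_fit(d$X, rep("A", 24), A = 1), "2 classes")
})

test_that("PLS-DA scores are mutually orthogonal", {
  d <- separable_xy(n_per = 8, p = 12, delta = 2, seed = 77)
  fit <- plsda_fit(d$X, d$y, A = 4)
  G <- crossprod(fit$Tt)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("prediction follows the sign rule with ties to the first class", {
  d <- separable_xy(n_per = 10, p = 6, delta = 8, noise = 1, seed = 3)
  fit <- plsda_fit(d$X, d$y, A = 1)
  pr <- plsda_predict(fit, d$X)
  expect_equal(sum(pr$class != d$y), 0)          # perfectly separated
  # the training centroid scores exactly 0 and takes the -1-coded class
  centroid <- matrix(colMeans(d$X), 1)
  pc <- plsda_predict(fit, centroid)
  expect_equal(pc$score, 0, tolerance = 1e-12)
  expect_equal(pc$class, "A")
  # a held-out sample at strong separation classifies correctly
  held <- matrix(rnorm(6), 1); held[1] <- held[1] + 8
  expect_equal(plsda_predict(fit, held)$class, "B")
  expect_error(plsda_predict(fit, matrix(0, 1, 5)), "mismatch")
})

test_that("LOO component selection picks the smallest best model", {
  d <- separable_xy(n_per = 8, p = 10, delta = 6, noise = 1, seed = 11)
  a <- select_components_loocv(d$X, d$y)
  expect_equal(as.integer(a), 1)                 # one informative direction
  errs <- attr(a, "errors")
  expect_true(all(errs >= errs[1]))
  # range contract and smallest-at-tie rule on noise-only data
  set.seed(14)
  Xn <- matrix(rnorm(16 * 5), 16, 5)
  yn <- rep(c("A", "B"), each = 8)
  an <- select_components_loocv(Xn, yn, A_max = 4)
  expect_gte(as.integer(an), 1); expect_lte(as.integer(an), 4)
  ties <- attr(an, "errors") == min(attr(an, "errors"))
  expect_equal(as.integer(an), which(ties)[1])
})

test_that("double cross-validation classifies separable cohorts and honors the tie rule", {
  d <- separable_xy(n_per = 9, p = 10, delta = 6, noise = 1, seed = 23)
  cv <- double_cv(d$X, d$y)
  expect_equal(cv$misclassifications, 0)
  # constant X: every prediction is 0, the tie rule assigns class "A",
  # so exactly the 9 "B" samples are wrong
  Xc <- matrix(1, 18, 4)
  cvc <- double_cv(Xc, d$y)
  expect_equal(cvc$misclassifications, 9)
  expect_true(all(cvc$predictions$predicted == "A"))
  # invariance under sample reordering
  set.seed(31)
  perm <- sample(18)
  cvp <- double_cv(d$X[perm, ], d$y[perm])
  expect_equal(cvp$misclassifications, cv$misclassifications)
})

test_that("double-CV error grows to chance under label permutation", {
  d <- separable_xy(n_per = 9, p = 8, delta = 4, noise = 1, seed = 41)
  set.seed(99)
  rates <- replicate(40, {
    yp <- sample(d$y)
    double_cv(d$X, yp, A_max = 3)$misclassifications / 18
  })
  expect_gte(mean(rates), 0.25)
})

test_that("VIP scores follow the projection-importance formula", {
  # single component, equal weights: every VIP is exactly 1
  X <- matrix(rnorm(40), 8, 5)
  Xeq <- X[, 1] %*% t(rep(1, 5)) + 0 * X
  y <- rep(c("A", "B"), 4)
  Xeq[y == "B", ] <- Xeq[y == "B", ] + 3
  feq <- plsda_fit(Xeq, y, A = 1)
  veq <- vip_scores(feq)
  expect_equal(veq$vip, rep(1, 5), tolerance = 1e-8)
  # single component closed form: sqrt(p) |w_j| / ||w||
  d <- separable_xy(n_per = 6, p = 7, seed = 13)
  f1 <- plsda_fit(d$X, d$y, A = 1)
  v1 <- vip_scores(f1)
  expect_equal(v1$vip, sqrt(7) * abs(f1$W[, 1]) / sqrt(sum(f1$W[, 1]^2)),
               tolerance = 1e-10)
  # two-component, 5-feature model vs a term-by-term evaluation
  d2 <- separable_xy(n_per = 6, p = 5, delta = 2, seed = 29)
  f2 <- plsda_fit(d2$X, d2$y, A = 2)
  ssy <- f2$q^2 * colSums(f2$Tt^2)
  oracle <- sqrt(5 * (sweep(f2$W^2, 2, colSums(f2$W^2), "/") %*% ssy) / sum(ssy))
  expect_equal(vip_scores(f2)$vip, as.numeric(oracle), tolerance = 1e-10)
  # normalization invariant: sum of squared VIPs equals feature count
  for (A in 1:3) {
    f <- plsda_fit(d$X, d$y, A = A)
    expect_equal(sum(vip_scores(f)$vip^2), 7, tolerance = 1e-8)
  }
})

test_that("signature overlap counts greedy position matches", {
  sig <- function(ppm, imp = TRUE)
    structure(tibble::tibble(feature = as.character(ppm), ppm = ppm,
                             vip = 2, important = imp),
              class = c("vip_signature", "tbl_df", "tbl", "data.frame"))
  a <- sig(c(1, 2, 3, 4, 5))
  expect_equal(signature_overlap(a, a)$shared, 5)
  expect_equal(signature_overlap(a, a)$only_a, 0)
  b <- sig(c(10, 11, 12))
  expect_equal(signature_overlap(a, b)$shared, 0)
  # constructed 60% overlap: 3 of 5 positions within tolerance
  c_ <- sig(c(1.001, 2.004, 3.002, 7, 8))
  ov <- signature_overlap(a, c_, match_tol = 0.005)
  expect_equal(ov$shared, 3)
  expect_equal(ov$only_a, 2)
  expect_equal(ov$only_b, 2)
  expect_error(signature_overlap(a, b, match_tol = 0), "positive")
})

test_that("PCA and one-component PLS agree when y tracks the first score", {
  set.seed(55)
  n <- 20
  t1 <- rnorm(n, sd = 4)
  X <- outer(t1, c(2, 1, -1, 0.5)) + matrix(rnorm(n * 4, sd = 0.05), n)
  y <- ifelse(t1 > 0, "hi", "lo")
  pc <- pca(toy_table(X), 1)
  pl <- plsda_fit(X, y, A = 1)
  cosang <- abs(sum(pc$loadings[, 1] * pl$W[, 1]))
  expect_gt(cosang, 0.99)
})
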