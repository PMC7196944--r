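#' Principal component analysis of a feature table
#'
#' Mean-centered (no variance scaling) PCA via singular value decomposition;
#' components are ordered by decreasing explained variance and loadings are
#' orthonormal.
#'
#' @param table Complete feature table (or numeric matrix).
#' @param n_components Number of components (<= min(n - 1, p)).
#' @return List of class `nmr_pca`: `scores` (tibble with sample metadata),
#'   `loadings` (matrix), `explained_variance` and
#'   `explained_variance_ratio`.
#' @export
pca <- function(table, n_components = 2) {
  X <- if (inherits(table, "feature_table")) ft_values(table) else as.matrix(table)
  if (anyNA(X)) stop("PCA requires a complete table")
  n <- nrow(X); p <- ncol(X)
  if (n_components > min(n - 1, p))
    stop("`n_components` may not exceed min(n - 1, p) = ", min(n - 1, p))
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  a <- seq_len(n_components)
  scores <- tibble::as_tibble(fit$x[, a, drop = FALSE])
  if (inherits(table, "feature_table"))
    scores <- dplyr::bind_cols(table[meta_cols], scores)
  ev <- fit$sdev^2
  structure(list(scores = scores,
                 loadings = fit$rotation[, a, drop = FALSE],
                 explained_variance = ev[a],
                 explained_variance_ratio = ev[a] / sum(ev),
                 center = fit$center),
            class = "nmr_pca")
}

encode_classes <- function(labels) {
  cls <- sort(unique(as.character(labels)))
  if (length(cls) != 2) stop("exactly 2 classes are required")
  counts <- table(labels)
  if (any(counts < 2)) stop("each class needs at least 2 samples")
  list(classes = cls, y = ifelse(labels == cls[2], 1, -1))
}

#' Fit a two-class PLS-DA model
#'
#' NIPALS-style sequential extraction on the mean-centered predictor matrix
#' against a centered +/-1-coded class column (PLS1): for each component the
#' weight vector is `w = X'y / ||X'y||`, scores `t = Xw`, x-loadings
#' `p = X't / (t't)`, y-loading `q = y't / (t't)`, and `X` is deflated by
#' `t p'`. Successive score vectors are mutually orthogonal. Only
#' mean-centering is applied by default; unit-variance scaling is available
#' but off by default.
#'
#' @param X Feature table or numeric matrix (samples x features).
#' @param y_labels Two-class factor/character vector; the alphabetically
#'   first class is coded -1.
#' @param A Number of latent components (>= 1; truncated to the data rank
#'   with a warning).
#' @param scale Apply unit-variance scaling in addition to centering.
#' @return An object of class `plsda` with weights `W`, scores `Tt`,
#'   x-loadings `P`, y-loadings `q`, per-component regression coefficients,
#'   training means and the class coding map.
#' @export
plsda_fit <- function(X, y_labels, A = 2, scale = FALSE) {
  if (inherits(X, "feature_table")) {
    if (missing(y_labels)) y_labels <- X$group
    X <- ft_values(X)
  }
  X <- as.matrix(X)
  stopifnot(A >= 1)
  enc <- encode_classes(y_labels)
  n <- nrow(X); p <- ncol(X)
  x_mean <- colMeans(X)
  x_sd <- if (scale) pmax(apply(X, 2, stats::sd), .Machine$double.eps) else rep(1, p)
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  y_mean <- mean(enc$y)
  yc <- enc$y - y_mean
  A_eff <- min(A, n - 1, p)
  W <- P <- matrix(0, p, A_eff)
  Tt <- matrix(0, n, A_eff)
  q <- numeric(A_eff)
  Xd <- Xc
  a <- 0L
  for (k in seq_len(A_eff)) {
    w <- crossprod(Xd, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    p_ <- crossprod(Xd, t_) / tt
    q_ <- sum(yc * t_) / tt
    Xd <- Xd - t_ %*% t(p_)
    a <- k
    W[, k] <- w; P[, k] <- p_; Tt[, k] <- t_; q[k] <- q_
  }
  if (a == 0L) stop("no predictive component could be extracted")
  if (a < A) warning("component count truncated to the data rank (", a, ")")
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  Tt <- Tt[, seq_len(a), drop = FALSE]; q <- q[seq_len(a)]
  # cumulative regression coefficients for each component count
  R <- W %*% solve(crossprod(P, W))            # X-rotation: Tt = Xc %*% R
  B <- purrr::map(seq_len(a), function(k)
    R[, seq_len(k), drop = FALSE] %*% q[seq_len(k)])
  structure(list(W = W, P = P, Tt = Tt, q = q, A = a, coefficients = B,
                 x_mean = x_mean, x_sd = x_sd, y_mean = y_mean,
                 classes = enc$classes, feature_names = colnames(X)),
            class = "plsda")
}

#' Predict classes from a PLS-DA model
#'
#' The continuous prediction is the centered regression estimate of the coded
#' class; the label is its sign (-1 -> first class, +1 -> second class), with
#' an exact 0 assigned to the class coded -1.
#'
#' @param model A [plsda_fit()] model.
#' @param X_new Matrix or feature table with matching features.
#' @param A Number of components to use (default: all fitted).
#' @return Tibble with `score` (continuous) and `class` columns.
#' @export
plsda_predict <- function(model, X_new, A = model$A) {
  if (inherits(X_new, "feature_table")) X_new <- ft_values(X_new)
  if (is.null(dim(X_new))) X_new <- matrix(X_new, nrow = 1)
  if (ncol(X_new) != length(model$x_mean)) stop("feature count mismatch")
  X_new <- matrix(as.numeric(X_new), ncol = length(model$x_mean))
  A <- min(A, model$A)
  Xc <- sweep(sweep(X_new, 2, model$x_mean), 2, model$x_sd, "/")
  score <- as.numeric(Xc %*% model$coefficients[[A]]) + model$y_mean
  tibble::tibble(score = score,
                 class = ifelse(score > 0, model$classes[2], model$classes[1]))
}

# Fit with up to A components; a degenerate training block (no extractable
# component, e.g. constant X) yields NULL, for which predictions fall back
# to the centered score 0 -- the tie rule's class coded -1.
fit_or_null <- function(X_train, y_train, A) {
  tryCatch(
    suppressWarnings(plsda_fit(X_train, y_train, A = A)),
    error = function(e) {
      if (!grepl("no predictive component", conditionMessage(e))) stop(e)
      NULL
    })
}

predict_or_tie <- function(fit, y_train, X_new, a) {
  if (is.null(fit)) {
    cls <- sort(unique(as.character(y_train)))
    n_new <- if (is.null(dim(X_new))) 1L else nrow(X_new)
    return(tibble::tibble(score = rep(0, n_new), class = cls[1]))
  }
  plsda_predict(fit, X_new, A = min(a, fit$A))
}

#' Select the component count by leave-one-out cross-validation
#'
#' For each candidate component count the leave-one-out misclassification
#' count is computed; the smallest count attaining the minimum is returned.
#'
#' @param X Matrix or feature table.
#' @param y Two-class labels.
#' @param A_max Largest component count considered (default
#'   `min(10, n - 2)`).
#' @return The selected count, with attribute `"errors"` (per-a LOO
#'   misclassification counts).
#' @export
select_components_loocv <- function(X, y, A_max = NULL) {
  if (inherits(X, "feature_table")) {
    if (missing(y)) y <- X$group
    X <- ft_values(X)
  }
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 samples")
  if (is.null(A_max)) A_max <- min(10, n - 2)
  A_max <- max(1, min(A_max, n - 2, ncol(X)))
  errs <- rep(0L, A_max)
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2) stop("a fold lost an entire class")
    fit <- fit_or_null(X[-i, , drop = FALSE], yi, A_max)
    for (a in seq_len(A_max)) {
      pr <- predict_or_tie(fit, yi, X[i, , drop = FALSE], a)
      if (pr$class != y[i]) errs[a] <- errs[a] + 1L
    }
  }
  a_star <- which.min(errs)          # smallest index attaining the minimum
  structure(a_star, errors = errs)
}

#' Double (nested leave-one-out) cross-validation of PLS-DA
#'
#' Outer leave-one-out: for each held-out sample the component count is
#' re-selected by inner leave-one-out on the remaining samples, the model is
#' refit, and the held-out sample classified. The total misclassification
#' count over outer folds is the headline error.
#'
#' @param X Matrix or feature table.
#' @param y Two-class labels.
#' @param A_max Inner-loop cap on components.
#' @return List of class `double_cv`: `misclassifications`, `predictions`
#'   (tibble with truth, predicted label, continuous score, per-fold
#'   component count) and `n`.
#' @export
double_cv <- function(X, y, A_max = NULL) {
  if (inherits(X, "feature_table")) {
    if (missing(y)) y <- X$group
    X <- ft_values(X)
  }
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 6) stop("need at least 6 samples")
  res <- purrr::map(seq_len(n), function(i) {
    yi <- y[-i]
    if (length(unique(yi)) < 2) stop("an outer fold lost an entire class")
    a_star <- select_components_loocv(X[-i, , drop = FALSE], yi, A_max = A_max)
    fit <- fit_or_null(X[-i, , drop = FALSE], yi, as.integer(a_star))
    pr <- predict_or_tie(fit, yi, X[i, , drop = FALSE], as.integer(a_star))
    tibble::tibble(sample = i, truth = as.character(y[i]), predicted = pr$class,
                   score = pr$score, a_star = as.integer(a_star))
  })
  pred <- dplyr::bind_rows(res)
  structure(list(misclassifications = sum(pred$predicted != pred$truth),
                 predictions = pred, n = n),
            class = "double_cv")
}

#' @export
print.double_cv <- function(x, ...) {
  cat(sprintf("Double cross-validated PLS-DA: %d/%d misclassified\n",
              x$misclassifications, x$n))
  cat("Selected components per fold:",
      paste(range(x$predictions$a_star), collapse = "-"), "\n")
  invisible(x)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt( p * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a )` with
#' `SSY_a = q_a^2 t_a' t_a`; the mean squared VIP is 1 by construction.
#' Features with VIP above `threshold` are flagged important.
#'
#' @param model A fitted [plsda_fit()] model.
#' @param threshold Importance threshold (conventional default 1).
#' @param positions Optional numeric ppm positions (taken from feature names
#'   when they parse as numbers).
#' @return Tibble of class `vip_signature`: `feature`, `ppm`, `vip`,
#'   `important`.
#' @export
vip_scores <- function(model, threshold = 1, positions = NULL) {
  W <- model$W
  ssy <- model$q^2 * colSums(model$Tt^2)
  if (sum(ssy) == 0) stop("zero total explained class variance")
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  p <- nrow(W)
  vip <- sqrt(p * as.numeric(wn2 %*% ssy) / sum(ssy))
  nms <- model$feature_names %||% paste0("V", seq_len(p))
  if (is.null(positions))
    positions <- suppressWarnings(as.numeric(sub("_[0-9]+$", "", nms)))
  out <- tibble::tibble(feature = nms, ppm = positions, vip = vip,
                        important = vip > threshold)
  class(out) <- c("vip_signature", class(out))
  out
}

#' Compare two VIP signatures by feature position
#'
#' Greedy nearest-position matching (closest pairs first) among the features
#' flagged important in each signature, within `match_tol` ppm.
#'
#' @param sig_a,sig_b [vip_scores()] tibbles with ppm positions.
#' @param match_tol Matching tolerance in ppm.
#' @return List: `shared`, `only_a`, `only_b` (counts) and `matches`
#'   (tibble of matched positions).
#' @export
signature_overlap <- function(sig_a, sig_b, match_tol = 0.005) {
  if (match_tol <= 0) stop("`match_tol` must be positive")
  pa <- sig_a$ppm[sig_a$important]
  pb <- sig_b$ppm[sig_b$important]
  if (anyNA(pa) || anyNA(pb)) stop("signatures must carry ppm positions")
  pairs <- tidyr::expand_grid(i = seq_along(pa), j = seq_along(pb))
  if (nrow(pairs) > 0) {
    pairs$d <- abs(pa[pairs$i] - pb[pairs$j])
    pairs <- pairs[pairs$d <= match_tol, ]
    pairs <- pairs[order(pairs$d), ]
  }
  used_i <- used_j <- integer(); keep <- integer()
  for (r in seq_len(nrow(pairs))) {
    if (pairs$i[r] %in% used_i || pairs$j[r] %in% used_j) next
    used_i <- c(used_i, pairs$i[r]); used_j <- c(used_j, pairs$j[r])
    keep <- c(keep, r)
  }
  matches <- if (length(keep))
    tibble::tibble(ppm_a = pa[pairs$i[keep]], ppm_b = pb[pairs$j[keep]]) else
    tibble::tibble(ppm_a = numeric(), ppm_b = numeric())
  list(shared = nrow(matches), only_a = length(pa) - nrow(matches),
       only_b = length(pb) - nrow(matches), matches = matches)
}
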