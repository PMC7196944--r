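format_ppm <- function(x) sprintf("%.4f", x)

#' Samples-by-features table
#'
#' A wide tibble with sample metadata columns (`sample_id`, `group`, `batch`)
#' followed by one numeric column per feature, named by the feature's ppm
#' position formatted to 4 decimals. Missing cells (`NA`) are non-detects.
#'
#' @param values Numeric matrix (samples x features) with ppm-named columns,
#'   or a data frame of feature columns.
#' @param samples Tibble with columns `sample_id`, `group`, `batch` (one row
#'   per row of `values`).
#' @return A tibble of class `feature_table`.
#' @export
feature_table <- function(values, samples) {
  values <- as.data.frame(values)
  # duplicate ppm labels (e.g. near-coincident peak groups) get a _k suffix
  names(values) <- make.unique(names(values), sep = "_")
  stopifnot(nrow(values) == nrow(samples),
            all(c("sample_id", "group", "batch") %in% names(samples)))
  out <- dplyr::bind_cols(tibble::as_tibble(samples[c("sample_id", "group", "batch")]),
                          tibble::as_tibble(values))
  attr(out, "steps") <- character()
  class(out) <- c("feature_table", class(out))
  out
}

meta_cols <- c("sample_id", "group", "batch")

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features", nrow(x),
              length(feature_positions(x))))
  st <- attr(x, "steps")
  if (length(st)) cat("  [", paste(st, collapse = " > "), "]", sep = "")
  cat("\n")
  NextMethod()
}

#' Feature positions of a table
#' @param table A `feature_table`.
#' @return Named numeric vector of ppm positions (names are column names).
#' @export
feature_positions <- function(table) {
  cols <- setdiff(names(table), meta_cols)
  stats::setNames(as.numeric(sub("_[0-9]+$", "", cols)), cols)
}

#' Numeric matrix of feature values
#' @param table A `feature_table`.
#' @return Samples x features matrix with sample ids as row names.
#' @export
ft_values <- function(table) {
  cols <- setdiff(names(table), meta_cols)
  m <- as.matrix(table[cols])
  rownames(m) <- table$sample_id
  m
}

ft_set_values <- function(table, m) {
  cols <- setdiff(names(table), meta_cols)
  stopifnot(ncol(m) == length(cols))
  table[cols] <- as.data.frame(m)
  table
}

# Conditioning steps must run in the canonical order; a later step never
# precedes an earlier recorded one.
ft_step_order <- c("presence_filter", "scale_to_reference", "pqn", "knn_impute", "glog")

restore_ft <- function(out, template, step = NULL) {
  attr(out, "steps") <- attr(template, "steps") %||% character()
  if (!inherits(out, "feature_table")) class(out) <- c("feature_table", class(out))
  if (!is.null(step)) {
    prior <- attr(out, "steps")
    pos <- match(step, ft_step_order)
    done <- match(prior, ft_step_order)
    if (length(done) && any(done > pos))
      stop("conditioning step '", step, "' called after '",
           ft_step_order[max(done)], "'; the chain order is ",
           paste(ft_step_order, collapse = " > "))
    attr(out, "steps") <- c(prior, step)
  }
  out
}

#' Group-wise presence filter
#'
#' Keeps a feature iff its non-missing fraction is at least `min_frac` within
#' at least one sample group (`rule = "any_group"`, the default class-wise
#' reading of the 80% rule). `rule = "all_groups"` requires the fraction in
#' every group.
#'
#' @param table Feature table.
#' @param min_frac Minimal presence fraction in `[0, 1]` (default 0.8).
#' @param rule `"any_group"` or `"all_groups"`.
#' @return Filtered feature table.
#' @export
presence_filter <- function(table, min_frac = 0.8,
                            rule = c("any_group", "all_groups")) {
  rule <- match.arg(rule)
  if (min_frac < 0 || min_frac > 1) stop("`min_frac` must lie in [0, 1]")
  m <- ft_values(table)
  frac <- rowsum((!is.na(m)) * 1, table$group) / as.vector(table(table$group)[sort(unique(table$group))])
  frac <- frac[sort(unique(table$group)), , drop = FALSE]
  keep <- if (rule == "any_group") apply(frac >= min_frac, 2, any)
          else apply(frac >= min_frac, 2, all)
  out <- dplyr::bind_cols(table[meta_cols],
                          tibble::as_tibble(as.data.frame(m[, keep, drop = FALSE])))
  restore_ft(out, table, "presence_filter")
}

#' Scale every sample to its internal-standard feature
#'
#' Divides each sample's feature values by that sample's value of the
#' reference feature (the feature nearest `ref_position`, within `tol`); the
#' reference column becomes exactly 1 everywhere.
#'
#' @param table Feature table.
#' @param ref_position Reference ppm (default 6.0, the maleic acid singlet).
#' @param tol Maximal distance (ppm) between `ref_position` and the matched
#'   feature.
#' @return Scaled feature table.
#' @export
scale_to_reference_feature <- function(table, ref_position = 6.0, tol = 0.02) {
  pos <- feature_positions(table)
  j <- which.min(abs(pos - ref_position))
  if (length(j) == 0 || abs(pos[j] - ref_position) > tol)
    stop("no feature within ", tol, " ppm of the reference position ", ref_position)
  m <- ft_values(table)
  ref <- m[, j]
  bad <- is.na(ref) | ref <= 0
  if (any(bad))
    stop("reference feature missing or non-positive in sample(s): ",
         paste(table$sample_id[bad], collapse = ", "))
  out <- ft_set_values(table, m / ref)
  restore_ft(out, table, "scale_to_reference")
}

#' Probabilistic quotient normalization
#'
#' The reference is the feature-wise median over all samples (ignoring
#' non-detects). Each sample's dilution factor is the median of its
#' feature-wise quotients to the reference (observed features only); the
#' sample is divided by its factor. Missing cells stay missing.
#'
#' @param table Feature table (>= 3 samples).
#' @return The normalized table, with the per-sample factors in attribute
#'   `"pqn_factors"` (also returned by [pqn_factors()]).
#' @export
pqn_normalize <- function(table) {
  if (nrow(table) < 3) stop("PQN needs at least 3 samples")
  m <- ft_values(table)
  ref <- apply(m, 2, stats::median, na.rm = TRUE)
  usable <- !is.na(ref) & ref != 0
  factors <- purrr::map_dbl(seq_len(nrow(m)), function(i) {
    q <- m[i, usable] / ref[usable]
    q <- q[!is.na(q)]
    if (length(q) < 3)
      stop("sample '", rownames(m)[i], "' shares fewer than 3 observed features with the reference")
    stats::median(q)
  })
  out <- ft_set_values(table, m / factors)
  out <- restore_ft(out, table, "pqn")
  attr(out, "pqn_factors") <- stats::setNames(factors, table$sample_id)
  out
}

#' @rdname pqn_normalize
#' @param table A table returned by `pqn_normalize`.
#' @return `pqn_factors` returns the named per-sample factor vector.
#' @export
pqn_factors <- function(table) attr(table, "pqn_factors")

#' K-nearest-neighbour imputation (features as neighbours)
#'
#' For a missing cell, the neighbours of its feature are the other features,
#' ranked by Euclidean distance computed over samples where both features are
#' observed and scaled by the number of co-observed samples (root mean square
#' difference). The imputed value is the inverse-distance-weighted mean of
#' the `k` nearest features' values in that sample; neighbours at distance 0
#' share uniform weights (and exclude farther neighbours). When fewer than
#' `k` neighbours have an observed value in that sample, the feature's own
#' mean over observed samples is used instead.
#'
#' @param table Feature table; no feature or sample may be entirely missing.
#' @param k Number of neighbours (default 10).
#' @return A complete feature table.
#' @export
knn_impute <- function(table, k = 10) {
  m <- ft_values(table)
  if (any(colSums(!is.na(m)) == 0)) stop("a feature is entirely missing")
  if (any(rowSums(!is.na(m)) == 0)) stop("a sample is entirely missing")
  if (!anyNA(m)) return(restore_ft(table, table, "knn_impute"))
  p <- ncol(m)
  obs <- !is.na(m)
  feat_means <- colMeans(m, na.rm = TRUE)
  # pairwise RMS distance between features over co-observed samples
  x0 <- m; x0[!obs] <- 0
  co <- crossprod(obs * 1)                       # co-observation counts
  ss <- matrix(0, p, p)
  # sum over co-observed samples of (xi - xj)^2, assembled from masked sums
  sq <- m^2; sq[!obs] <- 0
  ss <- crossprod(sq, obs) + crossprod(obs, sq) - 2 * crossprod(x0)
  d <- sqrt(pmax(ss, 0) / pmax(co, 1))
  d[co == 0] <- Inf
  diag(d) <- Inf
  for (j in which(colSums(!obs) > 0)) {
    ord <- order(d[, j])
    for (i in which(!obs[, j])) {
      nb <- ord[obs[i, ord] & is.finite(d[ord, j])]
      if (length(nb) < k) {
        m[i, j] <- feat_means[j]
      } else {
        nb <- nb[seq_len(k)]
        dd <- d[nb, j]
        if (any(dd == 0)) {
          m[i, j] <- mean(m[i, nb[dd == 0]])
        } else {
          w <- 1 / dd
          m[i, j] <- sum(w * m[i, nb]) / sum(w)
        }
      }
    }
  }
  restore_ft(ft_set_values(table, m), table, "knn_impute")
}

#' Generalized log transform
#'
#' `g(x) = ln(x + sqrt(x^2 + lambda))`. With `lambda = 0` this is
#' `ln(2x)`; at `x = 0` it is `ln(lambda) / 2`. Monotone increasing in `x`
#' for any fixed `lambda >= 0`; variance-stabilizing for data with mixed
#' additive and multiplicative error when `lambda` is calibrated on
#' technical replicates.
#'
#' @param x Numeric values.
#' @param lambda_ Transform parameter (>= 0).
#' @return Transformed values.
#' @export
glog_transform <- function(x, lambda_) {
  if (lambda_ < 0) stop("`lambda_` must be non-negative")
  arg <- x + sqrt(x^2 + lambda_)
  if (any(arg <= 0, na.rm = TRUE))
    stop("glog undefined: x + sqrt(x^2 + lambda) must be positive")
  log(arg)
}

glog_heterogeneity <- function(m_rep, lambda_) {
  v <- apply(glog_transform(m_rep, lambda_), 2, stats::var)
  mv <- mean(v)
  if (mv == 0) return(0)
  stats::sd(v) / mv
}

#' Calibrate the glog lambda on technical replicates
#'
#' Minimizes a variance-stabilization criterion — the standard deviation
#' across features of the per-feature variance of transformed replicate
#' values, normalized by their mean — by golden-section search on
#' `log(lambda)` over `[1e-12, 1e+12]` times the squared median table value.
#'
#' @param table Complete feature table.
#' @param replicate_group Group label of the technical replicates (>= 3
#'   samples).
#' @return The optimal `lambda`, with attribute `"objective"`; when the
#'   replicate block is constant the search lower bound is returned with a
#'   warning.
#' @export
estimate_glog_lambda <- function(table, replicate_group) {
  m <- ft_values(table)
  if (anyNA(m)) stop("impute the table before estimating lambda")
  rep_idx <- table$group == replicate_group
  if (sum(rep_idx) < 3) stop("the replicate group needs at least 3 samples")
  m_rep <- m[rep_idx, , drop = FALSE]
  scale2 <- stats::median(abs(m), na.rm = TRUE)^2
  if (scale2 == 0) scale2 <- 1
  lo <- log(1e-12 * scale2); hi <- log(1e12 * scale2)
  if (all(apply(m_rep, 2, stats::var) == 0)) {
    warning("replicate block is constant; returning the search lower bound")
    out <- exp(lo)
    attr(out, "objective") <- 0
    return(out)
  }
  opt <- stats::optimize(function(l) glog_heterogeneity(m_rep, exp(l)),
                         interval = c(lo, hi), tol = 1e-6)
  out <- exp(opt$minimum)
  attr(out, "objective") <- opt$objective
  out
}

#' Apply the glog transform to a feature table
#'
#' @param table Complete feature table.
#' @param lambda_ Transform parameter; calibrate with
#'   [estimate_glog_lambda()].
#' @return Transformed feature table.
#' @export
glog_table <- function(table, lambda_) {
  out <- ft_set_values(table, glog_transform(ft_values(table), lambda_))
  restore_ft(out, table, "glog")
  }

#' Run the full conditioning chain
#'
#' Presence filter, internal-standard scaling, PQN, KNN imputation and the
#' glog transform with lambda calibrated on the replicate group, in that
#' fixed order.
#'
#' @param table Raw feature table.
#' @param min_frac Presence threshold.
#' @param ref_position Internal-standard ppm.
#' @param replicate_group Group used for lambda calibration (`NULL` to skip
#'   the glog step).
#' @param k KNN neighbours.
#' @param exclusions Optional tibble of regions passed to [exclude_regions()]
#'   first.
#' @return Conditioned feature table; the processing log (feature counts per
#'   stage, PQN factors, lambda) is in attribute `"log"`.
#' @export
condition_features <- function(table, min_frac = 0.8, ref_position = 6.0,
                               replicate_group = NULL, k = 10,
                               exclusions = NULL) {
  log <- list(n_input = length(feature_positions(table)))
  if (!is.null(exclusions)) {
    table <- exclude_regions(table, exclusions)
    log$n_after_exclusion <- length(feature_positions(table))
  }
  table <- presence_filter(table, min_frac = min_frac)
  log$n_after_presence <- length(feature_positions(table))
  table <- scale_to_reference_feature(table, ref_position = ref_position)
  table <- pqn_normalize(table)
  log$pqn_factors <- pqn_factors(table)
  table <- knn_impute(table, k = k)
  if (!is.null(replicate_group)) {
    lambda_ <- estimate_glog_lambda(table, replicate_group)
    log$lambda <- as.numeric(lambda_)
    table <- glog_table(table, lambda_)
  }
  attr(table, "log") <- log
  table
}

#' Write / read a feature table as delimited text
#'
#' Rows are samples, the first three columns the sample metadata, remaining
#' columns the features labeled by center ppm; missing cells are empty.
#'
#' @param table Feature table.
#' @param path File path.
#' @return `read_feature_table` returns the table.
#' @export
write_feature_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  feature_table(df[setdiff(names(df), meta_cols)], df[meta_cols])
}
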