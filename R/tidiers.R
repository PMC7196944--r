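#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted PLS-DA model
#'
#' One row per feature and component with the weight, x-loading and VIP
#' score.
#'
#' @param x A [plsda_fit()] model.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.plsda <- function(x, ...) {
  p <- nrow(x$W)
  vip <- vip_scores(x)
  purrr::map_dfr(seq_len(x$A), function(a)
    tibble::tibble(feature = x$feature_names %||% paste0("V", seq_len(p)),
                   component = a, weight = x$W[, a], loading = x$P[, a])) |>
    dplyr::left_join(vip[c("feature", "vip")], by = "feature")
}

#' @rdname tidy.plsda
#' @return `glance` returns a one-row model summary.
#' @export
glance.plsda <- function(x, ...) {
  tibble::tibble(n = nrow(x$Tt), p = nrow(x$W), components = x$A,
                 classes = paste(x$classes, collapse = "/"),
                 ssy_explained = sum(x$q^2 * colSums(x$Tt^2)))
}

#' Tidy PCA results
#' @param x An [pca()] object.
#' @param ... Unused.
#' @return Tibble of per-component explained variance.
#' @export
tidy.nmr_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$explained_variance),
                 variance = x$explained_variance,
                 variance_ratio = x$explained_variance_ratio)
}

#' Tidy a double cross-validation result
#' @param x A [double_cv()] object.
#' @param ... Unused.
#' @return Per-sample predictions tibble.
#' @export
tidy.double_cv <- function(x, ...) x$predictions

#' @rdname tidy.double_cv
#' @export
glance.double_cv <- function(x, ...) {
  tibble::tibble(n = x$n, misclassifications = x$misclassifications,
                 error_rate = x$misclassifications / x$n)
}

#' Tidy a Bland-Altman analysis
#' @param x A [bland_altman()] object.
#' @param ... Unused.
#' @return Per-pair means and differences.
#' @export
tidy.bland_altman <- function(x, ...) x$pairs

#' @rdname tidy.bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_diff = x$sd_diff,
                 lower = x$limits[1], upper = x$limits[2], n = nrow(x$pairs))
}

#' Tidy a repeatability report
#' @param x A [repeatability_rsd()] object.
#' @param ... Unused.
#' @return Per-peak RSD tibble.
#' @export
tidy.repeatability_report <- function(x, ...) x$per_peak

#' @rdname tidy.repeatability_report
#' @export
glance.repeatability_report <- function(x, ...) {
  tibble::tibble(median_rsd = x$median_rsd, n_peaks = nrow(x$per_peak),
                 n_below_cutoff = x$n_below_cutoff,
                 fraction_below_cutoff = x$fraction_below_cutoff,
                 cutoff = x$cutoff)
}
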