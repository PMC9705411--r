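#' Hyperparameter grids for the SVM and random-forest model families
#'
#' Builds the default grid searched during cross-validation. For support
#' vector machines the grid crosses linear and radial-basis kernels with
#' cost C = 2^0..2^5 and (RBF only) gamma = 2^-3..2^3 / 20000; for random
#' forests it crosses ntree in \{500, 1000\} with mtry =
#' round(2^-5..2^5 * sqrt(20000)), clipped to \[1, p\] at fit time.
#' Enumeration order (kernel, then cost, then gamma; ntree, then mtry) is
#' the documented tie-break order for the grid-search argmin.
#'
#' @param family `"svm"` or `"rf"`.
#' @param kernels,cost,gamma SVM grid axes (gamma applies to RBF only).
#' @param ntree,mtry Random-forest grid axes.
#' @return A tibble with one row per hyperparameter combination, columns
#'   `family` plus the family's parameters.
#' @export
hyperparam_grid <- function(family = c("svm", "rf"),
                            kernels = c("linear", "radial"),
                            cost = 2^(0:5),
                            gamma = 2^(-3:3) / 20000,
                            ntree = c(500, 1000),
                            mtry = round(2^(-5:5) * sqrt(20000))) {
  family <- match.arg(family)
  if (family == "svm") {
    grid <- dplyr::bind_rows(purrr::map(kernels, function(k) {
      if (k == "linear") {
        tidyr::expand_grid(kernel = k, cost = cost, gamma = NA_real_)
      } else {
        tidyr::expand_grid(kernel = k, cost = cost, gamma = gamma)
      }
    }))
    dplyr::mutate(grid, family = "svm", .before = 1)
  } else {
    mtry <- pmax(1, as.integer(mtry))
    grid <- tidyr::expand_grid(ntree = ntree, mtry = unique(mtry))
    dplyr::mutate(grid, family = "rf", .before = 1)
  }
}
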