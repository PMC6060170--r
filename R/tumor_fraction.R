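.TF_EXCLUDED <- c("13", "18", "21", "X", "Y")

# Bins usable as tumour-fraction predictors: unmasked autosomal bins not on
# chromosomes 13/18/21 (screened for aneuploidy) or X/Y.
tf_included_bins <- function(grid) {
  bare <- sub("^chr", "", grid$chrom)
  which(!grid$excluded & grid$autosomal & !(bare %in% .TF_EXCLUDED))
}

# Predictor vector: included-bin fractions scaled to relative depth (~1 per
# bin), so the representation is invariant to total read count and to any
# perturbation confined to excluded chromosomes.
tf_predictors <- function(adjusted_counts, included) {
  x <- adjusted_counts[included]
  x / sum(x) * length(included)
}

#' Train the tumour-fraction regression model
#'
#' Ridge-regularized linear regression of known tumour fraction on regional
#' autosomal read depth: predictors are per-bin fractions over the included
#' bins (chromosomes 13, 18, 21, X and Y excluded), solved in closed form
#' via the kernel representation of ridge regression. Deterministic.
#'
#' @param nprofiles List of `normalized_profile`s (GC-adjusted) or a numeric
#'   matrix of adjusted counts (samples in columns).
#' @param fractions Known tumour fractions in [0, 1).
#' @param grid The shared `bin_grid`.
#' @param lambda Ridge regularization strength (> 0; on the scale of the
#'   kernel matrix of relative-depth predictors).
#' @param seed Recorded in the model metadata (the fit itself is
#'   deterministic).
#' @return A `tf_model` with coefficients, intercept, included-bin mask,
#'   training RMSE and metadata.
#' @export
train_tf_model <- function(nprofiles, fractions, grid, lambda = 1, seed = 1L) {
  if (is.list(nprofiles))
    counts <- vapply(nprofiles, `[[`, numeric(nrow(grid)), "adjusted_counts")
  else counts <- nprofiles
  n <- ncol(counts)
  stopifnot(length(fractions) == n, all(fractions >= 0), all(fractions < 1))
  if (n < 3) stop("need at least 3 training samples")
  included <- tf_included_bins(grid)
  X <- t(apply(counts, 2, tf_predictors, included = included))  # n x p
  xbar <- colMeans(X)
  ybar <- mean(fractions)
  Xc <- sweep(X, 2, xbar)
  yc <- fractions - ybar
  Kmat <- tcrossprod(Xc)
  if (lambda <= 0) {
    if (rcond(Kmat) < 1e-12)
      stop("rank-deficient training set with zero regularization; ",
           "use lambda > 0")
  }
  a <- tryCatch(solve(Kmat + lambda * diag(n), yc),
                error = function(e)
                  stop("ridge system is singular; use lambda > 0"))
  coef <- drop(crossprod(Xc, a))
  pred <- drop(Xc %*% coef) + ybar
  rmse <- sqrt(mean((pred - fractions)^2))
  structure(
    list(grid_hash = grid_hash(grid), included = included,
         coef = coef, xbar = xbar, intercept = ybar,
         lambda = lambda, rmse = rmse, n_train = n, seed = as.integer(seed)),
    class = "tf_model")
}

#' @export
print.tf_model <- function(x, ...) {
  cat(sprintf("<tf_model: %d bins, lambda = %g, trained on %d samples, RMSE %.4f>\n",
              length(x$included), x$lambda, x$n_train, x$rmse))
  invisible(x)
}

#' Estimate tumour fraction for a sample
#'
#' Linear prediction from the trained ridge model, clamped to [0, 1); the
#' model's training RMSE rides along as a crude uncertainty.
#'
#' @param model A `tf_model`.
#' @param nprofile A `normalized_profile` (GC-adjusted) on the model's grid,
#'   or a numeric vector of adjusted counts.
#' @param grid The `bin_grid`.
#' @return Estimated fraction with attribute `rmse`.
#' @export
estimate_tumor_fraction <- function(model, nprofile, grid) {
  if (model$grid_hash != grid_hash(grid))
    stop("tumour-fraction model was trained on a different grid")
  counts <- if (inherits(nprofile, "normalized_profile"))
    nprofile$adjusted_counts else nprofile
  x <- tf_predictors(counts, model$included)
  est <- sum((x - model$xbar) * model$coef) + model$intercept
  est <- min(max(est, 0), 1 - .Machine$double.eps)
  attr(est, "rmse") <- model$rmse
  est
}

#' Serialize a tumour-fraction model to JSON
#' @param path Output file.
#' @param model A `tf_model`.
#' @export
write_tf_model <- function(path, model) {
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a tumour-fraction model, refusing a mismatched grid
#' @param path Input file.
#' @param grid The `bin_grid` the model must match.
#' @return A `tf_model`.
#' @export
read_tf_model <- function(path, grid) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$grid_hash, grid_hash(grid)))
    stop("tumour-fraction model was trained on a different grid")
  class(obj) <- "tf_model"
  obj
}
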