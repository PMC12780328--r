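#' Scale a numeric vector without centering
#'
#' Divides by the root-mean-square \eqn{\sqrt{\sum x_i^2 / (n-1)}}, the
#' convention of `scale(x, center = FALSE)`. Covariates entering the model
#' (garden and home MCMT, genomic PCs) are scaled this way so that quadratic
#' and interaction terms are built from comparable columns while zero keeps
#' its meaning (no centering).
#'
#' @param values numeric vector, all finite, length >= 2.
#' @param divisor optional pre-computed divisor (used to apply training-set
#'   scaling to new data).
#' @return list with `scaled` (vector) and `divisor` (scalar).
#' @export
scale_no_center <- function(values, divisor = NULL) {
  if (length(values) < 2 && is.null(divisor)) {
    stop("need at least 2 values to compute a scaling divisor")
  }
  if (any(!is.finite(values))) stop("non-finite values cannot be scaled")
  if (is.null(divisor)) {
    divisor <- sqrt(sum(values^2) / (length(values) - 1))
  }
  if (divisor == 0) stop("all-zero vector: scaling divisor is 0")
  list(scaled = values / divisor, divisor = divisor)
}

#' Transform growth increment to the modeling scale
#'
#' `log(1 + x)` so that the structural zeros of dead trees map to exact
#' zeros (the zero-inflation coding must survive the transform) while
#' right-skewed positive growth is compressed. The inverse is
#' `exp(y) - 1`, floored at zero.
#'
#' @param growth_cm non-negative growth increments (cm).
#' @return transformed response values.
#' @export
transform_growth <- function(growth_cm) {
  if (any(growth_cm < 0, na.rm = TRUE)) {
    stop("negative growth increments must be filtered before transforming")
  }
  log1p(growth_cm)
}

#' Back-transform predictions from the modeling scale to cm
#'
#' @param y values on the transformed (log1p) scale.
#' @return growth in cm, floored at 0.
#' @export
inverse_transform_growth <- function(y) {
  pmax(expm1(y), 0)
}
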