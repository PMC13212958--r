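# Theil-Sen estimator: slope = median of all pairwise slopes, intercept =
# median of the residual offsets under that slope. Resistant to outlying
# separation bins in the delay-versus-distance fit.
theil_sen <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  ij <- utils::combn(length(x), 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  keep <- dx != 0
  if (!any(keep)) stop("all x values identical; slope undefined", call. = FALSE)
  slope <- stats::median(dy[keep] / dx[keep])
  intercept <- stats::median(y - slope * x)
  c(slope = slope, intercept = intercept)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
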