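#' Discretize one gene's expression into three states
#'
#' Mutual-information-based ranking needs discrete inputs; continuous
#' expression is reduced to `low` / `mid` / `high` around the gene's own
#' mean: `low` if `v < mu - sigma`, `high` if `v > mu + sigma`, else `mid`,
#' with `mu`, `sigma` the gene's mean and (n-1 denominator) SD. A constant
#' gene is all `mid`.
#'
#' @param values finite numeric vector (one gene across cells).
#' @return a factor with levels `low`, `mid`, `high`.
#' @export
discretize_gene <- function(values) {
  if (length(values) == 0L) stopf("cannot discretize an empty vector")
  if (!all(is.finite(values))) stopf("values must be finite")
  codes <- discretize_codes(values)
  factor(c("low", "mid", "high")[codes], levels = c("low", "mid", "high"))
}

# integer-coded variant (1=low, 2=mid, 3=high) used in the ranking hot loop
discretize_codes <- function(values) {
  mu <- mean(values)
  sigma <- stats::sd(values)
  codes <- rep.int(2L, length(values))
  if (is.finite(sigma) && sigma > 0) {
    codes[values < mu - sigma] <- 1L
    codes[values > mu + sigma] <- 3L
  }
  codes
}

#' Mutual information of two discrete vectors
#'
#' Plug-in estimate over the observed joint frequency table,
#' `sum p(x,y) log( p(x,y) / (p(x) p(y)) )`, in nats. Symmetric and
#' non-negative; `MI(x, x)` equals the entropy of `x`.
#'
#' @param x,y equal-length vectors (factor, character or integer states).
#' @return non-negative mutual information in nats.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) == 0L) stopf("x and y must be non-empty")
  xi <- as.integer(factor(x))
  yi <- as.integer(factor(y))
  mi_codes(xi, max(xi), yi, max(yi))
}

# MI (nats) on integer codes in 1..kx / 1..ky; no validation
mi_codes <- function(xi, kx, yi, ky) {
  n <- length(xi)
  # joint counts laid out column-major in y so they align with outer(px, py)
  joint <- tabulate((yi - 1L) * kx + xi, nbins = kx * ky)
  px <- tabulate(xi, nbins = kx) / n
  py <- tabulate(yi, nbins = ky) / n
  pj <- joint / n
  nz <- pj > 0
  pxy_ind <- as.vector(outer(px, py))
  sum(pj[nz] * log(pj[nz] / pxy_ind[nz]))
}
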