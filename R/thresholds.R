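#' Automatic intensity thresholds
#'
#' `threshold_otsu` computes Otsu's between-class-variance threshold
#' (via EBImage) on a 256-bin histogram over the image range.
#' `threshold_yen` implements Yen's maximum-correlation criterion on
#' the same binning, the method behind the "Yen" option of common image
#' analysis tools; it is written here because no installed R package
#' exposes it. Both return a value on the intensity scale of the input;
#' for a constant image the threshold is undefined and `NA` is
#' returned.
#'
#' @param img numeric matrix of intensities.
#' @param levels number of histogram bins; default 256.
#' @return Threshold value, or `NA_real_` for a constant image.
#' @export
threshold_otsu <- function(img, levels = 256) {
  rng <- range(img)
  if (diff(rng) <= 1e-8 * max(abs(rng), 1)) return(NA_real_)
  EBImage::otsu(EBImage::Image(img), range = rng, levels = levels)
}

#' @rdname threshold_otsu
#' @export
threshold_yen <- function(img, levels = 256) {
  rng <- range(img)
  if (diff(rng) <= 1e-8 * max(abs(rng), 1)) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = levels + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  idx <- findInterval(img, edges, rightmost.closed = TRUE, all.inside = TRUE)
  h <- tabulate(idx, nbins = levels)
  p <- h / sum(h)
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  P2sq <- rev(cumsum(rev(p)^2))
  i <- seq_len(levels - 1L)
  # maximum-correlation criterion; guards against log(0)
  a <- P1sq[i] * P2sq[i + 1L]
  b <- P1[i] * (1 - P1[i])
  crit <- ifelse(a > 0, -log(a), -Inf) + ifelse(b > 0, 2 * log(b), -Inf)
  centers[which.max(crit)]
}
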