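# BubbleFill baseline removal.
#
# The fluorescence baseline is constructed as the upper envelope of circular
# arcs ("bubbles") grown from below the spectrum until they touch it. Each
# touch point splits its interval in two and the refinement recurses, stopping
# once an interval is narrower than `min_bubble_width`. Wide bubbles cannot
# enter narrow Raman peaks, so peaks survive in the residual while any
# structure broader than the bubble width is absorbed into the baseline. The
# procedure is fully deterministic.

#' BubbleFill baseline estimation
#'
#' Splits a spectrum into a smooth baseline (fluorescence background) and a
#' nonnegative Raman residual. The spectrum is first rescaled so its intensity
#' range matches the axis span (making bubble geometry aspect-ratio
#' invariant); interior bubbles are semicircles of the interval width, edge
#' bubbles are larger-radius arcs anchored at the spectrum boundary so the
#' baseline does not dive at the ends.
#'
#' @param spectrum finite intensity vector.
#' @param axis wavenumber axis (same length, strictly increasing); defaults to
#'   the point index.
#' @param min_bubble_width smallest bubble width (in axis units) that is still
#'   refined; must exceed the axis step. Narrower than any fluorescence
#'   structure, wider than any Raman band: default 100 cm^-1. If it is at
#'   least the full axis span, only the single largest bubble is applied
#'   (degenerate envelope, not an error).
#' @return list with `baseline` and `raman` (`= spectrum - baseline`, >= 0);
#'   `baseline <= spectrum` everywhere within floating-point tolerance.
#' @export
bubblefill <- function(spectrum, axis = seq_along(spectrum),
                       min_bubble_width = 100) {
  n <- length(spectrum)
  if (!all(is.finite(spectrum))) stop("spectrum must be finite")
  if (length(axis) != n) stop("axis and spectrum lengths differ")
  if (n < 3) stop("spectrum too short for baseline estimation")
  if (min_bubble_width <= max(diff(axis))) {
    stop("min_bubble_width must exceed the axis spacing")
  }
  rng <- range(spectrum)
  if (diff(rng) == 0) {
    return(list(baseline = spectrum, raman = numeric(n)))
  }
  span <- axis[n] - axis[1]
  scale <- span / diff(rng)
  y <- (spectrum - rng[1]) * scale
  baseline <- rep(-Inf, n)

  # stack of index intervals; each entry applies one bubble
  stack <- list(c(1L, n))
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    l <- iv[1]; r <- iv[2]
    if (r - l < 2L) next
    xs <- axis[l:r]
    w <- axis[r] - axis[l]
    if (l == 1L && r == n) {
      # initial bubble: infinite radius, i.e. a flat line raised to the minimum
      arc <- numeric(r - l + 1L)
    } else if (l == 1L) {
      # dome topped at the spectrum edge so the baseline does not sag there
      arc <- sqrt(pmax(w^2 - (xs - axis[l])^2, 0))
    } else if (r == n) {
      arc <- sqrt(pmax(w^2 - (xs - axis[r])^2, 0))
    } else {
      radius <- w / 2
      arc <- sqrt(pmax(radius^2 - (xs - (axis[l] + axis[r]) / 2)^2, 0))
    }
    gap <- y[l:r] - arc
    t_rel <- which.min(gap)
    seg <- arc + gap[t_rel]
    baseline[l:r] <- pmax(baseline[l:r], seg)
    t <- l + t_rel - 1L
    # split at the touch point; a touch at an interval end shrinks the
    # interval by one point instead, so every recursion strictly shrinks
    sub <- if (t > l && t < r) {
      list(c(l, t), c(t, r))
    } else if (t == l) {
      list(c(l + 1L, r))
    } else {
      list(c(l, r - 1L))
    }
    for (s in sub) {
      if (axis[s[2]] - axis[s[1]] >= min_bubble_width) {
        stack[[length(stack) + 1L]] <- s
      }
    }
  }
  baseline <- baseline / scale + rng[1]
  baseline <- pmin(baseline, spectrum)
  list(baseline = baseline, raman = spectrum - baseline)
}
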