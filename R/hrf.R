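#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma HRF used throughout event-related fMRI analysis:
#' a positive response peaking at 6 s minus an undershoot peaking at 16 s with
#' a 1/6 amplitude ratio. The returned curve is rescaled to unit peak height
#' so evoked amplitudes are expressed directly in signal units.
#'
#' @param t Numeric vector of times in seconds (values < 0 return 0).
#' @param peak_s Time-to-peak of the positive lobe (shape of the first gamma),
#'   seconds. Default 6.
#' @param undershoot_s Time-to-peak of the undershoot lobe, seconds.
#'   Default 16.
#' @param undershoot_ratio Amplitude ratio undershoot/peak. Default 1/6.
#' @return Numeric vector of HRF values, unit peak height.
#' @examples
#' tt <- seq(0, 32, by = 0.5)
#' h <- canonical_hrf(tt)
#' tt[which.max(h)]  # ~6 s
#' @export
canonical_hrf <- function(t, peak_s = 6, undershoot_s = 16,
                          undershoot_ratio = 1 / 6) {
  stopifnot(peak_s > 0, undershoot_s > 0, undershoot_ratio >= 0)
  h <- function(x) {
    # a rate-1 gamma density with shape a peaks at a - 1, so shape = peak + 1
    stats::dgamma(x, shape = peak_s + 1, rate = 1) -
      undershoot_ratio * stats::dgamma(x, shape = undershoot_s + 1, rate = 1)
  }
  # unit-peak normalisation on a fine grid (peak location is near peak_s - 1
  # for rate-1 gammas but depends on the undershoot; solve numerically once)
  grid <- seq(0, undershoot_s + 16, by = 0.01)
  scale <- max(h(grid))
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- h(t[pos]) / scale
  out
}

#' Duration after which the canonical HRF is treated as fully decayed
#' @keywords internal
hrf_support_s <- function() 32
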