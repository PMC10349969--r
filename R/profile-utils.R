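# Shared profile-likelihood machinery.
#
# Given profile points (x, ll) and a target log-likelihood level, find the x
# where the profile crosses the target on each side of the maximum, by
# quadratic interpolation through the three points nearest the crossing
# (falling back to linear when the quadratic is degenerate or its root falls
# outside the bracket).

profile_crossing <- function(x, ll, target, side = c("lower", "upper")) {
  side <- match.arg(side)
  imax <- which.max(ll)
  if (side == "lower") {
    idx <- seq_len(imax)
  } else {
    idx <- seq.int(imax, length(x))
  }
  xs <- x[idx]; ls <- ll[idx]
  if (side == "lower") { xs <- rev(xs); ls <- rev(ls) }
  # walking away from the maximum, find the first point below target
  below <- which(ls < target)
  if (length(below) == 0) return(NA_real_)   # profile never drops: open side
  j <- below[1]
  if (j == 1) return(xs[1])                  # boundary already below target
  pts <- unique(pmin(pmax(c(j - 2, j - 1, j), 1), length(xs)))
  fit_x <- xs[pts]; fit_l <- ls[pts]
  root <- NA_real_
  if (length(pts) == 3 && length(unique(fit_x)) == 3) {
    co <- try(stats::coef(stats::lm(fit_l ~ fit_x + I(fit_x^2))),
              silent = TRUE)
    if (!inherits(co, "try-error") && is.finite(co[3]) &&
        abs(co[3]) > .Machine$double.eps) {
      disc <- co[2]^2 - 4 * co[3] * (co[1] - target)
      if (disc >= 0) {
        r <- (-co[2] + c(-1, 1) * sqrt(disc)) / (2 * co[3])
        lo <- min(xs[j - 1], xs[j]); hi <- max(xs[j - 1], xs[j])
        r <- r[r >= lo - 1e-12 & r <= hi + 1e-12]
        if (length(r)) root <- r[which.min(abs(r - xs[j - 1]))]
      }
    }
  }
  if (!is.finite(root)) {
    # linear interpolation between the bracketing pair
    root <- xs[j - 1] + (target - ls[j - 1]) *
      (xs[j] - xs[j - 1]) / (ls[j] - ls[j - 1])
  }
  root
}

# logit / inverse-logit with clamping for optimisation transforms
logit <- function(p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  log(p / (1 - p))
}
inv_logit <- function(x) 1 / (1 + exp(-x))
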