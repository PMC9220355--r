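#' Radial distribution function around the copper reference
#'
#' Histograms reference-target distances over all frames under the
#' minimum-image convention (orthorhombic boxes) and normalizes each bin
#' by the ideal-gas expectation `4 * pi * r^2 * dr * rho` per frame, where
#' the bulk density `rho` defaults to N_target / V_box. The result is the
#' dimensionless g(r): the probability of finding a water molecule at
#' distance r from the copper relative to a homogeneous water distribution.
#'
#' @param traj A [traj_frames()] object.
#' @param ref Role tag of the reference atom (exactly one per frame).
#' @param target Role tag of the target atoms (water oxygens; hydrogens
#'   are never counted).
#' @param dr Bin width, Angstrom.
#' @param r_max Histogram range, Angstrom; must not exceed half the
#'   smallest box length for periodic input.
#' @param density Bulk number density, atoms/Angstrom^3. Required for
#'   non-periodic input; for periodic input it defaults to N_target/V.
#' @return Object of class `rdf_profile`: `r` (bin centers), `g`, `counts`,
#'   `dr`, `r_max`, `density`, `n_frames`, `n_target`, plus the selection
#'   description.
#' @export
radial_distribution <- function(traj, ref = "copper", target = "water_oxygen",
                                dr = 0.02, r_max = 8, density = NULL) {
  stopifnot(inherits(traj, "traj_frames"))
  if (!(dr > 0 && r_max > dr)) stop("need dr > 0 and r_max > dr")
  iref <- which(traj$role == ref)
  itar <- which(traj$role == target)
  if (length(iref) != 1L)
    stop("reference selection '", ref, "' must match exactly one atom, got ",
         length(iref))
  if (!length(itar)) stop("no target atoms with role '", target, "'")
  box <- traj$box
  if (!is.null(box)) {
    if (r_max > min(box) / 2 + 1e-12)
      stop("r_max = ", r_max, " exceeds half the smallest box length (",
           min(box) / 2, ")")
    if (is.null(density)) density <- length(itar) / prod(box)
  } else if (is.null(density)) {
    stop("non-periodic trajectory: supply the bulk `density` explicitly")
  }

  nbin <- ceiling(r_max / dr)
  counts <- numeric(nbin)
  for (xyz in traj$coords) {
    d <- xyz[itar, , drop = FALSE] -
      matrix(xyz[iref, ], nrow = length(itar), ncol = 3L, byrow = TRUE)
    if (!is.null(box)) {
      for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    }
    r <- sqrt(rowSums(d * d))
    r <- r[r < r_max]
    if (length(r))
      counts <- counts + tabulate(pmin(floor(r / dr) + 1L, nbin), nbins = nbin)
  }
  centers <- (seq_len(nbin) - 0.5) * dr
  shell_vol <- 4 * pi * centers^2 * dr
  g <- counts / (length(traj$coords) * shell_vol * density)
  structure(list(r = centers, g = g, counts = counts, dr = dr,
                 r_max = r_max, density = density,
                 n_frames = length(traj$coords), n_target = length(itar),
                 ref = ref, target = target),
            class = "rdf_profile")
}

#' @export
print.rdf_profile <- function(x, ...) {
  cat(sprintf(
    "rdf_profile: %s -> %s, %d bins (dr = %g A, r_max = %g A), %d frames, rho = %.4g /A^3\n",
    x$ref, x$target, length(x$r), x$dr, x$r_max, x$n_frames, x$density))
  invisible(x)
}

#' Hydration-shell coordination number
#'
#' Integrates `4 * pi * rho * g(r) * r^2` over a shell by trapezoidal
#' quadrature on the binned profile: the mean number of target molecules
#' between the bounds.
#'
#' @param profile An [radial_distribution()] result.
#' @param bounds Numeric `c(r_lo, r_hi)`, Angstrom, within the profile.
#' @return Coordination number (waters).
#' @export
shell_coordination <- function(profile, bounds) {
  stopifnot(inherits(profile, "rdf_profile"), length(bounds) == 2L)
  if (bounds[1] >= bounds[2]) stop("inverted shell bounds")
  if (bounds[1] < 0 || bounds[2] > profile$r_max + profile$dr / 2)
    stop("shell bounds outside profile range")
  keep <- profile$r > bounds[1] & profile$r < bounds[2]
  if (sum(keep) < 2L) stop("fewer than 2 profile bins inside bounds")
  # trapezoid over the bin centers, with the exact bounds appended as grid
  # points (g held at the nearest-bin value) so no half-bin mass is lost
  r <- c(bounds[1], profile$r[keep], bounds[2])
  g <- stats::approx(profile$r, profile$g, xout = r, rule = 2)$y
  y <- g * r^2
  integral <- sum(diff(r) * (y[-1] + y[-length(y)]) / 2)
  4 * pi * profile$density * integral
}

#' Locate hydration shells in an RDF profile
#'
#' Smooths g(r) with a centered moving average and reports the first two
#' peaks and the minimum following each, plus per-shell coordination
#' numbers (first shell integrated from the profile start to the first
#' minimum, second shell between the two minima). With fewer than two
#' detectable peaks only the first shell is reported and the result is
#' flagged; a featureless profile is flagged `"no shells"`.
#'
#' @param profile An [radial_distribution()] result.
#' @param window Moving-average window, bins (odd; default 5).
#' @param min_height Peaks below this fraction of the profile maximum are
#'   ignored (default 0.2).
#' @return List of class `shell_report`: `peak1`, `min1`, `peak2`, `min2`
#'   (radii, Angstrom; `NA` where absent), `n_shell1`, `n_shell2`, `flag`.
#' @export
find_shells <- function(profile, window = 5, min_height = 0.2) {
  stopifnot(inherits(profile, "rdf_profile"))
  if (!length(profile$g)) stop("empty profile")
  w <- max(1L, as.integer(window))
  if (w %% 2L == 0L) w <- w + 1L
  s <- as.numeric(stats::filter(profile$g, rep(1 / w, w), sides = 2))
  # extend the ends with the nearest defined value so the window edge
  # cannot fabricate a spurious rise
  def <- which(!is.na(s))
  if (!length(def)) return(structure(list(
    peak1 = NA_real_, min1 = NA_real_, peak2 = NA_real_, min2 = NA_real_,
    n_shell1 = NA_real_, n_shell2 = NA_real_, flag = "no shells"),
    class = "shell_report"))
  s[seq_len(def[1] - 1L)] <- s[def[1]]
  last <- def[length(def)]
  if (last < length(s)) s[(last + 1L):length(s)] <- s[last]
  r <- profile$r
  n <- length(s)
  thr <- min_height * max(s)

  # local maxima of the smoothed profile, merged within one window
  cand <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n]) + 1L
  cand <- cand[s[cand] >= thr]
  peaks <- integer()
  for (i in cand) {
    if (length(peaks) && i - peaks[length(peaks)] <= w) {
      if (s[i] > s[peaks[length(peaks)]]) peaks[length(peaks)] <- i
    } else peaks <- c(peaks, i)
  }
  # two maxima separated by a dip shallower than 20% of the lower one are
  # sampling noise on a single feature (or the bulk plateau), not two
  # shells: keep only the higher
  if (length(peaks) > 1L) {
    kept <- peaks[1]
    for (p in peaks[-1]) {
      prev <- kept[length(kept)]
      valley <- min(s[prev:p])
      if (valley >= 0.8 * min(s[prev], s[p])) {
        if (s[p] > s[prev]) kept[length(kept)] <- p
      } else kept <- c(kept, p)
    }
    peaks <- kept
  }

  empty <- list(peak1 = NA_real_, min1 = NA_real_, peak2 = NA_real_,
                min2 = NA_real_, n_shell1 = NA_real_, n_shell2 = NA_real_,
                flag = "no shells")
  if (!length(peaks)) return(structure(empty, class = "shell_report"))

  min_after <- function(from, to) {
    idx <- from:to
    idx[which.min(s[idx])]
  }
  # sub-bin peak position by quadratic interpolation through the three
  # bins around the smoothed maximum
  refine <- function(p) {
    if (p <= 1L || p >= n) return(r[p])
    denom <- s[p - 1L] - 2 * s[p] + s[p + 1L]
    if (denom >= 0) return(r[p])
    off <- 0.5 * (s[p - 1L] - s[p + 1L]) / denom
    r[p] + max(-0.5, min(0.5, off)) * profile$dr
  }
  # first local minimum after index i (trough of the smoothed curve);
  # falls back to the argmin up to `to` when the curve only decays
  first_min_after <- function(i, to) {
    if (i + 1L >= to) return(min_after(i, to))
    for (j in (i + 1L):(to - 1L))
      if (s[j] <= s[j - 1L] && s[j] < s[j + 1L]) return(j)
    min_after(i, to)
  }
  p1 <- peaks[1]
  if (length(peaks) >= 2L) {
    p2 <- peaks[2]
    m1 <- min_after(p1, p2)
    nxt <- if (length(peaks) >= 3L) peaks[3] else n
    m2 <- first_min_after(p2, nxt)
    rep <- list(peak1 = refine(p1), min1 = r[m1], peak2 = refine(p2),
                min2 = r[m2],
                n_shell1 = shell_coordination(profile, c(r[1], r[m1])),
                n_shell2 = shell_coordination(profile, c(r[m1], r[m2])),
                flag = "ok")
  } else {
    m1 <- min_after(p1, n)
    rep <- list(peak1 = refine(p1), min1 = r[m1], peak2 = NA_real_,
                min2 = NA_real_,
                n_shell1 = shell_coordination(profile, c(r[1], r[m1])),
                n_shell2 = NA_real_, flag = "first shell only")
  }
  structure(rep, class = "shell_report")
}

#' @export
print.shell_report <- function(x, ...) {
  cat(sprintf(
    "shells: peak1 %.2f A (min %.2f, n = %.2f), peak2 %.2f A (min %.2f, n = %.2f) [%s]\n",
    x$peak1, x$min1, x$n_shell1, x$peak2, x$min2, x$n_shell2, x$flag))
  invisible(x)
}
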