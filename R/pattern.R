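#' Radially averaged power spectrum of a field
#'
#' Removes the field mean, takes the 2-D discrete Fourier transform, and
#' accumulates the spectral power into isotropic annular bins of width
#' `2 * pi / L` (the domain's wavenumber quantum), `L = n * dx`.  Wavenumbers
#' are in radians per dimensionless length, matching the bifurcation and
#' Floquet modules.
#'
#' @param field Numeric matrix (square grid).
#' @param dx Grid spacing.
#' @return List with `k` (bin centers, starting at 0), `power` (summed power
#'   per bin) and `bin_width`.
#' @examples
#' x <- seq(0, by = 0.25, length.out = 128)
#' f <- outer(x, x, function(x, y) cos(1.2 * x))
#' rps <- radial_power_spectrum(f, 0.25)
#' rps$k[which.max(rps$power[-1]) + 1]  # ~1.2 within one bin
#' @export
radial_power_spectrum <- function(field, dx) {
  stopifnot(is.matrix(field), all(is.finite(field)), dx > 0)
  n1 <- nrow(field)
  n2 <- ncol(field)
  P <- Mod(stats::fft(field - mean(field)))^2
  kx <- fft_wavenumbers(n1, dx)
  ky <- fft_wavenumbers(n2, dx)
  kmag <- sqrt(outer(kx^2, ky^2, "+"))
  dk <- 2 * pi / (max(n1, n2) * dx)
  bin <- as.integer(round(kmag / dk))
  nb <- max(bin) + 1L
  power <- vapply(0:(nb - 1L), function(j) sum(P[bin == j]), numeric(1))
  list(k = (0:(nb - 1L)) * dk, power = power, bin_width = dk)
}

# signed angular frequencies of an n-point DFT with spacing dx
fft_wavenumbers <- function(n, dx) {
  m <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  2 * pi * m / (n * dx)
}

# dominant nonzero-bin wavenumber of a spectrum from radial_power_spectrum
dominant_wavenumber <- function(rps) {
  if (length(rps$power) < 2L) return(0)
  j <- which.max(rps$power[-1])
  rps$k[j + 1L]
}

# concentration of ring power in a single orientation (angles mod pi);
# close to 1 for stripes, ~1/3 for a hexagonal three-mode planform
angular_concentration <- function(field, dx, k_dom, dk, nbins = 12L) {
  n1 <- nrow(field)
  n2 <- ncol(field)
  P <- Mod(stats::fft(field - mean(field)))^2
  kx <- fft_wavenumbers(n1, dx)
  ky <- fft_wavenumbers(n2, dx)
  kxm <- matrix(kx, n1, n2)
  kym <- matrix(ky, n1, n2, byrow = TRUE)
  kmag <- sqrt(kxm^2 + kym^2)
  ring <- abs(kmag - k_dom) <= dk / 2 & kmag > 0
  if (!any(ring)) return(0)
  theta <- atan2(kym[ring], kxm[ring]) %% pi
  w <- P[ring]
  bins <- pmin(nbins, 1L + floor(theta / pi * nbins))
  tot <- sum(w)
  if (tot <= 0) return(0)
  max(vapply(seq_len(nbins), function(b) sum(w[bins == b]), numeric(1))) / tot
}

# third standardized moment of the field values
field_skewness <- function(field) {
  x <- as.vector(field)
  s <- stats::sd(x)
  if (s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

#' Classify a snapshot sequence
#'
#' Assigns one of the qualitative state labels: `homogeneous-steady`,
#' `homogeneous-oscillatory`, `spots`, `stripes`, `mixed` or `irregular`.  A
#' state is homogeneous when the spatial standard deviation of the final
#' frame falls below `1e-3` times the field's amplitude scale; homogeneous
#' states are split by the temporal standard deviation at 16 fixed probe
#' points across the frames.  Patterned states are labelled spots when the
#' field distribution is strongly asymmetric (|skewness| above
#' `skew_threshold`; hexagonal planforms are asymmetric about the mean),
#' stripes when instead a single spectral orientation dominates, `irregular`
#' when no sharp spectral ring exists, and `mixed` otherwise.
#'
#' @param snapshots List of [field_state()] objects (at least 2), time
#'   ordered; classification statistics use the activator field `u`.
#' @param dx Grid spacing.
#' @param eps_scale Homogeneity threshold as a fraction of the amplitude
#'   scale (default 1e-3), applied to both spatial and temporal spread.
#' @param skew_threshold Spots discriminator on |skewness| (default 0.3).
#' @param angular_threshold Stripes discriminator on the angular spectral
#'   concentration (default 0.6).
#' @return An object of class `pattern_report`: list with `label`,
#'   `dominant_k` (0 for homogeneous states), `spatial_sd`, `temporal_sd`,
#'   `skewness`, `angular_concentration` and `bin_width`.
#' @export
classify_pattern <- function(snapshots, dx, eps_scale = 1e-3,
                             skew_threshold = 0.3, angular_threshold = 0.6) {
  if (!is.list(snapshots) || length(snapshots) < 2L)
    stop("need at least 2 snapshots to classify")
  if (!all(vapply(snapshots, inherits, logical(1), "field_state")))
    stop("'snapshots' must be a list of field_state objects")
  last <- snapshots[[length(snapshots)]]$u
  scale <- max(1, abs(mean(last)))
  eps <- eps_scale * scale
  spatial_sd <- stats::sd(as.vector(last))
  # temporal spread at a fixed 4 x 4 probe grid across all frames
  pi_idx <- unique(pmax(1L, round(seq(1, nrow(last), length.out = 4L))))
  pj_idx <- unique(pmax(1L, round(seq(1, ncol(last), length.out = 4L))))
  probes <- vapply(snapshots, function(s) as.vector(s$u[pi_idx, pj_idx]),
                   numeric(length(pi_idx) * length(pj_idx)))
  temporal_sd <- mean(apply(probes, 1L, stats::sd))
  skew <- field_skewness(last)

  if (spatial_sd < eps) {
    label <- if (temporal_sd < eps) "homogeneous-steady"
             else "homogeneous-oscillatory"
    return(pattern_report(label, 0, spatial_sd, temporal_sd, skew, NA_real_,
                          2 * pi / (max(dim(last)) * dx)))
  }
  rps <- radial_power_spectrum(last, dx)
  k_dom <- dominant_wavenumber(rps)
  ang <- angular_concentration(last, dx, k_dom, rps$bin_width)
  nz <- rps$power[-1]
  peak_sharp <- max(nz) > 0.5 * sum(nz)  # one ring carries most power
  label <- if (!peak_sharp) "irregular"
           else if (abs(skew) > skew_threshold) "spots"
           else if (ang > angular_threshold) "stripes"
           else "mixed"
  pattern_report(label, k_dom, spatial_sd, temporal_sd, skew, ang,
                 rps$bin_width)
}

pattern_report <- function(label, dominant_k, spatial_sd, temporal_sd,
                           skewness, angular, bin_width) {
  structure(list(label = label, dominant_k = dominant_k,
                 spatial_sd = spatial_sd, temporal_sd = temporal_sd,
                 skewness = skewness, angular_concentration = angular,
                 bin_width = bin_width),
            class = "pattern_report")
}

#' @export
print.pattern_report <- function(x, ...) {
  cat(sprintf(paste0("Pattern report: %s (dominant k = %.3g, spatial sd = ",
                     "%.3g, temporal sd = %.3g, skew = %.3g)\n"),
              x$label, x$dominant_k, x$spatial_sd, x$temporal_sd,
              x$skewness))
  invisible(x)
}

#' Is a pattern report patterned?
#'
#' `TRUE` for the spatially structured labels (spots, stripes, mixed,
#' irregular), `FALSE` for homogeneous states.
#'
#' @param report A `pattern_report`.
#' @return Logical.
#' @export
is_patterned <- function(report) {
  stopifnot(inherits(report, "pattern_report"))
  !(report$label %in% c("homogeneous-steady", "homogeneous-oscillatory"))
}

#' Wavelength locking across protocol stages
#'
#' `TRUE` when the dominant wavenumbers of three patterned reports (before,
#' during and after a forcing stage) agree within `tol_bins` spectral bins —
#' the hysteresis signature that the forcing changed the pattern's existence
#' but not its wavelength.
#'
#' @param before,during,after `pattern_report` objects; all must be
#'   patterned, otherwise locking is undefined and an error is raised.  A
#'   protocol that starts homogeneous (pattern induced by the forcing) has no
#'   pre-forcing wavelength: pass `before = NULL` to compare only the forced
#'   and post-forcing stages.
#' @param tol_bins Agreement tolerance in units of the spectral bin width.
#' @return Logical.
#' @export
wavelength_locked <- function(before, during, after, tol_bins = 1) {
  reports <- list(before, during, after)
  reports <- reports[!vapply(reports, is.null, logical(1))]
  stopifnot(all(vapply(reports, inherits, logical(1), "pattern_report")))
  if (!all(vapply(reports, is_patterned, logical(1))))
    stop("wavelength locking is undefined for homogeneous reports")
  ks <- vapply(reports, function(r) r$dominant_k, numeric(1))
  bw <- max(vapply(reports, function(r) r$bin_width, numeric(1)))
  max(ks) - min(ks) <= tol_bins * bw + 1e-12
}
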