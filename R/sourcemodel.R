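# Forward model (toy spherical geometry or user-supplied gain), dSPM
# minimum-norm inverse with identity noise covariance, and collapse of
# dipole signals to parcel means.

# Fibonacci lattice on the upper hemisphere (z >= z_min), radius r.
fibonacci_hemisphere <- function(n, r = 1, z_min = 0.05) {
  golden <- (1 + sqrt(5)) / 2
  i <- seq_len(n) - 0.5
  z <- z_min + (1 - z_min) * (i / n)       # upper cap only
  theta <- 2 * pi * i * golden
  rho <- sqrt(pmax(0, 1 - z^2))
  r * cbind(x = rho * cos(theta), y = rho * sin(theta), z = z)
}

# Surface potential of a radial dipole inside a homogeneous conducting
# sphere (insulating exterior), via the Legendre series
#   V(R, theta) = p / (4 pi sigma R^2) * sum_n (2n+1) f^(n-1) P_n(cos theta),
# f = b / R the relative dipole depth.  cosang: sensors x sources matrix
# of cos(angle between sensor and source directions); f: per-source.
sphere_gain <- function(cosang, f, R = 1, sigma = 0.33, nmax = 100) {
  ns <- nrow(cosang); nd <- ncol(cosang)
  P <- legendre_table(pmin(1, pmax(-1, as.vector(cosang))), nmax)
  G <- matrix(0, ns, nd)
  n <- seq_len(nmax)
  for (j in seq_len(nd)) {
    coef <- (2 * n + 1) * f[j]^(n - 1)
    G[, j] <- P[(j - 1) * ns + seq_len(ns), , drop = FALSE] %*% coef
  }
  G / (4 * pi * sigma * R^2)
}

#' Build a toy spherical lead-field bundle
#'
#' Desk-scale stand-in for an MRI/BEM head model: sensors on the upper
#' unit hemisphere, radially oriented dipoles on an inner shell with
#' slightly varying depth, gain from the analytic homogeneous-sphere
#' solution, parcels as contiguous angular patches (k-means on dipole
#' positions), and region labels (`F`/`C`/`T`/`O` x `left`/`right`)
#' assigned from each parcel centroid's position.  Conductivities for the
#' intracranial / skull / scalp compartments are carried as metadata for
#' user-supplied models.
#'
#' @param n_sensors number of sensors (>= 8).
#' @param n_sources number of dipoles (>= n_parcels).
#' @param n_parcels number of parcels (>= 2).
#' @param seed integer seed (parcellation and dipole depths).
#' @param identity if `TRUE`, returns the identity bundle: one sensor per
#'   source, one source per parcel, unit gain (requires
#'   `n_sensors == n_sources == n_parcels`).  The source stage is then a
#'   null transformation, which is used as a pipeline self-test.
#' @return a `lead_field_bundle`: `gain` (sensors x sources),
#'   `sensor_pos`, `source_pos`, `orientations`, `parcel_map`,
#'   `centroids`, `regions` (data.frame `region`, `hemisphere`),
#'   `conductivities`, `n_parcels`.
#' @export
make_toy_bundle <- function(n_sensors = 64, n_sources = 1024, n_parcels = 58,
                            seed = 1, identity = FALSE) {
  stopifnot(n_sources >= n_parcels, n_parcels >= 2)
  if (!identity && n_sensors < 8) stop("n_sensors must be >= 8")
  conduct <- c(intracranial = 1.79, skull = 0.1, scalp = 0.43)
  if (identity) {
    if (!(n_sensors == n_sources && n_sources == n_parcels))
      stop("identity bundle requires n_sensors == n_sources == n_parcels")
    pos <- fibonacci_hemisphere(n_sensors)
    bundle <- list(gain = diag(n_sensors), sensor_pos = pos,
                   source_pos = 0.8 * pos, orientations = pos,
                   parcel_map = seq_len(n_parcels),
                   centroids = 0.8 * pos,
                   regions = region_labels(pos),
                   conductivities = conduct, n_parcels = n_parcels)
    return(structure(bundle, class = "lead_field_bundle"))
  }
  with_seed(seed, {
    sens <- fibonacci_hemisphere(n_sensors, r = 1)
    dirs <- fibonacci_hemisphere(n_sources, r = 1)
    depth <- runif(n_sources, 0.6, 0.85)       # dipole radius (unit head)
    src <- dirs * depth
    cosang <- tcrossprod(sens, dirs)           # unit vectors: cos(angle)
    gain <- sphere_gain(cosang, f = depth)
    km <- kmeans(dirs, centers = n_parcels, nstart = 5, iter.max = 50)
    # guard against the (rare) empty cluster
    if (any(tabulate(km$cluster, n_parcels) == 0))
      stop("empty parcel in toy parcellation; change seed or counts")
    centroids <- rowsum(src, km$cluster) / as.vector(table(km$cluster))
    bundle <- list(gain = gain, sensor_pos = sens, source_pos = src,
                   orientations = dirs, parcel_map = km$cluster,
                   centroids = centroids,
                   regions = region_labels(centroids),
                   conductivities = conduct, n_parcels = n_parcels)
    structure(bundle, class = "lead_field_bundle")
  })
}

# Region labels from positions: hemisphere by x sign; frontal / occipital
# by y (anterior-posterior), central (superior) / temporal (inferior) in
# the mid zone.
region_labels <- function(pos) {
  y <- pos[, 2] / sqrt(rowSums(pos^2))
  z <- pos[, 3] / sqrt(rowSums(pos^2))
  region <- ifelse(y > 0.35, "F",
            ifelse(y < -0.35, "O",
            ifelse(z > 0.55, "C", "T")))
  data.frame(region = region,
             hemisphere = ifelse(pos[, 1] < 0, "left", "right"))
}

#' @export
print.lead_field_bundle <- function(x, ...) {
  cat(sprintf("<lead_field_bundle> %d sensors, %d sources, %d parcels\n",
              nrow(x$gain), ncol(x$gain), x$n_parcels))
  invisible(x)
}

#' Compute a dSPM minimum-norm inverse operator
#'
#' Minimum-norm kernel `K = G' (G G' + lambda I)^-1` with identity noise
#' covariance and no depth prior, plus the dSPM per-source normalization
#' `sqrt(diag(K K'))`.  The default regularization follows the SNR rule
#' `lambda = trace(G G') / (n_sensors * snr^2)`.
#'
#' @param bundle a `lead_field_bundle`.
#' @param lambda regularization; `NULL` uses the SNR rule.
#' @param snr assumed amplitude SNR for the default `lambda`.
#' @return an `inverse_operator`: `kernel` (sources x sensors),
#'   `dspm_norm`, `lambda`.
#' @export
compute_inverse_operator <- function(bundle, lambda = NULL, snr = 3) {
  stopifnot(inherits(bundle, "lead_field_bundle"))
  G <- bundle$gain
  ns <- nrow(G)
  GG <- tcrossprod(G)
  if (is.null(lambda)) lambda <- sum(diag(GG)) / (ns * snr^2)
  if (lambda <= 0) stop("lambda must be positive")
  A <- GG + lambda * diag(ns)
  cn <- kappa(A, exact = FALSE)
  if (!is.finite(cn) || cn > 1e12)
    stop(sprintf("inverse system ill-conditioned (condition number %.3g)", cn))
  kernel <- t(solve(A, G))            # G' A^-1
  dspm <- sqrt(rowSums(kernel^2))     # sqrt(diag(K C K')), C = I
  if (any(dspm <= 0)) dspm[dspm <= 0] <- min(dspm[dspm > 0])
  structure(list(kernel = kernel, dspm_norm = dspm, lambda = lambda),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("<inverse_operator> %d sources x %d sensors, lambda = %.4g\n",
              nrow(x$kernel), ncol(x$kernel), x$lambda))
  invisible(x)
}

#' Reconstruct source signals from sensor data
#'
#' Applies the minimum-norm kernel (optionally with dSPM normalization)
#' to an average-referenced, band-filtered recording.  Linear in the
#' data; the segment structure is preserved.
#'
#' @param rec an [eeg_recording()] (or plain channels x samples matrix).
#' @param inv an `inverse_operator`.
#' @param dspm apply the per-source dSPM normalization.
#' @return sources x samples matrix (with the recording's segments as
#'   attribute `"segments"` when the input is a recording).
#' @export
reconstruct_sources <- function(rec, inv, dspm = TRUE) {
  stopifnot(inherits(inv, "inverse_operator"))
  data <- if (inherits(rec, "eeg_recording")) rec$data else as.matrix(rec)
  if (ncol(inv$kernel) != nrow(data))
    stop(sprintf("kernel expects %d channels, recording has %d",
                 ncol(inv$kernel), nrow(data)))
  src <- inv$kernel %*% data
  if (dspm) src <- src / inv$dspm_norm
  if (inherits(rec, "eeg_recording")) attr(src, "segments") <- rec$segments
  src
}

#' Collapse dipole signals to parcel means
#'
#' Each parcel signal is the arithmetic mean of its member dipole time
#' courses.
#'
#' @param sources sources x samples matrix.
#' @param bundle the `lead_field_bundle` defining the parcel assignment.
#' @return parcels x samples matrix (segments attribute passed through).
#' @export
collapse_to_parcels <- function(sources, bundle) {
  stopifnot(inherits(bundle, "lead_field_bundle"))
  if (nrow(sources) != length(bundle$parcel_map))
    stop("source count does not match bundle")
  counts <- tabulate(bundle$parcel_map, bundle$n_parcels)
  if (any(counts == 0)) stop("empty parcel in bundle")
  out <- rowsum(sources, bundle$parcel_map) / counts
  attr(out, "segments") <- attr(sources, "segments")
  out
}

#' Precompute the sensor-to-parcel linear map
#'
#' The whole sensor -> source -> parcel chain is one linear map; this
#' returns the parcels x sensors matrix (collapse composed with the
#' kernel, including dSPM normalization), used by the fidelity module to
#' avoid repeating the chain per iteration.
#'
#' @param bundle a `lead_field_bundle`.
#' @param inv an `inverse_operator` for that bundle.
#' @param dspm apply dSPM normalization.
#' @return parcels x sensors matrix.
#' @export
parcel_operator <- function(bundle, inv, dspm = TRUE) {
  K <- inv$kernel
  if (dspm) K <- K / inv$dspm_norm
  counts <- tabulate(bundle$parcel_map, bundle$n_parcels)
  rowsum(K, bundle$parcel_map) / counts
}
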