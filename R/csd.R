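#' Laminar LFP container
#'
#' LFP responses recorded along a linear probe: one row per contact, ordered
#' superficial to deep, with uniform contact spacing.
#'
#' @param phi Matrix (channels x time) of potentials in uV.
#' @param depths_um Contact depths in micrometres, strictly increasing and
#'   uniformly spaced.
#' @param fs Sample rate in Hz (optional, for time labelling).
#' @return A `laminar_lfp` object.
#' @export
laminar_lfp <- function(phi, depths_um, fs = NULL) {
  phi <- as.matrix(phi)
  stopifnot(nrow(phi) == length(depths_um), nrow(phi) >= 2)
  sp <- diff(depths_um)
  if (any(sp <= 0) || diff(range(sp)) > 1e-6 * mean(sp)) {
    stop("contact depths must be strictly increasing and uniformly spaced")
  }
  out <- list(phi = phi, depths_um = as.numeric(depths_um),
              spacing_um = mean(sp), fs = fs)
  class(out) <- "laminar_lfp"
  out
}

#' Electrostatic forward matrix for delta-source inverse CSD
#'
#' Builds the forward solution P of the delta-source inverse CSD method:
#' current is assumed to originate in thin disks of diameter `disk_um`
#' centred on each contact plane, in a homogeneous isotropic medium of
#' conductivity `sigma`. The potential at contact j from a unit planar
#' source density at contact i is
#' `P[j, i] = h / (2 * sigma) * (sqrt((z_j - z_i)^2 + R^2) - |z_j - z_i|)`
#' with R the disk radius and h the contact spacing (the per-contact source
#' thickness). P is symmetric positive definite with entries decaying in
#' `|z_j - z_i|`; potentials relate to sources by `phi = P %*% C`, inverted
#' as `C_hat = solve(P, phi)`.
#'
#' @param depths_um Contact depths (um), uniformly spaced.
#' @param sigma Extracellular conductivity in S/m (default 0.3).
#' @param disk_um Source disk diameter in um (default 250, radius 125 um).
#' @return A `csd_forward_model`: list with `P` (channels x channels),
#'   `depths_um`, `sigma`, `disk_um`, `spacing_um`.
#' @export
build_forward_matrix <- function(depths_um, sigma = 0.3, disk_um = 250) {
  stopifnot(length(depths_um) >= 2, sigma > 0, disk_um > 0)
  sp <- diff(depths_um)
  if (any(sp <= 0) || diff(range(sp)) > 1e-6 * mean(sp)) {
    stop("contact depths must be strictly increasing and uniformly spaced")
  }
  z <- depths_um * 1e-6
  h <- mean(sp) * 1e-6
  r <- disk_um / 2 * 1e-6
  dz <- abs(outer(z, z, "-"))
  P <- h / (2 * sigma) * (sqrt(dz^2 + r^2) - dz)
  fm <- list(P = P, depths_um = as.numeric(depths_um), sigma = sigma,
             disk_um = disk_um, spacing_um = mean(sp))
  class(fm) <- "csd_forward_model"
  fm
}

#' Estimate current source density from laminar LFPs
#'
#' Inverts the delta-source forward model column-by-column over time:
#' `C_hat = P^-1 %*% phi`. Negative values are current sinks (net inward
#' membrane current, synaptic activity), positive values sources. The
#' estimate is linear in the potentials, and scales inversely with the
#' assumed conductivity - changing `sigma` rescales the CSD identically on
#' every channel, leaving the spatial pattern used for layer assignment
#' untouched.
#'
#' @param lfp A [laminar_lfp()].
#' @param fm A [build_forward_matrix()] with matching channel count.
#' @return A `csd_profile`: list with `csd` (channels x time), `depths_um`,
#'   `spacing_um`, `fs`.
#' @export
estimate_csd <- function(lfp, fm) {
  stopifnot(inherits(lfp, "laminar_lfp"), inherits(fm, "csd_forward_model"))
  if (nrow(lfp$phi) != nrow(fm$P)) {
    stop("channel count of LFP and forward model differ")
  }
  C <- solve(fm$P, lfp$phi)
  out <- list(csd = C, depths_um = lfp$depths_um,
              spacing_um = lfp$spacing_um, fs = lfp$fs)
  class(out) <- "csd_profile"
  out
}

#' Locate the layer 1 - layer 2/3 polarity reversal
#'
#' The most prominent landmark of the evoked CSD is the polarity reversal at
#' the border of layers 1 and 2/3. This routine finds the most superficial
#' pair of adjacent channels whose mean CSD within an early post-stimulus
#' window changes sign, with both magnitudes above a noise floor, and
#' returns the midpoint depth as the border. The default floor is twice the
#' SD of the pre-stimulus CSD when baseline columns are supplied.
#'
#' @param csd A `csd_profile` from [estimate_csd()].
#' @param window Column indices of the early response window (e.g. 5-30 ms
#'   post-stimulus).
#' @param baseline Column indices of a pre-stimulus window used for the
#'   noise floor, or `NULL`.
#' @param noise_floor Explicit magnitude floor; overrides `baseline`.
#'   Defaults to 0 when neither is given.
#' @return Border depth in um (midpoint of the qualifying channel pair),
#'   with attribute `channel_pair`.
#' @export
find_reversal_depth <- function(csd, window, baseline = NULL,
                                noise_floor = NULL) {
  stopifnot(inherits(csd, "csd_profile"))
  n_time <- ncol(csd$csd)
  stopifnot(all(window >= 1), all(window <= n_time))
  m <- rowMeans(csd$csd[, window, drop = FALSE])
  if (is.null(noise_floor)) {
    noise_floor <- if (is.null(baseline)) 0 else {
      2 * stats::sd(as.numeric(csd$csd[, baseline]))
    }
  }
  for (i in seq_len(length(m) - 1L)) {
    if (sign(m[i]) != 0 && sign(m[i + 1]) != 0 &&
        sign(m[i]) != sign(m[i + 1]) &&
        abs(m[i]) > noise_floor && abs(m[i + 1]) > noise_floor) {
      border <- (csd$depths_um[i] + csd$depths_um[i + 1]) / 2
      attr(border, "channel_pair") <- c(i, i + 1L)
      return(border)
    }
  }
  stop("no reversal found: no adjacent channel pair changes sign above the noise floor")
}

#' Assign cortical layers from depth below the L1-L2/3 border
#'
#' Maps depth below the layer 1 - layer 2/3 border to a cortical layer using
#' published laminar thicknesses: `[0, 225)` um is layer 2/3, `[225, 425)`
#' layer 4, `[425, 675)` layer 5 and `>= 675` layer 6 (half-open intervals).
#' Negative depths lie above the border, in layer 1, and are excluded from
#' laminar analyses.
#'
#' @param depth_below_border_um Depth(s) in um below the border.
#' @param bounds Increasing layer boundaries in um (defaults
#'   `c(225, 425, 675)`).
#' @return Factor with levels `"1"`, `"2/3"`, `"4"`, `"5"`, `"6"`.
#' @export
assign_layer <- function(depth_below_border_um, bounds = c(225, 425, 675)) {
  stopifnot(all(is.finite(depth_below_border_um)), length(bounds) == 3,
            all(diff(bounds) > 0))
  labels <- c("1", "2/3", "4", "5", "6")
  idx <- findInterval(depth_below_border_um, c(0, bounds)) + 1L
  factor(labels[idx], levels = labels)
}
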