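#' Standard error of a Bernoulli trial
#'
#' \eqn{\sqrt{p(1-p)/n}}, the error convention used throughout the
#' package's contact and propensity statistics.
#'
#' @param p Probability (vector or matrix) in \eqn{[0, 1]}.
#' @param n Effective sample size, at least 1. For replica-exchange
#'   ensembles this is typically the number of replicas times the mean
#'   number of temperature roundtrips per replica (see
#'   \code{\link{effective_samples}}).
#' @return Standard error(s), same shape as \code{p}.
#' @export
bernoulli_se <- function(p, n) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), all(n >= 1))
  sqrt(p * (1 - p) / n)
}

#' Effective sample size of a replica-exchange ensemble
#'
#' The product of the replica count and the mean number of temperature
#' roundtrips per replica.
#'
#' @param n_replicas Number of replicas.
#' @param mean_roundtrips Mean roundtrips per replica.
#' @return Effective n (>= 1 enforced).
#' @export
effective_samples <- function(n_replicas, mean_roundtrips) {
  n <- n_replicas * mean_roundtrips
  if (n < 1) stop("effective sample size must be >= 1", call. = FALSE)
  n
}

#' Count temperature roundtrips of a replica
#'
#' A roundtrip is one excursion of the replica from the lowest temperature
#' rung to the highest and back (each completed return to the bottom after
#' touching the top counts once).
#'
#' @param trace Integer vector of temperature-rung indices over time.
#' @param low,high Extreme rung values (default the trace's min and max).
#' @return Integer roundtrip count.
#' @export
roundtrip_count <- function(trace, low = min(trace), high = max(trace)) {
  if (length(trace) == 0L || low == high) return(0L)
  n <- 0L
  phase <- "seek_low"
  for (x in trace) {
    if (phase == "seek_low") {
      if (x == low) phase <- "seek_high"
    } else if (phase == "seek_high") {
      if (x == high) phase <- "return_low"
    } else {
      if (x == low) {
        n <- n + 1L
        phase <- "seek_high"
      }
    }
  }
  n
}

#' Secondary chemical shifts
#'
#' Per-residue difference between predicted (or measured) shifts and the
#' random-coil reference, \eqn{\Delta\delta = \delta - \delta_{RC}}.
#' Tables carry residue numbers and optionally a temperature attribute;
#' mixing tables labelled with different temperatures warns, since
#' random-coil references are temperature specific.
#'
#' @param pred,rc data.frames with columns \code{residue} and
#'   \code{shift_ppm} (predicted and random-coil tables over identical
#'   residue sets).
#' @return data.frame with \code{residue} and \code{delta_ppm}.
#' @export
secondary_shifts <- function(pred, rc) {
  stopifnot(all(c("residue", "shift_ppm") %in% names(pred)),
            all(c("residue", "shift_ppm") %in% names(rc)))
  ta <- attr(pred, "temperature")
  tb <- attr(rc, "temperature")
  if (!is.null(ta) && !is.null(tb) && !isTRUE(all.equal(ta, tb))) {
    warning("predicted (", ta, " K) and random-coil (", tb,
            " K) tables are at different temperatures")
  }
  mism <- c(setdiff(pred$residue, rc$residue), setdiff(rc$residue, pred$residue))
  if (length(mism) > 0L) {
    stop("residue sets are misaligned at: ", paste(sort(unique(mism)),
                                                   collapse = ", "),
         call. = FALSE)
  }
  rc_ord <- rc[match(pred$residue, rc$residue), ]
  data.frame(residue = pred$residue,
             delta_ppm = pred$shift_ppm - rc_ord$shift_ppm)
}

#' Combined CA - CB secondary-shift track
#'
#' Elementwise \eqn{\Delta\delta C_\alpha - \Delta\delta C_\beta}, a
#' standard residual secondary-structure indicator.
#'
#' @param delta_ca,delta_cb Tables from \code{\link{secondary_shifts}}
#'   over the same residues.
#' @return data.frame with \code{residue} and \code{delta_ppm}.
#' @export
shift_combo <- function(delta_ca, delta_cb) {
  mism <- c(setdiff(delta_ca$residue, delta_cb$residue),
            setdiff(delta_cb$residue, delta_ca$residue))
  if (length(mism) > 0L) {
    stop("residue sets are misaligned at: ",
         paste(sort(unique(mism)), collapse = ", "), call. = FALSE)
  }
  cb <- delta_cb[match(delta_ca$residue, delta_cb$residue), ]
  data.frame(residue = delta_ca$residue,
             delta_ppm = delta_ca$delta_ppm - cb$delta_ppm)
}

#' Root-mean-squared deviation between two shift tracks
#'
#' @param a,b Numeric vectors (or tables with a \code{delta_ppm} column)
#'   aligned by position.
#' @return RMSD in ppm.
#' @export
shift_rmsd <- function(a, b) {
  if (is.data.frame(a)) a <- a$delta_ppm
  if (is.data.frame(b)) b <- b$delta_ppm
  if (length(a) != length(b)) stop("tracks differ in length", call. = FALSE)
  sqrt(mean((a - b)^2))
}

#' Stokes-Einstein hydrodynamic radius
#'
#' \eqn{R_h = k_B T / (6 \pi \eta D_t)} with viscosity supplied in Poise
#' (converted internally to Pa s).
#'
#' @param Dt Translational diffusion constant (m^2/s).
#' @param T_kelvin Temperature (K).
#' @param eta_poise Solvent viscosity (Poise; 0.01 Poise = 1 mPa s).
#' @return Hydrodynamic radius in nm.
#' @export
stokes_einstein_rh <- function(Dt, T_kelvin, eta_poise) {
  stopifnot(all(Dt > 0), all(T_kelvin > 0), all(eta_poise > 0))
  kb <- 1.380649e-23 # J/K
  eta <- eta_poise * 0.1 # Pa s
  rh_m <- kb * T_kelvin / (6 * pi * eta * Dt)
  rh_m * 1e9
}
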