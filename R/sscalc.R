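#' Ramachandran state assignment
#'
#' Assigns each (phi, psi) pair to \code{"helix"}, \code{"beta"} or
#' \code{"other"}; \code{NA} angles (chain termini) give
#' \code{"undefined"}. The helical region is \eqn{-100 < \phi < -30} and
#' \eqn{-120 \le \psi \le 50}; the beta region is \eqn{\phi < -80} with
#' \eqn{\psi > 50} or \eqn{\psi < -120}. The second beta bound is a sign
#' correction of a vacuous printed condition (psi < 120 would always hold);
#' as implemented the two regions are disjoint by construction. Angles
#' outside \eqn{(-180, 180]} are normalised first.
#'
#' @param phi,psi Dihedral angles in degrees (vector, matrix or array;
#'   shapes must match).
#' @return Character object of the same shape with values "helix", "beta",
#'   "other" or "undefined".
#' @export
rama_state <- function(phi, psi) {
  stopifnot(identical(dim(phi), dim(psi)) || length(phi) == length(psi))
  norm_angle <- function(x) {
    y <- ((x + 180) %% 360) - 180
    y[!is.na(y) & y == -180] <- 180
    y
  }
  phi_n <- norm_angle(phi)
  psi_n <- norm_angle(psi)
  out <- rep("other", length(phi_n))
  helix <- phi_n > -100 & phi_n < -30 & psi_n >= -120 & psi_n <= 50
  beta <- phi_n < -80 & (psi_n > 50 | psi_n < -120)
  out[helix & !is.na(helix)] <- "helix"
  out[beta & !is.na(beta)] <- "beta"
  out[is.na(phi_n) | is.na(psi_n)] <- "undefined"
  if (!is.null(dim(phi))) dim(out) <- dim(phi)
  out
}

#' Ramachandran state track of an ensemble
#'
#' @param traj A \code{traj_ensemble} with dihedrals.
#' @return frames x residues character matrix of states.
#' @export
rama_track <- function(traj) {
  if (is.null(traj$phi) || is.null(traj$psi)) {
    stop("trajectory has no dihedrals", call. = FALSE)
  }
  rama_state(traj$phi, traj$psi)
}

#' Flag residues inside secondary-structure runs
#'
#' A residue is flagged for a state when it lies inside a maximal run of
#' that state of length at least \code{min_run} (default 4 consecutive
#' residues). "undefined" states break runs.
#'
#' @param track frames x residues character state matrix (or a single
#'   frame as a vector).
#' @param state State to flag ("helix" or "beta").
#' @param min_run Minimum run length (default 4).
#' @return Logical object of the same shape.
#' @export
annotate_runs <- function(track, state, min_run = 4L) {
  flag_row <- function(states) {
    r <- rle(states == state)
    inside <- r$values & r$lengths >= min_run
    rep(inside, r$lengths)
  }
  if (is.null(dim(track))) return(flag_row(track))
  out <- t(apply(track, 1L, flag_row))
  dim(out) <- dim(track)
  out
}

#' Exact run length at each residue
#'
#' For each frame and residue, the length of the maximal run of
#' \code{state} containing the residue (0 if the residue is not in that
#' state).
#'
#' @inheritParams annotate_runs
#' @return Integer matrix of the same shape as \code{track}.
#' @export
run_lengths <- function(track, state) {
  len_row <- function(states) {
    r <- rle(states == state)
    rep(ifelse(r$values, r$lengths, 0L), r$lengths)
  }
  if (is.null(dim(track))) return(len_row(track))
  out <- t(apply(track, 1L, len_row))
  dim(out) <- dim(track)
  out
}

#' Per-residue secondary-structure propensity
#'
#' Fraction of unmasked frames in which a residue sits inside a
#' sufficiently long run of the state, with Bernoulli standard errors.
#'
#' @param traj A \code{traj_ensemble} with dihedrals.
#' @param state "helix" or "beta".
#' @param min_run Minimum run length (default 4).
#' @param n_eff Effective sample size for the standard errors (defaults to
#'   the number of unmasked frames).
#' @return Object of class \code{"ss_propensity"}: data.frame with columns
#'   \code{residue}, \code{p}, \code{se}; the state and run threshold are
#'   attributes.
#' @export
ss_propensity <- function(traj, state = c("helix", "beta"), min_run = 4L,
                          n_eff = NULL) {
  state <- match.arg(state)
  keep <- .unmasked(traj)
  track <- rama_track(traj)[keep, , drop = FALSE]
  flags <- annotate_runs(track, state, min_run)
  p <- colMeans(flags)
  if (is.null(n_eff)) n_eff <- length(keep)
  out <- data.frame(residue = seq_along(p), p = p, se = bernoulli_se(p, n_eff))
  attr(out, "state") <- state
  attr(out, "min_run") <- min_run
  attr(out, "n_eff") <- n_eff
  class(out) <- c("ss_propensity", "data.frame")
  out
}

#' Length-resolved secondary-structure map
#'
#' Entry (residue, L) is the fraction of unmasked frames in which the
#' residue's maximal run of the state has length exactly L. Summing the
#' columns with L >= \code{min_run} recovers the run propensity exactly.
#'
#' @inheritParams ss_propensity
#' @param max_len Largest run length column (defaults to chain length).
#' @return residues x max_len probability matrix (column names "1".."L").
#' @export
ss_length_map <- function(traj, state = c("helix", "beta"),
                          max_len = NULL) {
  state <- match.arg(state)
  keep <- .unmasked(traj)
  track <- rama_track(traj)[keep, , drop = FALSE]
  lens <- run_lengths(track, state)
  nr <- ncol(lens)
  if (is.null(max_len)) max_len <- nr
  out <- matrix(0, nr, max_len,
                dimnames = list(NULL, as.character(seq_len(max_len))))
  for (L in seq_len(max_len)) out[, L] <- colMeans(lens == L)
  out
}

#' Difference between two ensembles' propensities
#'
#' Signed per-residue difference B - A with propagated standard errors.
#'
#' @param prop_a,prop_b \code{\link{ss_propensity}} tables over the same
#'   chain.
#' @return data.frame with \code{residue}, \code{diff}, \code{se}.
#' @export
ss_difference <- function(prop_a, prop_b) {
  if (nrow(prop_a) != nrow(prop_b)) {
    stop("chain length mismatch between ensembles", call. = FALSE)
  }
  data.frame(residue = prop_a$residue, diff = prop_b$p - prop_a$p,
             se = sqrt(prop_a$se^2 + prop_b$se^2))
}

#' Length-map difference (B - A)
#'
#' @param map_a,map_b Matrices from \code{\link{ss_length_map}} with equal
#'   dimensions.
#' @return Signed difference matrix.
#' @export
ss_length_difference <- function(map_a, map_b) {
  if (!identical(dim(map_a), dim(map_b))) {
    stop("length-map dimension mismatch", call. = FALSE)
  }
  map_b - map_a
}

#' Propensity curves split by frame label
#'
#' One propensity table per distinct frame label (replica or temperature).
#'
#' @inheritParams ss_propensity
#' @return Named list of \code{\link{ss_propensity}} tables.
#' @export
ss_propensity_by_label <- function(traj, state = c("helix", "beta"),
                                   min_run = 4L) {
  state <- match.arg(state)
  if (is.null(traj$labels)) stop("trajectory has no frame labels", call. = FALSE)
  labs <- unique(traj$labels[.unmasked(traj)])
  out <- lapply(labs, function(l) {
    ss_propensity(subset_frames(traj, which(traj$labels == l)),
                  state = state, min_run = min_run)
  })
  names(out) <- as.character(labs)
  out
}
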