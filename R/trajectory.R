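#' Conformational ensemble container
#'
#' Holds an ensemble of frames for a single chain: alpha-carbon coordinates
#' (frames x residues x 3, nanometres), optional per-residue backbone N and
#' O pseudo/real atoms, optional backbone dihedrals, per-frame labels
#' (replica or temperature), a QC mask and an optional periodic box edge.
#'
#' @param ca Numeric array frames x residues x 3 (nm).
#' @param n_atoms,o_atoms Optional arrays of the same shape holding the
#'   backbone amide nitrogen and carbonyl oxygen positions per residue.
#' @param phi,psi Optional frames x residues matrices of backbone dihedrals
#'   in degrees, \code{NA} where undefined (chain termini).
#' @param labels Optional per-frame label vector (length frames).
#' @param mask Logical per-frame vector, \code{TRUE} = frame retained.
#' @param box Optional cubic box edge length (nm).
#' @return An object of class \code{"traj_ensemble"}.
#' @export
traj_ensemble <- function(ca, n_atoms = NULL, o_atoms = NULL,
                          phi = NULL, psi = NULL, labels = NULL,
                          mask = NULL, box = NULL) {
  stopifnot(is.array(ca), length(dim(ca)) == 3L, dim(ca)[3] == 3L,
            dim(ca)[1] >= 1L)
  nf <- dim(ca)[1]
  nr <- dim(ca)[2]
  chk <- function(a, nm) {
    if (!is.null(a) && !identical(dim(a), dim(ca)))
      stop(nm, " must match ca dimensions", call. = FALSE)
    a
  }
  chkm <- function(m, nm) {
    if (!is.null(m) && !identical(dim(m), c(nf, nr)))
      stop(nm, " must be frames x residues", call. = FALSE)
    m
  }
  if (is.null(mask)) mask <- rep(TRUE, nf)
  stopifnot(is.logical(mask), length(mask) == nf)
  if (!is.null(labels)) stopifnot(length(labels) == nf)
  structure(list(ca = ca, n_atoms = chk(n_atoms, "n_atoms"),
                 o_atoms = chk(o_atoms, "o_atoms"),
                 phi = chkm(phi, "phi"), psi = chkm(psi, "psi"),
                 labels = labels, mask = mask, box = box),
            class = "traj_ensemble")
}

#' @export
print.traj_ensemble <- function(x, ...) {
  cat("<traj_ensemble> ", dim(x$ca)[1], " frames x ", dim(x$ca)[2],
      " residues (", sum(x$mask), " unmasked)",
      if (!is.null(x$n_atoms)) "; backbone N/O present",
      if (!is.null(x$phi)) "; dihedrals present",
      if (!is.null(x$box)) paste0("; box ", signif(x$box, 4), " nm"),
      "\n", sep = "")
  invisible(x)
}

#' Number of frames / residues
#' @param traj A \code{traj_ensemble}.
#' @return Integer count.
#' @export
n_frames <- function(traj) dim(traj$ca)[1]

#' @rdname n_frames
#' @export
n_residues <- function(traj) dim(traj$ca)[2]

.unmasked <- function(traj) which(traj$mask)

#' Keep a subset of frames
#'
#' @param traj A \code{traj_ensemble}.
#' @param idx Frame indices (or logical vector) to keep.
#' @return A new \code{traj_ensemble}.
#' @export
subset_frames <- function(traj, idx) {
  take <- function(a) if (is.null(a)) NULL else a[idx, , , drop = FALSE]
  takem <- function(m) if (is.null(m)) NULL else m[idx, , drop = FALSE]
  traj_ensemble(take(traj$ca), take(traj$n_atoms), take(traj$o_atoms),
                takem(traj$phi), takem(traj$psi),
                if (is.null(traj$labels)) NULL else traj$labels[idx],
                traj$mask[idx], traj$box)
}

#' Periodic-image frame QC
#'
#' Masks frames whose minimum separation from the nearest periodic image is
#' below \code{min_image}. For a cubic box of edge L the separation along
#' each axis is L minus the molecule's coordinate extent on that axis; the
#' frame value is the minimum over the three axes. Without box information
#' every frame passes, with a warning.
#'
#' @param traj A \code{traj_ensemble}.
#' @param min_image Minimum allowed image separation (nm, default 2.0).
#' @return The trajectory with its mask updated (previously masked frames
#'   stay masked). The per-frame separations are attached as attribute
#'   \code{"image_separation"}.
#' @export
frame_qc <- function(traj, min_image = 2.0) {
  stopifnot(inherits(traj, "traj_ensemble"))
  if (is.null(traj$box)) {
    warning("no box information; all frames pass image-distance QC")
    attr(traj, "image_separation") <- rep(NA_real_, n_frames(traj))
    return(traj)
  }
  sep <- apply(traj$ca, 1L, function(xyz) {
    ext <- apply(xyz, 2L, function(v) diff(range(v)))
    min(traj$box - ext)
  })
  traj$mask <- traj$mask & (sep >= min_image)
  attr(traj, "image_separation") <- sep
  traj
}

#' Centered moving-window average
#'
#' Moving mean of a series with the window truncated to the available
#' points at the edges (output has the same length as the input).
#'
#' @param series Numeric vector.
#' @param width Window width in samples (any positive integer).
#' @return Numeric vector of smoothed values.
#' @export
moving_window <- function(series, width) {
  width <- as.integer(width)
  stopifnot(width >= 1L)
  n <- length(series)
  half_lo <- (width - 1L) %/% 2L
  half_hi <- width %/% 2L
  vapply(seq_len(n), function(i) {
    mean(series[max(1L, i - half_lo):min(n, i + half_hi)])
  }, numeric(1))
}
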