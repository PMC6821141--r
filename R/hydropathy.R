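#' Kyte-Doolittle hydropathy values for the 20 canonical amino acids
#'
#' Raw Kyte-Doolittle hydropathy indices, from R (-4.5) to I (+4.5).
#' @format Named numeric vector, one-letter codes as names.
#' @export
kd_scale <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

.check_residues <- function(residues) {
  bad <- setdiff(unique(residues), names(kd_scale))
  if (length(bad) > 0L) {
    stop("non-canonical residue letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

.split_seq <- function(seq) {
  if (length(seq) == 1L && nchar(seq) > 1L) {
    seq <- strsplit(seq, "")[[1]]
  }
  seq <- toupper(seq)
  .check_residues(seq)
  seq
}

#' Scaled Kyte-Doolittle hydropathy
#'
#' Maps a residue's Kyte-Doolittle index onto \eqn{[0, 1]} via
#' \eqn{(KD + 4.5)/9}, so that R scores 0 and I scores 1.
#'
#' @param residue Character vector of one-letter residue codes, or a single
#'   string (split into residues).
#' @return Numeric vector of unit-interval hydropathy scores.
#' @examples
#' scale_hydropathy("R")          # 0
#' scale_hydropathy("I")          # 1
#' mean(scale_hydropathy("HVIEELLD"))
#' @export
scale_hydropathy <- function(residue) {
  residue <- .split_seq(residue)
  unname((kd_scale[residue] + 4.5) / 9)
}

#' Windowed hydropathy profile
#'
#' Per-residue scaled hydropathy smoothed with a centered moving mean.
#' At the termini the window is truncated to the available residues, so the
#' profile has the same length as the sequence.
#'
#' @param seq Amino-acid sequence (string or character vector).
#' @param window Odd window width (residues); 1 returns the raw scores.
#' @return Numeric vector, one smoothed score per residue.
#' @export
hydropathy_profile <- function(seq, window = 3L) {
  seq <- .split_seq(seq)
  if (length(seq) == 0L) stop("empty sequence", call. = FALSE)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 1", call. = FALSE)
  }
  raw <- scale_hydropathy(seq)
  half <- window %/% 2L
  n <- length(raw)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(raw[lo:hi])
  }, numeric(1))
}

#' Record a protein sequence with author numbering
#'
#' Light container tying a one-letter sequence to the author residue number
#' of its first residue (e.g. 23 for a prodomain construct starting at
#' author residue 23).
#'
#' @param residues One-letter sequence (string or character vector).
#' @param id Record identifier.
#' @param offset Author residue number of the first residue (default 1).
#' @return An object of class \code{"sequence_record"} with elements
#'   \code{id}, \code{residues} (character vector) and \code{offset}.
#' @export
sequence_record <- function(residues, id = "seq", offset = 1L) {
  residues <- .split_seq(residues)
  if (length(residues) < 1L) stop("length >= 1 required", call. = FALSE)
  structure(list(id = id, residues = residues, offset = as.integer(offset)),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat("<sequence_record> ", x$id, ": ", length(x$residues),
      " residues (author numbering ", x$offset, "-",
      x$offset + length(x$residues) - 1L, ")\n", sep = "")
  cat(" ", paste(x$residues, collapse = ""), "\n")
  invisible(x)
}

.as_seqrec <- function(seq, offset = 1L) {
  if (inherits(seq, "sequence_record")) seq else sequence_record(seq, offset = offset)
}
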