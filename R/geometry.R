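#' Contact-map container
#'
#' @param p Symmetric probability matrix.
#' @param counts Symmetric co-occurrence count matrix.
#' @param n Effective sample size used for the Bernoulli standard errors.
#' @param level "residue", "blob" or "region".
#' @param cutoff Distance cutoff (nm) used for the contact definition.
#' @param definition Free-text contact definition.
#' @param anchor_mode How blob anchors were obtained ("backbone" N/O atoms
#'   or "calpha" fallback), recorded so mixed conventions are detectable.
#' @return Object of class \code{"contact_map"} with elements \code{p},
#'   \code{counts}, \code{n}, \code{se}, and metadata.
#' @export
contact_map <- function(p, counts, n, level, cutoff, definition,
                        anchor_mode = NA_character_) {
  stopifnot(is.matrix(p), nrow(p) == ncol(p),
            all(p >= 0 & p <= 1, na.rm = TRUE))
  structure(list(p = p, counts = counts, n = n,
                 se = bernoulli_se(p, n), level = level, cutoff = cutoff,
                 definition = definition, anchor_mode = anchor_mode),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> level=", x$level, ", ", nrow(x$p), "x", ncol(x$p),
      ", cutoff=", x$cutoff, " nm, n=", x$n, "\n", sep = "")
  cat(" definition: ", x$definition, "\n", sep = "")
  invisible(x)
}

#' @export
plot.contact_map <- function(x, ...) {
  image(seq_len(nrow(x$p)), seq_len(ncol(x$p)), x$p,
        xlab = "index", ylab = "index", main = paste(x$level, "contacts"),
        ...)
  invisible(x)
}

.blob_ranges <- function(partition) {
  if (inherits(partition, "blob_partition")) {
    partition$blobs
  } else {
    stopifnot(is.data.frame(partition),
              all(c("start", "end") %in% names(partition)))
    if (is.null(partition$label)) {
      partition$label <- paste0("b", seq_len(nrow(partition)))
    }
    partition
  }
}

# per-frame anchors (frames x blobs x 3), Rg and Retoe (frames x blobs)
.blob_geom <- function(traj, partition) {
  b <- .blob_ranges(partition)
  nb <- nrow(b)
  nf <- n_frames(traj)
  backbone <- !is.null(traj$n_atoms) && !is.null(traj$o_atoms)
  first_atom <- if (backbone) traj$n_atoms else traj$ca
  last_atom <- if (backbone) traj$o_atoms else traj$ca
  anchors <- array(NA_real_, c(nf, nb, 3L))
  rg <- matrix(NA_real_, nf, nb)
  retoe <- matrix(NA_real_, nf, nb)
  for (k in seq_len(nb)) {
    s <- b$start[k]
    e <- b$end[k]
    a1 <- first_atom[, s, , drop = FALSE]
    a2 <- last_atom[, e, , drop = FALSE]
    anchors[, k, ] <- (a1[, 1L, ] + a2[, 1L, ]) / 2
    d <- a2[, 1L, ] - a1[, 1L, ]
    if (nf == 1L) d <- matrix(d, 1L, 3L)
    retoe[, k] <- sqrt(rowSums(d^2))
    X <- traj$ca[, s:e, , drop = FALSE]
    cm <- apply(X, c(1L, 3L), mean)
    if (nf == 1L) cm <- matrix(cm, 1L, 3L)
    sq <- 0
    for (ax in 1:3) sq <- sq + (X[, , ax, drop = FALSE] - c(cm[, ax]))^2
    rg[, k] <- sqrt(apply(sq, 1L, mean))
  }
  list(anchors = anchors, rg = rg, retoe = retoe, labels = b$label,
       anchor_mode = if (backbone) "backbone" else "calpha")
}

#' Per-frame blob anchor position
#'
#' Mean of a blob's N-terminal backbone N and C-terminal backbone O
#' positions; ensembles carrying only alpha carbons fall back to the mean
#' of the first and last CA (the mode is recorded downstream).
#'
#' @param traj A \code{traj_ensemble}.
#' @param frame Frame index.
#' @param blob Two-element integer vector \code{c(start, end)} of local
#'   residue indices, or a one-row slice of \code{partition$blobs}.
#' @return Numeric 3-vector (nm).
#' @export
blob_anchor <- function(traj, frame, blob) {
  b <- if (is.numeric(blob)) data.frame(start = blob[1], end = blob[2]) else blob
  g <- .blob_geom(subset_frames(traj, frame), b)
  c(g$anchors[1L, 1L, ])
}

#' Per-frame blob size and extension
#'
#' Radius of gyration (unweighted over CA positions) and end-to-end
#' distance (between the same terminal atoms used by
#' \code{\link{blob_anchor}}) for one blob in one frame.
#'
#' @inheritParams blob_anchor
#' @return Named numeric vector \code{c(rg = , retoe = )} in nm.
#' @export
blob_rg_retoe <- function(traj, frame, blob) {
  b <- if (is.numeric(blob)) data.frame(start = blob[1], end = blob[2]) else blob
  g <- .blob_geom(subset_frames(traj, frame), b)
  c(rg = g$rg[1L, 1L], retoe = g$retoe[1L, 1L])
}

#' Ensemble blob geometry summary
#'
#' Mean radius of gyration and end-to-end distance per blob over the
#' unmasked frames; the inputs to SAHP parameterization.
#'
#' @param traj A \code{traj_ensemble}.
#' @param partition A \code{blob_partition} (or data.frame of blob ranges).
#' @return Object of class \code{"blob_geometry"}: data.frame with columns
#'   \code{label}, \code{mean_rg}, \code{mean_retoe}; per-frame arrays kept
#'   in attributes \code{anchors}, \code{rg}, \code{retoe};
#'   \code{anchor_mode} records the anchor convention.
#' @export
blob_geometry <- function(traj, partition) {
  g <- .blob_geom(traj, partition)
  keep <- .unmasked(traj)
  if (length(keep) == 0L) stop("no unmasked frames", call. = FALSE)
  out <- data.frame(label = g$labels,
                    mean_rg = colMeans(g$rg[keep, , drop = FALSE]),
                    mean_retoe = colMeans(g$retoe[keep, , drop = FALSE]),
                    stringsAsFactors = FALSE)
  attr(out, "anchors") <- g$anchors
  attr(out, "rg") <- g$rg
  attr(out, "retoe") <- g$retoe
  attr(out, "anchor_mode") <- g$anchor_mode
  class(out) <- c("blob_geometry", "data.frame")
  out
}

#' Excess distance between two blobs in one frame
#'
#' \eqn{d_{e,ij} = |r_i - r_j| - (R_{g,i} + R_{g,j})} using the per-frame
#' anchors and per-frame radii of gyration.
#'
#' @param traj A \code{traj_ensemble}.
#' @param partition Blob partition or range table.
#' @param frame Frame index.
#' @param i,j Blob indices (or labels).
#' @return Excess distance in nm (can be negative).
#' @export
excess_distance <- function(traj, partition, frame, i, j) {
  b <- .blob_ranges(partition)
  if (is.character(i)) i <- match(i, b$label)
  if (is.character(j)) j <- match(j, b$label)
  stopifnot(i != j)
  g <- .blob_geom(subset_frames(traj, frame), b)
  sqrt(sum((g$anchors[1L, i, ] - g$anchors[1L, j, ])^2)) -
    (g$rg[1L, i] + g$rg[1L, j])
}

# frames x npair matrix of excess distances for all blob pairs (i < j)
.excess_series <- function(traj, partition) {
  g <- .blob_geom(traj, partition)
  nb <- length(g$labels)
  pairs <- which(upper.tri(matrix(0, nb, nb)), arr.ind = TRUE)
  nf <- n_frames(traj)
  de <- matrix(NA_real_, nf, nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]
    j <- pairs[k, 2L]
    d <- g$anchors[, i, , drop = FALSE] - g$anchors[, j, , drop = FALSE]
    dim(d) <- c(nf, 3L)
    de[, k] <- sqrt(rowSums(d^2)) - (g$rg[, i] + g$rg[, j])
  }
  list(de = de, pairs = pairs, labels = g$labels,
       anchor_mode = g$anchor_mode)
}

#' Blob-level contact map from an ensemble
#'
#' Two blobs are in contact in a frame when their excess distance is
#' strictly below \code{cutoff}. Probabilities are fractions of unmasked
#' frames; standard errors follow the Bernoulli convention with effective
#' sample size \code{n_eff}.
#'
#' @param traj A \code{traj_ensemble}.
#' @param partition Blob partition or range table.
#' @param cutoff Excess-distance cutoff in nm (default 0.55, strict "<").
#' @param n_eff Effective sample size for standard errors (defaults to the
#'   number of unmasked frames).
#' @return A \code{\link{contact_map}} at blob level.
#' @export
blob_contact_map <- function(traj, partition, cutoff = 0.55, n_eff = NULL) {
  keep <- .unmasked(traj)
  if (length(keep) == 0L) stop("no unmasked frames", call. = FALSE)
  es <- .excess_series(traj, partition)
  de <- es$de[keep, , drop = FALSE]
  nb <- length(es$labels)
  counts <- matrix(0, nb, nb, dimnames = list(es$labels, es$labels))
  for (k in seq_len(nrow(es$pairs))) {
    i <- es$pairs[k, 1L]
    j <- es$pairs[k, 2L]
    counts[i, j] <- counts[j, i] <- sum(de[, k] < cutoff)
  }
  p <- counts / length(keep)
  diag(p) <- NA_real_
  if (is.null(n_eff)) n_eff <- length(keep)
  contact_map(p, counts, n_eff, "blob", cutoff,
              "excess distance d_e < cutoff (strict), per-frame anchors and Rg",
              anchor_mode = es$anchor_mode)
}

#' Per-frame contact indicator for one blob pair
#'
#' @inheritParams blob_contact_map
#' @param x,y Blob labels or indices.
#' @return Logical vector over all frames (mask not applied).
#' @export
blob_pair_contact <- function(traj, partition, x, y, cutoff = 0.55) {
  b <- .blob_ranges(partition)
  if (is.character(x)) x <- match(x, b$label)
  if (is.character(y)) y <- match(y, b$label)
  es <- .excess_series(traj, b[sort(c(x, y)), , drop = FALSE])
  es$de[, 1L] < cutoff
}

#' Residue-level CA contact map
#'
#' Two residues are in contact when their CA-CA distance is at most
#' \code{cutoff} (inclusive).
#'
#' @inheritParams blob_contact_map
#' @param cutoff CA distance cutoff in nm (default 0.8, inclusive "<=").
#' @return A \code{\link{contact_map}} at residue level.
#' @export
residue_contact_map <- function(traj, cutoff = 0.8, n_eff = NULL) {
  keep <- .unmasked(traj)
  if (length(keep) == 0L) stop("no unmasked frames", call. = FALSE)
  nr <- n_residues(traj)
  counts <- matrix(0, nr, nr)
  for (f in keep) {
    d <- as.matrix(dist(traj$ca[f, , ]))
    counts <- counts + (d <= cutoff)
  }
  dimnames(counts) <- NULL
  diag(counts) <- 0
  p <- counts / length(keep)
  diag(p) <- NA_real_
  if (is.null(n_eff)) n_eff <- length(keep)
  contact_map(p, counts, n_eff, "residue", cutoff,
              "CA-CA distance <= cutoff (inclusive)")
}

#' All-atom contact maps by interaction flavor
#'
#' Residue-residue contact maps from an all-atom fixture. Flavors:
#' \describe{
#'   \item{backbone}{any backbone-backbone heavy-atom pair at <= 0.4 nm}
#'   \item{sidechain}{any sidechain-sidechain heavy-atom pair at <= 0.4 nm}
#'   \item{hydrophobic}{sidechain flavor restricted to hydrophobic residue
#'     pairs (A, C, F, I, L, M, V)}
#'   \item{saltbridge}{donor-acceptor distance strictly < 0.32 nm between
#'     K/R sidechain nitrogens and D/E sidechain oxygens}
#' }
#'
#' @param coords Array frames x atoms x 3 (nm).
#' @param atoms data.frame with one row per atom: \code{residue} (local
#'   index), \code{role} ("backbone" or "sidechain"), \code{element}
#'   (e.g. "N", "O", "C").
#' @param residues Character vector of one-letter residue codes.
#' @param flavor One of "backbone", "sidechain", "hydrophobic",
#'   "saltbridge".
#' @param n_eff Effective sample size for standard errors.
#' @return A \code{\link{contact_map}} at residue level.
#' @export
atom_contact_maps <- function(coords, atoms, residues,
                              flavor = c("backbone", "sidechain",
                                         "hydrophobic", "saltbridge"),
                              n_eff = NULL) {
  flavor <- match.arg(flavor)
  stopifnot(is.array(coords), length(dim(coords)) == 3L,
            nrow(atoms) == dim(coords)[2])
  nr <- length(residues)
  nf <- dim(coords)[1]
  hydrophobic <- c("A", "C", "F", "I", "L", "M", "V")
  heavy <- atoms$element != "H"

  sel <- switch(flavor,
    backbone = atoms$role == "backbone" & heavy,
    sidechain = atoms$role == "sidechain" & heavy,
    hydrophobic = atoms$role == "sidechain" & heavy &
      residues[atoms$residue] %in% hydrophobic,
    saltbridge = (atoms$role == "sidechain" & atoms$element == "N" &
                    residues[atoms$residue] %in% c("K", "R")) |
                 (atoms$role == "sidechain" & atoms$element == "O" &
                    residues[atoms$residue] %in% c("D", "E"))
  )
  if (!any(sel)) stop("no atoms available for flavor ", flavor, call. = FALSE)
  cutoff <- if (flavor == "saltbridge") 0.32 else 0.4
  strict <- flavor == "saltbridge"

  idx <- which(sel)
  res_of <- atoms$residue[idx]
  acc <- matrix(0, nr, nr)
  for (f in seq_len(nf)) {
    xyz <- matrix(coords[f, idx, ], nrow = length(idx), ncol = 3L)
    d <- as.matrix(dist(xyz))
    hit <- if (strict) d < cutoff else d <= cutoff
    diag(hit) <- FALSE
    ind <- matrix(FALSE, nr, nr)
    pairs <- which(hit & upper.tri(hit), arr.ind = TRUE)
    for (k in seq_len(nrow(pairs))) {
      ri <- res_of[pairs[k, 1L]]
      rj <- res_of[pairs[k, 2L]]
      if (ri == rj) next
      if (flavor == "saltbridge") {
        ok <- (residues[ri] %in% c("K", "R") && residues[rj] %in% c("D", "E")) ||
              (residues[ri] %in% c("D", "E") && residues[rj] %in% c("K", "R"))
        if (!ok) next
      }
      ind[ri, rj] <- TRUE
      ind[rj, ri] <- TRUE
    }
    acc <- acc + ind
  }
  p <- acc / nf
  diag(p) <- NA_real_
  if (is.null(n_eff)) n_eff <- nf
  contact_map(p, acc, n_eff, "residue", cutoff,
              paste0(flavor, " atoms, ",
                     if (strict) "strict <" else "inclusive <=",
                     " ", cutoff, " nm"))
}

#' Export a contact map as an edge list
#'
#' Keeps residue pairs whose contact probability exceeds
#' \code{persistence}, flagging long-range pairs separated by more than
#' \code{long_range_sep} positions.
#'
#' @param map A residue-level \code{\link{contact_map}}.
#' @param persistence Probability threshold (strict ">"; default 0.06).
#' @param long_range_sep Sequence-separation threshold for the long-range
#'   flag (default 20, strict ">").
#' @return data.frame with columns \code{i}, \code{j}, \code{probability},
#'   \code{long_range}.
#' @export
network_export <- function(map, persistence = 0.06, long_range_sep = 20L) {
  stopifnot(inherits(map, "contact_map"))
  ut <- which(upper.tri(map$p), arr.ind = TRUE)
  p <- map$p[ut]
  keep <- !is.na(p) & p > persistence
  data.frame(i = ut[keep, 1L], j = ut[keep, 2L], probability = p[keep],
             long_range = (ut[keep, 2L] - ut[keep, 1L]) > long_range_sep)
}

#' Region-pair mean contact probabilities
#'
#' Averages blob-pair contact probabilities over each region pair
#' (within-region pairs use distinct blob pairs only).
#'
#' @param map A blob-level \code{\link{contact_map}}.
#' @param regions Character vector of region labels, one per blob (in map
#'   order), or named by blob label.
#' @return data.frame with columns \code{region_a}, \code{region_b},
#'   \code{mean_p}, \code{n_pairs}.
#' @export
region_contact_stats <- function(map, regions) {
  stopifnot(inherits(map, "contact_map"))
  nb <- nrow(map$p)
  if (!is.null(names(regions)) && !is.null(rownames(map$p))) {
    regions <- regions[rownames(map$p)]
  }
  stopifnot(length(regions) == nb, !anyNA(regions))
  regs <- sort(unique(regions))
  out <- list()
  for (a in seq_along(regs)) {
    for (b2 in a:length(regs)) {
      ia <- which(regions == regs[a])
      ib <- which(regions == regs[b2])
      vals <- c()
      for (i in ia) for (j in ib) {
        if (i < j) vals <- c(vals, map$p[i, j])
        if (a != b2 && j < i) vals <- c(vals, map$p[j, i])
      }
      if (length(vals) > 0L) {
        out[[length(out) + 1L]] <-
          data.frame(region_a = regs[a], region_b = regs[b2],
                     mean_p = mean(vals), n_pairs = length(vals))
      }
    }
  }
  do.call(rbind, out)
}

#' Internal polymer-scaling (Flory) fit
#'
#' Fits \eqn{\log \langle R_{|i-j|} \rangle = \log A + \nu \log |i-j|} to
#' the mean CA-CA distances at each sequence separation \eqn{|i-j| \ge 2}
#' inside a domain. The prefactor defaults to the fixed reference value
#' A = 0.59 nm; pass \code{A = NULL} to estimate it as well.
#'
#' @param traj A \code{traj_ensemble}.
#' @param domain Two-element integer vector \code{c(start, end)} of local
#'   residue indices (defaults to the whole chain).
#' @param A Fixed prefactor in nm, or \code{NULL} to fit it.
#' @return Object of class \code{"scaling_fit"}: list with \code{nu},
#'   \code{A}, \code{A_fixed}, \code{nu_se}, \code{domain}, and the
#'   \code{data} (separation, mean distance) used.
#' @export
flory_fit <- function(traj, domain = NULL, A = 0.59) {
  keep <- .unmasked(traj)
  nr <- n_residues(traj)
  if (is.null(domain)) domain <- c(1L, nr)
  stopifnot(domain[2] - domain[1] + 1L >= 4L)
  res <- domain[1]:domain[2]
  seps <- 2:(length(res) - 1L)
  if (length(seps) < 2L) stop("degenerate domain for scaling fit", call. = FALSE)
  mean_r <- vapply(seps, function(s) {
    i <- res[seq_len(length(res) - s)]
    tot <- 0
    for (off in seq_along(i)) {
      d <- traj$ca[keep, i[off] + s, , drop = FALSE] -
           traj$ca[keep, i[off], , drop = FALSE]
      dim(d) <- c(length(keep), 3L)
      tot <- tot + mean(sqrt(rowSums(d^2)))
    }
    tot / length(i)
  }, numeric(1))
  dat <- data.frame(separation = seps, mean_r = mean_r)
  if (is.null(A)) {
    fit <- lm(log(mean_r) ~ log(separation), data = dat)
    nu <- unname(coef(fit)[2])
    A_est <- exp(unname(coef(fit)[1]))
    nu_se <- suppressWarnings(summary(fit)$coefficients[2, 2])
    fixed <- FALSE
  } else {
    fit <- lm(I(log(mean_r) - log(A)) ~ 0 + log(separation), data = dat)
    nu <- unname(coef(fit)[1])
    A_est <- A
    nu_se <- suppressWarnings(summary(fit)$coefficients[1, 2])
    fixed <- TRUE
  }
  structure(list(nu = nu, A = A_est, A_fixed = fixed, nu_se = nu_se,
                 domain = domain, data = dat),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("<scaling_fit> nu = ", signif(x$nu, 4), " (se ", signif(x$nu_se, 3),
      "), A = ", signif(x$A, 4), " nm",
      if (x$A_fixed) " [fixed]", ", domain ", x$domain[1], "-", x$domain[2],
      "\n", sep = "")
  cat(" reference exponents: 3/5 good solvent, 1/2 theta, 1/3 globule\n")
  invisible(x)
}
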