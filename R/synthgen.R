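#' Build a blob partition from a declared segment layout
#'
#' Constructs the partition object that \code{\link{identify_blobs}} would
#' produce for a chain whose blob layout is known by design: segments of
#' class "h" (hydrophobic blob), "p" (linker blob) or "u" (unassigned
#' spacer). Consecutive h blobs separated only by "u" segments share a
#' group, mirroring the sequence-based rule.
#'
#' @param lengths Integer segment lengths.
#' @param classes Character segment classes ("h", "p" or "u").
#' @param residues Optional residue letters for the chain (defaults to a
#'   glycine placeholder chain).
#' @param offset Author numbering offset.
#' @return A \code{blob_partition}.
#' @export
partition_from_layout <- function(lengths, classes, residues = NULL,
                                  offset = 1L) {
  stopifnot(length(lengths) == length(classes),
            all(classes %in% c("h", "p", "u")))
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  n <- sum(lengths)
  if (is.null(residues)) residues <- rep("G", n)
  keep <- classes != "u"
  segs <- data.frame(class = classes[keep], start = starts[keep],
                     end = ends[keep], stringsAsFactors = FALSE)
  unassigned <- unlist(lapply(which(!keep),
                              function(k) starts[k]:ends[k]))
  if (is.null(unassigned)) unassigned <- integer(0)

  groups <- list()
  labels <- character(nrow(segs))
  h_idx <- 0L
  p_idx <- 0L
  i <- 1L
  while (i <= nrow(segs)) {
    if (segs$class[i] == "p") {
      p_idx <- p_idx + 1L
      lab <- paste0("p", p_idx)
      labels[i] <- lab
      groups[[length(groups) + 1L]] <- list(label = lab, blobs = lab,
                                            unassigned = integer(0))
      i <- i + 1L
    } else {
      h_idx <- h_idx + 1L
      j <- i
      while (j < nrow(segs) && segs$class[j + 1L] == "h") j <- j + 1L
      members <- i:j
      labels[members] <- paste0("h", h_idx, letters[seq_along(members)])
      grp_un <- integer(0)
      if (length(members) > 1L) {
        for (k in members[-length(members)]) {
          if (segs$end[k] + 1L <= segs$start[k + 1L] - 1L) {
            grp_un <- c(grp_un, (segs$end[k] + 1L):(segs$start[k + 1L] - 1L))
          }
        }
      }
      groups[[length(groups) + 1L]] <- list(label = paste0("h", h_idx),
                                            blobs = labels[members],
                                            unassigned = grp_un)
      i <- j + 1L
    }
  }
  blobs <- data.frame(label = labels, class = segs$class,
                      start = segs$start, end = segs$end,
                      length = segs$end - segs$start + 1L,
                      stringsAsFactors = FALSE)
  rec <- sequence_record(residues, id = "synthetic", offset = offset)
  structure(list(blobs = blobs, groups = groups, unassigned = unassigned,
                 profile = NULL, sequence = rec, offset = as.integer(offset),
                 regions = NULL, cutoff = NA_real_, min_blob = 4L,
                 window = NA_integer_),
            class = "blob_partition")
}

#' Specification for a synthetic ensemble
#'
#' Declares the study conditions for a synthetic C-alpha ensemble: the
#' blob layout, per-blob compactness (spherical confinement radius around
#' the blob's first residue; NA = unconfined), planted blob-pair contact
#' probabilities, optional contact-beta coupling, background
#' secondary-structure run rates and the frame count.
#'
#' @param lengths,classes Segment layout as in
#'   \code{\link{partition_from_layout}}.
#' @param confinement Confinement radius (nm) per segment (NA for free
#'   segments). Defaults to 0.5 nm for "h" segments and NA otherwise.
#' @param planted_contacts data.frame with columns \code{x}, \code{y}
#'   (blob labels) and \code{p} (target contact probability), or NULL.
#' @param coupling data.frame with columns \code{x}, \code{y}, \code{q0}
#'   (beta-pairing probability without contact) and \code{odds_ratio}
#'   (multiplying the odds of beta-pairing when the pair is in contact),
#'   or NULL. Couples only pairs also listed in \code{planted_contacts}.
#' @param n_frames Number of frames.
#' @param bond CA-CA bond length (nm, default 0.38).
#' @param contact_cutoff Excess-distance contact cutoff used for planting
#'   (nm, default 0.55).
#' @param helix_rate,beta_rate Per-residue background probabilities of
#'   starting a helix / beta run (default 0.02 each).
#' @param min_run Planted and background run length floor (default 4).
#' @param margin Planting margin around the cutoff (nm, default 0.1).
#' @param n_labels Optional number of cyclic frame labels (replicas).
#' @return Object of class \code{"synth_spec"}.
#' @export
synth_spec <- function(lengths, classes, confinement = NULL,
                       planted_contacts = NULL, coupling = NULL,
                       n_frames = 2000L, bond = 0.38,
                       contact_cutoff = 0.55, helix_rate = 0.02,
                       beta_rate = 0.02, min_run = 4L, margin = 0.1,
                       n_labels = NULL) {
  stopifnot(length(lengths) == length(classes))
  if (is.null(confinement)) {
    confinement <- ifelse(classes == "h", 0.5, NA_real_)
  }
  stopifnot(length(confinement) == length(lengths))
  if (!is.null(planted_contacts)) {
    stopifnot(all(c("x", "y", "p") %in% names(planted_contacts)),
              all(planted_contacts$p >= 0 & planted_contacts$p <= 1))
  }
  if (!is.null(coupling)) {
    stopifnot(all(c("x", "y", "q0", "odds_ratio") %in% names(coupling)),
              all(coupling$odds_ratio > 0),
              all(coupling$q0 > 0 & coupling$q0 < 1))
  }
  structure(list(lengths = as.integer(lengths), classes = classes,
                 confinement = confinement,
                 planted_contacts = planted_contacts, coupling = coupling,
                 n_frames = as.integer(n_frames), bond = bond,
                 contact_cutoff = contact_cutoff, helix_rate = helix_rate,
                 beta_rate = beta_rate, min_run = as.integer(min_run),
                 margin = margin, n_labels = n_labels),
            class = "synth_spec")
}

#' Prodomain-like heterogeneous layout
#'
#' An 11-blob layout mimicking a 91-residue disordered chain: two
#' flanking globular multi-blob groups separated by a long unconfined
#' central linker, with short p linkers and 1-3 residue unassigned
#' spacers. Used as the default heterogeneous study condition for the
#' SAHP segmentation analyses.
#'
#' @param ... Overrides passed on to \code{\link{synth_spec}}.
#' @return A \code{synth_spec}.
#' @export
synth_spec_prodomain <- function(...) {
  lengths <- c(8L, 8L, 3L, 6L, 7L, 9L, 1L, 8L, 15L, 4L, 1L, 5L, 1L, 5L, 1L, 7L, 2L)
  classes <- c("p", "h", "u", "h", "p", "h", "u", "h", "p", "h", "u", "h",
               "u", "h", "u", "h", "u")
  conf <- ifelse(classes == "h", 0.45, NA_real_)
  conf[classes == "p" & lengths < 10L] <- 0.55 # short linkers stay compact
  synth_spec(lengths, classes, confinement = conf, ...)
}

.rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c0 <- cos(angle)
  s0 <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3L, 3L,
               byrow = TRUE)
  diag(3L) * c0 + s0 * ux + (1 - c0) * tcrossprod(u)
}

.blob_stat <- function(xyz, rng) {
  X <- xyz[rng, , drop = FALSE]
  cm <- colMeans(X)
  list(rg = sqrt(mean(rowSums(sweep(X, 2L, cm)^2))),
       anchor = (X[1L, ] + X[nrow(X), ]) / 2)
}

# excess distance for one pair in one frame (CA anchor convention)
.pair_de <- function(xyz, rng_i, rng_j) {
  si <- .blob_stat(xyz, rng_i)
  sj <- .blob_stat(xyz, rng_j)
  sqrt(sum((si$anchor - sj$anchor)^2)) - (si$rg + sj$rg)
}

# pivot the tail after a hinge residue until the pair's contact state
# matches; several hinges in the inter-blob gap are tried, and separation
# falls back to straightening the gap (both operations preserve every bond)
.plant_frame <- function(xyz, hinges, rng_i, rng_j, want, cutoff, margin,
                         bond, max_axes = 15L) {
  ok <- function(de) if (want) de < cutoff - margin else de >= cutoff + margin
  if (ok(.pair_de(xyz, rng_i, rng_j))) {
    return(list(xyz = xyz, achieved = TRUE))
  }
  si <- .blob_stat(xyz, rng_i)
  angles <- seq(0.25, 2 * pi - 0.25, length.out = 24L)
  try_hinge <- function(xyz, hinge, n_axes) {
    pivot <- xyz[hinge, ]
    tail_rows <- (hinge + 1L):nrow(xyz)
    sj <- .blob_stat(xyz, rng_j)
    for (t in seq_len(n_axes)) {
      ax <- rnorm(3L)
      for (ang in angles) {
        R <- .rotation_matrix(ax, ang)
        anchor_j <- c(R %*% (sj$anchor - pivot)) + pivot
        de <- sqrt(sum((si$anchor - anchor_j)^2)) - (si$rg + sj$rg)
        if (ok(de)) {
          xyz[tail_rows, ] <-
            t(R %*% t(sweep(xyz[tail_rows, , drop = FALSE], 2L, pivot))) +
            rep(pivot, each = length(tail_rows))
          return(xyz)
        }
      }
    }
    NULL
  }
  for (hinge in hinges) {
    res <- try_hinge(xyz, hinge, max_axes)
    if (!is.null(res)) return(list(xyz = res, achieved = TRUE))
  }
  if (!want) {
    # straighten the inter-blob gap away from blob i (max extension)
    gap <- (max(rng_i) + 1L):(min(rng_j) - 1L)
    d <- xyz[max(rng_i), ] - si$anchor
    nd <- sqrt(sum(d^2))
    if (nd < 1e-9) d <- c(1, 0, 0) else d <- d / nd
    prev <- xyz[max(rng_i), ]
    old_last <- xyz[max(gap), ]
    for (k in seq_along(gap)) {
      xyz[gap[k], ] <- prev + k * bond * d
    }
    delta <- xyz[max(gap), ] - old_last
    down <- min(rng_j):nrow(xyz)
    xyz[down, ] <- sweep(xyz[down, , drop = FALSE], 2L, delta, "+")
    if (ok(.pair_de(xyz, rng_i, rng_j))) {
      return(list(xyz = xyz, achieved = TRUE))
    }
  } else {
    for (hinge in hinges) {
      res <- try_hinge(xyz, hinge, 4L * max_axes)
      if (!is.null(res)) return(list(xyz = res, achieved = TRUE))
    }
  }
  list(xyz = xyz, achieved = FALSE)
}

#' Generate a synthetic ensemble with planted ground truth
#'
#' Builds freely-jointed C-alpha chains with per-blob spherical
#' confinement, plants blob-pair contacts at the declared Bernoulli
#' probabilities by bond-preserving pivot moves at a hinge residue between
#' the two blobs, and generates backbone dihedrals from a run-length state
#' model whose beta-pairing in the coupled blobs is conditioned on the
#' planted contact indicator with the declared odds ratio. Dihedrals are
#' independent of the coordinates except through that coupling.
#'
#' @param spec A \code{\link{synth_spec}}.
#' @param seed Integer seed (mandatory; fixed seeds give bit-identical
#'   ensembles).
#' @return List with \code{traj} (a \code{traj_ensemble}),
#'   \code{partition} (a \code{blob_partition}), and \code{truth}: per-pair
#'   planted contact indicators (and achievement flags), per-pair
#'   beta-pairing indicators, and the realised state matrix.
#' @export
gen_ensemble <- function(spec, seed) {
  stopifnot(inherits(spec, "synth_spec"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  part <- partition_from_layout(spec$lengths, spec$classes)
  n_res <- sum(spec$lengths)
  nf <- spec$n_frames

  # residue-wise confinement: radius around the segment's first residue
  seg_of <- rep(seq_along(spec$lengths), spec$lengths)
  seg_start <- cumsum(spec$lengths) - spec$lengths + 1L
  center_idx <- ifelse(is.na(spec$confinement[seg_of]), -1L,
                       seg_start[seg_of] - 1L) # 0-based
  first_of_seg <- seq_len(n_res) == seg_start[seg_of]
  center_idx[first_of_seg] <- -1L
  radius <- ifelse(is.na(spec$confinement[seg_of]), 0,
                   spec$confinement[seg_of])

  raw <- .gen_chain_frames_cpp(nf, n_res, spec$bond,
                               as.integer(center_idx), as.double(radius),
                               40L)
  ca <- aperm(raw, c(3L, 2L, 1L)) # frames x residues x 3

  blob_rng <- function(lab) {
    k <- match(lab, part$blobs$label)
    part$blobs$start[k]:part$blobs$end[k]
  }

  truth_contacts <- NULL
  pc <- spec$planted_contacts
  if (!is.null(pc) && nrow(pc) > 0L) {
    hinges_of <- function(k) {
      ri <- blob_rng(pc$x[k])
      rj <- blob_rng(pc$y[k])
      lo <- max(ri)
      hi <- min(rj)
      if (lo + 1L >= hi) stop("planted pair must be ordered and disjoint",
                              call. = FALSE)
      gap <- lo:(hi - 1L)
      gap[order(abs(gap - (lo + hi) / 2))] # midpoint first, then outward
    }
    hinges <- lapply(seq_len(nrow(pc)), hinges_of)
    ord <- order(vapply(hinges, function(h) h[1L], numeric(1)),
                 decreasing = TRUE)
    want <- matrix(runif(nf * nrow(pc)) <
                     rep(pc$p, each = nf), nf, nrow(pc))
    achieved <- matrix(NA, nf, nrow(pc))
    for (k in ord) {
      ri <- blob_rng(pc$x[k])
      rj <- blob_rng(pc$y[k])
      for (f in seq_len(nf)) {
        res <- .plant_frame(ca[f, , ], hinges[[k]], ri, rj, want[f, k],
                            spec$contact_cutoff, spec$margin, spec$bond)
        ca[f, , ] <- res$xyz
        achieved[f, k] <- res$achieved
      }
    }
    # realised contact indicator (equals `want` wherever planting succeeded)
    contact <- matrix(NA, nf, nrow(pc))
    for (k in seq_len(nrow(pc))) {
      ri <- blob_rng(pc$x[k])
      rj <- blob_rng(pc$y[k])
      contact[, k] <- vapply(seq_len(nf), function(f) {
        .pair_de(ca[f, , ], ri, rj) < spec$contact_cutoff
      }, logical(1))
    }
    truth_contacts <- list(pairs = pc, want = want, achieved = achieved,
                           contact = contact)
  }

  # secondary-structure state model
  states <- matrix("other", nf, n_res)
  geom_p <- 0.35 # run extension beyond the floor
  for (f in seq_len(nf)) {
    k <- 1L
    while (k <= n_res) {
      u <- runif(1)
      if (u < spec$helix_rate + spec$beta_rate) {
        st <- if (u < spec$helix_rate) "helix" else "beta"
        L <- spec$min_run + rgeom(1L, 1 - geom_p)
        states[f, k:min(n_res, k + L - 1L)] <- st
        k <- k + L
      } else {
        k <- k + 1L
      }
    }
  }

  truth_coupling <- NULL
  cp <- spec$coupling
  if (!is.null(cp) && nrow(cp) > 0L) {
    stopifnot(!is.null(truth_contacts))
    spair <- matrix(NA, nf, nrow(cp))
    for (k in seq_len(nrow(cp))) {
      m <- which(pc$x == cp$x[k] & pc$y == cp$y[k])
      if (length(m) != 1L) {
        stop("coupled pair must appear in planted_contacts", call. = FALSE)
      }
      odds0 <- cp$q0[k] / (1 - cp$q0[k])
      odds1 <- odds0 * cp$odds_ratio[k]
      q1 <- odds1 / (1 + odds1)
      contact <- truth_contacts$contact[, m]
      q <- ifelse(contact, q1, cp$q0[k])
      s <- runif(nf) < q
      spair[, k] <- s
      rx <- blob_rng(cp$x[k])
      ry <- blob_rng(cp$y[k])
      states[s, rx] <- "beta"
      states[s, ry] <- "beta"
    }
    truth_coupling <- list(pairs = cp, paired = spair)
  }

  # dihedrals drawn uniformly inside each Ramachandran region
  phi <- matrix(NA_real_, nf, n_res)
  psi <- matrix(NA_real_, nf, n_res)
  draw <- function(n, lo, hi) runif(n, lo, hi)
  for (st in c("helix", "beta", "other")) {
    idx <- which(states == st)
    if (length(idx) == 0L) next
    if (st == "helix") {
      phi[idx] <- draw(length(idx), -95, -35)
      psi[idx] <- draw(length(idx), -115, 45)
    } else if (st == "beta") {
      phi[idx] <- draw(length(idx), -170, -90)
      psi[idx] <- draw(length(idx), 60, 170)
    } else {
      phi[idx] <- draw(length(idx), 40, 140)
      psi[idx] <- draw(length(idx), -60, 60)
    }
  }
  phi[, 1L] <- NA_real_ # chain termini have undefined phi / psi
  psi[, n_res] <- NA_real_
  states[, 1L] <- "undefined"
  states[, n_res] <- "undefined"

  labels <- NULL
  if (!is.null(spec$n_labels)) {
    labels <- rep(seq_len(spec$n_labels), length.out = nf)
  }

  traj <- traj_ensemble(ca, phi = phi, psi = psi, labels = labels)
  list(traj = traj, partition = part,
       truth = list(contacts = truth_contacts, coupling = truth_coupling,
                    states = states, seed = seed))
}

#' Generate a sequence hitting composition targets
#'
#' Builds a sequence of the requested length with the requested charge
#' fractions (lysines and glutamates) and mean scaled hydropathy (a mix of
#' isoleucine and asparagine among the neutral positions), then shuffles
#' it. Targets are met within 1/N by construction. \code{segregate} places
#' the charges in terminal blocks (raising kappa) instead of shuffling.
#'
#' @param length Sequence length.
#' @param f_plus,f_minus Target charge fractions.
#' @param target_meanH Target unwindowed mean scaled hydropathy.
#' @param seed Integer seed.
#' @param segregate Place charges in blocks at the termini.
#' @return A \code{\link{sequence_record}}.
#' @export
gen_sequence <- function(length, f_plus = 0, f_minus = 0,
                         target_meanH = 0.5, seed = 1L, segregate = FALSE) {
  set.seed(seed)
  n <- as.integer(length)
  n_pos <- round(f_plus * n)
  n_neg <- round(f_minus * n)
  n0 <- n - n_pos - n_neg
  if (n0 < 0L) stop("infeasible charge fractions", call. = FALSE)
  h <- function(r) (kd_scale[[r]] + 4.5) / 9
  target_sum <- target_meanH * n
  fixed_sum <- n_pos * h("K") + n_neg * h("E")
  if (n0 > 0L) {
    lo <- fixed_sum + n0 * h("N")
    hi <- fixed_sum + n0 * h("I")
    if (target_sum < lo - 0.5 || target_sum > hi + 0.5) {
      stop("target mean hydropathy infeasible for this composition",
           call. = FALSE)
    }
    k <- round((target_sum - fixed_sum - n0 * h("N")) / (h("I") - h("N")))
    k <- max(0L, min(n0, k))
    neutrals <- c(rep("I", k), rep("N", n0 - k))
  } else {
    neutrals <- character(0)
  }
  if (segregate) {
    res <- c(rep("K", n_pos), neutrals, rep("E", n_neg))
  } else {
    res <- sample(c(rep("K", n_pos), rep("E", n_neg), neutrals))
  }
  sequence_record(res, id = sprintf("synthetic_n%d", n))
}

#' Add placeholder backbone N and O atoms to a C-alpha ensemble
#'
#' Places a pseudo amide nitrogen and carbonyl oxygen at fixed offsets
#' behind and ahead of each CA along the local chain direction, enabling
#' the backbone anchor convention on synthetic data. The local direction
#' at residue k is the normalised difference between its neighbours
#' (one-sided at the termini; a fixed x-axis for a single residue).
#'
#' @param traj A \code{traj_ensemble}.
#' @param offset Offset magnitude (nm, default 0.04).
#' @return The trajectory with \code{n_atoms} and \code{o_atoms} filled.
#' @export
gen_pseudo_backbone <- function(traj, offset = 0.04) {
  ca <- traj$ca
  nf <- dim(ca)[1]
  nr <- dim(ca)[2]
  n_at <- ca
  o_at <- ca
  for (f in seq_len(nf)) {
    X <- matrix(ca[f, , ], nr, 3L)
    if (nr == 1L) {
      dirs <- matrix(c(1, 0, 0), 1L, 3L)
    } else {
      nxt <- X[pmin(seq_len(nr) + 1L, nr), , drop = FALSE]
      prv <- X[pmax(seq_len(nr) - 1L, 1L), , drop = FALSE]
      dirs <- nxt - prv
      nrm <- sqrt(rowSums(dirs^2))
      nrm[nrm == 0] <- 1
      dirs <- dirs / nrm
    }
    n_at[f, , ] <- X - offset * dirs
    o_at[f, , ] <- X + offset * dirs
  }
  traj$n_atoms <- n_at
  traj$o_atoms <- o_at
  traj
}
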