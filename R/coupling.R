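.eligible_pair <- function(partition, x, y) {
  b <- partition$blobs
  i <- if (is.character(x)) match(x, b$label) else x
  j <- if (is.character(y)) match(y, b$label) else y
  if (is.na(i) || is.na(j)) stop("unknown blob label", call. = FALSE)
  grp_of <- function(k) {
    lab <- b$label[k]
    for (g in partition$groups) if (lab %in% g$blobs) return(g$label)
    NA_character_
  }
  same_group <- identical(grp_of(i), grp_of(j)) && !is.na(grp_of(i))
  adjacent <- abs(i - j) == 1L
  list(i = min(i, j), j = max(i, j), eligible = !same_group && !adjacent)
}

#' Four-cluster contact x beta labelling for a blob pair
#'
#' Splits the unmasked frames of an ensemble by two binary collective
#' variables: whether blobs X and Y are in contact (excess-distance rule)
#' and whether any residue of blob X lies inside a beta run of at least
#' \code{min_run} residues. Pairs that are sequence-adjacent or share a
#' group are filtered out (set \code{force = TRUE} to override).
#'
#' @param traj A \code{traj_ensemble} with dihedrals.
#' @param partition A \code{blob_partition}.
#' @param x,y Blob labels; X carries the structure variable.
#' @param cutoff Blob contact cutoff (nm, default 0.55).
#' @param min_run Beta run threshold (default 4).
#' @param force Analyse ineligible pairs anyway.
#' @return Object of class \code{"cluster_labeling"}: list with
#'   \code{contact} and \code{present} logical vectors (unmasked frames),
#'   \code{cluster} factor with levels "contacting.present",
#'   "contacting.absent", "distant.present", "distant.absent",
#'   \code{counts}, and the pair metadata.
#' @export
four_cluster <- function(traj, partition, x, y, cutoff = 0.55,
                         min_run = 4L, force = FALSE) {
  el <- .eligible_pair(partition, x, y)
  if (!el$eligible && !force) {
    stop("blobs ", x, " and ", y,
         " are adjacent or share a group; pass force = TRUE to analyse anyway",
         call. = FALSE)
  }
  keep <- .unmasked(traj)
  contact <- blob_pair_contact(traj, partition, x, y, cutoff)[keep]
  bx <- match(if (is.character(x)) x else partition$blobs$label[x],
              partition$blobs$label)
  xres <- partition$blobs$start[bx]:partition$blobs$end[bx]
  beta_flags <- annotate_runs(rama_track(traj)[keep, , drop = FALSE],
                              "beta", min_run)
  present <- rowSums(beta_flags[, xres, drop = FALSE]) > 0L
  cluster <- factor(paste0(ifelse(contact, "contacting", "distant"), ".",
                           ifelse(present, "present", "absent")),
                    levels = c("contacting.present", "contacting.absent",
                               "distant.present", "distant.absent"))
  structure(list(contact = contact, present = present, cluster = cluster,
                 counts = table(cluster), x = x, y = y,
                 beta_flags = beta_flags, min_run = min_run,
                 cutoff = cutoff),
            class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat("<cluster_labeling> pair ", x$x, "-", x$y, " (structure in ", x$x,
      ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Per-cluster per-residue beta propensity
#'
#' Beta-run propensity at every residue computed separately within each of
#' the four clusters, with cluster-size Bernoulli standard errors. Empty
#' clusters are reported with \code{NA} propensities.
#'
#' @param labeling A \code{\link{four_cluster}} labelling.
#' @return data.frame in long format: \code{cluster}, \code{residue},
#'   \code{p}, \code{se}, \code{n}.
#' @export
conditional_beta_profiles <- function(labeling) {
  stopifnot(inherits(labeling, "cluster_labeling"))
  out <- list()
  for (cl in levels(labeling$cluster)) {
    idx <- which(labeling$cluster == cl)
    nres <- ncol(labeling$beta_flags)
    if (length(idx) == 0L) {
      p <- rep(NA_real_, nres)
      se <- rep(NA_real_, nres)
    } else {
      p <- colMeans(labeling$beta_flags[idx, , drop = FALSE])
      se <- bernoulli_se(p, length(idx))
    }
    out[[length(out) + 1L]] <-
      data.frame(cluster = cl, residue = seq_len(nres), p = p, se = se,
                 n = length(idx))
  }
  do.call(rbind, out)
}

# mean beta propensity over the partner blob's residues within one cluster
.partner_peak <- function(labeling, partition, partner) {
  bi <- match(partner, partition$blobs$label)
  res <- partition$blobs$start[bi]:partition$blobs$end[bi]
  vapply(levels(labeling$cluster), function(cl) {
    idx <- which(labeling$cluster == cl)
    if (length(idx) == 0L) return(c(p = NA_real_, n = 0))
    c(p = mean(labeling$beta_flags[idx, res, drop = FALSE]),
      n = length(idx))
  }, numeric(2))
}

#' Detect symmetrically coupled contact / beta blob pairs
#'
#' A pair (X, Y) is reported when the mean beta propensity over Y's
#' residues in the (contacting, beta-present-in-X) cluster exceeds the
#' same statistic in each of the other three clusters by more than
#' \code{z} pooled standard errors, and the reciprocal test with the roles
#' of X and Y swapped also passes. Only non-adjacent pairs from different
#' groups are scanned.
#'
#' @param traj A \code{traj_ensemble} with dihedrals.
#' @param partition A \code{blob_partition}.
#' @param z Significance threshold in pooled standard errors (default 3).
#' @param pairs Optional two-column matrix / data.frame of blob labels to
#'   restrict the scan.
#' @param cutoff,min_run Passed to \code{\link{four_cluster}}.
#' @return data.frame of detected pairs with the forward and reciprocal
#'   minimal z-scores (zero rows when nothing is detected).
#' @export
detect_symmetric_coupling <- function(traj, partition, z = 3, pairs = NULL,
                                      cutoff = 0.55, min_run = 4L) {
  b <- partition$blobs
  if (is.null(pairs)) {
    cmb <- t(combn(b$label, 2L))
  } else {
    cmb <- as.matrix(pairs)
  }
  one_direction <- function(x, y) {
    lab <- four_cluster(traj, partition, x, y, cutoff = cutoff,
                        min_run = min_run, force = TRUE)
    pk <- .partner_peak(lab, partition, y)
    target <- pk["p", "contacting.present"]
    n_t <- pk["n", "contacting.present"]
    if (is.na(target) || n_t == 0) return(NA_real_)
    others <- setdiff(colnames(pk), "contacting.present")
    zs <- vapply(others, function(cl) {
      p2 <- pk["p", cl]
      n2 <- pk["n", cl]
      if (is.na(p2) || n2 == 0) return(NA_real_)
      pooled <- sqrt(bernoulli_se(target, n_t)^2 + bernoulli_se(p2, n2)^2)
      if (pooled == 0) {
        if (target > p2) Inf else 0
      } else {
        (target - p2) / pooled
      }
    }, numeric(1))
    if (anyNA(zs)) NA_real_ else min(zs)
  }
  hits <- list()
  for (k in seq_len(nrow(cmb))) {
    x <- cmb[k, 1L]
    y <- cmb[k, 2L]
    if (!.eligible_pair(partition, x, y)$eligible) next
    z_fwd <- one_direction(x, y)
    if (is.na(z_fwd) || z_fwd <= z) next
    z_rev <- one_direction(y, x)
    if (is.na(z_rev) || z_rev <= z) next
    hits[[length(hits) + 1L]] <-
      data.frame(x = x, y = y, z_forward = z_fwd, z_reverse = z_rev)
  }
  if (length(hits) == 0L) {
    return(data.frame(x = character(), y = character(),
                      z_forward = numeric(), z_reverse = numeric()))
  }
  do.call(rbind, hits)
}

#' Nine-cluster secondary-structure decomposition of residue contacts
#'
#' Each unmasked frame is labelled by the secondary-structure state of two
#' blobs (helix / beta / coil): a blob is "helix" when at least one of its
#' residues is inside a helix run and none inside a beta run, "beta"
#' symmetrically, and "coil" when neither; frames where a blob carries
#' both states are excluded and counted. Residue-level CA contact maps are
#' computed within each of the nine clusters.
#'
#' @param traj A \code{traj_ensemble} with dihedrals.
#' @param partition A \code{blob_partition}.
#' @param blob_a,blob_b Blob labels.
#' @param min_run Run threshold (default 4).
#' @param cutoff Residue contact cutoff (nm, default 0.8).
#' @return List with \code{counts} (3 x 3 matrix of frame counts),
#'   \code{excluded} (frames with mixed states), \code{maps} (named list
#'   of \code{\link{contact_map}}s for non-empty clusters) and the
#'   per-frame \code{state_a}, \code{state_b} factors.
#' @export
nine_cluster <- function(traj, partition, blob_a, blob_b, min_run = 4L,
                         cutoff = 0.8) {
  keep <- .unmasked(traj)
  track <- rama_track(traj)[keep, , drop = FALSE]
  helix_flags <- annotate_runs(track, "helix", min_run)
  beta_flags <- annotate_runs(track, "beta", min_run)
  blob_state <- function(label) {
    bi <- match(label, partition$blobs$label)
    res <- partition$blobs$start[bi]:partition$blobs$end[bi]
    h <- rowSums(helix_flags[, res, drop = FALSE]) > 0L
    bta <- rowSums(beta_flags[, res, drop = FALSE]) > 0L
    st <- rep("coil", length(h))
    st[h & !bta] <- "helix"
    st[bta & !h] <- "beta"
    st[h & bta] <- "mixed"
    st
  }
  sa <- blob_state(blob_a)
  sb <- blob_state(blob_b)
  ok <- sa != "mixed" & sb != "mixed"
  lv <- c("helix", "beta", "coil")
  counts <- table(factor(sa[ok], lv), factor(sb[ok], lv))
  maps <- list()
  sub <- subset_frames(traj, keep)
  for (a in lv) {
    for (b2 in lv) {
      idx <- which(ok & sa == a & sb == b2)
      if (length(idx) == 0L) next
      maps[[paste(a, b2, sep = ".")]] <-
        residue_contact_map(subset_frames(sub, idx), cutoff = cutoff)
    }
  }
  list(counts = counts, excluded = sum(!ok), maps = maps,
       state_a = factor(sa, c(lv, "mixed")),
       state_b = factor(sb, c(lv, "mixed")))
}
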