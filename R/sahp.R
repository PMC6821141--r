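#' Self-avoiding heteropolymer (SAHP) null model
#'
#' A freely-jointed chain of hard spheres, one monomer per blob in sequence
#' order. Monomer radii are the ensemble-mean blob radii of gyration; the
#' bond between monomers i-1 and i is constrained to
#' \eqn{(\langle R_{etoe,i-1}\rangle + \langle R_{etoe,i}\rangle)/2}. Two
#' monomers at sequence separation of at least 2 overlap (hard-core
#' rejection) when their distance is below \eqn{a (R_i + R_j)}.
#'
#' @param mean_rg Monomer radii: per-blob ensemble-mean Rg (nm).
#' @param mean_retoe Per-blob ensemble-mean end-to-end distance (nm).
#' @param labels Optional monomer labels (blob labels).
#' @param classes Optional blob classes ("h"/"p"), used by
#'   \code{\link{segment_regions}}.
#' @param a Hard-core factor (default 0.3).
#' @param step Monte Carlo displacement magnitude (nm, default 0.5).
#' @param cutoff Contact cutoff on the excess distance (nm, default 0.55).
#' @return Object of class \code{"sahp_model"}.
#' @export
sahp_model <- function(mean_rg, mean_retoe, labels = NULL, classes = NULL,
                       a = 0.3, step = 0.5, cutoff = 0.55) {
  stopifnot(length(mean_rg) == length(mean_retoe),
            all(mean_rg > 0), all(mean_retoe > 0), a > 0, step > 0)
  n <- length(mean_rg)
  if (n < 2L) stop("need at least 2 monomers", call. = FALSE)
  if (is.null(labels)) labels <- paste0("m", seq_len(n))
  bonds <- (mean_retoe[-n] + mean_retoe[-1L]) / 2
  structure(list(radii = as.numeric(mean_rg),
                 retoe = as.numeric(mean_retoe),
                 bonds = as.numeric(bonds),
                 labels = labels, classes = classes,
                 a = a, step = step, cutoff = cutoff),
            class = "sahp_model")
}

#' @export
print.sahp_model <- function(x, ...) {
  cat("<sahp_model> ", length(x$radii), " monomers, a = ", x$a,
      ", step = ", x$step, " nm, contact cutoff = ", x$cutoff, " nm\n",
      sep = "")
  print(data.frame(label = x$labels, radius = signif(x$radii, 3),
                   bond_to_next = signif(c(x$bonds, NA), 3)),
        row.names = FALSE)
  invisible(x)
}

#' Parameterize a SAHP from ensemble blob geometry
#'
#' @param geom A \code{\link{blob_geometry}} summary (or data.frame with
#'   columns \code{label}, \code{mean_rg}, \code{mean_retoe}).
#' @param classes Optional blob classes; taken from a partition via
#'   \code{partition$blobs$class} when building \code{geom} by hand.
#' @param ... Passed to \code{\link{sahp_model}}.
#' @return A \code{sahp_model}.
#' @export
sahp_parameterize <- function(geom, classes = NULL, ...) {
  stopifnot(all(c("label", "mean_rg", "mean_retoe") %in% names(geom)))
  sahp_model(geom$mean_rg, geom$mean_retoe, labels = geom$label,
             classes = classes, ...)
}

#' Swap two monomers of a SAHP model
#'
#' Exchanges the monomers' radii and end-to-end parameters (and labels /
#' classes) and recomputes every bond from the swapped order.
#'
#' @param model A \code{sahp_model}.
#' @param i,j Monomer indices or labels.
#' @return A new \code{sahp_model}.
#' @export
swap_monomers <- function(model, i, j) {
  stopifnot(inherits(model, "sahp_model"))
  if (is.character(i)) i <- match(i, model$labels)
  if (is.character(j)) j <- match(j, model$labels)
  ord <- seq_along(model$radii)
  ord[c(i, j)] <- ord[c(j, i)]
  sahp_model(model$radii[ord], model$retoe[ord], model$labels[ord],
             if (is.null(model$classes)) NULL else model$classes[ord],
             a = model$a, step = model$step, cutoff = model$cutoff)
}

#' One Monte Carlo trial move (reference implementation)
#'
#' The move set of the SAHP sampler, exposed for inspection and testing:
#' a bead \code{i > 1} is displaced by a random vector of fixed magnitude,
#' the displaced position is rescaled along the direction from bead i-1 so
#' the constrained bond length is preserved, and the whole tail from bead i
#' onward is translated rigidly by the final displacement.
#'
#' @param positions n x 3 matrix of bead positions.
#' @param bonds Length n-1 vector of constrained bond lengths.
#' @param i Bead to move (2..n); drawn uniformly when \code{NULL}.
#' @param step Displacement magnitude (nm).
#' @return The candidate n x 3 position matrix (bond lengths preserved).
#' @export
sahp_propose_move <- function(positions, bonds, i = NULL, step = 0.5) {
  n <- nrow(positions)
  if (is.null(i)) i <- sample(2:n, 1L)
  stopifnot(i >= 2L, i <= n)
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  cand <- positions[i, ] + step * u
  dir <- cand - positions[i - 1L, ]
  dir <- dir / sqrt(sum(dir^2))
  newp <- positions[i - 1L, ] + bonds[i - 1L] * dir
  delta <- newp - positions[i, ]
  positions[i:n, ] <- sweep(positions[i:n, , drop = FALSE], 2L, delta, "+")
  positions
}

#' Run the SAHP Metropolis Monte Carlo
#'
#' Samples the model by single-bead constrained displacements with rigid
#' tail translation; any trial causing a hard-core overlap is rejected and
#' every other trial is accepted. Configurations are recorded every
#' \code{sample_every} steps after a burn-in discard.
#'
#' @param model A \code{sahp_model}.
#' @param steps Total Monte Carlo steps (default 5e6).
#' @param sample_every Recording stride in steps (default 100).
#' @param burnin_frac Fraction of steps discarded before recording
#'   (default 0.1).
#' @param seed Optional integer seed (\code{set.seed}); identical seeds
#'   give bit-identical samples.
#' @param keep_positions Store recorded configurations (default TRUE).
#' @return Object of class \code{"sahp_sample"}: \code{counts} (contact
#'   co-occurrence), \code{n_samples}, \code{acceptance_rate},
#'   \code{positions} (n_samples x n x 3, if kept) and the \code{model}.
#' @export
sahp_run <- function(model, steps = 5e6, sample_every = 100L,
                     burnin_frac = 0.1, seed = NULL, keep_positions = TRUE) {
  stopifnot(inherits(model, "sahp_model"))
  if (!is.null(seed)) set.seed(seed)
  burnin <- floor(steps * burnin_frac)
  res <- .sahp_mc_cpp(model$bonds, model$radii, model$a, model$step,
                      as.double(steps), as.integer(sample_every),
                      as.double(burnin), model$cutoff, keep_positions)
  positions <- NULL
  if (keep_positions) {
    # C++ returns axis-major (3 x n x n_samples); reorder to samples x n x 3
    positions <- aperm(res$positions, c(3L, 2L, 1L))
  }
  structure(list(counts = res$counts, n_samples = res$n_samples,
                 acceptance_rate = res$acceptance_rate,
                 positions = positions, model = model),
            class = "sahp_sample")
}

#' @export
print.sahp_sample <- function(x, ...) {
  cat("<sahp_sample> ", x$n_samples, " recorded configurations, ",
      "acceptance ", signif(x$acceptance_rate, 3), "\n", sep = "")
  invisible(x)
}

#' Contact map of a SAHP sample
#'
#' Monomers i and j are in contact when
#' \eqn{|r_i - r_j| - (R_i + R_j) < cutoff}, mirroring the real-protein
#' excess-distance rule with the model's (ensemble-mean) radii.
#'
#' @param sample A \code{sahp_sample}.
#' @param cutoff Contact cutoff (nm); defaults to the model's. When it
#'   differs from the cutoff used during the run, contacts are recounted
#'   from the stored configurations.
#' @param n_eff Effective sample size for standard errors (defaults to the
#'   number of recorded configurations).
#' @return A \code{\link{contact_map}} at blob level.
#' @export
sahp_contact_map <- function(sample, cutoff = NULL, n_eff = NULL) {
  stopifnot(inherits(sample, "sahp_sample"))
  model <- sample$model
  if (is.null(cutoff)) cutoff <- model$cutoff
  n <- length(model$radii)
  if (cutoff == model$cutoff) {
    counts <- sample$counts
  } else {
    if (is.null(sample$positions)) {
      stop("positions not stored; rerun with keep_positions = TRUE",
           call. = FALSE)
    }
    counts <- matrix(0, n, n)
    for (s in seq_len(dim(sample$positions)[1])) {
      d <- as.matrix(dist(sample$positions[s, , ]))
      hit <- (d - outer(model$radii, model$radii, "+")) < cutoff
      diag(hit) <- FALSE
      counts <- counts + hit
    }
  }
  dimnames(counts) <- list(model$labels, model$labels)
  p <- counts / sample$n_samples
  diag(p) <- NA_real_
  if (is.null(n_eff)) n_eff <- sample$n_samples
  contact_map(p, counts, n_eff, "blob", cutoff,
              "SAHP monomer excess distance |r_i-r_j|-(R_i+R_j) < cutoff (strict)")
}

#' Direct (independence) sampler for the SAHP
#'
#' Unbiased reference sampler: bond directions drawn independently and
#' uniformly on the sphere, configurations with any hard-core overlap
#' rejected outright. Serves as an oracle for the Markov-chain sampler.
#'
#' @param model A \code{sahp_model}.
#' @param n_samples Number of accepted configurations to collect.
#' @param batch Proposals generated per vectorised batch.
#' @param max_batches Safety cap on batches.
#' @return A \code{\link{contact_map}} at blob level (attribute
#'   \code{"n_proposed"} records the total proposals used).
#' @export
sahp_direct_sample <- function(model, n_samples = 1e5, batch = 2e4,
                               max_batches = 5000L) {
  stopifnot(inherits(model, "sahp_model"))
  n <- length(model$radii)
  counts <- matrix(0, n, n)
  got <- 0
  proposed <- 0
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  far <- pairs[pairs[, 2L] - pairs[, 1L] >= 2L, , drop = FALSE]
  for (b in seq_len(max_batches)) {
    m <- min(batch, ceiling((n_samples - got) * 2) + 1000L)
    dirs <- array(rnorm(m * (n - 1L) * 3), c(m, n - 1L, 3L))
    nrm <- sqrt(dirs[, , 1L]^2 + dirs[, , 2L]^2 + dirs[, , 3L]^2)
    pos <- array(0, c(m, n, 3L))
    for (k in 2:n) {
      for (ax in 1:3) {
        pos[, k, ax] <- pos[, k - 1L, ax] +
          model$bonds[k - 1L] * dirs[, k - 1L, ax] / nrm[, k - 1L]
      }
    }
    pd <- function(i, j) {
      sqrt((pos[, i, 1L] - pos[, j, 1L])^2 + (pos[, i, 2L] - pos[, j, 2L])^2 +
             (pos[, i, 3L] - pos[, j, 3L])^2)
    }
    ok <- rep(TRUE, m)
    if (nrow(far) > 0L) {
      for (k in seq_len(nrow(far))) {
        i <- far[k, 1L]
        j <- far[k, 2L]
        ok <- ok & (pd(i, j) >= model$a * (model$radii[i] + model$radii[j]))
      }
    }
    idx <- which(ok)
    if (got + length(idx) > n_samples) idx <- idx[seq_len(n_samples - got)]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]
      j <- pairs[k, 2L]
      hit <- sum(pd(i, j)[idx] - (model$radii[i] + model$radii[j]) <
                   model$cutoff)
      counts[i, j] <- counts[i, j] + hit
      counts[j, i] <- counts[i, j]
    }
    got <- got + length(idx)
    proposed <- proposed + m
    if (got >= n_samples) break
  }
  if (got == 0L) stop("direct sampler accepted no configurations", call. = FALSE)
  dimnames(counts) <- list(model$labels, model$labels)
  p <- counts / got
  diag(p) <- NA_real_
  cm <- contact_map(p, counts, got, "blob", model$cutoff,
                    "direct-sampling SAHP reference (independent bonds + rejection)")
  attr(cm, "n_proposed") <- proposed
  cm
}

#' Enrichment of real-protein contacts over the SAHP expectation
#'
#' Ratio of real-protein (RP) contact probabilities to the SAHP null
#' expectation, per blob pair or aggregated to region pairs. Standard
#' errors are propagated from both Bernoulli errors; pairs with zero SAHP
#' probability but nonzero RP probability are flagged infinite.
#'
#' @param rp_map,sahp_map Blob-level \code{\link{contact_map}}s over the
#'   same blob set.
#' @param regions Optional region labels (per blob) switching to
#'   region-pair aggregation of mean probabilities.
#' @return For blob pairs: list with \code{ratio} and \code{se} matrices.
#'   For regions: data.frame with region pair, RP and SAHP means, ratio
#'   and propagated SE.
#' @export
enrichment <- function(rp_map, sahp_map, regions = NULL) {
  stopifnot(inherits(rp_map, "contact_map"), inherits(sahp_map, "contact_map"),
            identical(dim(rp_map$p), dim(sahp_map$p)))
  if (is.null(regions)) {
    ratio <- rp_map$p / sahp_map$p
    ratio[sahp_map$p == 0 & rp_map$p > 0] <- Inf
    rel <- sqrt((rp_map$se / rp_map$p)^2 + (sahp_map$se / sahp_map$p)^2)
    se <- abs(ratio) * rel
    se[!is.finite(ratio)] <- NA_real_
    return(list(ratio = ratio, se = se))
  }
  rp <- region_contact_stats(rp_map, regions)
  sp <- region_contact_stats(sahp_map, regions)
  stopifnot(identical(rp[c("region_a", "region_b")],
                      sp[c("region_a", "region_b")]))
  se_mean <- function(map, stats) {
    vapply(seq_len(nrow(stats)), function(k) {
      ia <- which(regions == stats$region_a[k])
      ib <- which(regions == stats$region_b[k])
      ses <- c()
      for (i in ia) for (j in ib) {
        if (i < j) ses <- c(ses, map$se[i, j])
        if (stats$region_a[k] != stats$region_b[k] && j < i)
          ses <- c(ses, map$se[j, i])
      }
      sqrt(sum(ses^2)) / length(ses)
    }, numeric(1))
  }
  rp_se <- se_mean(rp_map, rp)
  sp_se <- se_mean(sahp_map, sp)
  ratio <- rp$mean_p / sp$mean_p
  ratio[sp$mean_p == 0 & rp$mean_p > 0] <- Inf
  se <- abs(ratio) * sqrt((rp_se / rp$mean_p)^2 + (sp_se / sp$mean_p)^2)
  se[!is.finite(ratio)] <- NA_real_
  data.frame(region_a = rp$region_a, region_b = rp$region_b,
             rp_mean = rp$mean_p, sahp_mean = sp$mean_p,
             ratio = ratio, se = se)
}

#' Segment a chain into regions at its most isolating linker
#'
#' Among the model's p (linker) monomers with neighbours on both sides,
#' selects the one whose mean contact probability between the upstream and
#' downstream blocks is minimal; blobs before it form Region I, the linker
#' Region II, blobs after it Region III.
#'
#' @param map A blob-level \code{\link{contact_map}} (typically from the
#'   SAHP null model).
#' @param classes Character vector of blob classes ("h"/"p") in map order,
#'   or a \code{blob_partition} / \code{sahp_model} carrying them.
#' @return List with \code{regions} (character vector I/II/III per blob,
#'   named by blob label when available), \code{linker} (index of the
#'   segmenting blob) and \code{cross_means} (per candidate linker).
#' @export
segment_regions <- function(map, classes) {
  stopifnot(inherits(map, "contact_map"))
  if (inherits(classes, "blob_partition")) classes <- classes$blobs$class
  if (inherits(classes, "sahp_model")) classes <- classes$classes
  nb <- nrow(map$p)
  stopifnot(length(classes) == nb)
  cand <- which(classes == "p" & seq_len(nb) > 1L & seq_len(nb) < nb)
  if (length(cand) == 0L) {
    warning("no interior p blob; chain left unsegmented")
    regions <- rep("I", nb)
    names(regions) <- rownames(map$p)
    return(list(regions = regions, linker = NA_integer_,
                cross_means = numeric(0)))
  }
  cross <- vapply(cand, function(k) {
    mean(map$p[seq_len(k - 1L), (k + 1L):nb])
  }, numeric(1))
  names(cross) <- if (!is.null(rownames(map$p))) rownames(map$p)[cand] else cand
  linker <- cand[which.min(cross)]
  regions <- rep("III", nb)
  regions[seq_len(linker - 1L)] <- "I"
  regions[linker] <- "II"
  names(regions) <- rownames(map$p)
  list(regions = regions, linker = linker, cross_means = cross)
}
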