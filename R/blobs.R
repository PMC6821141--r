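#' Decompose a sequence into hydrophobic blobs, linkers and groups
#'
#' Digitizes the windowed scaled-hydropathy profile at \code{cutoff}
#' (strictly greater-than) and identifies maximal super-threshold runs of at
#' least \code{min_blob} residues as hydrophobic "h" blobs. The remaining
#' maximal stretches of at least \code{min_blob} residues become linker "p"
#' blobs; shorter leftover stretches are unassigned. Consecutive h blobs
#' with no intervening p blob are merged into a single group, and unassigned
#' stretches lying between two h blobs of a group belong to that group (but
#' to no blob). Blobs are labelled in sequence order: p groups carry their
#' single blob (p1, p2, ...), h groups index their blobs with letters
#' (h1a, h1b, ...).
#'
#' @param seq A \code{\link{sequence_record}} or a raw sequence string.
#' @param cutoff Hydropathy cutoff on the scaled profile (default 0.37).
#' @param min_blob Minimum blob length in residues (default 4).
#' @param window Smoothing window for \code{\link{hydropathy_profile}}.
#' @param offset Author numbering offset when \code{seq} is a raw string.
#' @return An object of class \code{"blob_partition"}: list with
#'   \code{blobs} (data.frame: label, class, start, end, length — local
#'   1-based inclusive indices), \code{groups} (list of label, blobs,
#'   unassigned indices), \code{unassigned} (integer vector of all
#'   unassigned residues), \code{profile}, \code{sequence}, \code{offset},
#'   and \code{regions} (NULL until assigned).
#' @export
identify_blobs <- function(seq, cutoff = 0.37, min_blob = 4L, window = 3L,
                           offset = 1L) {
  rec <- .as_seqrec(seq, offset = offset)
  n <- length(rec$residues)
  min_blob <- as.integer(min_blob)

  if (n < min_blob) {
    warning("sequence shorter than min_blob; single unassigned segment")
    part <- list(blobs = data.frame(label = character(), class = character(),
                                    start = integer(), end = integer(),
                                    length = integer(),
                                    stringsAsFactors = FALSE),
                 groups = list(), unassigned = seq_len(n),
                 profile = hydropathy_profile(rec$residues,
                                              min(window, n - !(n %% 2L))),
                 sequence = rec, offset = rec$offset, regions = NULL,
                 cutoff = cutoff, min_blob = min_blob, window = window)
    return(structure(part, class = "blob_partition"))
  }

  prof <- hydropathy_profile(rec$residues, window)
  digit <- prof > cutoff

  # maximal super-threshold runs of >= min_blob residues are h blobs
  r <- rle(digit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_h_run <- r$values & r$lengths >= min_blob

  h_runs <- cbind(starts[is_h_run], ends[is_h_run])

  # complement of the h blobs: gaps >= min_blob are p blobs, shorter gaps
  # are unassigned
  in_h <- rep(FALSE, n)
  if (nrow(h_runs) > 0L) {
    for (k in seq_len(nrow(h_runs))) in_h[h_runs[k, 1]:h_runs[k, 2]] <- TRUE
  }
  rg <- rle(in_h)
  g_ends <- cumsum(rg$lengths)
  g_starts <- g_ends - rg$lengths + 1L
  p_runs <- cbind(g_starts[!rg$values & rg$lengths >= min_blob],
                  g_ends[!rg$values & rg$lengths >= min_blob])
  u_runs <- cbind(g_starts[!rg$values & rg$lengths < min_blob],
                  g_ends[!rg$values & rg$lengths < min_blob])

  segs <- rbind(
    if (nrow(h_runs)) data.frame(class = "h", start = h_runs[, 1],
                                 end = h_runs[, 2]),
    if (nrow(p_runs)) data.frame(class = "p", start = p_runs[, 1],
                                 end = p_runs[, 2])
  )
  if (is.null(segs) || nrow(segs) == 0L) {
    segs <- data.frame(class = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  }
  segs <- segs[order(segs$start), , drop = FALSE]

  unassigned <- integer(0)
  if (nrow(u_runs) > 0L) {
    unassigned <- unlist(lapply(seq_len(nrow(u_runs)),
                                function(k) u_runs[k, 1]:u_runs[k, 2]))
  }

  # group assembly: consecutive h blobs (separated only by unassigned
  # stretches) share a group; each p blob is its own group
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
      # unassigned residues between member blobs belong to the group
      grp_un <- integer(0)
      if (length(members) > 1L) {
        for (k in members[-length(members)]) {
          gap <- (segs$end[k] + 1L):(segs$start[k + 1L] - 1L)
          if (length(gap) > 0L && segs$end[k] + 1L <= segs$start[k + 1L] - 1L) {
            grp_un <- c(grp_un, gap)
          }
        }
      }
      groups[[length(groups) + 1L]] <-
        list(label = paste0("h", h_idx),
             blobs = labels[members], unassigned = grp_un)
      i <- j + 1L
    }
  }

  blobs <- data.frame(label = labels, class = segs$class,
                      start = segs$start, end = segs$end,
                      length = segs$end - segs$start + 1L,
                      stringsAsFactors = FALSE)

  structure(list(blobs = blobs, groups = groups, unassigned = unassigned,
                 profile = prof, sequence = rec, offset = rec$offset,
                 regions = NULL, cutoff = cutoff, min_blob = min_blob,
                 window = window),
            class = "blob_partition")
}

#' @export
print.blob_partition <- function(x, ...) {
  cat("<blob_partition> ", length(x$sequence$residues), " residues: ",
      sum(x$blobs$class == "h"), " h blob(s), ",
      sum(x$blobs$class == "p"), " p blob(s), ",
      length(x$unassigned), " unassigned residue(s)\n", sep = "")
  if (nrow(x$blobs) > 0L) {
    b <- x$blobs
    b$author <- paste0(b$start + x$offset - 1L, "-", b$end + x$offset - 1L)
    b$sequence <- vapply(seq_len(nrow(b)), function(i) {
      paste(x$sequence$residues[b$start[i]:b$end[i]], collapse = "")
    }, character(1))
    print(b[, c("label", "class", "author", "length", "sequence")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Extract a blob's subsequence
#'
#' @param partition A \code{blob_partition}.
#' @param label Blob label (e.g. "h2b").
#' @return Character vector of residues.
#' @export
blob_sequence <- function(partition, label) {
  i <- match(label, partition$blobs$label)
  if (is.na(i)) stop("no blob labelled ", label, call. = FALSE)
  partition$sequence$residues[partition$blobs$start[i]:partition$blobs$end[i]]
}

.charge <- function(residues) {
  ch <- numeric(length(residues))
  ch[residues %in% c("D", "E")] <- -1
  ch[residues %in% c("K", "R")] <- 1
  ch
}

#' Per-blob sequence metrics
#'
#' Composition metrics for a (sub)sequence: residue count, unwindowed mean
#' scaled hydropathy, net charge per residue (NCPR), fraction of charged
#' residues (FCR), positive/negative fractions and proline fraction. D and
#' E carry charge -1, K and R +1; histidine and the termini are treated as
#' neutral. Charge-patterning kappa and the phase/Uversky classifications
#' are filled in from \code{\link{kappa}}, \code{\link{classify_phase}} and
#' \code{\link{classify_uversky}}.
#'
#' @param subsequence Sequence string or character vector.
#' @param kappa_windows Window sizes passed to \code{\link{kappa}}.
#' @return A one-row data.frame with columns \code{N}, \code{NCPR},
#'   \code{meanH}, \code{FCR}, \code{f_minus}, \code{f_plus}, \code{kappa},
#'   \code{proline_fraction}, \code{phase_region}, \code{uversky_class}.
#' @export
blob_metrics <- function(subsequence, kappa_windows = c(5L, 6L)) {
  res <- .split_seq(subsequence)
  if (length(res) == 0L) stop("non-empty subsequence required", call. = FALSE)
  n <- length(res)
  ch <- .charge(res)
  f_plus <- sum(ch > 0) / n
  f_minus <- sum(ch < 0) / n
  meanH <- mean(scale_hydropathy(res))
  ncpr <- f_plus - f_minus
  kap <- kappa(res, windows = kappa_windows)
  data.frame(N = n, NCPR = ncpr, meanH = meanH, FCR = f_plus + f_minus,
             f_minus = f_minus, f_plus = f_plus,
             kappa = as.numeric(kap),
             proline_fraction = sum(res == "P") / n,
             phase_region = classify_phase(f_plus, f_minus),
             uversky_class = classify_uversky(meanH, ncpr),
             stringsAsFactors = FALSE)
}

#' Das-Pappu phase-diagram region
#'
#' Classifies a sequence by its charge fractions into the five regions of
#' the Das-Pappu diagram of IDP states: 1 weak polyampholytes/polyelectrolytes
#' (globule formers), 2 Janus/boundary sequences, 3 strong polyampholytes,
#' 4 negative and 5 positive strong polyelectrolytes.
#'
#' @param f_plus,f_minus Fractions of positively and negatively charged
#'   residues, each in \eqn{[0, 1]} with sum at most 1.
#' @return Integer region 1-5 (vectorised).
#' @export
classify_phase <- function(f_plus, f_minus) {
  stopifnot(all(f_plus >= 0 & f_plus <= 1), all(f_minus >= 0 & f_minus <= 1),
            all(f_plus + f_minus <= 1 + 1e-12))
  fcr <- f_plus + f_minus
  ncpr <- f_plus - f_minus
  out <- integer(length(fcr))
  out[fcr < 0.25] <- 1L
  out[fcr >= 0.25 & fcr <= 0.35] <- 2L
  strong <- fcr > 0.35
  out[strong & abs(ncpr) <= 0.35] <- 3L
  out[strong & abs(ncpr) > 0.35 & ncpr < 0] <- 4L
  out[strong & abs(ncpr) > 0.35 & ncpr > 0] <- 5L
  out
}

#' Uversky folded/disordered classification
#'
#' Applies the Uversky charge-hydropathy boundary: a sequence is predicted
#' folded iff its normalized mean hydropathy exceeds
#' \eqn{(|NCPR| + 1.151)/2.785}; boundary points are classed disordered
#' (strict inequality for folded).
#'
#' @param meanH Normalized mean hydropathy in \eqn{[0, 1]}.
#' @param NCPR Net charge per residue.
#' @return Character vector, \code{"folded"} or \code{"disordered"}.
#' @export
classify_uversky <- function(meanH, NCPR) {
  stopifnot(all(meanH >= 0 & meanH <= 1))
  ifelse(meanH > (abs(NCPR) + 1.151) / 2.785, "folded", "disordered")
}

#' Blob metrics table for a partition
#'
#' Computes \code{\link{blob_metrics}} for every blob of a partition,
#' returning a table in the style used for publication blob summaries
#' (label, class, author-numbered range, metrics, sequence).
#'
#' @param partition A \code{blob_partition}.
#' @return data.frame, one row per blob.
#' @export
blob_table <- function(partition) {
  stopifnot(inherits(partition, "blob_partition"))
  b <- partition$blobs
  rows <- lapply(seq_len(nrow(b)), function(i) {
    sq <- blob_sequence(partition, b$label[i])
    m <- blob_metrics(sq)
    cbind(data.frame(blob = b$label[i], class = b$class[i],
                     start_author = b$start[i] + partition$offset - 1L,
                     end_author = b$end[i] + partition$offset - 1L,
                     stringsAsFactors = FALSE),
          m, data.frame(sequence = paste(sq, collapse = ""),
                        stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
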