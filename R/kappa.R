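#' Das-Pappu charge-patterning parameter kappa
#'
#' Quantifies how segregated (1) or well-mixed (0) the charged residues of
#' a sequence are. For each window size g the local charge asymmetry
#' \eqn{\sigma = (f_+ - f_-)^2 / (f_+ + f_-)} is computed over every
#' overlapping window and \eqn{\delta_g} is the mean squared deviation of
#' the window values from the whole-sequence asymmetry; \eqn{\delta} is the
#' mean of \eqn{\delta_g} over the requested window sizes, and
#' \eqn{\kappa = \delta / \delta_{max}} where \eqn{\delta_{max}} is the
#' maximum \eqn{\delta} over rearrangements of the same composition.
#' Windows with no charged residue contribute \eqn{\sigma = 0}.
#'
#' \eqn{\delta_{max}} is found by exhaustive enumeration of all distinct
#' charge patterns for sequences of up to 10 residues, and otherwise by a
#' constructive search over block arrangements (contiguous + and - blocks
#' with the neutral residues split around them, both charge orders)
#' refined by pairwise-swap hill climbing.
#'
#' @param subsequence Sequence string or character vector (or a numeric
#'   charge vector in \{-1, 0, 1\}).
#' @param windows Integer window sizes (default 5 and 6).
#' @return kappa in \eqn{[0, 1]}, or \code{NA} with attribute
#'   \code{"reason"} (\code{"too short"} or \code{"no charges"}) when
#'   undefined: the sequence must be at least \code{max(windows)} residues
#'   long and contain at least one charged residue.
#' @export
kappa <- function(subsequence, windows = c(5L, 6L)) {
  ch <- if (is.numeric(subsequence)) subsequence else .charge(.split_seq(subsequence))
  windows <- as.integer(windows)
  if (length(ch) < max(windows)) {
    return(structure(NA_real_, reason = "too short"))
  }
  if (all(ch == 0)) {
    return(structure(NA_real_, reason = "no charges"))
  }
  d <- charge_delta(ch, windows)
  dmax <- delta_max(ch, windows)
  if (dmax <= 0) return(structure(NA_real_, reason = "no charges"))
  unname(d / dmax)
}

.sigma <- function(fp, fm) {
  tot <- fp + fm
  ifelse(tot == 0, 0, (fp - fm)^2 / tot)
}

#' Charge-asymmetry deviation delta
#'
#' The window-averaged squared deviation of local charge asymmetry from the
#' whole-sequence asymmetry, averaged over the requested window sizes. This
#' is the numerator of \code{\link{kappa}}.
#'
#' @inheritParams kappa
#' @return Non-negative numeric scalar.
#' @export
charge_delta <- function(subsequence, windows = c(5L, 6L)) {
  ch <- if (is.numeric(subsequence)) subsequence else .charge(.split_seq(subsequence))
  n <- length(ch)
  pos <- cumsum(c(0, ch > 0))
  neg <- cumsum(c(0, ch < 0))
  sig_seq <- .sigma(sum(ch > 0) / n, sum(ch < 0) / n)
  per_g <- vapply(as.integer(windows), function(g) {
    if (g > n) return(NA_real_)
    i <- seq_len(n - g + 1L)
    fp <- (pos[i + g] - pos[i]) / g
    fm <- (neg[i + g] - neg[i]) / g
    mean((.sigma(fp, fm) - sig_seq)^2)
  }, numeric(1))
  mean(per_g, na.rm = TRUE)
}

# all distinct arrangements of a charge multiset (recursion over symbols)
.multiset_perms <- function(counts) {
  syms <- c(-1, 0, 1)
  out <- list()
  recurse <- function(prefix, cnt) {
    if (sum(cnt) == 0L) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (s in seq_along(syms)) {
      if (cnt[s] > 0L) {
        cnt2 <- cnt
        cnt2[s] <- cnt2[s] - 1L
        recurse(c(prefix, syms[s]), cnt2)
      }
    }
  }
  recurse(numeric(0), counts)
  out
}

.block_candidates <- function(n_plus, n_zero, n_minus) {
  cands <- list()
  for (a in 0:n_zero) {
    for (b in 0:(n_zero - a)) {
      cc <- n_zero - a - b
      cands[[length(cands) + 1L]] <-
        c(rep(0, a), rep(1, n_plus), rep(0, b), rep(-1, n_minus), rep(0, cc))
      cands[[length(cands) + 1L]] <-
        c(rep(0, a), rep(-1, n_minus), rep(0, b), rep(1, n_plus), rep(0, cc))
    }
  }
  # one charge species flanking the other from both termini, with the
  # neutrals as inner spacers (optimal for some asymmetric compositions)
  for (roles in list(c(1, -1), c(-1, 1))) {
    n_out <- if (roles[1] == 1) n_plus else n_minus
    n_in <- if (roles[1] == 1) n_minus else n_plus
    for (l in 0:n_out) {
      for (a in 0:n_zero) {
        cands[[length(cands) + 1L]] <-
          c(rep(roles[1], l), rep(0, a), rep(roles[2], n_in),
            rep(0, n_zero - a), rep(roles[1], n_out - l))
      }
    }
  }
  unique(cands)
}

.hill_climb <- function(ch, windows, max_pass = 50L) {
  best <- charge_delta(ch, windows)
  n <- length(ch)
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (ch[i] == ch[j]) next
        cand <- ch
        cand[c(i, j)] <- cand[c(j, i)]
        d <- charge_delta(cand, windows)
        if (d > best + 1e-15) {
          best <- d
          ch <- cand
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  best
}

#' Maximum delta over rearrangements of a composition
#'
#' @inheritParams kappa
#' @param exhaustive_limit Sequences of at most this many residues use full
#'   enumeration of distinct charge patterns.
#' @return The maximal \code{\link{charge_delta}} attainable by rearranging
#'   the sequence's charges.
#' @export
delta_max <- function(subsequence, windows = c(5L, 6L),
                      exhaustive_limit = 10L) {
  ch <- if (is.numeric(subsequence)) subsequence else .charge(.split_seq(subsequence))
  counts <- c(sum(ch == -1), sum(ch == 0), sum(ch == 1))
  if (sum(counts[c(1, 3)]) == 0L) return(0)
  if (length(ch) <= exhaustive_limit) {
    perms <- .multiset_perms(counts)
    return(max(vapply(perms, charge_delta, numeric(1), windows = windows)))
  }
  cands <- .block_candidates(counts[3], counts[2], counts[1])
  deltas <- vapply(cands, charge_delta, numeric(1), windows = windows)
  top <- order(deltas, decreasing = TRUE)[seq_len(min(3L, length(cands)))]
  max(vapply(cands[top], .hill_climb, numeric(1), windows = windows))
}
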