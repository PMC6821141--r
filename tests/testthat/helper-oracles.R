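# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities with the most literal possible loops so they share no
# code path with the package implementations.

# printed-table rounding: half away from zero
round_half_up <- function(x, digits) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# sliding mean with truncated windows at the termini
oracle_sliding_mean <- function(x, window) {
  half <- (window - 1) / 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- c()
    for (j in (i - half):(i + half)) {
      if (j >= 1 && j <= n) acc <- c(acc, x[j])
    }
    out[i] <- mean(acc)
  }
  out
}

# digitized-track scanner: per-residue class h/p/u given a profile
oracle_partition_classes <- function(profile, cutoff = 0.37, min_blob = 4) {
  n <- length(profile)
  above <- profile > cutoff
  cls <- rep("u", n)
  # h blobs: maximal above-threshold runs of >= min_blob
  i <- 1
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      if (j - i + 1 >= min_blob) cls[i:j] <- "h"
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  # p blobs: maximal non-h runs of >= min_blob
  i <- 1
  while (i <= n) {
    if (cls[i] != "h") {
      j <- i
      while (j < n && cls[j + 1] != "h") j <- j + 1
      if (j - i + 1 >= min_blob) cls[i:j] <- "p"
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  cls
}

# run flags by literal scanning
oracle_run_flags <- function(states, target, min_run = 4) {
  one <- function(v) {
    n <- length(v)
    out <- rep(FALSE, n)
    i <- 1
    while (i <= n) {
      if (v[i] == target) {
        j <- i
        while (j < n && v[j + 1] == target) j <- j + 1
        if (j - i + 1 >= min_run) out[i:j] <- TRUE
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
    out
  }
  if (is.null(dim(states))) return(one(states))
  t(apply(states, 1, one))
}

# exact maximal-run length at each position
oracle_run_lengths <- function(states, target) {
  one <- function(v) {
    n <- length(v)
    out <- integer(n)
    i <- 1
    while (i <= n) {
      if (v[i] == target) {
        j <- i
        while (j < n && v[j + 1] == target) j <- j + 1
        out[i:j] <- j - i + 1
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
    out
  }
  if (is.null(dim(states))) return(one(states))
  t(apply(states, 1, one))
}

# pairwise residue contact counting by explicit loops
oracle_residue_counts <- function(ca, cutoff = 0.8) {
  nf <- dim(ca)[1]
  nr <- dim(ca)[2]
  counts <- matrix(0, nr, nr)
  for (f in seq_len(nf)) {
    for (i in seq_len(nr - 1)) {
      for (j in (i + 1):nr) {
        d <- sqrt(sum((ca[f, i, ] - ca[f, j, ])^2))
        if (d <= cutoff) {
          counts[i, j] <- counts[i, j] + 1
          counts[j, i] <- counts[j, i] + 1
        }
      }
    }
  }
  counts
}

# blob-level contact counting from raw coordinates (CA anchor convention)
oracle_blob_counts <- function(ca, blobs, cutoff = 0.55) {
  nf <- dim(ca)[1]
  nb <- nrow(blobs)
  counts <- matrix(0, nb, nb)
  for (f in seq_len(nf)) {
    anc <- matrix(NA, nb, 3)
    rg <- numeric(nb)
    for (b in seq_len(nb)) {
      rng <- blobs$start[b]:blobs$end[b]
      X <- ca[f, rng, , drop = FALSE]
      anc[b, ] <- (X[1, 1, ] + X[1, length(rng), ]) / 2
      cm <- colMeans(X[1, , , drop = TRUE])
      if (length(rng) == 1) cm <- X[1, 1, ]
      rg[b] <- sqrt(mean(apply(X[1, , , drop = FALSE], 2,
                               function(r) sum((r - cm)^2))))
    }
    for (i in seq_len(nb - 1)) {
      for (j in (i + 1):nb) {
        de <- sqrt(sum((anc[i, ] - anc[j, ])^2)) - (rg[i] + rg[j])
        if (de < cutoff) {
          counts[i, j] <- counts[i, j] + 1
          counts[j, i] <- counts[j, i] + 1
        }
      }
    }
  }
  counts
}

# exhaustive delta-max by enumerating every charge pattern of the same
# composition (filters all 3^n patterns; only used for short sequences)
oracle_delta_max <- function(charges, windows = c(5, 6)) {
  n <- length(charges)
  target <- c(sum(charges == -1), sum(charges == 0), sum(charges == 1))
  grid <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), n)))
  best <- -Inf
  for (k in seq_len(nrow(grid))) {
    v <- grid[k, ]
    if (sum(v == -1) == target[1] && sum(v == 0) == target[2] &&
        sum(v == 1) == target[3]) {
      d <- charge_delta(v, windows)
      if (d > best) best <- d
    }
  }
  best
}

# roundtrip counting via string reduction: keep only visits to the two
# extremes, collapse repeats, and count "low high low" patterns
oracle_roundtrips <- function(trace, low = min(trace), high = max(trace)) {
  sym <- ifelse(trace == low, "L", ifelse(trace == high, "H", NA))
  sym <- sym[!is.na(sym)]
  if (length(sym) == 0) return(0)
  sym <- rle(sym)$values
  s <- paste(sym, collapse = "")
  count <- 0
  while (grepl("LHL", s)) {
    count <- count + 1
    s <- sub("LHL", "L", s)
  }
  count
}

# small deterministic all-atom fixture: two residues with named atoms
make_atom_fixture <- function(gap_nm) {
  atoms <- data.frame(
    residue = c(1, 1, 1, 2, 2, 2),
    role = c("backbone", "backbone", "sidechain",
             "backbone", "backbone", "sidechain"),
    element = c("N", "O", "N", "N", "O", "O"),
    stringsAsFactors = FALSE)
  coords <- array(0, c(1, 6, 3))
  coords[1, 1, ] <- c(0, 0, 0)       # res1 backbone N
  coords[1, 2, ] <- c(0.1, 0, 0)     # res1 backbone O
  coords[1, 3, ] <- c(0, 0.2, 0)     # res1 sidechain N (K donor)
  coords[1, 4, ] <- c(5, 0, 0)       # res2 backbone N
  coords[1, 5, ] <- c(5.1, 0, 0)     # res2 backbone O
  coords[1, 6, ] <- c(gap_nm, 0.2, 0) # res2 sidechain O (E acceptor)
  list(atoms = atoms, coords = coords, residues = c("K", "E"))
}

random_rotation <- function() {
  repeat {
    q <- rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

apply_rigid <- function(traj, R, shift) {
  tr <- traj
  for (f in seq_len(dim(tr$ca)[1])) {
    tr$ca[f, , ] <- t(R %*% t(tr$ca[f, , ])) +
      rep(shift, each = dim(tr$ca)[2])
    if (!is.null(tr$n_atoms)) {
      tr$n_atoms[f, , ] <- t(R %*% t(tr$n_atoms[f, , ])) +
        rep(shift, each = dim(tr$ca)[2])
      tr$o_atoms[f, , ] <- t(R %*% t(tr$o_atoms[f, , ])) +
        rep(shift, each = dim(tr$ca)[2])
    }
  }
  tr
}

# the printed 12-row blob reference table (sequence-level ground truth)
table1_reference <- function() {
  data.frame(
    blob = c("p1", "h1a", "h1b", "p2", "h2a", "h2b_V66", "h2b_M66", "p3",
             "h3a", "h3b", "h3c", "h3d"),
    sequence = c("EANIRGQG", "GLAYPGVR", "TLESVN", "GPKAGSR", "GLTSLADTF",
                 "HVIEELLD", "HMIEELLD", "EDQKVRPNEENNKDA", "DLYT",
                 "RVMLS", "QVPLE", "PLLFLLE"),
    N = c(8, 8, 6, 7, 9, 8, 8, 15, 4, 5, 5, 7),
    NCPR = c(0.00, 0.13, -0.17, 0.29, -0.11, -0.38, -0.38, -0.13, -0.25,
             0.20, -0.20, -0.14),
    meanH = c(0.37, 0.52, 0.49, 0.34, 0.58, 0.54, 0.50, 0.21, 0.45, 0.60,
              0.49, 0.70),
    FCR = c(0.25, 0.13, 0.17, 0.29, 0.11, 0.38, 0.38, 0.53, 0.25, 0.20,
            0.20, 0.14),
    f_minus = c(0.13, 0.00, 0.17, 0.00, 0.11, 0.38, 0.38, 0.33, 0.25,
                0.00, 0.20, 0.14),
    f_plus = c(0.13, 0.13, 0.00, 0.29, 0.00, 0.00, 0.00, 0.20, 0.00, 0.20,
               0.00, 0.00),
    kappa = c(0.8, 1.0, 0.1, 0.4, 0.7, 0.3, 0.3, 0.1, NA, NA, NA, 1.0),
    R = c(2, 1, 1, 2, 1, 4, 4, 3, 2, 1, 1, 1),
    P = c(0.00, 0.13, 0.00, 0.14, 0.00, 0.00, 0.00, 0.06, 0.00, 0.00,
          0.20, 0.14),
    stringsAsFactors = FALSE)
}

prodomain_fasta <- function(variant = "v66") {
  system.file("extdata",
              sprintf("prodomain_%s_reconstructed.fasta", variant),
              package = "idpblob")
}

# small coupling study layout shared by coupling tests
coupling_layout <- function() {
  list(lengths = c(6, 3, 5, 3, 8, 3, 5, 3, 6),
       classes = c("h", "u", "p", "u", "h", "u", "p", "u", "h"))
}

coupling_spec <- function(odds_ratio, n_frames = 2000, p_contact = 0.35,
                          q0 = 0.10) {
  lay <- coupling_layout()
  synth_spec(lay$lengths, lay$classes,
             planted_contacts = data.frame(x = "h1a", y = "h2a",
                                           p = p_contact),
             coupling = data.frame(x = "h1a", y = "h2a", q0 = q0,
                                   odds_ratio = odds_ratio),
             n_frames = n_frames)
}
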