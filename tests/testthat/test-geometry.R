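make_line_traj <- function(spacing = 0.38, n_res = 10, n_frames = 1) {
  ca <- array(0, c(n_frames, n_res, 3))
  for (f in seq_len(n_frames)) ca[f, , 1] <- (seq_len(n_res) - 1) * spacing
  traj_ensemble(ca)
}

test_that("blob anchors are midpoints and translate equivariantly", {
  tr <- make_line_traj(spacing = 1, n_res = 3)
  expect_equal(blob_anchor(tr, 1, c(1, 3)), c(1, 0, 0))
  tr2 <- tr
  tr2$ca[1, , ] <- sweep(tr2$ca[1, , ], 2, c(2, -1, 5), "+")
  expect_equal(blob_anchor(tr2, 1, c(1, 3)), c(1, 0, 0) + c(2, -1, 5))
})

test_that("backbone N/O anchors match a hand-computed two-atom mean", {
  ca <- array(0, c(1, 4, 3))
  ca[1, , 1] <- 0:3
  n_at <- ca
  o_at <- ca
  n_at[1, , 2] <- 0.1   # N displaced in y
  o_at[1, , 2] <- -0.1  # O displaced in -y
  tr <- traj_ensemble(ca, n_atoms = n_at, o_atoms = o_at)
  # anchor of blob 2..4 = mean of N(res2) and O(res4)
  expect_equal(blob_anchor(tr, 1, c(2, 4)),
               (c(1, 0.1, 0) + c(3, -0.1, 0)) / 2)
  g <- blob_geometry(tr, data.frame(label = "b", start = 2, end = 4))
  expect_equal(attr(g, "anchor_mode"), "backbone")
})

test_that("Rg and Retoe follow closed forms and rigid-motion invariance", {
  tr <- make_line_traj(spacing = 1, n_res = 2)
  expect_equal(unname(blob_rg_retoe(tr, 1, c(1, 2))["rg"]), 0.5)
  # collinear equally spaced N points: Rg^2 = d^2 (N^2-1)/12
  n <- 7
  d <- 0.38
  tr2 <- make_line_traj(spacing = d, n_res = n)
  expect_equal(unname(blob_rg_retoe(tr2, 1, c(1, n))["rg"]),
               d * sqrt((n^2 - 1) / 12))
  expect_equal(unname(blob_rg_retoe(tr2, 1, c(1, n))["retoe"]), d * (n - 1))
  set.seed(2)
  R <- random_rotation()
  tr3 <- apply_rigid(tr2, R, c(1, 2, 3))
  expect_equal(blob_rg_retoe(tr3, 1, c(1, n)), blob_rg_retoe(tr2, 1, c(1, n)))
})

test_that("excess distance follows its defining arithmetic", {
  # anchors 3 nm apart with Rg 1.0 and 0.5 -> 1.5 nm
  ca <- array(0, c(1, 4, 3))
  ca[1, 1, ] <- c(-1, 0, 0) # blob1: residues 1-2, anchor (0,0,0), Rg 1
  ca[1, 2, ] <- c(1, 0, 0)
  ca[1, 3, ] <- c(2.5, 0, 0) # blob2: residues 3-4, anchor (3,0,0), Rg 0.5
  ca[1, 4, ] <- c(3.5, 0, 0)
  tr <- traj_ensemble(ca)
  blobs <- data.frame(label = c("a", "b"), start = c(1, 3), end = c(2, 4))
  expect_equal(excess_distance(tr, blobs, 1, 1, 2), 1.5)
  # zero point: distance equal to the radius sum
  ca[1, 3, ] <- c(0.5, 0, 0)
  ca[1, 4, ] <- c(1.5, 0, 0) # anchor (1,0,0), Rg 0.5; dist 1 = 1 + 0.5 - 0.5
  tr <- traj_ensemble(ca)
  expect_equal(excess_distance(tr, blobs, 1, 1, 2), 1 - 1.5)
  set.seed(31)
  ca <- array(rnorm(5 * 8 * 3), c(5, 8, 3))
  tr <- traj_ensemble(ca)
  blobs <- data.frame(label = c("a", "b"), start = c(1, 5), end = c(4, 8))
  for (f in 1:5) {
    X1 <- ca[f, 1:4, ]
    X2 <- ca[f, 5:8, ]
    anc <- function(X) (X[1, ] + X[nrow(X), ]) / 2
    rg <- function(X) sqrt(mean(rowSums(sweep(X, 2, colMeans(X))^2)))
    expect_equal(excess_distance(tr, blobs, f, 1, 2),
                 sqrt(sum((anc(X1) - anc(X2))^2)) - (rg(X1) + rg(X2)))
  }
})

test_that("blob contact maps respect the strict cutoff and planted truth", {
  # permanently overlapping blobs
  ca <- array(rep(c(0, 0.1, 0.2, 0.3), each = 3), c(3, 4, 1))
  ca <- array(0, c(3, 4, 3))
  ca[, , 1] <- matrix(rep(c(0, 0.1, 0.2, 0.3), each = 3), 3, 4)
  tr <- traj_ensemble(ca)
  blobs <- data.frame(label = c("a", "b"), start = c(1, 3), end = c(2, 4))
  cmap <- blob_contact_map(tr, blobs)
  expect_equal(cmap$p[1, 2], 1)
  # excess distance exactly at the cutoff is not a contact (strict <)
  ca2 <- array(0, c(2, 4, 3))
  ca2[, 1, 1] <- -0.05
  ca2[, 2, 1] <- 0.05   # blob a: anchor 0, rg 0.05
  ca2[, 3, 1] <- 0.60   # blob b: anchor 0.65, rg 0.05
  ca2[, 4, 1] <- 0.70
  tr2 <- traj_ensemble(ca2)
  de <- excess_distance(tr2, blobs, 1, 1, 2)
  expect_equal(blob_contact_map(tr2, blobs, cutoff = de)$p[1, 2], 0)
  expect_equal(blob_contact_map(tr2, blobs, cutoff = de + 1e-9)$p[1, 2], 1)
  # planted contact probability recovered within 3 SE (fixed seed)
  gen <- gen_ensemble(coupling_spec(1, n_frames = 2000), seed = 404)
  cm <- blob_contact_map(gen$traj, gen$partition)
  expect_lt(abs(cm$p["h1a", "h2a"] - 0.35), 3 * cm$se["h1a", "h2a"])
})

test_that("residue contact maps use an inclusive cutoff and match brute force", {
  tr <- make_line_traj(spacing = 0.38, n_res = 6, n_frames = 2)
  cmap <- residue_contact_map(tr)
  expect_equal(cmap$p[1, 2], 1) # adjacent residues always within 0.8 nm
  # distance exactly 0.8 nm is a contact
  ca <- array(0, c(1, 2, 3))
  ca[1, 2, 1] <- 0.8
  expect_equal(residue_contact_map(traj_ensemble(ca))$p[1, 2], 1)
  set.seed(8)
  for (k in 1:5) {
    ca <- array(rnorm(4 * 7 * 3, sd = 0.5), c(4, 7, 3))
    tr <- traj_ensemble(ca)
    cmap <- residue_contact_map(tr)
    expect_equal(cmap$counts, oracle_residue_counts(ca))
  }
})

test_that("contact maps are symmetric and rigid-motion invariant", {
  set.seed(17)
  for (k in 1:20) {
    nb <- sample(3:5, 1)
    lens <- sample(4:6, nb, replace = TRUE)
    spec <- synth_spec(lengths = lens, classes = rep("h", nb),
                       n_frames = 30)
    gen <- gen_ensemble(spec, seed = 100 + k)
    cmap <- blob_contact_map(gen$traj, gen$partition)
    expect_equal(cmap$p, t(cmap$p))
    expect_true(all(cmap$p[upper.tri(cmap$p)] >= 0 &
                      cmap$p[upper.tri(cmap$p)] <= 1))
    expect_equal(unname(cmap$counts),
                 oracle_blob_counts(gen$traj$ca, gen$partition$blobs))
    R <- random_rotation()
    tr2 <- apply_rigid(gen$traj, R, rnorm(3))
    cmap2 <- blob_contact_map(tr2, gen$partition)
    expect_equal(cmap2$p, cmap$p, tolerance = 1e-10)
    rmap <- residue_contact_map(gen$traj)
    rmap2 <- residue_contact_map(tr2)
    expect_equal(rmap2$p, rmap$p, tolerance = 1e-10)
  }
})

test_that("atom-level flavors apply the printed distance rules", {
  fx <- make_atom_fixture(gap_nm = 0.30)
  sb <- atom_contact_maps(fx$coords, fx$atoms, fx$residues, "saltbridge")
  expect_equal(sb$p[1, 2], 1) # K-E donor-acceptor at 0.30 nm
  fx2 <- make_atom_fixture(gap_nm = 0.32)
  sb2 <- atom_contact_maps(fx2$coords, fx2$atoms, fx2$residues, "saltbridge")
  expect_equal(sb2$p[1, 2], 0) # exactly 0.32 nm fails the strict rule
  bb <- atom_contact_maps(fx$coords, fx$atoms, fx$residues, "backbone")
  expect_equal(bb$p[1, 2], 0) # backbones 5 nm apart
  # exhaustive atom-pair scan oracle on a random fixture
  set.seed(3)
  atoms <- data.frame(residue = rep(1:3, each = 2),
                      role = rep(c("backbone", "sidechain"), 3),
                      element = rep(c("N", "C"), 3))
  coords <- array(rnorm(2 * 6 * 3, sd = 0.3), c(2, 6, 3))
  bb2 <- atom_contact_maps(coords, atoms, c("A", "G", "L"), "backbone")
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expected <- 0
      for (f in 1:2) {
        ai <- which(atoms$residue == i & atoms$role == "backbone")
        aj <- which(atoms$residue == j & atoms$role == "backbone")
        hit <- FALSE
        for (a in ai) for (b in aj) {
          if (sqrt(sum((coords[f, a, ] - coords[f, b, ])^2)) <= 0.4) hit <- TRUE
        }
        expected <- expected + hit
      }
      expect_equal(bb2$counts[i, j], expected)
    }
  }
  expect_error(atom_contact_maps(fx$coords, fx$atoms, c("A", "G"),
                                 "saltbridge"), "flavor")
})

test_that("network export filters by persistence and flags long range", {
  p <- matrix(0, 30, 30)
  cm <- contact_map(p, p * 0, 100, "residue", 0.8, "test")
  expect_equal(nrow(network_export(cm)), 0L)
  p[2, 28] <- p[28, 2] <- 0.10
  p[3, 5] <- p[5, 3] <- 0.50
  p[4, 6] <- p[6, 4] <- 0.06 # exactly at threshold: excluded (strict >)
  cm <- contact_map(p, p * 100, 100, "residue", 0.8, "test")
  edges <- network_export(cm)
  expect_equal(nrow(edges), 2L)
  expect_equal(edges$long_range, c(FALSE, TRUE))
  # threshold filtering equals a brute-force filter
  set.seed(12)
  p2 <- matrix(0, 10, 10)
  p2[upper.tri(p2)] <- runif(45, 0, 0.2)
  p2 <- p2 + t(p2)
  cm2 <- contact_map(p2, p2 * 50, 50, "residue", 0.8, "test")
  edges2 <- network_export(cm2, persistence = 0.1, long_range_sep = 3)
  manual <- 0
  for (i in 1:9) for (j in (i + 1):10) if (p2[i, j] > 0.1) manual <- manual + 1
  expect_equal(nrow(edges2), manual)
})

test_that("region statistics aggregate blob pairs correctly", {
  p <- matrix(0.3, 4, 4)
  diag(p) <- NA
  cm <- contact_map(p, p * 0, 10, "blob", 0.55, "test")
  rs <- region_contact_stats(cm, c("I", "I", "III", "III"))
  expect_true(all(rs$mean_p == 0.3))
  # block matrix with known block means
  p2 <- matrix(0.1, 4, 4)
  p2[1:2, 3:4] <- 0.5
  p2[3:4, 1:2] <- 0.5
  diag(p2) <- NA
  cm2 <- contact_map(p2, p2 * 0, 10, "blob", 0.55, "test")
  rs2 <- region_contact_stats(cm2, c("I", "I", "III", "III"))
  expect_equal(rs2$mean_p[rs2$region_a == "I" & rs2$region_b == "I"], 0.1)
  expect_equal(rs2$mean_p[rs2$region_a == "I" & rs2$region_b == "III"], 0.5)
  # random map against hand aggregation
  set.seed(4)
  p3 <- matrix(runif(25), 5, 5)
  p3 <- (p3 + t(p3)) / 2
  diag(p3) <- NA
  regions <- c("I", "I", "II", "III", "III")
  cm3 <- contact_map(p3, p3 * 0, 10, "blob", 0.55, "test")
  rs3 <- region_contact_stats(cm3, regions)
  expect_equal(rs3$mean_p[rs3$region_a == "I" & rs3$region_b == "III"],
               mean(c(p3[1, 4], p3[1, 5], p3[2, 4], p3[2, 5])))
})

test_that("scaling fits recover exact and simulated exponents", {
  # a rigid rod spaced at the reference prefactor follows R = A * s^1
  # exactly, so the fixed-prefactor fit must return nu = 1
  rod <- make_line_traj(spacing = 0.59, n_res = 12)
  f_rod <- flory_fit(rod, A = 0.59)
  expect_equal(f_rod$nu, 1, tolerance = 1e-10)
  expect_true(f_rod$A_fixed)
  # the fit uses separations >= 2 only
  expect_gte(min(f_rod$data$separation), 2)
  # ideal-chain ensemble: free-prefactor fit recovers nu ~ 0.5
  gen <- gen_ensemble(synth_spec(lengths = 40, classes = "p",
                                 confinement = NA, n_frames = 300),
                      seed = 21)
  f_free <- flory_fit(gen$traj, A = NULL)
  expect_lt(abs(f_free$nu - 0.5), 0.03)
  expect_error(flory_fit(gen$traj, domain = c(1, 3)))
})

test_that("frame QC and moving windows behave as specified", {
  tr <- make_line_traj(n_res = 5)
  expect_warning(tr2 <- frame_qc(tr), "box")
  expect_true(all(tr2$mask))
  # with a box: extent 4*0.38 = 1.52; edge 3 -> separation 1.48 < 2 masked
  tr$box <- 3
  tr3 <- frame_qc(tr)
  expect_false(any(tr3$mask))
  tr$box <- 4
  expect_true(all(frame_qc(tr)$mask))
  expect_equal(moving_window(rep(3, 8), 5), rep(3, 8))
  set.seed(9)
  x <- rnorm(40)
  mw <- moving_window(x, 7)
  for (i in seq_along(x)) {
    lo <- max(1, i - 3)
    hi <- min(40, i + 3)
    expect_equal(mw[i], mean(x[lo:hi]))
  }
})
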