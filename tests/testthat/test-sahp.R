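test_that("parameterization derives bonds from neighbouring end-to-ends", {
  m <- sahp_model(rep(0.3, 3), rep(1, 3))
  expect_equal(m$bonds, c(1, 1))
  m2 <- sahp_model(c(0.3, 0.3), c(0.8, 1.2))
  expect_equal(m2$bonds, 1.0)
  # parameters from a synthetic trajectory equal hand-computed means
  gen <- gen_ensemble(synth_spec(lengths = c(5, 4, 6),
                                 classes = c("h", "u", "h"),
                                 n_frames = 40), seed = 77)
  geom <- blob_geometry(gen$traj, gen$partition)
  ca <- gen$traj$ca
  rg_hand <- mean(vapply(1:40, function(f) {
    X <- ca[f, 1:5, ]
    sqrt(mean(rowSums(sweep(X, 2, colMeans(X))^2)))
  }, numeric(1)))
  retoe_hand <- mean(vapply(1:40, function(f) {
    sqrt(sum((ca[f, 5, ] - ca[f, 1, ])^2))
  }, numeric(1)))
  expect_equal(geom$mean_rg[1], rg_hand)
  expect_equal(geom$mean_retoe[1], retoe_hand)
  model <- sahp_parameterize(geom)
  expect_equal(model$bonds[1], (geom$mean_retoe[1] + geom$mean_retoe[2]) / 2)
  expect_error(sahp_model(c(-1, 1), c(1, 1)))
})

test_that("trial moves preserve every bond and the tail's internal geometry", {
  set.seed(15)
  bonds <- runif(7, 0.5, 1.5)
  pos <- matrix(0, 8, 3)
  for (k in 2:8) {
    u <- rnorm(3)
    pos[k, ] <- pos[k - 1, ] + bonds[k - 1] * u / sqrt(sum(u^2))
  }
  for (rep in 1:25) {
    i <- sample(2:8, 1)
    cand <- sahp_propose_move(pos, bonds, i = i)
    for (k in 2:8) {
      expect_equal(sqrt(sum((cand[k, ] - cand[k - 1, ])^2)), bonds[k - 1],
                   tolerance = 1e-9)
    }
    # pairwise distances among the tail beads are untouched
    if (i < 8) {
      expect_equal(as.matrix(dist(cand[i:8, ])), as.matrix(dist(pos[i:8, ])),
                   tolerance = 1e-9)
    }
    pos <- cand
  }
  # move sequences are reproducible under a fixed seed
  set.seed(44)
  a <- sahp_propose_move(pos, bonds)
  set.seed(44)
  b <- sahp_propose_move(pos, bonds)
  expect_identical(a, b)
})

test_that("a two-bead chain has the analytic contact probability", {
  # bond - (Rg sum) below the cutoff: always in contact
  m_close <- sahp_model(c(0.3, 0.3), c(1.0, 1.0)) # bond 1.0, excess 0.4
  s <- sahp_run(m_close, steps = 1e4, seed = 1)
  expect_equal(sahp_contact_map(s)$p[1, 2], 1)
  # excess above the cutoff: never in contact
  m_far <- sahp_model(c(0.2, 0.2), c(1.0, 1.0)) # excess 0.6 > 0.55
  s2 <- sahp_run(m_far, steps = 1e4, seed = 1)
  expect_equal(sahp_contact_map(s2)$p[1, 2], 0)
})

test_that("MC contact probabilities match the direct-sampling oracle", {
  set.seed(61)
  m3 <- sahp_model(c(0.40, 0.50, 0.45), c(0.9, 1.1, 0.8))
  mc3 <- sahp_contact_map(sahp_run(m3, steps = 1e6, seed = 5,
                                   keep_positions = FALSE))
  or3 <- sahp_direct_sample(m3, n_samples = 1e5)
  m4 <- sahp_model(c(0.35, 0.5, 0.45, 0.3), c(0.8, 1.0, 0.9, 0.7))
  mc4 <- sahp_contact_map(sahp_run(m4, steps = 2e6, seed = 6,
                                   keep_positions = FALSE))
  or4 <- sahp_direct_sample(m4, n_samples = 1e5)
  for (pair in list(c(1, 3))) {
    d <- abs(mc3$p[pair[1], pair[2]] - or3$p[pair[1], pair[2]])
    tol <- 3 * sqrt(mc3$se[pair[1], pair[2]]^2 + or3$se[pair[1], pair[2]]^2)
    expect_lt(d, tol)
  }
  for (pair in list(c(1, 3), c(1, 4), c(2, 4))) {
    d <- abs(mc4$p[pair[1], pair[2]] - or4$p[pair[1], pair[2]])
    tol <- 3 * sqrt(mc4$se[pair[1], pair[2]]^2 + or4$se[pair[1], pair[2]]^2)
    expect_lt(d, tol)
  }
})

test_that("fixed seeds give bit-identical samples", {
  m <- sahp_model(c(0.4, 0.5, 0.45), c(0.9, 1.1, 0.8))
  s1 <- sahp_run(m, steps = 5e4, seed = 33)
  s2 <- sahp_run(m, steps = 5e4, seed = 33)
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$counts, s2$counts)
})

test_that("recorded configurations satisfy bonds and the hard core", {
  m <- sahp_model(c(0.4, 0.6, 0.5, 0.45), c(1.0, 0.9, 1.1, 0.8))
  s <- sahp_run(m, steps = 1e5, seed = 9)
  pos <- s$positions
  for (k in seq_len(dim(pos)[1])) {
    X <- pos[k, , ]
    for (b in seq_along(m$bonds)) {
      expect_equal(sqrt(sum((X[b + 1, ] - X[b, ])^2)), m$bonds[b],
                   tolerance = 1e-9)
    }
    d <- as.matrix(dist(X))
    for (i in 1:2) {
      for (j in (i + 2):4) {
        expect_gte(d[i, j], m$a * (m$radii[i] + m$radii[j]))
      }
    }
  }
  # infeasible geometry is refused up front
  expect_error(sahp_run(sahp_model(c(5, 5, 5), c(0.1, 0.1, 0.1)), steps = 100),
               "infeasible")
})

test_that("SAHP contact maps recount correctly and stay symmetric", {
  m <- sahp_model(c(0.4, 0.5, 0.45), c(0.9, 1.1, 0.8))
  s <- sahp_run(m, steps = 1e5, seed = 2)
  cmap <- sahp_contact_map(s)
  expect_equal(cmap$p, t(cmap$p))
  # brute-force recount from the stored configurations
  manual <- matrix(0, 3, 3)
  for (k in seq_len(dim(s$positions)[1])) {
    d <- as.matrix(dist(s$positions[k, , ]))
    hit <- (d - outer(m$radii, m$radii, "+")) < m$cutoff
    diag(hit) <- FALSE
    manual <- manual + hit
  }
  expect_equal(unname(cmap$counts), unname(manual))
  # a different cutoff triggers an equivalent recount path
  cmap2 <- sahp_contact_map(s, cutoff = 0.3)
  manual2 <- matrix(0, 3, 3)
  for (k in seq_len(dim(s$positions)[1])) {
    d <- as.matrix(dist(s$positions[k, , ]))
    hit <- (d - outer(m$radii, m$radii, "+")) < 0.3
    diag(hit) <- FALSE
    manual2 <- manual2 + hit
  }
  expect_equal(unname(cmap2$counts), unname(manual2))
})

test_that("monomer swaps are involutive and recompute bonds", {
  m <- sahp_model(c(0.3, 0.4, 0.5, 0.6), c(0.8, 1.0, 1.2, 1.4),
                  labels = c("a", "b", "c", "d"))
  expect_equal(swap_monomers(m, 2, 2), m)
  expect_equal(swap_monomers(swap_monomers(m, 2, 4), 2, 4), m)
  sw <- swap_monomers(m, "b", "d")
  expect_equal(sw$labels, c("a", "d", "c", "b"))
  expect_equal(sw$bonds, c((0.8 + 1.4) / 2, (1.4 + 1.2) / 2, (1.2 + 1) / 2))
})

test_that("enrichment ratios follow their defining identities", {
  p <- matrix(c(NA, 0.4, 0.2, 0.4, NA, 0.3, 0.2, 0.3, NA), 3, 3)
  cm <- contact_map(p, p * 100, 100, "blob", 0.55, "t")
  e <- enrichment(cm, cm)
  expect_true(all(e$ratio[!is.na(e$ratio)] == 1))
  p2 <- p * 2
  cm2 <- contact_map(p2, p2 * 100, 100, "blob", 0.55, "t")
  e2 <- enrichment(cm2, cm)
  expect_true(all(e2$ratio[!is.na(e2$ratio)] == 2))
  # zero null probability with observed contacts flags infinity, no crash
  p3 <- p
  p3[1, 2] <- p3[2, 1] <- 0
  cm3 <- contact_map(p3, p3 * 100, 100, "blob", 0.55, "t")
  e3 <- enrichment(cm, cm3)
  expect_equal(e3$ratio[1, 2], Inf)
})

test_that("region segmentation finds the most isolating linker", {
  # symmetric 3-monomer chain: middle linker selected
  p <- matrix(c(NA, 0.9, 0.05, 0.9, NA, 0.9, 0.05, 0.9, NA), 3, 3)
  cm <- contact_map(p, p * 10, 10, "blob", 0.55, "t")
  seg <- segment_regions(cm, c("h", "p", "h"))
  expect_equal(seg$linker, 2L)
  expect_equal(unname(seg$regions), c("I", "II", "III"))
  # no linker: warning, single region
  expect_warning(seg2 <- segment_regions(cm, c("h", "h", "h")), "p blob")
  expect_true(all(seg2$regions == "I"))
})

test_that("an 11-monomer heterogeneous SAHP segments at the long linker", {
  gen <- gen_ensemble(synth_spec_prodomain(n_frames = 200), seed = 11)
  geom <- blob_geometry(gen$traj, gen$partition)
  model <- sahp_parameterize(geom, classes = gen$partition$blobs$class)
  samp <- sahp_run(model, steps = 1e6, seed = 3, keep_positions = FALSE)
  map <- sahp_contact_map(samp)
  seg <- segment_regions(map, model)
  expect_equal(model$labels[seg$linker], "p3")
  # the cross-linker block is the least-contacting row structure
  rs <- region_contact_stats(map, seg$regions)
  cross <- rs$mean_p[rs$region_a == "I" & rs$region_b == "III"]
  within1 <- rs$mean_p[rs$region_a == "I" & rs$region_b == "I"]
  within3 <- rs$mean_p[rs$region_a == "III" & rs$region_b == "III"]
  expect_lt(cross, within1)
  expect_lt(cross, within3)
  # shifting the segmenting monomer moves the boundary with it
  sw <- swap_monomers(model, "p3", "h2a")
  samp2 <- sahp_run(sw, steps = 1e6, seed = 4, keep_positions = FALSE)
  seg2 <- segment_regions(sahp_contact_map(samp2), sw)
  expect_equal(seg2$linker, match("p3", sw$labels))
})
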