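test_that("four-cluster labels agree with a brute-force reconstruction", {
  gen <- gen_ensemble(coupling_spec(3, n_frames = 400), seed = 91)
  lab <- four_cluster(gen$traj, gen$partition, "h1a", "h2a")
  expect_equal(sum(lab$counts), 400)
  # brute force: recompute both collective variables independently
  contact_bf <- gen$truth$contacts$contact[, 1]
  track <- rama_track(gen$traj)
  xres <- with(gen$partition$blobs, start[label == "h1a"]:end[label == "h1a"])
  present_bf <- apply(oracle_run_flags(track, "beta")[, xres, drop = FALSE],
                      1, any)
  expect_equal(unname(lab$contact), unname(contact_bf))
  expect_equal(unname(lab$present), unname(present_bf))
  tab <- table(factor(paste0(ifelse(contact_bf, "contacting", "distant"), ".",
                             ifelse(present_bf, "present", "absent")),
                      levels = levels(lab$cluster)))
  expect_equal(as.vector(lab$counts), as.vector(tab))
})

test_that("ineligible pairs are filtered unless forced", {
  gen <- gen_ensemble(coupling_spec(1, n_frames = 50), seed = 3)
  # p1 and h2a are adjacent blobs
  expect_error(four_cluster(gen$traj, gen$partition, "p1", "h2a"),
               "adjacent")
  expect_s3_class(four_cluster(gen$traj, gen$partition, "p1", "h2a",
                               force = TRUE), "cluster_labeling")
})

test_that("conditional profiles reduce to the unconditional propensity", {
  # an ensemble with no contacts ever: only the distant clusters populate
  spec <- synth_spec(lengths = c(4, 30, 4), classes = c("h", "p", "h"),
                     confinement = c(0.4, NA, 0.4), n_frames = 150)
  gen <- gen_ensemble(spec, seed = 19)
  lab <- four_cluster(gen$traj, gen$partition, "h1a", "h2a", force = TRUE)
  prof <- conditional_beta_profiles(lab)
  uncond <- ss_propensity(gen$traj, "beta")
  if (all(lab$counts[c("contacting.present", "contacting.absent")] == 0)) {
    merged <- prof[prof$cluster %in% c("distant.present", "distant.absent"), ]
    pooled <- vapply(split(merged, merged$residue), function(d) {
      sum(d$p * d$n) / sum(d$n)
    }, numeric(1))
    expect_equal(unname(pooled[order(as.integer(names(pooled)))]), uncond$p)
  }
  # the constrained blob is saturated in its "present" clusters
  gen2 <- gen_ensemble(coupling_spec(3, n_frames = 400), seed = 92)
  lab2 <- four_cluster(gen2$traj, gen2$partition, "h1a", "h2a")
  prof2 <- conditional_beta_profiles(lab2)
  xres <- with(gen2$partition$blobs,
               start[label == "h1a"]:end[label == "h1a"])
  mean_at <- function(cl, res) {
    mean(prof2$p[prof2$cluster == cl & prof2$residue %in% res])
  }
  expect_gte(mean_at("contacting.present", xres),
             mean_at("contacting.absent", xres))
  expect_gte(mean_at("distant.present", xres), mean_at("distant.absent", xres))
})

test_that("planted symmetric coupling is detected and the null is quiet", {
  gen <- gen_ensemble(coupling_spec(3), seed = 301)
  det <- detect_symmetric_coupling(gen$traj, gen$partition)
  expect_equal(nrow(det), 1L)
  expect_setequal(c(det$x, det$y), c("h1a", "h2a"))
  gen0 <- gen_ensemble(coupling_spec(1), seed = 302)
  det0 <- detect_symmetric_coupling(gen0$traj, gen0$partition)
  expect_equal(nrow(det0), 0L)
  # no beta anywhere: empty result
  spec <- synth_spec(coupling_layout()$lengths, coupling_layout()$classes,
                     n_frames = 100, beta_rate = 0, helix_rate = 0)
  gen2 <- gen_ensemble(spec, seed = 303)
  expect_equal(nrow(detect_symmetric_coupling(gen2$traj, gen2$partition)), 0L)
})

test_that("detection strength increases with the planted odds ratio", {
  zmin <- function(or, seed) {
    gen <- gen_ensemble(coupling_spec(or, n_frames = 1000), seed = seed)
    det <- detect_symmetric_coupling(gen$traj, gen$partition, z = 0)
    row <- det[det$x == "h1a" & det$y == "h2a", ]
    if (nrow(row) == 0) 0 else min(row$z_forward, row$z_reverse)
  }
  seeds <- c(21, 22, 23)
  z1 <- mean(vapply(seeds, function(s) zmin(1, s), numeric(1)))
  z3 <- mean(vapply(seeds, function(s) zmin(3, s), numeric(1)))
  expect_lt(z1, z3)
})

test_that("nine-cluster decomposition partitions frames and maps", {
  # all-coil ensemble populates only (coil, coil)
  spec <- synth_spec(coupling_layout()$lengths, coupling_layout()$classes,
                     n_frames = 60, beta_rate = 0, helix_rate = 0)
  gen <- gen_ensemble(spec, seed = 8)
  nc <- nine_cluster(gen$traj, gen$partition, "h1a", "h2a")
  expect_equal(unname(nc$counts["coil", "coil"]), 60)
  expect_equal(sum(nc$counts), 60)
  expect_equal(nc$excluded, 0)
  expect_named(nc$maps, "coil.coil")
  # structured ensemble: counts plus exclusions cover every frame
  gen2 <- gen_ensemble(coupling_spec(3, n_frames = 400), seed = 93)
  nc2 <- nine_cluster(gen2$traj, gen2$partition, "h1a", "h2a")
  expect_equal(sum(nc2$counts) + nc2$excluded, 400)
  # brute-force state assignment for one blob
  track <- rama_track(gen2$traj)
  hfl <- oracle_run_flags(track, "helix")
  bfl <- oracle_run_flags(track, "beta")
  xres <- with(gen2$partition$blobs,
               start[label == "h1a"]:end[label == "h1a"])
  h <- apply(hfl[, xres, drop = FALSE], 1, any)
  b <- apply(bfl[, xres, drop = FALSE], 1, any)
  st <- ifelse(h & b, "mixed", ifelse(h, "helix", ifelse(b, "beta", "coil")))
  expect_equal(as.character(nc2$state_a), st)
  # conditional maps recount the frames of their cluster
  idx <- which(nc2$state_a == "coil" & nc2$state_b == "coil")
  manual <- oracle_residue_counts(gen2$traj$ca[idx, , , drop = FALSE])
  expect_equal(unname(nc2$maps[["coil.coil"]]$counts), manual)
})
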