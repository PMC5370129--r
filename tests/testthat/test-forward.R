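test_that("equal-conductivity lead field matches the homogeneous closed form", {
  sig <- 0.33
  shells <- shell_model(conductivities_sm = c(sig, sig, sig))
  montage <- montage_10_10_32()
  dips <- list(
    dipole(c(0.03, -0.02, 0.04), c(0, 0, 1), "a1_l"),          # oblique
    dipole(c(0.05, 0.01, -0.02), c(0.05, 0.01, -0.02), "cochlea"), # radial
    dipole(c(0, -0.04, 0.02), c(1, 0, 0), "brainstem")          # tangential
  )
  lf <- sphere_lead_field(dips, montage, shells)
  R <- shells$radii_m[3]
  for (d in seq_along(dips)) {
    oracle <- apply(as.matrix(montage[, c("x", "y", "z")]), 1, function(r) {
      homogeneous_sphere_potential(dips[[d]]$position_m,
                                   dips[[d]]$orientation, r, R, sig)
    })
    expect_lt(max(abs(lf[, d] - oracle)) / max(abs(oracle)), 1e-6)
  }
})

test_that("sagittal mirror symmetry holds for midline dipoles", {
  lf <- sphere_lead_field(
    dipole(c(0, -0.025, -0.03), c(0, 0.35, 0.94), "brainstem"),
    montage_10_10_32(), shell_model()
  )
  pairs <- list(c("Fp1", "Fp2"), c("F7", "F8"), c("F3", "F4"), c("T7", "T8"),
                c("C3", "C4"), c("P7", "P8"), c("O1", "O2"), c("TP9", "TP10"),
                c("FC5", "FC6"), c("CP1", "CP2"))
  for (p in pairs) {
    expect_equal(lf[p[1], 1], lf[p[2], 1], tolerance = 1e-10)
  }
})

test_that("potentials scale inversely with conductivity", {
  d <- dipole(c(0.02, 0.03, 0.01), c(0, 1, 0), "thalamus_r")
  base <- shell_model()
  scaled <- shell_model(conductivities_sm = 3 * base$conductivities_sm)
  lf1 <- sphere_lead_field(d, shells = base)
  lf2 <- sphere_lead_field(d, shells = scaled)
  expect_equal(unclass(lf1), 3 * unclass(lf2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("any dipole's mean potential over a dense uniform grid is near zero", {
  grid <- fibonacci_sphere(200) * 0.1
  montage <- tibble::tibble(label = paste0("g", 1:200),
                            x = grid[, 1], y = grid[, 2], z = grid[, 3])
  for (d in list(dipole(c(0.04, 0.02, 0.03), c(0, 0, 1), "a1_l"),
                 dipole(c(0.07, 0, 0), c(1, 0, 0), "cochlea"))) {
    lf <- sphere_lead_field(d, montage, shell_model())
    expect_lt(abs(mean(lf[, 1])), 0.01 * max(abs(lf[, 1])))
  }
})

test_that("dipoles outside the brain shell are rejected", {
  expect_error(
    sphere_lead_field(dipole(c(0.09, 0, 0), c(1, 0, 0), "cochlea")),
    "outside the brain shell"
  )
})

test_that("lead-field export and import round-trip exactly", {
  sim_lf <- sphere_lead_field(default_dipoles()["cochlea"])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lead_field(sim_lf, path)
  back <- load_lead_field(path)
  expect_equal(unclass(back), unclass(sim_lf), ignore_attr = TRUE)
  expect_identical(attr(back, "provenance"), "imported")
  expect_identical(rownames(back), rownames(sim_lf))
  # shape mismatch against the sidecar is an error
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  side$labels <- side$labels[-1]
  jsonlite::write_json(side, paste0(path, ".json"))
  expect_error(load_lead_field(path), "does not match sidecar")
})

test_that("synthesized datasets satisfy the mixing identity exactly", {
  sim <- quick_sim()
  expect_identical(sim$eeg$mix$data,
                   sim$eeg$assr$data + sim$eeg$art$data + sim$noise)
  expect_identical(dim(sim$eeg$mix$data), dim(sim$eeg$assr$data))
  expect_identical(sim$eeg$mix$labels, sim$eeg$art$labels)
})

test_that("zero artifact source gives mix = assr + noise", {
  src <- quick_sim()$sources
  src$sources["artifact", ] <- 0
  out <- synthesize_eeg(src, quick_sim()$lf1, quick_sim()$lf2, seed = 3)
  expect_identical(out$mix$data, out$assr$data + out$noise)
  expect_true(all(out$art$data == 0))
})

test_that("artifact scalp spread is maximal ipsilateral to the implant", {
  sim <- quick_sim() # right-side implant by default
  m <- rowMeans(abs(sim$eeg$art$data))
  right_side <- c("Fp2", "F4", "F8", "FC2", "FC6", "C4", "T8", "CP2", "CP6",
                  "TP10", "P4", "P8", "PO10", "O2")
  expect_true(names(which.max(m)) %in% right_side)
  # strongest near the implantation site, far weaker at the mirror electrode
  # (the contralateral hemisphere still carries the broad return lobe of the
  # radial dipole, so only the focal maximum is asserted)
  expect_gt(m["TP10"], 2 * m["TP9"])
  expect_gt(m["T8"], m["T7"])
  # left implant mirrors the pattern
  cfgl <- scenario_config("quick", seed = 1, duration_s = 2,
                          forward = list(implant_side = "left"))
  sl <- simulate_scenario(cfgl)
  ml <- rowMeans(abs(sl$eeg$art$data))
  expect_gt(ml["TP9"], 2 * ml["TP10"])
  expect_gt(ml["T7"], ml["T8"])
})

test_that("noiseless mixture covariance has at most six nonzero eigenvalues", {
  sim <- quick_sim()
  clean <- sim$eeg$mix$data - sim$noise
  ev <- eigen(tcrossprod(clean - rowMeans(clean)) / ncol(clean),
              symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[7] / ev[1], 1e-10)
  # with symmetric bilateral drive ~4 directions dominate
  expect_gt(ev[4] / ev[1], 1e-7)
  expect_lt(ev[5] / ev[4], 0.2)
})

test_that("montage is well-formed and exactly left-right symmetric", {
  m <- montage_10_10_32()
  expect_equal(nrow(m), 32)
  expect_false(anyDuplicated(m$label) > 0)
  r <- sqrt(m$x^2 + m$y^2 + m$z^2)
  expect_equal(r, rep(0.1, 32), tolerance = 1e-12)
  pos <- as.matrix(m[, c("x", "y", "z")])
  rownames(pos) <- m$label
  expect_equal(unname(pos["C3", ] * c(-1, 1, 1)), unname(pos["C4", ]))
  expect_equal(unname(pos["TP9", ] * c(-1, 1, 1)), unname(pos["TP10", ]))
})
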