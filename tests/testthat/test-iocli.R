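test_that("scenario configurations round-trip through YAML and JSON", {
  cfg <- scenario_config("quick", seed = 42, modulation_depth = 0.5,
                         forward = list(implant_side = "left"))
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_scenario(cfg, path)
    back <- read_scenario(path)
    expect_identical(back$seed, 42L)
    expect_identical(back$stimulus$modulation_depth, 0.5)
    expect_identical(back$forward$implant_side, "left")
    expect_identical(back$profile, "quick")
    expect_equal(unclass(back)[c("stimulus", "cochlea", "network", "analysis")],
                 unclass(cfg)[c("stimulus", "cochlea", "network", "analysis")])
  }
})

test_that("configuration validation rejects out-of-range physics", {
  expect_error(scenario_config("quick", modulation_depth = 1.2), "0, 1")
  expect_error(scenario_config("quick", forward = list(
    conductivities_sm = c(0.33, -0.01, 0.33))), "positive")
  expect_error(scenario_config("quick", forward = list(
    radii_m = c(0.1, 0.09, 0.087))), "increasing")
  expect_error(scenario_config("quick", network = list(noise_sd = -1)),
               "non-negative")
  expect_error(scenario_config("quick", forward = list(implant_side = "up")),
               "left")
  expect_error(scenario_config("quick", nonsense = list(a = 1)), "Unknown")
  # a config file with a bad value is rejected on read
  cfg <- scenario_config("quick")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(cfg, path)
  txt <- readLines(path)
  txt <- sub("modulation_depth: 0.75", "modulation_depth: 2.0", txt)
  writeLines(txt, path)
  expect_error(read_scenario(path), "0, 1")
})

test_that("EEGLAB .set export round-trips float32 data and metadata", {
  set.seed(8)
  d <- matrix(rnorm(8 * 500, sd = 10), 8)
  # float32-representable values so the round trip is lossless
  d <- matrix(readBin(writeBin(as.numeric(d), raw(), size = 4), "numeric",
                      n = length(d), size = 4), 8)
  ds <- eeg_dataset(d, 2000, paste0("E", 1:8), "assr",
                    meta = list(seed = 7L, scenario_hash = "abc"))
  path <- withr::local_tempfile(fileext = ".set")
  write_eeg(ds, path)
  back <- read_eeg(path)
  expect_equal(back$data, {x <- d; rownames(x) <- ds$labels; x})
  expect_identical(back$labels, ds$labels)
  expect_identical(back$kind, "assr")
  expect_equal(back$meta$seed, 7)
  expect_identical(back$meta$scenario_hash, "abc")
  expect_identical(back$sampling_rate_hz, 2000)
  # deterministic re-export is byte-identical
  path2 <- withr::local_tempfile(fileext = ".set")
  write_eeg(ds, path2)
  expect_identical(readBin(path, "raw", file.info(path)$size),
                   readBin(path2, "raw", file.info(path2)$size))
})

test_that("exported simulation triple shares shape and labels", {
  sim <- quick_sim()
  dir <- withr::local_tempdir()
  shapes <- lapply(c("mix", "assr", "art"), function(kind) {
    p <- file.path(dir, paste0(kind, ".set"))
    write_eeg(sim$eeg[[kind]], p)
    back <- read_eeg(p)
    expect_identical(back$kind, kind)
    list(dim = dim(back$data), labels = back$labels)
  })
  expect_identical(shapes[[1]], shapes[[2]])
  expect_identical(shapes[[1]], shapes[[3]])
})

# write a small BrainVision fixture by hand (text header + raw binary)
write_bv_fixture <- function(dir, data, fs = 1000, labels = NULL,
                             with_vmrk = TRUE, header_channels = nrow(data)) {
  labels <- labels %||% paste0("Ch", seq_len(nrow(data)))
  vhdr <- file.path(dir, "rec.vhdr")
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "DataFile=rec.eeg",
    if (with_vmrk) "MarkerFile=rec.vmrk",
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", header_channels),
    sprintf("SamplingInterval=%d", as.integer(1e6 / fs)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_along(labels), labels)
  ), vhdr)
  con <- file(file.path(dir, "rec.eeg"), "wb")
  writeBin(as.numeric(data), con, size = 4, endian = "little") # multiplexed
  close(con)
  if (with_vmrk) {
    writeLines(c(
      "[Marker Infos]",
      "Mk1=New Segment,,1,1,0",
      "Mk2=Stimulus,S  1,250,1,0"
    ), file.path(dir, "rec.vmrk"))
  }
  vhdr
}

test_that("BrainVision recordings are read with labels, rate and markers", {
  dir <- withr::local_tempdir()
  d <- matrix(seq(-1, 1, length.out = 4 * 100), nrow = 4) # multiplexed order
  vhdr <- write_bv_fixture(dir, d, fs = 500, labels = c("Fp1", "Cz", "Pz", "Oz"))
  eeg <- read_eeg(vhdr)
  expect_identical(eeg$labels, c("Fp1", "Cz", "Pz", "Oz"))
  expect_equal(eeg$sampling_rate_hz, 500)
  expect_equal(dim(eeg$data), c(4L, 100L))
  expect_equal(unname(eeg$data[, 1]), d[, 1], tolerance = 1e-6)
  expect_equal(nrow(eeg$meta$markers), 2)
  expect_identical(eeg$meta$markers$type[2], "Stimulus")
})

test_that("missing marker file warns; malformed headers error by name", {
  dir <- withr::local_tempdir()
  d <- matrix(rnorm(2 * 50), 2)
  vhdr <- write_bv_fixture(dir, d, with_vmrk = TRUE)
  file.remove(file.path(dir, "rec.vmrk"))
  expect_warning(eeg <- read_eeg(vhdr), "marker file")
  expect_null(eeg$meta$markers)
  # channel count mismatch between header and binary payload
  dir2 <- withr::local_tempdir()
  vhdr2 <- write_bv_fixture(dir2, matrix(rnorm(3 * 50), 3),
                            header_channels = 7)
  expect_error(read_eeg(vhdr2), "not a multiple of the channel count")
  # missing required header field
  dir3 <- withr::local_tempdir()
  vhdr3 <- write_bv_fixture(dir3, d)
  txt <- readLines(vhdr3)
  writeLines(txt[!grepl("^NumberOfChannels", txt)], vhdr3)
  expect_error(read_eeg(vhdr3), "NumberOfChannels")
})

test_that("fixtures are reproducible and manifests capture the run", {
  a <- simulate_scenario(scenario_config("quick", seed = 5, duration_s = 2))
  b <- simulate_scenario(scenario_config("quick", seed = 5, duration_s = 2))
  expect_identical(a$eeg$mix$data, b$eeg$mix$data)
  expect_identical(a$sources$sources, b$sources$sources)
  c_ <- simulate_scenario(scenario_config("quick", seed = 6, duration_s = 2))
  expect_false(identical(a$eeg$mix$data, c_$eeg$mix$data))

  man <- run_manifest(a$config, extra = list(stage = "test"))
  expect_identical(man$seed, 5L)
  expect_identical(man$stage, "test")
  expect_identical(man$config_hash, rlang::hash(unclass(a$config)))
  expect_identical(man$config$stimulus$duration_s, 2)
})

test_that("paper-scale profile echoes the full-scale recording conditions", {
  cfg <- scenario_config("paper_scale")
  expect_identical(cfg$stimulus$sampling_rate_hz, 50e3)
  expect_identical(cfg$stimulus$duration_s, 40)
  expect_identical(cfg$stimulus$carrier_freq_hz, 500)
  expect_identical(cfg$stimulus$modulation_depth, 0.75)
})
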