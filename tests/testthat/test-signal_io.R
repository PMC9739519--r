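test_that("label_from_ratings splits the rating square at the midpoint", {
  expect_equal(label_from_ratings(7, 8, c(1, 9)), "HVHA")
  expect_equal(label_from_ratings(2, 8, c(1, 9)), "LVHA")
  expect_equal(label_from_ratings(8, 2, c(1, 9)), "HVLA")
  expect_equal(label_from_ratings(2, 2, c(1, 9)), "LVLA")
  # exact midpoint maps low (deterministic tie rule)
  expect_equal(label_from_ratings(5, 5, c(1, 9)), "LVLA")
  expect_equal(label_from_ratings(5, 7, c(1, 9)), "LVHA")
  expect_error(label_from_ratings(0.5, 5, c(1, 9)), "outside bounds")
  # the four regions partition the square: every grid point gets exactly
  # one admissible label
  grid <- expand.grid(v = seq(1, 9, by = 0.5), a = seq(1, 9, by = 0.5))
  labs <- mapply(label_from_ratings, grid$v, grid$a)
  expect_true(all(labs %in% quadrant_levels()))
  expect_equal(sort(unique(labs)), sort(quadrant_levels()))
})

test_that("modality specs validate their pass-bands and channel counts", {
  ms <- modality_spec("EEG")
  expect_equal(ms$n_channels, 14L)
  expect_equal(ms$band, c(0.5, 45))
  expect_equal(modality_spec("GSR")$band, c(0.04, 0.25))
  expect_error(modality_spec("EEG", band = c(0, 45)), "0 < low")
  expect_error(modality_spec("EEG", band = c(1, 70)), "Nyquist")
  expect_error(modality_spec("EEG", n_channels = 0), "n_channels")
})

test_that("EDF round-trip preserves samples within 16-bit quantization", {
  rec <- tiny_recording(seed = 21)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  for (m in c("EEG", "ECG", "GSR")) {
    x <- rec$signals[[m]]
    qstep <- max(apply(x, 1, function(v) diff(range(v)))) / 65535
    expect_lt(max(abs(back$signals[[m]] - x)), qstep + 1e-12)
    expect_equal(back$sampling_rates[[m]], rec$sampling_rates[[m]])
  }
  expect_equal(back$subject_id, rec$subject_id)
  expect_equal(back$valence, rec$valence, tolerance = 1e-4)
  expect_equal(recording_label(back), recording_label(rec))
})

test_that("EDF reader groups channels by modality and reports bad labels", {
  rec <- tiny_recording(seed = 22)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(nrow(back$signals$EEG), 14)
  expect_equal(nrow(back$signals$ECG), 2)
  expect_equal(nrow(back$signals$GSR), 1)
  expect_equal(rownames(back$signals$EEG), eeg_channel_names(14))
  # a spec demanding a modality the file lacks names it
  rec2 <- rec
  rec2$signals$GSR <- NULL
  rec2$sampling_rates$GSR <- NULL
  path2 <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec2, path2)
  expect_error(read_edf(path2), "GSR")
  expect_error(read_edf(tempfile(fileext = ".edf")), "no such file")
})

test_that("AMIGOS-style container round-trips recordings and flags NaN", {
  spec <- tiny_synth_spec(seed = 31)
  recs <- list(generate_recording(spec, "HVHA", seed = 31, trial_id = "T01"),
               generate_recording(spec, "LVLA", seed = 32, trial_id = "T02"))
  path <- withr::local_tempfile(fileext = ".mat")
  write_amigos_container(recs, path)
  back <- read_amigos_container(path)
  expect_length(back, 2)
  for (i in 1:2) {
    for (m in c("EEG", "ECG", "GSR"))
      expect_equal(back[[i]]$signals[[m]], recs[[i]]$signals[[m]],
                   ignore_attr = TRUE)
    expect_equal(back[[i]]$valence, recs[[i]]$valence)
    expect_equal(back[[i]]$arousal, recs[[i]]$arousal)
  }
  # NaN self-assessment marks the trial unlabeled
  recs[[2]]$valence <- NaN
  write_amigos_container(recs, path)
  back <- read_amigos_container(path)
  expect_true(is.na(back[[2]]$valence))
  expect_true(is.na(recording_label(back[[2]])))
})

test_that("container reader validates the documented key layout eagerly", {
  # a MAT file missing required keys names the failing key
  path <- withr::local_tempfile(fileext = ".mat")
  emochart:::m5_write_file(list(emochart:::m5_numeric(diag(2), "junk")), path)
  expect_error(read_amigos_container(path), "joined_data")
})

test_that("containers written here are readable by an independent parser", {
  rec <- tiny_recording(seed = 41)
  path <- withr::local_tempfile(fileext = ".mat")
  write_amigos_container(list(rec), path)
  script <- paste0(
    "import scipy.io, sys; m = scipy.io.loadmat(sys.argv[1]);",
    "print(m['joined_data'][0,0].shape[1],",
    "round(float(abs(m['joined_data'][0,0][:,0]).sum()), 6))")
  out <- system2("python", c("-c", shQuote(script), shQuote(path)),
                 stdout = TRUE)
  parts <- strsplit(out, " ")[[1]]
  expect_equal(as.integer(parts[1]), 17L)
  expect_equal(as.numeric(parts[2]), round(sum(abs(rec$signals$EEG[1, ])), 6))
})

test_that("pipeline config validates and round-trips through JSON and YAML", {
  expect_error(pipeline_config(window_s = 10, hop_s = 15), "hop_s")
  expect_error(pipeline_config(k = 1), "k must be")
  cfg <- desk_scale_config(seed = 7)
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_config(cfg, path)
    back <- read_config(path)
    expect_equal(back$seed, 7L)
    expect_equal(back$scalogram_size, cfg$scalogram_size)
    expect_equal(back$sae$filters, cfg$sae$filters)
    expect_equal(back$modalities$GSR$band, c(0.04, 0.25))
  }
})
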