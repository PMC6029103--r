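# track classification, counting, flux balance, division extraction

test_that("a stationary track is attached at every frame", {
  trk <- one_cell_track(t_attach = 0, n_frames = 100, jitter = 0)
  att <- classify_attached(trk[, c("x_um", "y_um")])
  expect_true(all(att))
})

test_that("a fast random walk is mobile at every frame", {
  # step SD 2 um/frame >> 1 um threshold over a 5-frame window
  trk <- one_cell_track(t_attach = Inf, n_frames = 200, step_sd = 2, seed = 4)
  att <- classify_attached(trk[, c("x_um", "y_um")], window = 5, threshold = 1)
  expect_true(!any(att))
})

test_that("classifier finds a known attachment time within one window", {
  window <- 5
  for (seed in 1:5) {
    t_star <- 300
    trk <- one_cell_track(t_attach = t_star, n_frames = 300, dt = 3,
                          step_sd = 2, jitter = 0.02, seed = seed)
    att <- classify_attached(trk[, c("x_um", "y_um")], window = window,
                             threshold = 1)
    sw <- which(att)[1]
    truth <- which(trk$time_s >= t_star)[1]
    expect_lte(abs(sw - truth), window)
    expect_true(all(att[sw:length(att)]))
  }
})

test_that("tracks shorter than the window are classified by total displacement", {
  xy <- cbind(c(0, 0.1, 0.2), c(0, 0, 0))
  expect_true(all(classify_attached(xy, window = 5, threshold = 1)))
  xy2 <- cbind(c(0, 5, 10), c(0, 0, 0))
  expect_true(!any(classify_attached(xy2, window = 5, threshold = 1)))
})

test_that("count conservation holds and all-attached input counts trivially", {
  tab <- do.call(rbind, lapply(1:10, function(i) {
    d <- one_cell_track(t_attach = 0, n_frames = 50, jitter = 0,
                        cell_id = sprintf("c%04d", i), seed = i)
    d
  }))
  s <- count_series(tab)
  expect_true(all(s$n_surface == 10))
  expect_true(all(s$n_bulk == 0))
  expect_true(all(s$n_bulk + s$n_surface == s$n_total))
})

test_that("counting classified tracks reproduces generator truth when noise-free", {
  cfg <- sim_config(n_cells = 60, duration = 600, seed = 31,
                    jitter_attached = 0, diffusion_bulk = 5)
  trk <- simulate_attachment(mix_late_exponential(), cfg)
  truth <- count_series(trk)
  tab <- classify_tracks(track_table(trk), window = 5, threshold = 1)
  # windowed decisions lag the true switch by up to a window; compare to the
  # generator's own bookkeeping on the per-cell switch times instead of frames
  reclassified <- count_series(tab)
  expect_true(all(reclassified$n_bulk + reclassified$n_surface ==
                    reclassified$n_total))
  # per-cell: classified switch within one window of the true switch
  true_att <- track_table(trk)$attached
  lag_ok <- mapply(function(a, b) {
    ia <- which(a)[1]; ib <- which(b)[1]
    (is.na(ia) && is.na(ib)) || (!is.na(ia) && !is.na(ib) && abs(ia - ib) <= 5)
  }, split(tab$attached, tab$cell_id), split(true_att, tab$cell_id))
  expect_gt(mean(lag_ok), 0.95)
})

test_that("generator-truth series equals the generator's own bookkeeping", {
  trk <- simulate_attachment(mix_late_exponential(),
                             sim_config(n_cells = 80, duration = 300, seed = 8))
  s1 <- count_series(trk)                 # from event times
  s2 <- count_series(track_table(trk))    # from materialized attached flags
  expect_equal(s1$n_surface, s2$n_surface)
  expect_equal(s1$n_bulk, s2$n_bulk)
})

test_that("empty and inconsistent inputs are structural errors", {
  expect_error(count_series(data.frame()), "empty")
  a <- one_cell_track(0, n_frames = 10, cell_id = "a")
  b <- one_cell_track(0, n_frames = 12, cell_id = "b")
  expect_error(count_series(rbind(a, b)), "inconsistent frame grids")
})

test_that("surface count is non-decreasing without detachment", {
  trk <- simulate_attachment(mix_late_exponential(),
                             sim_config(n_cells = 500, duration = 1200, seed = 2))
  s <- count_series(trk)
  expect_true(all(diff(s$n_surface) >= 0))
})

test_that("flux check counts transitions and flags detachment-dominated data", {
  # beta = 0: no detach events at all
  trk0 <- simulate_attachment(mix_late_exponential(),
                              sim_config(n_cells = 400, duration = 1800, seed = 5))
  fx0 <- flux_check(trk0)
  expect_equal(fx0$n_detach_events, 0)
  expect_false(fx0$flag)
  # weak detachment: attachment still dominates, no flag
  mixb <- phenotype_mix(1, 5e-3, detach_rates = 5e-5)
  trkb <- simulate_attachment(mixb, sim_config(n_cells = 500, duration = 1800,
                                               seed = 6))
  fxb <- flux_check(trkb)
  expect_gt(fxb$ratio, 10)
  expect_false(fxb$flag)
  # detachment-dominated scenario raises the flag
  tab <- data.frame(cell_id = rep("a", 10), frame = 1:10,
                    attached = c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                 FALSE, FALSE, FALSE, FALSE, FALSE))
  fx <- flux_check(tab)
  expect_equal(fx$n_detach_events, 1)
  expect_true(fx$flag)
})

test_that("a single division with both daughters tracked to the end is (stay, stay)", {
  tab <- division_fixture(c("stay", "stay"))
  forest <- extract_division_events(tab)
  cnt <- classify_fates(forest)
  expect_equal(cnt$n_div, 1)
  expect_equal(cnt$n_both_stay, 1)
})

test_that("division extraction reproduces generator fates exactly (round trip)", {
  cfg <- lineage_config(n_founders = 120, fate_probs = c(0.2, 0.4, 0.4),
                        mean_division_interval = 2400, duration = 36000,
                        seed = 17)
  forest <- simulate_lineage(cfg)
  tab <- lineage_to_tracks(forest, frame_interval = 3, seed = 18)
  rebuilt <- extract_division_events(tab, censor_frames = 3)
  expect_length(attr(rebuilt, "orphans"), 0)
  truth <- censor_forest(forest, t_censor = 3 * 3)
  expect_identical(unclass(classify_fates(rebuilt))[1:5],
                   unclass(classify_fates(truth))[1:5])
})

test_that("tracks without divisions give an empty forest", {
  tab <- one_cell_track(0, n_frames = 30)
  forest <- extract_division_events(tab)
  cnt <- classify_fates(forest)
  expect_equal(cnt$n_div, 0)
})

test_that("orphan daughters are reported, not dropped", {
  tab <- division_fixture(c("stay", "leave"))
  ghost <- one_cell_track(0, n_frames = 5, cell_id = "g1")
  ghost$parent_id <- "nonexistent"
  ghost$frame <- 30:34
  ghost$time_s <- (ghost$frame - 1) * 3
  forest <- extract_division_events(rbind(tab, ghost))
  expect_true("g1" %in% attr(forest, "orphans"))
})

test_that("parent cycles are a structural error", {
  a <- one_cell_track(0, n_frames = 5, cell_id = "a")
  a$parent_id <- "b"
  b <- one_cell_track(0, n_frames = 5, cell_id = "b")
  b$parent_id <- "a"
  expect_error(extract_division_events(rbind(a, b)), "cycle")
})
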