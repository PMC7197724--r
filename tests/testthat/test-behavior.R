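bin_row <- function(animal_id = "a1", group = "RC", bin_start_s = 0,
                    bin_end_s = 300, lighting = "dark", smldist = 1,
                    lardist = 1, smldur = 1, lardur = 1) {
  data.frame(animal_id = animal_id, group = group, bin_start_s = bin_start_s,
             bin_end_s = bin_end_s, lighting = lighting, smldist = smldist,
             lardist = lardist, smldur = smldur, lardur = lardur,
             stringsAsFactors = FALSE)
}

default_bins <- function(animal_id, group, d, t) {
  # three protocol bins with per-bin distance d and movement duration t
  rbind(bin_row(animal_id, group, 0, 300, "dark", 0.3 * d, 0.7 * d,
                0.4 * t, 0.6 * t),
        bin_row(animal_id, group, 300, 600, "light", 0.3 * d, 0.7 * d,
                0.4 * t, 0.6 * t),
        bin_row(animal_id, group, 600, 900, "dark", 0.3 * d, 0.7 * d,
                0.4 * t, 0.6 * t))
}

test_that("swim speed is the ratio of summed distance to summed duration", {
  bins <- bin_row(smldist = 2, lardist = 4, smldur = 1, lardur = 2)
  s <- summarize_larvae(bins, protocol_spec("dark", 300))
  expect_equal(s$total_distance_mm, 6)
  expect_equal(s$swim_speed_mm_per_s, 2)

  # ratio of sums, not mean of per-bin speeds: bins (1,1,1,1) and (3,3,1,1)
  bins <- rbind(bin_row(smldist = 1, lardist = 1, smldur = 1, lardur = 1),
                bin_row(bin_start_s = 300, bin_end_s = 600,
                        lighting = "light", smldist = 3, lardist = 3,
                        smldur = 1, lardur = 1))
  s <- summarize_larvae(bins, protocol_spec(c("dark", "light"), c(300, 300)))
  expect_equal(s$total_distance_mm, 8)
  expect_equal(s$swim_speed_mm_per_s, 2)  # 8/4, not mean(1, 3) = 2 by luck:
  # distinguish from mean of per-bin speeds with unequal durations
  bins$smldur[2] <- 0.5
  bins$lardur[2] <- 0.5
  s <- summarize_larvae(bins, protocol_spec(c("dark", "light"), c(300, 300)))
  expect_equal(s$swim_speed_mm_per_s, 8 / 3)

  # all-zero movement: distance 0, speed undefined but animal retained
  s <- summarize_larvae(bin_row(smldist = 0, lardist = 0, smldur = 0,
                                lardur = 0), protocol_spec("dark", 300))
  expect_equal(s$total_distance_mm, 0)
  expect_true(is.na(s$swim_speed_mm_per_s))
  expect_false(s$speed_defined)
})

test_that("total distance equals the sum of per-phase distances", {
  sim <- simulate_tracks(track_sim_config(n_per_group = 4, seed = 2))
  s <- summarize_larvae(sim$bins, sim$protocol)
  per_phase <- s$distance_phase1 + s$distance_phase2 + s$distance_phase3
  expect_equal(s$total_distance_mm, per_phase)
  # overall speed lies between the per-bin extremes (weighted mean)
  bins <- sim$bins
  bins$speed <- (bins$smldist + bins$lardist) / (bins$smldur + bins$lardur)
  for (id in unique(bins$animal_id)) {
    v <- bins$speed[bins$animal_id == id]
    sp <- s$swim_speed_mm_per_s[s$animal_id == id]
    expect_gte(sp, min(v) - 1e-12)
    expect_lte(sp, max(v) + 1e-12)
  }
})

test_that("phase assignment uses half-open windows and rejects straddlers", {
  bins <- rbind(bin_row(bin_start_s = 0, bin_end_s = 300),
                bin_row(bin_start_s = 300, bin_end_s = 600,
                        lighting = "light"))
  out <- split_phases(bins, protocol_spec())
  expect_equal(out$phase, c(1L, 2L))
  expect_equal(out$phase_lighting, c("dark", "light"))
  straddle <- bin_row(bin_start_s = 250, bin_end_s = 550)
  expect_error(split_phases(straddle, protocol_spec()), "straddles")
})

test_that("tracking export validation rejects malformed rows, missing columns are fatal", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "t.csv")
  bins <- rbind(bin_row(),
                bin_row(smldur = 200, lardur = 200),   # 400 s in a 300 s bin
                bin_row(smldist = -1),
                bin_row(bin_start_s = 300, bin_end_s = 300))
  write_tracking_export(bins, path, seed = 1)
  expect_message(out <- read_tracking_export(path), "rejected")
  expect_equal(nrow(out), 1L)
  expect_setequal(attr(out, "rejected")$reason,
                  c("movement duration exceeds bin length",
                    "negative movement quantity", "bin_end_s <= bin_start_s"))

  writeLines("animal_id,group,bin_start_s", path)
  expect_error(read_tracking_export(path), "missing column")

  # header-only export parses to an empty frame
  write_tracking_export(bin_row()[0, ], path)
  expect_equal(nrow(read_tracking_export(path)), 0L)
})

test_that("tracking exports round-trip through write/read", {
  sim <- simulate_tracks(track_sim_config(n_per_group = 3, seed = 9))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "t.csv")
  write_tracking_export(sim$bins, path, seed = 9)
  back <- read_tracking_export(path)
  expect_equal(back[, names(sim$bins)], sim$bins, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("group comparison handles identical and degenerate inputs", {
  s <- data.frame(group = rep(c("A", "B"), each = 3),
                  total_distance_mm = c(1, 2, 3, 1, 2, 3))
  cmp <- compare_groups(s, "total_distance_mm", "A", "B")
  expect_equal(cmp$t_stat, 0)
  expect_equal(cmp$p_value, 1)
  expect_false(cmp$degenerate)

  s$total_distance_mm <- c(1, 1, 1, 11, 11, 11)  # zero within-group variance
  cmp <- compare_groups(s, "total_distance_mm", "A", "B")
  expect_true(cmp$degenerate)
  expect_equal(cmp$p_value, 0)
  expect_equal(cmp$fold_change, 11)

  expect_error(compare_groups(s[c(1, 4, 5), ], "total_distance_mm", "A", "B"),
               ">= 2")
  expect_error(compare_groups(s, "total_distance_mm", "A", "Z"),
               "not present")
})

test_that("swapping the groups negates t and preserves p", {
  set.seed(5)
  for (i in 1:10) {
    s <- data.frame(group = rep(c("A", "B"), each = 6),
                    total_distance_mm = c(rnorm(6, 10), rnorm(6, 8)))
    ab <- compare_groups(s, "total_distance_mm", "A", "B")
    ba <- compare_groups(s, "total_distance_mm", "B", "A")
    expect_equal(ab$t_stat, -ba$t_stat)
    expect_equal(ab$p_value, ba$p_value)
  }
})

test_that("replicate-level analysis averages animals within replicates", {
  s <- data.frame(group = rep(c("A", "B"), each = 4),
                  replicate = rep(c(1, 1, 2, 2), 2),
                  total_distance_mm = c(1, 3, 5, 7, 2, 4, 6, 8))
  cmp <- compare_groups(s, "total_distance_mm", "A", "B",
                        level = "replicate")
  expect_equal(cmp$n_a, 2L)
  expect_equal(cmp$mean_a, mean(c(mean(c(1, 3)), mean(c(5, 7)))))
})

test_that("zero-noise simulation realizes the planted multipliers exactly", {
  sim <- simulate_tracks(track_sim_config(
    n_per_group = 2, noise_cv = 0, hypoactivity_factor = 0.5,
    light_factor = 0.6, seed = 1))
  s <- summarize_larvae(sim$bins, sim$protocol)
  rc <- s[s$group == "RC", ]
  mo <- s[s$group == "tbMO", ]
  expect_equal(mo$total_distance_mm / rc$total_distance_mm, c(0.5, 0.5))
  # light phase scales distance by light_factor relative to dark
  expect_equal(rc$distance_phase2[1] / rc$distance_phase1[1], 0.6)
  # three 300-s phases produce exactly 3 bins per animal
  expect_equal(nrow(sim$bins), 4 * 3)
  expect_error(track_sim_config(noise_cv = -0.1), "noise_cv")
})

test_that("PTZ treatment with zero noise gives exact planted fold changes", {
  sim <- simulate_tracks(track_sim_config(
    n_per_group = 3, groups = c("NT", "PTZ"), hypo_groups = character(),
    ptz_groups = "PTZ", ptz_speed_factor = 2, ptz_distance_factor = 6,
    noise_cv = 0, seed = 1))
  s <- summarize_larvae(sim$bins, sim$protocol)
  res <- ptz_response(s, treated_label = "PTZ", untreated_label = "NT")
  expect_equal(res$distance$fold_change, 6)
  expect_equal(res$speed$fold_change, 2)
})

test_that("null PTZ contrast shows fold change near 1 and no significance", {
  sim <- simulate_tracks(track_sim_config(
    n_per_group = 20, groups = c("NT", "PTZ"), hypo_groups = character(),
    ptz_groups = character(), noise_cv = 0.2, seed = 4))
  s <- summarize_larvae(sim$bins, sim$protocol)
  res <- ptz_response(s, treated_label = "PTZ", untreated_label = "NT")
  expect_gt(res$distance$p_value, 0.05)
  expect_lt(abs(res$distance$fold_change - 1), 0.15)
})
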