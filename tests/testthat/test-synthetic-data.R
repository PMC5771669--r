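test_that("FLIP simulator limits behave as the two-compartment model dictates", {
  # no exchange: bud constant, mother a pure geometric decay
  cfg <- flip_sim_config(n_cells = 1, exchange_rate = 0, bleach_fraction = 0.05,
                         acquisition_decay = 0, noise_sd = 0, background = 0,
                         seed = 1)
  tr <- gen_flip_traces(cfg)
  bud <- tr$intensity[tr$role == "bud"]
  mom <- tr$intensity[tr$role == "mother"]
  expect_equal(bud, rep(1000, cfg$n_frames))
  expect_equal(mom, 1000 * 0.95^(0:(cfg$n_frames - 1)))

  # fast exchange: mother and bud converge toward each other
  tr2 <- gen_flip_traces(flip_sim_config(n_cells = 1, exchange_rate = 0.5,
                                         bleach_fraction = 0.05,
                                         acquisition_decay = 0, noise_sd = 0,
                                         background = 0, seed = 1))
  gap <- abs(tr2$intensity[tr2$role == "bud"] - tr2$intensity[tr2$role == "mother"])
  expect_lt(gap[length(gap)], gap[2])
  # post-bleach disequilibrium stays bounded by the per-pulse bleach loss
  expect_lt(max(gap[-1]) / 1000, 0.06)
})

test_that("FLIP latent state matches an independent recurrence iteration", {
  cfg <- flip_sim_config(n_cells = 1, bleach_fraction = 0.05,
                         exchange_rate = 0.01, acquisition_decay = 0.002,
                         noise_sd = 0, background = 0, n_frames = 30, seed = 9)
  tr <- gen_flip_traces(cfg)
  oracle <- flip_recurrence_oracle(30, b = 0.05, x = 0.01, a = 0.002)
  lat <- attr(tr, "latent")
  expect_equal(lat$latent[lat$role == "mother"][1:11], oracle$M[1:11],
               tolerance = 1e-12)
  expect_equal(lat$latent[lat$role == "bud"][1:11], oracle$B[1:11],
               tolerance = 1e-12)
  # controls decay by acquisition photobleaching only
  expect_equal(lat$latent[lat$role == "control" & lat$cell_id == "ctrl01"],
               1000 * (1 - 0.002)^(0:29), tolerance = 1e-12)
})

test_that("FLIP simulator conserves total signal without bleach or decay", {
  for (x in c(0.01, 0.1, 0.4)) {
    cfg <- flip_sim_config(n_cells = 1, bleach_fraction = 1e-12,
                           exchange_rate = x, acquisition_decay = 0,
                           noise_sd = 0, background = 0, seed = 2)
    lat <- attr(gen_flip_traces(cfg), "latent")
    tot <- lat$latent[lat$role == "mother"] + lat$latent[lat$role == "bud"]
    expect_equal(tot, rep(2000, cfg$n_frames), tolerance = 1e-6)
  }
})

test_that("FLIP config rejects overshooting exchange and bad noise", {
  expect_error(flip_sim_config(exchange_rate = 0.6), "overshoot")
  expect_error(flip_sim_config(noise_sd = -1), "noise_sd")
  expect_error(flip_sim_config(n_controls = 2), "n_controls")
})

test_that("segregation simulator hits its degenerate limits and its mean", {
  obs0 <- gen_circle_observations(segregation_sim_config(n_cells = 200,
                                                         p_pass = 0, seed = 3))
  expect_true(all(obs0$circles_in_mother == obs0$circle_count))
  obs1 <- gen_circle_observations(segregation_sim_config(n_cells = 200,
                                                         p_pass = 1, seed = 3))
  expect_true(all(obs1$circles_in_mother == 0))

  cfg <- segregation_sim_config(n_cells = 10000, class_mix = c(0.6, 0.3, 0.1),
                                p_pass = 0.17, seed = 4)
  obs <- gen_circle_observations(cfg)
  frac_bud <- sum(obs$circle_count - obs$circles_in_mother) / sum(obs$circle_count)
  se <- sqrt(0.17 * 0.83 / sum(obs$circle_count))
  expect_lt(abs(frac_bud - 0.17), 3 * se)
})

test_that("timeline simulator respects hazards, grid snapping and the survival law", {
  tl0 <- gen_timelines(timeline_sim_config(n_cells = 100, hazard_early = 0,
                                           hazard_late = 0, seed = 5))
  expect_true(all(tl0$passage_times_min == ""))

  # early-only hazard: P(passage) = 1 - exp(-h * early duration)
  cfg <- timeline_sim_config(n_cells = 5000, early_mean = 4, early_sd = 0,
                             late_mean = 15, late_sd = 0,
                             hazard_early = 0.05, hazard_late = 0, seed = 6)
  tl <- gen_timelines(cfg)
  p_hat <- mean(tl$passage_times_min != "")
  p_true <- 1 - exp(-0.05 * 4)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 5000))

  # 1-minute grid: every event time is an integer
  times <- unlist(parse_passage_times(tl))
  expect_true(all(times == round(times)))
  expect_true(all(tl$t_dumbbell_min == round(tl$t_dumbbell_min)))
  expect_true(all(tl$t_dumbbell_min > 0 & tl$t_karyo_min > tl$t_dumbbell_min))
})

test_that("rim simulator places peaks as configured", {
  flat <- gen_rim_profiles(rim_sim_config(n_cells = 5, npc_peak_amplitude = 1,
                                          noise_sd = 0, seed = 7))
  gfp <- flat$gfp[flat$cell_id == flat$cell_id[1]]
  expect_equal(gfp, rep(gfp[1], length(gfp)))

  att <- gen_rim_profiles(rim_sim_config(n_cells = 20, p_attached = 1,
                                         noise_sd = 0, seed = 8))
  for (id in unique(att$cell_id)) {
    cp <- att[att$cell_id == id, ]
    expect_equal(cp$position_index[which.max(cp$gfp)],
                 cp$position_index[which.max(cp$mcherry)])
  }

  half <- gen_rim_profiles(rim_sim_config(n_cells = 200, p_attached = 0.5,
                                          seed = 9))
  frac <- mean(attr(half, "attached"))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 200))
})

test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(gen_flip_traces(flip_sim_config(n_cells = 3, seed = 10)),
                   gen_flip_traces(flip_sim_config(n_cells = 3, seed = 10)))
  expect_identical(gen_circle_observations(segregation_sim_config(seed = 10)),
                   gen_circle_observations(segregation_sim_config(seed = 10)))
  expect_identical(gen_timelines(timeline_sim_config(n_cells = 30, seed = 10)),
                   gen_timelines(timeline_sim_config(n_cells = 30, seed = 10)))
  expect_identical(gen_rim_profiles(rim_sim_config(n_cells = 5, seed = 10)),
                   gen_rim_profiles(rim_sim_config(n_cells = 5, seed = 10)))
})

test_that("pipeline tables round-trip losslessly through the CSV layer", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  obs <- gen_circle_observations(segregation_sim_config(n_cells = 25, seed = 11))
  write_pipeline_csv(obs, tmp)
  back <- read_pipeline_csv(tmp)
  expect_equal(back, obs, ignore_attr = TRUE)
  expect_identical(attr(back, "seed"), 11L)

  tl <- gen_timelines(timeline_sim_config(n_cells = 25, hazard_early = 0.2,
                                          seed = 12))
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_pipeline_csv(tl, tmp2)
  tl2 <- read_pipeline_csv(tmp2)
  tl2$passage_times_min[is.na(tl2$passage_times_min)] <- ""
  expect_equal(parse_passage_times(tl2), parse_passage_times(tl))
  expect_equal(tl2$t_karyo_min, tl$t_karyo_min)
})
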