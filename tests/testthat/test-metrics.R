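seg_of <- function(ft, fp, dt = 0.1) {
  data.frame(t = (seq_along(ft) - 0.5) * dt, ft = ft, fp = fp)
}

test_that("distance, path and velocity follow their 3-4-5 hand cases", {
  ref <- c(ft = 0, fp = 0)

  still <- seg_of(rep(3, 5), rep(4, 5))
  expect_equal(roa_aid(still, c(ft = 3, fp = 4)), c(aid = 0, aid_ft = 0, aid_fp = 0))
  expect_equal(roa_aid(still, ref), c(aid = 5, aid_ft = 3, aid_fp = 4))

  step <- seg_of(c(0, 3), c(0, 4))
  expect_equal(roa_aip(step), c(aip = 5, aip_ft = 3, aip_fp = 4))
  expect_equal(roa_aip(seg_of(rep(1, 9), rep(1, 9))), c(aip = 0, aip_ft = 0, aip_fp = 0))

  square <- seg_of(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(roa_aip(square), c(aip = 4, aip_ft = 2, aip_fp = 2))

  # velocity is path over nominal duration: 5 frames at 10 Hz span 0.5 s
  expect_equal(roa_aiv(square), c(aiv = 8, aiv_ft = 4, aiv_fp = 4))
})

test_that("spread statistics are population-based and combine as RMS", {
  s <- roa_spread(seg_of(c(0, 2, 0, 2), rep(7, 4)))
  expect_equal(s[["std_ft"]], 1)
  expect_equal(s[["std_fp"]], 0)
  expect_equal(s[["ais"]], 1)
  expect_equal(s[["avg_ft"]], 1)
  expect_equal(s[["avg_fp"]], 7)

  set.seed(20)
  big <- seg_of(rnorm(2e4, 0, 2), rnorm(2e4, 0, 2))
  expect_equal(roa_spread(big)[["ais"]], 2 * sqrt(2), tolerance = 0.03)
})

test_that("ellipse area matches the large-N isotropic closed form and handles degeneracy", {
  set.seed(21)
  n <- 2e4
  seg <- seg_of(rnorm(n), rnorm(n))
  expect_equal(roa_aez(seg), 2 * pi * qf(0.95, 2, n - 2), tolerance = 0.05)

  expect_warning(a0 <- roa_aez(seg_of(1:10, 2 * (1:10))), "degenerate")
  expect_equal(a0, 0)
})

test_that("circle area reduces to pi R^2 on a ring and zero when still", {
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  ring <- seg_of(3 * cos(th), 3 * sin(th))
  expect_equal(roa_acz(ring), pi * 9, tolerance = 1e-9)
  expect_equal(roa_acz(seg_of(rep(1, 5), rep(2, 5))), 0)
})

test_that("swept area matches the shoelace oracle, circles and radial lines", {
  # one revolution of radius R in time T sweeps pi R^2 / T
  n <- 1e4
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  circ <- seg_of(2 * cos(th), 2 * sin(th), dt = 10 / n)
  expect_equal(roa_amz(circ), pi * 4 / 10, tolerance = 5e-3)

  radial <- seg_of(c(-2, -1, 0, 1, 2), c(-4, -2, 0, 2, 4))
  expect_equal(roa_amz(radial), 0)

  set.seed(22)
  for (i in 1:20) {
    seg <- rand_traj(50)
    expect_equal(roa_amz(seg),
                 oracle_amz(seg$ft, seg$fp, nrow(seg) * 0.1), tolerance = 1e-9)
  }
})

test_that("all trajectory metrics match brute-force oracles on random inputs", {
  set.seed(23)
  for (i in 1:60) {
    seg <- rand_traj(50)
    ref <- c(ft = rnorm(1, 10), fp = rnorm(1, 50))
    expect_equal(unname(roa_aid(seg, ref)),
                 oracle_dist(seg$ft, seg$fp, ref[["ft"]], ref[["fp"]]),
                 tolerance = 1e-9)
    expect_equal(unname(roa_aip(seg)), oracle_path(seg$ft, seg$fp),
                 tolerance = 1e-9)
    expect_equal(unname(roa_spread(seg)), oracle_spread(seg$ft, seg$fp),
                 tolerance = 1e-9)
  }
})

test_that("metrics are translation invariant; resultants rotation invariant", {
  set.seed(24)
  cfgm <- metric_config()
  for (i in 1:10) {
    seg <- rand_traj(40)
    ref <- c(ft = 10, fp = 50)
    shift <- c(rnorm(1, 0, 20), rnorm(1, 0, 20))
    seg_t <- seg; seg_t$ft <- seg$ft + shift[1]; seg_t$fp <- seg$fp + shift[2]
    ref_t <- c(ft = ref[["ft"]] + shift[1], fp = ref[["fp"]] + shift[2])

    expect_equal(roa_aid(seg_t, ref_t), roa_aid(seg, ref), tolerance = 1e-9)
    expect_equal(roa_aip(seg_t), roa_aip(seg), tolerance = 1e-9)
    expect_equal(roa_aez(seg_t, cfgm), roa_aez(seg, cfgm), tolerance = 1e-9)
    expect_equal(roa_acz(seg_t, cfgm), roa_acz(seg, cfgm), tolerance = 1e-9)
    expect_equal(roa_amz(seg_t), roa_amz(seg), tolerance = 1e-9)
    expect_equal(roa_spread(seg_t)[["ais"]], roa_spread(seg)[["ais"]],
                 tolerance = 1e-9)

    rot <- rotate_traj(seg, runif(1, 0, 2 * pi))
    expect_equal(roa_aip(rot)[["aip"]], roa_aip(seg)[["aip"]], tolerance = 1e-9)
    expect_equal(roa_aez(rot, cfgm), roa_aez(seg, cfgm), tolerance = 1e-9)
    expect_equal(roa_acz(rot, cfgm), roa_acz(seg, cfgm), tolerance = 1e-9)
    expect_equal(roa_amz(rot), roa_amz(seg), tolerance = 1e-9)
    expect_equal(roa_spread(rot)[["ais"]], roa_spread(seg)[["ais"]],
                 tolerance = 1e-9)

    # structural identities
    expect_equal(roa_aiv(seg) * (nrow(seg) * 0.1),
                 setNames(roa_aip(seg), c("aiv", "aiv_ft", "aiv_fp")))
    sp <- roa_spread(seg)
    expect_equal(sp[["ais"]]^2, sp[["std_ft"]]^2 + sp[["std_fp"]]^2)

    # spatial scaling: lengths scale as s, areas as s^2
    s <- 2.5
    seg_s <- seg; seg_s$ft <- s * seg$ft; seg_s$fp <- s * seg$fp
    expect_equal(roa_aip(seg_s)[["aip"]], s * roa_aip(seg)[["aip"]])
    expect_equal(roa_aez(seg_s, cfgm), s^2 * roa_aez(seg, cfgm))
    expect_equal(roa_acz(seg_s, cfgm), s^2 * roa_acz(seg, cfgm))
  }
})

test_that("displacement is the T1-to-T3 distance of mean positions", {
  region <- analysis_region(0, 30)
  traj <- seg_of(c(rep(0, 100), rep(1, 100), rep(3, 100)),
                 c(rep(0, 100), rep(2, 100), rep(4, 100)))
  expect_equal(roa_displacement(traj, region), 5)
  expect_equal(roa_displacement(seg_of(rep(1, 300), rep(1, 300)), region), 0)

  empty <- traj; empty$ft[201:300] <- NA
  expect_error(roa_displacement(empty, region), "T1 or T3")
})

test_that("segment table carries all variables and maxima are element-wise", {
  cfg <- quick_cfg(30)
  sub <- simulate_subject(cfg)
  a <- analyze_subject(sub$rec, sub$torque)
  vars <- c("torque_mean", "torque_cov", "envelope_mean", "aif",
            "aid", "aid_fp", "aid_ft", "aip", "aip_fp", "aip_ft",
            "aiv", "aiv_fp", "aiv_ft", "aez", "amz", "acz",
            "ais", "std_ft", "std_fp", "avg_ft", "avg_fp")
  expect_equal(a$metrics$label, c("T1", "T2", "T3"))
  expect_true(all(vars %in% names(a$metrics)))
  for (v in vars)
    expect_equal(a$maxima[[v]], max(a$metrics[[v]]))
  # non-negativity of distance/area/velocity/spread metrics
  for (v in setdiff(vars, c("torque_mean", "torque_cov", "envelope_mean", "aif")))
    expect_true(all(a$metrics[[v]] >= 0))
})

test_that("a long gap invalidates path metrics but not dispersion metrics", {
  traj <- rand_traj(300)
  traj$ft[131:170] <- NA    # 4 s hole inside T2 = [10, 20) s
  traj$fp[131:170] <- NA
  region <- analysis_region(0, 30)
  env <- structure(list(values = matrix(1, 1, 300), t = traj$t,
                        frame_rate = 10), class = "envelope_series")
  sp <- structure(list(aif = matrix(100, 1, 60), t = (1:60 - 0.5) * 0.5,
                       frame_s = 0.5), class = "spectral_series")
  tq <- torque_trace(rep(60, 3000), 100, 100)
  lay <- grid_layout(1, 1)
  expect_warning(
    sm <- segment_metrics(traj, env, sp, tq, region, lay),
    "gap")
  bad_seg <- sm$metrics$label == "T2"
  expect_true(all(is.na(sm$metrics$aip[bad_seg])))
  expect_true(all(!is.na(sm$metrics$ais)))
})
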