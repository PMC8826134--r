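test_that("completeness, datum and AGL stages follow their definitions", {
  ras <- toy_rasters()
  f <- rbind(toy_fix(ground_speed = NA), toy_fix(altitude_raw = NA),
             toy_fix())
  expect_equal(nrow(require_complete(f)), 1)
  expect_equal(nrow(require_complete(f[0, ])), 0)

  # msl passes through; ellipsoid subtracts the undulation (sign matters)
  f <- to_msl(toy_fix(altitude_raw = 2000, altitude_datum = "msl"))
  expect_equal(f$altitude_msl, 2000)
  f <- to_msl(toy_fix(altitude_raw = 1000, altitude_datum = "ellipsoid"),
              ras$undulation)
  expect_equal(f$altitude_msl, 950)
  neg_und <- grid_raster(matrix(-30, 20, 20), cellsize = 25)
  f <- to_msl(toy_fix(altitude_raw = 1000, altitude_datum = "ellipsoid"),
              neg_und)
  expect_equal(f$altitude_msl, 1030)
  out <- toy_fix(altitude_datum = "ellipsoid", x = 1e6)
  expect_error(to_msl(out, ras$undulation), "coverage")

  f <- compute_agl(to_msl(toy_fix(altitude_raw = 2500)), ras$dem)
  expect_equal(f$agl, 1500)
  f <- compute_agl(to_msl(toy_fix(altitude_raw = 900)), ras$dem)
  expect_equal(f$agl, -100)              # negative AGL allowed here
})

test_that("quality filter applies HDOP when present, else position error", {
  f <- rbind(toy_fix(hdop = 10.0), toy_fix(hdop = 9.9),
             toy_fix(position_error = 30), toy_fix(position_error = 29.9),
             toy_fix(hdop = 3, position_error = 100),  # HDOP governs
             toy_fix())                                # neither field
  kept <- quality_filter(f)
  expect_equal(nrow(kept), 4)
  expect_true(all(is.na(kept$hdop) | kept$hdop < 10))
})

test_that("AGL range bounds are inclusive", {
  f <- toy_fix()[rep(1, 4), ]
  f$agl <- c(-50, -50.1, 4000, 4000.1)
  expect_equal(agl_range_filter(f)$agl, c(-50, 4000))
})

test_that("flight filter removes only slow AND low fixes", {
  f <- toy_fix()[rep(1, 4), ]
  f$ground_speed <- c(1, 1, 5, 1.9)
  f$agl <- c(50, 150, 50, 99.9)
  kept <- flight_filter(f)
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$agl == c(150, 50)))
})

test_that("region filter keeps only mask-1 cells", {
  ras <- toy_rasters()
  f <- rbind(toy_fix(x = 10, y = 10),    # masked-out corner cell
             toy_fix(x = 200, y = 200))
  expect_equal(nrow(region_filter(f, ras$mask)), 1)
  allone <- grid_raster(matrix(1, 20, 20), cellsize = 25)
  expect_equal(region_filter(f, allone), f)
  expect_equal(nrow(region_filter(f[0, ], ras$mask)), 0)
})

test_that("post-release filter drops exactly the first 56 days", {
  meta <- data.frame(bird_id = "T1", fledge_date = as.Date("2020-01-01"))
  f <- rbind(toy_fix(utc("2020-02-25 12:00:00")),    # day 55.5: removed
             toy_fix(utc("2020-02-26 00:00:00")),    # exactly +56 d: kept
             toy_fix(utc("2020-06-10 12:00:00")))
  kept <- post_release_filter(f, meta)
  expect_equal(nrow(kept), 2)
  expect_error(post_release_filter(toy_fix(bird_id = "T2"), meta), "T2")
  # adult bird, fledged long ago: nothing removed
  old <- data.frame(bird_id = "T1", fledge_date = as.Date("1999-01-01"))
  expect_equal(nrow(post_release_filter(f, old)), 3)
})

test_that("per-minute subsampling keeps the earliest fix per minute", {
  burst <- do.call(rbind, lapply(0:59, function(s)
    toy_fix(utc("2020-06-10 12:00:00") + s)))
  one_more <- toy_fix(utc("2020-06-10 12:01:00"))
  out <- subsample_per_minute(rbind(burst, one_more))
  expect_equal(nrow(out), 2)
  expect_equal(out$timestamp, c(utc("2020-06-10 12:00:00"),
                                utc("2020-06-10 12:01:00")))
  sparse <- rbind(toy_fix(utc("2020-06-10 12:00:10")),
                  toy_fix(utc("2020-06-10 12:01:30")))
  expect_equal(subsample_per_minute(sparse), sparse)
  same_min <- rbind(toy_fix(utc("2020-06-10 12:00:50")),
                    toy_fix(utc("2020-06-10 12:00:10")))
  expect_equal(subsample_per_minute(same_min)$timestamp,
               utc("2020-06-10 12:00:10"))
})

test_that("minimum-fix rule is inclusive at the threshold", {
  f <- rbind(toy_fix(bird_id = "A")[rep(1, 100), ],
             toy_fix(bird_id = "B")[rep(1, 99), ])
  kept <- min_fix_filter(f)
  expect_setequal(unique(kept$bird_id), "A")
  expect_warning(min_fix_filter(f[1:5, ]), "no bird")
})

test_that("a hand-built toy track survives cleaning exactly as the manual oracle", {
  ras <- toy_rasters()
  meta <- data.frame(bird_id = "T1", fledge_date = as.Date("2020-01-01"))
  fixes <- rbind(
    toy_fix(utc("2020-06-01 12:00:00"), ground_speed = NA),           # 1 completeness
    toy_fix(utc("2020-06-02 12:00:00"), altitude_raw = 1250,
            altitude_datum = "ellipsoid"),                            # 2 kept (agl 200)
    toy_fix(utc("2020-06-03 12:00:00"), hdop = 10),                   # 3 quality
    toy_fix(utc("2020-06-04 12:00:00"), position_error = 30),         # 4 quality
    toy_fix(utc("2020-06-05 12:00:00"), hdop = 3, position_error = 100), # 5 kept
    toy_fix(utc("2020-06-06 12:00:00"), altitude_raw = 949.9),        # 6 agl -50.1
    toy_fix(utc("2020-06-07 12:00:00"), altitude_raw = 950),          # 7 kept (agl -50)
    toy_fix(utc("2020-06-08 00:00:00")),                              # 8 night
    toy_fix(utc("2020-06-09 12:00:00"), altitude_raw = 1050,
            ground_speed = 1),                                        # 9 perched
    toy_fix(utc("2020-06-10 12:00:00"), altitude_raw = 1150,
            ground_speed = 1),                                        # 10 kept (agl 150)
    toy_fix(utc("2020-06-11 12:00:00"), x = 10, y = 10),              # 11 out of region
    toy_fix(utc("2020-02-25 12:00:00")),                              # 12 post-release
    toy_fix(utc("2020-06-12 12:00:50")),                              # 13 same minute,
    toy_fix(utc("2020-06-12 12:00:10"))                               # 14 earliest kept
  )
  # manual rule-by-rule application leaves fixes 2, 5, 7, 10, 14
  res <- clean_tracks(fixes, meta, ras$dem, ras$undulation, ras$mask,
                      equator_latlon, min_fixes = 1)
  expect_equal(nrow(res$fixes), 5)
  expect_equal(sort(res$fixes$timestamp),
               sort(c(utc("2020-06-02 12:00:00"), utc("2020-06-05 12:00:00"),
                      utc("2020-06-07 12:00:00"), utc("2020-06-10 12:00:00"),
                      utc("2020-06-12 12:00:10"))))
  rep <- res$report
  expect_equal(rep$removed[rep$stage == "completeness"], 1)
  expect_equal(rep$removed[rep$stage == "quality"], 2)
  expect_equal(rep$removed[rep$stage == "agl_range"], 1)
  expect_equal(rep$removed[rep$stage == "daylight"], 1)
  expect_equal(rep$removed[rep$stage == "flight"], 1)
  expect_equal(rep$removed[rep$stage == "region"], 1)
  expect_equal(rep$removed[rep$stage == "post_release"], 1)
  expect_equal(rep$removed[rep$stage == "subsample"], 1)
})

test_that("report stages chain and every filter is monotone and idempotent", {
  sw <- small_world()
  res <- clean_tracks(sw$tracks$fixes, sw$tracks$meta, sw$world$dem,
                      sw$world$undulation, sw$world$region_mask,
                      world_latlon(sw$cfg))
  rep <- res$report
  expect_true(all(rep$n_out <= rep$n_in))
  expect_equal(rep$n_in[-1], rep$n_out[-nrow(rep)])
  # idempotence on the cleaned output
  f <- res$fixes
  expect_equal(nrow(quality_filter(f)), nrow(f))
  expect_equal(nrow(agl_range_filter(f)), nrow(f))
  expect_equal(nrow(flight_filter(f)), nrow(f))
  expect_equal(subsample_per_minute(subsample_per_minute(f)),
               subsample_per_minute(f))
})

test_that("per-stage removals equal the injected contamination counts", {
  sw <- small_world()
  cfg <- sw$cfg
  res <- clean_tracks(sw$tracks$fixes, sw$tracks$meta, sw$world$dem,
                      sw$world$undulation, sw$world$region_mask,
                      world_latlon(cfg))
  rep <- res$report
  injected <- table(sw$tracks$fixes$contam)
  expect_equal(rep$removed[rep$stage == "quality"],
               unname(injected["quality"]))
  expect_equal(rep$removed[rep$stage == "daylight"],
               unname(injected["night"]))
  expect_equal(rep$removed[rep$stage == "flight"],
               unname(injected["perched"]))
  expect_equal(rep$removed[rep$stage == "region"],
               unname(injected["out_of_region"]))
  expect_equal(rep$removed[rep$stage == "post_release"],
               unname(injected["post_release"]))
})

test_that("a contamination-free run removes nothing before subsampling", {
  rf <- recovery_fixture()
  rep <- rf$clean$report
  for (st in c("completeness", "quality", "agl_range", "daylight",
               "flight", "region", "post_release"))
    expect_equal(rep$removed[rep$stage == st], 0)
})

test_that("subsampling must run after the removals, not before", {
  # a burst minute whose earliest fix is quality-bad: subsampling first
  # would elect the bad fix and lose the minute entirely
  burst <- rbind(toy_fix(utc("2020-06-10 12:00:00"), hdop = 15),
                 toy_fix(utc("2020-06-10 12:00:10")))
  correct <- subsample_per_minute(quality_filter(burst))
  wrong <- quality_filter(subsample_per_minute(burst))
  expect_equal(nrow(correct), 1)
  expect_equal(nrow(wrong), 0)
})
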