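test_that("configuration validation enforces the stage rules", {
  expect_s3_class(rkseg_config("L", "E", 6, 32, 1, 2), "rkseg_config")
  # alternately-updated backbones need an even node count ...
  expect_error(rkseg_config("L", "I", 5, 32, 1, 2), "odd depth")
  expect_error(rkseg_config("R", "R", 5, 32, 1, 2), "odd depth")
  # ... and at least two stages
  expect_error(rkseg_config("R", "R", 2, 1, 1, 1), "at least two stages")
  expect_error(rkseg_config("L", "I", 2, 8, 1, 2), "at least two stages")
  # non-positive fields are rejected
  expect_error(rkseg_config("L", "E", 0, 32, 1, 2), "positive")
  expect_error(rkseg_config("L", "E", 3, 32, 0, 2), "positive")
  expect_error(rkseg_config("L", "E", 3, -1, 1, 2), "positive")
})

test_that("stage count follows the backbone", {
  expect_equal(n_stages(rkseg_config("L", "E", 6, 8, 1, 2)), 6L)
  expect_equal(n_stages(rkseg_config("L", "I", 6, 8, 1, 2)), 3L)
  expect_equal(n_stages(rkseg_config("R", "R", 4, 8, 1, 2)), 2L)
})

test_that("closed-form counts reproduce the published table values", {
  # frozen expected totals, cross-checked by per-layer enumeration below
  cases <- list(
    list(cfg = rkseg_config("L", "E", 6, 32, 1, 2), total = 278370, mm = 0.28),
    list(cfg = rkseg_config("L", "I", 6, 32, 1, 2), total = 223074, mm = 0.22),
    list(cfg = rkseg_config("L", "E", 5, 32, 4, 4), total = 214596, mm = 0.21),
    list(cfg = rkseg_config("L", "E", 3, 32, 1, 3), total = 111939, mm = 0.11),
    list(cfg = rkseg_config("L", "E", 7, 32, 1, 3), total = 352323, mm = 0.35))
  for (cs in cases) {
    rep <- count_parameters(cs$cfg)
    expect_identical(as.integer(rep$total), as.integer(cs$total))
    expect_equal(rep$total_millions_2dp, cs$mm)
    expect_equal(rep$total, sum(rep$per_component))
    o <- oracle_total_count(cs$cfg$backbone, cs$cfg$depth, cs$cfg$width,
                            cs$cfg$in_channels, cs$cfg$num_classes)
    expect_equal(rep$total, o)
  }
})

test_that("degenerate one-stage explicit network counts 74 scalars", {
  cfg <- rkseg_config("L", "E", 1, 1, 1, 1)
  expect_identical(as.integer(count_parameters(cfg)$total), 74L)
  expect_identical(oracle_total_count("E", 1, 1, 1, 1), 74)
})

test_that("counts are orientation-independent and monotone in every size", {
  for (b in c("E", "I", "R")) {
    d <- if (b == "E") 3L else 4L
    cl <- count_parameters(rkseg_config("L", b, d, 8, 2, 3))$total
    cr <- count_parameters(rkseg_config("R", b, d, 8, 2, 3))$total
    expect_identical(cl, cr)
  }
  base <- count_parameters(rkseg_config("L", "E", 3, 8, 2, 3))$total
  expect_gt(count_parameters(rkseg_config("L", "E", 4, 8, 2, 3))$total, base)
  expect_gt(count_parameters(rkseg_config("L", "E", 3, 9, 2, 3))$total, base)
  expect_gt(count_parameters(rkseg_config("L", "E", 3, 8, 3, 3))$total, base)
  expect_gt(count_parameters(rkseg_config("L", "E", 3, 8, 2, 4))$total, base)
})

test_that("scale schedule halves per stage and reverses with orientation", {
  sl <- scale_schedule(rkseg_config("L", "E", 3, 8, 1, 2))
  expect_equal(sl$node, c("E1", "E2", "E3"))
  expect_equal(sl$scale_divisor, c(2L, 4L, 8L))
  sr <- scale_schedule(rkseg_config("R", "E", 3, 8, 1, 2))
  expect_equal(sr$scale_divisor, c(8L, 4L, 2L))
  si <- scale_schedule(rkseg_config("L", "I", 4, 8, 1, 2))
  expect_equal(si$node, c("X1", "X2", "I1", "I2"))
  expect_equal(si$scale_divisor, c(2L, 4L, 8L, 16L))
})

test_that("rounding of millions is half-up to two decimals", {
  rep <- count_parameters(rkseg_config("L", "E", 6, 32, 1, 2))
  expect_equal(rep$total_millions_2dp, round(rep$total / 1e6 + 1e-9, 2))
})
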