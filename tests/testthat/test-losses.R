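test_that("hard Dice coefficient handles the canonical cases", {
  a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
  expect_equal(dice_coefficient(a, a), 1)
  b <- matrix(0, 4, 4); b[3:4, 3:4] <- 1
  expect_equal(dice_coefficient(a, b), 0)              # disjoint
  cc <- matrix(0, 4, 4); cc[2:3, 1:2] <- 1             # |overlap| = 2
  expect_equal(dice_coefficient(a, cc), 0.5)           # 2*2/(4+4)
  expect_equal(dice_coefficient(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  expect_error(dice_coefficient(a, matrix(0, 3, 3)), "shapes")
})

test_that("Dice is symmetric and permutation-invariant", {
  set.seed(1)
  for (rep in 1:5) {
    a <- matrix(sample(0:1, 64, TRUE), 8, 8)
    b <- matrix(sample(0:1, 64, TRUE), 8, 8)
    expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
    perm <- sample(64)
    expect_equal(dice_coefficient(a, b),
                 dice_coefficient(matrix(a[perm], 8, 8),
                                  matrix(b[perm], 8, 8)))
  }
})

test_that("uniform two-class logits give cross-entropy log(2)", {
  lg <- array(0, c(8, 8, 2))
  lab <- matrix(rep(0:1, 32), 8, 8)
  l <- dice_ce_loss(lg, lab)
  expect_equal(l$ce, log(2), tolerance = 1e-12)
})

test_that("saturated correct logits drive the loss to its epsilon floor", {
  lab <- matrix(c(rep(0L, 40), rep(1L, 24)), 8, 8)
  lg <- array(0, c(8, 8, 2))
  lg[, , 1][lab == 0] <- 50; lg[, , 2][lab == 1] <- 50
  l <- dice_ce_loss(lg, lab)
  expect_lt(l$ce, 1e-8)
  expect_equal(l$dice_term, -1, tolerance = 1e-5)      # negated-Dice convention
  expect_equal(l$loss, -1, tolerance = 1e-5)
})

test_that("loss matches a straight-line recomputation on random logits", {
  set.seed(42)
  lg <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  lab <- matrix(sample(0:2, 64, TRUE), 8, 8)
  l <- dice_ce_loss(lg, lab)
  o <- oracle_dice_ce(lg, lab)
  expect_equal(l$ce, o$ce, tolerance = 1e-12)
  expect_equal(l$loss, o$loss, tolerance = 1e-12)
  expect_error(dice_ce_loss(lg, lab + 5L), "label out of range")
})

test_that("soft Dice on one-hot probabilities equals the hard coefficient", {
  set.seed(7)
  lab <- matrix(sample(0:1, 64, TRUE), 8, 8)
  pred <- matrix(sample(0:1, 64, TRUE), 8, 8)
  lg <- array(0, c(8, 8, 2))
  lg[, , 1][pred == 0] <- 60; lg[, , 2][pred == 1] <- 60
  l <- dice_ce_loss(lg, lab)
  expect_equal(-l$dice_term,
               dice_coefficient(pred == 1, lab == 1), tolerance = 1e-4)
})

test_that("loss gradient matches finite differences on the logits", {
  set.seed(3)
  lg <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  lab <- matrix(sample(0:2, 36, TRUE), 6, 6)
  g <- dice_ce_loss(lg, lab, grad = TRUE)$grad[[1]]
  h <- 1e-6
  for (probe in list(c(1, 1, 1), c(3, 4, 2), c(6, 6, 3), c(2, 5, 1))) {
    lp <- lg; lp[probe[1], probe[2], probe[3]] <- lp[probe[1], probe[2], probe[3]] + h
    lm <- lg; lm[probe[1], probe[2], probe[3]] <- lm[probe[1], probe[2], probe[3]] - h
    fd <- (dice_ce_loss(lp, lab)$loss - dice_ce_loss(lm, lab)$loss) / (2 * h)
    expect_equal(g[probe[1], probe[2], probe[3]], fd, tolerance = 1e-5)
  }
})

test_that("dataset evaluation averages per case then per class", {
  set.seed(4)
  cfg <- rkseg_config("L", "E", 2, 2, 1, 2)
  m <- build_rkseg(cfg)
  ds <- lapply(1:3, function(i) {
    lab <- matrix(0L, 16, 16); lab[4:8, 4:8] <- 1L
    list(image = array(rnorm(16 * 16), c(16, 16, 1)), label = lab,
         case_id = sprintf("c%d", i))
  })
  rep <- evaluate_dataset(m, ds)
  expect_s3_class(rep, "dice_report")
  expect_equal(rep$n_cases, 3)
  expect_true(all(rep$per_case$dice >= 0 & rep$per_case$dice <= 1))
  expect_equal(rep$mean, mean(rep$per_class))
  # hand-checked aggregation on printed 4x4 masks: dice 0.5 and 1.0 -> 0.75
  preds <- list(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2))
  refs <- list(matrix(c(1, 0, 1, 0), 2), matrix(c(1, 0, 1, 0), 2))
  d <- mapply(dice_coefficient, preds, refs)
  expect_equal(mean(d), 0.75)
})

test_that("perfect and all-background predictions hit the Dice extremes", {
  set.seed(5)
  spec <- synth_spec(n_cases = 3, image_size = c(32, 32), noise_sd = 0,
                     contrast = 10, seed = 8)
  ds <- synth_generate(spec)
  # oracle model: predictions equal to references
  fake_perfect <- lapply(ds, function(s) s$label)
  d_perfect <- mapply(function(p, s) dice_coefficient(p == 1, s$label == 1),
                      fake_perfect, ds)
  expect_true(all(d_perfect == 1))
  d_empty <- vapply(ds, function(s)
    dice_coefficient(matrix(FALSE, 32, 32), s$label == 1), numeric(1))
  expect_true(all(d_empty == 0))
})
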