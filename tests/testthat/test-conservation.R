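test_that("interval means respect missing scores and the 0.8 boundary", {
  track <- c(1.0, 0.8, 0.6, rep(NA_real_, 5), 0.2)
  r <- mean_conservation(c(0, 3), track)
  expect_equal(r$mean, 0.8)
  expect_equal(r$n_scored, 3L)
  # boundary inclusive: mean exactly 0.8 is conserved
  v <- conservation_verdicts(
    data.frame(name = "x", mature_start = 0L, mature_end = 3L), track)
  expect_true(v$conserved)
  # all-missing interval: undefined, not conserved
  r2 <- mean_conservation(c(3, 8), track)
  expect_true(is.na(r2$mean))
  v2 <- conservation_verdicts(
    data.frame(name = "y", mature_start = 3L, mature_end = 8L), track)
  expect_false(v2$conserved)
})

test_that("interval means equal direct summation on random tracks", {
  set.seed(71)
  track <- runif(500)
  track[sample(500, 60)] <- NA
  for (i in 1:25) {
    s <- sample(0:(500 - 22), 1)
    v <- track[(s + 1):(s + 22)]
    r <- mean_conservation(c(s, s + 22), track)
    expect_equal(r$mean, sum(v, na.rm = TRUE) / sum(!is.na(v)))
  }
})

test_that("background simulation is composition-matched and calibrated", {
  st <- small_study()
  pr <- st$truth$precursors
  cons <- pr[pr$conserved, ]
  mat <- data.frame(chrom = cons$chrom, mature_start = cons$mature_start,
                    mature_end = cons$mature_end)
  set.seed(72)
  bg <- background_conservation(mat, st$truth$annotations, st$track,
                                st$genome, n_sim = 200)
  # every simulated set places each candidate once
  expect_true(all(rowSums(bg$bin_counts) == nrow(mat)))
  # planted conserved matures far exceed the intron/intergenic background
  expect_equal(bg$p_emp, 1 / 201)
  expect_lt(bg$expected_conserved, bg$observed_conserved)
  expect_equal(bg$observed_conserved, nrow(mat))
})

test_that("a saturated track cannot show conservation excess", {
  st <- small_study()
  pr <- st$truth$precursors
  cons <- pr[pr$conserved, ][1:4, ]
  mat <- data.frame(chrom = cons$chrom, mature_start = cons$mature_start,
                    mature_end = cons$mature_end)
  sat <- setNames(list(rep(0.9, nchar(st$genome[[1]]))),
                  names(st$genome))
  set.seed(73)
  bg <- background_conservation(mat, st$truth$annotations, sat,
                                st$genome, n_sim = 50)
  expect_equal(bg$expected_conserved, nrow(mat))
  expect_gte(bg$p_emp, 1)  # observed can never exceed the saturated null
})
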