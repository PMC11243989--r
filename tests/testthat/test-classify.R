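test_that("mtsps threshold maximizes sensitivity plus specificity", {
  # clean separation: any t in (0.2, 0.8] maximizes; lowest observed
  # maximizer is 0.8
  expect_equal(mtsps_threshold(c(0.8, 0.9), c(0.1, 0.2)), 0.8)
  # identical distributions: sens + spec = 1 everywhere; lowest candidate
  expect_equal(mtsps_threshold(c(0.3, 0.6), c(0.3, 0.6)), 0.3)
  # single replicate equals that replicate's maximizer; averaging works
  t1 <- mtsps_threshold(list(c(0.8, 0.9)), list(c(0.1, 0.2)))
  expect_equal(t1, 0.8)
  t2 <- mtsps_threshold(list(c(0.8, 0.9), c(0.6, 0.7)),
                        list(c(0.1, 0.2), c(0.1, 0.2)))
  expect_equal(t2, round((0.8 + 0.6) / 2, 4))
})

test_that("classification boundaries reproduce the printed arithmetic", {
  g <- suit_grid()
  cm1 <- classify(g, 0.4062)
  expect_equal(cm1$b1, 0.6041)
  expect_equal(cm1$b2, 0.8021)
  cm2 <- classify(g, 0.2683)
  expect_equal(cm2$b1, 0.5122)
  expect_equal(cm2$b2, 0.7561)
  cm3 <- classify(g, 0.6144)
  expect_equal(cm3$b1, 0.7429)
  expect_equal(cm3$b2, 0.8715)
})

test_that("classify partitions every usable cell exactly once", {
  v <- matrix(runif(100), 10, 10); v[c(3, 50, 99)] <- NA
  g <- raster_grid(v)
  cm <- classify(g, 0.37)
  cls <- cm$grid$values
  expect_equal(sum(!is.na(cls)), 97)
  expect_equal(sum(cm$counts$cells), 97)
  expect_true(all(na.omit(as.numeric(cls)) %in% 0:3))
  # boundary membership: lower-closed, top class closed at 1
  gb <- raster_grid(matrix(c(cm$threshold, cm$b1_exact, cm$b2_exact, 1),
                           2, 2))
  cb <- classify(gb, 0.37)
  expect_setequal(as.numeric(cb$grid$values), c(1, 2, 3, 3))
})

test_that("binary maps agree with the class map and the p >= t rule", {
  g <- raster_grid(matrix(c(0.4, 0.5, 0.6, NA), 2, 2))
  b <- binary_map(g, 0.5)
  # {0.4, 0.5, 0.6} at t = 0.5 -> {0, 1, 1} (p >= t is suitable)
  expect_equal(c(b$values[1, 1], b$values[2, 1], b$values[1, 2]),
               c(0, 1, 1))
  expect_true(is.na(b$values[2, 2]))
  v <- matrix(runif(64), 8, 8)
  gg <- raster_grid(v)
  for (t in c(0.2, 0.5, 0.8)) {
    cm <- classify(gg, t)
    bm <- binary_map(gg, t)
    expect_equal(sum(bm$values == 1),
                 sum(cm$counts$cells[cm$counts$code > 0]))
  }
  # all below threshold: all zeros
  low <- raster_grid(matrix(0.1, 3, 3))
  expect_true(all(binary_map(low, 0.9)$values == 0))
  # raising t never increases the suitable count
  ts <- seq(0.05, 0.95, by = 0.05)
  counts <- vapply(ts, function(t) sum(binary_map(gg, t)$values), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("range change reproduces the printed loss/stable/gain arithmetic", {
  mk <- function(cur, fut) {
    n <- length(cur)
    side <- ceiling(sqrt(n))
    pad <- rep(NA_real_, side^2 - n)
    list(cur = raster_grid(matrix(c(cur, pad), side)),
         fut = raster_grid(matrix(c(fut, pad), side)))
  }
  # loss 252, stable 202, gain 0 over a 625-cell grid
  cur <- c(rep(1, 454), rep(0, 171))
  fut <- c(rep(0, 252), rep(1, 202), rep(0, 171))
  g <- mk(cur, fut)
  rc <- range_change(g$cur, g$fut)
  expect_equal(c(rc$loss, rc$stable, rc$gain), c(252, 202, 0))
  expect_equal(rc$pct_loss, 55.51)
  expect_equal(rc$pct_gain, 0)
  expect_equal(rc$src, -55.51)
  expect_equal(rc$crs, 454)
  expect_equal(rc$crs_km2, 315.28)
  # loss 297, stable 16, gain 98 (CRS 313)
  cur2 <- c(rep(1, 313), rep(0, 312))
  fut2 <- c(rep(0, 297), rep(1, 16), rep(1, 98), rep(0, 214))
  g2 <- mk(cur2, fut2)
  rc2 <- range_change(g2$cur, g2$fut)
  expect_equal(rc2$pct_loss, 94.89)
  expect_equal(rc2$pct_gain, 31.31)
  expect_equal(rc2$src, -63.58)
  # identity: no change
  rc3 <- range_change(g$cur, g$cur)
  expect_equal(c(rc3$loss, rc3$gain, rc3$src), c(0, 0, 0))
})

test_that("range change identities hold exactly before rounding", {
  set.seed(71)
  for (i in 1:10) {
    cur <- raster_grid(matrix(rbinom(100, 1, 0.5), 10))
    fut <- raster_grid(matrix(rbinom(100, 1, 0.5), 10))
    rc <- range_change(cur, fut)
    expect_identical(rc$crs, rc$loss + rc$stable)
    expect_equal(rc$src_exact, rc$pct_gain_exact - rc$pct_loss_exact)
    expect_true(all(c(rc$loss, rc$stable, rc$gain) >= 0))
  }
  # misalignment and mask mismatch are refused
  a <- raster_grid(matrix(1, 2, 2)); b <- raster_grid(matrix(1, 3, 3))
  expect_error(range_change(a, b), "not aligned")
  d <- raster_grid(matrix(c(1, NA, 1, 1), 2, 2))
  expect_error(range_change(a, d), "masks differ")
})

test_that("area accounting converts cells to km2 as printed", {
  # 454 cells at 25/36 km2 = 315.28 km2; 454/595 usable = 76.30%
  expect_equal(round_half_up(454 * 25 / 36, 2), 315.28)
  v <- matrix(NA_real_, 25, 25)
  v[seq_len(595)] <- c(rep(0.9, 454), rep(0.1, 141))
  g <- raster_grid(v)
  cm <- classify(g, 0.4062)
  suitable <- sum(cm$counts$cells[cm$counts$code > 0])
  expect_equal(suitable, 454)
  a <- area_summary(list(present = cm))
  expect_equal(sum(a$km2[a$class != "unsuitable"]), 315.28)
  expect_equal(sum(a$pct_of_total[a$class != "unsuitable"]), 76.30)
})

test_that("area summary tracks change vs present and flags empty classes", {
  g1 <- raster_grid(matrix(c(0.1, 0.45, 0.45, 0.95), 2, 2))
  g2 <- raster_grid(matrix(c(0.45, 0.45, 0.45, 0.65), 2, 2))
  c1 <- classify(g1, 0.4); c2 <- classify(g2, 0.4)
  a <- area_summary(list(present = c1, future = c2))
  lowp <- a[a$scenario == "present" & a$class == "low", ]
  lowf <- a[a$scenario == "future" & a$class == "low", ]
  expect_true(is.na(lowp$pct_change_vs_present))
  expect_equal(lowf$pct_change_vs_present, 50)  # 2 -> 3 cells
  # moderate class: absent at present, present in future -> flagged NA
  modf <- a[a$scenario == "future" & a$class == "moderate", ]
  expect_true(is.na(modf$pct_change_vs_present))
  expect_true(modf$undefined_change)
  # unchanged class counts report 0.00
  highf <- a[a$scenario == "future" & a$class == "unsuitable", ]
  expect_true(is.finite(highf$pct_change_vs_present) ||
                is.na(highf$pct_change_vs_present))
})
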