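test_that("calibrate_date gives the Gaussian mass the curve implies", {
  cv <- identity_curve(2000, 0)
  d <- calibrate_date(1000, 10, cv, normalize = TRUE)
  expect_equal(d$cal_bp[which.max(d$mass)], 1000)
  # hand-computed Gaussian ratio one sigma out
  m1000 <- d$mass[d$cal_bp == 1000]
  m1010 <- d$mass[d$cal_bp == 1010]
  expect_equal(m1000 / m1010, exp(0.5), tolerance = 1e-10)
  expect_equal(sum(d$mass), 1, tolerance = 1e-9)
})

test_that("curve error widens the calibrated density", {
  cv0 <- identity_curve(2000, 0, sigma = 0)
  cv20 <- identity_curve(2000, 0, sigma = 20)
  d0 <- calibrate_date(1000, 15, cv0, normalize = TRUE)
  d20 <- calibrate_date(1000, 15, cv20, normalize = TRUE)
  sd_of <- function(d) {
    mu <- sum(d$cal_bp * d$mass)
    sqrt(sum((d$cal_bp - mu)^2 * d$mass))
  }
  expect_equal(sd_of(d0), 15, tolerance = 0.01)
  expect_equal(sd_of(d20), sqrt(15^2 + 20^2), tolerance = 0.01)
})

test_that("a symmetric wiggle maps one age onto two equal calendar peaks", {
  # curve symmetric about cal BP 500 over a window: both branches cross the
  # same 14C age, so the calibrated density must be bimodal with equal peaks
  grid <- seq(1000, 0, by = -1)
  c14 <- 500 + 200 * cos(2 * pi * (grid - 500) / 400)
  cv <- cal_curve(grid, c14, rep(0, length(grid)))
  d <- calibrate_date(500, 8, cv, normalize = TRUE)
  peaks <- d$cal_bp[d$mass > 0.95 * max(d$mass)]
  expect_true(any(peaks > 500) && any(peaks < 500))
  m_old <- max(d$mass[d$cal_bp > 500])
  m_young <- max(d$mass[d$cal_bp < 500])
  expect_equal(m_old, m_young, tolerance = 1e-6)
})

test_that("calibrate_date rejects dates off the curve span", {
  cv <- identity_curve(2000, 1000)
  expect_error(calibrate_date(NA, 10, cv))
  expect_error(calibrate_date(1000, -1, cv), "positive")
})

test_that("hpd_interval returns minimal contiguous interval sets", {
  cv <- identity_curve(2000, 0)
  d <- calibrate_date(1000, 10, cv, normalize = TRUE)
  h <- hpd_interval(d, 0.954)
  expect_equal(nrow(h), 1L)
  # symmetric about the mode, covering about +/- 2 sigma
  expect_equal(h$start - 1000, 1000 - h$end, tolerance = 0.11)
  expect_true(h$mass >= 0.954)
  expect_true(abs(h$start - 1020) <= 1)

  # near-point mass: single year holds everything
  pt <- structure(list(cal_bp = c(1002, 1001, 1000),
                       mass = c(0, 1, 0), normalized = TRUE),
                  class = "cal_density")
  hp <- hpd_interval(pt, 0.954)
  expect_equal(c(hp$start, hp$end), c(1001, 1001))

  expect_error(hpd_interval(calibrate_date(1000, 10, cv)), "normalized")
})

test_that("bimodal densities give two disjoint HPD intervals that agree with a greedy oracle", {
  grid <- seq(1000, 0, by = -1)
  mass <- dnorm(grid, 700, 15) + dnorm(grid, 300, 15)
  mass <- mass / sum(mass)
  d <- structure(list(cal_bp = grid, mass = mass, normalized = TRUE),
                 class = "cal_density")
  h <- hpd_interval(d, 0.90)
  expect_equal(nrow(h), 2L)
  expect_true(h$end[1] > h$start[2])  # disjoint, oldest first
  # oracle: smallest year set by greedy mass ranking
  ord <- order(mass, decreasing = TRUE)
  k <- which(cumsum(mass[ord]) >= 0.90)[1]
  got <- sort(unname(unlist(apply(h, 1, function(r) r[["end"]]:r[["start"]]))))
  expect_equal(got, sort(grid[ord[seq_len(k)]]))
})

test_that("bin_dates pools within sites by complete linkage at h = 50", {
  dd <- toy_dates(c(1000, 1020, 1200))
  bb <- bin_dates(dd)
  expect_equal(bb$bin_id[1], bb$bin_id[2])
  expect_false(bb$bin_id[1] == bb$bin_id[3])

  # complete linkage: 1000/1040/1080 pairwise gaps 40,40 but range 80 > 50,
  # so the chain must be cut (single linkage would keep one bin)
  d2 <- toy_dates(c(1000, 1040, 1080))
  expect_equal(length(unique(bin_dates(d2)$bin_id)), 2L)

  expect_equal(nrow(unique(bin_dates(toy_dates(1500))["bin_id"])), 1L)

  # identical ages at different sites never pool
  d3 <- toy_dates(c(1000, 1000), site = c("A", "B"))
  expect_equal(length(unique(bin_dates(d3)$bin_id)), 2L)
})

test_that("binning is invariant to input order", {
  set.seed(31)
  cra <- sample(seq(900, 1900, by = 17))
  dd <- toy_dates(cra, site = rep(c("A", "B", "C"), length.out = length(cra)))
  b1 <- bin_dates(dd)
  perm <- sample(nrow(dd))
  b2 <- bin_dates(dd[perm, ])
  b2 <- b2[match(b1$lab_id, b2$lab_id), ]
  # same partition (bin labels may differ)
  f1 <- as.integer(factor(b1$bin_id, levels = unique(b1$bin_id)))
  f2 <- as.integer(factor(b2$bin_id, levels = unique(b2$bin_id)))
  expect_equal(f1, f2)
})

test_that("build_spd averages within bins and sums across bins", {
  cv <- identity_curve(3000, 0)
  d1 <- calibrate_date(1500, 20, cv, normalize = TRUE)
  # two identical dates, one bin: SPD equals a single density
  dd <- toy_dates(c(1500, 1500))
  spd1 <- build_spd(list(d1, d1), bin_dates(dd), c(2500, 500))
  spd_single <- build_spd(list(d1), NULL, c(2500, 500))
  expect_equal(spd1$spd, spd_single$spd)
  expect_equal(spd1$n_bins, 1L)

  # same two dates in different bins: SPD doubles
  dd2 <- toy_dates(c(1500, 1500), site = c("A", "B"))
  spd2 <- build_spd(list(d1, d1), bin_dates(dd2), c(2500, 500))
  expect_equal(spd2$spd, 2 * spd_single$spd)

  expect_error(build_spd(list(), NULL, c(2500, 500)), "no densities")
})

test_that("normalized SPD mass equals the number of bins", {
  cv <- identity_curve(5000, 0)
  cras <- c(1200, 1210, 2400, 3100, 3105, 3500)
  dd <- toy_dates(cras, site = c("A", "A", "B", "C", "C", "D"))
  dens <- lapply(cras, function(m) calibrate_date(m, 25, cv,
                                                  normalize = TRUE))
  bb <- bin_dates(dd)
  spd <- build_spd(dens, bb, c(4500, 500))
  expect_equal(spd$n_bins, 4L)
  expect_equal(sum(spd$spd), 4, tolerance = 1e-6)
})

test_that("sample_uncal back-calibrates with the stated noise model", {
  cv <- identity_curve(5000, 0)
  expect_equal(sample_uncal(2500, cv, lab_error = 0, seed = 1), 2500)
  expect_identical(sample_uncal(2500, cv, 25, seed = 9),
                   sample_uncal(2500, cv, 25, seed = 9))
  draws <- sample_uncal(rep(2500, 10000), cv, 10, seed = 4)
  expect_equal(sd(draws), 10, tolerance = 0.05 * 10)
  expect_equal(mean(draws), 2500, tolerance = 0.5)
  expect_error(sample_uncal(9000, cv, 10), "span")
})

test_that("calibrating a noiseless back-calibrated date recovers its year", {
  cv <- identity_curve(4000, 0)
  for (t in c(500, 1776, 3210)) {
    cra <- sample_uncal(t, cv, lab_error = 0, seed = 1)
    d <- calibrate_date(cra, 10, cv, normalize = TRUE)
    expect_equal(d$cal_bp[which.max(d$mass)], t)
  }
})

test_that("read_dates maps alternate column headers and validates", {
  df <- data.frame(LabID = "X1", SiteID = "S", C14Age = 1000, C14SD = 30)
  dd <- read_dates(df, col_map = c(lab_id = "LabID", site_id = "SiteID",
                                   cra = "C14Age", error = "C14SD"))
  expect_equal(dd$cra, 1000)
  expect_error(read_dates(data.frame(lab_id = 1, site_id = 1, cra = 1)),
               "error")
  expect_error(read_dates(data.frame(lab_id = 1, site_id = 1, cra = 1,
                                     error = 0)), "positive")
})
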