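test_that("powder averaging is exact on constant volumes and scale-invariant per Delta", {
  p <- clinical_protocol()
  vols <- volume_table(p)
  arr <- array(1, c(2, 2, 1, nrow(vols)))
  pa <- powder_average(arr, vols[c("b", "Delta", "delta")])
  expect_true(all(pa$curves == 1))
  # doubling one Delta's volumes leaves its normalized curve unchanged
  arr2 <- arr
  arr2[, , , vols$Delta == 45] <- 2 * arr2[, , , vols$Delta == 45]
  pa2 <- powder_average(arr2, vols[c("b", "Delta", "delta")])
  expect_equal(pa2$curves, pa$curves)
  # b = 0 entries are exactly 1 after normalization
  expect_true(all(pa2$curves[, p$is_b0] == 1))
})

test_that("powder averaging validates its inputs", {
  p <- clinical_protocol()
  vols <- volume_table(p)[c("b", "Delta", "delta")]
  arr <- array(1, c(2, 1, 1, nrow(vols)))
  expect_error(powder_average(arr[, , , -1, drop = FALSE], vols), "do not match")
  no_b0 <- vols[vols$b > 0, ]
  expect_error(powder_average(arr[, , , vols$b > 0, drop = FALSE], no_b0),
               "no b = 0")
})

test_that("powder-average then fit is the identity on noiseless synthetic volumes", {
  p <- clinical_protocol()
  truth <- c(25, 3.1, 0.9, 0.45)
  gt <- ground_truth_table(data.frame(t_ex = truth[1], D_i = truth[2],
                                      D_e = truth[3], f = truth[4]))
  ds <- generate_dataset(gt, p, "nexi", sigma = 0, seed = 1, as_volume = TRUE)
  pa <- powder_average(ds$volume, ds$vols)
  fit <- fit_curve(pa$curves[1, ], 0, "nexi", protocol = pa$protocol)
  expect_equal(unname(fit$params), truth, tolerance = 0.01)
})

test_that("the slope test flags decreasing signal and respects degenerate input", {
  Deltas <- c(28.3, 36, 45, 55, 65)
  exact <- 1 - 0.002 * Deltas
  st <- slope_test(exact, Deltas)
  expect_equal(st$slope, -0.002, tolerance = 1e-12)
  expect_lt(st$p_value, 1e-12)
  flat <- slope_test(rep(0.5, 5), Deltas)
  expect_equal(flat$slope, 0)
  expect_error(slope_test(c(1, 0.9), c(28.3, 36)), "at least 3")
})

test_that("forward curves at b = 2 show the negative exchange-signature slope", {
  Deltas <- c(28.3, 36, 45, 55, 65)
  p2 <- acq_protocol(rep(2, 5), Deltas, 16.5, 20)
  st <- slope_test(nexi_signal(mid_params, p2), Deltas)
  expect_lt(st$slope, 0)
  expect_lt(st$p_value / 2, 0.05)
})

test_that("slope-test p-values are uniform under the null", {
  set.seed(99)
  Deltas <- c(28.3, 36, 45, 55, 65)
  pvals <- replicate(1000, slope_test(0.5 + rnorm(5, 0, 0.01), Deltas)$p_value)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("mode and HDI recover the normal-distribution benchmarks", {
  set.seed(123)
  x <- rnorm(20000)
  mh <- mode_hdi(x, 0.95)
  expect_lt(abs(mh$mode), 0.12)
  expect_equal(mh$interval, c(-1.96, 1.96), tolerance = 0.08)
  # the interval contains the mode and about the requested sample mass
  expect_true(mh$interval[1] <= mh$mode && mh$mode <= mh$interval[2])
  frac <- mean(x >= mh$interval[1] & x <= mh$interval[2])
  expect_lt(abs(frac - 0.95), 0.03)
})

test_that("mode_hdi handles degenerate and skewed samples", {
  expect_equal(mode_hdi(rep(3.2, 50)), list(mode = 3.2, interval = c(3.2, 3.2)))
  set.seed(4)
  skew <- rexp(5000)
  mh <- mode_hdi(skew, 0.9)
  expect_lt(mh$mode, mean(skew))
  expect_error(mode_hdi(c(1, 2, 3), 0.95), "at least 10")
})

sim_cohort <- function(n_subj = 8, n_roi = 30, sd_subj = 1, sd_sess = 0.1,
                       seed = 1) {
  set.seed(seed)
  roi_base <- rnorm(n_roi, 10, 2)
  subj_off <- rnorm(n_subj, 0, sd_subj)
  do.call(rbind, lapply(seq_len(n_subj), function(s) {
    do.call(rbind, lapply(1:2, function(sess) {
      data.frame(roi = paste0("roi", seq_len(n_roi)), subject = paste0("s", s),
                 session = sess,
                 value = roi_base + subj_off[s] + rnorm(n_roi, 0, sd_sess))
    }))
  }))
}

test_that("duplicated sessions give zero intra-subject differences", {
  tab <- sim_cohort(sd_sess = 0)
  r <- repeatability(tab)
  expect_true(all(r$intra$diff == 0))
  expect_equal(r$intra_cor, 1)
})

test_that("independent tables give near-zero inter-subject correlation", {
  set.seed(2)
  n_subj <- 10; n_roi <- 40
  tab <- do.call(rbind, lapply(seq_len(n_subj), function(s)
    do.call(rbind, lapply(1:2, function(sess)
      data.frame(roi = paste0("roi", seq_len(n_roi)), subject = paste0("s", s),
                 session = sess, value = rnorm(n_roi))))))
  r <- repeatability(tab)
  expect_lt(abs(r$inter_cor), 0.1)
})

test_that("subject-level structure makes intra correlation exceed inter", {
  tab <- sim_cohort(sd_subj = 1.5, sd_sess = 0.2, seed = 5)
  r <- repeatability(tab)
  expect_gt(r$intra_cor, r$inter_cor)
  # comparing a second, noisier method yields a paired Wilcoxon p-value
  tab_b <- sim_cohort(sd_subj = 1.5, sd_sess = 0.8, seed = 6)
  rb <- repeatability(tab, tab_b)
  expect_true(is.numeric(rb$wilcoxon_intra_p))
  expect_lt(rb$wilcoxon_intra_p, 0.05) # method b is noisier between sessions
})

test_that("repeatability validates the session structure", {
  tab <- sim_cohort()
  expect_error(repeatability(tab[tab$session == 1, ]), "two sessions")
  drop_one <- tab[!(tab$subject == "s1" & tab$session == 2), ]
  expect_error(repeatability(drop_one), "both sessions")
})

test_that("ROI map correlation reproduces exact linear relations", {
  a <- data.frame(roi = paste0("r", 1:20), value = rnorm(20))
  b <- data.frame(roi = a$roi, value = 2 * a$value + 1)
  expect_equal(correlate_roi_maps(a, b)$r, 1, tolerance = 1e-12)
  b2 <- data.frame(roi = a$roi, value = -a$value)
  expect_equal(correlate_roi_maps(a, b2)$r, -1, tolerance = 1e-12)
  set.seed(3)
  b3 <- data.frame(roi = a$roi, value = sample(a$value))
  expect_lt(abs(correlate_roi_maps(a, b3)$r), 0.6)
  expect_error(correlate_roi_maps(a[1:2, ], b[1:2, ]), "at least 3")
})

test_that("subject-wise tables are averaged before ROI correlation", {
  a <- rbind(data.frame(roi = c("r1", "r2", "r3"), subject = "s1", value = c(1, 2, 3)),
             data.frame(roi = c("r1", "r2", "r3"), subject = "s2", value = c(3, 4, 5)))
  b <- data.frame(roi = c("r1", "r2", "r3"), value = c(2, 3, 4))
  cr <- correlate_roi_maps(a, b)
  expect_equal(cr$data$value_a, c(2, 3, 4))
  expect_equal(cr$r, 1, tolerance = 1e-12)
})

test_that("roi_means aggregates labelled voxels", {
  map <- array(c(1, 2, 3, 4, NA, 6), c(3, 2, 1))
  labels <- array(c(1, 1, 2, 2, 2, 0), c(3, 2, 1))
  tab <- roi_means(map, labels)
  expect_equal(tab$value, c(1.5, 3.5))
  expect_equal(tab$n_voxels, c(2, 2))
  lut <- data.frame(id = c(1, 2), name = c("precentral", "insula"))
  tab2 <- roi_means(map, labels, lut = lut)
  expect_equal(tab2$roi, c("precentral", "insula"))
})
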