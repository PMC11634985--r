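# ROI connectivity engine: bandpass, Fisher-z correlation, paired edge
# contrasts with BH FDR, behavior association, synthetic generation.

make_ts <- function(values, tr = 2, subject = "s1", phase = "PRE") {
  roi_timeseries(values, tr = tr, subject = subject, phase = phase)
}

test_that("bandpass keeps in-band sinusoids and kills out-of-band ones", {
  tr <- 2; n <- 300
  t_axis <- (0:(n - 1)) * tr
  inband <- sin(2 * pi * 0.05 * t_axis)
  outband <- sin(2 * pi * 0.2 * t_axis)
  x <- cbind(inband, outband)
  ts <- make_ts(x, tr = tr)
  f <- bandpass(ts, 0.01, 0.09)
  expect_gt(cor(f$values[, 1], inband), 0.99)
  expect_lt(sum(f$values[, 2]^2), 0.01 * sum(outband^2))
  # mean removal when f_lo > 0
  ts_dc <- make_ts(x + 5, tr = tr)
  expect_lt(max(abs(colMeans(bandpass(ts_dc, 0.01, 0.09)$values))), 1e-10)

  # all-pass band is the identity up to numerical tolerance
  set.seed(1)
  noise <- matrix(rnorm(200), 100, 2)
  tsn <- make_ts(noise, tr = 2)
  expect_equal(bandpass(tsn, 0, 1 / (2 * 2))$values, noise,
               tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(bandpass(ts, 0.05, 0.3), class = "hwnav_domain_error")
  expect_error(bandpass(ts, 0.09, 0.01), class = "hwnav_domain_error")
})

test_that("connectivity applies the Fisher z transform with capping", {
  set.seed(2)
  base <- rnorm(100)
  x <- cbind(base, base, rnorm(100))
  cm <- connectivity(make_ts(x))
  expect_true(is.na(cm$z[1, 1]))
  expect_equal(cm$z, t(cm$z))
  expect_gt(cm$z[1, 2], 13)  # atanh(1 - 1e-12) ~ 14.2, capped but finite
  expect_true(is.finite(cm$z[1, 2]))

  # constructed pair with sample correlation exactly 0.5 -> z = atanh(0.5)
  n <- 60
  u <- scale(rnorm(n))[, 1]
  v <- scale(residuals(lm(rnorm(n) ~ u)))[, 1]
  y <- 0.5 * u + sqrt(1 - 0.25) * v
  expect_equal(cor(u, y), 0.5, tolerance = 1e-12)
  cm2 <- connectivity(make_ts(cbind(u, y)))
  expect_equal(cm2$z[1, 2], atanh(0.5), tolerance = 1e-10)
  expect_equal(cm2$z[1, 2], 0.5493, tolerance = 1e-4)

  # constant region flags its edges as undefined
  cm3 <- connectivity(make_ts(cbind(rnorm(50), rep(1, 50), rnorm(50))))
  expect_true(all(is.na(cm3$z[2, c(1, 3)])))
  expect_true(cm3$undefined_edges[1, 2])
  expect_false(cm3$undefined_edges[1, 3])
})

test_that("white-noise connectivity is centered at zero", {
  zs <- vapply(1:1000, function(s) {
    set.seed(s)
    connectivity(make_ts(matrix(rnorm(1000), 500, 2)))$z[1, 2]
  }, numeric(1))
  # mean z ~ 0 with sd ~ 1/sqrt((T-3) n_rep)
  expect_lt(abs(mean(zs)), 4 / sqrt(497 * 1000))
  expect_lt(max(abs(zs)), 0.25)
})

test_that("the edge contrast respects pairing and the BH step-up rule", {
  ds <- synth_roi_dataset(n_subjects = 6, n_rois = 5, T = 120, seed = 4)
  pre <- lapply(ds$pre, connectivity)
  post <- lapply(ds$pre, connectivity)  # identical phases: exact null
  res <- paired_edge_contrast(pre, post, q = 0.05)
  expect_equal(sum(res$edges$significant), 0)
  expect_equal(nrow(res$edges), choose(5, 2))

  bad <- post
  bad[[1]]$subject <- "someone_else"
  expect_error(paired_edge_contrast(pre, bad),
               class = "hwnav_pairing_error")
  expect_error(paired_edge_contrast(pre[1:2], post[1:2]),
               class = "hwnav_pairing_error")
})

test_that("BH agrees with the brute-force step-up definition", {
  # the two textbook boundary examples
  expect_equal(bh_bruteforce(c(0.01, 0.02, 0.03, 0.04), 0.05),
               rep(TRUE, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH") <= 0.05,
               rep(TRUE, 4))
  expect_equal(bh_bruteforce(c(0.04, 0.5, 0.9), 0.05), rep(FALSE, 3))
  expect_equal(p.adjust(c(0.04, 0.5, 0.9), "BH") <= 0.05, rep(FALSE, 3))

  set.seed(6)
  for (i in 1:500) {
    n <- sample(1:100, 1)
    p <- runif(n)^sample(c(1, 2, 4), 1)
    q <- runif(1, 0.01, 0.2)
    expect_identical(p.adjust(p, "BH") <= q, bh_bruteforce(p, q))
  }
})

test_that("planted connectivity increases are recovered and ordered", {
  planted <- cbind(c(1, 2, 3), c(4, 5, 6))
  ds <- synth_roi_dataset(n_subjects = 12, n_rois = 8, T = 250,
                          planted_edges = planted, delta_r = 0.3, seed = 8)
  res <- paired_edge_contrast(lapply(ds$pre, connectivity),
                              lapply(ds$post, connectivity), q = 0.05)
  hits <- res$mask[planted]
  expect_gte(mean(hits), 2 / 3)
  planted_dirs <- res$edges$direction[
    paste(res$edges$roi_i, res$edges$roi_j) %in%
      paste(planted[, 1], planted[, 2])]
  expect_true(all(planted_dirs == "increase"))

  # sensitivity grows with effect size (small grid)
  sens <- sapply(c(0.1, 0.35), function(dr) {
    d <- synth_roi_dataset(n_subjects = 12, n_rois = 8, T = 250,
                           planted_edges = planted, delta_r = dr, seed = 9)
    r <- paired_edge_contrast(lapply(d$pre, connectivity),
                              lapply(d$post, connectivity), q = 0.05)
    mean(r$mask[planted])
  })
  expect_lte(sens[1], sens[2])
})

test_that("the synthetic generator is deterministic and guards definiteness", {
  d1 <- synth_roi_dataset(n_subjects = 3, n_rois = 4, T = 60, seed = 5)
  d2 <- synth_roi_dataset(n_subjects = 3, n_rois = 4, T = 60, seed = 5)
  expect_identical(d1$pre[[2]]$values, d2$pre[[2]]$values)
  expect_identical(d1$post[[3]]$values, d2$post[[3]]$values)

  bad_cov <- matrix(0.99, 4, 4); diag(bad_cov) <- c(1, 1, 1, -1)
  expect_error(
    synth_roi_dataset(n_subjects = 3, n_rois = 4, T = 60,
                      baseline_cov = bad_cov, seed = 1),
    class = "hwnav_generation_error")
  planted <- cbind(1, 2)
  expect_error(
    synth_roi_dataset(n_subjects = 3, n_rois = 4, T = 60,
                      planted_edges = planted, delta_r = 2, seed = 1),
    class = "hwnav_generation_error")
})

test_that("behavior association delegates to the Spearman correlation", {
  expect_equal(behavior_association(1:8, (1:8)^2)$rho, 1)
  expect_equal(behavior_association(1:8, -(1:8)^2)$rho, -1)
  set.seed(10)
  edge <- rnorm(17); beh <- 0.6 * edge + rnorm(17, 0, 0.8)
  ours <- behavior_association(edge, beh)
  ref <- suppressWarnings(cor.test(edge, beh, method = "spearman",
                                   exact = FALSE))
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
})

test_that("manifest-driven matrix I/O round-trips", {
  dir <- tempfile(); dir.create(dir)
  ds <- synth_roi_dataset(n_subjects = 2, n_rois = 3, T = 40, seed = 2)
  rows <- list()
  for (ph in c("pre", "post")) for (i in 1:2) {
    ts <- ds[[ph]][[i]]
    fn <- sprintf("%s_%s.tsv", ts$subject, ph)
    write.table(ts$values, file.path(dir, fn), row.names = FALSE,
                col.names = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      subject = ts$subject, phase = toupper(ph), path = fn, tr = ts$tr)
  }
  man <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), man, row.names = FALSE)
  back <- read_roi_manifest(man)
  expect_length(back$pre, 2)
  expect_equal(back$pre[[1]]$values, ds$pre[[1]]$values,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$post[[2]]$phase, "POST")
  unlink(dir, recursive = TRUE)
})
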