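test_that("fit_gaussian uses sample moments with n-1 denominator", {
  g <- fit_gaussian(c(5, 5, 5))
  expect_equal(g$mean, 5)
  expect_equal(g$sd, 0)

  g <- fit_gaussian(c(0, 2))
  expect_equal(g$mean, 1)
  expect_equal(g$sd, sqrt(2))

  expect_equal(fit_gaussian(7)$sd, 0)
  expect_error(fit_gaussian(numeric()), "finite")

  set.seed(42)
  x <- rnorm(1e5, 10, 2)
  g <- fit_gaussian(x)
  se_mean <- 2 / sqrt(1e5)
  se_sd <- 2 / sqrt(2 * (1e5 - 1))
  expect_lt(abs(g$mean - 10), 3 * se_mean)
  expect_lt(abs(g$sd - 2), 3 * se_sd)
})

test_that("CGI crossing: equal widths give the exact midpoint", {
  # build a work set whose fitted Gaussians are exactly N(12,3) and N(8,3):
  # three points with mean m and sd s are m + s*c(-1,0,1)/sqrt(...) -- easier
  # to check the intersection kernel plus a moment-matched set
  expect_equal(sorbfe:::gaussian_intersection(12, 3, 8, 3)$value, 10)
  expect_equal(sorbfe:::gaussian_intersection(-4, 0.5, 2, 0.5)$value, -1)
  # equal-variance midpoint to machine precision, via the full estimator
  wf <- c(11, 12, 13)            # mean 12, sd 1
  wr <- -c(7, 8, 9)              # negated-reverse mean 8, sd 1
  ws <- work_set(c(wf, wr), rep(c("forward", "reverse"), each = 3))
  expect_identical(cgi_free_energy(ws)$value, 10)
})

test_that("CGI crossing with unequal widths matches a dense density scan", {
  root <- sorbfe:::gaussian_intersection(12, 2, 8, 4)$value
  oracle <- scan_gaussian_crossing(12, 2, 8, 4)
  expect_gt(root, 8); expect_lt(root, 12)
  expect_equal(root, oracle, tolerance = 1e-5)
})

test_that("CGI recovers the planted free energy on Crooks-consistent works", {
  ws <- crooks_gaussian_workset(-9.9, sigma = 5, temperature = 300,
                                n_per_direction = 75, seed = 101)
  est <- bootstrap_estimate(ws, "cgi", n_boot = 1000, seed = 102)
  expect_lt(abs(est$value - (-9.9)), 3 * est$uncertainty)
})

test_that("CGI validates input and flags poor overlap", {
  ws_f <- work_set(c(1, 2, 3), "forward")
  expect_error(cgi_free_energy(ws_f), "both forward and reverse")
  # forward mean ~ +100, negated-reverse mean ~ -100: means far apart
  # relative to the widths -> poor-overlap diagnostic
  ws <- work_set(c(100, 100.1, 100.2, 100, 100.1, 100.2),
                 rep(c("forward", "reverse"), each = 3))
  expect_true("poor_overlap" %in% cgi_free_energy(ws)$flags)
})

test_that("Jarzynski estimator: identities and Gaussian closed form", {
  expect_equal(jarzynski_free_energy(7, "forward", 300)$value, 7)
  expect_equal(jarzynski_free_energy(rep(0, 4), "forward", 250)$value, 0)
  expect_error(jarzynski_free_energy(numeric(), "forward"), "finite")

  # Gaussian work: value -> mu - sigma^2/(2RT)
  set.seed(7)
  sigma <- 2; dG <- 4
  w <- rnorm(1e5, dG + sigma^2 / (2 * RT300), sigma)
  est <- jarzynski_free_energy(w, "forward", 300)
  expect_equal(est$value, dG, tolerance = 0.05)

  # no overflow for huge works (shifted log-sum-exp)
  expect_equal(jarzynski_free_energy(c(5000, 5000), "forward", 300)$value, 5000)
})

test_that("Jensen bounds hold on every synthetic work set", {
  for (s in 1:5) {
    ws <- crooks_gaussian_workset(runif(1, -20, 20), runif(1, 0.5, 8),
                                  300, 50, seed = 200 + s)
    wf <- ws$work[ws$direction == "forward"]
    wr <- ws$work[ws$direction == "reverse"]
    expect_lte(jarzynski_free_energy(wf, "forward", 300)$value, mean(wf))
    expect_gte(jarzynski_free_energy(wr, "reverse", 300)$value, -mean(wr))
  }
})

test_that("all estimators converge to the planted value at large n", {
  dG <- 3.7; sigma <- 2
  ws <- crooks_gaussian_workset(dG, sigma, 300, 1e4, seed = 31)
  tol <- 3 * sigma / sqrt(1e4)          # sampling scale of the mean
  expect_lt(abs(cgi_free_energy(ws)$value - dG), tol)
  wf <- ws$work[ws$direction == "forward"]
  wr <- ws$work[ws$direction == "reverse"]
  # the exponential average converges more slowly at sigma/RT ~ 0.8; allow a
  # wider but still tight band
  jtol <- 0.5
  expect_lt(abs(jarzynski_free_energy(wf, "forward", 300)$value - dG), jtol)
  expect_lt(abs(jarzynski_free_energy(wr, "reverse", 300)$value - dG), jtol)
})

test_that("bootstrap is reproducible, degenerate-safe, and defaults to 1000", {
  expect_identical(formals(bootstrap_estimate)$n_boot, 1000)

  ws <- work_set(c(rep(5, 4), rep(-5, 4)),
                 rep(c("forward", "reverse"), each = 4))
  est <- bootstrap_estimate(ws, "cgi", n_boot = 50, seed = 1)
  expect_equal(est$uncertainty, 0)
  expect_equal(est$value, 5)

  ws2 <- crooks_gaussian_workset(2, 3, 300, 40, seed = 5)
  a <- bootstrap_estimate(ws2, "cgi", n_boot = 200, seed = 99)
  b <- bootstrap_estimate(ws2, "cgi", n_boot = 200, seed = 99)
  expect_identical(a, b)
})

test_that("bootstrap sd tracks the sd over independent regenerations", {
  n_regen <- 200
  vals <- vapply(seq_len(n_regen), function(s) {
    ws <- crooks_gaussian_workset(0, 2, 300, 200, seed = 1000 + s)
    jarzynski_free_energy(ws$work[ws$direction == "forward"], "forward",
                          300)$value
  }, numeric(1))
  sd_regen <- sd(vals)
  ws <- crooks_gaussian_workset(0, 2, 300, 200, seed = 1500)
  est <- bootstrap_estimate(ws, "jarzynski_forward", n_boot = 500, seed = 2)
  ratio <- est$uncertainty / sd_regen
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})

test_that("convergence profile nests correctly and tightens with data", {
  ws <- crooks_gaussian_workset(-5, 4, 300, 100, seed = 61)
  prof <- convergence_profile(ws, c(0.2, 0.5, 1.0), estimator = "cgi",
                              n_boot = 300, seed = 62)
  full <- bootstrap_estimate(ws, "cgi", n_boot = 300, seed = 62)
  expect_equal(prof$value[3], full$value)
  expect_equal(prof$uncertainty[3], full$uncertainty)
  expect_gte(prof$uncertainty[1], prof$uncertainty[3])
  expect_error(convergence_profile(ws, 0.01, n_boot = 10, seed = 1),
               "fewer than 2")
  expect_error(convergence_profile(ws, c(0, 0.5)), "fractions")
})

test_that("CGI profile is flatter than one-directional Jarzynski on wide works", {
  # sigma/RT = 3: strongly dissipative regime where the exponential average
  # is dominated by rare low-work tails
  ws <- crooks_gaussian_workset(0, 3 * RT300, 300, 150, seed = 71)
  fr <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  p_cgi <- convergence_profile(ws, fr, "cgi", n_boot = 200, seed = 72)
  p_jar <- convergence_profile(ws, fr, "jarzynski_forward", n_boot = 200,
                               seed = 72)
  expect_lt(var(p_cgi$value), var(p_jar$value))
})
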