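test_that("covariate sampling honors the requested proportions", {
  pr <- default_covariate_proportions()
  r <- sample_covariates(1e5, pr, seed = 4L)
  expect_lt(abs(mean(r$residence) - 0.707), 0.01)
  expect_lt(abs(mean(r$private_insurance) - 0.467), 0.01)
  expect_lt(abs(mean(r$catastrophic) - 0.1699), 0.01)
  expect_lt(max(abs(prop.table(table(r$age_band)) - pr$age_bands)), 0.01)
  # degenerate probabilities
  pr0 <- pr; pr0$gender <- 0
  expect_true(all(sample_covariates(50, pr0, seed = 1)$gender == 0))
  pr1 <- pr; pr1$gender <- 1
  expect_true(all(sample_covariates(50, pr1, seed = 1)$gender == 1))
  prx <- pr; prx$income <- 1.4
  expect_error(sample_covariates(10, prx, seed = 1), "income")
})

test_that("latent recursion reproduces the implied moments", {
  p <- default_true_params()
  p$gamma[] <- 0; p$lambda[] <- 0
  r <- sample_covariates(1e5, seed = 2L)
  # pure disturbances: iid standard normal
  lat <- simulate_latents(r, p, seed = 3L)
  for (v in c("HR", "AW", "VAL")) {
    expect_lt(abs(mean(lat[[v]])), 0.02)
    expect_lt(abs(var(lat[[v]]) - 1), 0.03)
  }
  # single AW -> VAL path: cov(AW, VAL) = lambda
  p2 <- p; p2$lambda["aw_val"] <- 0.528
  lat2 <- simulate_latents(r, p2, seed = 3L)
  expect_lt(abs(cov(lat2$AW, lat2$VAL) - 0.528), 0.03)
  # variance algebra: var(AW) = lambda^2 var(HR) + 1
  p3 <- p; p3$lambda["hr_aw"] <- 0.5
  lat3 <- simulate_latents(r, p3, seed = 3L)
  expect_lt(abs(var(lat3$AW) - (0.25 * var(lat3$HR) + 1)), 0.04)
})

test_that("ordered-logit measurement has the closed-form category
           probabilities", {
  # zeta = 1, LV = 0, thresholds (-2,-1,1,2): P(3) = plogis(1) - plogis(-1)
  pr <- ordered_logit_probs(0, c(-2, -1, 1, 2))
  expect_equal(pr[1, 3], plogis(1) - plogis(-1), tolerance = 1e-12)
  expect_equal(rowSums(pr), 1, tolerance = 1e-12)
  # zero loading: probabilities independent of the latent, symmetric
  p <- default_true_params()
  p$zeta[] <- 0
  p$tau[] <- matrix(rep(c(-1.5, -0.5, 0.5, 1.5), each = 11), 11)
  lat <- data.frame(id = 1:20000, HR = rnorm(20000), AW = 0, VAL = 0)
  y <- simulate_indicators(lat, p, seed = 9L)
  tab <- prop.table(table(y$hr1))
  expect_lt(abs(tab[["1"]] - tab[["5"]]), 0.02)
  expect_lt(abs(tab[["2"]] - tab[["4"]]), 0.02)
  expect_lt(abs(cor(y$hr1, lat$HR)), 0.02)
  # huge loading: response saturates at the extreme category
  p$zeta[] <- 50
  yy <- simulate_indicators(data.frame(id = 1, HR = 2, AW = 2, VAL = 2), p, 1L)
  expect_true(all(yy[-1] == 5))
  # non-monotone thresholds are refused
  p$tau[3, ] <- c(1, 0.5, 2, 3)
  expect_error(hcm_params(p$gamma, p$lambda, p$zeta, p$tau, p$b, p$sigma,
                          p$theta, p$delta, p$phi), "hr3")
})

test_that("generated Likert marginals match numeric quadrature over the
           latent", {
  p <- default_true_params()
  p$gamma[] <- 0; p$lambda[] <- 0
  p$zeta["hr1"] <- 2
  lat <- data.frame(id = seq_len(1e5), HR = rnorm(1e5), AW = 0, VAL = 0)
  y <- simulate_indicators(lat, p, seed = 31L)$hr1
  emp <- prop.table(table(factor(y, levels = 1:5)))
  cuts <- c(-Inf, p$tau["hr1", ], Inf)
  theo <- vapply(1:5, function(k) {
    integrate(function(x) {
      (plogis(cuts[k + 1] - 2 * x) - plogis(cuts[k] - 2 * x)) * dnorm(x)
    }, -Inf, Inf)$value
  }, numeric(1))
  expect_lt(max(abs(as.numeric(emp) - theo)), 0.01)
})

test_that("choice simulation reproduces closed-form aggregate shares", {
  d <- fx_design()
  p <- default_true_params()
  p$gamma[] <- 0; p$lambda[] <- 0; p$phi[] <- 0; p$theta$value[] <- 0
  p$b[] <- 0; p$sigma[] <- 0
  r <- sample_covariates(2500, seed = 5L)
  lat <- simulate_latents(r, p, seed = 6L)
  # all parameters zero: uniform shares over the three alternatives
  p0 <- p; p0$delta <- 0
  ch <- simulate_choices(r, lat, d, p0, seed = 7L)$choices
  ch <- ch[!ch$is_qc & ch$chosen == 1L, ]
  shares <- prop.table(table(ch$alt_id))
  expect_lt(max(abs(shares - 1 / 3)), 0.01)
  # opt-out constant alone: share exp(delta) / (2 + exp(delta)) ~ 0.0102
  p1 <- p; p1$delta <- -3.889
  ch1 <- simulate_choices(r, lat, d, p1, seed = 8L)$choices
  ch1 <- ch1[!ch1$is_qc & ch1$chosen == 1L, ]
  target <- exp(-3.889) / (2 + exp(-3.889))
  expect_equal(unname(target), 0.0102, tolerance = 0.01)
  expect_lt(abs(mean(ch1$alt_id == 3) - target), 0.003)
})

test_that("the designated inattentive fraction fails the QC task exactly", {
  ds <- fx_survey(n = 1203L, seed = 13L, inattentive_fraction = 67 / 1203)
  qc_choices <- ds$choices[ds$choices$is_qc & ds$choices$chosen == 1L, ]
  expect_equal(nrow(qc_choices), 1203)
  expect_equal(sum(qc_choices$alt_id == 2L), 67)
  expect_equal(length(ds$inattentive_ids), 67)
})

test_that("survey generation is bit-reproducible and round-trips", {
  a <- fx_survey(n = 40L, seed = 21L)
  b <- fx_survey(n = 40L, seed = 21L)
  expect_identical(a$respondents, b$respondents)
  expect_identical(a$indicators, b$indicators)
  expect_identical(a$choices, b$choices)
  # every respondent: 6 experimental tasks + 1 QC task, one choice each
  tasks <- table(a$choices$id[a$choices$chosen == 1L])
  expect_true(all(tasks == 7))
  per_task <- aggregate(chosen ~ id + set_id, a$choices, sum)
  expect_true(all(per_task$chosen == 1))
  dir <- tempfile()
  write_survey(a, dir)
  back <- read_survey(dir)
  expect_equal(back$respondents$gender, a$respondents$gender)
  expect_equal(back$choices$chosen, a$choices$chosen)
  expect_equal(nrow(back$indicators), nrow(a$indicators))
})

test_that("the reference parameter set carries the published magnitudes", {
  p <- default_true_params()
  expect_equal(unname(p$b["premium"]), -0.007)
  expect_equal(unname(p$lambda["aw_val"]), 0.528)
  expect_equal(unname(p$zeta["aw1"]), 4.227)
  expect_equal(p$delta, -3.889)
  expect_equal(nrow(p$theta), 21)
  expect_true(all(p$sigma >= 0))
  expect_true(all(apply(p$tau, 1, function(r) all(diff(r) > 0))))
  # YAML round trip
  path <- tempfile(fileext = ".yaml")
  write_params(p, path)
  q <- read_params(path)
  expect_equal(q$gamma, p$gamma)
  expect_equal(q$b, p$b)
  expect_equal(q$theta$value, p$theta$value)
})
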