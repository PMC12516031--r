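test_that("MNL probabilities have the closed forms and invariances", {
  expect_equal(mnl_probabilities(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(mnl_probabilities(c(log(2), 0, 0)), c(0.5, 0.25, 0.25))
  u <- c(0.3, -1.2, 0.7)
  expect_equal(mnl_probabilities(u), mnl_probabilities(u + 5), tolerance = 1e-12)
  expect_equal(sum(mnl_probabilities(u)), 1)
  p <- mnl_probabilities(c(0, 100, 200))
  expect_equal(p[3], 1, tolerance = 1e-12)
})

test_that("conditional utilities accumulate coefficients, draws and
           interactions", {
  p <- default_true_params()
  x <- setNames(numeric(8), names(p$b))
  zero <- p
  zero$b[] <- 0; zero$sigma[] <- 0; zero$theta$value[] <- 0
  zero$delta <- 0; zero$phi[] <- 0
  xx <- x; xx["premium"] <- 130
  expect_equal(conditional_utility(xx, zero), 0)
  # premium mean alone: -0.007 * 130 = -0.91
  pm <- zero; pm$b["premium"] <- -0.007
  expect_equal(conditional_utility(xx, pm), -0.91)
  # latent interaction alone: HR draw 1 on the strong-government dummy
  th <- zero
  th$theta <- data.frame(var = "HR", level = "government_strong",
                         value = -0.178, stringsAsFactors = FALSE)
  xs <- x; xs["government_strong"] <- 1
  expect_equal(conditional_utility(xs, th, latents = c(HR = 1)), -0.178)
  # opt-out: delta plus latent shifts
  expect_equal(conditional_utility(params = p, optout = TRUE,
                                   latents = c(HR = 1, AW = 2, VAL = 0)),
               p$delta + p$phi[["HR"]] + 2 * p$phi[["AW"]])
  # random draw enters through sigma
  rd <- zero; rd$sigma["premium"] <- 0.01
  expect_equal(conditional_utility(xx, rd, xi = c(premium = 2)), 0.01 * 2 * 130)
})

test_that("the per-draw person likelihood factorizes and matches hand
           arithmetic", {
  p <- default_true_params()
  p$gamma[] <- 0; p$lambda[] <- 0; p$zeta[] <- 0
  p$b[] <- 0; p$sigma[] <- 0; p$theta$value[] <- 0; p$delta <- 0; p$phi[] <- 0
  ds <- fx_survey(n = 3L, seed = 17L, params = default_true_params())
  covi <- ds$respondents[1, ]
  chi <- ds$choices[ds$choices$id == covi$id, ]
  indi <- as.list(ds$indicators[ds$indicators$id == covi$id, -1])
  drw <- list(eta = c(0, 0, 0), xi = setNames(numeric(8), names(p$b)))
  # zero loadings: measurement term is a threshold-only constant
  mprob <- prod(vapply(seq_along(indi), function(i) {
    pk <- diff(plogis(c(-Inf, p$tau[i, ], Inf)))
    pk[indi[[i]]]
  }, numeric(1)))
  expect_equal(person_likelihood(chi, indi, covi, drw, p),
               (1 / 3)^6 * mprob, tolerance = 1e-12)
  expect_equal(person_likelihood(chi, indi, covi, drw, p, measurement = FALSE),
               (1 / 3)^6, tolerance = 1e-12)
  # hand-built single-task, single-indicator oracle
  p2 <- p
  p2$b["premium"] <- -0.01
  p2$delta <- -1
  p2$zeta["hr1"] <- 1.5
  one <- chi[!chi$is_qc, ][1:3, ]
  u <- c(-0.01 * one$premium[1], -0.01 * one$premium[2], -1)
  pr <- exp(u) / sum(exp(u))
  drw2 <- list(eta = c(0.4, 0, 0), xi = setNames(numeric(8), names(p$b)))
  # with zero structural part, HR equals its disturbance 0.4
  ind_pr <- plogis(p2$tau["hr1", 2] - 1.5 * 0.4) -
    plogis(p2$tau["hr1", 1] - 1.5 * 0.4)
  got <- person_likelihood(one, list(hr1 = 2), covi, drw2, p2)
  expect_equal(got, unname(pr[one$chosen == 1] * ind_pr), tolerance = 1e-12)
  # monotone: raising the chosen alternative's disutility lowers the value
  opt_task <- one
  opt_task$chosen <- as.integer(opt_task$alt_id == 3L)
  hi <- person_likelihood(opt_task, list(hr1 = 2), covi, drw2, p2)
  p3 <- p2
  p3$delta <- -2  # worse opt-out, opt-out chosen
  lo <- person_likelihood(opt_task, list(hr1 = 2), covi, drw2, p3)
  expect_lt(lo, hi)
})

test_that("the compiled simulated likelihood equals the R reference", {
  ds <- fx_survey(n = 25L, seed = 11L, inattentive_fraction = 0)
  p <- default_true_params()
  spec <- hcm_spec()
  dr <- draw_config("halton", 7L, seed = 3L)
  ll_cpp <- simulated_loglik(ds, p, dr, spec)
  ed <- hcmdce:::build_estimation_data(ds, spec)
  dd <- hcmdce:::draws_for(ed, dr)
  ll_r <- 0
  for (i in seq_along(ed$ids)) {
    id <- ed$ids[i]
    chi <- ds$choices[ds$choices$id == id & !ds$choices$is_qc, ]
    indi <- as.list(ds$indicators[ds$indicators$id == id, -1])
    covi <- ds$respondents[ds$respondents$id == id, ]
    Ls <- vapply(seq_len(dr$n_draws), function(r) {
      row <- (i - 1L) * dr$n_draws + r
      person_likelihood(chi, indi, covi,
                        list(eta = dd$eta[row, ],
                             xi = setNames(dd$xi[row, ], names(p$b))), p)
    }, numeric(1))
    ll_r <- ll_r + log(mean(Ls))
  }
  expect_equal(ll_cpp, ll_r, tolerance = 1e-10)
  # deterministic given the draw configuration
  expect_identical(ll_cpp, simulated_loglik(ds, p, dr, spec))
})

test_that("the analytic gradient matches central finite differences", {
  ds <- fx_survey(n = 20L, seed = 23L, inattentive_fraction = 0)
  spec <- hcm_spec()
  ed <- hcmdce:::build_estimation_data(ds, spec)
  parmap <- hcmdce:::make_parmap(spec, ed)
  dr <- draw_config("halton", 4L, seed = 9L)
  dd <- hcmdce:::draws_for(ed, dr)
  o <- hcmdce:::make_objective(ed, parmap, dd$eta, dd$xi, dr$n_draws)
  comp <- hcmdce:::comp_from_params(default_true_params(), spec, ed)
  v <- hcmdce:::pack_v(comp, parmap)
  g <- o$gr(v)
  fd <- fd_gradient(o$obj, v)
  expect_lt(max(abs(fd - g) / pmax(1e-4, abs(fd))), 1e-5)
  # per-person scores sum to the total gradient
  S <- o$scores_at(v)
  expect_equal(colSums(S), unname(-g), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("the likelihood is invariant to respondent relabeling,
           alternative relabeling, and sigma sign flips", {
  ds <- fx_survey(n = 30L, seed = 29L, inattentive_fraction = 0)
  p <- default_true_params()
  spec <- hcm_spec()
  dr <- draw_config("halton", 5L, seed = 2L)
  base <- simulated_loglik(ds, p, dr, spec)
  # shuffling record order (ids unchanged) leaves the likelihood untouched
  perm <- ds
  perm$respondents <- perm$respondents[sample(nrow(perm$respondents)), ]
  perm$indicators <- perm$indicators[sample(nrow(perm$indicators)), ]
  perm$choices <- perm$choices[sample(nrow(perm$choices)), ]
  expect_equal(simulated_loglik(perm, p, dr, spec), base, tolerance = 1e-9)
  # relabeling alternatives 1 and 2 within every task
  swap <- ds
  ins <- swap$choices$alt_id %in% 1:2
  swap$choices$alt_id[ins] <- 3L - swap$choices$alt_id[ins]
  expect_equal(simulated_loglik(swap, p, dr, spec), base, tolerance = 1e-9)
  # sigma sign flips leave the likelihood unchanged up to simulation noise
  # (exact in distribution; a fixed finite draw set is not symmetric)
  dr2 <- draw_config("halton", 500L, seed = 2L)
  ed <- hcmdce:::build_estimation_data(ds, spec)
  dd <- hcmdce:::draws_for(ed, dr2)
  comp <- hcmdce:::comp_from_params(p, spec, ed)
  l1 <- hcmdce:::call_engine(ed, comp, dd$eta, dd$xi, dr2$n_draws)$loglik
  comp$sigma <- -comp$sigma
  l2 <- hcmdce:::call_engine(ed, comp, dd$eta, dd$xi, dr2$n_draws)$loglik
  expect_lt(abs(l1 - l2) / abs(l1), 0.005)
})

test_that("the frozen-sigma MNL fit matches an independent conditional
           logit", {
  skip_if_not_installed("survival")
  library(survival)  # clogit dispatches to coxph in the attached namespace
  ds <- apply_qc_filter(fx_survey(n = 250L, seed = 31L))$dataset
  m <- fit_mnl(ds)
  ch <- ds$choices[!ds$choices$is_qc, ]
  ch$optout <- as.integer(ch$alt_id == 3L)
  ch$strat <- paste(ch$id, ch$set_id)
  cl <- survival::clogit(
    chosen ~ premium + government_moderate + government_strong + deductible +
      reimbursement + services_expanded1 + services_expanded2 +
      services_expanded3 + optout + survival::strata(strat), data = ch)
  expect_lt(max(abs(c(m$b, m$delta) - unname(coef(cl)))), 1e-4)
  expect_equal(m$loglik, as.numeric(logLik(cl)), tolerance = 1e-8)
})

test_that("mixed logit shrinks spurious heterogeneity and recovers a real
           standard deviation", {
  d <- fx_design()
  p0 <- default_true_params()
  p0$gamma[] <- 0; p0$lambda[] <- 0; p0$phi[] <- 0; p0$theta$value[] <- 0
  p0$sigma[] <- 0
  ds0 <- simulate_survey(400L, d, p0, seed = 41L, inattentive_fraction = 0)
  f0 <- fit_mixed_logit(ds0, draws = draw_config("halton", 100L, seed = 5L),
                        control = list(se = FALSE))
  expect_lt(median(abs(f0$estimates$sigma)), 0.1)
  # nonzero deductible SD recovered across replicates
  p1 <- p0
  p1$sigma["deductible"] <- 0.110
  est <- vapply(1:3, function(rep) {
    ds1 <- simulate_survey(600L, d, p1, seed = 50L + rep,
                           inattentive_fraction = 0)
    f1 <- fit_mixed_logit(ds1, draws = draw_config("halton", 200L,
                                                   seed = 60L + rep),
                          control = list(se = FALSE))
    unname(f1$estimates$sigma["deductible"])
  }, numeric(1))
  mcse <- sd(est)
  expect_true(all(abs(est - 0.110) <= 3 * mcse + 1e-8))
})

test_that("robust sandwich standard errors match a hand-computed oracle and
           scale under dataset duplication", {
  ds <- apply_qc_filter(fx_survey(n = 150L, seed = 43L))$dataset
  spec <- hcm_spec(latent = FALSE, random_levels = character(0),
                   interactions = data.frame(var = character(),
                                             level = character()),
                   optout_latents = FALSE)
  f <- fit_mixed_logit(ds, spec = spec,
                       draws = draw_config("halton", 1L, seed = 1L),
                       control = list(se = TRUE))
  expect_true(f$se_available)
  b <- f$estimates$b
  delta <- f$estimates$delta
  # hand-computed per-person scores and analytic information for plain MNL
  cn <- names(b)
  ids <- sort(unique(ds$choices$id))
  P <- length(cn) + 1L
  Sc <- matrix(0, length(ids), P)
  H <- matrix(0, P, P)
  for (i in seq_along(ids)) {
    ch <- ds$choices[ds$choices$id == ids[i] & !ds$choices$is_qc, ]
    for (sid in unique(ch$set_id)) {
      task <- ch[ch$set_id == sid, ]
      task <- task[order(task$alt_id), ]
      X <- cbind(as.matrix(task[cn]), as.integer(task$alt_id == 3L))
      u <- drop(X %*% c(b, delta))
      pr <- exp(u - max(u)); pr <- pr / sum(pr)
      Sc[i, ] <- Sc[i, ] + drop((task$chosen - pr) %*% X)
      H <- H + t(X) %*% (diag(pr) - pr %*% t(pr)) %*% X
    }
  }
  Hi <- solve(H)
  hand <- sqrt(diag(Hi %*% crossprod(Sc) %*% Hi))
  expect_equal(unname(f$robust_se), unname(hand), tolerance = 1e-3)
  # classical and robust agree broadly under correct specification
  expect_true(all(f$robust_se / f$classical_se > 0.75 &
                  f$robust_se / f$classical_se < 1.3))
  # duplicating every respondent shrinks robust SEs by 1/sqrt(2)
  dup <- ds
  shift <- max(ds$respondents$id)
  r2 <- ds$respondents; r2$id <- r2$id + shift
  i2 <- ds$indicators; i2$id <- i2$id + shift
  c2 <- ds$choices; c2$id <- c2$id + shift
  dup$respondents <- rbind(ds$respondents, r2)
  dup$indicators <- rbind(ds$indicators, i2)
  dup$choices <- rbind(ds$choices, c2)
  se_dup <- robust_se(f, dup)
  expect_equal(unname(se_dup / f$robust_se), rep(1 / sqrt(2), P),
               tolerance = 0.01)
})

test_that("willingness to pay is the negative coefficient ratio with a
           delta-method standard error", {
  fake <- structure(list(
    estimates = list(b = c(premium = -0.007, government_strong = 0.880)),
    parmap_names = c("b.premium", "b.government_strong"),
    vcov_robust = matrix(c(1e-8, 2e-7, 2e-7, 0.01), 2, 2,
                         dimnames = list(c("b.premium", "b.government_strong"),
                                         c("b.premium", "b.government_strong"))),
    se_available = TRUE,
    spec = list(attrs = huimin_attributes())), class = "hcm_fit")
  w <- wtp(fake)
  expect_equal(w$wtp[w$level == "government_strong"], 0.880 / 0.007,
               tolerance = 1e-10)
  # zero coefficient: zero WTP
  fake0 <- fake
  fake0$estimates$b["government_strong"] <- 0
  expect_equal(wtp(fake0)$wtp, 0)
  # near-zero premium coefficient is refused
  faket <- fake
  faket$estimates$b["premium"] <- 1e-9
  expect_error(wtp(faket), "unstable")
  # delta-method SE against a parametric bootstrap oracle
  skip_if_not_installed("MASS")
  set.seed(99)
  V <- matrix(c(1e-8, 5e-8, 5e-8, 0.004), 2, 2)
  draws <- MASS::mvrnorm(2e5, mu = c(-0.007, 0.880), Sigma = V)
  boot_se <- sd(-draws[, 2] / draws[, 1])
  fake2 <- fake
  fake2$vcov_robust <- V
  dimnames(fake2$vcov_robust) <- dimnames(fake$vcov_robust)
  se <- wtp(fake2)$se
  expect_lt(abs(se / boot_se - 1), 0.05)
})

test_that("candidate interaction grids cross the heterogeneous levels with
           the interacting variables", {
  grid <- candidate_interactions()
  expect_equal(length(unique(grid$level)), 7)
  expect_equal(length(unique(grid$var)), 9)
  expect_equal(anyDuplicated(grid), 0)
  custom <- candidate_interactions(levels = c("premium", "deductible"),
                                   variables = c("HR", "gender"))
  expect_equal(nrow(custom), 4)
})
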