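# ---------------------------------------------------------------------------
# Maximum simulated likelihood fitting, sandwich standard errors, WTP.

default_control <- function(control = list()) {
  utils::modifyList(list(maxit = 1000L, grad_tol = 1e-6, se = TRUE,
                         rel_tol = 1e-10, trace = FALSE), control)
}

# Memoized objective/gradient pair in the free-parameter space.
make_objective <- function(ed, parmap, eta, xi, R) {
  layout <- ed$layout
  cache <- new.env(parent = emptyenv())
  cache$v <- NULL
  eval_point <- function(v) {
    if (!is.null(cache$v) && identical(v, cache$v)) return(cache$res)
    comp <- unpack_v(v, parmap)
    res <- call_engine(ed, comp, eta, xi, R, want_grad = TRUE)
    gv <- chain_to_v(as.numeric(res$grad), comp, parmap, layout)
    out <- list(ll = res$loglik, grad = gv, pl = res$pl)
    cache$v <- v + 0  # force a copy: the optimizer mutates `v` in place
    cache$res <- out
    out
  }
  list(
    eval_point = eval_point,
    obj = function(v) {
      r <- eval_point(v)
      if (!is.finite(r$ll)) return(1e10)
      -r$ll
    },
    gr = function(v) {
      r <- eval_point(v)
      g <- -r$grad
      g[!is.finite(g)] <- 0
      g
    },
    scores_at = function(v) {
      comp <- unpack_v(v, parmap)
      res <- call_engine(ed, comp, eta, xi, R, want_grad = TRUE,
                         want_scores = TRUE)
      chain_to_v(res$scores, comp, parmap, layout)
    })
}

# Central finite differences of the analytic gradient: observed information
# (Hessian of the negative log-likelihood) in v-space.
numeric_hessian <- function(gr, v, h_rel = 1e-5) {
  P <- length(v)
  H <- matrix(0, P, P)
  for (j in seq_len(P)) {
    h <- h_rel * max(1, abs(v[j]))
    vp <- v; vp[j] <- vp[j] + h
    vm <- v; vm[j] <- vm[j] - h
    H[, j] <- (gr(vp) - gr(vm)) / (2 * h)
  }
  (H + t(H)) / 2
}

starting_values <- function(ed, parmap, spec, dataset, draws, control) {
  comp0 <- list(gamma = matrix(if (parmap$use_lat) 0.1 else 0, 3, parmap$C),
                lambda = rep(0.1, 3), zeta = rep(1, parmap$I),
                taut = matrix(0, parmap$I, 4),
                b = numeric(parmap$K), sigma = numeric(parmap$K),
                theta = rep(0.1, parmap$M), delta = 0,
                phi = rep(0.1, 3))
  if (parmap$I > 0) {
    # quantile-matched thresholds from the observed cumulative shares
    tau0 <- t(vapply(seq_len(parmap$I), function(i) {
      y <- ed$Y[, i]; y <- y[y > 0]
      cp <- vapply(1:4, function(k) mean(y <= k), numeric(1))
      cp <- pmin(pmax(cp, 0.005), 0.995)
      cp <- cummax(cp + (1:4) * 1e-6)
      qlogis(pmin(cp, 0.999))
    }, numeric(4)))
    comp0$taut <- taut_from_tau(tau0)
  }
  # choice means and opt-out constant from a plain MNL fit
  mnl <- fit_mnl_ed(ed_no_latent(dataset, spec), control)
  comp0$b <- mnl$b
  comp0$delta <- mnl$delta
  comp0$sigma[parmap$sig_free] <- 0.1
  pack_v(comp0, parmap)
}

ed_no_latent <- function(dataset, spec) {
  spec0 <- hcm_spec(latent = FALSE,
                    random_levels = character(0),
                    interactions = data.frame(var = character(),
                                              level = character(),
                                              stringsAsFactors = FALSE),
                    optout_latents = FALSE, attrs = spec$attrs)
  list(ed = build_estimation_data(dataset, spec0), spec = spec0)
}

# MNL on prepared data (R = 1, no randomness): returns named b and delta.
fit_mnl_ed <- function(prep, control) {
  ed <- prep$ed
  parmap <- make_parmap(prep$spec, ed)
  eta <- matrix(0, 0, 0)
  xi <- matrix(0, ed$N, ed$K)
  o <- make_objective(ed, parmap, eta, xi, 1L)
  v0 <- numeric(parmap$P)
  names(v0) <- parmap$names
  opt <- nlminb(v0, o$obj, o$gr,
                control = list(iter.max = control$maxit,
                               eval.max = 3L * control$maxit))
  comp <- unpack_v(opt$par, parmap)
  list(b = stats::setNames(comp$b, ed$coded), delta = comp$delta,
       loglik = -opt$objective, v = opt$par, parmap = parmap, opt = opt)
}

#' Fit a plain multinomial (conditional) logit
#'
#' All coefficients fixed (no random heterogeneity, no latent component):
#' the closed-form MNL benchmark and the source of starting values for the
#' simulated-likelihood fits.
#'
#' @param dataset A QC-filtered `survey_dataset`.
#' @param control Optimizer control list.
#' @return List with `b`, `delta` and `loglik`.
#' @export
fit_mnl <- function(dataset, control = list()) {
  control <- default_control(control)
  prep <- ed_no_latent(dataset, hcm_spec(latent = FALSE,
                                         attrs = dataset$design$attrs))
  fit_mnl_ed(prep, control)[c("b", "delta", "loglik")]
}

fit_engine <- function(dataset, spec, draws, control, v0 = NULL) {
  control <- default_control(control)
  ed <- build_estimation_data(dataset, spec)
  parmap <- make_parmap(spec, ed)
  d <- draws_for(ed, draws)
  o <- make_objective(ed, parmap, d$eta, d$xi, draws$n_draws)
  if (is.null(v0) && !is.null(control$start)) {
    v0 <- if (inherits(control$start, "hcm_fit")) control$start$v else control$start
    if (length(v0) != parmap$P) stop("start vector does not match the specification")
  }
  if (is.null(v0)) v0 <- starting_values(ed, parmap, spec, dataset, draws, control)
  ctl <- list(iter.max = control$maxit, eval.max = 3L * control$maxit,
              rel.tol = control$rel_tol,
              trace = if (control$trace) 1L else 0L)
  opt <- nlminb(v0, o$obj, o$gr, control = ctl)
  iterations <- opt$iterations
  # quasi-Newton restarts: PORT often reports relative convergence while the
  # gradient is still above tolerance; a fresh Hessian approximation fixes it
  for (polish in seq_len(5L)) {
    g <- max(abs(o$eval_point(opt$par + 0)$grad))
    if (g <= control$grad_tol * max(1, abs(opt$objective))) break
    opt2 <- nlminb(opt$par, o$obj, o$gr, control = ctl)
    iterations <- iterations + opt2$iterations
    no_progress <- opt2$objective > opt$objective - 1e-8
    if (opt2$objective <= opt$objective) opt <- opt2
    if (no_progress) break
  }
  v <- opt$par
  names(v) <- parmap$names
  res <- o$eval_point(v)
  opt$iterations <- iterations
  gnorm <- max(abs(res$grad))
  converged <- gnorm <= control$grad_tol * max(1, abs(res$ll))
  comp <- unpack_v(v, parmap)

  se_r <- se_c <- rep(NA_real_, parmap$P)
  vcov_r <- vcov_c <- NULL
  se_available <- FALSE
  if (isTRUE(control$se)) {
    H <- numeric_hessian(o$gr, v)
    Hi <- try(solve(H), silent = TRUE)
    if (!inherits(Hi, "try-error")) {
      S <- o$scores_at(v)
      B <- crossprod(S)
      vcov_c <- Hi
      vcov_r <- Hi %*% B %*% Hi
      se_c <- sqrt(pmax(diag(vcov_c), 0))
      se_r <- sqrt(pmax(diag(vcov_r), 0))
      se_available <- TRUE
    } else {
      warning("singular Hessian: robust standard errors unavailable")
    }
  }
  names(se_r) <- names(se_c) <- parmap$names

  estimates <- estimates_as_params(comp, parmap, ed, spec)
  structure(list(
    estimates = estimates, v = v, parmap_names = parmap$names,
    robust_se = se_r, classical_se = se_c,
    vcov_robust = vcov_r, vcov_classical = vcov_c,
    se_available = se_available,
    loglik = res$ll, gradient_norm = gnorm, converged = converged,
    n_individuals = ed$N, n_tasks = ed$N * ed$T,
    iterations = opt$iterations, message = opt$message,
    draw_config = draws, spec = spec, coded = ed$coded),
    class = "hcm_fit")
}

# Reported estimates on the natural scale (thresholds monotone, SDs unsigned).
estimates_as_params <- function(comp, parmap, ed, spec) {
  cn <- ed$coded
  b <- stats::setNames(comp$b, cn)
  sigma <- stats::setNames(abs(comp$sigma), cn)
  theta <- cbind(spec$interactions,
                 value = if (parmap$M) comp$theta else numeric(0))
  if (parmap$use_lat) {
    gamma <- comp$gamma
    colnames(gamma) <- colnames(ed$Z)
    rownames(gamma) <- latent_names()
    zeta <- stats::setNames(comp$zeta, colnames(ed$Y))
    tau <- comp$tau
    rownames(tau) <- colnames(ed$Y)
    list(gamma = gamma,
         lambda = stats::setNames(comp$lambda, c("hr_aw", "hr_val", "aw_val")),
         zeta = zeta, tau = tau, b = b, sigma = sigma, theta = theta,
         delta = comp$delta,
         phi = stats::setNames(comp$phi, latent_names()))
  } else {
    list(b = b, sigma = sigma, theta = theta, delta = comp$delta)
  }
}

#' @export
print.hcm_fit <- function(x, ...) {
  cat("Hybrid choice model fit (",
      if (x$spec$latent) "joint latent + choice" else "mixed logit", ")\n",
      sep = "")
  cat("  respondents:", x$n_individuals, "| tasks:", x$n_tasks,
      "| draws:", x$draw_config$n_draws, x$draw_config$scheme, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      "| converged:", x$converged,
      "(max |grad| =", format(x$gradient_norm, digits = 3), ")\n")
  cat("  choice means:\n")
  print(round(x$estimates$b, 4))
  invisible(x)
}

#' Fit the joint hybrid choice model by maximum simulated likelihood
#'
#' Estimates all components simultaneously: structural covariate weights and
#' latent-to-latent effects, ordered-logit measurement loadings and
#' thresholds, mixed-logit choice means and standard deviations, the
#' specified interaction weights, and the opt-out constant with latent
#' shifts. The per-respondent likelihood is simulated with per-individual
#' blocks of joint draws (three structural disturbances plus one shock per
#' coded attribute) and maximized by a quasi-Newton optimizer with the
#' analytic gradient. Starting values: plain-MNL choice means and opt-out
#' constant, 0.1 for standard deviations and latent effects, loadings 1,
#' thresholds quantile-matched to the observed indicator shares.
#'
#' @param dataset A QC-filtered `survey_dataset`.
#' @param spec An `hcm_spec` (default: full latent specification with the
#'   21 reference interactions).
#' @param draws A `draw_config` (default 500 scrambled Halton draws).
#' @param control List: `maxit` (1000), `grad_tol` (1e-6, relative to the
#'   log-likelihood magnitude), `se` (compute sandwich/classical standard
#'   errors, default `TRUE`), `rel_tol`, `trace`, and optionally `start` (a
#'   previous `hcm_fit` with the same specification, or its free-parameter
#'   vector, used as warm start; convergence is still judged by the gradient
#'   at the new optimum).
#' @return An `hcm_fit`: estimates on the natural scale, robust and
#'   classical standard errors, log-likelihood, convergence diagnostics and
#'   the draw configuration.
#' @export
fit_hcm <- function(dataset, spec = hcm_spec(attrs = dataset$design$attrs),
                    draws = draw_config(), control = list()) {
  stopifnot(isTRUE(spec$latent))
  fit_engine(dataset, spec, draws, control)
}

#' Fit the main-effects panel mixed logit
#'
#' The heterogeneity check: random coefficients on the coded attribute
#' columns, an opt-out constant, no latent component. Identical simulation
#' machinery to [fit_hcm()] with the measurement and structural parts
#' removed.
#'
#' @inheritParams fit_hcm
#' @param spec An `hcm_spec` with `latent = FALSE`
#'   (default [main_effects_spec()]).
#' @return An `hcm_fit`.
#' @export
fit_mixed_logit <- function(dataset,
                            spec = main_effects_spec(dataset$design$attrs),
                            draws = draw_config(), control = list()) {
  stopifnot(!isTRUE(spec$latent))
  fit_engine(dataset, spec, draws, control)
}

#' Robust (sandwich) standard errors
#'
#' `H^{-1} B H^{-1}` with `H` the observed information (finite differences
#' of the analytic gradient) and `B` the outer-product sum of the
#' per-respondent score vectors, evaluated at the fitted parameters. With
#' `dataset` supplied the sandwich is recomputed from scratch (e.g. on a
#' modified dataset); otherwise the standard errors stored in the fit are
#' returned.
#'
#' @param fit An `hcm_fit`.
#' @param dataset Optional `survey_dataset` to recompute on.
#' @return Named vector of robust standard errors.
#' @export
robust_se <- function(fit, dataset = NULL) {
  if (is.null(dataset)) {
    if (!fit$se_available) stop("standard errors unavailable (singular Hessian)")
    return(fit$robust_se)
  }
  ed <- build_estimation_data(dataset, fit$spec)
  parmap <- make_parmap(fit$spec, ed)
  stopifnot(identical(parmap$names, fit$parmap_names))
  d <- draws_for(ed, fit$draw_config)
  o <- make_objective(ed, parmap, d$eta, d$xi, fit$draw_config$n_draws)
  H <- numeric_hessian(o$gr, fit$v)
  Hi <- try(solve(H), silent = TRUE)
  if (inherits(Hi, "try-error")) stop("singular Hessian: robust standard errors unavailable")
  S <- o$scores_at(fit$v)
  se <- sqrt(pmax(diag(Hi %*% crossprod(S) %*% Hi), 0))
  stats::setNames(se, parmap$names)
}

#' Willingness to pay for attribute improvements
#'
#' Money-metric value of each non-premium mean coefficient:
#' `WTP_k = -b_k / b_premium`, in RMB per year (the premium enters utility
#' per RMB). Standard errors by the delta method on the robust covariance of
#' the two coefficients.
#'
#' @param fit An `hcm_fit`.
#' @param tol Minimum `|b_premium|` below which the ratio is refused.
#' @return Data frame with `level`, `wtp` and (when a covariance is
#'   available) `se`.
#' @export
wtp <- function(fit, tol = 1e-6) {
  b <- fit$estimates$b
  if (!"premium" %in% names(b)) stop("no premium coefficient in fit")
  bp <- b[["premium"]]
  if (abs(bp) < tol) stop("unstable WTP ratio: |b_premium| below tolerance")
  lev <- setdiff(names(b), "premium")
  out <- data.frame(level = lev, wtp = -b[lev] / bp, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (fit$se_available && !is.null(fit$vcov_robust)) {
    V <- fit$vcov_robust
    nm <- fit$parmap_names
    ip <- match("b.premium", nm)
    out$se <- vapply(lev, function(l) {
      ik <- match(paste0("b.", l), nm)
      g <- c(-1 / bp, b[[l]] / bp^2)  # d wtp / d (b_k, b_premium)
      idx <- c(ik, ip)
      sqrt(drop(t(g) %*% V[idx, idx] %*% g))
    }, numeric(1))
  }
  out
}

# two-sided normal p-values and significance stars at 1/5/10%
p_and_stars <- function(est, se) {
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  stars <- ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.10, "*", "")))
  list(p = p, stars = stars)
}
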