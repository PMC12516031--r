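# ---------------------------------------------------------------------------
# Data marshalling and parameter bookkeeping for the C++ likelihood engine.
# Raw engine layout (must match src/hcm_engine.cpp):
#   gamma (3*C col-major), lambda (3), zeta (I), tau (I*4 col-major),
#   b (K), sigma (K), theta (M), delta (1), phi (3)

engine_layout <- function(C, I, K, M) {
  sizes <- c(gamma = 3L * C, lambda = 3L, zeta = I, tau = 4L * I, b = K,
             sigma = K, theta = M, delta = 1L, phi = 3L)
  off <- cumsum(c(0L, sizes))[seq_along(sizes)]
  names(off) <- names(sizes)
  list(sizes = sizes, off = off, P = sum(sizes))
}

raw_index <- function(layout, comp) {
  layout$off[[comp]] + seq_len(layout$sizes[[comp]])
}

#' Prepare a survey dataset for estimation
#'
#' Converts the long-format choice records, indicator matrix and covariates
#' into the dense arrays consumed by the likelihood engine. Only experimental
#' (non-QC) tasks enter; every respondent must have the same number of tasks
#' with exactly one chosen alternative each. Missing indicator responses are
#' coded 0 and contribute nothing to the measurement likelihood.
#'
#' @param dataset A `survey_dataset` (typically QC-filtered).
#' @param spec An `hcm_spec`.
#' @return List with the engine arrays (`X`, `chosen`, `Z`, `Y`, ...).
#' @export
build_estimation_data <- function(dataset, spec = hcm_spec()) {
  attrs <- dataset$design$attrs
  cn <- coded_names(attrs)
  resp <- dataset$respondents[order(dataset$respondents$id), , drop = FALSE]
  ids <- resp$id
  ch <- dataset$choices[!dataset$choices$is_qc, , drop = FALSE]
  ch <- ch[ch$id %in% ids, , drop = FALSE]
  ch <- ch[order(match(ch$id, ids), ch$set_id, ch$alt_id), , drop = FALSE]
  n_rows <- tabulate(match(ch$id, ids), nbins = length(ids))
  if (length(unique(n_rows)) != 1L) {
    stop("unbalanced panel: respondents differ in number of experimental tasks")
  }
  T_tasks <- n_rows[1] / 3L
  stopifnot(T_tasks == round(T_tasks))
  ins <- ch[ch$alt_id != 3L, , drop = FALSE]
  X <- as.matrix(ins[cn])
  task_key <- paste(ch$id, ch$set_id)
  picked <- ch[ch$chosen == 1L, , drop = FALSE]
  if (nrow(picked) != length(ids) * T_tasks ||
      anyDuplicated(paste(picked$id, picked$set_id))) {
    stop("each task must have exactly one chosen alternative")
  }
  picked <- picked[order(match(picked$id, ids), picked$set_id), , drop = FALSE]
  chosen <- as.integer(picked$alt_id)

  Z <- covariate_matrix(resp)
  use_lat <- isTRUE(spec$latent)
  if (use_lat) {
    ind <- dataset$indicators
    ind <- ind[match(ids, ind$id), , drop = FALSE]
    Y <- as.matrix(ind[names(indicator_map())])
    Y[is.na(Y)] <- 0L
    storage.mode(Y) <- "integer"
    ind_lat <- match(indicator_map(), latent_names()) - 1L
  } else {
    Y <- matrix(0L, length(ids), 0)
    ind_lat <- integer(0)
  }
  inter <- spec$interactions
  inter_idx <- if (nrow(inter)) {
    cbind(match(inter$var, c(latent_names(), structural_covariates())) - 1L,
          match(inter$level, cn) - 1L)
  } else matrix(0L, 0, 2)
  storage.mode(inter_idx) <- "integer"
  list(X = X, chosen = chosen, N = length(ids), T = as.integer(T_tasks),
       K = length(cn), Z = Z, Y = Y, ind_lat = as.integer(ind_lat),
       inter = inter_idx, use_lat = use_lat, ids = ids, coded = cn,
       layout = engine_layout(ncol(Z), ncol(Y), length(cn), nrow(inter_idx)))
}

# Raw engine components from an hcm_params restricted to a spec.
comp_from_params <- function(params, spec, ed) {
  cn <- ed$coded
  sig <- params$sigma[cn]
  sig[!cn %in% spec$random_levels] <- 0
  th <- numeric(nrow(spec$interactions))
  if (length(th)) {
    key <- paste(spec$interactions$var, spec$interactions$level)
    pkey <- paste(params$theta$var, params$theta$level)
    hit <- match(key, pkey)
    th[!is.na(hit)] <- params$theta$value[hit[!is.na(hit)]]
  }
  if (ed$use_lat) {
    list(gamma = params$gamma, lambda = params$lambda, zeta = params$zeta,
         tau = params$tau, b = params$b[cn], sigma = sig, theta = th,
         delta = params$delta,
         phi = if (spec$optout_latents) params$phi else c(HR = 0, AW = 0, VAL = 0))
  } else {
    list(gamma = matrix(0, 3, ncol(ed$Z)), lambda = numeric(3),
         zeta = numeric(0), tau = matrix(0, 0, 4), b = params$b[cn],
         sigma = sig, theta = th, delta = params$delta, phi = numeric(3))
  }
}

call_engine <- function(ed, comp, eta, xi, R, want_grad = FALSE,
                        want_scores = FALSE) {
  hcm_engine(ed$X, ed$chosen, ed$N, ed$T, ed$K, ed$Z, ed$Y, ed$ind_lat,
             ed$inter, eta, xi, as.integer(R), comp$gamma, comp$lambda,
             comp$zeta, comp$tau, comp$b, comp$sigma, comp$theta, comp$delta,
             comp$phi, ed$use_lat, want_grad, want_scores)
}

draws_for <- function(ed, draws) {
  dims <- (if (ed$use_lat) 3L else 0L) + ed$K
  D <- make_draws(draws, ed$N, dims)
  if (ed$use_lat) list(eta = D[, 1:3, drop = FALSE],
                       xi = D[, 3 + seq_len(ed$K), drop = FALSE])
  else list(eta = matrix(0, 0, 0), xi = D)
}

#' Simulated log-likelihood of a parameter set
#'
#' Averages, per respondent, the joint choice-times-measurement likelihood
#' over `R` joint draws of the structural disturbances and random-coefficient
#' shocks, and sums the log of that average over respondents. Accumulation is
#' in log space, so nondegenerate parameter values never yield `-Inf`.
#' Deterministic given the draw configuration. With all standard deviations,
#' loadings and latent effects at zero the value equals the closed-form
#' multinomial-logit likelihood (plus the closed-form ordered-logit
#' measurement terms when indicators are modelled).
#'
#' @param dataset A QC-filtered `survey_dataset`.
#' @param params An `hcm_params`.
#' @param draws A `draw_config`.
#' @param spec An `hcm_spec` (default the full latent specification).
#' @return Scalar log-likelihood.
#' @export
simulated_loglik <- function(dataset, params, draws = draw_config(),
                             spec = hcm_spec()) {
  ed <- build_estimation_data(dataset, spec)
  comp <- comp_from_params(params, spec, ed)
  d <- draws_for(ed, draws)
  call_engine(ed, comp, d$eta, d$xi, draws$n_draws)$loglik
}

#' Multinomial logit choice probabilities
#'
#' `exp(u_j) / sum(exp(u))`, computed stably; invariant to adding a constant
#' to all utilities.
#'
#' @param utilities Numeric vector of alternative utilities.
#' @return Probability vector summing to 1.
#' @export
mnl_probabilities <- function(utilities) {
  e <- exp(utilities - max(utilities))
  e / sum(e)
}

#' Conditional utility of one alternative
#'
#' For an insurance alternative, `V = sum_k (b_k + sigma_k xi_k) x_k +
#' sum_m theta_m w_m x_{k(m)}` where `w` stacks the latent constructs and
#' covariates; for the opt-out, `V = delta + phi'(HR, AW, VAL)`.
#'
#' @param x Named coded attribute vector (ignored for the opt-out).
#' @param params An `hcm_params`.
#' @param latents Named vector `c(HR=, AW=, VAL=)` (defaults 0).
#' @param covariates Named covariate vector for covariate interactions
#'   (defaults 0).
#' @param xi Named random-coefficient draw (defaults 0).
#' @param optout Is this the opt-out alternative?
#' @return Scalar utility.
#' @export
conditional_utility <- function(x = NULL, params, latents = NULL,
                                covariates = NULL, xi = NULL, optout = FALSE) {
  lv <- c(HR = 0, AW = 0, VAL = 0)
  if (!is.null(latents)) lv[names(latents)] <- latents
  if (optout) return(unname(params$delta + sum(params$phi * lv[names(params$phi)])))
  stopifnot(!is.null(x), all(names(params$b) %in% names(x)))
  cv <- stats::setNames(numeric(length(structural_covariates())),
                        structural_covariates())
  if (!is.null(covariates)) cv[names(covariates)] <- unlist(covariates)
  xiv <- stats::setNames(numeric(length(params$b)), names(params$b))
  if (!is.null(xi)) xiv[names(xi)] <- xi
  co <- params$b + params$sigma * xiv
  if (nrow(params$theta)) {
    w <- c(lv, cv)
    for (m in seq_len(nrow(params$theta))) {
      co[params$theta$level[m]] <- co[params$theta$level[m]] +
        params$theta$value[m] * w[[params$theta$var[m]]]
    }
  }
  unname(sum(co * x[names(params$b)]))
}

#' Per-respondent likelihood for one joint draw
#'
#' Reference (pure R) implementation of the integrand of the simulated
#' likelihood: the product over the respondent's experimental tasks of the
#' chosen-alternative MNL probability times the product over indicators of
#' the ordered-logit category probability, conditional on one joint draw of
#' the structural disturbances and coefficient shocks.
#'
#' @param choices Long-format records of one respondent (QC rows dropped
#'   internally): columns `set_id`, `alt_id`, `chosen`, `optout` and the
#'   coded attribute columns.
#' @param indicators Named integer vector of Likert responses (NA = missing).
#' @param covariates One-row data frame (or named list) of covariates.
#' @param draw List with `eta` (3 structural disturbances) and `xi` (named
#'   coefficient shocks).
#' @param params An `hcm_params`.
#' @param measurement Include the indicator product? (default `TRUE`).
#' @return Likelihood contribution in (0, 1].
#' @export
person_likelihood <- function(choices, indicators, covariates, draw, params,
                              measurement = TRUE) {
  if ("is_qc" %in% names(choices)) choices <- choices[!choices$is_qc, , drop = FALSE]
  Z <- covariate_matrix(as.data.frame(covariates))
  eta <- unname(draw$eta)
  hr <- sum(Z[1, ] * params$gamma["HR", ]) + eta[1]
  aw <- sum(Z[1, ] * params$gamma["AW", ]) + params$lambda[["hr_aw"]] * hr + eta[2]
  val <- sum(Z[1, ] * params$gamma["VAL", ]) + params$lambda[["hr_val"]] * hr +
    params$lambda[["aw_val"]] * aw + eta[3]
  lv <- c(HR = hr, AW = aw, VAL = val)
  lik <- 1
  cv <- as.list(as.data.frame(covariates))
  for (sid in unique(choices$set_id)) {
    task <- choices[choices$set_id == sid, , drop = FALSE]
    task <- task[order(task$alt_id), , drop = FALSE]
    u <- vapply(seq_len(nrow(task)), function(j) {
      if (task$optout[j] == 1L) {
        conditional_utility(params = params, latents = lv, optout = TRUE)
      } else {
        conditional_utility(unlist(task[j, names(params$b)]), params,
                            latents = lv, covariates = cv, xi = draw$xi)
      }
    }, numeric(1))
    p <- mnl_probabilities(u)
    lik <- lik * p[task$chosen == 1L]
  }
  if (measurement) {
    imap <- indicator_map()
    for (ind in names(imap)) {
      y <- indicators[[ind]]
      if (is.null(y) || is.na(y)) next
      pr <- ordered_logit_probs(params$zeta[[ind]] * lv[[imap[[ind]]]],
                                params$tau[ind, ])
      lik <- lik * pr[1, y]
    }
  }
  unname(lik)
}

# --- free-parameter vector <-> engine components ---------------------------
# Thresholds are estimated through (t1, log-increments); everything else is
# unconstrained. `make_parmap` freezes the spec-dependent structure.

make_parmap <- function(spec, ed) {
  covs <- colnames(ed$Z)
  inds <- colnames(ed$Y)
  cn <- ed$coded
  blocks <- list()
  add <- function(blocks, comp, nms) {
    if (!length(nms)) return(blocks)
    c(blocks, list(list(comp = comp, names = nms)))
  }
  if (ed$use_lat) {
    gnames <- as.vector(outer(latent_names(), covs,
                              function(l, c) paste0("gamma.", l, ".", c)))
    blocks <- add(blocks, "gamma", gnames)  # column-major, matches engine
    blocks <- add(blocks, "lambda", paste0("lambda.", c("hr_aw", "hr_val", "aw_val")))
    blocks <- add(blocks, "zeta", paste0("zeta.", inds))
    blocks <- add(blocks, "taut", as.vector(outer(inds, c("t1", "d2", "d3", "d4"),
                                                  function(i, j) paste0("tau.", i, ".", j))))
  }
  blocks <- add(blocks, "b", paste0("b.", cn))
  sig_free <- which(cn %in% spec$random_levels)
  if (length(sig_free)) {
    blocks <- add(blocks, "sigma", paste0("sigma.", cn[sig_free]))
  }
  if (nrow(spec$interactions)) {
    blocks <- add(blocks, "theta", paste0("theta.", spec$interactions$var, ":",
                                          spec$interactions$level))
  }
  blocks <- add(blocks, "delta", "delta")
  if (ed$use_lat && spec$optout_latents) {
    blocks <- add(blocks, "phi", paste0("phi.", latent_names()))
  }
  sizes <- vapply(blocks, function(b) length(b$names), integer(1))
  off <- cumsum(c(0L, sizes))[seq_along(sizes)]
  names(off) <- vapply(blocks, `[[`, "", "comp")
  list(blocks = blocks, off = off, sizes = sizes,
       names = unlist(lapply(blocks, `[[`, "names")),
       P = sum(sizes), sig_free = sig_free,
       C = ncol(ed$Z), I = ncol(ed$Y), K = ed$K, M = nrow(ed$inter),
       use_lat = ed$use_lat, optout_latents = isTRUE(spec$optout_latents))
}

vslice <- function(parmap, comp) {
  i <- match(comp, names(parmap$off))
  if (is.na(i)) return(integer(0))
  parmap$off[[i]] + seq_len(parmap$sizes[i])
}

tau_from_taut <- function(taut) {
  # taut: I x 4 (t1, d2, d3, d4) -> monotone thresholds
  t1 <- taut[, 1]
  cbind(t1, t1 + exp(taut[, 2]),
        t1 + exp(taut[, 2]) + exp(taut[, 3]),
        t1 + exp(taut[, 2]) + exp(taut[, 3]) + exp(taut[, 4]),
        deparse.level = 0)
}

taut_from_tau <- function(tau) {
  d <- t(apply(tau, 1, diff))
  if (nrow(tau) == 1) d <- matrix(d, 1)
  cbind(tau[, 1], log(d), deparse.level = 0)
}

# v -> engine components
unpack_v <- function(v, parmap) {
  C <- parmap$C; I <- parmap$I; K <- parmap$K; M <- parmap$M
  comp <- list(gamma = matrix(0, 3, C), lambda = numeric(3),
               zeta = numeric(I), tau = matrix(0, I, 4), taut = matrix(0, I, 4),
               b = numeric(K), sigma = numeric(K), theta = numeric(M),
               delta = 0, phi = numeric(3))
  if (parmap$use_lat) {
    comp$gamma <- matrix(v[vslice(parmap, "gamma")], 3, C)
    comp$lambda <- v[vslice(parmap, "lambda")]
    comp$zeta <- v[vslice(parmap, "zeta")]
    comp$taut <- matrix(v[vslice(parmap, "taut")], I, 4)
    comp$tau <- tau_from_taut(comp$taut)
  }
  comp$b <- v[vslice(parmap, "b")]
  comp$sigma[parmap$sig_free] <- v[vslice(parmap, "sigma")]
  if (M) comp$theta <- v[vslice(parmap, "theta")]
  comp$delta <- v[vslice(parmap, "delta")]
  if (parmap$optout_latents) comp$phi <- v[vslice(parmap, "phi")]
  comp
}

pack_v <- function(comp, parmap) {
  v <- numeric(parmap$P)
  if (parmap$use_lat) {
    v[vslice(parmap, "gamma")] <- as.vector(comp$gamma)
    v[vslice(parmap, "lambda")] <- comp$lambda
    v[vslice(parmap, "zeta")] <- comp$zeta
    v[vslice(parmap, "taut")] <- as.vector(if (!is.null(comp$taut)) comp$taut
                                           else taut_from_tau(comp$tau))
  }
  v[vslice(parmap, "b")] <- comp$b
  v[vslice(parmap, "sigma")] <- comp$sigma[parmap$sig_free]
  if (parmap$M) v[vslice(parmap, "theta")] <- comp$theta
  v[vslice(parmap, "delta")] <- comp$delta
  if (parmap$optout_latents) v[vslice(parmap, "phi")] <- comp$phi
  names(v) <- parmap$names
  v
}

# chain rule raw-gradient -> v-gradient; G may be a vector (P_raw) or a
# matrix with P_raw columns (per-person scores)
chain_to_v <- function(G, comp, parmap, layout) {
  if (parmap$use_lat && is.null(comp$taut)) comp$taut <- taut_from_tau(comp$tau)
  vec_in <- is.null(dim(G))
  if (vec_in) G <- matrix(G, nrow = 1)
  out <- matrix(0, nrow(G), parmap$P)
  colnames(out) <- parmap$names
  pick <- function(comp_name) G[, raw_index(layout, comp_name), drop = FALSE]
  if (parmap$use_lat) {
    out[, vslice(parmap, "gamma")] <- pick("gamma")
    out[, vslice(parmap, "lambda")] <- pick("lambda")
    out[, vslice(parmap, "zeta")] <- pick("zeta")
    Gt <- pick("tau")  # columns: I x 4 col-major
    I <- parmap$I
    g1 <- Gt[, 1:I, drop = FALSE]
    g2 <- Gt[, I + 1:I, drop = FALSE]
    g3 <- Gt[, 2 * I + 1:I, drop = FALSE]
    g4 <- Gt[, 3 * I + 1:I, drop = FALSE]
    e2 <- exp(comp$taut[, 2]); e3 <- exp(comp$taut[, 3]); e4 <- exp(comp$taut[, 4])
    gt <- cbind(g1 + g2 + g3 + g4,
                sweep(g2 + g3 + g4, 2, e2, `*`),
                sweep(g3 + g4, 2, e3, `*`),
                sweep(g4, 2, e4, `*`))
    out[, vslice(parmap, "taut")] <- gt
  }
  out[, vslice(parmap, "b")] <- pick("b")
  if (length(parmap$sig_free)) {
    out[, vslice(parmap, "sigma")] <- pick("sigma")[, parmap$sig_free, drop = FALSE]
  }
  if (parmap$M) out[, vslice(parmap, "theta")] <- pick("theta")
  out[, vslice(parmap, "delta")] <- pick("delta")
  if (parmap$optout_latents) out[, vslice(parmap, "phi")] <- pick("phi")
  if (vec_in) drop(out) else out
}
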