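# Shared fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

# one modest-quality study design reused across tests (1 restart is enough
# for fixture purposes; design-quality properties are tested separately)
fx_design <- function() {
  if (is.null(.fx$design)) {
    .fx$design <- generate_design(huimin_attributes(), n_restarts = 1L,
                                  seed = 7L)
  }
  .fx$design
}

fx_survey <- function(n = 200L, seed = 1L, params = default_true_params(),
                      inattentive_fraction = 67 / 1203) {
  simulate_survey(n, fx_design(), params = params, seed = seed,
                  inattentive_fraction = inattentive_fraction)
}

# two-attribute toy dictionary (binary linear attributes with opposing
# preference signs, so that enough mutually non-dominated pairs exist to
# identify the utility-neutral design) for exhaustive-search comparisons
toy_attrs2 <- function() {
  attribute_dictionary(list(
    a1 = list(levels = c(0, 1), coding = "linear", sign = "+", unit_scale = 1),
    a2 = list(levels = c(0, 1), coding = "linear", sign = "-", unit_scale = 1)))
}

toy_attrs3 <- function() {
  attribute_dictionary(list(
    a1 = list(levels = c(0, 1, 2), coding = "linear", sign = "+", unit_scale = 1),
    a2 = list(levels = c(0, 1), coding = "linear", sign = "-", unit_scale = 1),
    a3 = list(levels = c("x", "y", "z"), coding = "dummy",
              reference_level = "x", sign = "ref")))
}

# Independent D-error oracle under zero priors: all MNL probabilities equal
# 1/3 (two insurance alternatives plus opt-out), information accumulated by
# explicit matrix arithmetic.
oracle_derror_neutral <- function(design, attrs) {
  sets <- design$sets[!design$sets$is_qc, , drop = FALSE]
  Xc <- code_profiles(sets, attrs)
  K <- ncol(Xc) + 1L
  info <- matrix(0, K, K)
  p <- rep(1 / 3, 3)
  Wp <- diag(p) - p %*% t(p)
  for (sid in unique(sets$set_id)) {
    rows <- which(sets$set_id == sid)
    X <- rbind(cbind(Xc[rows, , drop = FALSE], c(0, 0)),
               c(rep(0, ncol(Xc)), 1))
    info <- info + t(X) %*% Wp %*% X
  }
  det(info)^(-1 / K)
}

# closed-form MNL log-likelihood computed by direct arithmetic (independent
# of the likelihood engine)
oracle_mnl_loglik <- function(dataset, b, delta) {
  ch <- dataset$choices[!dataset$choices$is_qc, , drop = FALSE]
  ll <- 0
  for (key in unique(paste(ch$id, ch$set_id))) {
    task <- ch[paste(ch$id, ch$set_id) == key, , drop = FALSE]
    task <- task[order(task$alt_id), , drop = FALSE]
    u <- as.matrix(task[names(b)]) %*% b
    u[task$alt_id == 3] <- delta
    p <- exp(u - max(u)); p <- p / sum(p)
    ll <- ll + log(p[task$chosen == 1])
  }
  ll
}

# closed-form ordered-logit measurement log-likelihood for zero loadings:
# category probabilities depend on thresholds only
oracle_measurement_loglik_zero_loadings <- function(dataset, tau) {
  imap <- indicator_map()
  ll <- 0
  for (ind in names(imap)) {
    y <- dataset$indicators[[ind]]
    cuts <- c(-Inf, tau[ind, ], Inf)
    pk <- diff(plogis(cuts))
    ll <- ll + sum(log(pk[y]))
  }
  ll
}

fd_gradient <- function(f, v, h_rel = 1e-6) {
  vapply(seq_along(v), function(j) {
    h <- h_rel * max(1, abs(v[j]))
    vp <- v; vp[j] <- vp[j] + h
    vm <- v; vm[j] <- vm[j] - h
    (f(vp) - f(vm)) / (2 * h)
  }, numeric(1))
}
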