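#' Sample synthetic respondent covariates
#'
#' Independent Bernoulli draws for the binary covariates and one multinomial
#' draw over the three ordered age bands per respondent, with the default
#' proportions of [default_covariate_proportions()]. Education and income are
#' sampled for the descriptive table but do not enter the structural or
#' choice models.
#'
#' @param n Number of respondents.
#' @param proportions List as returned by [default_covariate_proportions()].
#' @param seed Integer seed; draws are deterministic given the seed.
#' @return Data frame with columns `id`, `gender`, `age_band` (factor
#'   `young`/`mid`/`old`), `age_mid`, `age_old`, `residence`, `education`,
#'   `income`, `private_insurance`, `catastrophic`.
#' @export
sample_covariates <- function(n, proportions = default_covariate_proportions(),
                              seed = 1L) {
  p <- proportions
  for (f in c("gender", "residence", "education", "income",
              "private_insurance", "catastrophic")) {
    v <- p[[f]]
    if (is.null(v) || !is.numeric(v) || v < 0 || v > 1) {
      stop("invalid probability for field '", f, "'")
    }
  }
  if (length(p$age_bands) != 3 || any(p$age_bands < 0) ||
      abs(sum(p$age_bands) - 1) > 1e-8) {
    stop("invalid probability for field 'age_bands' (must be 3 values summing to 1)")
  }
  rs <- local_rng(seed)
  bern <- function(prob) as.integer(rs$runif(n) < prob)
  gender <- bern(p$gender)
  residence <- bern(p$residence)
  education <- bern(p$education)
  income <- bern(p$income)
  private_insurance <- bern(p$private_insurance)
  catastrophic <- bern(p$catastrophic)
  u <- rs$runif(n)
  cuts <- cumsum(p$age_bands)
  age_band <- factor(ifelse(u < cuts[1], "young", ifelse(u < cuts[2], "mid", "old")),
                     levels = c("young", "mid", "old"))
  data.frame(id = seq_len(n), gender = gender, age_band = age_band,
             age_mid = as.integer(age_band == "mid"),
             age_old = as.integer(age_band == "old"),
             residence = residence, education = education, income = income,
             private_insurance = private_insurance,
             catastrophic = catastrophic, stringsAsFactors = FALSE)
}

# N x 6 structural covariate matrix in canonical order
covariate_matrix <- function(respondents) {
  covs <- structural_covariates()
  miss <- setdiff(covs, names(respondents))
  if (length(miss)) stop("respondents lack covariate(s): ", paste(miss, collapse = ", "))
  as.matrix(respondents[covs])
}

#' Simulate the three latent constructs
#'
#' Evaluates the sequential structural recursion with independent standard
#' normal disturbances:
#' `HR = gamma_HR'z + e1`, `AW = gamma_AW'z + lambda_hr_aw HR + e2`,
#' `VAL = gamma_VAL'z + lambda_hr_val HR + lambda_aw_val AW + e3`.
#'
#' @param respondents Covariate data frame from [sample_covariates()].
#' @param params An `hcm_params`.
#' @param seed Integer seed.
#' @return Data frame with columns `id`, `HR`, `AW`, `VAL`.
#' @export
simulate_latents <- function(respondents, params, seed = 1L) {
  Z <- covariate_matrix(respondents)
  n <- nrow(Z)
  rs <- local_rng(seed)
  e <- matrix(rs$rnorm(3L * n), n, 3)
  HR <- drop(Z %*% params$gamma["HR", ]) + e[, 1]
  AW <- drop(Z %*% params$gamma["AW", ]) + params$lambda[["hr_aw"]] * HR + e[, 2]
  VAL <- drop(Z %*% params$gamma["VAL", ]) + params$lambda[["hr_val"]] * HR +
    params$lambda[["aw_val"]] * AW + e[, 3]
  data.frame(id = respondents$id, HR = HR, AW = AW, VAL = VAL)
}

#' Ordered-logit category probabilities
#'
#' `P(Y = k) = plogis(tau_k - eta) - plogis(tau_{k-1} - eta)` with
#' `tau_0 = -Inf`, `tau_K = Inf`, for linear predictor `eta = zeta * LV`.
#'
#' @param eta Numeric vector of linear predictor values.
#' @param tau Strictly increasing threshold vector (length K-1 for K
#'   categories).
#' @return Matrix `length(eta)` x `K` of category probabilities (rows sum
#'   to 1).
#' @export
ordered_logit_probs <- function(eta, tau) {
  if (any(diff(tau) <= 0)) stop("thresholds must be strictly increasing")
  cum <- vapply(tau, function(t) plogis(t - eta), numeric(length(eta)))
  cum <- matrix(cum, nrow = length(eta))
  cbind(cum[, 1, drop = FALSE], cum[, -1, drop = FALSE] - cum[, -ncol(cum), drop = FALSE],
        1 - cum[, ncol(cum)])
}

#' Simulate the 11 five-point Likert indicators
#'
#' Each indicator is an ordered-logit draw with loading `zeta_i` on its
#' construct and thresholds `tau_i`.
#'
#' @param latents Data frame from [simulate_latents()].
#' @param params An `hcm_params`.
#' @param seed Integer seed.
#' @return Data frame with `id` and the 11 indicator columns, values 1-5.
#' @export
simulate_indicators <- function(latents, params, seed = 1L) {
  imap <- indicator_map()
  n <- nrow(latents)
  rs <- local_rng(seed)
  out <- data.frame(id = latents$id)
  for (ind in names(imap)) {
    tau <- params$tau[ind, ]
    if (any(diff(tau) <= 0)) stop("non-monotone thresholds for indicator ", ind)
    eta <- params$zeta[[ind]] * latents[[imap[[ind]]]]
    u <- rs$runif(n)
    # P(Y <= k) = plogis(tau_k - eta); invert the CDF at u
    y <- rep(1L, n)
    for (k in seq_along(tau)) y <- y + as.integer(u > plogis(tau[k] - eta))
    out[[ind]] <- y
  }
  out
}

#' Simulate panel choices over the experimental design
#'
#' Respondents are assigned to design blocks in a balanced, seeded rotation.
#' Each respondent draws one random coefficient vector
#' `beta_n = b + sigma * xi_n` (shared across their six experimental tasks),
#' conditional utilities add the latent- and covariate-by-attribute
#' interaction shifts, the opt-out utility is
#' `delta + phi'(HR, AW, VAL)`, and one alternative per task is drawn from
#' the implied multinomial-logit probabilities. On the quality-control task
#' a designated `inattentive_fraction` of respondents (selected by seeded
#' sampling, exactly `round(n * inattentive_fraction)` of them) choose the
#' dominated alternative and everyone else the dominant one.
#'
#' @param respondents Covariate data frame.
#' @param latents Data frame from [simulate_latents()].
#' @param design A `choice_design` containing a QC set.
#' @param params An `hcm_params`.
#' @param seed Integer seed.
#' @param inattentive_fraction Fraction of respondents that fail the QC task.
#' @return List with `choices` (long data frame: `id`, `set_id`, `block_id`,
#'   `alt_id`, `is_qc`, `optout`, coded attribute columns, `chosen`) and
#'   `blocks` (block id per respondent).
#' @export
simulate_choices <- function(respondents, latents, design, params, seed = 1L,
                             inattentive_fraction = 0) {
  n <- nrow(respondents)
  attrs <- design$attrs
  cn <- coded_names(attrs)
  stopifnot(identical(names(params$b), cn))
  rs <- local_rng(seed)
  blocks_avail <- sort(unique(design$sets$block_id[!design$sets$is_qc]))
  block_of <- rep(blocks_avail, length.out = n)[rs$sample(n, n)]
  n_fail <- round(n * inattentive_fraction)
  fail_ids <- if (n_fail > 0) respondents$id[rs$sample(n, n)][seq_len(n_fail)] else integer(0)

  exp_sets <- design$sets[!design$sets$is_qc, , drop = FALSE]
  qc_sets <- design$sets[design$sets$is_qc, , drop = FALSE]
  if (nrow(qc_sets) == 0) stop("design has no QC set")
  coded_exp <- code_profiles(exp_sets, attrs)
  Z <- covariate_matrix(respondents)
  LV <- as.matrix(latents[latent_names()])
  K <- length(cn)

  # per-respondent effective coefficients: b + sigma*xi + theta shifts
  xi <- matrix(rs$rnorm(n * K), n, K)
  C <- matrix(rep(params$b, each = n), n, K) +
    xi * matrix(rep(params$sigma, each = n), n, K)
  colnames(C) <- cn
  if (nrow(params$theta)) {
    W <- cbind(LV, Z)  # columns HR, AW, VAL, covariates
    for (m in seq_len(nrow(params$theta))) {
      C[, params$theta$level[m]] <- C[, params$theta$level[m]] +
        params$theta$value[m] * W[, params$theta$var[m]]
    }
  }
  v_opt <- params$delta + drop(LV %*% params$phi)

  res <- vector("list", n)
  for (i in seq_len(n)) {
    b <- block_of[i]
    rows <- which(exp_sets$block_id == b)
    sets_i <- exp_sets[rows, , drop = FALSE]
    coded_i <- coded_exp[rows, , drop = FALSE]
    sids <- unique(sets_i$set_id)
    v_ins <- matrix(drop(coded_i %*% C[i, ]), ncol = 2, byrow = TRUE)
    u <- cbind(v_ins, v_opt[i])
    p <- exp(u - apply(u, 1, max))
    p <- p / rowSums(p)
    cum <- t(apply(p, 1, cumsum))
    draw <- rs$runif(length(sids))
    pick <- 1L + rowSums(cum < draw)  # compares per row
    qc_pick <- if (respondents$id[i] %in% fail_ids) 2L else 1L
    df <- data.frame(
      id = respondents$id[i],
      set_id = c(rep(sids, each = 3), rep(qc_sets$set_id[1], 3)),
      block_id = b,
      alt_id = rep(1:3, length(sids) + 1L),
      is_qc = c(rep(FALSE, 3 * length(sids)), rep(TRUE, 3)),
      stringsAsFactors = FALSE)
    df$optout <- as.integer(df$alt_id == 3L)
    coded_all <- matrix(0, nrow(df), K, dimnames = list(NULL, cn))
    ins_rows <- df$alt_id != 3L & !df$is_qc
    coded_all[ins_rows, ] <- coded_i
    coded_all[df$is_qc & df$alt_id != 3L, ] <- code_profiles(qc_sets, attrs)
    chosen <- integer(nrow(df))
    for (t in seq_along(sids)) chosen[3 * (t - 1) + pick[t]] <- 1L
    chosen[df$is_qc][qc_pick] <- 1L
    df$chosen <- chosen
    res[[i]] <- cbind(df, coded_all)
  }
  choices <- do.call(rbind, res)
  rownames(choices) <- NULL
  list(choices = choices, blocks = block_of, inattentive_ids = fail_ids)
}

#' Simulate a complete synthetic survey dataset
#'
#' Runs [sample_covariates()], [simulate_latents()],
#' [simulate_indicators()] and [simulate_choices()] with sub-seeds derived
#' deterministically from `seed`, and bundles the results with the design.
#'
#' @param n Number of respondents (the study fielded 1203 completers).
#' @param design A `choice_design`.
#' @param params An `hcm_params` (default [default_true_params()]).
#' @param proportions Covariate proportions.
#' @param seed Integer seed.
#' @param inattentive_fraction Fraction failing the QC task (default 67/1203,
#'   the observed inattention rate).
#' @return Object of class `survey_dataset`: list with `respondents`,
#'   `indicators`, `choices`, `design`, `seed`; the true latents are kept in
#'   `latents` for simulation diagnostics only.
#' @export
simulate_survey <- function(n = 1203L, design, params = default_true_params(),
                            proportions = default_covariate_proportions(),
                            seed = 1L, inattentive_fraction = 67 / 1203) {
  respondents <- sample_covariates(n, proportions, seed = seed * 7L + 1L)
  latents <- simulate_latents(respondents, params, seed = seed * 7L + 2L)
  indicators <- simulate_indicators(latents, params, seed = seed * 7L + 3L)
  ch <- simulate_choices(respondents, latents, design, params,
                         seed = seed * 7L + 4L,
                         inattentive_fraction = inattentive_fraction)
  respondents$block_id <- ch$blocks
  structure(list(respondents = respondents, indicators = indicators,
                 choices = ch$choices, design = design, latents = latents,
                 seed = seed, inattentive_ids = ch$inattentive_ids),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("Survey dataset:", nrow(x$respondents), "respondents,",
      sum(!x$choices$is_qc & x$choices$alt_id == 1), "experimental tasks,",
      ncol(x$indicators) - 1L, "Likert indicators\n")
  invisible(x)
}

#' Write / read a survey dataset as three CSV files plus a YAML manifest
#'
#' Writes `respondents.csv`, `indicators.csv`, `choices.csv`,
#' `design.csv` and `manifest.yaml` (seed and provenance) into `dir`.
#'
#' @param dataset A `survey_dataset`.
#' @param dir Output directory (created if needed).
#' @export
write_survey <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(dataset$respondents, file.path(dir, "respondents.csv"), row.names = FALSE)
  write.csv(dataset$indicators, file.path(dir, "indicators.csv"), row.names = FALSE)
  write.csv(dataset$choices, file.path(dir, "choices.csv"), row.names = FALSE)
  write_design(dataset$design, file.path(dir, "design.csv"))
  yaml::write_yaml(list(seed = dataset$seed,
                        n_respondents = nrow(dataset$respondents),
                        generator = "hcmdce synthetic survey",
                        files = c("respondents.csv", "indicators.csv",
                                  "choices.csv", "design.csv")),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_survey
#' @param attrs Attribute dictionary for re-reading the design.
#' @export
read_survey <- function(dir, attrs = huimin_attributes()) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  structure(list(
    respondents = read.csv(file.path(dir, "respondents.csv"), stringsAsFactors = FALSE),
    indicators = read.csv(file.path(dir, "indicators.csv"), stringsAsFactors = FALSE),
    choices = read.csv(file.path(dir, "choices.csv"), stringsAsFactors = FALSE),
    design = read_design(file.path(dir, "design.csv"), attrs),
    latents = NULL, seed = man$seed), class = "survey_dataset")
}
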