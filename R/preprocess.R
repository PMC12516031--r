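#' Apply the dominance quality-control filter
#'
#' A respondent is excluded if and only if their choice on the
#' quality-control task is the dominated alternative (the profile that is
#' weakly worse on every attribute). Choosing the dominant alternative or the
#' opt-out retains the respondent.
#'
#' @param dataset A `survey_dataset` whose design contains a QC set.
#' @return List with `retained` and `excluded` respondent ids,
#'   `n_excluded`, and `dataset` (the filtered `survey_dataset`, QC task
#'   records retained for audit).
#' @export
apply_qc_filter <- function(dataset) {
  ch <- dataset$choices
  qc <- ch[ch$is_qc & ch$chosen == 1L, , drop = FALSE]
  ids <- dataset$respondents$id
  miss <- setdiff(ids, qc$id)
  if (length(miss)) stop("missing QC record for respondent(s): ",
                         paste(head(miss, 5), collapse = ", "))
  # identify the dominated alternative of the QC set from the design
  qs <- dataset$design$sets[dataset$design$sets$is_qc, , drop = FALSE]
  attrs <- dataset$design$attrs
  p1 <- qs[qs$alt_id == 1, names(attrs$attributes), drop = FALSE]
  p2 <- qs[qs$alt_id == 2, names(attrs$attributes), drop = FALSE]
  dominated_alt <- if (is_dominated(p2, p1, attrs)) 2L else if (is_dominated(p1, p2, attrs)) 1L else
    stop("QC set does not contain a dominated alternative")
  excluded <- qc$id[qc$alt_id == dominated_alt]
  retained <- setdiff(ids, excluded)
  out <- dataset
  out$respondents <- dataset$respondents[dataset$respondents$id %in% retained, , drop = FALSE]
  out$indicators <- dataset$indicators[dataset$indicators$id %in% retained, , drop = FALSE]
  out$choices <- ch[ch$id %in% retained, , drop = FALSE]
  if (!is.null(dataset$latents)) {
    out$latents <- dataset$latents[dataset$latents$id %in% retained, , drop = FALSE]
  }
  list(retained = retained, excluded = excluded,
       n_excluded = length(excluded), dataset = out)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Descriptive statistics table
#'
#' Counts and percentages for each binary/categorical respondent covariate
#' (both coding levels reported, like a published descriptives table) and,
#' for each Likert scale, the mean and SD of respondent-level indicator
#' averages.
#'
#' @param dataset A `survey_dataset` (typically after [apply_qc_filter()]).
#' @return List with `covariates` (data frame: `variable`, `level`, `n`,
#'   `percent` exact and `pct_1dp` rounded half-up to one decimal) and
#'   `scales` (data frame: `scale`, `mean`, `sd`).
#' @export
descriptives <- function(dataset) {
  r <- dataset$respondents
  if (nrow(r) == 0) stop("empty dataset")
  n <- nrow(r)
  row2 <- function(variable, level, count) {
    data.frame(variable = variable, level = level, n = count,
               percent = 100 * count / n,
               stringsAsFactors = FALSE)
  }
  binaries <- c(residence = "residence", gender = "gender",
                education = "education", income = "income",
                private_insurance = "private_insurance",
                catastrophic = "catastrophic")
  cov_rows <- list()
  for (v in binaries) {
    k <- sum(r[[v]] == 1L)
    cov_rows[[length(cov_rows) + 1L]] <- rbind(row2(v, "0", n - k), row2(v, "1", k))
  }
  for (band in levels(factor(r$age_band, levels = c("young", "mid", "old")))) {
    cov_rows[[length(cov_rows) + 1L]] <-
      row2("age_band", band, sum(r$age_band == band))
  }
  cov <- do.call(rbind, cov_rows)
  cov$pct_1dp <- round_half_up(cov$percent, 1)
  rownames(cov) <- NULL

  imap <- indicator_map()
  sc <- lapply(latent_names(), function(l) {
    items <- names(imap)[imap == l]
    avg <- rowMeans(dataset$indicators[items])
    data.frame(scale = l, mean = mean(avg), sd = sd(avg), stringsAsFactors = FALSE)
  })
  list(covariates = cov, scales = do.call(rbind, sc))
}

#' Cronbach's alpha
#'
#' Internal consistency of a multi-item scale:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`.
#' Invariant to item order; at most 1.
#'
#' @param items Numeric matrix or data frame, one column per item.
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  k <- ncol(m)
  if (k < 2) stop("Cronbach's alpha needs at least 2 items")
  vt <- var(rowSums(m))
  if (!is.finite(vt) || vt <= 0) stop("degenerate scale: zero total variance")
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / vt)
}

#' Composite reliability and average variance extracted
#'
#' For standardized loadings `lambda`:
#' `CR = (sum lambda)^2 / ((sum lambda)^2 + sum(1 - lambda^2))` and
#' `AVE = mean(lambda^2)`.
#'
#' @param loadings Numeric vector of standardized loadings in (-1, 1].
#' @return Scalar in `[0, 1]`.
#' @export
composite_reliability <- function(loadings) {
  stopifnot(all(abs(loadings) <= 1))
  s <- sum(loadings)^2
  denom <- s + sum(1 - loadings^2)
  if (denom == 0) return(0)
  s / denom
}

#' @rdname composite_reliability
#' @export
average_variance_extracted <- function(loadings) {
  stopifnot(all(abs(loadings) <= 1))
  mean(loadings^2)
}

#' Standardize ordered-logit loadings
#'
#' Converts a raw ordered-logit measurement loading `zeta` (unit-variance
#' latent, logistic error with variance `pi^2/3`) into a standardized factor
#' loading `zeta / sqrt(zeta^2 + pi^2/3)`.
#'
#' @param zeta Numeric vector of raw loadings.
#' @return Standardized loadings in (-1, 1).
#' @export
standardize_loadings <- function(zeta) {
  zeta / sqrt(zeta^2 + pi^2 / 3)
}

#' Scale reliability and validity diagnostics
#'
#' Cronbach's alpha per scale from the indicator matrix plus, when loadings
#' are supplied (raw ordered-logit loadings, standardized internally),
#' composite reliability and average variance extracted.
#'
#' @param indicators Indicator data frame (columns of [indicator_map()]).
#' @param zeta Optional named vector of raw measurement loadings.
#' @return Data frame with one row per scale: `scale`, `n_items`, `alpha`,
#'   and (if loadings given) `cr`, `ave`.
#' @export
scale_diagnostics <- function(indicators, zeta = NULL) {
  imap <- indicator_map()
  out <- lapply(latent_names(), function(l) {
    items <- names(imap)[imap == l]
    row <- data.frame(scale = l, n_items = length(items),
                      alpha = cronbach_alpha(indicators[items]),
                      stringsAsFactors = FALSE)
    if (!is.null(zeta)) {
      ls <- standardize_loadings(zeta[items])
      row$cr <- composite_reliability(ls)
      row$ave <- average_variance_extracted(ls)
    }
    row
  })
  do.call(rbind, out)
}
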