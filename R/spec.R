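#' Model specification for the hybrid choice estimator
#'
#' Declares which pieces of the integrated model are estimated: whether the
#' latent-variable component (structural equations, ordered-logit measurement
#' and opt-out latent shifts) is included, which coded attribute columns
#' carry random coefficients, and which latent/covariate-by-attribute
#' interaction terms enter the choice utilities.
#'
#' @param latent Include the latent-variable component? (default `TRUE`).
#' @param random_levels Coded column names with estimated standard
#'   deviations; default all eight.
#' @param interactions Data frame with columns `var` and `level`; default the
#'   21 interaction terms of the reference parameter set
#'   ([default_true_params()]).
#' @param optout_latents Estimate latent shifts on the opt-out utility?
#'   (default `latent`).
#' @param attrs Attribute dictionary (default [huimin_attributes()]).
#' @return Object of class `hcm_spec`.
#' @export
hcm_spec <- function(latent = TRUE, random_levels = NULL, interactions = NULL,
                     optout_latents = latent, attrs = huimin_attributes()) {
  cn <- coded_names(attrs)
  if (is.null(random_levels)) random_levels <- cn
  stopifnot(all(random_levels %in% cn))
  if (is.null(interactions)) {
    interactions <- if (latent) default_true_params()$theta[c("var", "level")]
                    else data.frame(var = character(), level = character(),
                                    stringsAsFactors = FALSE)
  }
  interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
  if (nrow(interactions)) {
    stopifnot(all(c("var", "level") %in% names(interactions)))
    ok <- interactions$var %in% c(latent_names(), structural_covariates())
    if (!all(ok)) stop("unknown interaction variable: ", interactions$var[!ok][1])
    stopifnot(all(interactions$level %in% cn))
    if (!latent && any(interactions$var %in% latent_names())) {
      stop("latent interactions require latent = TRUE")
    }
  }
  if (optout_latents && !latent) stop("optout_latents requires latent = TRUE")
  structure(list(latent = latent, random_levels = random_levels,
                 interactions = interactions[c("var", "level")],
                 optout_latents = optout_latents, attrs = attrs),
            class = "hcm_spec")
}

#' @export
print.hcm_spec <- function(x, ...) {
  cat("HCM specification:", if (x$latent) "latent + choice" else "choice only",
      "\n  random levels:", paste(x$random_levels, collapse = ", "),
      "\n  interactions:", nrow(x$interactions),
      "| opt-out latent shifts:", x$optout_latents, "\n")
  invisible(x)
}

#' Main-effects mixed logit specification
#'
#' The heterogeneity-check model: random coefficients on every coded
#' attribute column, an opt-out constant, no latent component and no
#' interactions.
#'
#' @param attrs Attribute dictionary.
#' @return An `hcm_spec` with `latent = FALSE`.
#' @export
main_effects_spec <- function(attrs = huimin_attributes()) {
  hcm_spec(latent = FALSE, random_levels = coded_names(attrs),
           interactions = data.frame(var = character(), level = character(),
                                     stringsAsFactors = FALSE),
           optout_latents = FALSE, attrs = attrs)
}

#' Enumerate candidate interaction terms
#'
#' The full cross of attribute levels showing preference heterogeneity with
#' the interacting variables. With the study's defaults — the seven coded
#' levels whose main-effects mixed-logit standard deviations were
#' significant (all but moderate government involvement) crossed with nine
#' variables (three latent constructs and six socio-demographic covariates)
#' — this yields 63 candidate terms.
#'
#' @param levels Coded attribute columns to interact (default the seven
#'   significant-SD levels).
#' @param variables Interacting variables (default latents plus covariates).
#' @return Data frame with columns `var` and `level`.
#' @export
candidate_interactions <- function(levels = NULL, variables = NULL) {
  if (is.null(levels)) {
    levels <- setdiff(coded_names(huimin_attributes()), "government_moderate")
  }
  if (is.null(variables)) variables <- c(latent_names(), structural_covariates())
  out <- expand.grid(var = variables, level = levels, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out[c("var", "level")]
}
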