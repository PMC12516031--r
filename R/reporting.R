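#' Default pipeline configuration
#'
#' Study-scale defaults: 1203 completers with a 67/1203 inattention rate, a
#' 24-set four-block design, 500 scrambled Halton draws.
#'
#' @param ... Named overrides of the default fields.
#' @return Nested list understood by [run_pipeline()].
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 20230901L,
    n_respondents = 1203L,
    inattentive_fraction = 67 / 1203,
    params_file = NULL,
    design = list(n_sets = 24L, n_blocks = 4L, n_restarts = 20L),
    draws = list(scheme = "halton", n_draws = 500L),
    fit = list(model = "hcm", se = TRUE, maxit = 1000L),
    out_dir = "hcmdce-run")
  utils::modifyList(cfg, list(...))
}

#' Render estimation results as publication-style tables
#'
#' Produces the latent-variable table (structural weights and measurement
#' loadings) and the choice-model table (means, standard deviations,
#' interactions, opt-out block), each with estimate, robust SE, two-sided
#' normal p-value and significance stars at the 1/5/10% levels. Reference
#' levels of the categorical attributes are printed as `"ref"` rows without
#' estimates.
#'
#' @param fit An `hcm_fit`.
#' @return List of data frames `latent` (absent for a choice-only fit) and
#'   `choice`.
#' @export
render_tables <- function(fit) {
  nm <- fit$parmap_names
  se <- if (fit$se_available) fit$robust_se else rep(NA_real_, length(nm))
  row_of <- function(label, vname, est) {
    s <- se[match(vname, nm)]
    ps <- p_and_stars(est, s)
    data.frame(term = label, estimate = est, robust_se = s,
               p = ps$p, stars = ps$stars, stringsAsFactors = FALSE)
  }
  est <- fit$estimates
  out <- list()
  if (fit$spec$latent) {
    rows <- list()
    for (l in rownames(est$gamma)) for (cv in colnames(est$gamma)) {
      rows[[length(rows) + 1L]] <-
        row_of(paste0(l, " ~ ", cv), paste0("gamma.", l, ".", cv), est$gamma[l, cv])
    }
    lam_lab <- c(hr_aw = "AW ~ HR", hr_val = "VAL ~ HR", aw_val = "VAL ~ AW")
    for (k in names(est$lambda)) {
      rows[[length(rows) + 1L]] <-
        row_of(lam_lab[[k]], paste0("lambda.", k), est$lambda[[k]])
    }
    for (i in names(est$zeta)) {
      rows[[length(rows) + 1L]] <-
        row_of(paste0("loading ", i), paste0("zeta.", i), est$zeta[[i]])
    }
    out$latent <- do.call(rbind, rows)
  }
  rows <- list()
  attrs <- fit$spec$attrs
  for (a in names(attrs$attributes)) {
    at <- attrs$attributes[[a]]
    if (at$coding == "dummy") {
      rows[[length(rows) + 1L]] <- data.frame(
        term = paste0(a, ": ", at$reference_level, " (ref)"),
        estimate = NA_real_, robust_se = NA_real_, p = NA_real_, stars = "ref",
        stringsAsFactors = FALSE)
      for (lev in setdiff(at$levels, at$reference_level)) {
        cnk <- paste0(a, "_", lev)
        rows[[length(rows) + 1L]] <- row_of(paste0(a, ": ", lev, " (mean)"),
                                            paste0("b.", cnk), est$b[[cnk]])
        if (cnk %in% fit$spec$random_levels) {
          rows[[length(rows) + 1L]] <- row_of(paste0(a, ": ", lev, " (SD)"),
                                              paste0("sigma.", cnk),
                                              est$sigma[[cnk]])
        }
      }
    } else {
      rows[[length(rows) + 1L]] <- row_of(paste0(a, " (mean)"),
                                          paste0("b.", a), est$b[[a]])
      if (a %in% fit$spec$random_levels) {
        rows[[length(rows) + 1L]] <- row_of(paste0(a, " (SD)"),
                                            paste0("sigma.", a), est$sigma[[a]])
      }
    }
  }
  rows[[length(rows) + 1L]] <- row_of("opt-out ASC", "delta", est$delta)
  if (fit$spec$latent && fit$spec$optout_latents) {
    for (l in names(est$phi)) {
      rows[[length(rows) + 1L]] <- row_of(paste0(l, " x opt-out"),
                                          paste0("phi.", l), est$phi[[l]])
    }
  }
  if (nrow(fit$spec$interactions)) {
    th <- est$theta
    for (m in seq_len(nrow(th))) {
      rows[[length(rows) + 1L]] <- row_of(
        paste0(th$var[m], " x ", th$level[m]),
        paste0("theta.", th$var[m], ":", th$level[m]), th$value[m])
    }
  }
  out$choice <- do.call(rbind, rows)
  rownames(out$choice) <- NULL
  if (!is.null(out$latent)) rownames(out$latent) <- NULL
  out
}

log_stage <- function(run_log, stage, t0, msg = "") {
  dt <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  line <- sprintf("[%s] %s (%.2fs) %s", format(Sys.time(), "%H:%M:%S"),
                  stage, dt, msg)
  message(line)
  c(run_log, line)
}

#' Run the full analysis pipeline
#'
#' Orchestrates design generation, survey simulation, quality-control
#' filtering, descriptive and reliability diagnostics, model fitting and
#' table rendering, writing every artifact plus a manifest of seeds and file
#' hashes into the configured output directory. Re-running with the same
#' configuration reproduces all numeric outputs bit-for-bit. Any stage
#' failure aborts with the stage name and cause.
#'
#' @param config A list from [pipeline_config()] or the path of a YAML file
#'   with the same fields.
#' @return (Invisibly) list with the run directory and the in-memory
#'   artifacts (`design`, `dataset`, `qc`, `descriptives`, `diagnostics`,
#'   `fit`, `tables`, `wtp`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(pipeline_config(), config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  run_log <- character(0)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    run_log <<- log_stage(run_log, name, t0)
    res
  }
  attrs <- huimin_attributes()
  params <- if (!is.null(config$params_file)) read_params(config$params_file)
            else default_true_params()

  design <- stage("design", generate_design(
    attrs, n_sets = config$design$n_sets, n_blocks = config$design$n_blocks,
    seed = config$seed, n_restarts = config$design$n_restarts))
  write_design(design, file.path(config$out_dir, "design.csv"))

  dataset <- stage("simulate", simulate_survey(
    n = config$n_respondents, design = design, params = params,
    seed = config$seed, inattentive_fraction = config$inattentive_fraction))
  write_survey(dataset, file.path(config$out_dir, "dataset"))

  qc <- stage("filter", apply_qc_filter(dataset))
  writeLines(c(
    sprintf("respondents completing: %d", nrow(dataset$respondents)),
    sprintf("excluded (dominated QC choice): %d", qc$n_excluded),
    sprintf("retained: %d", length(qc$retained))),
    file.path(config$out_dir, "qc_report.txt"))

  desc <- stage("descriptives", descriptives(qc$dataset))
  write.csv(desc$covariates, file.path(config$out_dir, "descriptives.csv"),
            row.names = FALSE)
  write.csv(desc$scales, file.path(config$out_dir, "scale_means.csv"),
            row.names = FALSE)

  diag <- stage("diagnose", scale_diagnostics(qc$dataset$indicators,
                                              zeta = params$zeta))
  write.csv(diag, file.path(config$out_dir, "scale_diagnostics.csv"),
            row.names = FALSE)

  draws <- draw_config(config$draws$scheme, config$draws$n_draws,
                       seed = config$seed + 1L)
  control <- list(se = isTRUE(config$fit$se), maxit = config$fit$maxit)
  fit <- stage("fit", {
    if (identical(config$fit$model, "hcm")) {
      fit_hcm(qc$dataset, draws = draws, control = control)
    } else {
      fit_mixed_logit(qc$dataset, draws = draws, control = control)
    }
  })
  tables <- stage("report", render_tables(fit))
  if (!is.null(tables$latent)) {
    write.csv(tables$latent, file.path(config$out_dir, "table_latent.csv"),
              row.names = FALSE)
  }
  write.csv(tables$choice, file.path(config$out_dir, "table_choice.csv"),
            row.names = FALSE)
  wtp_tab <- wtp(fit)
  write.csv(wtp_tab, file.path(config$out_dir, "wtp.csv"), row.names = FALSE)

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  # run.log carries wall times; keep it out of the reproducibility manifest
  files <- setdiff(files, file.path(config$out_dir, c("manifest.yaml", "run.log")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("hcmdce")),
    seed = config$seed,
    draw_seed = draws$seed,
    n_respondents = config$n_respondents,
    n_retained = length(qc$retained),
    loglik = fit$loglik,
    converged = fit$converged,
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  writeLines(run_log, file.path(config$out_dir, "run.log"))
  invisible(list(dir = config$out_dir, design = design, dataset = dataset,
                 qc = qc, descriptives = desc, diagnostics = diag, fit = fit,
                 tables = tables, wtp = wtp_tab, manifest = manifest))
}
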