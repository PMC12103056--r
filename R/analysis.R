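#' Measure families of the analysis stage
#'
#' The two Holm families: the central-auditory measures (dichotic scores,
#' right ear advantage, speech-in-noise, four temporal-processing
#' thresholds) and the cognitive measures (digit span, trail making,
#' mental rotation, attention network effects). `efa_measure_set()` is
#' the variable set entering the per-group factor analysis (hearing
#' thresholds plus all behavioral measures except the derived REA).
#'
#' @return Character vector of cohort column names.
#' @export
auditory_measure_set <- function() {
  c("dcs", "total_r", "total_l", "forced_rcs", "forced_lcs", "rea",
    "quicksin", "fmdl", "mdt", "attr", "tfs_af")
}

#' @rdname auditory_measure_set
#' @export
cognitive_measure_set <- function() {
  c("dsf_rt", "dsb_rt", "dsf_len", "dsb_len", "tmt_number", "tmt_mixed",
    "mrt_mirror_acc", "mrt_nonmirror_acc", "mrt_mirror_rt",
    "mrt_nonmirror_rt", "alerting", "orienting", "conflict")
}

#' @rdname auditory_measure_set
#' @export
efa_measure_set <- function() {
  c("pta_right", "pta_left", "pta_speech_right", "pta_speech_left",
    "dcs", "total_r", "total_l", "forced_rcs", "forced_lcs", "quicksin",
    "fmdl", "attr", "mdt", "tfs_af",
    "dsf_rt", "dsf_len", "dsb_rt", "dsb_len", "tmt_number", "tmt_mixed",
    "mrt_mirror_rt", "mrt_mirror_acc", "mrt_nonmirror_rt",
    "mrt_nonmirror_acc", "alerting", "orienting", "conflict")
}

#' Regression model specifications
#'
#' The four models predicting MoCA in the MCI subset: 1 dichotic (DCS,
#' REA), 2 speech-in-noise, 3 temporal processing (FMDL, ATTR, MDT,
#' TFS-AF), 4 covariates (gender, education, bilateral PTA).
#'
#' @return Named list of predictor vectors.
#' @export
regression_model_specs <- function() {
  list(
    dichotic = c("dcs", "rea"),
    quicksin = "quicksin",
    temporal = c("fmdl", "attr", "mdt", "tfs_af"),
    covariates = c("gender_male", "education", "pta_bilateral"))
}

#' Analysis configuration
#'
#' @param efa_factors named vector: factors to extract per group.
#' @param loading_cutoff EFA exclusion threshold.
#' @param alpha family-wise significance level.
#' @param power_d,power_alpha,power_target,power_tails,dropout_rate
#'   parameters of the recomputed power analysis.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(efa_factors = c(MCI = 3, control = 4),
                            loading_cutoff = 0.4, alpha = 0.05,
                            power_d = 0.8, power_alpha = 0.05,
                            power_target = 0.90, power_tails = 1,
                            dropout_rate = 0.25) {
  structure(
    list(efa_factors = efa_factors, loading_cutoff = loading_cutoff,
         alpha = alpha, power_d = power_d, power_alpha = power_alpha,
         power_target = power_target, power_tails = power_tails,
         dropout_rate = dropout_rate),
    class = "analysis_config"
  )
}

validate_cohort_schema <- function(cohort, require_moca = TRUE) {
  need <- c("id", "group", "gender", "education",
            auditory_measure_set(), cognitive_measure_set(),
            "pta_right", "pta_left")
  if (require_moca) need <- c(need, "moca")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort schema error; missing columns: ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

group_descriptives <- function(cohort, measures) {
  rows <- lapply(measures, function(m) {
    do.call(rbind, lapply(c("MCI", "control"), function(g) {
      x <- cohort[[m]][cohort$group == g]
      data.frame(measure = m, group = g, n = length(x),
                 median = stats::median(x), iqr = stats::IQR(x),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

compare_groups <- function(cohort, measures, family) {
  rows <- lapply(measures, function(m) {
    x <- cohort[[m]][cohort$group == "MCI"]
    y <- cohort[[m]][cohort$group == "control"]
    mw <- mann_whitney_u(x, y)
    data.frame(measure = m, family = family,
               median_mci = stats::median(x), iqr_mci = stats::IQR(x),
               median_control = stats::median(y), iqr_control = stats::IQR(y),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p)
  out
}

#' Run the full statistical analysis stage
#'
#' Reproduces the analysis pipeline on a cohort table: per-group
#' descriptives (median/IQR), Mann-Whitney comparisons with Holm
#' correction applied separately within the central-auditory and
#' cognitive families, per-group minres/oblimin EFA with the 0.4-loading
#' exclusion pass (3 factors for MCI, 4 for control by default), the four
#' regression models predicting MoCA in the MCI subset, ROC analysis of
#' every central-auditory measure (MCI positive, fixed direction), and
#' the noncentral-t power computation.
#'
#' @param cohort a [generate_cohort()] table (or one read back from CSV).
#' @param config an [analysis_config()].
#' @return A list of class `capsim_report`.
#' @export
run_full_analysis <- function(cohort, config = analysis_config()) {
  validate_cohort_schema(cohort)
  cohort$gender_male <- as.numeric(cohort$gender == "male")
  cohort$pta_bilateral <- (cohort$pta_right + cohort$pta_left) / 2

  descriptives <- group_descriptives(
    cohort, c(auditory_measure_set(), cognitive_measure_set()))
  comparisons <- rbind(
    compare_groups(cohort, auditory_measure_set(), "central_auditory"),
    compare_groups(cohort, cognitive_measure_set(), "cognitive"))

  efa <- lapply(c(MCI = "MCI", control = "control"), function(g) {
    dat <- cohort[cohort$group == g, efa_measure_set()]
    efa_fit(dat, n_factors = config$efa_factors[[g]],
            loading_cutoff = config$loading_cutoff)
  })

  mci <- cohort[cohort$group == "MCI", ]
  specs <- regression_model_specs()
  regressions <- lapply(seq_along(specs), function(i) {
    hierarchical_regression(mci, "moca", specs[[i]],
                            model_id = names(specs)[i])
  })
  names(regressions) <- names(specs)

  roc <- lapply(auditory_measure_set(), function(m) {
    r <- roc_analysis(cohort[[m]], cohort$group, positive = "MCI")
    r$curve <- NULL
    c(list(measure = m), r)
  })
  names(roc) <- auditory_measure_set()

  n_grp <- power_n_per_group(config$power_d, config$power_alpha,
                             config$power_target, config$power_tails)
  power <- list(d = config$power_d, alpha = config$power_alpha,
                power = config$power_target, tails = config$power_tails,
                n_per_group = n_grp, total_n = 2L * n_grp,
                dropout_rate = config$dropout_rate,
                inflated_n = inflate_for_dropout(2L * n_grp,
                                                 config$dropout_rate))

  structure(
    list(seed = attr(cohort, "seed"),
         n = nrow(cohort),
         n_per_group = as.vector(table(cohort$group)[c("MCI", "control")]),
         config = unclass(config),
         descriptives = descriptives,
         comparisons = comparisons,
         efa = efa,
         regressions = regressions,
         roc = roc,
         power = power),
    class = "capsim_report"
  )
}

#' @export
print.capsim_report <- function(x, ...) {
  cat(sprintf("Battery analysis report: %d participants (%d MCI / %d control)\n",
              x$n, x$n_per_group[1], x$n_per_group[2]))
  sig <- x$comparisons[x$comparisons$p_holm < x$config$alpha, "measure"]
  cat("Holm-significant measures:", paste(sig, collapse = ", "), "\n")
  for (g in names(x$efa)) {
    e <- x$efa[[g]]
    cat(sprintf("EFA %s: %d factors, KMO %.3f, Bartlett chi2(%d) = %.0f\n",
                g, e$n_factors, e$kmo, e$bartlett$df, e$bartlett$chisq))
  }
  m3 <- x$regressions$temporal
  cat(sprintf("Temporal regression: R2 = %.3f, F(%d, %d) = %.2f\n",
              m3$r_squared, m3$df1, m3$df2, m3$f))
  invisible(x)
}

# serializable view of a report (drops lm fit objects and matrices to lists)
report_as_list <- function(report) {
  r <- unclass(report)
  r$efa <- lapply(r$efa, function(e) {
    list(n_factors = e$n_factors,
         retained = e$retained,
         excluded = as.list(e$excluded),
         kmo = e$kmo,
         bartlett = e$bartlett,
         cumulative_variance = e$cumulative_variance,
         loadings = as.data.frame(round(e$loadings, 4)),
         phi = as.data.frame(round(e$phi, 4)),
         uniqueness = as.list(round(e$uniqueness, 4)))
  })
  r$regressions <- lapply(r$regressions, function(m) {
    list(model_id = m$model_id, n = m$n, predictors = m$predictors,
         estimate = as.list(round(m$estimate, 5)),
         se = as.list(round(m$se, 5)),
         beta_std = as.list(round(m$beta_std, 4)),
         t = as.list(round(m$t, 3)), p = as.list(round(m$p, 4)),
         r = m$r, r_squared = m$r_squared, f = m$f,
         df1 = m$df1, df2 = m$df2, p_overall = m$p_overall,
         warning = m$warning)
  })
  r
}

#' Write an analysis report as JSON and Markdown
#'
#' @param report a `capsim_report`.
#' @param json_path,md_path output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, json_path = NULL, md_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(report_as_list(report), json_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  if (!is.null(md_path)) {
    lines <- c(
      "# Battery analysis report",
      sprintf("Participants: %d (%d MCI / %d control); seed %s",
              report$n, report$n_per_group[1], report$n_per_group[2],
              report$seed %||% "NA"),
      "", "## Group comparisons (Mann-Whitney, Holm within family)", "")
    cmp <- report$comparisons
    lines <- c(lines,
      "| measure | family | MCI median (IQR) | control median (IQR) | U | p | Holm p |",
      "|---|---|---|---|---|---|---|",
      sprintf("| %s | %s | %.3g (%.3g) | %.3g (%.3g) | %.1f | %.4f | %.4f |",
              cmp$measure, cmp$family, cmp$median_mci, cmp$iqr_mci,
              cmp$median_control, cmp$iqr_control, cmp$U, cmp$p, cmp$p_holm))
    for (g in names(report$efa)) {
      e <- report$efa[[g]]
      lines <- c(lines, "",
        sprintf("## EFA: %s group", g),
        sprintf("%d factors; KMO = %.3f; Bartlett chi2(%d) = %.1f (p = %.3g); cumulative variance %.1f%%; excluded: %s",
                e$n_factors, e$kmo, e$bartlett$df, e$bartlett$chisq,
                e$bartlett$p, 100 * e$cumulative_variance,
                if (length(e$excluded)) paste(names(e$excluded), collapse = ", ")
                else "none"))
    }
    lines <- c(lines, "", "## Regression models (MoCA, MCI subset)", "")
    for (m in report$regressions) {
      lines <- c(lines,
        sprintf("- %s: R = %.3f, R^2 = %.3f, F(%d, %d) = %.2f, p = %.3g",
                m$model_id, m$r, m$r_squared, m$df1, m$df2, m$f, m$p_overall))
    }
    lines <- c(lines, "", "## ROC (positive class: MCI)", "",
      "| measure | AUC | threshold | sensitivity % | specificity % |",
      "|---|---|---|---|---|")
    for (r in report$roc) {
      lines <- c(lines, sprintf("| %s | %.3f | %.3g | %.1f | %.1f |",
        r$measure, r$auc, r$threshold, r$sensitivity, r$specificity))
    }
    p <- report$power
    lines <- c(lines, "", "## Power",
      sprintf("d = %.2f, alpha = %.2f, power = %.2f, %d-tailed: %d per group (total %d); with %.0f%% dropout: %d",
              p$d, p$alpha, p$power, p$tails, p$n_per_group, p$total_n,
              100 * p$dropout_rate, p$inflated_n))
    writeLines(lines, md_path)
  }
  invisible(c(json = json_path, md = md_path))
}
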