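#' Pipeline configuration
#'
#' Collects the settings of every stage of the end-to-end analysis: cohort
#' simulation, feature selection, discretization, network learning,
#' prognosis prediction and arm assignment, phantom segmentation and
#' measurement, response simulation, efficacy rates and progression-free
#' survival.  Defaults reproduce the study conditions described in the
#' methods vignette.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param truth ground-truth network (default [make_ground_truth()]).
#' @param train_n training-cohort size (default 2000).
#' @param validate_n validation-cohort size (default 40).
#' @param alpha_screen,alpha_filter significance levels of the chi-square
#'   screen and the logistic filter.
#' @param mmhc list of learner settings: \code{alpha}, \code{maxk},
#'   \code{score}, \code{pseudocount}.
#' @param response per-arm response-simulation settings: for each arm a
#'   list with \code{mean_shrink} (mean fractional diameter shrinkage),
#'   \code{sd_shrink} and \code{new_lesion_p}.
#' @param pfs_median per-arm exponential PFS medians in months (hazard =
#'   ln 2 / median).
#' @param censor_time administrative censoring time in months.
#' @param recist_dialect \code{"paper"} or \code{"standard"} (see
#'   [classify_response()]).
#' @param yates Yates correction in the group comparison.
#' @param phantom_enabled run the imaging stages (default TRUE).
#' @param baseline_mm mean and sd of the simulated baseline diameter sum.
#' @param fit optional pre-fitted \code{mmhc} model: skips the simulation /
#'   selection / learning stages (used when many pipeline replicates share
#'   one model).
#' @param out_dir optional output directory; when given, every tabular
#'   artifact is written there as delimited text.
#' @export
pipeline_config <- function(seed = 1L,
                            truth = make_ground_truth(),
                            train_n = 2000L,
                            validate_n = 40L,
                            alpha_screen = 0.05,
                            alpha_filter = 0.05,
                            mmhc = list(alpha = 0.05, maxk = 3,
                                        score = "bic", pseudocount = 1),
                            response = list(
                              control = list(mean_shrink = 0.10,
                                             sd_shrink = 0.18,
                                             new_lesion_p = 0.15),
                              research = list(mean_shrink = 0.25,
                                              sd_shrink = 0.15,
                                              new_lesion_p = 0.04)),
                            pfs_median = c(control = 4.8, research = 7.1),
                            censor_time = 24,
                            recist_dialect = "paper",
                            yates = FALSE,
                            phantom_enabled = TRUE,
                            baseline_mm = c(mean = 80, sd = 15),
                            fit = NULL,
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: simulate a training cohort from the
#' ground-truth network (with independent nuisance variables from the
#' 16-variable catalog), chi-square screen, logistic filter, equidistant
#' discretization, MMHC structure and parameter learning, posterior
#' survival-status prediction for a fresh validation cohort, arm assignment
#' (predicted-good prognosis joins the research arm), simulated tumor
#' response with RECIST classification and ORR/DCR, phantom segmentation
#' and lesion measurement for one exemplar per arm and timepoint, and
#' two-arm Kaplan-Meier progression-free survival.  Re-running with the
#' same configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return object of class \code{"prognet_run"}: a list of per-stage
#'   results plus a \code{log} of stage records (name, seed, runtime).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list(config = config)
  log <- list()
  stage <- function(name, seed, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log[[length(log) + 1L]] <<- list(stage = name, seed = seed,
                                     seconds = proc.time()[["elapsed"]] - t0)
    out
  }
  truth <- config$truth
  outcome <- truth$outcome

  if (is.null(config$fit)) {
    s1 <- derive_seed(config$seed, 1L)
    res$cohort <- stage("simulate_cohort", s1, {
      add_nuisance_variables(sample_cohort(truth, config$train_n, seed = s1),
                             seed = derive_seed(config$seed, 2L))
    })
    res$screen <- stage("chi_square_screen", NA, {
      chi_square_screen(res$cohort, outcome, alpha = config$alpha_screen,
                        specs = truth$continuous)
    })
    kept <- res$screen$variable[res$screen$kept %in% TRUE]
    res$filter <- stage("logistic_filter", NA, {
      logistic_filter(res$cohort, kept, outcome,
                      alpha = config$alpha_filter)
    })
    res$selected <- res$filter$retained
    res$train_disc <- stage("discretize", NA, {
      specs <- truth$continuous[intersect(names(truth$continuous),
                                          res$selected)]
      discretize_cohort(res$cohort[, c(res$selected, outcome)], specs)
    })
    res$fit <- stage("mmhc_learn", NA, {
      mmhc(res$train_disc, outcome = outcome,
           alpha = config$mmhc$alpha, maxk = config$mmhc$maxk,
           score = config$mmhc$score,
           pseudocount = config$mmhc$pseudocount)
    })
  } else {
    res$fit <- config$fit
    res$selected <- setdiff(res$fit$nodes, outcome)
  }

  s3 <- derive_seed(config$seed, 3L)
  res$validate <- stage("simulate_validation", s3, {
    v <- sample_cohort(truth, config$validate_n, seed = s3)
    discretize_cohort(v, truth$continuous)
  })
  res$posterior <- stage("predict_prognosis", NA, {
    predict(res$fit, res$validate, type = "posterior")
  })
  good <- truth$levels[[outcome]][1L]     # first level = favourable status
  p_good <- res$posterior[, good]
  res$arm <- factor(ifelse(p_good >= 0.5, "research", "control"),
                    levels = c("control", "research"))

  s4 <- derive_seed(config$seed, 4L)
  res$assessments <- stage("simulate_response", s4, with_seed(s4, {
    n <- length(res$arm)
    base <- pmax(stats::rnorm(n, config$baseline_mm[["mean"]],
                              config$baseline_mm[["sd"]]), 20)
    shr <- vapply(seq_len(n), function(i) {
      p <- config$response[[as.character(res$arm[i])]]
      stats::rnorm(1, p$mean_shrink, p$sd_shrink)
    }, 0)
    newl <- vapply(seq_len(n), function(i) {
      p <- config$response[[as.character(res$arm[i])]]
      stats::runif(1) < p$new_lesion_p
    }, TRUE)
    fup <- pmax(base * (1 - shr), 0)
    data.frame(id = seq_len(n), arm = res$arm, baseline_mm = base,
               followup_mm = fup, new_lesion = newl)
  }))
  res$response <- stage("classify_response", NA, {
    vapply(seq_len(nrow(res$assessments)), function(i) {
      a <- res$assessments[i, ]
      as.character(classify_response(
        lesion_assessment(a$baseline_mm, a$followup_mm,
                          undetectable = FALSE, new_lesion = a$new_lesion,
                          id = a$id),
        dialect = config$recist_dialect))
    }, "")
  })
  res$efficacy <- stage("efficacy_rates", NA, {
    lapply(stats::setNames(levels(res$arm), levels(res$arm)), function(g) {
      cat <- factor(res$response[res$arm == g],
                    levels = c("CR", "PR", "SD", "PD"))
      cnt <- table(cat)
      efficacy_rates(cnt[["CR"]], cnt[["PR"]], cnt[["SD"]], cnt[["PD"]],
                     group = g)
    })
  })
  res$dcr_test <- stage("chi2_compare", NA, {
    e <- res$efficacy
    ok <- vapply(e, function(x) sum(x$counts[c("CR", "PR", "SD")]), 0)
    n <- vapply(e, function(x) x$n, 0)
    if (all(n > 0) && sum(ok) > 0 && sum(n - ok) > 0)
      chi2_compare(ok[1], n[1], ok[2], n[2], correct = config$yates)
    else NULL
  })

  s5 <- derive_seed(config$seed, 5L)
  res$followup <- stage("simulate_followup", s5, {
    sizes <- table(res$arm)
    arms <- levels(res$arm)[table(res$arm) > 0]
    simulate_followup(followup_spec(
      hazards = log(2) / config$pfs_median[arms],
      censor_time = config$censor_time,
      arm_sizes = stats::setNames(as.integer(sizes[arms]), arms),
      seed = s5))
  })
  res$km <- stage("km_curves", NA, {
    lapply(split(res$followup, res$followup$arm), km_curve)
  })

  if (isTRUE(config$phantom_enabled)) {
    s6 <- derive_seed(config$seed, 6L)
    res$imaging <- stage("phantom_segmentation", s6,
                         run_imaging_stage(s6))
  }
  res$log <- log
  class(res) <- "prognet_run"
  if (!is.null(config$out_dir)) write_run(res, config$out_dir)
  res
}

# Imaging exemplars: one phantom per arm and timepoint; the classifier is
# trained on the baseline phantom of each arm and reused at follow-up.
run_imaging_stage <- function(seed) {
  shapes <- list(
    control  = list(pre = c(6, 13, 13), post = c(5.6, 12.4, 12.4)),
    research = list(pre = c(6, 13, 13), post = c(4.2, 9.5, 9.5)))
  out <- list()
  for (arm in names(shapes)) {
    arm_out <- list()
    train_net <- NULL
    for (tp in c("pre", "post")) {
      spec <- phantom_spec(shape = c(8L, 40L, 40L), spacing = c(2.5, 1, 1),
                           semiaxes = shapes[[arm]][[tp]],
                           background = 70, lesion = 170, noise_sd = 6,
                           seed = derive_seed(seed, match(tp, c("pre", "post"))))
      ph <- make_phantom(spec)
      pre <- fuzzy_enhance(wiener_denoise(ph$image, 3L))
      if (is.null(train_net)) {
        feats <- pixel_features(pre)
        lab <- as.integer(as.vector(aperm(ph$mask, c(2, 3, 1))))
        pos <- which(lab == 1L); neg <- which(lab == 0L)
        sel <- c(pos, with_seed(derive_seed(seed, 7L),
                                sample(neg, min(length(neg), 2L * length(pos)))))
        train_net <- train_pixel_classifier(feats[sel, ], lab[sel],
                                            rate = 0.5, epochs = 30L,
                                            seed = derive_seed(seed, 8L))
      }
      mask <- segment(pre, train_net)
      meas <- measure_lesion(mask, spacing = spec$spacing)
      arm_out[[tp]] <- list(measurement = meas, truth = ph$truth)
    }
    arm_out$volume_change_cm3 <- volume_change(
      arm_out$pre$measurement$volume_cm3,
      arm_out$post$measurement$volume_cm3)
    out[[arm]] <- arm_out
  }
  out
}

#' @export
print.prognet_run <- function(x, ...) {
  cat("prognet pipeline run (seed ", x$config$seed, ")\n", sep = "")
  if (!is.null(x$selected))
    cat("  selected variables:", paste(x$selected, collapse = ", "), "\n")
  if (!is.null(x$fit))
    cat("  learned network:", sum(lengths(x$fit$parents)), "edges\n")
  cat("  arms:", paste(names(table(x$arm)), table(x$arm),
                       sep = " = ", collapse = ", "), "\n")
  for (e in x$efficacy) print(e)
  if (!is.null(x$dcr_test))
    cat(sprintf("  DCR comparison: chi2 = %.3f, p = %.3f\n",
                x$dcr_test$statistic, x$dcr_test$p))
  for (a in names(x$km))
    cat(sprintf("  %s median PFS: %s months\n", a,
                if (x$km[[a]]$median_defined)
                  sprintf("%.2f", x$km[[a]]$median) else "undefined"))
  if (!is.null(x$imaging))
    for (a in names(x$imaging))
      cat(sprintf("  %s exemplar tumor volume change: %.1f cm^3\n",
                  a, x$imaging[[a]]$volume_change_cm3))
  invisible(x)
}

# Write the tabular artifacts of a run as delimited text.
write_run <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(res$cohort)) write_cohort(res$cohort, file.path(dir, "cohort.csv"))
  if (!is.null(res$screen))
    utils::write.csv(res$screen, file.path(dir, "screen.csv"), row.names = FALSE)
  if (!is.null(res$filter))
    utils::write.csv(res$filter$table, file.path(dir, "logistic_filter.csv"),
                     row.names = FALSE)
  write_network(res$fit, file.path(dir, "network.txt"))
  pred <- data.frame(res$validate, arm = res$arm,
                     p_good = res$posterior[, 1])
  utils::write.csv(pred, file.path(dir, "predictions.csv"), row.names = FALSE)
  eff <- do.call(rbind, lapply(res$efficacy, function(e)
    data.frame(group = e$group, n = e$n, CR = e$counts[["CR"]],
               PR = e$counts[["PR"]], SD = e$counts[["SD"]],
               PD = e$counts[["PD"]], ORR = e$orr, DCR = e$dcr)))
  utils::write.csv(eff, file.path(dir, "efficacy.csv"), row.names = FALSE)
  for (a in names(res$km)) {
    utils::write.csv(
      data.frame(time = res$km[[a]]$time, surv = res$km[[a]]$surv,
                 n_risk = res$km[[a]]$n_risk),
      file.path(dir, paste0("km_", a, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}
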