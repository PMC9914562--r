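#' Configuration for the chained classification/quantification run
#'
#' @param folds,repetitions Partitioning scheme (default 10 x 10).
#' @param seed Integer seed driving all randomness of the run.
#' @param lv_max,lv_max_reg Largest candidate latent-variable count for the
#'   PLS-DA classifier and the PLS regressions (each additionally capped by
#'   the training size, the variable count and the achievable rank).
#' @param modes Evaluation modes: `"plsda_dependent"` routes each test case
#'   to the regression model of its *predicted* class, so classification
#'   errors propagate into quantification; `"known_identity"` routes by the
#'   true class, isolating the regression models' own performance.
#' @param overall_model Also fit one regression over all adulterants?
#' @param include_pure_evoo Include pure-EVOO training cases (0% adulterant)
#'   in the regression training pools?
#' @param route_pure_adulterant Route test cases predicted as a *pure*
#'   adulterant class to that adulterant's regression model (otherwise they
#'   are treated as unquantified and predicted 0)?
#' @param compute_cv Also estimate training-set cross-validation metrics
#'   (RMSECV, R2cv) by an inner sample-level CV of each training pool?
#' @param inner_folds Folds of that inner CV.
#' @param se_from Whose standard error enters the one-SE rule, see
#'   [select_lv()].
#' @param baseline,normalize Preprocessing applied once to the dataset
#'   (per-spectrum, so no information leaks across folds), see
#'   [preprocess_dataset()].
#' @return A validated list of class `chain_config`.
#' @export
chain_config <- function(folds = 10, repetitions = 10, seed = 1,
                         lv_max = 35, lv_max_reg = 35,
                         modes = c("plsda_dependent", "known_identity"),
                         overall_model = TRUE, include_pure_evoo = TRUE,
                         route_pure_adulterant = TRUE,
                         compute_cv = FALSE, inner_folds = 5,
                         se_from = "candidate",
                         baseline = TRUE, normalize = TRUE) {
  modes <- match.arg(modes, c("plsda_dependent", "known_identity"),
                     several.ok = TRUE)
  stopifnot(folds >= 2, repetitions >= 2, lv_max >= 1, lv_max_reg >= 1,
            inner_folds >= 2, length(modes) >= 1)
  structure(list(folds = folds, repetitions = repetitions, seed = seed,
                 lv_max = lv_max, lv_max_reg = lv_max_reg, modes = modes,
                 overall_model = overall_model,
                 include_pure_evoo = include_pure_evoo,
                 route_pure_adulterant = route_pure_adulterant,
                 compute_cv = compute_cv, inner_folds = inner_folds,
                 se_from = se_from,
                 baseline = baseline, normalize = normalize),
            class = "chain_config")
}

#' Collapse 13-class predictions to pure-vs-adulterated accuracy
#'
#' Restricted to cases whose true class is pure EVOO or an adulterated
#' blend ("EVOO+..."), a prediction counts as "pure" iff the predicted
#' class is EVOO and as "adulterated" otherwise; so an EVOO+corn case
#' predicted EVOO+safflower is still a correct "adulterated" call.
#'
#' @param truth,predicted Equal-length class-label vectors.
#' @return Percent correct on the binary task.
#' @export
collapse_to_binary <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  keep <- truth == "EVOO" | startsWith(truth, "EVOO+")
  if (!any(keep)) stop("no pure-EVOO or adulterated-EVOO cases present")
  tb <- ifelse(truth[keep] == "EVOO", "pure", "adulterated")
  pb <- ifelse(predicted[keep] == "EVOO", "pure", "adulterated")
  100 * mean(tb == pb)
}

# Quiet NIPALS fit: rank exhaustion inside the resampling loop is expected
# (noiseless data have low rank) and is tallied, not surfaced per fold.
.fit_quiet <- function(expr) {
  truncated <- FALSE
  out <- withCallingHandlers(expr, warning = function(w) {
    if (grepl("rank exhausted|no variance", conditionMessage(w))) {
      truncated <<- TRUE
      invokeRestart("muffleWarning")
    }
  })
  list(fit = out, truncated = truncated)
}

#' Run the chained PLS-DA -> PLS analysis
#'
#' Implements the two-stage validation scheme: over `repetitions` random
#' sample-level `folds`-fold partitions, each fold is held out once; a
#' 13-class PLS-DA is fitted on the training folds and applied to the test
#' fold, and PLS regressions (one per adulterant, plus an overall model)
#' trained on the same training folds quantify the adulterant mass
#' percentage of the test cases. The held-out fold is never used to fit
#' any model; latent-variable counts are chosen by the one-SE rule on
#' curves of held-out performance across repetitions, separately for the
#' classifier and for every regression model and evaluation mode.
#'
#' In `plsda_dependent` mode a test case is quantified by the regression
#' model of its predicted class (cases predicted pure EVOO get predicted
#' concentration 0), so misclassification transfers error into the
#' concentration estimate; in `known_identity` mode routing uses the true
#' class. Regression metrics are grouped by the true blend type and
#' restricted to cases within the trained concentration range (pure
#' adulterant cases are classified but not quantified).
#'
#' @param dataset A `spectral_dataset` whose rows align with
#'   `design_cases(design)`.
#' @param design The `oil_design` that generated the dataset.
#' @param config A [chain_config()].
#' @return Object of class `chain_report`; see [print.chain_report()],
#'   [summary.chain_report()], [write_chain_report()].
#' @export
run_chain <- function(dataset, design, config = chain_config()) {
  stopifnot(inherits(dataset, "spectral_dataset"),
            inherits(design, "oil_design"),
            inherits(config, "chain_config"))
  cases <- design_cases(design)
  if (!identical(cases$case_id, dataset$case_id)) {
    bad <- setdiff(cases$case_id, dataset$case_id)
    stop("dataset rows do not align with the design cases; offending ids: ",
         paste(utils::head(c(bad, setdiff(dataset$case_id, cases$case_id)), 5),
               collapse = ", "))
  }
  if (is.null(dataset$preprocess) && (config$baseline || config$normalize)) {
    dataset <- preprocess_dataset(dataset, baseline = config$baseline,
                                  normalize = config$normalize)
  }
  X <- dataset$X
  n <- nrow(X); p <- ncol(X)
  truth <- cases$class_label
  y_pct <- cases$mass_fraction * 100
  classes <- unique(design$class_label)
  ads <- adulterant_oils()[adulterant_oils() %in% design$adulterant]
  models <- c(if (config$overall_model) "overall", ads)
  max_level_pct <- max(design$mass_fraction[design$category == "adulterated"]) * 100
  quantifiable <- cases$mass_fraction * 100 <= max_level_pct &
    (cases$category != "pure_adulterant")
  parts <- make_partitions(design, config$folds, config$repetitions,
                           config$seed)
  samp_of_case <- match(cases$sample_id, design$sample_id)

  # training pools per regression model (case indices, given a train mask)
  pool_of <- function(model, mask) {
    if (model == "overall") {
      sel <- cases$category == "adulterated"
    } else {
      sel <- cases$category == "adulterated" & cases$adulterant == model
      sel[is.na(sel)] <- FALSE
    }
    if (config$include_pure_evoo) sel <- sel | cases$category == "pure_evoo"
    which(sel & mask)
  }

  # candidate LV caps from the worst-case training sizes
  fold_sizes <- apply(parts$assignment, 2, function(a)
    tabulate(a[samp_of_case], nbins = config$folds))
  min_train <- n - max(fold_sizes)
  A_cls <- min(config$lv_max, p, min_train - 1)
  A_reg <- stats::setNames(vapply(models, function(m) {
    sizes <- apply(parts$assignment, 2, function(a) {
      vapply(seq_len(config$folds), function(k)
        length(pool_of(m, a[samp_of_case] != k)), integer(1))
    })
    min(config$lv_max_reg, p, min(sizes) - 1)
  }, numeric(1)), models)
  if (A_cls < 1 || any(A_reg < 1)) stop("training pools too small for PLS")

  n_trunc <- 0L
  missing_class_events <- 0L
  cls_idx <- vector("list", config$repetitions)    # n x A_cls predicted class index
  reg_pred <- vector("list", config$repetitions)   # per model: n x A_reg
  cv_store <- if (config$compute_cv) {
    stats::setNames(lapply(models, function(m)
      list(measured = list(), predicted = list(), rep = list())), models)
  }

  for (r in seq_len(config$repetitions)) {
    fold_of_case <- parts$assignment[samp_of_case, r]
    cls_idx[[r]] <- matrix(NA_integer_, n, A_cls)
    reg_pred[[r]] <- lapply(A_reg, function(a) matrix(NA_real_, n, a))
    for (k in seq_len(config$folds)) {
      te <- which(fold_of_case == k)
      tr <- which(fold_of_case != k)
      if (length(te) == 0) next
      if (length(unique(truth[tr])) < length(classes)) {
        missing_class_events <- missing_class_events + 1L
      }
      fq <- .fit_quiet(nipals_plsda(X[tr, , drop = FALSE], truth[tr],
                                    ncomp = A_cls))
      if (fq$truncated) n_trunc <- n_trunc + 1L
      fit <- fq$fit
      if (fit$ncomp >= 1) {
        resp <- predict(fit, X[te, , drop = FALSE],
                        ncomp = seq_len(fit$ncomp), type = "response")
        for (a in seq_len(fit$ncomp)) {
          m <- resp[, , a, drop = FALSE]; dim(m) <- dim(resp)[1:2]
          loc <- max.col(m, ties.method = "first")
          cls_idx[[r]][te, a] <- match(fit$levels[loc], classes)
        }
        if (fit$ncomp < A_cls) {  # carry the deepest model to unreached LVs
          for (a in (fit$ncomp + 1):A_cls) {
            cls_idx[[r]][te, a] <- cls_idx[[r]][te, fit$ncomp]
          }
        }
      }
      for (m in models) {
        pool <- pool_of(m, fold_of_case != k)
        fq <- .fit_quiet(nipals_pls(X[pool, , drop = FALSE], y_pct[pool],
                                    ncomp = A_reg[[m]]))
        if (fq$truncated) n_trunc <- n_trunc + 1L
        rfit <- fq$fit
        if (rfit$ncomp >= 1) {
          pr <- predict(rfit, X[te, , drop = FALSE],
                        ncomp = seq_len(rfit$ncomp))
          dim(pr) <- c(length(te), rfit$ncomp)
          reg_pred[[r]][[m]][te, seq_len(rfit$ncomp)] <- pr
          if (rfit$ncomp < A_reg[[m]]) {
            for (a in (rfit$ncomp + 1):A_reg[[m]]) {
              reg_pred[[r]][[m]][te, a] <- pr[, rfit$ncomp]
            }
          }
        } else {
          # degenerate pool (e.g. all its mixtures fell into the test
          # fold): the model can only predict the training mean
          reg_pred[[r]][[m]][te, ] <- mean(y_pct[pool])
        }
        if (config$compute_cv) {
          icv <- .inner_cv(X, y_pct, pool, samp_of_case, config$inner_folds,
                           A_reg[[m]], seed = config$seed * 1000L + r * 10L + k)
          n_trunc <- n_trunc + icv$n_trunc
          cv_store[[m]]$measured <- c(cv_store[[m]]$measured, list(icv$measured))
          cv_store[[m]]$predicted <- c(cv_store[[m]]$predicted, list(icv$predicted))
          cv_store[[m]]$rep <- c(cv_store[[m]]$rep, list(rep(r, length(icv$measured))))
        }
      }
    }
  }

  # ---- classification: curve, one-SE selection, pooled confusion ----
  cc_mat <- t(vapply(seq_len(config$repetitions), function(r) {
    vapply(seq_len(A_cls), function(a)
      correct_classification(truth, classes[cls_idx[[r]][, a]]), numeric(1))
  }, numeric(A_cls)))
  if (A_cls == 1) cc_mat <- matrix(cc_mat, ncol = 1)
  cls_curve <- performance_curve(cc_mat, type = "classification")
  lv_cls <- select_lv(cls_curve, config$se_from)
  pred_labels <- lapply(seq_len(config$repetitions), function(r)
    classes[cls_idx[[r]][, lv_cls]])
  pooled_truth <- rep(truth, config$repetitions)
  pooled_pred <- unlist(pred_labels)
  confusion <- confusion_matrix(pooled_truth, pooled_pred, labels = classes)
  cc13_rep <- vapply(pred_labels, function(pl)
    correct_classification(truth, pl), numeric(1))
  bin_rep <- vapply(pred_labels, function(pl)
    collapse_to_binary(truth, pl), numeric(1))

  # routing target per case per repetition (model name, or "" for none)
  route <- lapply(pred_labels, function(pl) {
    out <- rep("", n)
    mix <- startsWith(pl, "EVOO+")
    out[mix] <- sub("^EVOO\\+", "", pl[mix])
    pure <- pl %in% ads
    if (config$route_pure_adulterant) out[pure] <- pl[pure]
    out[!(out %in% ads)] <- ""
    out
  })

  # ---- regression: per-model, per-mode curves and selection ----
  dep_on <- "plsda_dependent" %in% config$modes
  known_on <- "known_identity" %in% config$modes
  truth_pool <- function(m) {
    if (m == "overall") which(cases$category == "adulterated")
    else which(cases$category == "adulterated" & !is.na(cases$adulterant) &
                 cases$adulterant == m)
  }
  rmsep_of <- function(meas, pred) if (length(meas) < 1) NA_real_ else
    sqrt(mean((pred - meas)^2))

  dep_pred_at <- function(r, m, idx, a) {
    # routed prediction for cases idx under dependent mode, model column m
    # is only used for the overall model; per-adulterant routing picks the
    # routed model's own column
    pr <- numeric(length(idx))
    rt <- route[[r]][idx]
    for (i in seq_along(idx)) {
      if (rt[i] == "") { pr[i] <- 0; next }
      tgt <- if (m == "overall") "overall" else rt[i]
      aa <- min(a, A_reg[[tgt]])
      pr[i] <- reg_pred[[r]][[tgt]][idx[i], aa]
    }
    pr
  }

  sel_rows <- list(); pred_rows <- list(); curves_reg <- list()
  for (m in models) {
    tp <- intersect(truth_pool(m), which(quantifiable))
    if (known_on) {
      vals <- t(vapply(seq_len(config$repetitions), function(r)
        vapply(seq_len(A_reg[[m]]), function(a)
          rmsep_of(y_pct[tp], reg_pred[[r]][[m]][tp, a]), numeric(1)),
        numeric(A_reg[[m]])))
      if (A_reg[[m]] == 1) vals <- matrix(vals, ncol = 1)
      cv_known <- performance_curve(vals, type = "regression")
      lv_known <- select_lv(cv_known, config$se_from)
      meas <- rep(y_pct[tp], config$repetitions)
      pred <- unlist(lapply(seq_len(config$repetitions), function(r)
        reg_pred[[r]][[m]][tp, lv_known]))
      mt <- regression_metrics(meas, pred)
      sel_rows[[length(sel_rows) + 1]] <- data.frame(
        model = m, mode = "known_identity", lv = lv_known, r2 = mt$r2,
        slope = mt$slope, intercept = mt$intercept, rmsep = mt$rmse,
        rpd = mt$rpd, n = mt$n, stringsAsFactors = FALSE)
      curves_reg[[paste(m, "known_identity", sep = ".")]] <- cv_known
      pred_rows[[length(pred_rows) + 1]] <- data.frame(
        model = m, mode = "known_identity",
        rep = rep(seq_len(config$repetitions), each = length(tp)),
        case_id = rep(cases$case_id[tp], config$repetitions),
        truth_class = rep(truth[tp], config$repetitions),
        measured = meas, predicted = pred, stringsAsFactors = FALSE)
    }
    if (dep_on) {
      # LV selection on the cases actually routed to this model
      vals <- t(vapply(seq_len(config$repetitions), function(r) {
        routed <- if (m == "overall") which(quantifiable & route[[r]] != "")
        else which(quantifiable & route[[r]] == m)
        vapply(seq_len(A_reg[[m]]), function(a)
          rmsep_of(y_pct[routed], reg_pred[[r]][[m]][routed, a]), numeric(1))
      }, numeric(A_reg[[m]])))
      if (A_reg[[m]] == 1) vals <- matrix(vals, ncol = 1)
      lv_dep <- if (all(is.na(vals))) 1L else
        select_lv(performance_curve(vals, type = "regression"), config$se_from)
      attr(lv_dep, "curve_ok") <- !all(is.na(vals))
      curves_reg[[paste(m, "plsda_dependent", sep = ".")]] <-
        if (all(is.na(vals))) NULL else performance_curve(vals, type = "regression")
      sel_rows[[length(sel_rows) + 1]] <- data.frame(
        model = m, mode = "plsda_dependent", lv = as.integer(lv_dep),
        r2 = NA_real_, slope = NA_real_, intercept = NA_real_,
        rmsep = NA_real_, rpd = NA_real_, n = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  sel <- do.call(rbind, sel_rows)
  # dependent-mode final metrics need every model's selected LV first
  if (dep_on) {
    lv_dep_of <- stats::setNames(
      sel$lv[sel$mode == "plsda_dependent"][match(models,
        sel$model[sel$mode == "plsda_dependent"])], models)
    for (m in models) {
      tp <- intersect(truth_pool(m), which(quantifiable))
      meas <- rep(y_pct[tp], config$repetitions)
      pred <- unlist(lapply(seq_len(config$repetitions), function(r) {
        if (m == "overall") {
          dep_pred_at(r, "overall", tp, lv_dep_of[["overall"]])
        } else {
          vapply(tp, function(i) {
            rt <- route[[r]][i]
            if (rt == "") return(0)
            reg_pred[[r]][[rt]][i, min(lv_dep_of[[rt]], A_reg[[rt]])]
          }, numeric(1))
        }
      }))
      mt <- regression_metrics(meas, pred)
      i <- which(sel$model == m & sel$mode == "plsda_dependent")
      sel$r2[i] <- mt$r2; sel$slope[i] <- mt$slope
      sel$intercept[i] <- mt$intercept; sel$rmsep[i] <- mt$rmse
      sel$rpd[i] <- mt$rpd; sel$n[i] <- mt$n
      pred_rows[[length(pred_rows) + 1]] <- data.frame(
        model = m, mode = "plsda_dependent",
        rep = rep(seq_len(config$repetitions), each = length(tp)),
        case_id = rep(cases$case_id[tp], config$repetitions),
        truth_class = rep(truth[tp], config$repetitions),
        measured = meas, predicted = pred, stringsAsFactors = FALSE)
    }
  }

  # ---- inner-CV (training-set) metrics ----
  cv_tab <- NULL
  if (config$compute_cv) {
    cv_tab <- do.call(rbind, lapply(models, function(m) {
      meas <- unlist(cv_store[[m]]$measured)
      predm <- do.call(rbind, cv_store[[m]]$predicted)
      reps <- unlist(cv_store[[m]]$rep)
      vals <- t(vapply(seq_len(config$repetitions), function(r)
        vapply(seq_len(ncol(predm)), function(a)
          rmsep_of(meas[reps == r], predm[reps == r, a]), numeric(1)),
        numeric(ncol(predm))))
      if (ncol(predm) == 1) vals <- matrix(vals, ncol = 1)
      lv_cv <- select_lv(performance_curve(vals, type = "regression"),
                         config$se_from)
      mt <- regression_metrics(meas, predm[, lv_cv])
      data.frame(model = m, lv = lv_cv, r2_cv = mt$r2, rmsecv = mt$rmse,
                 rpd = mt$rpd, slope = mt$slope, intercept = mt$intercept,
                 n = mt$n, stringsAsFactors = FALSE)
    }))
  }

  structure(list(
    modality = dataset$modality, config = config, n_cases = n,
    classes = classes, adulterants = ads,
    classification = list(
      curve = cls_curve, lv = lv_cls, confusion = confusion,
      cc13_mean = mean(cc13_rep), cc13_se = stats::sd(cc13_rep) /
        sqrt(length(cc13_rep)),
      binary_mean = mean(bin_rep), binary_se = stats::sd(bin_rep) /
        sqrt(length(bin_rep)),
      cc13_per_rep = cc13_rep, binary_per_rep = bin_rep,
      predicted_labels = pred_labels, truth = truth,
      case_id = cases$case_id,
      total_classified = n * config$repetitions,
      missing_class_events = missing_class_events),
    regression = sel,
    cv = cv_tab,
    curves = curves_reg,
    predictions = if (length(pred_rows) > 0) do.call(rbind, pred_rows),
    rank_truncations = n_trunc
  ), class = "chain_report")
}

# inner sample-level CV of one training pool: held-out predictions per LV
.inner_cv <- function(X, y, pool, samp_of_case, inner_folds, A, seed) {
  set.seed(seed)
  samples <- unique(samp_of_case[pool])
  nf <- min(inner_folds, length(samples))
  fold_of_sample <- stats::setNames(sample(rep_len(seq_len(nf),
                                                   length(samples))), samples)
  fold_of <- fold_of_sample[as.character(samp_of_case[pool])]
  pred <- matrix(NA_real_, length(pool), A)
  n_trunc <- 0L
  for (k in seq_len(nf)) {
    te <- pool[fold_of == k]; tr <- pool[fold_of != k]
    if (length(te) == 0 || length(tr) < 3) next
    a_here <- min(A, length(tr) - 1)
    fq <- .fit_quiet(nipals_pls(X[tr, , drop = FALSE], y[tr],
                                ncomp = a_here))
    if (fq$truncated) n_trunc <- n_trunc + 1L
    rfit <- fq$fit
    if (rfit$ncomp < 1) next
    pr <- predict(rfit, X[te, , drop = FALSE], ncomp = seq_len(rfit$ncomp))
    dim(pr) <- c(length(te), rfit$ncomp)
    rows <- match(te, pool)
    pred[rows, seq_len(rfit$ncomp)] <- pr
    if (rfit$ncomp < A) {
      for (a in (rfit$ncomp + 1):A) pred[rows, a] <- pr[, rfit$ncomp]
    }
  }
  keep <- !is.na(pred[, 1])
  list(measured = y[pool][keep], predicted = pred[keep, , drop = FALSE],
       n_trunc = n_trunc)
}

#' @export
print.chain_report <- function(x, ...) {
  cl <- x$classification
  cat("Chained PLS-DA -> PLS report (", x$modality, ")\n", sep = "")
  cat(sprintf("  classification: %d classes, %d LVs; CC = %.2f +/- %.2f %%; pure-vs-adulterated CC = %.2f +/- %.2f %%\n",
              length(x$classes), cl$lv, cl$cc13_mean, cl$cc13_se,
              cl$binary_mean, cl$binary_se))
  cat("  cases classified:", cl$total_classified, "\n")
  cat("  regression models (", paste(unique(x$regression$mode),
                                     collapse = ", "), "):\n", sep = "")
  print.data.frame(within(x$regression, {
    r2 <- round(r2, 3); slope <- round(slope, 3)
    intercept <- round(intercept, 3); rmsep <- round(rmsep, 3)
    rpd <- round(rpd, 2)
  }), row.names = FALSE)
  invisible(x)
}

#' @export
summary.chain_report <- function(object, ...) {
  print(object)
  cat("\nPooled confusion matrix:\n")
  print(object$classification$confusion)
  if (!is.null(object$cv)) {
    cat("\nTraining-set cross-validation metrics:\n")
    print.data.frame(object$cv, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.chain_report <- function(x, model = "overall",
                              mode = x$config$modes[1], ...) {
  pr <- x$predictions
  pr <- pr[pr$model == model & pr$mode == mode, ]
  if (nrow(pr) == 0) stop("no predictions stored for ", model, "/", mode)
  graphics::plot(pr$measured, pr$predicted,
                 xlab = "measured adulterant (mass-%)",
                 ylab = "predicted adulterant (mass-%)",
                 main = paste(model, "model,", mode), pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.4), ...)
  graphics::abline(0, 1, lty = 2)
  row <- x$regression[x$regression$model == model & x$regression$mode == mode, ]
  graphics::abline(row$intercept, row$slope, col = "firebrick")
  invisible(x)
}

#' Write a chain report to files
#'
#' Emits `confusion.csv` (counts with row percentages), `metrics.csv`
#' (one row per regression model and evaluation mode: LVs, R2, fitted
#' line, RMSEP, RPD), `summary.csv` (classification summary), and
#' `report.json` (full dump including the run configuration).
#'
#' @param report A `chain_report`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_chain_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cm <- report$classification$confusion
  conf <- data.frame(class = rownames(cm$counts), cm$counts,
                     check.names = FALSE)
  utils::write.csv(conf, file.path(dir, "confusion.csv"), row.names = FALSE)
  met <- report$regression
  met$fitted_line <- sprintf("y = %.2fx %+.2f", met$slope, met$intercept)
  utils::write.csv(met, file.path(dir, "metrics.csv"), row.names = FALSE)
  cl <- report$classification
  utils::write.csv(data.frame(
    modality = report$modality, lv = cl$lv,
    cc13_mean = cl$cc13_mean, cc13_se = cl$cc13_se,
    binary_mean = cl$binary_mean, binary_se = cl$binary_se,
    total_classified = cl$total_classified),
    file.path(dir, "summary.csv"), row.names = FALSE)
  dump <- list(modality = report$modality,
               config = unclass(report$config),
               classification = cl[c("lv", "cc13_mean", "cc13_se",
                                     "binary_mean", "binary_se",
                                     "total_classified")],
               regression = report$regression,
               cv = report$cv)
  jsonlite::write_json(dump, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
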