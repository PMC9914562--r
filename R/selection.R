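#' Repeated random k-fold partitions at the sample level
#'
#' Assigns every sample to exactly one fold per repetition, with fold sizes
#' as even as possible (they differ by at most one sample). Partitioning is
#' at the sample level, so all measurement replicates of a sample share a
#' fold and never straddle the train/test boundary. Within a repetition
#' every fold serves as the test set exactly once.
#'
#' @param design An `oil_design`.
#' @param folds Number of folds (default 10); at most the number of samples.
#' @param repetitions Number of independent random partitions (default 10).
#' @param seed Integer seed; identical seeds give identical schemes.
#' @return Object of class `partition_scheme`: list with `assignment`
#'   (samples x repetitions matrix of fold indices, rownames = sample ids),
#'   `folds`, `repetitions`, `seed`.
#' @export
make_partitions <- function(design, folds = 10, repetitions = 10, seed = 1) {
  stopifnot(inherits(design, "oil_design"), repetitions >= 1)
  n <- nrow(design)
  if (folds > n) stop("more folds (", folds, ") than samples (", n, ")")
  set.seed(seed)
  assignment <- sapply(seq_len(repetitions), function(r)
    sample(rep_len(seq_len(folds), n)))
  rownames(assignment) <- design$sample_id
  structure(list(assignment = assignment, folds = folds,
                 repetitions = repetitions, seed = seed),
            class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat("Partition scheme:", x$repetitions, "repetitions x", x$folds,
      "folds over", nrow(x$assignment), "samples (seed", x$seed, ")\n")
  invisible(x)
}

#' Serialize a partition scheme to JSON
#'
#' @param scheme A `partition_scheme`.
#' @param path File path.
#' @export
write_partitions <- function(scheme, path) {
  jsonlite::write_json(
    list(seed = scheme$seed, folds = scheme$folds,
         repetitions = scheme$repetitions,
         sample_id = rownames(scheme$assignment),
         assignment = unname(as.data.frame(scheme$assignment))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-latent-variable performance curve across repetitions
#'
#' Collapses a repetitions x latent-variables matrix of performance values
#' (percent correct classification for PLS-DA, RMSEP for PLS) into the mean
#' and its standard error per latent-variable count. The standard error is
#' the sample standard deviation across repetition means divided by the
#' square root of the number of repetitions.
#'
#' @param values Numeric matrix, repetitions in rows, candidate
#'   latent-variable counts in columns (`NA` entries are dropped per
#'   column).
#' @param lv Latent-variable counts labelling the columns (default
#'   `1:ncol`).
#' @param type `"classification"` (higher is better) or `"regression"`
#'   (lower is better); consumed by [select_lv()].
#' @return Object of class `selection_curve`: data frame with columns
#'   `lv`, `mean`, `se`, plus attributes `type` and `values`.
#' @export
performance_curve <- function(values, lv = NULL,
                              type = c("classification", "regression")) {
  type <- match.arg(type)
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("at least 2 repetitions are required")
  if (is.null(lv)) lv <- seq_len(ncol(values))
  if (length(lv) != ncol(values)) stop("lv length does not match columns")
  m <- apply(values, 2, mean, na.rm = TRUE)
  se <- apply(values, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    stats::sd(v) / sqrt(length(v))
  })
  out <- data.frame(lv = lv, mean = m, se = se)
  rownames(out) <- NULL
  attr(out, "type") <- type
  attr(out, "values") <- values
  class(out) <- c("selection_curve", "data.frame")
  out
}

#' One-standard-error latent-variable selection
#'
#' Identifies the absolute best model (highest mean correct classification,
#' or lowest mean RMSEP) and returns the smallest latent-variable count
#' whose mean performance is within one standard error of it:
#' for classification, the smallest LV with `mean CC + SE > mean CC*`;
#' for regression, the smallest LV with `mean RMSEP - SE < mean RMSEP*`.
#' If no candidate qualifies the best model's LV count is returned. By
#' default the candidate's own SE enters the inequality; set
#' `se_from = "best"` to use the best model's SE instead.
#'
#' @param curve A `selection_curve` from [performance_curve()].
#' @param se_from `"candidate"` (default) or `"best"`.
#' @return The chosen latent-variable count (scalar).
#' @export
select_lv <- function(curve, se_from = c("candidate", "best")) {
  se_from <- match.arg(se_from)
  stopifnot(inherits(curve, "selection_curve"))
  ok <- !is.na(curve$mean)
  if (!any(ok)) stop("empty selection curve")
  type <- attr(curve, "type")
  maximize <- type == "classification"
  means <- curve$mean
  ses <- ifelse(is.na(curve$se), 0, curve$se)
  best_i <- if (maximize) which.max(means) else which.min(means)
  best_mean <- means[best_i]
  slack <- if (se_from == "candidate") ses else rep(ses[best_i], length(ses))
  qual <- ok & if (maximize) means + slack > best_mean else means - slack < best_mean
  if (any(qual)) curve$lv[which(qual)[1]] else curve$lv[best_i]
}

#' @rdname select_lv
#' @export
select_lv_classification <- function(curve, se_from = "candidate") {
  if (attr(curve, "type") != "classification") {
    stop("curve was built for ", attr(curve, "type"))
  }
  select_lv(curve, se_from)
}

#' @rdname select_lv
#' @export
select_lv_regression <- function(curve, se_from = "candidate") {
  if (attr(curve, "type") != "regression") {
    stop("curve was built for ", attr(curve, "type"))
  }
  select_lv(curve, se_from)
}

#' @export
print.selection_curve <- function(x, ...) {
  cat("Selection curve (", attr(x, "type"), "), ",
      nrow(attr(x, "values")), " repetitions x ", nrow(x),
      " latent-variable counts\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.selection_curve <- function(x, ...) {
  ylab <- if (attr(x, "type") == "classification") "mean CC (%)" else "mean RMSEP"
  graphics::plot(x$lv, x$mean, type = "b", pch = 16,
                 xlab = "latent variables", ylab = ylab, ...)
  graphics::arrows(x$lv, x$mean - x$se, x$lv, x$mean + x$se,
                   angle = 90, code = 3, length = 0.03)
  chosen <- select_lv(x)
  graphics::abline(v = chosen, lty = 2)
  invisible(x)
}
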