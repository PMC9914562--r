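#' Oil classes used in the adulteration study
#'
#' The seven pure-oil identities: extra virgin olive oil (EVOO, the base oil)
#' and the six cheaper edible oils used as adulterants.
#'
#' @return Character vector of length 7; the first element is always
#'   `"EVOO"`.
#' @export
oil_classes <- function() {
  c("EVOO", "safflower", "corn", "soybean", "canola", "sunflower", "sesame")
}

#' @rdname oil_classes
#' @export
adulterant_oils <- function() oil_classes()[-1]

#' Default adulteration levels (mass fraction of adulterant)
#'
#' The nonzero blend levels of the gravimetric mixture series
#' 100:0, 99:1, 98:2, 96:4, 92:8, 88:12, 84:16 and 80:20 (EVOO:adulterant,
#' m/m).
#'
#' @return Numeric vector of mass fractions in (0, 1).
#' @export
default_levels <- function() c(0.01, 0.02, 0.04, 0.08, 0.12, 0.16, 0.20)

#' Class label of a sample
#'
#' Maps sample category and adulterant identity onto one of the 13 study
#' classes: `"EVOO"`, the six pure adulterant oils, and the six
#' `"EVOO+<adulterant>"` groups. All adulteration levels of one adulterant
#' share a single class, since the level of an unknown sample submitted for
#' authentication cannot be known in advance.
#'
#' @param category Character vector with values among `"pure_evoo"`,
#'   `"pure_adulterant"`, `"adulterated"`.
#' @param adulterant Character vector of adulterant oil names (ignored, and
#'   may be `NA`, for `"pure_evoo"`).
#' @return Character vector of class labels.
#' @export
class_label <- function(category, adulterant) {
  stopifnot(length(category) == length(adulterant) || all(category == "pure_evoo"))
  bad <- setdiff(unique(category),
                 c("pure_evoo", "pure_adulterant", "adulterated"))
  if (length(bad) > 0) {
    stop("unknown sample category: ", paste(bad, collapse = ", "))
  }
  out <- character(length(category))
  out[category == "pure_evoo"] <- "EVOO"
  pa <- category == "pure_adulterant"
  ad <- category == "adulterated"
  if (any((pa | ad) & (is.na(adulterant) | adulterant == "EVOO"))) {
    stop("adulterant must be a non-EVOO oil for non-pure-EVOO samples")
  }
  unknown <- setdiff(unique(adulterant[pa | ad]), adulterant_oils())
  if (length(unknown) > 0) {
    stop("unknown adulterant oil: ", paste(unknown, collapse = ", "))
  }
  out[pa] <- adulterant[pa]
  out[ad] <- paste0("EVOO+", adulterant[ad])
  out
}

#' Build the sample plan of the adulteration study
#'
#' Constructs the experimental design as data: `n_evoo` authentic EVOO
#' samples, one pure sample of each adulterant oil, and one blended sample
#' per adulterant per adulteration level, each measured in
#' `replicates` replicates. The defaults reproduce the 61-sample plan
#' (13 EVOO + 6 pure adulterants + 6 x 7 blends) measured in triplicate,
#' i.e. 183 cases.
#'
#' Sample ids are deterministic strings encoding class and level, so a
#' design is reproducible without any seed.
#'
#' @param n_evoo Number of authentic EVOO samples.
#' @param n_adulterants Number of adulterant oils (first `n_adulterants`
#'   of [adulterant_oils()]).
#' @param levels Nonzero adulterant mass fractions in (0, 1), no duplicates.
#' @param replicates Measurement replicates per sample.
#' @return An object of class `oil_design`: a data frame with one row per
#'   sample and columns `sample_id`, `category`, `adulterant`,
#'   `mass_fraction`, `replicate_count`, `class_label`.
#' @examples
#' d <- build_design()
#' nrow(d)                  # 61 samples
#' sum(d$replicate_count)   # 183 cases
#' @export
build_design <- function(n_evoo = 13, n_adulterants = 6,
                         levels = default_levels(), replicates = 3) {
  stopifnot(n_evoo >= 1, n_adulterants >= 1, replicates >= 1)
  if (n_adulterants > length(adulterant_oils())) {
    stop("at most ", length(adulterant_oils()), " adulterant oils are defined")
  }
  if (anyDuplicated(levels)) stop("invalid design: duplicate adulteration levels")
  if (any(levels <= 0 | levels > 1)) {
    stop("invalid design: levels must be mass fractions in (0, 1]")
  }
  ads <- adulterant_oils()[seq_len(n_adulterants)]
  samples <- rbind(
    data.frame(sample_id = sprintf("EVOO_%02d", seq_len(n_evoo)),
               category = "pure_evoo", adulterant = NA_character_,
               mass_fraction = 0, stringsAsFactors = FALSE),
    data.frame(sample_id = paste0("PURE_", ads),
               category = "pure_adulterant", adulterant = ads,
               mass_fraction = 1, stringsAsFactors = FALSE),
    do.call(rbind, lapply(ads, function(a) {
      data.frame(sample_id = sprintf("MIX_%s_%g", a, 100 * sort(levels)),
                 category = "adulterated", adulterant = a,
                 mass_fraction = sort(levels), stringsAsFactors = FALSE)
    }))
  )
  samples$replicate_count <- replicates
  samples$class_label <- class_label(samples$category, samples$adulterant)
  rownames(samples) <- NULL
  class(samples) <- c("oil_design", "data.frame")
  samples
}

#' Expand a design to the case level
#'
#' Each sample contributes `replicate_count` cases; replicates share the
#' `sample_id` (and therefore always share a cross-validation fold).
#'
#' @param design An `oil_design` from [build_design()].
#' @return Data frame with one row per case and columns `case_id`,
#'   `sample_id`, `replicate`, `category`, `adulterant`, `mass_fraction`,
#'   `class_label`.
#' @export
design_cases <- function(design) {
  stopifnot(inherits(design, "oil_design"))
  idx <- rep(seq_len(nrow(design)), design$replicate_count)
  rep_no <- sequence(design$replicate_count)
  out <- data.frame(
    case_id = paste0(design$sample_id[idx], "_r", rep_no),
    sample_id = design$sample_id[idx],
    replicate = rep_no,
    category = design$category[idx],
    adulterant = design$adulterant[idx],
    mass_fraction = design$mass_fraction[idx],
    class_label = design$class_label[idx],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' @export
print.oil_design <- function(x, ...) {
  cat("Oil adulteration design:", nrow(x), "samples,",
      sum(x$replicate_count), "cases\n")
  cat("  classes:", length(unique(x$class_label)), "\n")
  tab <- table(x$category)
  cat("  ", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Read and write a design as CSV
#'
#' The file holds the case-level table (columns `sample_id`, `category`,
#' `adulterant`, `mass_fraction`, `class_label`, `replicate`); reading
#' collapses it back to the sample level. The round trip is exact.
#'
#' @param design An `oil_design`.
#' @param path File path.
#' @return `read_design` returns an `oil_design`.
#' @export
write_design <- function(design, path) {
  cases <- design_cases(design)
  utils::write.csv(cases[, c("case_id", "sample_id", "category", "adulterant",
                             "mass_fraction", "class_label", "replicate")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  cases <- utils::read.csv(path, stringsAsFactors = FALSE)
  agg <- cases[!duplicated(cases$sample_id), ]
  out <- data.frame(
    sample_id = agg$sample_id,
    category = agg$category,
    adulterant = ifelse(is.na(agg$adulterant) | agg$adulterant == "",
                        NA_character_, agg$adulterant),
    mass_fraction = agg$mass_fraction,
    replicate_count = as.vector(table(cases$sample_id)[agg$sample_id]),
    class_label = agg$class_label,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("oil_design", "data.frame")
  out
}
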