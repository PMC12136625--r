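#' Assemble a trial data object
#'
#' Couples plot-level yields with the design they were observed under and
#' the per-treatment mean yields. Means are the arithmetic average of each
#' treatment's replicate plots unless a table of (typically more precise)
#' means is supplied explicitly.
#'
#' @param plots data frame with columns `treatment` (code), `replicate`
#'   (positive integer) and `yield` (fresh-bud mass, g/plant).
#' @param design a [build_3414_design()] object (or compatible design data
#'   frame) covering every treatment appearing in `plots`.
#' @param means optional data frame with columns `treatment` and `yield`
#'   overriding the computed means (e.g. means printed at higher precision
#'   than the individual plots).
#' @return A `trial_data` object: list with elements `design`, `plots`,
#'   `means`.
#' @export
trial_data <- function(plots, design = build_3414_design(), means = NULL) {
  req <- c("treatment", "replicate", "yield")
  if (!all(req %in% names(plots))) {
    stop("plots must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  plots <- as.data.frame(plots)[, req]
  plots$treatment <- treatment_code(parse_treatment_code(plots$treatment))
  unknown <- setdiff(plots$treatment, design$treatment)
  if (length(unknown)) {
    stop("plot treatments not in design: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(plots$yield) || anyNA(plots$yield)) {
    stop("plot yields must be numeric and non-missing", call. = FALSE)
  }
  if (any(plots$yield < 0)) {
    stop("plot yields must be nonnegative", call. = FALSE)
  }
  if (is.null(means) && nrow(plots) == 0L) {
    means <- data.frame(treatment = character(0), yield = numeric(0))
  } else if (is.null(means)) {
    agg <- stats::aggregate(yield ~ treatment, data = plots, FUN = mean)
    means <- agg[match(intersect(design$treatment, agg$treatment),
                       agg$treatment), ]
    rownames(means) <- NULL
  } else {
    means <- as.data.frame(means)[, c("treatment", "yield")]
    means$treatment <- treatment_code(parse_treatment_code(means$treatment))
  }
  structure(list(design = design, plots = plots, means = means),
            class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat("'3414' trial data:", nrow(x$plots), "plots,",
      nrow(x$means), "treatments with means\n")
  cat("mean yield range:", round(min(x$means$yield), 2), "-",
      round(max(x$means$yield), 2), "g/plant\n")
  invisible(x)
}

#' Treatment mean yields
#'
#' @param trial a [trial_data()] object.
#' @param treatments optional treatment codes or design row indices to
#'   select; defaults to all treatments with means.
#' @return named numeric vector of mean yields (g/plant).
#' @export
treatment_means <- function(trial, treatments = NULL) {
  means <- trial$means
  out <- stats::setNames(means$yield, means$treatment)
  if (is.null(treatments)) {
    return(out)
  }
  codes <- design_row(trial$design, treatments)$treatment
  missing <- setdiff(codes, names(out))
  if (length(missing)) {
    stop("no mean yield for treatment: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out[codes]
}

#' Read a trial table from CSV
#'
#' Expects a comma-separated file (header required, UTF-8) with columns
#' `treatment`, `replicate` and `yield`; level and dose columns
#' (`n_level`, ..., `k_dose`) may be present and are checked against the
#' design when they are. Row order is preserved.
#'
#' @param path file path or connection.
#' @param design the trial design to attach; defaults to the canonical
#'   '3414' design unless the file carries its own dose columns, in which
#'   case a design is reconstructed from them.
#' @param means optional means table forwarded to [trial_data()].
#' @return a `trial_data` object.
#' @export
read_trial_table <- function(path, design = NULL, means = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  req <- c("treatment", "replicate", "yield")
  if (!all(req %in% names(raw))) {
    stop("trial table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | !nzchar(trimws(raw[[col]])))
    if (length(bad)) {
      stop("malformed '", col, "' value in row ", bad[1L], ": '",
           raw[[col]][bad[1L]], "'", call. = FALSE)
    }
    v
  }
  plots <- data.frame(
    treatment = raw$treatment,
    replicate = as.integer(num("replicate")),
    yield = num("yield"),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(plots))) {
    ok <- tryCatch({parse_treatment_code(plots$treatment[i]); TRUE},
                   error = function(e) FALSE)
    if (!ok) {
      stop("unknown treatment code in row ", i, ": '",
           plots$treatment[i], "'", call. = FALSE)
    }
  }
  if (is.null(design)) {
    design <- if (all(c("n_dose", "p_dose", "k_dose") %in% names(raw))) {
      design_from_doses(raw)
    } else {
      build_3414_design()
    }
  }
  trial_data(plots, design = design, means = means)
}

# Reconstruct a design data frame from the dose/level columns of a table.
design_from_doses <- function(raw) {
  lev <- parse_treatment_code(raw$treatment)
  d <- data.frame(
    treatment = treatment_code(lev),
    n_level = lev[, "N"], p_level = lev[, "P"], k_level = lev[, "K"],
    n_dose = as.numeric(raw$n_dose), p_dose = as.numeric(raw$p_dose),
    k_dose = as.numeric(raw$k_dose),
    stringsAsFactors = FALSE
  )
  d <- unique(d)
  if (anyDuplicated(d$treatment)) {
    stop("inconsistent doses for a treatment across rows", call. = FALSE)
  }
  lvl2 <- c(
    N = unique(d$n_dose[d$n_level == 2L]),
    P = unique(d$p_dose[d$p_level == 2L]),
    K = unique(d$k_dose[d$k_level == 2L])
  )
  attr(d, "level2") <- lvl2
  class(d) <- c("trial_design", "data.frame")
  d
}

#' Write a trial table to CSV
#'
#' Emits one row per plot with the treatment's levels and doses joined in,
#' so that [read_trial_table()] round-trips the object exactly.
#'
#' @param trial a [trial_data()] object.
#' @param path destination file path or connection.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trial, path) {
  idx <- match(trial$plots$treatment, trial$design$treatment)
  out <- data.frame(
    treatment = trial$plots$treatment,
    n_level = trial$design$n_level[idx],
    p_level = trial$design$p_level[idx],
    k_level = trial$design$k_level[idx],
    n_dose = trial$design$n_dose[idx],
    p_dose = trial$design$p_dose[idx],
    k_dose = trial$design$k_dose[idx],
    replicate = trial$plots$replicate,
    yield = trial$plots$yield,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
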