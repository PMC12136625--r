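#' @keywords internal
"_PACKAGE"

# Factor ids used throughout: "N" is elemental nitrogen, "P" is P2O5 and
# "K" is K2O (the oxide conventions of fertilizer trade and soil testing).
fert_factors <- function() c("N", "P", "K")

# Level multipliers of the '3414' scheme: level 2 is the locally optimal
# dose, level 1 is half of it, level 3 one-and-a-half times, level 0 none.
level_multipliers <- function() c(`0` = 0, `1` = 0.5, `2` = 1, `3` = 1.5)

# The 14 coded treatments of the '3414' incomplete factorial, in the order
# prescribed by the soil-testing / formula-fertilization specification.
treatment_levels_3414 <- function() {
  matrix(c(
    0L, 0L, 0L,
    0L, 2L, 2L,
    1L, 2L, 2L,
    2L, 0L, 2L,
    2L, 1L, 2L,
    2L, 2L, 2L,
    2L, 3L, 2L,
    2L, 2L, 0L,
    2L, 2L, 1L,
    2L, 2L, 3L,
    3L, 2L, 2L,
    1L, 1L, 2L,
    1L, 2L, 1L,
    2L, 1L, 1L
  ), ncol = 3L, byrow = TRUE, dimnames = list(NULL, fert_factors()))
}

#' Format a treatment code
#'
#' @param levels integer vector or matrix of N, P, K levels in 0..3.
#' @return character treatment codes in the compact `"N2P2K2"` form.
#' @export
treatment_code <- function(levels) {
  if (is.matrix(levels)) {
    apply(levels, 1L, treatment_code)
  } else {
    stopifnot(length(levels) == 3L)
    paste0("N", levels[1L], "P", levels[2L], "K", levels[3L])
  }
}

#' Parse a treatment code
#'
#' Accepts the compact form `"N2P3K2"` case-insensitively with arbitrary
#' separators (`"n2 p3 k2"`, `"N2-P3-K2"`), or a bare numeric triple such
#' as `"232"`.
#'
#' @param code character vector of treatment codes.
#' @return integer matrix with one row per code and columns N, P, K.
#' @export
parse_treatment_code <- function(code) {
  clean <- toupper(gsub("[^0-9NPKnpk]", "", as.character(code)))
  out <- matrix(NA_integer_, nrow = length(code), ncol = 3L,
                dimnames = list(NULL, fert_factors()))
  full <- regmatches(clean, regexec("^N([0-3])P([0-3])K([0-3])$", clean))
  bare <- regmatches(clean, regexec("^([0-3])([0-3])([0-3])$", clean))
  for (i in seq_along(code)) {
    m <- if (length(full[[i]])) full[[i]] else bare[[i]]
    if (!length(m)) {
      stop("cannot parse treatment code: '", code[i], "'", call. = FALSE)
    }
    out[i, ] <- as.integer(m[2:4])
  }
  out
}

#' Build the canonical '3414' trial design
#'
#' Constructs the 14-treatment design for a three-factor (N, P2O5, K2O)
#' four-level fertilization trial. Level 2 carries the full reference dose
#' of each nutrient; levels 0, 1 and 3 apply 0, 0.5 and 1.5 times that
#' amount.
#'
#' @param level2 named numeric vector of reference (level 2) doses in
#'   g/plant for N, P (as P2O5) and K (as K2O). All must be positive.
#' @return A `trial_design`: a data frame with one row per treatment and
#'   columns `treatment`, `n_level`, `p_level`, `k_level`, `n_dose`,
#'   `p_dose`, `k_dose` (doses in g/plant).
#' @examples
#' build_3414_design(c(N = 30, P = 10, K = 16))
#' @export
build_3414_design <- function(level2 = c(N = 30, P = 10, K = 16)) {
  level2 <- unlist(level2)
  if (is.null(names(level2)) || !all(names(level2) %in% fert_factors())) {
    names(level2) <- fert_factors()
  }
  level2 <- level2[fert_factors()]
  if (any(!is.finite(level2)) || any(level2 <= 0)) {
    stop("all level-2 doses must be positive and finite", call. = FALSE)
  }
  lev <- treatment_levels_3414()
  mult <- level_multipliers()
  doses <- sweep(matrix(mult[as.character(lev)], ncol = 3L), 2L, level2, `*`)
  design <- data.frame(
    treatment = treatment_code(lev),
    n_level = lev[, "N"], p_level = lev[, "P"], k_level = lev[, "K"],
    n_dose = doses[, 1L], p_dose = doses[, 2L], k_dose = doses[, 3L],
    stringsAsFactors = FALSE
  )
  attr(design, "level2") <- level2
  class(design) <- c("trial_design", "data.frame")
  design
}

#' @export
print.trial_design <- function(x, ...) {
  cat("'3414' trial design:", nrow(x), "treatments\n")
  cat("level-2 doses (g/plant): N =", attr(x, "level2")[["N"]],
      ", P2O5 =", attr(x, "level2")[["P"]],
      ", K2O =", attr(x, "level2")[["K"]], "\n\n")
  print.data.frame(x, row.names = TRUE)
  invisible(x)
}

# Dose triple (g/plant) of one treatment; `treatment` may be a code or a
# row index into the design.
design_doses <- function(design, treatment) {
  row <- design_row(design, treatment)
  c(N = row$n_dose, P = row$p_dose, K = row$k_dose)
}

design_row <- function(design, treatment) {
  if (is.numeric(treatment)) {
    if (any(treatment < 1 | treatment > nrow(design))) {
      stop("treatment index out of range: ", treatment, call. = FALSE)
    }
    return(design[treatment, , drop = FALSE])
  }
  code <- treatment_code(parse_treatment_code(treatment))
  idx <- match(code, design$treatment)
  if (anyNA(idx)) {
    stop("treatment not in design: ", paste(code[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  design[idx, , drop = FALSE]
}

# Level (0..3) of `factor_id` for each treatment code in `codes`.
design_levels <- function(design, codes, factor_id) {
  col <- paste0(tolower(factor_id), "_level")
  if (!col %in% names(design)) {
    stop("unknown factor: '", factor_id, "' (expected N, P or K)",
         call. = FALSE)
  }
  design[[col]][match(codes, design$treatment)]
}
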