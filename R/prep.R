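#' Blood-pressure composites
#'
#' `pulse_pressure()` computes PP = sBP - dBP. `mean_arterial_pressure()`
#' computes the standard clinical estimate mBP = dBP + (sBP - dBP)/3 (one
#' third of the pulse pressure above diastolic, reflecting the longer
#' diastolic phase of the cardiac cycle). Both are vectorised and require
#' sBP > dBP > 0.
#'
#' @param sbp,dbp Systolic and diastolic pressures in mmHg.
#' @return Numeric vector in mmHg.
#' @examples
#' pulse_pressure(140, 90)          # 50
#' mean_arterial_pressure(120, 90)  # 100
#' @export
pulse_pressure <- function(sbp, dbp) {
  check_bp(sbp, dbp)
  sbp - dbp
}

#' @rdname pulse_pressure
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  check_bp(sbp, dbp)
  dbp + (sbp - dbp) / 3
}

check_bp <- function(sbp, dbp) {
  if (any(!is.finite(sbp)) || any(!is.finite(dbp))) {
    stop("blood pressures must be finite", call. = FALSE)
  }
  if (any(dbp <= 0)) stop("diastolic pressure must be positive", call. = FALSE)
  if (any(sbp <= dbp)) {
    stop("systolic pressure must exceed diastolic pressure", call. = FALSE)
  }
  invisible(NULL)
}

#' Assign hypertension group labels
#'
#' Classifies each subject from their hypertension-diagnosis history and
#' mean measured pressures: `PMHTN` (poorly managed hypertension) requires a
#' history of diagnosis AND a mean sBP over 140 or mean dBP over 90 mmHg;
#' `NTN` (normotensive) requires no history AND mean sBP below 140 AND mean
#' dBP below 90. Every other combination — a treated hypertensive at goal,
#' an untreated subject with elevated readings, or a reading exactly at the
#' 140/90 boundary — is `UNCLASSIFIED` and excluded from the two analysed
#' groups.
#'
#' @param history Logical, history of hypertension diagnosis.
#' @param sbp,dbp Mean systolic / diastolic pressure (mmHg) over the two
#'   office measurements.
#' @return Factor with levels `PMHTN`, `NTN`, `UNCLASSIFIED`.
#' @examples
#' assign_group(c(TRUE, FALSE, TRUE), c(150, 120, 130), c(85, 70, 80))
#' @export
assign_group <- function(history, sbp, dbp) {
  stopifnot(is.logical(history), length(history) == length(sbp),
            length(sbp) == length(dbp))
  check_bp(sbp, dbp)
  lab <- rep("UNCLASSIFIED", length(history))
  lab[history & (sbp > 140 | dbp > 90)] <- "PMHTN"
  lab[!history & sbp < 140 & dbp < 90] <- "NTN"
  factor(lab, levels = c("PMHTN", "NTN", "UNCLASSIFIED"))
}

#' Prepare a raw cohort table for analysis
#'
#' Ingest-time derivations for cohorts recorded in raw form: duplicate
#' blood-pressure readings (`sBP_1`/`sBP_2`, `dBP_1`/`dBP_2`) are averaged
#' into `sBP`/`dBP`; left/right arm-curl repetitions
#' (`arm_curl_left`/`arm_curl_right`) are averaged into `arm_curl`; `PP` and
#' `mBP` are derived from `sBP`/`dBP` when absent; and, if a logical
#' `history_of_hypertension` column is present, a `group` column is assigned
#' with [assign_group()]. Columns already present are left untouched.
#'
#' @param table Raw cohort tibble.
#' @return The prepared tibble.
#' @export
prepare_cohort <- function(table) {
  tab <- tibble::as_tibble(table)
  avg_pair <- function(tab, out, a, b) {
    if (!out %in% names(tab) && all(c(a, b) %in% names(tab))) {
      tab[[out]] <- (tab[[a]] + tab[[b]]) / 2
      tab[[a]] <- tab[[b]] <- NULL
    }
    tab
  }
  tab <- avg_pair(tab, "sBP", "sBP_1", "sBP_2")
  tab <- avg_pair(tab, "dBP", "dBP_1", "dBP_2")
  tab <- avg_pair(tab, "arm_curl", "arm_curl_left", "arm_curl_right")
  if (all(c("sBP", "dBP") %in% names(tab))) {
    if (!"PP" %in% names(tab)) tab$PP <- pulse_pressure(tab$sBP, tab$dBP)
    if (!"mBP" %in% names(tab)) tab$mBP <- mean_arterial_pressure(tab$sBP, tab$dBP)
    if (!"group" %in% names(tab) && "history_of_hypertension" %in% names(tab)) {
      tab$group <- assign_group(as.logical(tab$history_of_hypertension),
                                tab$sBP, tab$dBP)
    }
  }
  tab
}

#' Between-group descriptive comparison
#'
#' Compares every shared panel variable between two cohorts with the
#' assumption-gated test-selection rule: within each group a Shapiro-Wilk
#' normality test and across groups a Levene test of variance homogeneity,
#' both at alpha = 0.05; when both assumptions hold an independent
#' two-sample t-test (pooled variance) is used, otherwise a tie-corrected
#' Mann-Whitney U test. Effect sizes accompany significant rows only:
#' r = Z/sqrt(N) for the Mann-Whitney branch and the point-biserial
#' conversion r = sign(t) * sqrt(t^2 / (t^2 + df)) for the t branch.
#' Variables with fewer than 4 observations in either group are skipped
#' with a warning.
#'
#' @param table_a,table_b Cohort tibbles sharing variable columns; group A
#'   is the reference, so negative Z / t means group B's values are larger.
#' @param alpha Gate and significance level (default 0.05).
#' @return A tibble with one row per variable: `variable`, `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `test_used`, `statistic`, `z`, `p_value`,
#'   `effect_size_r` (NA unless `p_value < alpha`).
#' @export
compare_groups <- function(table_a, table_b, alpha = 0.05) {
  vars <- intersect(setdiff(names(table_a), "group"),
                    setdiff(names(table_b), "group"))
  vars <- vars[vapply(vars, function(v) {
    is.numeric(table_a[[v]]) && is.numeric(table_b[[v]])
  }, TRUE)]
  if (length(vars) == 0) stop("no shared numeric variables to compare", call. = FALSE)
  rows <- lapply(vars, function(v) {
    x <- table_a[[v]][!is.na(table_a[[v]])]
    y <- table_b[[v]][!is.na(table_b[[v]])]
    if (length(x) < 4 || length(y) < 4) {
      warning("skipping '", v, "': fewer than 4 observations in a group",
              call. = FALSE)
      return(NULL)
    }
    normal_ok <- tryCatch(
      stats::shapiro.test(x)$p.value >= alpha &&
        stats::shapiro.test(y)$p.value >= alpha,
      error = function(e) FALSE)  # e.g. a constant sample
    lev <- car::leveneTest(
      c(x, y), factor(rep(c("a", "b"), c(length(x), length(y)))))
    var_ok <- lev[["Pr(>F)"]][1] >= alpha
    n_tot <- length(x) + length(y)
    if (normal_ok && var_ok) {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      stat <- unname(tt$statistic)
      p <- tt$p.value
      r <- sign(stat) * sqrt(stat^2 / (stat^2 + unname(tt$parameter)))
      z <- NA_real_
      test <- "t_test"
    } else {
      mw <- mann_whitney(x, y)
      stat <- mw$U
      z <- mw$Z
      p <- mw$p_value
      r <- effect_size_r(z, n_tot)
      test <- "mann_whitney"
    }
    tibble::tibble(
      variable = v,
      mean_a = mean(x), sd_a = stats::sd(x),
      mean_b = mean(y), sd_b = stats::sd(y),
      test_used = test, statistic = stat, z = z, p_value = p,
      effect_size_r = ifelse(p < alpha, r, NA_real_),
      n_a = length(x), n_b = length(y)
    )
  })
  dplyr::bind_rows(rows)
}
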