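#' The default 30-variable study panel
#'
#' Returns the panel of physiological, cognitive, biochemical and social
#' variables over which the two group networks are built: four blood-pressure
#' indices, five cognitive scores, depression symptom intensity, six body
#' composition indicators, four physical-performance tests, six serum
#' adipokines/myokines/trophic factors, and four demographic / activity
#' ("social") variables. Each variable carries a display label, a category
#' (one of the seven node categories used for colouring exported networks),
#' units, and a marginal distribution spec used by the copula sampler.
#'
#' Marginal families are `normal`, `lognormal`, `truncated-normal` and
#' `discrete-uniform`; parameters are plausible values for community-dwelling
#' older adults. Group-specific marginals (e.g. a hypertensive group with
#' higher blood pressure and adiposity) are obtained with
#' [panel_with_marginals()].
#'
#' @return A tibble with one row per variable and columns `name`, `label`,
#'   `category`, `units`, and a list-column `marginal` (each element a list
#'   with `family`, parameters, `min`, `max`).
#' @examples
#' panel <- default_panel()
#' nrow(panel)            # 30
#' table(panel$category)
#' @export
default_panel <- function() {
  tn <- function(mean, sd, min, max) {
    list(family = "truncated-normal", mean = mean, sd = sd, min = min, max = max)
  }
  ln <- function(meanlog, sdlog, min = 0, max = Inf) {
    list(family = "lognormal", meanlog = meanlog, sdlog = sdlog, min = min, max = max)
  }
  du <- function(min, max) list(family = "discrete-uniform", min = min, max = max)

  rows <- list(
    list("sBP", "systolic blood pressure", "blood_pressure", "mmHg", tn(135, 14, 95, 200)),
    list("dBP", "diastolic blood pressure", "blood_pressure", "mmHg", tn(80, 9, 55, 115)),
    list("mBP", "mean blood pressure", "blood_pressure", "mmHg", tn(98, 9, 70, 140)),
    list("PP", "pulse pressure", "blood_pressure", "mmHg", tn(55, 12, 20, 100)),
    list("MMSE", "Mini-Mental State Examination", "cognitive_function", "points", tn(27.5, 2, 18, 30)),
    list("MoCA", "Montreal Cognitive Assessment", "cognitive_function", "points", tn(24, 3, 10, 30)),
    list("MoCA_DR", "MoCA Delayed Recall", "cognitive_function", "points", tn(3, 1.3, 0, 5)),
    list("VF", "Verbal Fluency", "cognitive_function", "words", tn(16, 4, 5, 30)),
    list("TMT_B", "Trail Making Test part B", "cognitive_function", "s", ln(log(120), 0.35, 30, 600)),
    list("GDS", "Geriatric Depression Scale", "depression", "points", tn(3.5, 2.5, 0, 15)),
    list("BMR", "basal metabolic rate", "body_composition", "kcal", tn(1350, 180, 900, 2200)),
    list("BWC", "body water content", "body_composition", "%", tn(50, 5, 35, 65)),
    list("BMI", "body mass index", "body_composition", "kg/m2", tn(26, 4, 17, 45)),
    list("body_fat", "body fat", "body_composition", "%", tn(33, 7, 10, 55)),
    list("visceral_fat", "visceral fat", "body_composition", "units", tn(9.5, 2.6, 2, 25)),
    list("muscle_mass", "muscle mass", "body_composition", "kg", tn(42, 6, 25, 70)),
    list("sixMWT", "six-minute walk test", "physical_performance", "m", tn(480, 80, 150, 800)),
    list("up_and_go", "Up and Go test", "physical_performance", "s", ln(log(7.5), 0.25, 3, 30)),
    list("arm_curl", "30-s arm curl (mean L/R)", "physical_performance", "reps", tn(16, 4, 4, 35)),
    list("chair_stand", "30-s chair stand", "physical_performance", "reps", tn(13, 3.5, 2, 30)),
    list("adiponectin", "adiponectin", "biochemical", "ug/mL", ln(log(10), 0.45)),
    list("irisin", "irisin", "biochemical", "ug/mL", ln(log(3.5), 0.4)),
    list("vaspin", "vaspin", "biochemical", "ng/mL", ln(log(0.9), 0.5)),
    list("visfatin", "visfatin", "biochemical", "ng/mL", ln(log(2.5), 0.45)),
    list("IGF_1", "insulin-like growth factor 1", "biochemical", "ng/mL", tn(130, 40, 40, 300)),
    list("IGFBP_3", "IGF binding protein 3", "biochemical", "ng/mL", tn(3800, 900, 1500, 7000)),
    list("age", "chronological age", "social", "years", tn(69, 6, 60, 90)),
    list("education_years", "years of education", "social", "years", du(7, 20)),
    list("cognitive_activity", "cognitive activity level", "social", "score", du(5, 35)),
    list("physical_activity", "physical activity level", "social", "score", du(5, 35))
  )
  tibble::tibble(
    name = vapply(rows, `[[`, "", 1L),
    label = vapply(rows, `[[`, "", 2L),
    category = vapply(rows, `[[`, "", 3L),
    units = vapply(rows, `[[`, "", 4L),
    marginal = lapply(rows, `[[`, 5L)
  )
}

#' Node categories used in the panel
#'
#' The seven node categories distinguishing cognitive, affective, somatic,
#' biochemical, performance, blood-pressure and social variables in exported
#' networks.
#' @return Character vector of the seven category names.
#' @export
panel_categories <- function() {
  c("cognitive_function", "depression", "body_composition", "biochemical",
    "physical_performance", "blood_pressure", "social")
}

#' Override marginals of a panel
#'
#' Replaces the marginal spec of selected variables, e.g. to give a
#' hypertensive group higher blood pressure and adiposity marginals while
#' keeping the panel names, order and categories fixed (both groups of a
#' scenario must share an identical panel up to marginals).
#'
#' @param panel A panel tibble as returned by [default_panel()].
#' @param ... Named arguments `variable_name = marginal_spec`, each spec a
#'   list with at least `family` and its parameters.
#' @return The panel with the named marginals replaced.
#' @export
panel_with_marginals <- function(panel, ...) {
  overrides <- list(...)
  validate_panel(panel)
  unknown <- setdiff(names(overrides), panel$name)
  if (length(unknown) > 0) {
    stop("unknown panel variable(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(overrides)) {
    panel$marginal[[match(nm, panel$name)]] <- overrides[[nm]]
  }
  panel
}

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("name", "category", "marginal") %in% names(panel)))
  if (anyDuplicated(panel$name)) {
    stop("panel variable names must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(panel$category), panel_categories())
  if (length(bad) > 0) {
    stop("unknown panel categor", if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ok <- vapply(panel$marginal, function(m) {
    is.list(m) && !is.null(m$family) &&
      m$family %in% c("normal", "lognormal", "truncated-normal", "discrete-uniform")
  }, TRUE)
  if (!all(ok)) stop("invalid marginal spec for: ",
                     paste(panel$name[!ok], collapse = ", "), call. = FALSE)
  invisible(panel)
}

# Quantile function of a declared marginal, used by the copula sampler and
# by distribution-fidelity tests.
marginal_quantile <- function(marginal, p) {
  switch(marginal$family,
    "normal" = stats::qnorm(p, marginal$mean, marginal$sd),
    "lognormal" = {
      q <- stats::qlnorm(p, marginal$meanlog, marginal$sdlog)
      pmin(pmax(q, marginal$min %||% 0), marginal$max %||% Inf)
    },
    "truncated-normal" = {
      pa <- stats::pnorm(marginal$min, marginal$mean, marginal$sd)
      pb <- stats::pnorm(marginal$max, marginal$mean, marginal$sd)
      stats::qnorm(pa + p * (pb - pa), marginal$mean, marginal$sd)
    },
    "discrete-uniform" = {
      k <- marginal$max - marginal$min + 1L
      pmin(marginal$min + floor(p * k), marginal$max)
    },
    stop("unknown marginal family: ", marginal$family, call. = FALSE)
  )
}

# CDF of a declared marginal (continuous families only), for KS-style checks.
marginal_cdf <- function(marginal) {
  switch(marginal$family,
    "normal" = function(x) stats::pnorm(x, marginal$mean, marginal$sd),
    "lognormal" = function(x) stats::plnorm(x, marginal$meanlog, marginal$sdlog),
    "truncated-normal" = function(x) {
      pa <- stats::pnorm(marginal$min, marginal$mean, marginal$sd)
      pb <- stats::pnorm(marginal$max, marginal$mean, marginal$sd)
      pmin(pmax((stats::pnorm(x, marginal$mean, marginal$sd) - pa) / (pb - pa), 0), 1)
    },
    stop("no closed-form CDF for family: ", marginal$family, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
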