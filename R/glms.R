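glm_term_table <- function(fit, test, tests) {
  if (tests == "sequential") {
    a <- anova(fit, test = test)
    a <- a[rownames(a) != "NULL", , drop = FALSE]
    data.frame(term = rownames(a), df = a$Df,
               statistic = if (test == "F") a$F else a$Deviance,
               statistic_type = if (test == "F") "F" else "Chisq",
               p = a[[grep("^Pr", names(a))]],
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    a <- car::Anova(fit, type = 3,
                    test.statistic = if (test == "F") "F" else "LR")
    a <- a[!rownames(a) %in% c("(Intercept)", "Residuals"), , drop = FALSE]
    data.frame(term = rownames(a), df = a$Df,
               statistic = if (test == "F") a$F else a[["LR Chisq"]],
               statistic_type = if (test == "F") "F" else "Chisq",
               p = a[[grep("^Pr", names(a))]],
               row.names = NULL, stringsAsFactors = FALSE)
  }
}

check_factors <- function(tab) {
  for (f in c("tide", "camera_position")) {
    if (length(unique(tab[[f]])) < 2)
      stop("factor '", f, "' needs >= 2 observed levels")
  }
}

#' Quasi-Poisson GLM for per-minute fish abundance
#'
#' Log-link count model of maximum per-minute abundance on tide direction,
#' camera position and their interaction, with the quasi-Poisson variance
#' function (variance = dispersion x mean). Term tests are dispersion-scaled
#' analysis-of-deviance F tests, sequential (Type I) by default with a switch
#' for marginal (Type III) tests. The interaction is retained in the fitted
#' model and its p-value reported.
#'
#' @param table A (typically thinned) `count_table`.
#' @param tests `"sequential"` (default) or `"marginal"`.
#' @return A `glm_report`: `family`, `terms` (term, df, statistic,
#'   statistic_type, p), `dispersion`, `coefficients`, and the underlying
#'   `fit`.
#' @export
fit_abundance_glm <- function(table, tests = c("sequential", "marginal")) {
  tests <- match.arg(tests)
  validate_count_table(table)
  check_factors(table)
  if (all(table$abundance == 0)) stop("all-zero abundance response")
  fit <- glm(abundance ~ tide * camera_position, data = table,
             family = quasipoisson())
  if (fit$rank < length(coef(fit))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; aliased: ", paste(aliased, collapse = ", "))
  }
  structure(list(family = "quasipoisson",
                 terms = glm_term_table(fit, "F", tests),
                 dispersion = summary(fit)$dispersion,
                 coefficients = coef(summary(fit)),
                 tests = tests, fit = fit, contrasts = NULL),
            class = "glm_report")
}

#' Binomial GLM for the water-column proportion
#'
#' Logit-link binomial model of the number of fish in the water column out of
#' the total abundance, on tide direction, camera position and their
#' interaction. Term tests are analysis-of-deviance chi-square tests
#' (sequential by default). Rows with zero abundance carry no information
#' about the proportion and are dropped. Fitted probabilities pinned at 0 or
#' 1 trigger a separation warning.
#'
#' @inheritParams fit_abundance_glm
#' @return A `glm_report` with `family = "binomial"` and chi-square term
#'   statistics.
#' @export
fit_proportion_glm <- function(table, tests = c("sequential", "marginal")) {
  tests <- match.arg(tests)
  validate_count_table(table)
  tab <- table[table$abundance > 0, , drop = FALSE]
  if (nrow(tab) == 0) stop("no rows with positive abundance")
  check_factors(tab)
  fit <- glm(cbind(watercolumn_count, abundance - watercolumn_count) ~
               tide * camera_position,
             data = tab, family = binomial())
  if (fit$rank < length(coef(fit))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; aliased: ", paste(aliased, collapse = ", "))
  }
  pr <- fitted(fit)
  if (any(pr < 1e-8) || any(pr > 1 - 1e-8))
    warning("fitted probabilities at 0 or 1: possible separation; ",
            "coefficients may diverge")
  structure(list(family = "binomial",
                 terms = glm_term_table(fit, "Chisq", tests),
                 dispersion = 1,
                 coefficients = coef(summary(fit)),
                 tests = tests, fit = fit, contrasts = NULL),
            class = "glm_report")
}

#' @export
print.glm_report <- function(x, ...) {
  cat(sprintf("<glm_report> %s GLM (%s tests), dispersion %.3f\n",
              x$family, x$tests, x$dispersion))
  print(x$terms, digits = 4)
  if (!is.null(x$contrasts)) {
    cat("Tukey-adjusted pairwise contrasts:\n")
    print(x$contrasts, digits = 4)
  }
  invisible(x)
}

#' Tukey HSD pairwise contrasts for a fitted GLM factor
#'
#' All pairwise contrasts among the levels of `factor` on the linear-predictor
#' scale, with family-wise p-value adjustment by the studentized-range (Tukey
#' HSD) method, averaging over the other factor as the model includes an
#' interaction.
#'
#' @param result A `glm_report` from [fit_abundance_glm()] or
#'   [fit_proportion_glm()].
#' @param factor Factor name (default `"camera_position"`; its four levels
#'   give C(4,2) = 6 contrasts).
#' @return The `glm_report` is returned invisibly with its `contrasts` slot
#'   filled; the contrasts `data.frame` (`pair`, `estimate`, `se`,
#'   `adjusted_p`) is attached and also returned as attribute-free value via
#'   `$contrasts`.
#' @export
tukey_pairwise <- function(result, factor = "camera_position") {
  stopifnot(inherits(result, "glm_report"))
  if (!factor %in% all.vars(stats::formula(result$fit)))
    stop("factor '", factor, "' not in the fitted model")
  emm <- suppressMessages(emmeans::emmeans(result$fit, specs = factor))
  pr <- suppressMessages(as.data.frame(
    emmeans::contrast(emm, method = "pairwise", adjust = "tukey")))
  result$contrasts <- data.frame(pair = as.character(pr$contrast),
                                 estimate = pr$estimate, se = pr$SE,
                                 adjusted_p = pr$p.value,
                                 stringsAsFactors = FALSE)
  result
}
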