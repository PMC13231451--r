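#' Mixed-effects model of a stage-dependent outcome
#'
#' Fits `outcome ~ stage + (1 | g)` for each random grouping factor `g`
#' (patient, night, template, unit -- whichever the analysis design
#' names), by REML via `lmerTest::lmer`, with the pre-sleep period as the
#' reference level. On a singular fit the zero-variance random terms are
#' dropped with a message and the model refitted; if no random term
#' survives, an ordinary linear model is returned.
#'
#' @param data data.frame with the outcome, a `stage` column and the
#'   grouping columns.
#' @param outcome name of the outcome column.
#' @param random character vector of random-intercept grouping columns
#'   (each must have >= 2 levels).
#' @param reference reference stage (default `"Pre"`; must be present).
#' @param stage_col name of the stage column.
#' @return List of class `stage_fit`: `fit` (the lmer/lm object),
#'   `formula`, `fixed` (coefficient table), `dropped` (random terms
#'   removed for singularity), `singular`.
#' @export
fit_stage_model <- function(data, outcome, random = "patient",
                            reference = "Pre", stage_col = "stage") {
  data <- data[!is.na(data[[stage_col]]) & !is.na(data[[outcome]]), , drop = FALSE]
  stages <- unique(data[[stage_col]])
  if (length(stages) < 2) stop("need at least 2 stages")
  if (!reference %in% stages) stop(sprintf("reference stage '%s' absent", reference))
  data[[stage_col]] <- stats::relevel(factor(data[[stage_col]],
                                             levels = intersect(STAGES, stages)),
                                      ref = reference)
  for (g in random) {
    if (length(unique(data[[g]])) < 2)
      stop(sprintf("random factor '%s' has a single level", g))
    data[[g]] <- factor(data[[g]])
  }
  dropped <- character(0)
  repeat {
    if (length(random)) {
      f <- as.formula(paste(outcome, "~", stage_col, "+",
                            paste(sprintf("(1 | %s)", random), collapse = " + ")))
      fit <- lmerTest::lmer(f, data = data, REML = TRUE)
      if (!lme4::isSingular(fit, tol = 1e-5)) break
      vc <- as.data.frame(lme4::VarCorr(fit))
      zero <- vc$grp[vc$grp != "Residual" & vc$vcov < 1e-8]
      if (!length(zero)) break  # singular for another reason; keep the fit
      message("singular fit: dropping random term(s) ", paste(zero, collapse = ", "))
      dropped <- c(dropped, zero)
      random <- setdiff(random, zero)
    } else {
      f <- as.formula(paste(outcome, "~", stage_col))
      fit <- lm(f, data = data)
      break
    }
  }
  fixed <- if (inherits(fit, "lmerMod") || inherits(fit, "lmerModLmerTest"))
    as.data.frame(coef(summary(fit))) else as.data.frame(coef(summary(fit)))
  structure(list(fit = fit, formula = f, fixed = fixed, dropped = dropped,
                 singular = inherits(fit, "merMod") && lme4::isSingular(fit, tol = 1e-5),
                 reference = reference, data = data),
            class = "stage_fit")
}

#' Tukey post-hoc stage contrasts
#'
#' Pairwise stage contrasts with Tukey family-wise adjustment via
#' `emmeans`; the full family is computed and the contrasts against the
#' reference (pre-sleep) period are reported separately with the star
#' convention `p < 0.05` = ".", `p < 0.01` = "*", `p < 0.001` = "**",
#' `p < 0.0001` = "***".
#'
#' @param fit a `stage_fit` from [fit_stage_model()].
#' @param reference reference stage (defaults to the fit's).
#' @return List with `all_pairs` (full Tukey family) and `vs_reference`
#'   (stage minus reference: `estimate`, `SE`, `p_adj`, `stars`).
#' @export
posthoc_contrasts <- function(fit, reference = NULL) {
  reference <- reference %||% fit$reference
  emm <- emmeans::emmeans(fit$fit, "stage")
  prs <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "tukey"))
  ## rows involving the reference, oriented as stage - reference
  sides <- strsplit(as.character(prs$contrast), " - ")
  inv <- vapply(sides, function(s) s[1] == reference, TRUE)
  hit <- vapply(sides, function(s) reference %in% s, TRUE)
  vs <- prs[hit, , drop = FALSE]
  vs$stage <- vapply(sides[hit], function(s) setdiff(s, reference)[1], "")
  vs$estimate[inv[hit]] <- -vs$estimate[inv[hit]]
  out <- data.frame(stage = vs$stage, estimate = vs$estimate, SE = vs$SE,
                    p_adj = vs$p.value, stars = significance_stars(vs$p.value))
  rownames(out) <- NULL
  list(all_pairs = prs, vs_reference = out)
}

#' Significance stars
#'
#' Annotation convention for stage contrasts: `p < 0.05` gives ".",
#' `p < 0.01` "*", `p < 0.001` "**", `p < 0.0001` "***".
#'
#' @param p numeric vector of p-values.
#' @return Character vector of annotations ("" when `p >= 0.05`).
#' @export
significance_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) ""
    else if (x < 1e-4) "***"
    else if (x < 1e-3) "**"
    else if (x < 1e-2) "*"
    else if (x < 0.05) "."
    else ""
  }, "")
}

#' Per-stage descriptive summary
#'
#' Group means per combination of the `by` identifiers and stage, plus
#' the display normalizations used for stage figures: the ratio to the
#' same group's pre-sleep mean and the symmetric relative change
#' `(x - Pre) / (x + Pre)` (0 at parity, 0.5 at a three-fold increase).
#'
#' @param data data.frame with the outcome, `stage`, and grouping
#'   columns.
#' @param outcome outcome column name.
#' @param by grouping columns (e.g. patient, night).
#' @param reference reference stage.
#' @param stage_col stage column name.
#' @return data.frame with group columns, `stage`, `mean`,
#'   `rel_to_pre`, `sym_change` (the latter two `NA` when the group has
#'   no reference windows).
#' @export
stage_summary <- function(data, outcome, by = "patient", reference = "Pre",
                          stage_col = "stage") {
  data <- data[!is.na(data[[stage_col]]), , drop = FALSE]
  fml <- as.formula(paste(outcome, "~", paste(c(by, stage_col), collapse = " + ")))
  agg <- aggregate(fml, data = data, FUN = mean)
  names(agg)[names(agg) == outcome] <- "mean"
  names(agg)[names(agg) == stage_col] <- "stage"
  key <- interaction(agg[by], drop = TRUE)
  agg$rel_to_pre <- NA_real_
  agg$sym_change <- NA_real_
  for (g in levels(key)) {
    rows <- which(key == g)
    pre <- agg$mean[rows][agg$stage[rows] == reference]
    if (length(pre) == 1) {
      x <- agg$mean[rows]
      agg$rel_to_pre[rows] <- x / pre
      agg$sym_change[rows] <- (x - pre) / (x + pre)
    }
  }
  agg[order(key, match(agg$stage, STAGES)), , drop = FALSE]
}
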