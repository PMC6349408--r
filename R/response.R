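#' Genotype-by-condition interaction test
#'
#' Likelihood-ratio test for a condition-dependent genotype effect on a
#' phenotype measured in overlapping donors across conditions. Two linear
#' mixed models with a donor random intercept are fitted by maximum
#' likelihood (ML, not REML, so the fixed-effect LRT is valid):
#'
#' * H0: `phenotype ~ genotype + condition + (1|donor)`
#' * H1: `phenotype ~ genotype + condition + condition:genotype + (1|donor)`
#'
#' and `2 * (ll1 - ll0)` is referred to a chi-squared distribution with
#' `n_conditions - 1` degrees of freedom (1 for the usual stimulated vs
#' naive contrast). If either fit is singular (zero donor variance), both
#' models are refitted as plain fixed-effects regressions and the result is
#' flagged.
#'
#' @param t long-format data.frame with columns `donor_id`, `condition`,
#'   `dosage`, `phenotype` (see [simulate_conditions()]). Donors observed in
#'   a single condition are retained; dosage must be constant within donor.
#' @return List with `lrt_p`, `chisq`, `df`, `singular`.
#' @export
interaction_lrt <- function(t) {
  check_long_table(t)
  d <- data.frame(
    y = t$phenotype,
    g = t$dosage,
    cond = factor(t$condition),
    donor = factor(t$donor_id)
  )
  n_cond <- nlevels(d$cond)
  ctrl <- lme4::lmerControl(
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4),
    calc.derivs = FALSE
  )
  m0 <- lme4::lmer(y ~ g + cond + (1 | donor), data = d, REML = FALSE,
                   control = ctrl)
  m1 <- lme4::lmer(y ~ g + cond + cond:g + (1 | donor), data = d,
                   REML = FALSE, control = ctrl)
  singular <- lme4::isSingular(m0) || lme4::isSingular(m1)
  if (singular) {
    f0 <- stats::lm(y ~ g + cond, data = d)
    f1 <- stats::lm(y ~ g + cond + cond:g, data = d)
    ll0 <- as.numeric(stats::logLik(f0))
    ll1 <- as.numeric(stats::logLik(f1))
  } else {
    ll0 <- as.numeric(stats::logLik(m0))
    ll1 <- as.numeric(stats::logLik(m1))
  }
  chisq <- max(0, 2 * (ll1 - ll0))
  df <- n_cond - 1L
  list(
    lrt_p = stats::pchisq(chisq, df = df, lower.tail = FALSE),
    chisq = chisq,
    df = df,
    singular = singular
  )
}

check_long_table <- function(t) {
  need <- c("donor_id", "condition", "dosage", "phenotype")
  missing_cols <- setdiff(need, colnames(t))
  if (length(missing_cols)) {
    stop("long phenotype table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (length(unique(t$condition)) < 2L) {
    stop("need at least 2 conditions, found ",
         length(unique(t$condition)))
  }
  per_donor <- tapply(t$condition, t$donor_id, function(x) length(unique(x)))
  if (sum(per_donor >= 2L) < 3L) {
    stop("need >= 3 donors observed in more than one condition")
  }
  dos <- tapply(t$dosage, t$donor_id, function(x) length(unique(x)))
  if (any(dos > 1L)) {
    stop("dosage varies within donor(s): ",
         paste(names(dos)[dos > 1L], collapse = ", "))
  }
  if (length(unique(t$dosage)) < 2L) stop("dosage is constant across donors")
  invisible(TRUE)
}

#' Random-effects variance decomposition of a QTL
#'
#' Quantifies how much of a QTL's genetic variance is condition-dependent by
#' fitting `phenotype ~ (1|genotype) + (1|condition) + (1|condition:genotype)`
#' with all three factors as random effects (genotype as an unordered factor
#' of dosage levels — a deliberate simplification that ignores the expected
#' linear dose-response; an additive-coding alternative is available via
#' `additive = TRUE` for sensitivity analysis) and reporting
#' `sigma2_relative = sigma2_interaction / (sigma2_interaction + sigma2_genotype)`.
#'
#' @param t long-format table as for [interaction_lrt()].
#' @param additive use additive (linear dosage) coding instead of factor
#'   coding; components are then variances of the fitted fixed-effect parts.
#' @return List with `sigma2_genotype`, `sigma2_condition`,
#'   `sigma2_interaction`, `sigma2_relative` (0 with a flag when both
#'   genetic components vanish) and `degenerate`.
#' @export
variance_components <- function(t, additive = FALSE) {
  check_long_table(t)
  d <- data.frame(
    y = t$phenotype,
    geno = factor(t$dosage),
    cond = factor(t$condition),
    dose = t$dosage
  )
  if (additive) {
    f <- stats::lm(y ~ dose * cond, data = d)
    mm <- stats::model.matrix(f)
    cf <- stats::coef(f)
    int_cols <- grepl(":", names(cf))
    g_part <- mm[, "dose"] * cf["dose"]
    i_part <- mm[, int_cols, drop = FALSE] %*% cf[int_cols]
    s2g <- stats::var(g_part)
    s2i <- stats::var(as.numeric(i_part))
    s2c <- stats::var(as.numeric(
      mm[, grepl("^cond", names(cf)) & !int_cols, drop = FALSE] %*%
        cf[grepl("^cond", names(cf)) & !int_cols]
    ))
  } else {
    ctrl <- lme4::lmerControl(
      check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4),
      calc.derivs = FALSE
    )
    m <- lme4::lmer(y ~ (1 | geno) + (1 | cond) + (1 | geno:cond), data = d,
                    REML = FALSE, control = ctrl)
    vc <- as.data.frame(lme4::VarCorr(m))
    comp <- function(name) {
      v <- vc$vcov[vc$grp == name]
      if (length(v)) v else 0
    }
    s2g <- comp("geno")
    s2c <- comp("cond")
    s2i <- comp("geno:cond")
  }
  tot <- s2i + s2g
  list(
    sigma2_genotype = s2g,
    sigma2_condition = s2c,
    sigma2_interaction = s2i,
    sigma2_relative = if (tot > 0) s2i / tot else 0,
    degenerate = tot <= 0
  )
}

#' Classify response QTLs
#'
#' A QTL detected in a stimulated condition is called a response QTL when
#' the genotype-by-condition interaction is significant after BH correction
#' across the condition's candidates (FDR < `fdr_threshold`) *and* more than
#' `sigma2_threshold` of its genetic variance is explained by the
#' interaction term.
#'
#' @param candidates data.frame with columns `lrt_p`, `sigma2_relative` and
#'   optionally `condition` (BH correction is applied within condition).
#' @param fdr_threshold interaction FDR threshold (default 0.10).
#' @param sigma2_threshold relative-variance threshold (default 0.5,
#'   strict `>`).
#' @return The input with `fdr` and logical `is_response` columns appended.
#' @export
classify_response <- function(candidates, fdr_threshold = 0.10,
                              sigma2_threshold = 0.5) {
  stopifnot(all(c("lrt_p", "sigma2_relative") %in% colnames(candidates)))
  out <- candidates
  out$fdr <- NA_real_
  grp <- if ("condition" %in% colnames(out)) out$condition else
    rep("all", nrow(out))
  for (cc in unique(grp)) {
    i <- grp == cc
    out$fdr[i] <- bh_fdr(out$lrt_p[i])
  }
  out$is_response <- out$fdr < fdr_threshold &
    out$sigma2_relative > sigma2_threshold
  out
}
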