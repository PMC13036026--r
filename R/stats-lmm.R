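#' Fit the per-region factorial model
#'
#' For one region, density is modeled with full-factorial fixed effects of
#' treatment, time and sex (all two-way interactions and the three-way) and
#' a random intercept per mouse. Reference levels are (saline, 1h, male),
#' so the treatment main effect is the morphine effect in 1h males. REML
#' estimation via \pkg{lme4} is used whenever a mouse contributes more than
#' one row; in the common per-region layout each mouse contributes exactly
#' one observation, the intercept/residual split is then unidentifiable and
#' the model is fit by ordinary least squares with the random-intercept
#' variance reported as zero — downstream standardization only ever uses
#' the identifiable SUM \code{sigma2_resid + sigma2_intercept}.
#'
#' @param dm a [DensityMatrix].
#' @param region region id or acronym.
#' @return list (class \code{"fosmap_lmm"}) with \code{region},
#'   \code{beta}, \code{cov_beta}, \code{sigma2_resid},
#'   \code{sigma2_intercept}, \code{converged}, \code{n}.
#' @export
fitRegionLmm <- function(dm, region) {
    rd <- SummarizedExperiment::rowData(dm)
    i <- if (is.character(region)) match(region, rd$acronym) else
        match(as.integer(region), rd$id)
    if (is.na(i)) stop("region not present in the density matrix: ", region)
    cd <- as.data.frame(SummarizedExperiment::colData(dm))
    dat <- data.frame(
        density = as.numeric(SummarizedExperiment::assay(dm, "density")[i, ]),
        treatment = factor(cd$treatment, levels = c("saline", "morphine")),
        time = factor(cd$time, levels = c("1h", "4h")),
        sex = factor(cd$sex, levels = c("male", "female")),
        mouse = factor(cd$animal_id))
    cells <- table(dat$treatment, dat$time, dat$sex)
    if (any(cells == 0)) {
        empty <- which(cells == 0, arr.ind = TRUE)[1, ]
        stop(sprintf("design error: empty cell (%s, %s, %s)",
                     dimnames(cells)[[1]][empty[1]],
                     dimnames(cells)[[2]][empty[2]],
                     dimnames(cells)[[3]][empty[3]]))
    }
    form_fixed <- density ~ treatment * time * sex
    repeated <- any(duplicated(dat$mouse))
    if (repeated) {
        fit <- try(lme4::lmer(density ~ treatment * time * sex + (1 | mouse),
                              data = dat, REML = TRUE), silent = TRUE)
        if (!inherits(fit, "try-error")) {
            vc <- lme4::VarCorr(fit)
            s2u <- as.numeric(vc$mouse[1, 1])
            s2e <- attr(vc, "sc")^2
            beta <- lme4::fixef(fit)
            covb <- as.matrix(vcov(fit))
            conv <- length(fit@optinfo$conv$lme4) == 0L
            return(structure(list(region = rd$acronym[i], beta = beta,
                                  cov_beta = covb, sigma2_resid = s2e,
                                  sigma2_intercept = s2u, converged = conv,
                                  n = nrow(dat)),
                             class = "fosmap_lmm"))
        }
    }
    fit <- lm(form_fixed, data = dat)
    s2e <- sum(resid(fit)^2) / fit$df.residual
    ## a numerically-zero residual variance (constant input) is reported
    ## as exactly zero so downstream standardization fails loudly instead
    ## of dividing by rounding noise
    tol2 <- (1e-8 * (sd(dat$density) + abs(mean(dat$density)) + 1))^2
    if (s2e < tol2) s2e <- 0
    ## vcov warns on an exactly-perfect fit; that case is already snapped
    ## to zero variance above and rejected downstream
    covb <- suppressWarnings(vcov(fit))
    structure(list(region = rd$acronym[i], beta = coef(fit),
                   cov_beta = covb, sigma2_resid = s2e,
                   sigma2_intercept = 0, converged = TRUE, n = nrow(dat)),
              class = "fosmap_lmm")
}

#' The eight reported contrasts
#'
#' Group morphine effects at each time x sex combination and the
#' treatment:time / treatment:sex interaction contrasts at each level of
#' the other factor, expressed as contrast vectors over the full-factorial
#' coefficient vector (treatment main effect = morphine at 1h in males):
#' for example the female-4h morphine effect is
#' \code{beta_treat + beta_treat:time + beta_treat:sex +
#' beta_treat:time:sex}.
#'
#' @return named list of contrast vectors (names are coefficient names).
#' @export
standardContrasts <- function() {
    cn <- c("(Intercept)", "treatmentmorphine", "time4h", "sexfemale",
            "treatmentmorphine:time4h", "treatmentmorphine:sexfemale",
            "time4h:sexfemale", "treatmentmorphine:time4h:sexfemale")
    cv <- function(terms) {
        v <- setNames(numeric(length(cn)), cn)
        v[terms] <- 1
        v
    }
    list(
        "treat@M1h" = cv("treatmentmorphine"),
        "treat@F1h" = cv(c("treatmentmorphine",
                           "treatmentmorphine:sexfemale")),
        "treat@M4h" = cv(c("treatmentmorphine",
                           "treatmentmorphine:time4h")),
        "treat@F4h" = cv(c("treatmentmorphine", "treatmentmorphine:time4h",
                           "treatmentmorphine:sexfemale",
                           "treatmentmorphine:time4h:sexfemale")),
        "treat:time@M" = cv("treatmentmorphine:time4h"),
        "treat:time@F" = cv(c("treatmentmorphine:time4h",
                              "treatmentmorphine:time4h:sexfemale")),
        "treat:sex@1h" = cv("treatmentmorphine:sexfemale"),
        "treat:sex@4h" = cv(c("treatmentmorphine:sexfemale",
                              "treatmentmorphine:time4h:sexfemale")))
}

#' Standardized effect sizes for a fitted region model
#'
#' For a contrast vector c the effect is beta_c = c'beta with standard
#' error \code{sqrt(c' cov c)}. Cohen's d standardizes beta_c by the total
#' SD \code{sqrt(sigma2_resid + sigma2_intercept)} — the model's residual
#' SD and random-intercept variance combined — and the 95% CI on d scales
#' the Wald CI of beta_c by the same SD (the SD is treated as known; no
#' small-sample correction is applied). p-values are two-sided normal
#' (Wald) tests of beta_c.
#'
#' @param fit a [fitRegionLmm()] result.
#' @param contrasts named list of contrast vectors; defaults to
#'   [standardContrasts()].
#' @param d_threshold large-effect cut on |d|.
#' @return data.frame with one row per contrast: \code{region},
#'   \code{contrast}, \code{beta}, \code{d}, \code{d_lower},
#'   \code{d_upper}, \code{p}, \code{large_effect}.
#' @export
effectSizes <- function(fit, contrasts = standardContrasts(),
                        d_threshold = 0.8) {
    if (!isTRUE(fit$converged)) stop("model did not converge")
    total_var <- fit$sigma2_resid + fit$sigma2_intercept
    if (total_var <= 0)
        stop("degenerate-variance error: total variance is zero, d undefined")
    sd_tot <- sqrt(total_var)
    rows <- lapply(names(contrasts), function(nm) {
        cvec <- contrasts[[nm]]
        stopifnot(all(names(cvec) %in% names(fit$beta)))
        cc <- setNames(numeric(length(fit$beta)), names(fit$beta))
        cc[names(cvec)] <- cvec
        bc <- sum(cc * fit$beta)
        se <- sqrt(as.numeric(t(cc) %*% fit$cov_beta %*% cc))
        d <- bc / sd_tot
        z <- if (se > 0) bc / se else 0
        data.frame(region = fit$region, contrast = nm, beta = bc, d = d,
                   d_lower = (bc - 1.96 * se) / sd_tot,
                   d_upper = (bc + 1.96 * se) / sd_tot,
                   p = 2 * pnorm(-abs(z)),
                   large_effect = abs(d) > d_threshold,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
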