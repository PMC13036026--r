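#' Factorial cohort specification
#'
#' Describes the cohort design and the generative model behind synthetic
#' density matrices. The default group sizes reproduce the study design this
#' workflow targets: a treatment (morphine/saline) x time (1 h/4 h) x sex
#' (male/female) factorial with group sizes 5/3/4/3 (morphine) and 3/2/3/4
#' (saline), 27 animals in total (15 males, 12 females).
#'
#' Effects are injected additively on the density scale but scaled by the
#' total SD \code{sqrt(sigma_mouse^2 + sigma_resid^2)}, so the injected
#' numbers ARE the standardized effect sizes (Cohen's d) the inference stack
#' should recover.
#'
#' @param groups data.frame with columns \code{treatment}, \code{time},
#'   \code{sex}, \code{n}; defaults to the 8-group design above.
#' @param baseline_density named numeric, baseline cells/mm^3 per region
#'   acronym.
#' @param effect_map named list: per region acronym a numeric 3-vector
#'   \code{c(d_treat, d_treat_time, d_treat_sex)} of standardized effects
#'   (all zero when absent).
#' @param sigma_mouse between-animal SD (cells/mm^3); default 20% of the
#'   mean baseline.
#' @param sigma_resid within-animal per-region residual SD; default 30% of
#'   the mean baseline.
#' @return a list with class \code{"fosmap_cohort_spec"}.
#' @export
cohortSpec <- function(groups = defaultGroups(), baseline_density,
                       effect_map = list(), sigma_mouse = NULL,
                       sigma_resid = NULL) {
    stopifnot(all(c("treatment", "time", "sex", "n") %in% names(groups)))
    if (nrow(groups) == 0L || any(groups$n < 1))
        stop("design error: every group needs at least one animal")
    if (is.null(sigma_mouse)) sigma_mouse <- 0.2 * mean(baseline_density)
    if (is.null(sigma_resid)) sigma_resid <- 0.3 * mean(baseline_density)
    stopifnot(sigma_mouse >= 0, sigma_resid >= 0)
    structure(list(groups = groups, baseline_density = baseline_density,
                   effect_map = effect_map, sigma_mouse = sigma_mouse,
                   sigma_resid = sigma_resid),
              class = "fosmap_cohort_spec")
}

#' @rdname cohortSpec
#' @export
defaultGroups <- function() {
    data.frame(
        treatment = rep(c("morphine", "saline"), each = 4),
        time = rep(c("1h", "1h", "4h", "4h"), 2),
        sex = rep(c("male", "female"), 4),
        n = c(5L, 3L, 4L, 3L, 3L, 2L, 3L, 4L),
        stringsAsFactors = FALSE)
}

#' Simulate a cohort density matrix with known effects
#'
#' Generative mirror of the inference model: for each animal a mouse
#' intercept is drawn from \code{N(0, sigma_mouse^2)}; for each region,
#' density = baseline + (d_treat I(morphine) + d_treat_time I(morphine) I(4h)
#' + d_treat_sex I(morphine) I(female)) * total SD + intercept +
#' \code{N(0, sigma_resid^2)}. The reference cell is (saline, 1 h, male).
#' Negative densities are clipped at zero with a warning.
#'
#' @param atlas an [AtlasBundle]; regions named in \code{spec} must be
#'   leaf acronyms of its ontology.
#' @param spec a [cohortSpec()].
#' @param seed integer seed.
#' @return list with \code{dm} (a [DensityMatrix]) and \code{truth_effects}
#'   (data.frame of the injected standardized effects per region).
#' @export
simulateCohort <- function(atlas, spec, seed = 1L) {
    set.seed(seed)
    s <- structures(atlas)
    acrs <- names(spec$baseline_density)
    if (!all(acrs %in% s$acronym))
        stop("baseline_density names must be ontology acronyms")
    if (length(spec$effect_map) &&
        !all(names(spec$effect_map) %in% acrs))
        stop("effect_map regions must appear in baseline_density")
    g <- spec$groups
    meta <- do.call(rbind, lapply(seq_len(nrow(g)), function(i)
        data.frame(treatment = g$treatment[i], time = g$time[i],
                   sex = g$sex[i], stringsAsFactors = FALSE)[rep(1, g$n[i]), ,
                                                            drop = FALSE]))
    rownames(meta) <- NULL
    meta$animal_id <- sprintf("%s-%s-%s-%02d",
                              substr(meta$treatment, 1, 1), meta$time,
                              substr(meta$sex, 1, 1),
                              stats::ave(seq_len(nrow(meta)),
                                         paste(meta$treatment, meta$time,
                                               meta$sex),
                                         FUN = seq_along))
    n_animal <- nrow(meta)
    total_sd <- sqrt(spec$sigma_mouse^2 + spec$sigma_resid^2)
    intercept <- rnorm(n_animal, 0, spec$sigma_mouse)
    dens <- matrix(0, length(acrs), n_animal,
                   dimnames = list(acrs, meta$animal_id))
    truth <- data.frame(acronym = acrs, d_treat = 0, d_treat_time = 0,
                        d_treat_sex = 0, stringsAsFactors = FALSE)
    for (r in seq_along(acrs)) {
        eff <- spec$effect_map[[acrs[r]]]
        if (is.null(eff)) eff <- c(0, 0, 0)
        truth[r, 2:4] <- eff
        mu <- spec$baseline_density[[acrs[r]]] +
            total_sd * (eff[1] * (meta$treatment == "morphine") +
                        eff[2] * (meta$treatment == "morphine") *
                            (meta$time == "4h") +
                        eff[3] * (meta$treatment == "morphine") *
                            (meta$sex == "female"))
        dens[r, ] <- mu + intercept + rnorm(n_animal, 0, spec$sigma_resid)
    }
    if (any(dens < 0)) {
        warning(sum(dens < 0), " negative densities clipped at 0")
        dens[dens < 0] <- 0
    }
    ids <- s$id[match(acrs, s$acronym)]
    dm <- densityMatrix(dens, region_id = ids, acronym = acrs, meta = meta)
    list(dm = dm, truth_effects = truth)
}
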