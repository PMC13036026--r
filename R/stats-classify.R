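#' Classify regions as treatment-responsive, time-different, sex-different
#'
#' Applies the reporting rules to a table of per-region effect records. A
#' region responds to treatment if any of the four group contrasts
#' (\code{treat@M1h}, \code{treat@F1h}, \code{treat@M4h}, \code{treat@F4h})
#' has a large standardized effect (|d| > \code{d_threshold}) whose
#' confidence interval excludes 0. Time differences and sex differences use
#' the same rule on the \code{treat:time@*} and \code{treat:sex@*}
#' interaction contrasts. FDR is controlled separately within each contrast
#' family across regions (the conservative reading of per-family starring),
#' and stars are assigned from q (* q < 0.05, ** q < 0.01, *** q < 0.001).
#'
#' @param effects data.frame from [effectSizes()] rows over multiple
#'   regions (columns \code{region}, \code{contrast}, \code{beta},
#'   \code{d}, \code{d_lower}, \code{d_upper}, \code{p},
#'   \code{large_effect}).
#' @param config an [analysisConfig()].
#' @return list with \code{effects} (input plus \code{q}, \code{stars},
#'   \code{responsive}), \code{responsive_regions},
#'   \code{responsive_by_group}, \code{time_difference} (per sex),
#'   \code{sex_difference} (per time point), \code{significant_regions}
#'   (q < threshold in any group contrast).
#' @export
classifyResponses <- function(effects, config = analysisConfig()) {
    group_contrasts <- c("treat@M1h", "treat@F1h", "treat@M4h", "treat@F4h")
    time_contrasts <- c("treat:time@M", "treat:time@F")
    sex_contrasts <- c("treat:sex@1h", "treat:sex@4h")
    need <- c(group_contrasts, time_contrasts, sex_contrasts)
    tab <- table(effects$region)
    per_region <- tapply(effects$contrast, effects$region,
                         function(x) all(need %in% x))
    if (!all(unlist(per_region)))
        stop("consistency error: some regions lack required contrasts")
    ## FDR within each contrast family (one family = one contrast name
    ## across all regions)
    effects$q <- ave(effects$p, effects$contrast, FUN = bhFdr)
    effects$stars <- starsFromQ(effects$q)
    hit <- function(df) abs(df$d) > config$d_threshold &
        (df$d_lower > 0 | df$d_upper < 0)
    effects$responsive <- FALSE
    gsel <- effects$contrast %in% group_contrasts
    effects$responsive[gsel] <- hit(effects[gsel, ])
    regions <- unique(effects$region)
    by_group <- lapply(setNames(group_contrasts, group_contrasts),
                       function(ct) {
                           df <- effects[effects$contrast == ct, ]
                           sort(df$region[hit(df)])
                       })
    responsive_regions <- sort(unique(unlist(by_group)))
    time_diff <- lapply(setNames(time_contrasts, c("male", "female")),
                        function(ct) {
                            df <- effects[effects$contrast == ct, ]
                            sort(df$region[hit(df)])
                        })
    sex_diff <- lapply(setNames(sex_contrasts, c("1h", "4h")),
                       function(ct) {
                           df <- effects[effects$contrast == ct, ]
                           sort(df$region[hit(df)])
                       })
    sig <- effects$region[gsel & effects$q < config$q_threshold]
    list(effects = effects, responsive_regions = responsive_regions,
         responsive_by_group = by_group, time_difference = time_diff,
         sex_difference = sex_diff,
         significant_regions = sort(unique(sig)))
}

#' Run the full inference stack on a density matrix
#'
#' Region selection (random forest, nonzero importance, ancestor pruning),
#' per-region factorial fits, standardized effects for the eight standard
#' contrasts, per-family FDR and response classification.
#'
#' @param dm a [DensityMatrix].
#' @param ontology the [BrainOntology].
#' @param config an [analysisConfig()].
#' @param regions optional explicit region ids (skips selection).
#' @return the [classifyResponses()] report, plus \code{selection} when
#'   selection ran.
#' @export
analyzeCohort <- function(dm, ontology, config = analysisConfig(),
                          regions = NULL) {
    selection <- NULL
    if (is.null(regions)) {
        selection <- selectRegions(dm, ontology,
                                   n_trees = config$rf_n_trees,
                                   cv_folds = config$rf_cv_folds,
                                   seed = config$rng_seed)
        regions <- selection$pruned
    }
    rd <- SummarizedExperiment::rowData(dm)
    regions <- regions[regions %in% rd$id]
    if (!length(regions)) stop("no regions to analyze")
    eff <- do.call(rbind, lapply(regions, function(r)
        effectSizes(fitRegionLmm(dm, r), d_threshold = config$d_threshold)))
    rep_ <- classifyResponses(eff, config)
    rep_$selection <- selection
    rep_
}
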