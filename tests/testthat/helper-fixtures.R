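## shared fixtures, built in code

## hand-made 7-structure ontology:
## root(1) -> {A(2) -> {A1(4, 0.1), A2(5, 0.25)}, B(3) -> {B1(6, 0.3), B2(7, 2.0)}}
toyOntologyTable <- function() {
    data.frame(
        id = 1:7,
        acronym = c("root", "A", "B", "A1", "A2", "B1", "B2"),
        name = paste("structure", 1:7),
        parent_id = c(NA, 1L, 1L, 2L, 2L, 3L, 3L),
        volume_mm3 = c(2.65, 0.35, 2.3, 0.1, 0.25, 0.3, 2.0),
        is_gray_matter = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
        stringsAsFactors = FALSE)
}

toyOntology <- function() ontologyFromTable(toyOntologyTable())

## small imaging fixture shared across detection/classification tests;
## built once per test run
.fixtureEnv <- new.env(parent = emptyenv())

smallPhantom <- function() {
    if (!is.null(.fixtureEnv$phantom)) return(.fixtureEnv$phantom)
    atlas <- makeToyAtlas(2L, c(40L, 96L, 96L), c(5.33, 1.5, 1.5),
                          seed = 3L)
    s <- structures(atlas)
    leaf <- s$id[s$is_gray_matter]
    spec <- phantomSpec(spacing_um = spacing(atlas),
                        region_rates = setNames(rep(40000, length(leaf)),
                                                leaf))
    sim <- simulateVolume(atlas, spec, seed = 7L)
    .fixtureEnv$phantom <- list(atlas = atlas, spec = spec,
                                volume = sim$volume, truth = sim$truth)
    .fixtureEnv$phantom
}

smallClassifier <- function() {
    if (!is.null(.fixtureEnv$model)) return(.fixtureEnv$model)
    ph <- smallPhantom()
    .fixtureEnv$model <- fosmap:::.trainOnPhantom(ph$atlas, ph$spec,
                                                  seed = 99L)
    .fixtureEnv$model
}

## an isolated noise-free Gaussian blob
singleBlobVolume <- function(center_vox = c(15, 20, 22),
                             dims = c(30L, 40L, 40L),
                             spacing = c(5.33, 1.5, 1.5),
                             sigma_um = c(4, 1.5, 1.5), amplitude = 10) {
    vol <- array(0, dims)
    center_um <- (center_vox) * spacing   # 0-based voxel index * spacing
    vol <- fosmap:::.renderBlob(vol, center_um, sigma_um, amplitude,
                                spacing)
    list(volume = vol, center_um = center_um, spacing = spacing,
         sigma_um = sigma_um)
}
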