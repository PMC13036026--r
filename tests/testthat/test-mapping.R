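test_that("trilinear interpolation matches the hand computation", {
    ## 1D-linear displacement field d(x) = 0.1 * x sampled on a 10-um grid:
    ## at x = 15 (between nodes at 10 and 20) the displacement is 1.5
    n <- c(2L, 2L, 5L)
    disp <- array(0, c(n, 3L))
    xs <- (0:4) * 10
    for (i in 1:5) disp[, , i, 3] <- 0.1 * xs[i]
    field <- new("DeformationField", displacements = disp,
                 grid_spacing_um = c(10, 10, 10))
    st <- spotTable(x_um = 15, y_um = 5, z_um = 5)
    out <- spots(transformSpots(st, field))
    expect_equal(out$x_um, 15 + 1.5)
    expect_equal(out$y_um, 5)
    expect_false(out$out_of_grid)
})

test_that("out-of-grid spots are clamped and flagged, not dropped", {
    n <- c(2L, 2L, 2L)
    disp <- array(0, c(n, 3L))
    disp[, , , 3] <- 7
    field <- new("DeformationField", displacements = disp,
                 grid_spacing_um = c(10, 10, 10))
    st <- spotTable(x_um = c(5, 500), y_um = c(5, 5), z_um = c(5, 5))
    out <- spots(transformSpots(st, field))
    expect_identical(nrow(out), 2L)
    expect_identical(out$out_of_grid, c(FALSE, TRUE))
    expect_equal(out$x_um, c(12, 507))
    ## degenerate grids are rejected
    bad <- new("DeformationField",
               displacements = array(0, c(1, 2, 2, 3)),
               grid_spacing_um = c(10, 10, 10))
    expect_error(transformSpots(st, bad), "format error")
})

test_that("region assignment looks up nearest voxels and background", {
    a <- makeToyAtlas(2L, c(20L, 24L, 24L), c(10, 5, 5), seed = 1)
    lab <- labelVolume(a)
    idx <- which(lab > 0, arr.ind = TRUE)[10, ]
    sp <- spacing(a)
    st <- spotTable(x_um = c((idx[3] - 1) * sp[3], 0),
                    y_um = c((idx[2] - 1) * sp[2], 0),
                    z_um = c((idx[1] - 1) * sp[1], 0))
    out <- spots(assignRegions(st, a))
    expect_identical(out$region_id[1], lab[idx[1], idx[2], idx[3]])
    expect_true(is.na(out$region_id[2]))      # corner voxel is background
    ## mirrored pair across the midline shares a region id
    nx <- dim(lab)[3]
    xl <- (idx[3] - 1) * sp[3]
    xr <- (nx - idx[3]) * sp[3]
    pair <- spotTable(x_um = c(xl, xr),
                      y_um = rep((idx[2] - 1) * sp[2], 2),
                      z_um = rep((idx[1] - 1) * sp[1], 2))
    rid <- spots(assignRegions(pair, a))$region_id
    expect_identical(rid[1], rid[2])
})

test_that("aggregation divides counts by volume and rolls up the tree", {
    ont <- toyOntology()
    ## 10 spots in B2 (volume 2.0 mm^3) -> density 5
    st <- spotTable(x_um = 1:10, y_um = 0, z_um = 0)
    df <- spots(st); df$region_id <- 7L
    rc <- aggregateRegions(new("SpotTable", spots = df), ont)
    expect_equal(rc$density[rc$acronym == "B2"], 5)
    expect_equal(rc$density[rc$acronym == "A1"], 0)
    expect_error(aggregateRegions(
        new("SpotTable", spots = transform(df, region_id = 999L)), ont),
        "unknown region")
})

test_that("cumulative counts equal direct plus descendant recount", {
    ont <- toyOntology()
    set.seed(12)
    n <- 120L
    ids <- sample(c(NA, 1:7), n, replace = TRUE)
    df <- spots(spotTable(x_um = runif(n), y_um = runif(n),
                          z_um = runif(n)))
    df$region_id <- as.integer(ids)
    st <- new("SpotTable", spots = df)
    rc <- aggregateRegions(st, ont, animal_id = "m1")
    direct <- function(id) sum(!is.na(ids) & ids == id)
    for (id in 1:7) {
        want <- direct(id) +
            sum(vapply(bruteForceDescendants(toyOntologyTable(), id),
                       direct, numeric(1)))
        expect_identical(rc$cumulative_count[rc$id == id],
                         as.integer(want))
    }
    ## conservation: root cumulative = all assigned; attributes agree
    expect_identical(rc$cumulative_count[rc$id == 1],
                     as.integer(sum(!is.na(ids))))
    expect_identical(attr(rc, "n_assigned") + attr(rc, "n_unassigned"), n)
})

test_that("density matrices assemble deterministically and round-trip", {
    ont <- toyOntology()
    mk <- function(seed, id) {
        set.seed(seed)
        n <- 50
        df <- spots(spotTable(x_um = runif(n), y_um = runif(n),
                              z_um = runif(n)))
        df$region_id <- sample(c(4:7, NA), n, replace = TRUE)
        aggregateRegions(new("SpotTable", spots = df), ont,
                         animal_id = id)
    }
    counts <- list(m1 = mk(1, "m1"), m2 = mk(2, "m2"))
    meta <- data.frame(animal_id = c("m1", "m2"),
                       treatment = c("morphine", "saline"),
                       time = "1h", sex = c("male", "female"))
    dm <- buildDensityMatrix(counts, meta, ont)
    expect_identical(dim(dm), c(7L, 2L))
    ## column order of regions is the depth-first ontology order
    expect_identical(SummarizedExperiment::rowData(dm)$acronym,
                     c("root", "A", "A1", "A2", "B", "B1", "B2"))
    ## duplicate animals are rejected
    expect_error(densityMatrix(matrix(0, 2, 2), 1:2, c("a", "b"),
                               data.frame(animal_id = c("m", "m"),
                                          treatment = "t", time = "1h",
                                          sex = "male")),
                 "duplicate")
    ## CSV round trip is exact (numbers re-read bit-identically)
    path <- withr::local_tempfile(fileext = ".csv")
    writeDensityMatrix(dm, path)
    back <- readDensityMatrix(path,
                              SummarizedExperiment::rowData(dm)$id)
    expect_equal(SummarizedExperiment::assay(back, "density"),
                 SummarizedExperiment::assay(dm, "density"))
    path2 <- withr::local_tempfile(fileext = ".csv")
    writeDensityMatrix(back, path2)
    expect_identical(readLines(path), readLines(path2))
})

test_that("aggregate after translation equals analytic shift oracle", {
    a <- makeToyAtlas(3L, c(24L, 24L, 24L), c(10, 10, 10), seed = 4)
    set.seed(9)
    n <- 80
    st <- spotTable(x_um = runif(n, 20, 200), y_um = runif(n, 20, 200),
                    z_um = runif(n, 20, 200))
    shift <- c(15, -10, 5)               # (dz, dy, dx)
    field <- simulateDeformation(a, "translation", vector_um = shift)
    via_field <- aggregateRegions(
        assignRegions(transformSpots(st, field), a), a@ontology)
    manual <- spotTable(x_um = spots(st)$x_um + shift[3],
                        y_um = spots(st)$y_um + shift[2],
                        z_um = spots(st)$z_um + shift[1])
    via_manual <- aggregateRegions(assignRegions(manual, a), a@ontology)
    expect_identical(via_field$cumulative_count,
                     via_manual$cumulative_count)
})

test_that("heatmap slabs carry exact pre-smoothing mass", {
    a <- makeToyAtlas(2L, c(30L, 40L, 40L), c(100, 25, 25), seed = 2)
    ## empty input -> all-zero maps
    empty <- coronalHeatmaps(spotTable(), a, n_animals = 2)
    expect_true(all(vapply(empty, function(m) all(m == 0), logical(1))))
    ## 6 spots in the first slab, 2 animals -> pre-smoothing mass 3;
    ## spots sit well inside the map so smoothing can conserve mass
    st <- spotTable(x_um = seq(400, 650, by = 50),
                    y_um = seq(400, 650, by = 50), z_um = 500)
    maps <- coronalHeatmaps(st, a, n_animals = 2, slab_um = 1000,
                            sigma_um = 0)
    expect_equal(attr(maps[[1]], "mass"), 3)
    expect_equal(sum(maps[[1]]), 3)
    expect_equal(sum(vapply(maps[-1], sum, numeric(1))), 0)
    ## smoothing conserves interior mass within 1%
    sm <- coronalHeatmaps(st, a, n_animals = 2, slab_um = 1000,
                          sigma_um = 50)
    expect_lt(abs(sum(sm[[1]]) - 3) / 3, 0.01)
    expect_error(coronalHeatmaps(st, a, 2, slab_um = -5), "slab_um")
})
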