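test_that("pool layout fixes the 13-pool structure", {
  lay <- pool_layout()
  expect_length(lay$names, 13L)
  counts <- table(lay$class_of)
  expect_equal(as.integer(counts[c("vegetation", "litter", "soil")]),
               c(4L, 5L, 4L))
  expect_identical(pool_indices(lay, "vegetation"), 1:4)
})

test_that("metabolic fraction follows the clamped linear L/N form", {
  expect_equal(metabolic_fraction(20), 0.49)  # 0.85 - 0.018 * 20
  # monotonically non-increasing in L/N
  LN <- c(1, 5, 10, 20, 40, 60)
  expect_true(all(diff(metabolic_fraction(LN)) <= 0))
  # extreme L/N clamps to 0, never negative
  expect_equal(metabolic_fraction(1e6), 0)
  expect_true(all(metabolic_fraction(seq(0.1, 200, by = 0.7)) >= 0))
  expect_error(metabolic_fraction(0), "positive")
  expect_error(metabolic_fraction(-3), "positive")
})

test_that("allocation vector expands biome fractions and validates", {
  p <- shipped_params[["EBF"]]
  B <- build_allocation_vector(p)
  expect_equal(sum(B), 1)
  expect_equal(unname(B[1:4]), unname(p$b))
  expect_equal(unname(B[5:13]), rep(0, 9))
  # degenerate leaf-only allocation
  p1 <- biome_params("toy", b = c(1, 0, 0, 0), LN = 10, Lleaf = 0.2,
                     Lfroot = 0.2, Lwood = 0.3, c = rep(1, 13))
  expect_equal(unname(build_allocation_vector(p1)),
               c(1, rep(0, 12)))
  expect_error(
    biome_params("bad", b = c(0.3, 0.3, 0.2, 0.1), LN = 10, Lleaf = 0.2,
                 Lfroot = 0.2, Lwood = 0.3, c = rep(1, 13)),
    "sum to")
})

test_that("forest biomes allocate 0.3-0.5 of NPP to wood", {
  forests <- Filter(function(p) isTRUE(p$forest), shipped_params)
  expect_gt(length(forests), 0)
  for (p in forests) {
    B <- build_allocation_vector(p)
    expect_gte(unname(B["woody"]), 0.3)
    expect_lte(unname(B["woody"]), 0.5)
  }
})

test_that("transfer matrix satisfies sign, column-sum and topology invariants", {
  set.seed(4)
  for (p in shipped_params) {
    tex <- soil_texture(clay = runif(1, 0.05, 0.4),
                        silt = runif(1, 0.2, 0.5),
                        porosity = runif(1, 0.35, 0.55))
    A <- build_transfer_matrix(p, tex)
    expect_equal(unname(diag(A)), rep(1, 13))
    off <- A - diag(diag(A))
    expect_true(all(off <= 0))
    routed <- 1 - colSums(A)
    expect_true(all(routed <= 1 + 1e-12))
    expect_true(all(routed >= 0))
    # carbon conservation: routed + respired = 1 per donor
    expect_equal(unname(routed + colSums(A)), rep(1, 13))
    # woody and coarse root route their whole exiting flux to coarse detritus
    for (donor in c("woody", "croot")) {
      col <- A[, donor]
      nz <- which(col < 0)
      expect_identical(names(nz), "coarse_detritus")
      expect_equal(unname(col[nz]), -1)
    }
    # leaf splits between the two surface litter pools by L/N
    fmet <- metabolic_fraction(p$LN)
    expect_equal(unname(-A["surface_metabolic", "leaf"]), fmet)
    expect_equal(unname(-A["surface_structural", "leaf"]), 1 - fmet)
  }
})

test_that("vanishing lignin sends all structural transfer to microbes", {
  p <- biome_params("lowlig", b = c(0.4, 0.2, 0.3, 0.1), LN = 15,
                    Lleaf = 1e-9, Lfroot = 1e-9, Lwood = 1e-9,
                    c = rep(1, 13))
  A <- build_transfer_matrix(p, loam)
  expect_equal(unname(-A["slow", "surface_structural"]), 0, tolerance = 1e-8)
  expect_equal(unname(-A["slow", "soil_structural"]), 0, tolerance = 1e-8)
  expect_gt(-A["surface_microbe", "surface_structural"], 0.5)
})

test_that("transfer matrix is deterministic and climate-independent", {
  p <- shipped_params[["DBF"]]
  expect_identical(build_transfer_matrix(p, loam),
                   build_transfer_matrix(p, loam))
  # C depends on neither climate nor texture
  expect_identical(build_turnover_matrix(p), build_turnover_matrix(p))
})

test_that("turnover matrix is diagonal with the biome's rate ordering", {
  p1 <- biome_params("unit", b = c(0.25, 0.25, 0.25, 0.25), LN = 10,
                     Lleaf = 0.2, Lfroot = 0.2, Lwood = 0.3, c = rep(1, 13))
  expect_equal(build_turnover_matrix(p1), diag(13),
               ignore_attr = TRUE)
  lay <- pool_layout()
  for (p in shipped_params) {
    C <- diag(build_turnover_matrix(p))
    names(C) <- lay$names
    if (isTRUE(p$forest)) {
      expect_lt(C["woody"], C["leaf"])
      expect_lt(C["woody"], C["froot"])
      expect_lt(C["croot"], C["leaf"])
      expect_lt(C["croot"], C["froot"])
    }
    litter <- C[pool_indices(lay, "litter")]
    expect_equal(names(which.min(litter)), "coarse_detritus")
  }
})

test_that("soil texture validates fractions and porosity", {
  expect_error(soil_texture(0.5, 0.6, sand = 0.1), "must equal 1")
  expect_error(soil_texture(0.5, 0.6), "fractions")  # implied sand < 0
  expect_error(soil_texture(0.2, 0.3, porosity = 1.2), "porosity")
  tx <- soil_texture(0.25, 0.35)
  expect_equal(tx$sand, 0.4)
})
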