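test_that("PDMS oligomers have the right site inventory and mass", {
  counts <- list(`1` = c(Si = 3, O = 2, CH3 = 8),
                 `2` = c(Si = 4, O = 3, CH3 = 10),
                 `3` = c(Si = 5, O = 4, CH3 = 12))
  for (n in 1:3) {
    tm <- build_pdms_oligomer(n, ff_default)
    tab <- table(tm$kinds)
    expect_equal(as.integer(tab[c("Si", "O", "CH3")]),
                 unname(counts[[as.character(n)]]), label = paste("n =", n))
    expect_equal(nrow(tm$pos), 4 * n + 9)
    # mass bookkeeping: template mass equals sum of site masses
    masses <- vapply(ff_default$site_kinds[tm$kinds], `[[`, 0, "mass")
    expect_equal(tm$mass, sum(masses))
  }
  expect_error(build_pdms_oligomer(4), "unsupported")
})

test_that("organic templates carry their molecular formulas", {
  masses <- c("phenol" = 94.11, "chlorophenol" = 128.56, "guaiacol" = 124.14,
              "benzyl alcohol" = 108.14, "phenethyl alcohol" = 122.17)
  for (nm in names(masses))
    expect_equal(organic_template(nm, ff_default)$mass, masses[[nm]],
                 tolerance = 1e-3, label = nm)
})

test_that("80:20 mixture composition from counts and template masses", {
  mix <- build_mixture_80_20(75, 14, ff_default)
  expect_length(mix$molecules, 89)
  expect_equal(mix$weight_fraction, 0.803, tolerance = 1e-3)
  expect_equal(round(mix$weight_fraction, 2), 0.80)
  expect_equal(build_mixture_80_20(1, 0, ff_default)$weight_fraction, 1.0)
  deg <- build_mixture_80_20(0, 0, ff_default)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$weight_fraction))
})

test_that("saturation loading follows the mole-percent convention", {
  expect_identical(organics_at_saturation(1.6, 6418), 104L)
  expect_identical(organics_at_saturation(0.3, 6418), 19L)
  expect_identical(organics_at_saturation(0, 6418), 0L)
  expect_identical(organics_at_saturation(3.5, 6418), 232L)
  expect_error(organics_at_saturation(100, 10), "mol %")
})

test_that("packing respects min distance, determinism and capacity bounds", {
  wt <- water_template(ff_default)
  reg <- c(0, 20, 0, 20, 0, 20)
  pk <- pack_nonoverlapping(list(wt), 10L, reg, min_dist = 2.0, seed = 7)
  # all intermolecular site pairs >= min_dist
  d <- as.matrix(stats::dist(pk$pos))
  same_mol <- outer(pk$site_mol, pk$site_mol, `==`)
  expect_gte(min(d[!same_mol & upper.tri(d)]), 2.0)
  expect_true(all(pk$pos >= 0 & pk$pos <= 20))
  # determinism under the seed
  pk2 <- pack_nonoverlapping(list(wt), 10L, reg, min_dist = 2.0, seed = 7)
  expect_identical(pk$pos, pk2$pos)
  # close-packing bound rejects impossible requests up front
  expect_error(pack_nonoverlapping(list(wt), 10000L, c(0, 10, 0, 10, 0, 10),
                                   min_dist = 2.0, seed = 1),
               "packing error")
})

test_that("slab system has walls at both ends, PDMS in the slab, full inventory", {
  spec <- slab_spec(pdms_width = 14, water_width = 12,
                    cross_section = c(14, 14))
  sys <- build_slab_system(spec, n_pdms1 = 4, n_pdms2 = 1, n_water = 60,
                           organic = "phenol", n_organic = 3,
                           ff = ff_default, seed = 2)
  # x non-periodic, y/z periodic
  expect_equal(sys$periodic, c(FALSE, TRUE, TRUE))
  # wall atoms present at both x extremes
  wall_x <- sys$pos[sys$frozen, 1]
  expect_true(any(wall_x == 0) && any(wall_x == spec$box[1]))
  # PDMS initially confined to the slab region
  pd <- startsWith(sys$mol_species[sys$site_mol], "pdms")
  expect_true(all(sys$pos[pd, 1] >= spec$pdms[1] - 1e-9 &
                    sys$pos[pd, 1] <= spec$pdms[2] + 1e-9))
  # site count equals the template inventory
  n1 <- nrow(build_pdms_oligomer(1, ff_default)$pos)
  n2 <- nrow(build_pdms_oligomer(2, ff_default)$pos)
  no <- nrow(organic_template("phenol", ff_default)$pos)
  expect_equal(sum(!sys$frozen), 4 * n1 + n2 + 60 * 3 + 3 * no)
  # mass bookkeeping
  t1 <- build_pdms_oligomer(1, ff_default)$mass
  t2 <- build_pdms_oligomer(2, ff_default)$mass
  tw <- water_template(ff_default)$mass
  to <- organic_template("phenol", ff_default)$mass
  mob <- !sys$frozen
  expect_equal(sum(site_masses(sys)[mob]), 4 * t1 + t2 + 60 * tw + 3 * to,
               tolerance = 1e-9)
  # no mobile site outside the box
  expect_true(all(sys$pos[mob, 1] >= 0 & sys$pos[mob, 1] <= spec$box[1]))
})

test_that("two-species slab (zero organics) builds cleanly and deterministically", {
  spec <- slab_spec(pdms_width = 12, water_width = 10,
                    cross_section = c(12, 12))
  s1 <- build_slab_system(spec, n_pdms1 = 3, n_pdms2 = 1, n_water = 40,
                          ff = ff_default, seed = 5)
  s2 <- build_slab_system(spec, n_pdms1 = 3, n_pdms2 = 1, n_water = 40,
                          ff = ff_default, seed = 5)
  expect_identical(s1$pos, s2$pos)
  expect_setequal(unique(s1$mol_species), c("pdms1", "pdms2", "water", "wall"))
})

test_that("default slab geometry reproduces the reference layout", {
  spec <- slab_spec()
  expect_equal(spec$box, c(128, 40, 40))
  expect_equal(spec$pdms, c(50, 78))
  expect_equal(spec$water1, c(1, 49))
  expect_equal(spec$water2, c(79, 127))
})

test_that("FCC wall layer spans the cross-section at the requested plane", {
  w <- build_fcc_wall(0, c(40, 40), a = 3.92)
  expect_true(all(w[, "x"] == 0))
  expect_true(all(w[, c("y", "z")] >= 0 & w[, c("y", "z")] <= 40))
  expect_gt(nrow(w), 50)
})
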