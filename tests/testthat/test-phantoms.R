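test_that("baseline phantom carries the default tissue parameters", {
  mf <- make_baseline(dims = c(6, 6, 4))
  expect_true(all(mf$mu_a == 900))
  expect_true(all(mf$k == 0.35))
  expect_true(all(mf$q_met == 200))
  expect_true(all(mf$w_perf == 0.001))
  expect_equal(mf$T_init, 303.45)
  expect_equal(mf$T_amb, 296.45)
  expect_equal(mf$emissivity, 0.98)
  low <- make_baseline(list(k = 0.21), dims = c(6, 6, 4))
  expect_true(all(low$k == 0.21))
  expect_error(make_baseline(list(rho = -5), dims = c(6, 6, 4)), "positive")
  expect_error(make_baseline(list(bogus = 1), dims = c(6, 6, 4)), "unknown")
})

test_that("porcine fat and muscle phantoms match their tissue parameters", {
  fat <- make_porcine("fat", dims = c(6, 6, 4))
  mus <- make_porcine("muscle", dims = c(6, 6, 4))
  expect_true(all(fat$k == 0.24))
  expect_true(all(fat$mu_a == 150))
  expect_equal(fat$T_init, 294.99)
  expect_true(all(mus$mu_a == 950))
  expect_true(all(mus$k == 0.56))
  expect_equal(mus$T_init, 293.34)
  # ex vivo: perfusion and metabolism switched off
  expect_true(all(fat$w_perf == 0) && all(fat$q_met == 0))
  expect_true(all(mus$w_perf == 0) && all(mus$q_met == 0))
  expect_error(make_porcine("liver"), "arg")
})

test_that("pillar phantom geometry is periodic and two-valued", {
  mf <- make_pillar_phantom(n_pillars = 3, spacing = 1e-4)
  expect_equal(length(unique(as.numeric(mf$k))), 2L)
  expect_equal(length(mf$geometry$pillar_centers), 3L)
  expect_equal(diff(mf$geometry$pillar_centers),
               rep(2e-3, 2), tolerance = 1e-12)
  # ink film covers the whole surface; stripes sit underneath
  expect_true(all(mf$k[, , 1] == 0.60))
  kstripe <- mf$k[, 1, round(0.8e-3 / 1e-4) + 1]
  runs <- rle(kstripe == 0.13)
  expect_equal(runs$lengths[runs$values], c(10, 10, 10))
  # flush construction puts the stripes at the surface
  mf0 <- make_pillar_phantom(n_pillars = 2, cover = 0, spacing = 1e-4)
  runs0 <- rle(mf0$k[, 1, 1] == 0.13)
  expect_equal(runs0$lengths[runs0$values], c(10, 10))
  expect_error(make_pillar_phantom(pillar_width = 5e-5, spacing = 1e-4),
               "narrower")
})

test_that("cohort generation is deterministic and respects null settings", {
  c1 <- make_cohort(n_per_arm = 3, seed = 11, dims = c(10, 10, 6),
                    spacing = 2e-4)
  c2 <- make_cohort(n_per_arm = 3, seed = 11, dims = c(10, 10, 6),
                    spacing = 2e-4)
  expect_equal(c1[[2]]$mf$k, c2[[2]]$mf$k, tolerance = 1e-15)
  expect_equal(vapply(c1, `[[`, "", "label"),
               rep(c("healthy", "tumor"), 3))
  # null generator: no inclusion, no heterogeneity -> every sample uniform
  c0 <- make_cohort(n_per_arm = 2, tumor_effect = 0, heterogeneity = 0,
                    seed = 4, dims = c(10, 10, 6), spacing = 2e-4)
  for (s in c0)
    expect_lt(diff(range(s$mf$k)) / mean(s$mf$k), 1e-12)
  expect_error(make_cohort(2, corr_len = 0), "correlation length")
})

test_that("tumor samples have elevated conductivity inside the inclusion", {
  co <- make_cohort(n_per_arm = 4, heterogeneity = 0, seed = 2,
                    incl_radius = 1e-3, incl_depth = 1e-3,
                    dims = c(20, 20, 10), spacing = 2e-4)
  labs <- vapply(co, `[[`, "", "label")
  k_contrast <- vapply(co[labs == "tumor"], function(s)
    max(s$mf$k) / min(s$mf$k), numeric(1))
  expect_equal(k_contrast, rep(1.4, 4), tolerance = 1e-9)
  k_flat <- vapply(co[labs == "healthy"], function(s)
    max(s$mf$k) / min(s$mf$k), numeric(1))
  expect_equal(k_flat, rep(1, 4), tolerance = 1e-12)
})

test_that("all emitted phantoms satisfy the material invariants", {
  samples <- c(list(make_baseline(dims = c(6, 6, 4)),
                    make_porcine("fat", dims = c(6, 6, 4)),
                    make_pillar_phantom(spacing = 2e-4)),
               lapply(make_cohort(2, seed = 3, dims = c(8, 8, 4),
                                  spacing = 2e-4), `[[`, "mf"))
  for (mf in samples)
    expect_silent(fdti:::validate_material_field(mf))
})
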