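test_that("oligomer condensation arithmetic is right", {
  # a pure G dimer: 2 x C10H12O3 - H2O
  design <- default_group_design()[2, ]
  design$n_units <- list(2L)
  design$ch2_max <- 0L; design$o_shift <- 0L; design$o_span <- 1L
  design$size <- 1L
  cfg <- synthetic_config(groups = design)
  lib <- build_library(cfg)
  expect_equal(lib$formula, "C20H22O5")
})

test_that("every library formula is admissible and groups hit their bands", {
  lim <- elemental_limits()
  lib <- build_library(synthetic_config(), lim)
  expect_equal(sort(unique(lib$group_label)), 1:4)
  expect_true(all(lib$c >= 1 & lib$c <= 90))
  expect_true(all(lib$h >= 4 & lib$h <= 200))
  expect_true(all(lib$n <= 5, lib$o >= 1, lib$o <= 23, lib$s <= 1))
  expect_true(all(lib$h <= 2 * lib$c + lib$n + 2))        # valence
  d <- dbe(lib)
  expect_true(all(d >= 0 & d <= 50 & d == floor(d)))
  expect_true(all(lib$neutral_mass >= 150 & lib$neutral_mass <= 800))
  expect_false(anyDuplicated(lib$formula[lib$group_label == 1]) > 0)

  # designed contrast: aromatic, O-rich groups 1-2 vs aliphatic-leaning 3-4
  means <- tapply(d, lib$group_label, mean)
  expect_gt(min(means[1:2]), max(means[3:4]))
  hc <- tapply(lib$h / lib$c, lib$group_label, mean)
  expect_gt(min(hc[3:4]), max(hc[1:2]))

  # banning sulfur from the design removes it from the library
  des <- default_group_design()
  des$s_atoms <- 0L
  lib_nos <- build_library(synthetic_config(groups = des))
  expect_true(all(lib_nos$s == 0))
})

test_that("CH2-decorated series share exact KMD before jitter", {
  lib <- build_library(synthetic_config())
  base <- kendrick_base("CH2")
  g2 <- lib[lib$group_label == 2 & lib$n == 0, ]
  km <- g2$neutral_mass * base$nominal_mass / base$exact_mass
  kmd <- floor(km + 0.5) - km
  # within one (n_mer, o) scaffold all CH2 homologs share kmd exactly
  scaffold <- paste(g2$o, round(g2$neutral_mass - g2$c * 14) %/% 1)
  for (sc in unique(scaffold)) {
    vals <- kmd[scaffold == sc]
    if (length(vals) > 1) expect_lt(max(vals) - min(vals), 1e-9)
  }
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- synthetic_config()
  lib <- build_library(cfg)
  sv <- cfg$solvents[4, ]
  a <- simulate_spectrum(lib, sv, cfg, seed = 77)
  b <- simulate_spectrum(lib, sv, cfg, seed = 77)
  expect_identical(a, b)
  expect_identical(simulate_blank(cfg, seed = 8), simulate_blank(cfg, seed = 8))
  d1 <- simulate_dataset(cfg, seed = 5)
  d2 <- simulate_dataset(cfg, seed = 5)
  expect_identical(d1$peaks, d2$peaks)
})

test_that("zero solvent slope yields ~50% inclusion", {
  des <- default_group_design()
  des$solvent_slope <- 0
  cfg <- synthetic_config(groups = des)
  lib <- build_library(cfg)
  included <- 0; total <- 0
  for (s in 1:10) {
    sim <- simulate_spectrum(lib, cfg$solvents[1, ], cfg, seed = 1000 + s)
    included <- included + sum(sim$truth$kind == "component")
    total <- total + nrow(lib)
  }
  expect_gt(included / total, 0.46)
  expect_lt(included / total, 0.54)
})

test_that("mass jitter behaves like the configured Gaussian", {
  cfg <- synthetic_config()
  lib <- build_library(cfg)
  errs <- numeric(0)
  for (s in 1:20) {
    sim <- simulate_spectrum(lib, cfg$solvents[5, ], cfg, seed = 2000 + s)
    tr <- sim$truth[sim$truth$kind == "component", ]
    errs <- c(errs, (tr$mz - tr$true_mz) / tr$true_mz * 1e6)
  }
  expect_gt(length(errs), 500)
  expect_equal(sd(errs), 0.15, tolerance = 0.15)
  expect_gt(mean(abs(errs) < 4 * 0.15), 0.999)
})

test_that("blanks carry only contaminants and noise; subtraction removes them", {
  cfg <- synthetic_config()
  blk <- simulate_blank(cfg, seed = 3)
  expect_equal(nrow(blk), length(cfg$blank_contaminants) + cfg$noise_peaks)

  lib <- build_library(cfg)
  sim <- simulate_spectrum(lib, cfg$solvents[2, ], cfg, seed = 4)
  out <- subtract_blank(sim$peaks, blk, preprocess_config(blank_tol_ppm = 1))
  cont_mz <- sim$truth$mz[sim$truth$kind == "contaminant"]
  expect_false(any(cont_mz %in% out$mz))
  comp_mz <- sim$truth$mz[sim$truth$kind == "component"]
  expect_true(all(comp_mz %in% out$mz))

  # no contaminants configured: subtraction never touches components
  cfg0 <- synthetic_config(blank_contaminants = numeric(0))
  blk0 <- simulate_blank(cfg0, seed = 5)
  sim0 <- simulate_spectrum(build_library(cfg0), cfg0$solvents[2, ], cfg0,
                            seed = 6)
  out0 <- subtract_blank(sim0$peaks, blk0, preprocess_config())
  comp0 <- sim0$truth$mz[sim0$truth$kind == "component"]
  expect_true(all(comp0 %in% out0$mz))
})

test_that("a simulated study round-trips through files", {
  cfg <- synthetic_config()
  ds <- simulate_dataset(cfg, seed = 12)
  dir <- withr::local_tempdir()
  man <- write_synthetic_dataset(ds, dir)
  back <- load_dataset(man)
  expect_equal(nrow(back), nrow(ds))
  expect_equal(back$peaks[[1]]$mz, ds$peaks[[1]]$mz, tolerance = 1e-9)
  expect_equal(sum(!is.na(back$blank_row)), 10L)
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
})

test_that("recovery_report scores joins correctly at the extremes", {
  truth <- tibble::tibble(kind = "component",
                          formula = c("C9H10O2", "C20H22O5"),
                          group_label = 1L, true_mz = c(149.1, 341.1),
                          mz = c(149.1, 341.1), solvent_label = "A",
                          peak_index = 1:2)
  perfect <- tibble::tibble(mz = c(149.1, 341.1), solvent_label = "A",
                            assigned = TRUE,
                            formula = c("C9H10O2", "C20H22O5"))
  expect_equal(recovery_report(truth, perfect)$overall$recovery, 1.0)
  none <- perfect; none$assigned <- FALSE; none$formula <- NA_character_
  expect_equal(recovery_report(truth, none)$overall$recovery, 0.0)
  expect_error(recovery_report(truth, perfect[0, ]), "do not join")
})

test_that("group summaries bracket the true component ranges end-to-end", {
  cfg <- synthetic_config()
  ds <- simulate_dataset(cfg, seed = 21)
  lib <- attr(ds, "library")
  pp <- suppressWarnings(preprocess_dataset(ds))
  base <- kendrick_base("CH2")
  polys <- library_gate_polygons(lib)

  i <- which(!pp$is_blank & pp$solvent_label == "3:1 MeOH:H2O")
  pk <- pp$peaks[[i]]
  pts <- kendrick_transform(pk, base)
  grp <- suppressWarnings(gate_groups(pts, polys))
  asg <- assign_formulas(pk, elemental_limits(), "negative")
  sm <- summarize_groups(grp, asg)

  truth <- ds$truth[[i]]
  truth <- truth[truth$kind == "component" & truth$mz %in% pk$mz, ]
  truth <- dplyr::left_join(truth,
                            lib[c("formula", "group_label", "c", "h", "n",
                                  "o", "s", "neutral_mass")],
                            by = c("formula", "group_label"))
  for (g in sm$group_id) {
    tg <- truth[truth$group_label == g, ]
    if (nrow(tg) < 2) next
    row <- sm[sm$group_id == g, ]
    d <- dbe(tg)
    # reported ranges must contain the surviving true members' ranges
    expect_lte(row$dbe_min, min(d)); expect_gte(row$dbe_max, max(d))
    expect_lte(row$hc_min, min(tg$h / tg$c) + 1e-9)
    expect_gte(row$hc_max, max(tg$h / tg$c) - 1e-9)
    expect_lte(row$oc_min, min(tg$o / tg$c) + 1e-9)
    expect_gte(row$oc_max, max(tg$o / tg$c) - 1e-9)
  }
})
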