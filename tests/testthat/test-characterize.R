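make_group <- function(group_id, peak_index, km, kmd) {
  tibble::tibble(group_id = group_id, peak_index = peak_index,
                 km = km, kmd = kmd)
}

make_assignments <- function(peak_index, dbe, h_c, o_c, het_class) {
  tibble::tibble(peak_index = peak_index, assigned = TRUE,
                 dbe = dbe, h_c = h_c, o_c = o_c, het_class = het_class)
}

test_that("group summaries report min/max ranges and class sets", {
  grp <- make_group(1L, 1:6, km = c(430, 450, 500, 520, 560, 569),
                    kmd = seq(0.15, 0.29, length.out = 6))
  asg <- make_assignments(1:6, dbe = c(0, 3, 5, 9, 14, 17),
                          h_c = c(1.1, 1.5, 1.8, 2.0, 2.1, 1.3),
                          o_c = c(0.03, 0.1, 0.2, 0.3, 0.42, 0.2),
                          het_class = c("N5O2", "N5O3", "N5O4", "N5O2",
                                        "N5O3", "N5O4"))
  sm <- summarize_groups(grp, asg)
  expect_equal(sm$dbe_min, 0); expect_equal(sm$dbe_max, 17)
  expect_equal(sm$hc_min, 1.1); expect_equal(sm$hc_max, 2.1)
  expect_equal(sm$oc_min, 0.03); expect_equal(sm$oc_max, 0.42)
  expect_equal(sm$km_min, 430); expect_equal(sm$km_max, 569)
  expect_setequal(sm$classes[[1]], c("N5O2", "N5O3", "N5O4"))

  # singleton group: degenerate ranges
  s1 <- summarize_groups(make_group(1L, 1L, 500, 0.2),
                         make_assignments(1L, 5, 1.2, 0.3, "O4"))
  expect_equal(s1$dbe_min, s1$dbe_max)

  # no assigned members: KM/KMD only
  s0 <- summarize_groups(make_group(1L, 9L, 500, 0.2),
                         make_assignments(1L, 5, 1.2, 0.3, "O4"))
  expect_true(is.na(s0$dbe_min) && is.na(s0$hc_min))
  expect_equal(s0$km_min, 500)
  expect_length(s0$classes[[1]], 0L)

  expect_error(summarize_group(grp[0, ], asg), "empty")
})

test_that("unique classes are computed within the comparison set", {
  grp <- dplyr::bind_rows(make_group(1L, 1:2, c(300, 310), 0.2),
                          make_group(2L, 3:4, c(400, 410), 0.3))
  asg <- make_assignments(1:4, dbe = 5, h_c = 1, o_c = 0.3,
                          het_class = c("O4", "O5", "O5", "S1N2O10"))
  sm <- summarize_groups(grp, asg)
  expect_equal(sm$unique_classes[[1]], "O4")
  expect_equal(sm$unique_classes[[2]], "S1N2O10")
})

test_that("ranges only widen when members are added (monotonicity)", {
  withr::local_seed(13)
  asg <- make_assignments(1:20, dbe = sample(0:20, 20, TRUE),
                          h_c = runif(20, 0.5, 2.5),
                          o_c = runif(20, 0, 1), het_class = "O4")
  km <- runif(20, 200, 800); kmd <- runif(20, -0.4, 0.4)
  s_small <- summarize_groups(make_group(1L, 1:10, km[1:10], kmd[1:10]), asg)
  s_big <- summarize_groups(make_group(1L, 1:20, km, kmd), asg)
  expect_lte(s_big$km_min, s_small$km_min)
  expect_gte(s_big$km_max, s_small$km_max)
  expect_lte(s_big$dbe_min, s_small$dbe_min)
  expect_gte(s_big$dbe_max, s_small$dbe_max)
})

fake_dataset <- function(counts) {
  tibble::tibble(
    sample_code = "S",
    solvent_label = names(counts),
    organic_aqueous_ratio = seq(0.25, 0.75, length.out = length(counts)),
    ion_mode = "negative",
    is_blank = FALSE,
    peaks = lapply(counts, function(n) make_peaks(seq_len(n) + 100)),
    blank_row = NA_integer_
  )
}

test_that("solvent ranking sorts by count with alphabetical tie-break", {
  ds <- fake_dataset(c(A = 120L, C = 80L, B = 80L))
  rk <- rank_solvents(ds)
  expect_equal(rk$solvent_label, c("A", "B", "C"))
  expect_equal(rk$score, c(120, 80, 80))
  expect_equal(rk$rank, 1:3)

  # invariant to row order
  rk2 <- rank_solvents(ds[c(3, 1, 2), ])
  expect_equal(rk2, rk)

  # single solvent
  expect_equal(nrow(rank_solvents(fake_dataset(c(A = 5L)))), 1L)
  expect_error(rank_solvents(fake_dataset(c(A = 5L))[0, ]), "no sample")
})

test_that("per-group optimum solvents truncate and flag non-extraction", {
  # peaks at m/z 200..: km in (199, 206); group polygon spans only some
  ds <- tibble::tibble(
    sample_code = "S",
    solvent_label = c("A", "B", "C", "D"),
    organic_aqueous_ratio = c(0.25, 0.5, 0.5, 0.75),
    ion_mode = "negative", is_blank = FALSE,
    peaks = list(make_peaks(200 + 1:8), make_peaks(200 + 1:6),
                 make_peaks(500 + 1:3), make_peaks(500 + 1:2)),
    blank_row = NA_integer_
  )
  polys <- list(square_polygon(195, 215, -0.5, 0.5),   # covers A, B only
                square_polygon(480, 520, -0.5, 0.5),   # covers C, D
                square_polygon(900, 950, -0.5, 0.5))   # covers nothing
  tops <- top_solvents_per_group(ds, polys)
  expect_equal(tops$top_solvents[[1]], c("A", "B"))  # only 2 nonzero
  expect_equal(tops$top_solvents[[2]], c("C", "D"))
  expect_true(tops$not_extracted[3])
  expect_length(tops$top_solvents[[3]], 0L)
})

test_that("ratio trends report group means and rank correlation", {
  rk <- tibble::tibble(organic_aqueous_ratio = c(0.25, 0.5, 0.75),
                       score = c(10, 20, 30))
  tr <- ratio_trend(rk)
  expect_equal(tr$spearman, 1.0)
  expect_equal(tr$difference, mean(c(20, 30)) - 10)

  flat <- tibble::tibble(organic_aqueous_ratio = c(0.25, 0.75),
                         score = c(5, 5))
  tr_flat <- ratio_trend(flat)
  expect_equal(tr_flat$spearman, 0)
  expect_false(tr_flat$spearman_defined)

  expect_error(ratio_trend(tibble::tibble(organic_aqueous_ratio = 0.5,
                                          score = 1)), "two distinct")
})

fake_summary <- function(ids, km0, km1, kmd0, kmd1) {
  tibble::tibble(group_id = ids, km_min = km0, km_max = km1,
                 kmd_min = kmd0, kmd_max = kmd1)
}

test_that("identical group sets match perfectly; disjoint sets do not", {
  a <- fake_summary(1:3, c(100, 300, 500), c(200, 400, 600),
                    c(0, 0.1, 0.2), c(0.05, 0.15, 0.25))
  m <- match_groups(a, a)
  expect_equal(nrow(m$pairs), 3L)
  expect_true(all(m$pairs$overlap == 1))
  expect_length(m$unique_to_a, 0L)
  expect_length(m$unique_to_b, 0L)

  b <- fake_summary(1:2, c(1000, 1500), c(1100, 1600), c(0.3, 0.4),
                    c(0.35, 0.45))
  m2 <- match_groups(a, b)
  expect_equal(nrow(m2$pairs), 0L)
  expect_setequal(m2$unique_to_a, 1:3)
  expect_setequal(m2$unique_to_b, 1:2)
})

test_that("the min_overlap threshold separates matched from unique", {
  # boxes [0,13]x[0,1] and [7,20]x[0,1]: inter 6, union 20, IoU = 0.3
  a <- fake_summary(1L, 0, 13, 0, 1)
  b <- fake_summary(1L, 7, 20, 0, 1)
  m_at <- match_groups(a, b, min_overlap = 0.3)
  expect_equal(nrow(m_at$pairs), 1L)
  expect_equal(m_at$pairs$overlap, 0.3, tolerance = 1e-12)
  m_above <- match_groups(a, b, min_overlap = 0.31)
  expect_equal(nrow(m_above$pairs), 0L)
})

test_that("match_groups is symmetric up to relabeling", {
  a <- fake_summary(1:2, c(100, 300), c(200, 400), c(0, 0.1), c(0.1, 0.2))
  b <- fake_summary(1:3, c(105, 600, 800), c(205, 700, 900),
                    c(0, 0.3, 0.4), c(0.1, 0.35, 0.45))
  ab <- match_groups(a, b)
  ba <- match_groups(b, a)
  expect_equal(ab$unique_to_a, ba$unique_to_b)
  expect_equal(ab$unique_to_b, ba$unique_to_a)
  expect_equal(ab$pairs$overlap, ba$pairs$overlap)

  # broom-style accessors
  expect_equal(glance(ab)$n_pairs, 1L)
  expect_equal(nrow(tidy(ab)), 1L + 1L + 2L)
})
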