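# run code under a temporary RNG state so generator calls never disturb
# the caller's random stream
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic lignin-spectrum generator
#'
#' Describes a simulated solvent-extraction ESI study of a lignin-like
#' mixture: a component library built from H/G/S phenylpropanoid
#' monomers, a solvent panel, and the noise model. Defaults emulate the
#' study conditions the package targets: the ten-solvent panel of
#' [solvent_mixtures()], negative-mode ESI, 0.15 ppm Gaussian mass
#' jitter (comfortably inside the 0.5 ppm search window, so assignment
#' errors are dominated by compositional ambiguity, not jitter),
#' log-normal component intensities, uniform low-intensity background
#' peaks, and a fixed set of contaminant masses shared between samples
#' and blanks.
#'
#' @param groups Group design tibble; see [default_group_design()].
#' @param solvents Solvent panel tibble ([solvent_mixtures()] layout).
#' @param ion_mode `"negative"` (default) or `"positive"`.
#' @param ppm_sigma SD of the Gaussian m/z jitter, in ppm (default 0.15).
#' @param intensity_sdlog SD of component log-intensities (default 0.5).
#' @param noise_peaks Number of random background peaks per spectrum
#'   (default 30).
#' @param noise_intensity Intensity range of background peaks (default
#'   20–200 counts, far below component intensities so the S/N filter
#'   has something to remove).
#' @param blank_contaminants Numeric vector of contaminant m/z values
#'   emitted in both blanks and samples (default: 12 typical ESI
#'   background masses).
#' @param contaminant_meanlog Mean log-intensity of contaminant peaks
#'   (default `log(2e4)`).
#' @param mass_range Neutral-mass window the library is restricted to
#'   (default 150–800 u).
#' @param mz_range Admissible m/z window of emitted peaks (default
#'   100–2000 Th, the acquisition range emulated).
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(groups = default_group_design(),
                             solvents = solvent_mixtures(),
                             ion_mode = "negative",
                             ppm_sigma = 0.15,
                             intensity_sdlog = 0.5,
                             noise_peaks = 30L,
                             noise_intensity = c(20, 200),
                             blank_contaminants = .default_contaminants(),
                             contaminant_meanlog = log(2e4),
                             mass_range = c(150, 800),
                             mz_range = c(100, 2000)) {
  stopifnot(ppm_sigma >= 0, noise_peaks >= 0,
            length(noise_intensity) == 2L, length(mass_range) == 2L)
  structure(
    list(groups = groups, solvents = solvents,
         ion_mode = canonical_ion_mode(ion_mode),
         ppm_sigma = ppm_sigma, intensity_sdlog = intensity_sdlog,
         noise_peaks = as.integer(noise_peaks),
         noise_intensity = noise_intensity,
         blank_contaminants = blank_contaminants,
         contaminant_meanlog = contaminant_meanlog,
         mass_range = mass_range, mz_range = mz_range),
    class = "synthetic_config"
  )
}

# typical negative-mode ESI background masses (fatty acids, TFA, PEG-like)
.default_contaminants <- function() {
  c(112.98559, 116.92834, 153.01930, 171.13910, 255.23295, 283.26425,
    311.16862, 325.18390, 339.20060, 407.27900, 471.32400, 509.29000)
}

#' Default four-group lignin component design
#'
#' The generator's components are oligomers of the three lignin
#' monolignol-derived units — H (p-hydroxyphenyl, C9H10O2),
#' G (guaiacyl, C10H12O3) and S (syringyl, C11H14O4) — condensed with
#' loss of one water per linkage, then decorated within the CHNOS
#' limits: a CH2 homologous ladder (so Kendrick series exist by
#' construction), extra or missing oxygens, dehydrogenation (-H2, which
#' raises DBE) or hydrogenation (+H2), and N (added as NH, preserving
#' integer DBE) and S heteroatoms.
#'
#' The four groups realize the contrast the analysis is meant to
#' resolve: groups 1 and 2 are oxygen-rich with high DBE and low H/C,
#' groups 3 and 4 have higher H/C, lower O/C and lower DBE; groups 1 and
#' 4 respond positively to the organic/aqueous ratio of the extraction
#' solvent (logistic inclusion with positive slope), groups 2 and 3
#' negatively. Group sizes are deliberately unequal so that total
#' expected peak counts vary monotonically enough across the ratio
#' levels for rank recovery to be well-posed.
#'
#' @return A tibble with one row per group: `group_label`, `monomer`,
#'   `n_units` (list of oligomer sizes), `ch2_max`, `h2_shift`,
#'   `o_shift`, `n_atoms`, `s_atoms`, `size`, `base_meanlog`,
#'   `solvent_slope`, `solvent_midpoint`.
#' @export
default_group_design <- function() {
  tibble::tibble(
    group_label = 1:4,
    monomer = c("C11H14O4", "C10H12O3", "C9H10O2", "C10H12O3"),
    n_units = list(2:3, 2:4, 2:3, 2:3),
    ch2_max = c(9L, 9L, 9L, 9L),
    h2_shift = c(-5L, 0L, 2L, 3L),     # minus = dehydrogenate (DBE up)
    o_shift = c(4L, 2L, 0L, -1L),
    o_span = c(4L, 4L, 2L, 2L),        # O-count variants per scaffold
    n_atoms = c(2L, 0L, 1L, 0L),
    s_atoms = c(1L, 0L, 0L, 0L),
    size = c(40L, 25L, 20L, 30L),
    base_meanlog = log(1e5),
    solvent_slope = c(10, -10, -6, 12),
    solvent_midpoint = c(0.5, 0.5, 0.5, 0.5)
  )
}

#' Build the concrete component library of a synthetic study
#'
#' Expands the group design into concrete formulas: for each group, the
#' grid of oligomer sizes and CH2 ladder positions is decorated as
#' specified, checked against the elemental limits, the valence rule and
#' the neutral-mass window, and the first `size` passing combinations
#' are kept. The library is deterministic given the configuration.
#'
#' @param config A [synthetic_config()].
#' @param limits [elemental_limits()] every formula must satisfy.
#' @return A tibble with one row per component: `component_id`,
#'   `group_label`, element counts, `formula`, `neutral_mass`,
#'   `base_meanlog`, `solvent_slope`, `solvent_midpoint`.
#' @export
build_library <- function(config = synthetic_config(),
                          limits = elemental_limits()) {
  am <- atomic_masses()
  water <- c(h = 2L, o = 1L)
  out <- purrr::pmap_dfr(config$groups, function(group_label, monomer,
                                                 n_units, ch2_max, h2_shift,
                                                 o_shift, o_span, n_atoms,
                                                 s_atoms, size, base_meanlog,
                                                 solvent_slope,
                                                 solvent_midpoint, ...) {
    mono <- parse_formula(monomer)
    grid <- expand.grid(o_extra = seq_len(o_span) - 1L,
                        k = 0:ch2_max, n_mer = n_units,
                        KEEP.OUT.ATTRS = FALSE)
    cand <- purrr::pmap_dfr(grid, function(o_extra, k, n_mer) {
      c_ <- mono$c * n_mer + k
      h_ <- mono$h * n_mer - water[["h"]] * (n_mer - 1L) + 2L * k +
        2L * h2_shift + n_atoms
      o_ <- mono$o * n_mer - water[["o"]] * (n_mer - 1L) + o_shift + o_extra
      tibble::tibble(c = c_, h = h_, n = n_atoms, o = o_, s = s_atoms)
    })
    cand$neutral_mass <- monoisotopic_mass(cand)
    ok <- cand$c >= limits$c[1] & cand$c <= limits$c[2] &
      cand$h >= limits$h[1] & cand$h <= limits$h[2] &
      cand$n >= limits$n[1] & cand$n <= limits$n[2] &
      cand$o >= limits$o[1] & cand$o <= limits$o[2] &
      cand$s >= limits$s[1] & cand$s <= limits$s[2] &
      .passes_filters(cand$c, cand$h, cand$n, cand$o, cand$s, limits) &
      cand$neutral_mass >= config$mass_range[1] &
      cand$neutral_mass <= config$mass_range[2]
    cand <- cand[ok, , drop = FALSE]
    cand <- cand[!duplicated(cand[c("c", "h", "n", "o", "s")]), ,
                 drop = FALSE]
    if (nrow(cand) < size) {
      stop("group ", group_label, " design yields only ", nrow(cand),
           " admissible formulas (needs ", size, ")", call. = FALSE)
    }
    cand <- cand[seq_len(size), , drop = FALSE]
    cand$group_label <- group_label
    cand$base_meanlog <- base_meanlog
    cand$solvent_slope <- solvent_slope
    cand$solvent_midpoint <- solvent_midpoint
    cand
  })
  out$formula <- formula_label(out$c, out$h, out$n, out$o, out$s)
  out$component_id <- seq_len(nrow(out))
  dplyr::relocate(out, "component_id", "group_label", "formula")
}

#' Designed inclusion propensity of each solvent
#'
#' Expected number of library components a solvent extracts: the sum of
#' logistic inclusion probabilities
#' `plogis(slope * (ratio - midpoint))` over the component library.
#' This is the generator-side ground truth that recovered solvent
#' rankings are compared against.
#'
#' @param library A [build_library()] tibble.
#' @param solvents Solvent panel tibble.
#' @return Tibble: `solvent_label`, `organic_aqueous_ratio`,
#'   `expected_components`.
#' @export
designed_propensity <- function(library, solvents = solvent_mixtures()) {
  purrr::map_dfr(seq_len(nrow(solvents)), function(i) {
    r <- solvents$organic_aqueous_ratio[i]
    p <- stats::plogis(library$solvent_slope *
                         (r - library$solvent_midpoint))
    tibble::tibble(solvent_label = solvents$solvent_label[i],
                   organic_aqueous_ratio = r,
                   expected_components = sum(p))
  })
}

.jitter_mz <- function(mz, ppm_sigma) {
  mz * (1 + stats::rnorm(length(mz)) * ppm_sigma * 1e-6)
}

.dedupe_mz <- function(mz) {
  while (anyDuplicated(mz)) {
    mz[duplicated(mz)] <- mz[duplicated(mz)] + 1e-9
  }
  mz
}

#' Simulate one sample spectrum for a solvent
#'
#' Each library component is included with probability
#' `plogis(slope * (ratio - midpoint))`; included components are emitted
#' at the theoretical m/z of their singly (de)protonated ion plus
#' Gaussian ppm jitter, with log-normal intensities. Background noise
#' peaks (uniform m/z, low uniform intensity) and the configured
#' contaminant masses are appended. Output is bit-identical under a
#' fixed seed.
#'
#' @param library A [build_library()] tibble.
#' @param solvent One row of the solvent panel.
#' @param config A [synthetic_config()].
#' @param seed Integer seed (mandatory).
#' @return A list with `peaks` (peak tibble sorted by m/z) and `truth`
#'   (tibble joinable by `peak_index`: `kind` of
#'   component/noise/contaminant, `formula`, `group_label`, `true_mz`,
#'   `solvent_label`).
#' @export
simulate_spectrum <- function(library, solvent, config = synthetic_config(),
                              seed) {
  stopifnot(!missing(seed), nrow(solvent) == 1L)
  .with_seed(seed, {
    r <- solvent$organic_aqueous_ratio
    p <- stats::plogis(library$solvent_slope *
                         (r - library$solvent_midpoint))
    inc <- stats::runif(nrow(library)) < p
    comp <- library[inc, , drop = FALSE]
    mz_true <- theoretical_mz(comp, config$ion_mode)
    comp_mz <- .jitter_mz(mz_true, config$ppm_sigma)
    comp_int <- stats::rlnorm(nrow(comp), meanlog = comp$base_meanlog,
                              sdlog = config$intensity_sdlog)
    cont_true <- config$blank_contaminants
    cont_mz <- .jitter_mz(cont_true, config$ppm_sigma)
    cont_int <- stats::rlnorm(length(cont_true),
                              meanlog = config$contaminant_meanlog,
                              sdlog = config$intensity_sdlog)
    noise_mz <- stats::runif(config$noise_peaks,
                             config$mz_range[1], config$mz_range[2])
    noise_int <- stats::runif(config$noise_peaks,
                              config$noise_intensity[1],
                              config$noise_intensity[2])
    truth <- tibble::tibble(
      kind = c(rep("component", nrow(comp)),
               rep("contaminant", length(cont_true)),
               rep("noise", length(noise_mz))),
      formula = c(comp$formula, rep(NA_character_, length(cont_true)),
                  rep(NA_character_, length(noise_mz))),
      group_label = c(comp$group_label,
                      rep(NA_integer_, length(cont_true) + length(noise_mz))),
      true_mz = c(mz_true, cont_true, rep(NA_real_, length(noise_mz))),
      mz = .dedupe_mz(c(comp_mz, cont_mz, noise_mz)),
      intensity = c(comp_int, cont_int, noise_int),
      solvent_label = solvent$solvent_label
    )
    keep <- truth$mz >= config$mz_range[1] & truth$mz <= config$mz_range[2]
    truth <- truth[keep, , drop = FALSE]
    truth <- truth[order(truth$mz), , drop = FALSE]
    truth$peak_index <- seq_len(nrow(truth))
    peaks <- tibble::tibble(mz = truth$mz, intensity = truth$intensity,
                            rel_intensity = NA_real_)
    list(peaks = peaks,
         truth = truth[c("peak_index", "kind", "formula", "group_label",
                         "true_mz", "mz", "solvent_label")])
  })
}

#' Simulate a solvent blank
#'
#' Blanks carry only the contaminant masses (independently jittered) and
#' background noise peaks — never a library component.
#'
#' @inheritParams simulate_spectrum
#' @return A peak tibble.
#' @export
simulate_blank <- function(config = synthetic_config(), seed) {
  stopifnot(!missing(seed))
  .with_seed(seed, {
    cont_mz <- .jitter_mz(config$blank_contaminants, config$ppm_sigma)
    cont_int <- stats::rlnorm(length(cont_mz),
                              meanlog = config$contaminant_meanlog,
                              sdlog = config$intensity_sdlog)
    noise_mz <- stats::runif(config$noise_peaks,
                             config$mz_range[1], config$mz_range[2])
    noise_int <- stats::runif(config$noise_peaks,
                              config$noise_intensity[1],
                              config$noise_intensity[2])
    mz <- .dedupe_mz(c(cont_mz, noise_mz))
    ord <- order(mz)
    tibble::tibble(mz = mz[ord],
                   intensity = c(cont_int, noise_int)[ord],
                   rel_intensity = NA_real_)
  })
}

#' Simulate a full solvent-panel dataset with ground truth
#'
#' One sample spectrum and one paired blank per solvent mixture, in the
#' [load_dataset()] layout (so the whole preprocessing and
#' characterization pipeline runs on it unchanged), with a `truth`
#' list-column on sample rows.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed for the whole dataset.
#' @param sample_code Sample code stamped on the rows (default "SYN1").
#' @return A dataset tibble with attribute `library` (the component
#'   library used).
#' @export
simulate_dataset <- function(config = synthetic_config(), seed,
                             sample_code = "SYN1") {
  stopifnot(!missing(seed))
  lib <- build_library(config)
  ns <- nrow(config$solvents)
  sub <- .with_seed(seed, sample.int(1e8, 2L * ns))
  rows <- purrr::map_dfr(seq_len(ns), function(i) {
    sv <- config$solvents[i, ]
    sim <- simulate_spectrum(lib, sv, config, seed = sub[2L * i - 1L])
    blk <- simulate_blank(config, seed = sub[2L * i])
    tibble::tibble(
      file = NA_character_,
      sample_code = c(sample_code, paste0(sample_code, "_blank")),
      solvent_label = sv$solvent_label,
      organic_aqueous_ratio = sv$organic_aqueous_ratio,
      ion_mode = config$ion_mode,
      is_blank = c(FALSE, TRUE),
      peaks = list(sim$peaks, blk),
      truth = list(sim$truth, NULL)
    )
  })
  rows$n_peaks <- vapply(rows$peaks, nrow, 1L)
  rows$blank_row <- ifelse(rows$is_blank, NA_integer_,
                           match(paste(rows$solvent_label, TRUE),
                                 paste(rows$solvent_label, rows$is_blank)))
  attr(rows, "library") <- lib
  rows
}

#' Write a simulated dataset to ".xy" files plus manifest and truth CSV
#'
#' Emits one ".xy" file per spectrum, a manifest in the [load_dataset()]
#' dialect, and `ground_truth.csv` for the sample rows, so a simulated
#' study round-trips through the file-based entry points.
#'
#' @param dataset A [simulate_dataset()] tibble.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- dataset
  ds$file <- sprintf("spec_%02d_%s.xy", seq_len(nrow(ds)),
                     ifelse(ds$is_blank, "blank", "sample"))
  for (i in seq_len(nrow(ds))) {
    write_xy(ds$peaks[[i]], file.path(dir, ds$file[i]))
  }
  man <- ds[c("file", "sample_code", "solvent_label",
              "organic_aqueous_ratio", "ion_mode", "is_blank")]
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  truth <- dplyr::bind_rows(ds$truth[!vapply(ds$truth, is.null,
                                             logical(1))])
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(man_path)
}

#' Gate polygons from a component library's true Kendrick footprint
#'
#' Rectangular gate polygons covering each group's theoretical (KM, KMD)
#' bounding box, padded so ppm-jittered peaks still fall inside. These
#' stand in for the interactive lasso selection when benchmarking
#' against ground truth.
#'
#' @param library A [build_library()] tibble.
#' @param base [kendrick_base()] (default CH2).
#' @param ion_mode Ion mode of the simulated spectra.
#' @param pad_km,pad_kmd Padding in u (defaults 1 and 0.005).
#' @return Named list of polygon tibbles (`km`, `kmd`), one per group in
#'   group-label order.
#' @export
library_gate_polygons <- function(library, base = kendrick_base("CH2"),
                                  ion_mode = "negative",
                                  pad_km = 1, pad_kmd = 0.005) {
  mz <- theoretical_mz(library, ion_mode)
  km <- mz * base$nominal_mass / base$exact_mass
  kmd <- round_half_up(km) - km
  out <- lapply(sort(unique(library$group_label)), function(g) {
    i <- library$group_label == g
    tibble::tibble(
      km = c(min(km[i]) - pad_km, max(km[i]) + pad_km,
             max(km[i]) + pad_km, min(km[i]) - pad_km),
      kmd = c(min(kmd[i]) - pad_kmd, min(kmd[i]) - pad_kmd,
              max(kmd[i]) + pad_kmd, max(kmd[i]) + pad_kmd)
    )
  })
  names(out) <- paste0("group", sort(unique(library$group_label)))
  out
}

#' Score formula recovery against generator ground truth
#'
#' Joins a spectrum's ground truth with its formula assignments by peak
#' index and reports the exact-formula recovery rate over component
#' peaks, broken down by group and by 100-u mass decade (high-mass bins
#' expose compositional ambiguity).
#'
#' @param truth Ground-truth tibble from [simulate_spectrum()] (or
#'   several bound together). Rows are joined to `assignments` on the
#'   emitted `mz` values (carried through the pipeline unchanged; peaks
#'   removed by preprocessing simply drop out of the join) plus
#'   `solvent_label` when both sides carry it.
#' @param assignments Assignment tibble(s) from [assign_formulas()],
#'   with a `solvent_label` column when truth spans several spectra.
#' @return Object of class `"recovery_report"`: list of `overall`,
#'   `by_group`, `by_decade` tibbles. [glance()] returns `overall`;
#'   [tidy()] returns `by_group`.
#' @export
recovery_report <- function(truth, assignments) {
  keys <- intersect(intersect(c("solvent_label", "mz"), names(assignments)),
                    names(truth))
  if (!"mz" %in% keys) stop("assignments lack an mz column", call. = FALSE)
  j <- dplyr::inner_join(
    truth, assignments[c(keys, "assigned", "formula")],
    by = keys, suffix = c("_true", "_assigned"))
  if (nrow(j) == 0L) stop("truth and assignments do not join",
                          call. = FALSE)
  comp <- j[j$kind == "component", , drop = FALSE]
  comp$correct <- !is.na(comp$formula_assigned) &
    comp$formula_assigned == comp$formula_true
  overall <- tibble::tibble(
    n_component_peaks = nrow(comp),
    n_assigned = sum(comp$assigned),
    n_correct = sum(comp$correct),
    recovery = mean(comp$correct)
  )
  by_group <- comp |>
    dplyr::group_by(group_label = .data$group_label) |>
    dplyr::summarise(n = dplyr::n(), recovery = mean(.data$correct),
                     .groups = "drop")
  by_decade <- comp |>
    dplyr::mutate(mass_bin = 100 * floor(.data$true_mz / 100)) |>
    dplyr::group_by(.data$mass_bin) |>
    dplyr::summarise(n = dplyr::n(), recovery = mean(.data$correct),
                     .groups = "drop")
  structure(list(overall = overall, by_group = by_group,
                 by_decade = by_decade),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Formula recovery:", sprintf("%.1f%%", 100 * x$overall$recovery),
      "of", x$overall$n_component_peaks, "component peaks\n")
  print(x$by_decade)
  invisible(x)
}

#' Tidy per-group recovery rates
#'
#' @param x A `"recovery_report"`.
#' @param ... Unused.
#' @export
#' @method tidy recovery_report
tidy.recovery_report <- function(x, ...) x$by_group

#' @rdname tidy.recovery_report
#' @export
#' @method glance recovery_report
glance.recovery_report <- function(x, ...) x$overall

#' Agreement between a recovered solvent ranking and the designed one
#'
#' Spearman rank correlation between the recovered ranking score and
#' the expected component count of [designed_propensity()].
#'
#' @param ranking A [rank_solvents()] tibble.
#' @param library The [build_library()] tibble behind the data.
#' @param solvents Solvent panel.
#' @return One-row tibble with `spearman`.
#' @export
rank_agreement <- function(ranking, library,
                           solvents = solvent_mixtures()) {
  dp <- designed_propensity(library, solvents)
  j <- dplyr::inner_join(ranking, dp,
                         by = c("solvent_label", "organic_aqueous_ratio"))
  tibble::tibble(spearman = suppressWarnings(
    stats::cor(j$score, j$expected_components, method = "spearman")))
}
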