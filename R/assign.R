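#' Elemental limits and search window for formula finding
#'
#' Bundles the constraints of the exact-mass CHNOS search: per-element
#' count ranges, the symmetric ppm error window, double-bond-equivalent
#' bounds, and two chemical-plausibility switches. The defaults are the
#' search settings used throughout the package for lignin spectra:
#' C 1-90, H 4-200, N 0-5, O 1-23, S 0-1, a 0.5 ppm window, and DBE in
#' \[0, 50\].
#'
#' @param c_min,c_max,h_min,h_max,n_min,n_max,o_min,o_max,s_min,s_max
#'   Element count bounds. Oxygen defaults to a minimum of 1 (lignin
#'   compositions are oxygenated); set `o_min = 0` to allow oxygen-free
#'   formulas.
#' @param ppm_window Symmetric mass-error tolerance in ppm (default 0.5).
#' @param dbe_min,dbe_max DBE bounds (default 0 and 50).
#' @param require_integer_dbe Keep only integer-DBE (even-electron
#'   neutral) formulas (default `TRUE`).
#' @param enforce_valence Apply the hydrogen valence cap
#'   `H <= 2C + N + 2` (default `TRUE`).
#' @return A list of class `"elemental_limits"`.
#' @export
elemental_limits <- function(c_min = 1L, c_max = 90L,
                             h_min = 4L, h_max = 200L,
                             n_min = 0L, n_max = 5L,
                             o_min = 1L, o_max = 23L,
                             s_min = 0L, s_max = 1L,
                             ppm_window = 0.5,
                             dbe_min = 0, dbe_max = 50,
                             require_integer_dbe = TRUE,
                             enforce_valence = TRUE) {
  lim <- list(c = c(c_min, c_max), h = c(h_min, h_max),
              n = c(n_min, n_max), o = c(o_min, o_max),
              s = c(s_min, s_max),
              ppm_window = ppm_window,
              dbe_min = dbe_min, dbe_max = dbe_max,
              require_integer_dbe = require_integer_dbe,
              enforce_valence = enforce_valence)
  for (el in c("c", "h", "n", "o", "s")) {
    stopifnot(lim[[el]][1] >= 0, lim[[el]][1] <= lim[[el]][2])
  }
  stopifnot(ppm_window > 0, dbe_min <= dbe_max)
  structure(lim, class = "elemental_limits")
}

# shared candidate filters; both search routes apply the same chemistry
.passes_filters <- function(c, h, n, o, s, limits) {
  d <- c - h / 2 + n / 2 + 1
  ok <- d >= limits$dbe_min & d <= limits$dbe_max
  if (limits$require_integer_dbe) ok <- ok & ((h %% 2L) == (n %% 2L))
  if (limits$enforce_valence) ok <- ok & (h <= 2 * c + n + 2)
  ok
}

.order_candidates <- function(df) {
  df[order(abs(df$error_ppm), df$n + df$o + df$s,
           df$c, df$h, df$n, df$o, df$s), , drop = FALSE]
}

.candidate_tibble <- function(c, h, n, o, s, theo, err) {
  tibble::tibble(
    c = as.integer(c), h = as.integer(h), n = as.integer(n),
    o = as.integer(o), s = as.integer(s),
    formula = formula_label(c, h, n, o, s),
    theo_neutral_mass = theo,
    error_ppm = err,
    dbe = c - h / 2 + n / 2 + 1,
    h_c = h / c, o_c = o / c,
    het_class = heteroatom_class(
      tibble::tibble(c = c, h = h, n = n, o = o, s = s))
  )
}

#' Enumerate candidate formulas for a neutral mass
#'
#' Finds every CHNOS formula within the elemental limits whose
#' monoisotopic mass lies within `ppm_window` of the query neutral mass
#' and which passes the DBE, integer-DBE and valence filters. The search
#' loops over S, N, O and C counts and solves the hydrogen count from
#' the mass residual, so only a handful of H values are examined per
#' heteroatom combination.
#'
#' The mass error is reported as
#' `(observed - theoretical) / theoretical * 1e6` ppm on the neutral-mass
#' scale. Candidates are ordered by `|error_ppm|` ascending, ties broken
#' by fewer heteroatoms (N+O+S), then lexicographically on
#' (C, H, N, O, S), which makes the downstream lowest-error selection
#' deterministic.
#'
#' @param neutral_mass Query neutral monoisotopic mass (u), a scalar.
#' @param limits An [elemental_limits()] object.
#' @return A tibble of candidates (possibly zero rows) with element
#'   counts, `formula`, `theo_neutral_mass`, `error_ppm`, `dbe`, `h_c`,
#'   `o_c` and `het_class`.
#' @seealso [brute_force_candidates()] for the exhaustive reference
#'   search used to validate this routine.
#' @export
enumerate_candidates <- function(neutral_mass, limits = elemental_limits()) {
  stopifnot(length(neutral_mass) == 1L, neutral_mass > 0)
  am <- atomic_masses()
  tol <- limits$ppm_window * 1e-6 * neutral_mass
  hi <- neutral_mass + tol
  rows <- vector("list", 64L); nr <- 0L
  cs <- seq.int(limits$c[1], limits$c[2])
  for (s in seq.int(limits$s[1], limits$s[2])) {
    for (n in seq.int(limits$n[1], limits$n[2])) {
      for (o in seq.int(limits$o[1], limits$o[2])) {
        base <- s * am[["S"]] + n * am[["N"]] + o * am[["O"]]
        if (base + limits$c[1] * am[["C"]] + limits$h[1] * am[["H"]] > hi) {
          break  # o only grows; nothing heavier can fit
        }
        cc <- cs[base + cs * am[["C"]] + limits$h[1] * am[["H"]] <= hi]
        if (length(cc) == 0L) next
        rem <- neutral_mass - base - cc * am[["C"]]
        h0 <- round(rem / am[["H"]])
        for (dh in -1:1) {
          h <- h0 + dh
          theo <- base + cc * am[["C"]] + h * am[["H"]]
          err <- (neutral_mass - theo) / theo * 1e6
          keep <- h >= limits$h[1] & h <= limits$h[2] &
            abs(err) <= limits$ppm_window &
            .passes_filters(cc, h, n, o, s, limits)
          if (any(keep)) {
            nr <- nr + 1L
            rows[[nr]] <- .candidate_tibble(cc[keep], h[keep], n, o, s,
                                            theo[keep], err[keep])
          }
        }
      }
    }
  }
  if (nr == 0L) {
    return(.candidate_tibble(integer(), integer(), integer(), integer(),
                             integer(), numeric(), numeric()))
  }
  out <- dplyr::bind_rows(rows[seq_len(nr)])
  out <- .order_candidates(out)
  rownames(out) <- NULL
  out
}

# full-grid cache for the exhaustive search, keyed by element bounds
.bf_cache <- new.env(parent = emptyenv())

#' Exhaustive reference formula search
#'
#' Enumerates *every* element-count combination inside the limits (a
#' full nested grid), computes all masses, and applies the same filters
#' and ordering as [enumerate_candidates()]. This is the brute-force
#' oracle used to validate the production search; it refuses to run when
#' the grid exceeds `cap` combinations rather than truncating silently.
#' The grid is cached per element-bounds so repeated queries under one
#' limit set are cheap.
#'
#' @inheritParams enumerate_candidates
#' @param cap Maximum tolerated grid size (default 1e7).
#' @return A candidate tibble in the [enumerate_candidates()] layout.
#' @export
brute_force_candidates <- function(neutral_mass,
                                   limits = elemental_limits(),
                                   cap = 1e7) {
  stopifnot(length(neutral_mass) == 1L, neutral_mass > 0)
  nsz <- prod(vapply(list(limits$c, limits$h, limits$n, limits$o, limits$s),
                     function(r) diff(r) + 1, numeric(1)))
  if (nsz > cap) {
    stop("brute-force grid of ", format(nsz, big.mark = ","),
         " combinations exceeds the cap", call. = FALSE)
  }
  key <- paste(c(limits$c, limits$h, limits$n, limits$o, limits$s),
               collapse = "_")
  grid <- .bf_cache[[key]]
  if (is.null(grid)) {
    am <- atomic_masses()
    grid <- expand.grid(c = seq.int(limits$c[1], limits$c[2]),
                        h = seq.int(limits$h[1], limits$h[2]),
                        n = seq.int(limits$n[1], limits$n[2]),
                        o = seq.int(limits$o[1], limits$o[2]),
                        s = seq.int(limits$s[1], limits$s[2]),
                        KEEP.OUT.ATTRS = FALSE)
    # same left-associative summation order as the production search so
    # the two routes agree to the last bit
    grid$mass <- grid$s * am[["S"]] + grid$n * am[["N"]] +
      grid$o * am[["O"]] + grid$c * am[["C"]] + grid$h * am[["H"]]
    .bf_cache[[key]] <- grid
  }
  tol <- limits$ppm_window * 1e-6 * neutral_mass
  hit <- grid[abs(grid$mass - neutral_mass) <= tol, , drop = FALSE]
  if (nrow(hit) > 0L) {
    ok <- .passes_filters(hit$c, hit$h, hit$n, hit$o, hit$s, limits)
    hit <- hit[ok, , drop = FALSE]
  }
  err <- (neutral_mass - hit$mass) / hit$mass * 1e6
  out <- .candidate_tibble(hit$c, hit$h, hit$n, hit$o, hit$s, hit$mass, err)
  out <- .order_candidates(out)
  rownames(out) <- NULL
  out
}

#' Assign molecular formulas to a spectrum
#'
#' Runs the candidate search for every peak of a (preprocessed) peak
#' list and keeps, per peak, the single best candidate: the formula with
#' the lowest absolute m/z error, ties resolved by the deterministic
#' chain of [enumerate_candidates()]. Peaks with no in-window candidate
#' are kept in the output flagged `assigned = FALSE`.
#'
#' @param peaks Peak tibble (columns `mz`, `intensity`, optionally
#'   `rel_intensity`).
#' @param limits An [elemental_limits()] object.
#' @param ion_mode `"negative"` or `"positive"`; peaks are read as
#'   singly (de)protonated ions.
#' @return A tibble with one row per peak: `peak_index`, `mz`,
#'   `intensity`, `rel_intensity`, `assigned`, `formula`, element counts,
#'   `neutral_mass` (observed), `theo_neutral_mass`, `theoretical_mz`,
#'   `error_ppm`, `dbe`, `h_c`, `o_c`, `het_class`. The assignment rate
#'   is attached as attribute `assignment_rate` and in the `summary()` of
#'   the returned object.
#' @export
assign_formulas <- function(peaks, limits = elemental_limits(),
                            ion_mode = "negative") {
  stopifnot(is.data.frame(peaks), nrow(peaks) > 0)
  mode <- canonical_ion_mode(ion_mode)
  mp <- atomic_masses()[["proton"]]
  nm <- neutral_mass(peaks$mz, mode)
  best <- lapply(nm, function(m) {
    cand <- enumerate_candidates(m, limits)
    if (nrow(cand) == 0L) NULL else cand[1L, ]
  })
  assigned <- !vapply(best, is.null, logical(1))
  empty <- tibble::tibble(
    c = NA_integer_, h = NA_integer_, n = NA_integer_, o = NA_integer_,
    s = NA_integer_, formula = NA_character_, theo_neutral_mass = NA_real_,
    error_ppm = NA_real_, dbe = NA_real_, h_c = NA_real_, o_c = NA_real_,
    het_class = NA_character_)
  rows <- dplyr::bind_rows(lapply(best, function(b) if (is.null(b)) empty
                                  else b))
  out <- tibble::tibble(
    peak_index = seq_len(nrow(peaks)),
    mz = peaks$mz,
    intensity = peaks$intensity,
    rel_intensity = if ("rel_intensity" %in% names(peaks))
      peaks$rel_intensity else NA_real_,
    assigned = assigned,
    neutral_mass = nm
  )
  out <- dplyr::bind_cols(out, rows)
  out$theoretical_mz <- ifelse(out$assigned,
                               if (mode == "negative")
                                 out$theo_neutral_mass - mp
                               else out$theo_neutral_mass + mp,
                               NA_real_)
  attr(out, "assignment_rate") <- mean(assigned)
  attr(out, "ion_mode") <- mode
  out
}
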