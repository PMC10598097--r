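#' Parse CHNOS molecular formulas
#'
#' Parses formula strings such as `"C9H10O2"` or `"CH2"` into element
#' counts over the supported element set C, H, N, O, S. Element symbols
#' without an explicit count are read as 1.
#'
#' @param formula Character vector of formula strings.
#' @return A tibble with one row per input formula and integer columns
#'   `c`, `h`, `n`, `o`, `s`.
#' @examples
#' parse_formula(c("CH2", "C9H10O2"))
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) >= 1)
  rows <- lapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) {
      stop("empty formula string", call. = FALSE)
    }
    m <- gregexpr("[A-Z][a-z]?[0-9]*", f)[[1]]
    tokens <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
    if (sum(attr(m, "match.length")) != nchar(f)) {
      stop("cannot parse formula: ", f, call. = FALSE)
    }
    counts <- stats::setNames(rep(0L, 5L), .element_order)
    for (tok in tokens) {
      sym <- sub("[0-9]*$", "", tok)
      if (!sym %in% .element_order) {
        stop("unsupported element '", sym, "' in formula: ", f, call. = FALSE)
      }
      k <- sub("^[A-Za-z]+", "", tok)
      counts[sym] <- counts[sym] + if (nzchar(k)) as.integer(k) else 1L
    }
    counts
  })
  mat <- do.call(rbind, rows)
  tibble::tibble(
    c = as.integer(mat[, "C"]), h = as.integer(mat[, "H"]),
    n = as.integer(mat[, "N"]), o = as.integer(mat[, "O"]),
    s = as.integer(mat[, "S"])
  )
}

#' Serialize element counts to formula strings
#'
#' Inverse of [parse_formula()]: elements are printed in the fixed order
#' C, H, N, O, S, zero counts omitted, and a count of 1 written without a
#' digit (`"CH4"`, not `"C1H4"`).
#'
#' @param c,h,n,o,s Integer vectors of element counts (recycled).
#' @return Character vector of formula strings.
#' @examples
#' formula_label(c = 9, h = 10, o = 2)
#' @export
formula_label <- function(c, h = 0L, n = 0L, o = 0L, s = 0L) {
  counts <- cbind(C = c, H = h, N = n, O = o, S = s)
  if (nrow(counts) == 0L) return(character(0))
  apply(counts, 1L, function(row) {
    keep <- row > 0
    if (!any(keep)) return("")
    paste0(names(row)[keep],
           ifelse(row[keep] == 1L, "", row[keep]),
           collapse = "")
  })
}

#' Monoisotopic mass of a CHNOS formula
#'
#' Sum of element counts times the pinned monoisotopic atomic masses of
#' [atomic_masses()].
#'
#' @param formula A data frame with columns `c`, `h`, `n`, `o`, `s`
#'   (as returned by [parse_formula()]), or a character vector of formula
#'   strings.
#' @return Numeric vector of neutral monoisotopic masses (u).
#' @examples
#' monoisotopic_mass("CH2")  # 14.01565
#' @export
monoisotopic_mass <- function(formula) {
  f <- .as_formula_df(formula)
  am <- atomic_masses()
  f$c * am[["C"]] + f$h * am[["H"]] + f$n * am[["N"]] +
    f$o * am[["O"]] + f$s * am[["S"]]
}

#' Double-bond equivalents of a neutral formula
#'
#' Rings plus double bonds: `DBE = C - H/2 + N/2 + 1`. Oxygen and sulfur
#' (divalent) do not enter.
#'
#' @inheritParams monoisotopic_mass
#' @return Numeric vector of DBE values (may be half-integer for
#'   odd-electron compositions).
#' @examples
#' dbe("C6H6")  # 4
#' @export
dbe <- function(formula) {
  f <- .as_formula_df(formula)
  f$c - f$h / 2 + f$n / 2 + 1
}

#' Heteroatom class label of a formula
#'
#' Concatenates, in the fixed order S, N, O, every heteroatom present
#' with its count (`"S1N2O10"`); elements with count zero are omitted and
#' pure hydrocarbons are labeled `"CH"`.
#'
#' @inheritParams monoisotopic_mass
#' @return Character vector of class labels.
#' @examples
#' heteroatom_class("C9H10O2")  # "O2"
#' @export
heteroatom_class <- function(formula) {
  f <- .as_formula_df(formula)
  lab <- paste0(
    ifelse(f$s > 0, paste0("S", f$s), ""),
    ifelse(f$n > 0, paste0("N", f$n), ""),
    ifelse(f$o > 0, paste0("O", f$o), "")
  )
  ifelse(nzchar(lab), lab, "CH")
}

#' Neutral mass of an ESI (de)protonated ion
#'
#' Converts an observed m/z to the neutral monoisotopic mass under the
#' singly charged (de)protonation model: negative mode reads the ion as
#' \[M - H\]- (neutral = m/z + proton mass), positive mode as \[M + H\]+
#' (neutral = m/z - proton mass). Adducts and multiple charging are out
#' of scope.
#'
#' @param mz Numeric vector of observed m/z (Th).
#' @param ion_mode `"negative"` or `"positive"` (aliases `"neg"`, `"pos"`,
#'   `"-"`, `"+"` accepted).
#' @return Numeric vector of neutral masses (u).
#' @examples
#' neutral_mass(149.060803, "negative")  # approx C9H10O2
#' @export
neutral_mass <- function(mz, ion_mode) {
  mode <- canonical_ion_mode(ion_mode)
  mp <- atomic_masses()[["proton"]]
  if (mode == "negative") {
    if (any(mz <= mp)) {
      stop("negative-mode m/z must exceed the proton mass", call. = FALSE)
    }
    mz + mp
  } else {
    mz - mp
  }
}

#' Theoretical m/z of a formula in a given ion mode
#'
#' @inheritParams monoisotopic_mass
#' @inheritParams neutral_mass
#' @return Numeric vector of theoretical m/z for the singly (de)protonated
#'   ion.
#' @export
theoretical_mz <- function(formula, ion_mode) {
  mode <- canonical_ion_mode(ion_mode)
  mp <- atomic_masses()[["proton"]]
  m <- monoisotopic_mass(formula)
  if (mode == "negative") m - mp else m + mp
}

#' Canonicalize an ion-mode token
#'
#' @param ion_mode Character scalar or vector of polarity tokens.
#' @return Character vector with values `"negative"` or `"positive"`.
#' @export
canonical_ion_mode <- function(ion_mode) {
  tok <- tolower(trimws(as.character(ion_mode)))
  out <- ifelse(tok %in% c("negative", "neg", "-", "esi-"), "negative",
         ifelse(tok %in% c("positive", "pos", "+", "esi+"), "positive",
                NA_character_))
  if (anyNA(out)) {
    stop("unknown ion_mode token: ",
         paste(unique(tok[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

.as_formula_df <- function(formula) {
  if (is.character(formula)) return(parse_formula(formula))
  stopifnot(is.data.frame(formula),
            all(c("c", "h", "n", "o", "s") %in% names(formula)))
  formula
}
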