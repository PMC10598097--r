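#' Pinned monoisotopic atomic masses
#'
#' Monoisotopic masses (u) of the most abundant isotope of each element
#' supported by the formula search, plus the proton mass used for
#' (de)protonation arithmetic. Values follow the CODATA/AME compilations
#' and are pinned here so every mass computed by the package traces to a
#' single constants table.
#'
#' @format Named numeric vector with elements `C`, `H`, `N`, `O`, `S` and
#'   `proton`.
#' @examples
#' atomic_masses()[["C"]]
#' @export
atomic_masses <- function() {
  c(
    C = 12.0,           # 12C, exact by definition
    H = 1.00782503207,  # 1H
    N = 14.0030740048,  # 14N
    O = 15.9949146196,  # 16O
    S = 31.97207100,    # 32S
    proton = 1.007276466
  )
}

# element order used everywhere a formula is serialized or compared
.element_order <- c("C", "H", "N", "O", "S")
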