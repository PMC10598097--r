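#' Read a two-column ".xy" ASCII peak list
#'
#' Reads a centroided peak list exported as ASCII text with two numeric
#' columns, m/z and intensity. The delimiter (whitespace, comma, or tab)
#' is auto-detected per line; empty lines are skipped. Peaks are returned
#' sorted strictly ascending in m/z; duplicate m/z values are merged by
#' keeping the maximum intensity, with a warning.
#'
#' @param path Path to the ".xy" file.
#' @return A tibble of peaks with columns `mz` (Th), `intensity`
#'   (arbitrary counts) and `rel_intensity` (`NA` until
#'   [normalize_intensity()] is applied).
#' @seealso [write_xy()], [load_dataset()]
#' @export
read_xy <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    stop("zero parsable lines in ", path, call. = FALSE)
  }
  fields <- strsplit(trimws(lines[keep]), "[,\t ]+")
  bad_n <- vapply(fields, length, 1L) != 2L
  if (any(bad_n)) {
    stop("line ", keep[which(bad_n)[1L]], " of ", path,
         " does not hold two fields", call. = FALSE)
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = 2L, byrow = TRUE)
  if (anyNA(mat)) {
    bad <- which(rowSums(is.na(mat)) > 0)[1L]
    stop("non-numeric field on line ", keep[bad], " of ", path,
         call. = FALSE)
  }
  if (any(mat[, 1L] <= 0) || any(mat[, 2L] < 0)) {
    stop("peaks require mz > 0 and intensity >= 0 in ", path,
         call. = FALSE)
  }
  pk <- tibble::tibble(mz = mat[, 1L], intensity = mat[, 2L])
  if (anyDuplicated(pk$mz)) {
    ndup <- sum(duplicated(pk$mz))
    warning(ndup, " duplicate m/z value(s) in ", path,
            "; keeping maximum intensity", call. = FALSE)
    pk <- pk |>
      dplyr::group_by(.data$mz) |>
      dplyr::summarise(intensity = max(.data$intensity), .groups = "drop")
  }
  pk |>
    dplyr::arrange(.data$mz) |>
    dplyr::mutate(rel_intensity = NA_real_)
}

#' Write a peak list as a two-column ".xy" ASCII file
#'
#' Writes m/z and raw intensity, space-delimited, at full double
#' precision (17 significant digits) so that a read/write round trip
#' reproduces both columns. Relative intensities are not part of the
#' format and are not written.
#'
#' @param peaks A data frame with columns `mz` and `intensity`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xy <- function(peaks, path) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (nrow(peaks) == 0L) {
    stop("refusing to write an empty spectrum", call. = FALSE)
  }
  lines <- paste(format(peaks$mz, digits = 17, scientific = FALSE, trim = TRUE),
                 format(peaks$intensity, digits = 17, scientific = FALSE,
                        trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' The ten extraction solvent mixtures of the study design
#'
#' Default solvent panel used throughout the package: binary and ternary
#' aqueous mixtures of acetone, methanol, ethanol and acetonitrile with
#' their organic/aqueous volume ratios (the volume fraction of organic
#' co-solvent).
#'
#' @return A tibble with columns `solvent_label`,
#'   `organic_aqueous_ratio`, and `components` (a list-column of tibbles
#'   with `solvent` and `fraction`; fractions sum to 1).
#' @examples
#' solvent_mixtures()
#' @export
solvent_mixtures <- function() {
  spec <- list(
    list("1:1 acetone:H2O",       c(acetone = 1, H2O = 1)),
    list("1:1 MeOH:H2O",          c(MeOH = 1, H2O = 1)),
    list("1:1 EtOH:H2O",          c(EtOH = 1, H2O = 1)),
    list("1:1 AcN:H2O",           c(AcN = 1, H2O = 1)),
    list("3:1 MeOH:H2O",          c(MeOH = 3, H2O = 1)),
    list("3:1 AcN:H2O",           c(AcN = 3, H2O = 1)),
    list("1:3 MeOH:H2O",          c(MeOH = 1, H2O = 3)),
    list("1:3 AcN:H2O",           c(AcN = 1, H2O = 3)),
    list("1:1:2 acetone:AcN:H2O", c(acetone = 1, AcN = 1, H2O = 2)),
    list("1:1:2 acetone:MeOH:H2O", c(acetone = 1, MeOH = 1, H2O = 2))
  )
  purrr::map_dfr(spec, function(x) solvent_mixture(x[[1]], x[[2]]))
}

#' Construct a solvent-mixture record
#'
#' @param label Display label, e.g. `"1:1 AcN:H2O"`.
#' @param parts Named numeric vector of volume parts; the aqueous
#'   component must be named `"H2O"`.
#' @return One-row tibble in the [solvent_mixtures()] layout.
#' @export
solvent_mixture <- function(label, parts) {
  stopifnot(is.numeric(parts), !is.null(names(parts)), all(parts > 0))
  frac <- parts / sum(parts)
  ratio <- sum(frac[names(frac) != "H2O"])
  tibble::tibble(
    solvent_label = label,
    organic_aqueous_ratio = unname(ratio),
    components = list(tibble::tibble(solvent = names(frac),
                                     fraction = unname(frac)))
  )
}

#' Load a dataset of peak lists from a manifest
#'
#' The manifest is a CSV with header
#' `file,sample_code,solvent_label,organic_aqueous_ratio,ion_mode,is_blank`,
#' one row per ".xy" file. Each file is read with [read_xy()]; ion-mode
#' tokens are canonicalized; every non-blank spectrum is paired with at
#' most one blank of identical (`solvent_label`, `ion_mode`). Relative
#' manifest paths are resolved against the manifest's directory.
#'
#' @param manifest Path to the manifest CSV, or an equivalent data frame
#'   (then `dir` resolves the file paths).
#' @param dir Base directory for relative file paths when `manifest` is a
#'   data frame; defaults to the working directory.
#' @return A tibble with one row per spectrum: the manifest metadata
#'   columns, `peaks` (list-column of peak tibbles), `n_peaks`, and
#'   `blank_row` (row index of the paired blank, `NA` for blanks and for
#'   samples without a matching blank).
#' @export
load_dataset <- function(manifest, dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(dir)) dir <- dirname(manifest)
    man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  } else {
    man <- as.data.frame(manifest)
    if (is.null(dir)) dir <- "."
  }
  need <- c("file", "sample_code", "solvent_label", "organic_aqueous_ratio",
            "ion_mode", "is_blank")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols)) {
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  man$ion_mode <- canonical_ion_mode(man$ion_mode)
  man$is_blank <- as.logical(man$is_blank)
  key <- paste(man$sample_code, man$solvent_label, man$ion_mode, man$is_blank)
  if (anyDuplicated(key)) {
    stop("duplicate (sample, solvent, mode, is_blank) manifest rows",
         call. = FALSE)
  }
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$file), man$file,
                  file.path(dir, man$file))
  missing_f <- !file.exists(paths)
  if (any(missing_f)) {
    stop("manifest references missing file(s): ",
         paste(man$file[missing_f], collapse = ", "), call. = FALSE)
  }
  ds <- tibble::as_tibble(man[need])
  ds$peaks <- lapply(paths, read_xy)
  ds$n_peaks <- vapply(ds$peaks, nrow, 1L)

  blank_key <- paste(ds$solvent_label, ds$ion_mode)
  ds$blank_row <- NA_integer_
  for (i in which(!ds$is_blank)) {
    hit <- which(ds$is_blank & blank_key == blank_key[i])
    if (length(hit) >= 1L) {
      ds$blank_row[i] <- hit[1L]
    } else {
      warning("no blank for (", ds$solvent_label[i], ", ", ds$ion_mode[i],
              "); blank subtraction will be skipped", call. = FALSE)
    }
  }
  ds
}
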