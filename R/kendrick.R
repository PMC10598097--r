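#' Define a Kendrick base unit
#'
#' A Kendrick base is the repeating unit whose nominal/exact mass ratio
#' rescales the m/z axis so that homologous series differing by that
#' unit share a mass defect. The classic choice for lignin oligomer
#' series is CH2 (nominal mass 14, exact mass 14.01565).
#'
#' @param formula Formula string of the repeating unit over C, H, N, O, S.
#' @return One-row tibble with `formula`, `nominal_mass` (integer u) and
#'   `exact_mass` (monoisotopic, u).
#' @examples
#' kendrick_base("CH2")
#' @export
kendrick_base <- function(formula = "CH2") {
  em <- monoisotopic_mass(formula)
  stopifnot(em > 0)
  tibble::tibble(formula = formula,
                 nominal_mass = as.integer(round(em)),
                 exact_mass = em)
}

# round-half-up; base R round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

#' Transform a peak list into Kendrick mass-defect space
#'
#' Computes the Kendrick mass `KM = mz * nominal / exact` and the
#' Kendrick mass defect. Under the default nearest-integer convention,
#' `KMD = round(KM) - KM` with half-up rounding, so KMD lies in
#' (-0.5, 0.5] and members of an exact homologous ladder share KMD
#' exactly. The `"ceiling"` convention (`KMD = ceiling(KM) - KM`, range
#' \[0, 1)) is provided for comparison with tools that use it.
#'
#' @param peaks Peak tibble with columns `mz` and `intensity`.
#' @param base A [kendrick_base()] row.
#' @param convention `"round"` (default) or `"ceiling"`.
#' @return A tibble with one row per peak: `peak_index`, `mz`,
#'   `intensity`, `rel_intensity` (if present), `km`, `kmd`.
#' @examples
#' kendrick_transform(data.frame(mz = c(300, 314.01565), intensity = 1))
#' @export
kendrick_transform <- function(peaks, base = kendrick_base("CH2"),
                               convention = c("round", "ceiling")) {
  stopifnot(is.data.frame(peaks), nrow(peaks) > 0)
  convention <- match.arg(convention)
  km <- peaks$mz * base$nominal_mass / base$exact_mass
  kmd <- switch(convention,
                round = round_half_up(km) - km,
                ceiling = ceiling(km) - km)
  out <- tibble::tibble(peak_index = seq_len(nrow(peaks)),
                        mz = peaks$mz,
                        intensity = peaks$intensity,
                        km = km, kmd = kmd)
  if ("rel_intensity" %in% names(peaks)) {
    out$rel_intensity <- peaks$rel_intensity
  }
  out
}

#' Read / write a gate polygon
#'
#' Gate polygons are stored as plain CSV files with header `km,kmd`, one
#' vertex per row in order, making interactive lasso selections
#' reproducible as files.
#'
#' @param path CSV file path.
#' @return `read_polygon()`: a tibble with columns `km` and `kmd`.
#' @export
read_polygon <- function(path) {
  poly <- tibble::as_tibble(utils::read.csv(path))
  stopifnot(all(c("km", "kmd") %in% names(poly)))
  validate_polygon(poly)
  poly
}

#' @rdname read_polygon
#' @param polygon Data frame of polygon vertices (`km`, `kmd`).
#' @export
write_polygon <- function(polygon, path) {
  validate_polygon(polygon)
  utils::write.csv(polygon[c("km", "kmd")], path, row.names = FALSE)
  invisible(path)
}

#' Validate a gate polygon
#'
#' Checks that a polygon has at least 3 vertices and that no two
#' non-adjacent edges cross.
#'
#' @param polygon Data frame with `km` and `kmd` vertex columns.
#' @return The polygon, invisibly; errors if invalid.
#' @export
validate_polygon <- function(polygon) {
  stopifnot(is.data.frame(polygon),
            all(c("km", "kmd") %in% names(polygon)))
  n <- nrow(polygon)
  if (n < 3L) stop("a gate polygon needs at least 3 vertices", call. = FALSE)
  x <- polygon$km; y <- polygon$kmd
  # non-adjacent edge pairs must not cross
  seg <- cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (i == 1L && j == n) next  # adjacent through the closure
      if (.segments_cross(x[seg[i, ]], y[seg[i, ]],
                          x[seg[j, ]], y[seg[j, ]])) {
        stop("self-intersecting gate polygon", call. = FALSE)
      }
    }
  }
  invisible(polygon)
}

.segments_cross <- function(ax, ay, bx, by) {
  d <- function(px, py, qx, qy, rx, ry) {
    (qx - px) * (ry - py) - (qy - py) * (rx - px)
  }
  d1 <- d(bx[1], by[1], bx[2], by[2], ax[1], ay[1])
  d2 <- d(bx[1], by[1], bx[2], by[2], ax[2], ay[2])
  d3 <- d(ax[1], ay[1], ax[2], ay[2], bx[1], by[1])
  d4 <- d(ax[1], ay[1], ax[2], ay[2], bx[2], by[2])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# points on the boundary count as inside (crossing-number with an
# explicit on-edge test; eps scales with the polygon extent)
.point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  eps <- 1e-9 * max(diff(range(vx)), diff(range(vy)), 1)
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    inside <- FALSE
    j <- n
    for (k in seq_len(n)) {
      x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[k]; y2 <- vy[k]
      # on-edge check
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) <= eps * max(abs(x2 - x1), abs(y2 - y1), 1) &&
          x >= min(x1, x2) - eps && x <= max(x1, x2) + eps &&
          y >= min(y1, y2) - eps && y <= max(y1, y2) + eps) {
        return(TRUE)
      }
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
        if (x < xint) inside <- !inside
      }
      j <- k
    }
    inside
  }, logical(1))
}

#' Gate a peak group from Kendrick space
#'
#' Selects the Kendrick points inside (or on the boundary of) a gate
#' polygon. Following the convention that a sparse region is not a
#' meaningful group, gates capturing fewer than `min_members` points are
#' rejected: a zero-row result is returned with a warning naming the
#' count.
#'
#' @param points Kendrick-point tibble from [kendrick_transform()].
#' @param polygon Polygon data frame (`km`, `kmd` vertices).
#' @param group_id Integer id attached to the gated members.
#' @param min_members Minimum group size (default 5).
#' @return Tibble of member points with a leading `group_id` column.
#'   Attributes: `polygon`, `accepted` (logical), `n_inside` (count of
#'   points captured before the size rule).
#' @export
gate_points <- function(points, polygon, group_id = 1L, min_members = 5L) {
  validate_polygon(polygon)
  stopifnot(is.data.frame(points), all(c("km", "kmd") %in% names(points)))
  inside <- .point_in_polygon(points$km, points$kmd,
                              polygon$km, polygon$kmd)
  members <- points[inside, , drop = FALSE]
  accepted <- nrow(members) >= min_members
  if (!accepted) {
    warning("gate rejected: only ", nrow(members), " point(s) inside (< ",
            min_members, ")", call. = FALSE)
    members <- members[0L, , drop = FALSE]
  }
  out <- dplyr::bind_cols(tibble::tibble(group_id =
                                           rep(as.integer(group_id),
                                               nrow(members))),
                          members)
  attr(out, "polygon") <- polygon
  attr(out, "accepted") <- accepted
  attr(out, "n_inside") <- sum(inside)
  out
}

#' Gate several polygons at once
#'
#' @param points Kendrick-point tibble.
#' @param polygons Named or unnamed list of polygon data frames; group
#'   ids are taken as their position in the list.
#' @param min_members Minimum group size (default 5).
#' @return A tibble binding the accepted [gate_points()] results.
#' @export
gate_groups <- function(points, polygons, min_members = 5L) {
  res <- purrr::imap(polygons, function(poly, i) {
    gate_points(points, poly,
                group_id = if (is.character(i)) match(i, names(polygons))
                           else as.integer(i),
                min_members = min_members)
  })
  dplyr::bind_rows(res)
}

#' Detect homologous series in Kendrick space
#'
#' Homologs repeating in the base unit share a Kendrick mass defect and
#' sit at Kendrick masses separated by integer multiples of the base's
#' nominal mass. Points are first clustered on KMD by single linkage
#' within `kmd_tol`; inside each cluster, a series is a maximal set of
#' points whose KM values differ pairwise by an integer multiple of the
#' nominal mass to within `2 * kmd_tol` (a maximal clique of the
#' pairwise-compatibility graph). Only series with at least
#' `min_members` points are returned.
#'
#' @param points Kendrick-point tibble from [kendrick_transform()].
#' @param base The [kendrick_base()] used for the transform.
#' @param kmd_tol KMD tolerance in u (e.g. 0.001 for 1 mu).
#' @param min_members Minimum series length (default 3, must be >= 2).
#' @return A list of integer vectors of row indices into `points`, each
#'   sorted by KM; the list is ordered by first-member KM, then length.
#' @export
find_series <- function(points, base = kendrick_base("CH2"),
                        kmd_tol = 0.001, min_members = 3L) {
  stopifnot(kmd_tol > 0, min_members >= 2L)
  n <- nrow(points)
  if (n < min_members) return(list())
  nm <- base$nominal_mass
  ord <- order(points$kmd)
  kmd_s <- points$kmd[ord]
  breaks <- which(diff(kmd_s) > kmd_tol)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  out <- list()
  for (ci in seq_along(starts)) {
    idx <- ord[starts[ci]:ends[ci]]
    m <- length(idx)
    if (m < min_members) next
    km <- points$km[idx]
    dmat <- abs(outer(km, km, "-"))
    dev <- abs(dmat - nm * round(dmat / nm))
    adj <- dev <= 2 * kmd_tol
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    cl <- igraph::max_cliques(g, min = min_members)
    for (cc in cl) {
      memb <- idx[as.integer(cc)]
      out[[length(out) + 1L]] <- memb[order(points$km[memb])]
    }
  }
  if (length(out) == 0L) return(list())
  key <- vapply(out, function(i) points$km[i[1L]], numeric(1))
  out[order(key, vapply(out, length, 1L))]
}
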