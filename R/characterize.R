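#' Summarize gated peak groups
#'
#' Builds a characterization table in the style used for lignin
#' mass-defect groups: per group, the KM/KMD extent, the H/C, O/C and
#' DBE ranges over formula-assigned members, the heteroatom classes
#' present, and the classes unique to the group within the supplied
#' comparison set (the other groups of the same table).
#'
#' Unassigned members contribute only to the KM/KMD ranges; a group with
#' no assigned member gets `NA` ratio/DBE ranges and an empty class set.
#'
#' @param groups Gated member tibble from [gate_points()] /
#'   [gate_groups()] (columns `group_id`, `peak_index`, `km`, `kmd`).
#' @param assignments Assignment tibble from [assign_formulas()] for the
#'   same spectrum.
#' @return A tibble with one row per group: `group_id`, `n_members`,
#'   `n_assigned`, `km_min`, `km_max`, `kmd_min`, `kmd_max`, `hc_min`,
#'   `hc_max`, `oc_min`, `oc_max`, `dbe_min`, `dbe_max`, `classes` and
#'   `unique_classes` (list-columns of class labels).
#' @export
summarize_groups <- function(groups, assignments) {
  stopifnot(is.data.frame(groups), nrow(groups) > 0,
            all(c("group_id", "peak_index", "km", "kmd") %in% names(groups)))
  asg <- assignments[assignments$assigned,
                     c("peak_index", "h_c", "o_c", "dbe", "het_class")]
  joined <- dplyr::left_join(groups, asg, by = "peak_index")
  rng <- function(x) if (all(is.na(x))) c(NA_real_, NA_real_)
                     else range(x, na.rm = TRUE)
  out <- joined |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      n_assigned = sum(!is.na(.data$het_class)),
      km_min = min(.data$km), km_max = max(.data$km),
      kmd_min = min(.data$kmd), kmd_max = max(.data$kmd),
      hc_min = rng(.data$h_c)[1], hc_max = rng(.data$h_c)[2],
      oc_min = rng(.data$o_c)[1], oc_max = rng(.data$o_c)[2],
      dbe_min = rng(.data$dbe)[1], dbe_max = rng(.data$dbe)[2],
      classes = list(sort(unique(stats::na.omit(.data$het_class)))),
      .groups = "drop"
    )
  out$unique_classes <- lapply(seq_len(nrow(out)), function(i) {
    others <- unique(unlist(out$classes[-i]))
    setdiff(out$classes[[i]], others)
  })
  out
}

#' @rdname summarize_groups
#' @param group One gated group (a [gate_points()] result).
#' @export
summarize_group <- function(group, assignments) {
  if (nrow(group) == 0L) stop("empty group", call. = FALSE)
  summarize_groups(group, assignments)
}

#' Rank solvents by recovered peak count
#'
#' Orders the solvent mixtures of a preprocessed dataset by the number
#' of peaks each one's spectrum retains after filtering — the working
#' definition of how well a solvent extracted and ionized the mixture.
#' With a gate polygon the count is restricted to the points the gate
#' captures (group scope). Ties are broken alphabetically by label so
#' the ranking is deterministic.
#'
#' @param dataset Preprocessed dataset tibble ([preprocess_dataset()]);
#'   blank rows are ignored.
#' @param polygon Optional gate polygon (`km`, `kmd` data frame) for
#'   group scope.
#' @param base [kendrick_base()] used when gating (default CH2).
#' @param metric `"count"` (default) or `"intensity"` (summed raw
#'   intensity of the counted peaks).
#' @return A tibble sorted by decreasing score: `solvent_label`,
#'   `organic_aqueous_ratio`, `n_peaks`, `score`, `rank`.
#' @export
rank_solvents <- function(dataset, polygon = NULL,
                          base = kendrick_base("CH2"),
                          metric = c("count", "intensity")) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(dataset))
  smp <- dataset[!dataset$is_blank, , drop = FALSE]
  if (nrow(smp) == 0L) stop("dataset holds no sample spectra", call. = FALSE)
  per <- purrr::map_dfr(seq_len(nrow(smp)), function(i) {
    pk <- smp$peaks[[i]]
    if (!is.null(polygon) && nrow(pk) > 0L) {
      pts <- kendrick_transform(pk, base)
      inside <- .point_in_polygon(pts$km, pts$kmd, polygon$km, polygon$kmd)
      pk <- pk[inside, , drop = FALSE]
    }
    tibble::tibble(
      solvent_label = smp$solvent_label[i],
      organic_aqueous_ratio = smp$organic_aqueous_ratio[i],
      n_peaks = nrow(pk),
      score = if (metric == "count") nrow(pk) else sum(pk$intensity)
    )
  })
  out <- per |>
    dplyr::group_by(.data$solvent_label, .data$organic_aqueous_ratio) |>
    dplyr::summarise(n_peaks = sum(.data$n_peaks),
                     score = sum(.data$score), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$solvent_label)
  out$rank <- seq_len(nrow(out))
  out
}

#' Optimum solvents per gated group
#'
#' For each gate polygon, ranks solvents by the number of points the
#' gate captures in that solvent's spectrum and reports the top three
#' with a nonzero count — the per-group "optimum 3 solvents". Groups
#' captured by no solvent are flagged `not_extracted`.
#'
#' @param dataset Preprocessed dataset tibble; blank rows ignored.
#' @param polygons List of gate polygons (group ids = list positions).
#' @param base [kendrick_base()] (default CH2).
#' @param n_top Number of solvents to report (default 3).
#' @param metric Passed to [rank_solvents()].
#' @return A tibble with one row per group: `group_id`, `top_solvents`
#'   (list-column of ordered labels, length <= `n_top`), `counts`
#'   (list-column of their scores) and `not_extracted`.
#' @export
top_solvents_per_group <- function(dataset, polygons,
                                   base = kendrick_base("CH2"),
                                   n_top = 3L,
                                   metric = c("count", "intensity")) {
  metric <- match.arg(metric)
  purrr::imap_dfr(polygons, function(poly, i) {
    rk <- rank_solvents(dataset, polygon = poly, base = base,
                        metric = metric)
    rk <- rk[rk$score > 0, , drop = FALSE]
    top <- utils::head(rk, n_top)
    tibble::tibble(
      group_id = if (is.character(i)) match(i, names(polygons))
                 else as.integer(i),
      top_solvents = list(top$solvent_label),
      counts = list(top$score),
      not_extracted = nrow(rk) == 0L
    )
  })
}

#' Organic/aqueous-ratio trend of a solvent ranking
#'
#' Descriptive report of how recovered peak counts relate to the
#' organic/aqueous volume ratio of the extraction solvent: the mean
#' count for mixtures with ratio >= 0.5 versus below 0.5, their
#' difference, and the Spearman rank correlation between count and
#' ratio. When every count is identical the correlation is undefined and
#' reported as 0 with `spearman_defined = FALSE`. No significance test
#' is attached; the report is descriptive.
#'
#' @param ranking A [rank_solvents()] tibble.
#' @return One-row tibble: `mean_count_high`, `mean_count_low`,
#'   `difference`, `spearman`, `spearman_defined`.
#' @export
ratio_trend <- function(ranking) {
  stopifnot(is.data.frame(ranking),
            all(c("organic_aqueous_ratio", "score") %in% names(ranking)))
  if (length(unique(ranking$organic_aqueous_ratio)) < 2L) {
    stop("ratio trend needs at least two distinct ratios", call. = FALSE)
  }
  hi <- ranking$score[ranking$organic_aqueous_ratio >= 0.5]
  lo <- ranking$score[ranking$organic_aqueous_ratio < 0.5]
  defined <- stats::sd(ranking$score) > 0
  rho <- if (defined) {
    suppressWarnings(stats::cor(ranking$score,
                                ranking$organic_aqueous_ratio,
                                method = "spearman"))
  } else 0
  tibble::tibble(
    mean_count_high = mean(hi), mean_count_low = mean(lo),
    difference = mean(hi) - mean(lo),
    spearman = rho, spearman_defined = defined
  )
}

.box_iou <- function(a, b) {
  ix <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[3], b[3]))
  inter <- ix * iy
  area <- function(r) (r[2] - r[1]) * (r[4] - r[3])
  un <- area(a) + area(b) - inter
  if (un <= 0) return(if (isTRUE(all.equal(a, b))) 1 else 0)
  inter / un
}

#' Match peak groups across two samples
#'
#' Pairs the groups of two characterization tables (same Kendrick base)
#' by the overlap of their (KM, KMD) bounding boxes: the
#' intersection-over-union of the boxes, matched greedily in descending
#' overlap, with pairs below `min_overlap` dissolved. Groups left
#' unmatched on either side are reported unique — the operation behind
#' "group present in the degraded lignin but not the non-degraded one".
#'
#' @param summary_a,summary_b [summarize_groups()] tibbles.
#' @param min_overlap Minimum IoU to accept a pair (default 0.3).
#' @return An object of class `"group_match"`: list with `pairs` (tibble
#'   `group_a`, `group_b`, `overlap`), `unique_to_a`, `unique_to_b`
#'   (integer group ids).
#' @export
match_groups <- function(summary_a, summary_b, min_overlap = 0.3) {
  boxes <- function(s) lapply(seq_len(nrow(s)), function(i)
    c(s$km_min[i], s$km_max[i], s$kmd_min[i], s$kmd_max[i]))
  ba <- boxes(summary_a); bb <- boxes(summary_b)
  if (length(ba) == 0L || length(bb) == 0L) {
    return(structure(
      list(pairs = tibble::tibble(group_a = integer(), group_b = integer(),
                                  overlap = numeric()),
           unique_to_a = summary_a$group_id,
           unique_to_b = summary_b$group_id,
           min_overlap = min_overlap),
      class = "group_match"))
  }
  sc <- outer(seq_along(ba), seq_along(bb),
              Vectorize(function(i, j) .box_iou(ba[[i]], bb[[j]])))
  pairs <- tibble::tibble(group_a = integer(), group_b = integer(),
                          overlap = numeric())
  free_a <- rep(TRUE, length(ba)); free_b <- rep(TRUE, length(bb))
  repeat {
    sc_live <- sc
    sc_live[!free_a, ] <- -Inf
    sc_live[, !free_b] <- -Inf
    best <- which(sc_live == max(sc_live), arr.ind = TRUE)
    if (nrow(best) == 0L || max(sc_live) < min_overlap) break
    i <- best[1, 1]; j <- best[1, 2]
    pairs <- dplyr::bind_rows(pairs, tibble::tibble(
      group_a = summary_a$group_id[i], group_b = summary_b$group_id[j],
      overlap = sc[i, j]))
    free_a[i] <- FALSE; free_b[j] <- FALSE
    if (!any(free_a) || !any(free_b)) break
  }
  structure(
    list(pairs = pairs,
         unique_to_a = summary_a$group_id[free_a],
         unique_to_b = summary_b$group_id[free_b],
         min_overlap = min_overlap),
    class = "group_match"
  )
}

#' @export
print.group_match <- function(x, ...) {
  cat("Group match (min IoU ", x$min_overlap, ")\n", sep = "")
  cat(nrow(x$pairs), "matched pair(s);",
      length(x$unique_to_a), "unique to A;",
      length(x$unique_to_b), "unique to B\n")
  if (nrow(x$pairs)) print(x$pairs)
  invisible(x)
}

#' Tidy a group match into its pair table
#'
#' @param x A `"group_match"` object.
#' @param ... Unused.
#' @return The `pairs` tibble, with unmatched groups appended as rows
#'   with `NA` partners and `overlap = NA`.
#' @export
#' @method tidy group_match
tidy.group_match <- function(x, ...) {
  dplyr::bind_rows(
    x$pairs,
    tibble::tibble(group_a = x$unique_to_a, group_b = NA_integer_,
                   overlap = NA_real_),
    tibble::tibble(group_a = NA_integer_, group_b = x$unique_to_b,
                   overlap = NA_real_)
  )
}

#' @rdname tidy.group_match
#' @export
#' @method glance group_match
glance.group_match <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    n_unique_a = length(x$unique_to_a),
    n_unique_b = length(x$unique_to_b),
    mean_overlap = if (nrow(x$pairs)) mean(x$pairs$overlap) else NA_real_,
    min_overlap_rule = x$min_overlap
  )
}
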