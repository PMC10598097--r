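# small construction helpers shared across test files

make_peaks <- function(mz, intensity = rep(1000, length(mz)),
                       rel = NA_real_) {
  tibble::tibble(mz = mz, intensity = intensity,
                 rel_intensity = rep(rel, length.out = length(mz)))
}

write_tmp_xy <- function(lines) {
  path <- withr::local_tempfile(fileext = ".xy",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

random_peaks <- function(n, mz_range = c(100, 1000),
                         int_range = c(10, 1e6)) {
  make_peaks(sort(runif(n, mz_range[1], mz_range[2])),
             runif(n, int_range[1], int_range[2]))
}

square_polygon <- function(km0, km1, kmd0, kmd1) {
  tibble::tibble(km = c(km0, km1, km1, km0),
                 kmd = c(kmd0, kmd0, kmd1, kmd1))
}

# memoised heavy artifacts shared between acceptance blocks
.accept_cache <- new.env(parent = emptyenv())

acceptance_dataset <- function(seed = 101) {
  key <- paste0("ds_", seed)
  if (is.null(.accept_cache[[key]])) {
    cfg <- synthetic_config()
    .accept_cache[[key]] <- simulate_dataset(cfg, seed = seed)
  }
  .accept_cache[[key]]
}

acceptance_assignments <- function(seed = 101) {
  key <- paste0("asg_", seed)
  if (is.null(.accept_cache[[key]])) {
    ds <- acceptance_dataset(seed)
    smp <- ds[!ds$is_blank, ]
    .accept_cache[[key]] <- purrr::map_dfr(seq_len(nrow(smp)), function(i) {
      a <- assign_formulas(smp$peaks[[i]], ion_mode = "negative")
      a$solvent_label <- smp$solvent_label[i]
      a
    })
  }
  .accept_cache[[key]]
}
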