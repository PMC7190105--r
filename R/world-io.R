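#' Read and write a synthetic world as a directory of CSV tables
#'
#' Serialises the five world tables (`cells.csv`, `responses.csv`,
#' `climate.csv`, `macro.csv`, `market_params.csv`) to a directory, and reads
#' them back. Units: areas in ha, yields in t fresh matter/ha, N inputs in
#' kg N/ha, soil-carbon deltas in t C/ha/yr, season lengths in days.
#' The generator config and seed are not serialised; a round-tripped world
#' carries the data only.
#'
#' @param world A `csa_world` from [generate_world()].
#' @param dir Directory path (created if needed).
#'
#' @return `write_world()` returns `dir` invisibly; `read_world()` returns a
#'   `csa_world`.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "csa_world"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("cells", "responses", "climate", "macro", "market_params")
  for (tb in tabs) {
    readr::write_csv(world[[tb]], file.path(dir, paste0(tb, ".csv")))
  }
  invisible(dir)
}

#' @rdname write_world
#' @export
read_world <- function(dir) {
  tabs <- c("cells", "responses", "climate", "macro", "market_params")
  out <- purrr::map(tabs, function(tb) {
    path <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(path)) {
      stopf("csascen_io_error", "world table missing: %s", path)
    }
    tb_df <- readr::read_csv(path, show_col_types = FALSE)
    if (tb == "responses") {
      # all-NA override columns must stay numeric
      tb_df <- dplyr::mutate(
        tb_df,
        dplyr::across(c("n_mineral_new", "n_manure_new"), as.numeric)
      )
    }
    tb_df
  })
  names(out) <- tabs
  out$config <- NULL
  out$seed <- NA_integer_
  structure(out, class = c("csa_world", "list"))
}
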