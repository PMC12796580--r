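#' Load a deterministic test fixture
#'
#' The package ships a registry of small, hand-computable fixtures (a
#' PSTH normalization worked example, interneuron and layer boundary
#' cases, a 2x2 repeated-measures table with hand-computed sums of
#' squares, a noise-free onset-step PSTH, a robust-outlier contaminant
#' set, Bonferroni arithmetic cases) that the test suite uses as
#' independent oracles. Fixtures live as plain data files under
#' `inst/extdata/fixtures` with a JSON manifest recording each one's
#' provenance and, for derived fixtures, the brute-force oracle that
#' produced the expected values.
#'
#' @param name registered fixture name; see [list_fixtures()]
#' @return list with `name`, `provenance`, `description`, `data` (the
#'   literal inputs), and `expected` where the fixture carries separate
#'   expected outputs
#' @export
build_fixture <- function(name) {
  root <- system.file("extdata", "fixtures", package = "whiskloop")
  manifest <- jsonlite::read_json(file.path(root, "manifest.json"),
                                  simplifyVector = FALSE)
  if (!name %in% names(manifest))
    stop(sprintf("unknown fixture '%s'; see list_fixtures()", name))
  entry <- manifest[[name]]
  read_any <- function(f) {
    path <- file.path(root, f)
    if (grepl("\\.json$", f)) jsonlite::read_json(path, simplifyVector = TRUE)
    else read.csv(path, stringsAsFactors = FALSE)
  }
  out <- list(name = name,
              provenance = entry$provenance,
              description = entry$description,
              oracle = entry$oracle,
              data = read_any(entry$file))
  if (!is.null(entry$expected_file))
    out$expected <- read_any(entry$expected_file)
  out
}

#' List the registered fixtures
#' @return character vector of fixture names
#' @export
list_fixtures <- function() {
  root <- system.file("extdata", "fixtures", package = "whiskloop")
  names(jsonlite::read_json(file.path(root, "manifest.json"),
                            simplifyVector = FALSE))
}
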