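# Seed registries for predefined dictionary keys and two-letter SSAM/MIAM
# markers. The full registries behind the language are external, extensible
# resources; these files are small editable seeds, and unknown entries
# produce warnings rather than errors.

.csm_registry_env <- new.env(parent = emptyenv())

csm_read_registry_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) return(character(0))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(parts, `[[`, "", 1L)
  vals <- vapply(parts, function(p) if (length(p) >= 2L) p[[2]] else "", "")
  stats::setNames(vals, keys)
}

#' Load annotation registries
#'
#' Loads the registries of predefined dictionary keys and of known SSAM
#' (state-and-shape) and MIAM (miscellaneous-interest) annotation markers.
#' By default the seed registries shipped with the package are used; a
#' directory of replacement files (`dict_keys.tsv`, `ssam_markers.tsv`,
#' `miam_markers.tsv`, tab-separated `entry<TAB>description` lines) can be
#' supplied instead.
#'
#' @param dir Directory containing registry files, or `NULL` for the
#'   packaged seeds.
#' @return A named list with character vectors `dict_keys`, `ssam`, `miam`
#'   (names are the registered entries, values their descriptions).
#' @export
csm_load_registries <- function(dir = NULL) {
  if (is.null(dir)) dir <- system.file("extdata", package = "curlysmiles")
  reg <- list(dict_keys = character(0), ssam = character(0), miam = character(0))
  files <- c(dict_keys = "dict_keys.tsv", ssam = "ssam_markers.tsv",
             miam = "miam_markers.tsv")
  for (nm in names(files)) {
    path <- file.path(dir, files[[nm]])
    if (file.exists(path)) reg[[nm]] <- csm_read_registry_file(path)
  }
  assign("registries", reg, envir = .csm_registry_env)
  invisible(reg)
}

csm_registries <- function() {
  if (!exists("registries", envir = .csm_registry_env)) csm_load_registries()
  get("registries", envir = .csm_registry_env)
}
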