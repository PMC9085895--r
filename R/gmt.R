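#' Read a GMT gene-set file
#'
#' GMT is the tab-separated format used for gene-set collections: one set per
#' line as `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors of gene identifiers.
#' @export
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' write_gmt(list(a = c("g1", "g2"), b = "g3"), f)
#' read_gmt(f)
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) abort("Malformed GMT line: fewer than two fields.")
    unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets))) warn("Duplicate gene-set names in GMT; keeping all.")
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors of gene identifiers.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("All gene sets must be named.")
  }
  descriptions <- descriptions %||% names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
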