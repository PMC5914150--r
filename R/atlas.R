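#' Region atlas
#'
#' An ordered set of region labels defining the nodes of every graph in an
#' analysis.  The order of the names fixes the node index used throughout the
#' package (column order of time-series files, row/column order of
#' connectivity matrices, bit order of selection masks).
#'
#' @param names Character vector of unique region labels, length >= 3.
#' @return An object of class `"region_atlas"`: a list with elements `names`
#'   and `d` (the region count).
#' @examples
#' atl <- region_atlas(c("Frontal_L", "Frontal_R", "Parietal_L", "Parietal_R"))
#' atl$d
#' @export
region_atlas <- function(names) {
  names <- as.character(names)
  if (length(names) < 3L)
    stop("an atlas needs at least 3 regions, got ", length(names))
  if (anyDuplicated(names))
    stop("duplicated region names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  structure(list(names = names, d = length(names)), class = "region_atlas")
}

#' Read a region atlas from a plain-text file
#'
#' One region name per line; line order defines node order.
#'
#' @param path Path to the atlas file.
#' @return A [region_atlas()].
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  nm <- readLines(path, warn = FALSE)
  nm <- trimws(nm)
  region_atlas(nm[nzchar(nm)])
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("Region atlas:", x$d, "regions\n")
  show <- utils::head(x$names, 6L)
  cat("  ", paste(show, collapse = ", "),
      if (x$d > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

as_atlas <- function(x) {
  if (inherits(x, "region_atlas")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) return(read_atlas(x))
  if (is.character(x)) return(region_atlas(x))
  stop("cannot interpret 'atlas': give a region_atlas, a character vector, ",
       "or a file path")
}
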