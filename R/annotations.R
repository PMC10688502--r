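#' Bundle of biological annotations
#'
#' Holds the four annotation sources used for biological weighting: GO term
#' assignments, protein complexes, subcellular localizations, and the
#' essential-protein gold standard. All maps may be partial; a protein
#' missing from a map simply has the empty set. Complexes with fewer than
#' two distinct members are dropped.
#'
#' @param go_terms named list: protein ID -> character vector of GO term IDs.
#' @param complexes list of character vectors, one protein complex each.
#' @param subcellular named list: protein ID -> character vector of
#'   compartment names.
#' @param essentials character vector of essential protein IDs.
#' @return An object of class `annotation_bundle`.
#' @export
annotation_bundle <- function(go_terms = list(), complexes = list(),
                              subcellular = list(), essentials = character()) {
  norm_setlist <- function(sl) {
    if (!length(sl)) return(structure(list(), names = character()))
    stopifnot(!is.null(names(sl)))
    lapply(sl, function(x) sort_ids(unique(as.character(x))))
  }
  complexes <- lapply(complexes, function(x) sort_ids(unique(as.character(x))))
  sizes <- vapply(complexes, length, integer(1L))
  n_drop <- sum(sizes < 2L)
  if (n_drop > 0L)
    message(sprintf("annotation_bundle: dropped %d complex(es) with < 2 members", n_drop))
  structure(
    list(go_terms = norm_setlist(go_terms),
         complexes = complexes[sizes >= 2L],
         subcellular = norm_setlist(subcellular),
         essentials = sort_ids(unique(as.character(essentials)))),
    class = "annotation_bundle"
  )
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat(sprintf(paste0("<annotation_bundle> %d proteins with GO terms, ",
                     "%d complexes, %d proteins with localizations, ",
                     "%d essential proteins\n"),
              length(x$go_terms), length(x$complexes),
              length(x$subcellular), length(x$essentials)))
  invisible(x)
}

# Read a two-column protein<TAB>label file into a named list of label sets.
read_pair_file <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           colClasses = "character", quote = "")
  if (ncol(tab) < 2L) stop("expected two tab-separated columns in ", path)
  ids <- tab[[1L]]
  split(tab[[2L]], factor(ids, levels = sort_ids(unique(ids))))
}

#' Read annotation files into a bundle
#'
#' Each file is optional (pass `NULL` to omit it); a missing component
#' yields the corresponding empty map with a warning. GO and subcellular
#' files are two-column protein/label TSVs, the complex file holds one
#' complex per line (tab- or space-separated member IDs), and the
#' essentials file one protein ID per line.
#'
#' @param go_path,complex_path,subcell_path,essential_path file paths or `NULL`.
#' @return An [annotation_bundle()].
#' @export
read_annotations <- function(go_path = NULL, complex_path = NULL,
                             subcell_path = NULL, essential_path = NULL) {
  available <- function(p) !is.null(p) && file.exists(p)
  if (!available(go_path) && !available(complex_path) &&
      !available(subcell_path) && !available(essential_path))
    stop("no annotation file available: all four inputs missing")
  miss <- function(what) warning(sprintf("read_annotations: no %s file; component left empty", what))

  go <- list()
  if (available(go_path)) go <- read_pair_file(go_path) else miss("GO annotation")

  complexes <- list()
  if (available(complex_path)) {
    lines <- readLines(complex_path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    complexes <- strsplit(lines, "[ \t]+")
  } else miss("protein complex")

  subcell <- list()
  if (available(subcell_path)) subcell <- read_pair_file(subcell_path) else miss("subcellular localization")

  essentials <- character()
  if (available(essential_path)) {
    essentials <- trimws(readLines(essential_path, warn = FALSE))
    essentials <- essentials[nzchar(essentials) & !startsWith(essentials, "#")]
  } else miss("essential protein")

  annotation_bundle(go_terms = go, complexes = complexes,
                    subcellular = subcell, essentials = essentials)
}
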