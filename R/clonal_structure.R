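#' Clonal structure of a tumor sample
#'
#' The number of subclones G and their fractions B, as estimated by an
#' external subclone caller. Fractions are normalized to sum to one and
#' sorted in descending order, so the primary clone is always first.
#'
#' @param B Numeric vector of positive clone fractions.
#' @return Object of class `clonal_structure` with fields `G` and `B`.
#' @examples
#' clonal_structure(c(0.707, 0.293))
#' @export
clonal_structure <- function(B) {
  B <- as.numeric(B)
  if (length(B) < 1) stop("at least one clone fraction required")
  if (anyNA(B) || any(B <= 0)) stop("clone fractions must be positive")
  s <- sum(B)
  if (abs(s - 1) > 0.05) {
    warning("clone fractions sum to ", format(s), "; normalizing to 1")
  }
  B <- sort(B / s, decreasing = TRUE)
  structure(list(G = length(B), B = B), class = "clonal_structure")
}

#' @export
print.clonal_structure <- function(x, ...) {
  cat("<clonal_structure> G=", x$G, " B=[",
      paste(format(x$B, digits = 4), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Read a clonal-structure file
#'
#' Accepts either JSON of the form `{"clones": [0.7, 0.3]}` or a TSV with
#' columns `clone_id<TAB>fraction` (header optional).
#'
#' @param path File path.
#' @return A [clonal_structure].
#' @export
read_clonal_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- trimws(readLines(path, n = 1L, warn = FALSE))
  if (length(first) == 1 && startsWith(first, "{")) {
    obj <- jsonlite::fromJSON(path)
    if (is.null(obj$clones)) stop("JSON clone file must contain a 'clones' array")
    return(clonal_structure(as.numeric(obj$clones)))
  }
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("clone TSV must have columns clone_id, fraction")
  fr <- suppressWarnings(as.numeric(tab[[2]]))
  if (is.na(fr[1]) && nrow(tab) > 1) {  # header row present
    fr <- fr[-1]
  }
  if (anyNA(fr)) stop("non-numeric clone fraction in ", path)
  clonal_structure(fr)
}
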