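#' Microsatellite length spectrum
#'
#' A length spectrum is the integer histogram of repeat lengths observed
#' across the sequencing reads covering one microsatellite locus in one
#' sample. Lengths are counted in repeat units (not base pairs).
#'
#' @param locus_id Character scalar naming the locus.
#' @param lengths Integer vector of repeat lengths (each >= 0), or a named
#'   count vector whose names are the lengths (then `counts` is omitted).
#' @param counts Non-negative integer vector of read counts, parallel to
#'   `lengths`.
#'
#' @return An object of class `length_spectrum` with fields `locus_id`,
#'   `lengths` (sorted, unique, zero-count entries dropped), `counts` and
#'   `n` (total reads).
#' @examples
#' sp <- length_spectrum("locusA", c(12L, 13L), c(5, 10))
#' sp$n  # 15
#' @export
length_spectrum <- function(locus_id, lengths, counts = NULL) {
  if (is.null(counts)) {
    counts <- unname(lengths)
    lengths <- as.numeric(names(lengths))
  }
  if (length(lengths) != length(counts)) {
    stop("lengths and counts must have equal length")
  }
  lengths <- as.numeric(lengths)
  counts <- as.numeric(counts)
  if (length(lengths) > 0) {
    if (anyNA(lengths) || anyNA(counts)) stop("NA in spectrum for ", locus_id)
    if (any(lengths < 0) || any(lengths != round(lengths))) {
      stop("repeat lengths must be non-negative integers (locus ", locus_id, ")")
    }
    if (any(counts < 0)) {
      stop("negative read count in spectrum for locus ", locus_id)
    }
    if (any(counts != round(counts))) {
      stop("read counts must be integers (locus ", locus_id, ")")
    }
  }
  keep <- counts > 0
  lengths <- lengths[keep]
  counts <- counts[keep]
  o <- order(lengths)
  lengths <- as.integer(lengths[o])
  counts <- counts[o]
  if (anyDuplicated(lengths)) {
    counts <- as.numeric(tapply(counts, lengths, sum))
    lengths <- sort(unique(lengths))
  }
  structure(
    list(locus_id = as.character(locus_id), lengths = lengths,
         counts = counts, n = sum(counts)),
    class = "length_spectrum"
  )
}

#' @export
print.length_spectrum <- function(x, ...) {
  cat("<length_spectrum>", x$locus_id, " n=", x$n, "\n", sep = "")
  if (x$n > 0) {
    cat(paste0(x$lengths, ":", x$counts, collapse = " "), "\n")
  }
  invisible(x)
}

#' Expand a spectrum to the per-read length list
#'
#' Inverse of histogramming: returns the multiset of read lengths `L_n`
#' in deterministic (ascending) order.
#'
#' @param spec A [length_spectrum].
#' @return Integer vector of length `spec$n`.
#' @export
expand_reads <- function(spec) {
  stopifnot(inherits(spec, "length_spectrum"))
  if (spec$n < 1) stop("empty spectrum for locus ", spec$locus_id)
  rep(spec$lengths, times = spec$counts)
}

#' Weighted mean and standard deviation of a spectrum
#'
#' The standard deviation uses the population (1/N) normalization, i.e. the
#' Gaussian maximum-likelihood estimate on the histogram.
#'
#' @param spec A [length_spectrum].
#' @return List with `mu`, `sigma` and `n`.
#' @export
spectrum_stats <- function(spec) {
  stopifnot(inherits(spec, "length_spectrum"))
  if (spec$n < 1) return(list(mu = NA_real_, sigma = NA_real_, n = 0))
  mu <- sum(spec$lengths * spec$counts) / spec$n
  sigma <- sqrt(sum(spec$counts * (spec$lengths - mu)^2) / spec$n)
  list(mu = mu, sigma = sigma, n = spec$n)
}

.parse_pairs <- function(field, locus_id, line_no) {
  field <- trimws(field)
  if (field == "" || field == ".") {
    return(length_spectrum(locus_id, integer(0), numeric(0)))
  }
  parts <- strsplit(field, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) {
    stop("malformed spectrum field at line ", line_no, ": '", field, "'")
  }
  lens <- suppressWarnings(as.numeric(vapply(kv, `[[`, "", 1L)))
  cnts <- suppressWarnings(as.numeric(vapply(kv, `[[`, "", 2L)))
  if (anyNA(lens) || anyNA(cnts)) {
    stop("non-numeric length:count pair at line ", line_no)
  }
  length_spectrum(locus_id, lens, cnts)
}

#' Read a spectrum table
#'
#' Two on-disk dialects are supported:
#' \describe{
#'   \item{`simple_tsv`}{the native format: a header line
#'     `locus_id<TAB>sample<TAB>spectrum` followed by one row per locus and
#'     sample, where `spectrum` is a comma-separated list of `length:count`
#'     pairs (`.` or empty for a zero-read locus).}
#'   \item{`msisensor_dis`}{per-locus distribution blocks as emitted by
#'     read-level MSI scanners: a site header line whose first two
#'     whitespace-separated fields are chromosome and position (trailing
#'     columns tolerated), followed by `N:` and/or `T:` lines of positional
#'     counts, the j-th number being the read count for repeat length j.
#'     `N`/`T` map to sample tags `normal`/`tumor`; the locus id is
#'     `chrom_position`.}
#' }
#'
#' @param path File path.
#' @param dialect `"simple_tsv"` (default) or `"msisensor_dis"`.
#' @return A list of records, each `list(sample = <tag>, spectrum =
#'   <length_spectrum>)`.
#' @seealso [spectra_for_sample()], [write_spectrum_table()]
#' @export
read_spectrum_table <- function(path, dialect = c("simple_tsv", "msisensor_dis")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "simple_tsv") .read_simple_tsv(lines) else .read_msisensor_dis(lines)
}

.read_simple_tsv <- function(lines) {
  records <- list()
  seen <- character(0)
  start <- 1L
  if (length(lines) >= 1 && grepl("^locus_id\t", lines[[1]])) start <- 2L
  for (i in seq_along(lines)) {
    if (i < start) next
    ln <- lines[[i]]
    if (trimws(ln) == "") next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("malformed line ", i, ": expected 3 tab-separated fields")
    }
    locus <- fields[[1]]
    tag <- fields[[2]]
    key <- paste(locus, tag, sep = "\r")
    if (key %in% seen) stop("duplicate locus/sample pair at line ", i, ": ", locus)
    seen <- c(seen, key)
    records[[length(records) + 1L]] <-
      list(sample = tag, spectrum = .parse_pairs(fields[[3]], locus, i))
  }
  records
}

.read_msisensor_dis <- function(lines) {
  records <- list()
  current <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (grepl("^[NT][[:space:]]*:", ln)) {
      if (is.null(current)) stop("distribution line before any site header at line ", i)
      tag <- if (substr(ln, 1, 1) == "N") "normal" else "tumor"
      body <- sub("^[NT][[:space:]]*:", "", ln)
      cnts <- suppressWarnings(as.numeric(strsplit(trimws(body), "[[:space:]]+")[[1]]))
      if (anyNA(cnts)) stop("non-numeric count in distribution line ", i)
      if (any(cnts < 0)) stop("negative count in distribution line ", i)
      lens <- seq_along(cnts)
      records[[length(records) + 1L]] <-
        list(sample = tag, spectrum = length_spectrum(current, lens, cnts))
    } else {
      fields <- strsplit(ln, "[[:space:]]+")[[1]]
      if (length(fields) < 2) stop("malformed site header at line ", i)
      current <- paste(fields[[1]], fields[[2]], sep = "_")
    }
  }
  records
}

#' Write spectra in the native TSV dialect
#'
#' @param records List of `list(sample =, spectrum =)` records as returned by
#'   [read_spectrum_table()].
#' @param path Output file path.
#' @export
write_spectrum_table <- function(records, path) {
  rows <- vapply(records, function(rec) {
    sp <- rec$spectrum
    field <- if (sp$n == 0) "." else paste0(sp$lengths, ":", sp$counts, collapse = ",")
    paste(sp$locus_id, rec$sample, field, sep = "\t")
  }, "")
  writeLines(c("locus_id\tsample\tspectrum", rows), path)
  invisible(NULL)
}

#' Extract the spectra of one sample tag as a named list
#'
#' @param records Record list from [read_spectrum_table()].
#' @param tag Sample tag to keep (e.g. `"tumor"`).
#' @return Named list of [length_spectrum] keyed by locus id.
#' @export
spectra_for_sample <- function(records, tag) {
  keep <- vapply(records, function(r) identical(r$sample, tag), TRUE)
  out <- lapply(records[keep], `[[`, "spectrum")
  names(out) <- vapply(out, `[[`, "", "locus_id")
  out
}

#' Wrap a list of spectra as sample records
#'
#' @param spectra List of [length_spectrum].
#' @param tag Sample tag to attach to each.
#' @return Record list usable by [write_spectrum_table()].
#' @export
as_records <- function(spectra, tag) {
  lapply(spectra, function(sp) list(sample = tag, spectrum = sp))
}
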