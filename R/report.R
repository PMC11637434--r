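#' Write a sample report as TSV
#'
#' One data row per (locus, clone) mirroring a per-site call table: locus,
#' clone, component, fitted mu/sigma/pi, normal mu/sigma, test statistic,
#' p-value and MSI/MSS status, with numeric fields rounded to 4 decimals.
#' A comment footer carries the sample-level score and verdict. The file
#' round-trips through [read_report()].
#'
#' @param report A `sample_report` from [call_sample()].
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "sample_report"))
  cols <- c("locus_id", "clone", "component", "mu", "sigma", "pi",
            "normal_mu", "normal_sigma", "statistic", "p_value", "status")
  frames <- lapply(report$locus_calls, function(lc) lc$clone_calls)
  frames <- frames[!vapply(frames, is.null, TRUE)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (length(frames) > 0) {
    tab <- do.call(rbind, frames)[, cols]
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], function(x) sprintf("%.4f", x))
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, na = "NA")
  }
  writeLines(c(
    sprintf("#sample_score=%.4f", report$sample_score),
    sprintf("#sample_status=%s", report$sample_status),
    sprintf("#n_loci=%d", report$n_loci)
  ), con)
  invisible(NULL)
}

#' Read a sample report written by [write_report()]
#'
#' @param path File path.
#' @return List with `calls` (data frame of clone rows), `sample_score`,
#'   `sample_status` and `n_loci`.
#' @export
read_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  footer <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  calls <- utils::read.delim(text = paste(body, collapse = "\n"),
                             stringsAsFactors = FALSE)
  get <- function(key) {
    ln <- grep(paste0("^#", key, "="), footer, value = TRUE)
    if (length(ln) == 0) NA_character_ else sub(paste0("^#", key, "="), "", ln[1])
  }
  list(calls = calls,
       sample_score = as.numeric(get("sample_score")),
       sample_status = get("sample_status"),
       n_loci = as.integer(get("n_loci")))
}
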