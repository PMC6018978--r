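#' Read / write titration and saturation series as TSV
#'
#' Titration files carry the header columns `lane`, `applied_protein`,
#' `frac_free`, `frac_one_dimer`, `frac_two_dimers`; saturation files carry
#' `free_probe`, `bound`. Comment lines starting with `#` are ignored on
#' read and used for metadata on write.
#'
#' @param path file path.
#' @param series series object to write.
#' @name series_io
NULL

#' @rdname series_io
#' @export
read_titration_tsv <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", check.names = TRUE)
  need <- c("applied_protein", "frac_free", "frac_one_dimer",
            "frac_two_dimers")
  if (!all(need %in% names(d))) {
    stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "),
         call. = FALSE)
  }
  titration_series(d$applied_protein, d$frac_free, d$frac_one_dimer,
                   d$frac_two_dimers,
                   label = sub("[.]tsv$", "", basename(path)))
}

#' @rdname series_io
#' @export
write_titration_tsv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# titration series '%s', probe '%s'",
                     attr(series, "label"), attr(series, "probe_id")), con)
  utils::write.table(as.data.frame(series), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname series_io
#' @export
read_saturation_tsv <- function(path) {
  d <- utils::read.delim(path, comment.char = "#")
  if (!all(c("free_probe", "bound") %in% names(d))) {
    stop("saturation TSV needs columns free_probe, bound", call. = FALSE)
  }
  saturation_series(d$free_probe, d$bound,
                    label = sub("[.]tsv$", "", basename(path)))
}

#' @rdname series_io
#' @export
write_saturation_tsv <- function(series, path) {
  stopifnot(inherits(series, "saturation_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# saturation series '%s'", attr(series, "label")), con)
  utils::write.table(as.data.frame(series), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fit as key-value TSV plus JSON diagnostics
#'
#' @param fit a `cooperative_fit` or `saturation_fit`.
#' @param path output TSV path; a sibling `<path>.json` carries the full
#'   diagnostics blob.
#' @return invisibly, the TSV path.
#' @export
write_fit_tsv <- function(fit, path) {
  stopifnot(inherits(fit, c("cooperative_fit", "saturation_fit")))
  keep <- vapply(fit, function(v) is.atomic(v) && length(v) == 1, logical(1))
  kv <- data.frame(key = names(fit)[keep],
                   value = vapply(fit[keep], as.character, character(1)))
  utils::write.table(kv, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(fit[keep], paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
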