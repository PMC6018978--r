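#' DNA probe record
#'
#' @param id probe identifier.
#' @param sequence DNA string (A/C/G/T only).
#' @param description free text.
#' @return object of class `probe_record`.
#' @export
probe_record <- function(id, sequence, description = "") {
  sequence <- toupper(gsub("\\s", "", sequence))
  if (grepl("[^ACGT]", sequence)) {
    stop("probe sequence must contain only A/C/G/T", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, description = description),
            class = "probe_record")
}

#' @export
print.probe_record <- function(x, ...) {
  cat(sprintf("probe '%s' (%d nt): %s\n", x$id, nchar(x$sequence),
              x$description))
  invisible(x)
}

#' Bundled EMSA probe fixtures
#'
#' The two DNA probes used for the binding assays, stored 5'->3':
#' `"two_carg"`, the 151-nt probe with two CArG-boxes 63 bp apart (six
#' helical turns), used for cooperative-binding titrations; and
#' `"one_carg"`, the 51-nt probe with a single central CArG-box, used for
#' saturation assays.
#'
#' @param which `"two_carg"` or `"one_carg"`.
#' @return a [probe_record()].
#' @export
load_probe <- function(which = c("two_carg", "one_carg")) {
  which <- match.arg(which)
  f <- c(two_carg = "probe_2carg.fa", one_carg = "probe_1carg.fa")[[which]]
  dna <- Biostrings::readDNAStringSet(
    system.file("extdata", f, package = "quartetbind", mustWork = TRUE))
  nm <- strsplit(names(dna)[1], "\\s+")[[1]]
  probe_record(nm[1], as.character(dna[[1]]),
               description = sub("^\\S+\\s*", "", names(dna)[1]))
}

#' The CArG-box motif and consensus
#'
#' The exact CArG-box used on the probes (from the AGAMOUS regulatory
#' intron) and the serum-response-element-type consensus `CC(A/T)6GG`
#' written with IUPAC codes.
#' @name carg
NULL

#' @rdname carg
#' @export
CARG_MOTIF <- "CCAAATAAGG"

#' @rdname carg
#' @export
CARG_CONSENSUS <- "CCWWWWWWGG"

hits_frame <- function(starts0, width, strand, probe_seq) {
  matched <- vapply(starts0, function(s) {
    substr(probe_seq, s + 1L, s + width)
  }, character(1))
  data.frame(start = as.integer(starts0), end = as.integer(starts0 + width),
             strand = rep(strand, length(starts0)), matched = matched,
             stringsAsFactors = FALSE)
}

scan_one <- function(probe, pattern, fixed) {
  hits <- Biostrings::matchPattern(pattern,
                                   Biostrings::DNAString(probe$sequence),
                                   fixed = fixed)
  Biostrings::start(hits) - 1L
}

#' Exact motif scan of a probe
#'
#' All exact occurrences of `motif` on the probe, 0-based half-open
#' coordinates on the stored (plus) strand, sorted by start. With
#' `both_strands`, occurrences of the motif on the reverse complement are
#' reported on the minus strand at their plus-strand coordinates.
#'
#' @param probe a [probe_record()].
#' @param motif DNA string (A/C/G/T).
#' @param both_strands also scan the reverse complement (default FALSE).
#' @return data.frame of hits: `probe_id`, `start`, `end` (0-based
#'   half-open), `strand`, `matched` (the plus-strand slice).
#' @export
scan_exact <- function(probe, motif = CARG_MOTIF, both_strands = FALSE) {
  stopifnot(inherits(probe, "probe_record"))
  motif <- toupper(motif)
  if (!nzchar(motif) || grepl("[^ACGT]", motif)) {
    stop("motif must be non-empty A/C/G/T", call. = FALSE)
  }
  w <- nchar(motif)
  out <- hits_frame(scan_one(probe, motif, fixed = TRUE), w, "+",
                    probe$sequence)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(probe$sequence)))
    rc_starts <- scan_one(probe_record(probe$id, rc), motif, fixed = TRUE)
    # map to plus-strand coordinates
    plus_starts <- nchar(probe$sequence) - rc_starts - w
    out <- rbind(out, hits_frame(plus_starts, w, "-", probe$sequence))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  cbind(probe_id = rep(probe$id, nrow(out)), out)
}

#' Consensus CArG-box scan
#'
#' Matches the degenerate consensus (IUPAC codes, default `CCWWWWWWGG`,
#' i.e. CC + six A/T + GG) against the probe. Every exact
#' [CARG_MOTIF] occurrence is necessarily also a consensus hit.
#'
#' @param probe a [probe_record()].
#' @param pattern IUPAC consensus (default [CARG_CONSENSUS]).
#' @param both_strands also scan the reverse complement (default FALSE).
#' @return hits data.frame as in [scan_exact()].
#' @export
scan_consensus <- function(probe, pattern = CARG_CONSENSUS,
                           both_strands = FALSE) {
  stopifnot(inherits(probe, "probe_record"))
  pattern <- toupper(pattern)
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  if (!nzchar(pattern) ||
      !all(strsplit(pattern, "")[[1]] %in% iupac)) {
    stop("pattern must consist of IUPAC nucleotide codes", call. = FALSE)
  }
  w <- nchar(pattern)
  out <- hits_frame(scan_one(probe, pattern, fixed = FALSE), w, "+",
                    probe$sequence)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(probe$sequence)))
    rc_starts <- scan_one(probe_record(probe$id, rc), pattern, fixed = FALSE)
    plus_starts <- nchar(probe$sequence) - rc_starts - w
    out <- rbind(out, hits_frame(plus_starts, w, "-", probe$sequence))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  cbind(probe_id = rep(probe$id, nrow(out)), out)
}

#' Start-to-start spacing of two motif hits
#'
#' For equal-length motifs, start-to-start equals center-to-center; 63 bp
#' at 10.5 bp per helical turn is six turns, placing the two boxes on the
#' same face of the double helix.
#'
#' @param hits hits data.frame with exactly 2 rows on the same strand.
#' @param bp_per_turn helical periodicity (default 10.5 bp).
#' @return list with `bp` (integer start-to-start distance) and `turns`.
#' @export
spacing <- function(hits, bp_per_turn = 10.5) {
  if (!is.data.frame(hits) || nrow(hits) != 2) {
    stop("spacing requires exactly 2 hits", call. = FALSE)
  }
  if (length(unique(hits$strand)) != 1) {
    stop("spacing requires both hits on the same strand", call. = FALSE)
  }
  bp <- abs(diff(sort(hits$start)))
  list(bp = as.integer(bp), turns = bp / bp_per_turn)
}

#' Write motif hits as BED-like TSV
#'
#' Coordinates are 0-based half-open (BED convention); a header comment
#' states this and the 1-based inclusive equivalent.
#'
#' @param hits hits data.frame from [scan_exact()] / [scan_consensus()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_hits_tsv <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# motif hits; start/end are 0-based half-open (BED convention);",
    "# the 1-based inclusive interval is [start+1, end]"), con)
  utils::write.table(hits, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
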