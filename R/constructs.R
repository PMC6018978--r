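#' Parse a substitution construct name
#'
#' Construct names are hyphen-joined tokens of the form
#' `<FromAA><Position><ToAA>` in 1-based full-protein coordinates, e.g.
#' `"L164P"` or the double mutant `"E161L-N168L"`.
#'
#' @param text construct name.
#' @return object of class `substitution_spec`: a data.frame with columns
#'   `position`, `from`, `to`, ordered by position.
#' @export
parse_spec <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(text)) {
    stop("construct name must be a single non-empty string", call. = FALSE)
  }
  tokens <- strsplit(text, "-", fixed = TRUE)[[1]]
  m <- regmatches(tokens, regexec("^([A-Z])([0-9]+)([A-Z])$", tokens))
  bad <- lengths(m) != 4
  if (any(bad)) {
    stop("malformed token(s): ", paste(tokens[bad], collapse = ", "),
         call. = FALSE)
  }
  spec <- data.frame(
    position = as.integer(vapply(m, `[`, character(1), 3)),
    from = vapply(m, `[`, character(1), 2),
    to = vapply(m, `[`, character(1), 4))
  aa_ok <- spec$from %in% AA_CANONICAL & spec$to %in% AA_CANONICAL
  if (!all(aa_ok)) {
    stop("non-canonical residue in token(s): ",
         paste(tokens[!aa_ok], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(spec$position)) {
    stop("duplicate position in construct: ", text, call. = FALSE)
  }
  if (any(spec$from == spec$to)) {
    stop("substitution with identical source and target residue: ", text,
         call. = FALSE)
  }
  spec <- spec[order(spec$position), , drop = FALSE]
  rownames(spec) <- NULL
  structure(spec, class = c("substitution_spec", "data.frame"))
}

#' Format a substitution spec back to its construct name
#'
#' Round-trips with [parse_spec()].
#'
#' @param spec a `substitution_spec`.
#' @return the hyphen-joined construct name.
#' @export
format_spec <- function(spec) {
  stopifnot(inherits(spec, "substitution_spec"))
  paste(sprintf("%s%d%s", spec$from, spec$position, spec$to), collapse = "-")
}

#' Invert a substitution spec
#'
#' @param spec a `substitution_spec`.
#' @return the spec with `from` and `to` swapped; applying it after the
#'   original restores the starting sequence.
#' @export
invert_spec <- function(spec) {
  stopifnot(inherits(spec, "substitution_spec"))
  out <- data.frame(position = spec$position, from = spec$to, to = spec$from)
  structure(out, class = c("substitution_spec", "data.frame"))
}

#' Apply substitutions to a protein sequence
#'
#' In-silico site-directed mutagenesis: each `from` residue must match the
#' sequence at its 1-based position, otherwise a coordinate-validation
#' error reports the position, the expected and the found residue.
#'
#' @param sequence residue string (full-protein coordinates).
#' @param spec a [parse_spec()] result or construct name string.
#' @return the mutated sequence, same length as the input.
#' @export
apply_spec <- function(sequence, spec) {
  if (is.character(spec)) spec <- parse_spec(spec)
  stopifnot(inherits(spec, "substitution_spec"),
            is.character(sequence), length(sequence) == 1)
  res <- strsplit(sequence, "")[[1]]
  if (any(spec$position > length(res))) {
    stop("position beyond sequence length ", length(res), call. = FALSE)
  }
  found <- res[spec$position]
  bad <- found != spec$from
  if (any(bad)) {
    stop(paste(sprintf(
      "position %d: expected %s, found %s",
      spec$position[bad], spec$from[bad], found[bad]), collapse = "; "),
      call. = FALSE)
  }
  res[spec$position] <- spec$to
  paste(res, collapse = "")
}

#' Chimera (domain swap) specification
#'
#' @param host_region,donor_region 1-based inclusive `(start, end)` pairs
#'   delimiting the replaced host region and the donor region inserted in
#'   its place.
#' @return object of class `chimera_spec`.
#' @export
chimera_spec <- function(host_region, donor_region = host_region) {
  chk <- function(r, nm) {
    if (length(r) != 2 || any(r < 1) || r[1] > r[2]) {
      stop("`", nm, "` must be (start, end) with 1 <= start <= end",
           call. = FALSE)
    }
    as.integer(r)
  }
  structure(list(host_region = chk(host_region, "host_region"),
                 donor_region = chk(donor_region, "donor_region")),
            class = "chimera_spec")
}

#' Build a chimeric protein by domain substitution
#'
#' In-silico analogue of megaprimer domain-swap mutagenesis: the host
#' region is excised and the donor region inserted in its place, e.g.
#' replacing the K3 subdomain (tetramerization interface, residues 150-181)
#' of a SEP3-like host with the homologous region of an AP3-like donor.
#'
#' @param host,donor residue strings.
#' @param spec a [chimera_spec()].
#' @return the chimeric sequence; its length is
#'   `nchar(host) - host span + donor span`.
#' @export
make_chimera <- function(host, donor, spec = chimera_spec(c(150L, 181L))) {
  stopifnot(inherits(spec, "chimera_spec"))
  hr <- spec$host_region
  dr <- spec$donor_region
  if (hr[2] > nchar(host)) {
    stop("host_region exceeds host length ", nchar(host), call. = FALSE)
  }
  if (dr[2] > nchar(donor)) {
    stop("donor_region exceeds donor length ", nchar(donor), call. = FALSE)
  }
  paste0(substr(host, 1, hr[1] - 1L),
         substr(donor, dr[1], dr[2]),
         substr(host, hr[2] + 1L, nchar(host)))
}

#' Read a single protein sequence from FASTA
#'
#' @param path FASTA file with one (or more; the first is taken) sequence.
#' @return residue string.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("no sequences in ", path, call. = FALSE)
  as.character(aa[[1]])
}

#' Bundled synthetic reference proteins
#'
#' Synthetic stand-ins (not natural sequences) that carry the documented
#' residues at their published coordinates: a SEP3-like reference (S94, the
#' 12 interaction leucines, L145, M150, E161, N168, G178), an AMtrAGL9-like
#' reference (I141, L160) and an AP3-like donor (T157, Q164) aligned to the
#' SEP3 coordinates.
#'
#' @param which `"sep3"`, `"amtragl9"` or `"ap3"`.
#' @return residue string.
#' @export
reference_protein <- function(which = c("sep3", "amtragl9", "ap3")) {
  which <- match.arg(which)
  f <- c(sep3 = "sep3_synthetic.fa", amtragl9 = "amtragl9_synthetic.fa",
         ap3 = "ap3_synthetic.fa")[[which]]
  read_protein_fasta(
    system.file("extdata", f, package = "quartetbind", mustWork = TRUE))
}
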