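#' Aligned protein family with subfamily labels
#'
#' Container for gap-aware aligned K-domain sequences. Rows are aligned
#' residue strings of equal length over the 20 canonical amino acids plus
#' the gap character `-` and the unknown-residue code `X`. An optional
#' `column_map` translates alignment columns to SEP3 full-protein positions.
#'
#' @param ids sequence identifiers.
#' @param rows aligned residue strings, all the same length.
#' @param subfamily one label per sequence (recycled if length 1).
#' @param column_map optional integer vector, one SEP3 position per column.
#' @return object of class `aligned_family`.
#' @export
aligned_family <- function(ids, rows, subfamily = "unassigned",
                           column_map = NULL) {
  stopifnot(length(ids) == length(rows))
  if (length(rows) == 0) stop("empty family", call. = FALSE)
  rows <- toupper(rows)
  w <- unique(nchar(rows))
  if (length(w) != 1) stop("rows must have equal length", call. = FALSE)
  bad <- grepl(paste0("[^", paste(AA_CANONICAL, collapse = ""), "X-]"), rows)
  if (any(bad)) {
    stop("invalid residue characters in sequence(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  subfamily <- rep_len(subfamily, length(rows))
  if (!is.null(column_map)) {
    column_map <- as.integer(column_map)
    if (length(column_map) != w) {
      stop("column_map length must equal alignment width", call. = FALSE)
    }
  }
  structure(list(ids = as.character(ids), rows = rows,
                 subfamily = as.character(subfamily),
                 column_map = column_map, width = w),
            class = "aligned_family")
}

#' @export
print.aligned_family <- function(x, ...) {
  cat(sprintf("aligned_family: %d sequences x %d columns; subfamilies: %s\n",
              length(x$rows), x$width,
              paste(unique(x$subfamily), collapse = ", ")))
  invisible(x)
}

#' @export
length.aligned_family <- function(x) length(x$rows)

# alignment as a character matrix (sequences x columns)
family_matrix <- function(family) {
  do.call(rbind, strsplit(family$rows, ""))
}

#' Read / write an aligned family as FASTA plus a label sidecar
#'
#' The FASTA holds the aligned residues; the sidecar TSV has columns `id`
#' and `subfamily`. On read, sequences without a sidecar entry get the
#' label `"unassigned"`.
#'
#' @param fasta path to an aligned FASTA file.
#' @param labels optional path to the label TSV.
#' @param family an `aligned_family` to write.
#' @return an [aligned_family()] (read) or the FASTA path, invisibly (write).
#' @name family_io
NULL

#' @rdname family_io
#' @export
read_family_fasta <- function(fasta, labels = NULL) {
  aa <- Biostrings::readAAStringSet(fasta)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1)
  rows <- unname(as.character(aa))
  sub <- rep("unassigned", length(ids))
  if (!is.null(labels)) {
    lab <- utils::read.delim(labels, comment.char = "#")
    if (!all(c("id", "subfamily") %in% names(lab))) {
      stop("label TSV needs columns id, subfamily", call. = FALSE)
    }
    missing_ids <- setdiff(lab$id, ids)
    if (length(missing_ids)) {
      stop("label ids not present in FASTA: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    sub[match(lab$id, ids)] <- lab$subfamily
  }
  aligned_family(ids, rows, subfamily = sub)
}

#' @rdname family_io
#' @export
write_family_fasta <- function(family, fasta, labels = NULL) {
  stopifnot(inherits(family, "aligned_family"))
  aa <- Biostrings::AAStringSet(stats::setNames(family$rows, family$ids))
  Biostrings::writeXStringSet(aa, fasta)
  if (!is.null(labels)) {
    utils::write.table(
      data.frame(id = family$ids, subfamily = family$subfamily),
      labels, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(fasta)
}

#' Read a substitution matrix in NCBI text format
#'
#' @param path path to a whitespace-delimited matrix file with `#` comment
#'   lines and residue row/column labels (the format BLAST distributes).
#' @return integer matrix with residue dimnames.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  rn <- vapply(body, `[`, character(1), 1)
  m <- t(vapply(body, function(x) as.numeric(x[-1]),
                numeric(length(header))))
  dimnames(m) <- list(rn, header)
  m
}

#' The BLOSUM40 substitution matrix
#'
#' BLOSUM40 is appropriate here because the K-domains being compared share
#' roughly 40% identity on average.
#'
#' @return the standard NCBI BLOSUM40 matrix (24 x 24, including B/Z/X/*).
#' @export
blosum40 <- function() {
  read_substitution_matrix(
    system.file("extdata", "BLOSUM40.txt", package = "quartetbind",
                mustWork = TRUE))
}

#' Normalized similarity of one alignment column
#'
#' Every unordered pair of usable residues (gaps and `X` excluded) is scored
#' with the substitution matrix normalized by row maxima:
#' \deqn{s(a,b) = \tfrac12\left(\frac{B(a,b)}{\max_x B(a,x)} +
#'   \frac{B(a,b)}{\max_x B(b,x)}\right)}
#' and the column score is the mean over pairs. Row maxima are taken over
#' the 20 canonical residues; for BLOSUM-family matrices they sit on the
#' diagonal, so a column of identical residues scores exactly 1. Negative
#' normalized scores are retained (flooring them would bias column
#' comparisons).
#'
#' @param column character vector of single residues (one per sequence).
#' @param matrix substitution matrix (default [blosum40()]).
#' @param normalization `"symmetric"` (default; the mean of both one-sided
#'   normalizations), `"first"` or `"second"` for the one-sided variants.
#' @return mean pair score (<= 1 for diagonal-dominant matrices), or `NA`
#'   when fewer than 2 usable residues remain.
#' @export
column_similarity <- function(column, matrix = blosum40(),
                              normalization = c("symmetric", "first",
                                                "second")) {
  normalization <- match.arg(normalization)
  res <- column[column %in% AA_CANONICAL]
  if (length(res) < 2) return(NA_real_)
  rowmax <- apply(matrix[AA_CANONICAL, AA_CANONICAL], 1, max)
  idx <- utils::combn(length(res), 2)
  a <- res[idx[1, ]]
  b <- res[idx[2, ]]
  s_ab <- matrix[cbind(a, b)]
  s <- switch(normalization,
    symmetric = 0.5 * (s_ab / rowmax[a] + s_ab / rowmax[b]),
    first = s_ab / rowmax[a],
    second = s_ab / rowmax[b])
  mean(s)
}

#' Per-column mean relative similarity profile
#'
#' Applies [column_similarity()] to every alignment column of a family.
#' Columns with fewer than two usable (non-gap, non-X) residues are flagged
#' missing rather than raising an error.
#'
#' @param family an [aligned_family()] with >= 2 sequences.
#' @param matrix substitution matrix (default [blosum40()]).
#' @param normalization passed to [column_similarity()].
#' @return data.frame of class `similarity_profile` with columns `column`,
#'   `position` (from the family's `column_map`, else the column index),
#'   `similarity` and `n_pairs`.
#' @export
similarity_profile <- function(family, matrix = blosum40(),
                               normalization = "symmetric") {
  stopifnot(inherits(family, "aligned_family"))
  if (length(family) < 2) {
    stop("similarity profile needs at least 2 sequences", call. = FALSE)
  }
  m <- family_matrix(family)
  sim <- numeric(family$width)
  np <- integer(family$width)
  for (j in seq_len(family$width)) {
    col <- m[, j]
    n_use <- sum(col %in% AA_CANONICAL)
    np[j] <- if (n_use >= 2) as.integer(choose(n_use, 2)) else 0L
    sim[j] <- column_similarity(col, matrix, normalization)
  }
  pos <- if (is.null(family$column_map)) seq_len(family$width) else
    family$column_map
  structure(data.frame(column = seq_len(family$width), position = pos,
                       similarity = sim, n_pairs = np),
            class = c("similarity_profile", "data.frame"))
}

#' Partition of K-domain sites into interacting and non-interacting classes
#'
#' @param interacting SEP3 positions of interface residues.
#' @param span all analysed SEP3 positions.
#' @return object of class `site_partition` with elements `interacting` and
#'   `non_interacting` (disjoint, union = `span`).
#' @export
site_partition <- function(interacting, span = 94:178) {
  interacting <- sort(unique(as.integer(interacting)))
  if (!all(interacting %in% span)) {
    stop("interacting sites must lie within the analysed span",
         call. = FALSE)
  }
  structure(list(interacting = interacting,
                 non_interacting = setdiff(span, interacting),
                 span = span),
            class = "site_partition")
}

#' Default 15-site interacting partition
#'
#' The hydrophobic inter- and intramolecular interaction sites of the SEP3
#' homotetramer: the 12 leucines ([INTERACTING_LEUCINES]) plus, as a
#' user-replaceable default for the remaining interface residues, V104,
#' I111 and M150 (hydrophobic heptad-core positions of the reference; M150
#' is part of the hydrophobic stripe of the tetramerization interface).
#'
#' @param span analysed SEP3 positions (default 94:178).
#' @return a [site_partition()] with 15 interacting sites.
#' @export
default_site_partition <- function(span = 94:178) {
  site_partition(c(INTERACTING_LEUCINES, 104L, 111L, 150L), span = span)
}

#' Mann-Whitney U comparison of site-class similarities
#'
#' Two-sided Mann-Whitney U test of the per-column similarity scores of the
#' interacting class against the non-interacting class. Missing columns are
#' dropped. When the smaller class has at most `exact_max` members the exact
#' permutation distribution of U is enumerated (ties handled exactly);
#' otherwise the tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param profile a [similarity_profile()].
#' @param partition a [site_partition()]; matched against the profile's
#'   `position` column.
#' @param exact_max largest small-class size for exact enumeration
#'   (default 8).
#' @return list of class `site_class_test`: `U` (interacting class),
#'   `p_value`, `direction` (`"interacting_higher"`, `"non_interacting_higher"`
#'   or `"tied"`), `median_interacting`, `median_non_interacting`, `method`,
#'   `n_interacting`, `n_non_interacting`.
#' @export
compare_site_classes <- function(profile, partition, exact_max = 8) {
  stopifnot(inherits(profile, "similarity_profile"),
            inherits(partition, "site_partition"))
  ok <- !is.na(profile$similarity)
  x <- profile$similarity[ok & profile$position %in% partition$interacting]
  y <- profile$similarity[ok & profile$position %in%
                            partition$non_interacting]
  if (length(x) == 0 || length(y) == 0) {
    stop("both site classes must be non-empty after dropping missing columns",
         call. = FALSE)
  }
  mw <- mann_whitney_u(x, y, exact_max = exact_max)
  med_x <- stats::median(x)
  med_y <- stats::median(y)
  direction <- if (med_x > med_y) "interacting_higher"
    else if (med_x < med_y) "non_interacting_higher" else "tied"
  structure(c(mw, list(direction = direction, median_interacting = med_x,
                       median_non_interacting = med_y,
                       n_interacting = length(x),
                       n_non_interacting = length(y))),
            class = "site_class_test")
}

#' @export
print.site_class_test <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney U = %g (%s), p = %.4g [%s]\n", x$U, x$direction,
    x$p_value, x$method))
  cat(sprintf("  median similarity: interacting %.3f (n=%d), non-interacting %.3f (n=%d)\n",
              x$median_interacting, x$n_interacting,
              x$median_non_interacting, x$n_non_interacting))
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' U is counted for the first sample (ties contribute 1/2). Exact p-values
#' come from full enumeration of the permutation distribution of U over all
#' reassignments of the pooled values, valid with ties; the two-sided p is
#' \eqn{P(|U' - n_1 n_2/2| \ge |U - n_1 n_2/2|)}. Larger samples use the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_max enumerate exactly when `min(length(x), length(y))` is at
#'   most this (default 8).
#' @return list with `U`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("empty sample", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (min(n1, n2) <= exact_max && choose(n1 + n2, n1) <= 5e5) {
    combs <- utils::combn(n1 + n2, n1)
    u_all <- apply(combs, 2, function(idx) {
      sum(r[idx]) - n1 * (n1 + 1) / 2
    })
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    p <- min(p, 1)
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U, p_value = p, method = method)
}

#' Per-site amino-acid frequency table
#'
#' Relative residue frequencies over the non-gap residues of each requested
#' site; residues rarer than `collapse_threshold` are pooled into
#' `"others"`, mirroring how subfamily preference profiles condense rare
#' residues.
#'
#' @param family an [aligned_family()].
#' @param sites SEP3 positions (matched via the family's `column_map`) or
#'   raw column indices when no map is present.
#' @param collapse_threshold pooling threshold (default 0.05).
#' @return data.frame with columns `position`, `residue`, `frequency`;
#'   frequencies sum to 1 per site; all-gap sites yield a single `NA` row.
#' @export
aa_frequency <- function(family, sites = NULL, collapse_threshold = 0.05) {
  stopifnot(inherits(family, "aligned_family"))
  pos_of <- if (is.null(family$column_map)) seq_len(family$width) else
    family$column_map
  if (is.null(sites)) sites <- pos_of
  cols <- match(sites, pos_of)
  if (anyNA(cols)) {
    stop("site(s) outside the alignment span: ",
         paste(sites[is.na(cols)], collapse = ", "), call. = FALSE)
  }
  m <- family_matrix(family)
  out <- lapply(seq_along(sites), function(k) {
    col <- m[, cols[k]]
    col <- col[col %in% AA_CANONICAL]
    if (length(col) == 0) {
      return(data.frame(position = sites[k], residue = NA_character_,
                        frequency = NA_real_))
    }
    f <- table(col) / length(col)
    rare <- f < collapse_threshold
    freqs <- c(as.numeric(f[!rare]),
               if (any(rare)) sum(f[rare]))
    res <- c(names(f)[!rare], if (any(rare)) "others")
    o <- order(-freqs)
    data.frame(position = sites[k], residue = res[o], frequency = freqs[o])
  })
  do.call(rbind, out)
}

#' Named hydropathy scales
#'
#' @return list of named per-residue scales; currently the Kyte-Doolittle
#'   hydropathy index (`kyte_doolittle`) and the Hopp-Woods hydrophilicity
#'   scale (`hopp_woods`).
#' @export
hydropathy_scales <- function() {
  list(
    kyte_doolittle = c(
      A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
      G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
      P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2),
    hopp_woods = c(
      A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0, Q = 0.2, E = 3.0,
      G = 0.0, H = -0.5, I = -1.8, L = -1.8, K = 3.0, M = -1.3, F = -2.5,
      P = 0.0, S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5)
  )
}

#' Per-column mean hydropathy profile
#'
#' @param family an [aligned_family()].
#' @param scale a scale name from [hydropathy_scales()] or a named numeric
#'   vector covering the 20 canonical residues.
#' @return data.frame with `column`, `position`, `hydropathy` (mean scale
#'   value over non-gap residues; `NA` for all-gap columns) and `n_residues`.
#' @export
hydropathy_profile <- function(family, scale = "kyte_doolittle") {
  stopifnot(inherits(family, "aligned_family"))
  if (is.character(scale)) {
    scales <- hydropathy_scales()
    if (!scale %in% names(scales)) {
      stop("unknown hydropathy scale '", scale, "'; available: ",
           paste(names(scales), collapse = ", "), call. = FALSE)
    }
    scale <- scales[[scale]]
  }
  if (!all(AA_CANONICAL %in% names(scale))) {
    stop("scale must cover all 20 canonical residues", call. = FALSE)
  }
  m <- family_matrix(family)
  h <- apply(m, 2, function(col) {
    col <- col[col %in% AA_CANONICAL]
    if (length(col) == 0) NA_real_ else mean(scale[col])
  })
  n <- apply(m, 2, function(col) sum(col %in% AA_CANONICAL))
  pos <- if (is.null(family$column_map)) seq_len(family$width) else
    family$column_map
  data.frame(column = seq_len(family$width), position = pos,
             hydropathy = h, n_residues = n)
}

#' Default heptad anchoring of the K-subdomains
#'
#' Register phases fixed so that the published assignments hold: L145 at a
#' 'd' position (K2), E161 and N168 at 'a' and L164 at 'd' (K3). Subdomain
#' spans follow the K-domain annotation of the SEP3 crystal structure and
#' are replaceable.
#'
#' @return data.frame with columns `subdomain`, `start`, `end`,
#'   `anchor_pos`, `anchor_letter`.
#' @export
default_heptad_anchors <- function() {
  data.frame(
    subdomain = c("K1", "K2", "K3"),
    start = c(94L, 122L, 150L),
    end = c(121L, 149L, 181L),
    anchor_pos = c(101L, 145L, 161L),
    anchor_letter = c("a", "d", "a"))
}

#' Heptad register of a K-domain position
#'
#' @param position SEP3 full-protein position(s).
#' @param anchors anchoring table as in [default_heptad_anchors()].
#' @return character vector of register letters in `a`..`g`.
#' @export
heptad_register <- function(position, anchors = default_heptad_anchors()) {
  letters7 <- letters[1:7]
  vapply(as.integer(position), function(p) {
    row <- which(anchors$start <= p & p <= anchors$end)
    if (length(row) == 0) {
      stop("position ", p, " is outside every annotated subdomain span",
           call. = FALSE)
    }
    row <- row[1]
    off <- match(anchors$anchor_letter[row], letters7) - 1L
    letters7[((p - anchors$anchor_pos[row] + off) %% 7) + 1L]
  }, character(1))
}

#' Helical wheel projection of a residue window
#'
#' Coiled-coil wheel: consecutive residues advance by 360 * 2 / 7 degrees
#' (~102.857; seven residues per two turns), so residues seven apart
#' coincide. The first residue takes the register `start_register` and sits
#' at angle 0 by convention.
#'
#' @param window residue string or character vector.
#' @param start_register register letter of the first residue (default
#'   `"a"`).
#' @return data.frame with `index`, `residue`, `register`, `angle`
#'   (degrees in \[0, 360)).
#' @export
helical_wheel <- function(window, start_register = "a") {
  if (length(window) == 1 && nchar(window) > 1) {
    window <- strsplit(window, "")[[1]]
  }
  if (length(window) == 0 || !nzchar(paste(window, collapse = ""))) {
    stop("empty window", call. = FALSE)
  }
  if (!start_register %in% letters[1:7]) {
    stop("start_register must be one of a..g", call. = FALSE)
  }
  n <- length(window)
  step <- 360 * 2 / 7
  reg0 <- match(start_register, letters[1:7]) - 1L
  data.frame(
    index = seq_len(n),
    residue = window,
    register = letters[1:7][((reg0 + seq_len(n) - 1L) %% 7) + 1L],
    angle = (step * (seq_len(n) - 1L)) %% 360)
}

#' Sliding-window heptad periodicity score
#'
#' A deliberately simple stand-in for full coiled-coil prediction: for each
#' window placement, the score is the best over the 7 possible register
#' phases of the fraction of 'a'/'d' core positions occupied by hydrophobic
#' residues (L, I, V, M, F, A, W, Y). Each sequence position receives the
#' maximum score over all windows covering it. Scores lie in \[0, 1\]; an
#' ideal leucine zipper scores 1, a polar sequence 0. This heuristic ranks
#' heptad-periodic hydrophobicity only; it is not a probability of
#' coiled-coil formation.
#'
#' @param sequence residue string.
#' @param window window length, one of 14, 21, 28.
#' @return numeric vector, one score per sequence position.
#' @export
heptad_periodicity_score <- function(sequence, window = 21) {
  if (!window %in% c(14, 21, 28)) {
    stop("window must be 14, 21 or 28", call. = FALSE)
  }
  res <- strsplit(toupper(sequence), "")[[1]]
  n <- length(res)
  if (n < window) stop("sequence shorter than the window", call. = FALSE)
  hydro <- res %in% AA_HYDROPHOBIC
  n_win <- n - window + 1L
  win_score <- numeric(n_win)
  for (s in seq_len(n_win)) {
    idx <- s:(s + window - 1L)
    best <- 0
    for (phase in 0:6) {
      reg <- (idx - s + phase) %% 7   # 0 = 'a', 3 = 'd'
      core <- reg == 0 | reg == 3
      best <- max(best, mean(hydro[idx][core]))
    }
    win_score[s] <- best
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - window + 1L)
    hi <- min(i, n_win)
    out[i] <- max(win_score[lo:hi])
  }
  out
}
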