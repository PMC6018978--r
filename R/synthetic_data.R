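#' Noise model for simulated band quantification
#'
#' Additive Gaussian noise on each band fraction (or on each bound amount,
#' expressed as a fraction of the saturation plateau), followed by clipping
#' to \[0, 1\], a detection floor below which a band is recorded as absent,
#' and per-lane renormalization. This is the simplest error model consistent
#' with densitometric quantification of gel bands.
#'
#' @param sd standard deviation of the additive noise (default 0.05).
#' @param detection_floor fractions below this value are recorded as 0
#'   (default 0, must be < 0.5).
#' @param seed integer seed making the simulation reproducible; `NULL` uses
#'   the session RNG stream.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(sd = 0.05, detection_floor = 0, seed = NULL) {
  if (!is.numeric(sd) || length(sd) != 1 || sd < 0) {
    stop("`sd` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(detection_floor) || length(detection_floor) != 1 ||
      detection_floor < 0 || detection_floor >= 0.5) {
    stop("`detection_floor` must lie in [0, 0.5)", call. = FALSE)
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(sd = sd, detection_floor = detection_floor, seed = seed),
            class = "noise_model")
}

with_noise_seed <- function(noise, expr) {
  if (is.null(noise$seed)) expr
  else withr::with_seed(noise$seed, expr)
}

perturb_fractions <- function(fr, noise) {
  if (noise$sd > 0) fr <- fr + stats::rnorm(length(fr), sd = noise$sd)
  fr <- pmin(pmax(fr, 0), 1)
  fr[fr < noise$detection_floor] <- 0
  fr
}

#' Default protein ladder for simulated EMSA titrations
#'
#' Log-spaced applied-protein amounts emulating titrations of in vitro
#' translation mix from 0.05 to 3 volume units.
#'
#' @param n number of lanes (default 12).
#' @param from,to smallest and largest amount (defaults 0.05 and 3).
#' @return numeric vector of length `n`.
#' @export
emsa_protein_ladder <- function(n = 12, from = 0.05, to = 3) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Default probe ladder for simulated saturation assays
#'
#' Geometric ladder of probe amounts from 0.05 to 32 units.
#'
#' @param n number of points (default 12).
#' @param from,to smallest and largest amount (defaults 0.05 and 32).
#' @return numeric vector of length `n`.
#' @export
saturation_probe_ladder <- function(n = 12, from = 0.05, to = 32) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Simulate an EMSA titration series
#'
#' Forward-simulates the three band fractions from the cooperative two-site
#' model ([predict_fractions()] with `kd2 = kd1 / kcoop`), perturbs them
#' with the [noise_model()], and renormalizes each lane. With `sd = 0` and
#' no detection floor the output reproduces the model values exactly.
#'
#' @param kd1 positive first dissociation constant (protein units).
#' @param kcoop positive cooperativity constant.
#' @param protein_amounts non-negative applied protein amounts, one per
#'   lane (default [emsa_protein_ladder()]).
#' @param noise a [noise_model()].
#' @param label,probe_id identifiers attached to the series.
#' @return a [titration_series()].
#' @export
simulate_titration <- function(kd1, kcoop,
                               protein_amounts = emsa_protein_ladder(),
                               noise = noise_model(), label = "simulated",
                               probe_id = "probe_2carg") {
  check_scalar_pos(kd1, "kd1")
  check_scalar_pos(kcoop, "kcoop")
  stopifnot(inherits(noise, "noise_model"))
  if (length(protein_amounts) < 1) {
    stop("need at least one protein amount", call. = FALSE)
  }
  pred <- predict_fractions(protein_amounts, kd1, kd1 / kcoop)
  if (noise$sd == 0 && noise$detection_floor == 0) {
    # bitwise-stable fixed point of the forward model
    return(titration_series(protein_amounts, pred$y0, pred$y2, pred$y4,
                            label = label, probe_id = probe_id))
  }
  fr <- with_noise_seed(noise, {
    m <- cbind(perturb_fractions(pred$y0, noise),
               perturb_fractions(pred$y2, noise),
               perturb_fractions(pred$y4, noise))
    m
  })
  s <- rowSums(fr)
  dead <- s == 0
  fr[dead, ] <- matrix(rep(c(1, 0, 0), each = sum(dead)), ncol = 3)
  s[dead] <- 1
  fr <- fr / s
  titration_series(protein_amounts, fr[, 1], fr[, 2], fr[, 3],
                   label = label, probe_id = probe_id)
}

#' Simulate a saturation binding series
#'
#' Forward-simulates bound complex from the single-site model
#' ([predict_saturation()]) at the given free-probe amounts; the noise sd is
#' applied in units of the plateau `pt` so that `sd = 0.05` means 5% of full
#' saturation per point.
#'
#' @param pt positive total protein (plateau), in probe units.
#' @param kd positive dissociation constant, in probe units.
#' @param probe_amounts free-probe amounts (default
#'   [saturation_probe_ladder()], 0.05 to 32).
#' @param noise a [noise_model()].
#' @param label identifier.
#' @return a [saturation_series()].
#' @export
simulate_saturation <- function(pt, kd,
                                probe_amounts = saturation_probe_ladder(),
                                noise = noise_model(), label = "simulated") {
  check_scalar_pos(pt, "pt")
  check_scalar_pos(kd, "kd")
  stopifnot(inherits(noise, "noise_model"))
  if (length(probe_amounts) < 1) {
    stop("need at least one probe amount", call. = FALSE)
  }
  b <- predict_saturation(probe_amounts, pt, kd)
  b <- with_noise_seed(noise, {
    if (noise$sd > 0) b <- b + stats::rnorm(length(b), sd = noise$sd * pt)
    b
  })
  b <- pmax(b, 0)
  b[b < noise$detection_floor * pt] <- 0
  saturation_series(probe_amounts, b, label = label)
}

#' Per-column residue distribution
#'
#' @param position 1-based alignment column index.
#' @param probs named numeric vector of residue probabilities over the 20
#'   canonical amino acids; must sum to 1.
#' @return object of class `column_profile`.
#' @export
column_profile <- function(position, probs) {
  if (!all(names(probs) %in% AA_CANONICAL) || is.null(names(probs))) {
    stop("profile residues must be canonical amino acids", call. = FALSE)
  }
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
    stop("probabilities must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(position = as.integer(position), probs = probs),
            class = "column_profile")
}

AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# hydrophobic residues used for heptad-core scoring and presets
AA_HYDROPHOBIC <- c("L", "I", "V", "M", "F", "A", "W", "Y")

#' Simulate an aligned K-domain family
#'
#' Draws `n_seqs` aligned sequences column-independently from per-column
#' residue distributions. Columns are independent by design: adequate for
#' testing per-column statistics, not for covariation analyses.
#'
#' @param profiles list of [column_profile()]s, one per alignment column.
#' @param n_seqs number of sequences (>= 2).
#' @param label subfamily label attached to every sequence.
#' @param seed integer seed.
#' @return an [aligned_family()]; the profiles' positions become the
#'   family's `column_map`.
#' @export
simulate_family <- function(profiles, n_seqs, label = "synthetic",
                            seed = 1L) {
  if (length(profiles) == 0) stop("empty profile list", call. = FALSE)
  stopifnot(all(vapply(profiles, inherits, logical(1), "column_profile")))
  if (n_seqs < 2) stop("need at least 2 sequences", call. = FALSE)
  cols <- withr::with_seed(as.integer(seed), {
    lapply(profiles, function(pr) {
      sample(names(pr$probs), n_seqs, replace = TRUE, prob = pr$probs)
    })
  })
  m <- do.call(cbind, cols)
  rows <- apply(m, 1, paste, collapse = "")
  ids <- sprintf("%s_%03d", label, seq_len(n_seqs))
  aligned_family(ids, rows, subfamily = rep(label, n_seqs),
                 column_map = vapply(profiles, `[[`, integer(1), "position"))
}

#' Preset column profiles emulating MIKC-subfamily K-domains
#'
#' Deterministic per-column residue distributions over the analysed K-domain
#' span (SEP3 positions 94-178) that emulate the conservation structure the
#' downstream statistics assume:
#' \describe{
#'   \item{`SEP3-like`}{near-invariant leucine (probability
#'     `leucine_prob`, default 0.95) at the 12 interaction leucines
#'     (101, 108, 115, 120, 123, 128, 131, 135, 154, 157, 164, 171) and at
#'     the further default interacting sites, diffuse residue usage
#'     elsewhere.}
#'   \item{`AP3-like`}{threonine-dominant at the column mapped to 157 and
#'     glutamine-dominant at 164 (leucine probability ~0 there), other
#'     hydrophobics at the remaining interface columns.}
#'   \item{`PI-like`}{polar/charged residues dominant at the
#'     tetramerization-interface columns.}
#'   \item{`background`}{the diffuse distribution at every column (null
#'     model).}
#' }
#'
#' @param style one of `"SEP3-like"`, `"AP3-like"`, `"PI-like"`,
#'   `"background"`.
#' @param span SEP3 positions covered (default 94:178).
#' @param leucine_prob dominant-residue probability at conserved interface
#'   columns (default 0.95).
#' @return list of [column_profile()]s, one per position in `span`.
#' @export
preset_profiles <- function(style = c("SEP3-like", "AP3-like", "PI-like",
                                      "background"),
                            span = 94:178, leucine_prob = 0.95) {
  style <- match.arg(style)
  rest <- 1 - leucine_prob

  # diffuse background: polar/charged majority with some hydrophobics
  bg_res <- c("E", "Q", "K", "R", "N", "S", "T", "D", "A", "G",
              "L", "I", "V", "M")
  bg_w <- c(rep(1, 10), rep(0.5, 4))
  background <- stats::setNames(bg_w / sum(bg_w), bg_res)

  dominated <- function(res, p = leucine_prob, among = AA_HYDROPHOBIC) {
    among <- setdiff(among, res)
    stats::setNames(c(p, rep((1 - p) / length(among), length(among))),
                    c(res, among))
  }

  leu_sites <- INTERACTING_LEUCINES
  extra_sites <- setdiff(default_site_partition()$interacting, leu_sites)

  lapply(span, function(pos) {
    pr <- switch(style,
      "SEP3-like" = {
        if (pos %in% leu_sites) dominated("L")
        else if (pos == 150) dominated("M")
        else if (pos %in% extra_sites) dominated(if (pos %% 2 == 0) "V" else "I")
        else background
      },
      "AP3-like" = {
        if (pos == 157) dominated("T", among = c("S", "A", "N", "Q"))
        else if (pos == 164) dominated("Q", among = c("E", "N", "T", "S"))
        else if (pos %in% c(leu_sites, extra_sites)) {
          stats::setNames(rep(0.25, 4), c("I", "M", "V", "L"))
        } else background
      },
      "PI-like" = {
        if (pos %in% c(154, 157, 164, 171)) {
          stats::setNames(c(0.4, 0.3, 0.2, 0.1), c("Q", "E", "N", "S"))
        } else if (pos %in% c(leu_sites, extra_sites)) {
          stats::setNames(rep(0.25, 4), c("I", "M", "L", "V"))
        } else background
      },
      "background" = background
    )
    column_profile(pos, pr)
  })
}

#' The 12 interaction leucines of the SEP3 K-domain
#'
#' Full-protein positions of the leucine residues that mediate inter- and
#' intramolecular hydrophobic interactions in the SEP3 homotetramer:
#' dimerization interface (101, 108), kink region (115, 120, 123, 128, 131,
#' 135) and tetramerization interface (154, 157, 164, 171).
#' @export
INTERACTING_LEUCINES <- c(101L, 108L, 115L, 120L, 123L, 128L, 131L, 135L,
                          154L, 157L, 164L, 171L)
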