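# Labelled synthetic sequence generator.
#
# Emulates the targeting-signal structure the classifier exploits:
#   * nuclear-encoded classes start with a transit-peptide-like region
#     (S/T-enriched, D/E-depleted);
#   * thylakoid-lumen classes carry a Sec- or Tat-type lumenal signal after a
#     compact stroma-targeting region (Tat: twin-arginine RR at the start of
#     a weakly hydrophobic stretch; Sec: a hydrophobic h-region without RR);
#   * membrane classes contain >= 1 run of >= 15 residues from the
#     hydrophobic alphabet {A,I,L,V,F,M}, with envelope and thylakoid
#     membranes drawing from differently weighted hydrophobic mixtures and
#     different segment counts;
#   * plastid-encoded classes draw mature regions from a composition shifted
#     by +delta on {F,I,L} relative to the uniform nuclear background.

HYDROPHOBIC <- c("A", "I", "L", "V", "F", "M")

#' Configuration for the synthetic dataset generator
#'
#' @param n_per_class Records per fine class; a scalar or a named vector over
#'   the eight fine classes (to mimic unbalanced class sizes).
#' @param seed Integer seed; all randomness flows through one local generator.
#' @param length_range Length range (min, max) of the mature region; min >= 30.
#' @param tp_length Transit peptide length range for N_E / N_TM / N_S.
#' @param tp_lumen_length Stroma-targeting region length range for the two
#'   thylakoid-lumen classes (kept compact so the lumenal signal lies in the
#'   N-terminal window).
#' @param tp_st Total S+T probability in the transit peptide (split equally).
#' @param tp_de Total D+E probability in the transit peptide (split equally).
#' @param delta Compositional shift added to each of F, I, L for
#'   plastid-encoded mature regions (others renormalized).
#' @param tm_run_length Length range of one transmembrane segment (min >= 15).
#' @param n_tm_envelope Number of TM segments in envelope membrane classes.
#' @param n_tm_thylakoid Number of TM segments in thylakoid membrane classes.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_per_class = 60L, seed = 1L,
                             length_range = c(100L, 240L),
                             tp_length = c(30L, 80L),
                             tp_lumen_length = c(30L, 37L),
                             tp_st = 0.30, tp_de = 0.02,
                             delta = 0.02,
                             tm_run_length = c(15L, 19L),
                             n_tm_envelope = 2L, n_tm_thylakoid = 3L) {
  if (any(n_per_class <= 0)) stop("n_per_class must be positive")
  if (length_range[1] < 30) stop("minimum mature length must be >= 30")
  if (tm_run_length[1] < 15) stop("TM segments must be >= 15 residues")
  if (!is.null(names(n_per_class))) {
    miss <- setdiff(fine_classes(), names(n_per_class))
    if (length(miss) > 0) stop("n_per_class missing classes: ",
                               paste(miss, collapse = ", "))
  }
  structure(list(
    n_per_class = n_per_class, seed = seed, length_range = length_range,
    tp_length = tp_length, tp_lumen_length = tp_lumen_length,
    tp_st = tp_st, tp_de = tp_de, delta = delta,
    tm_run_length = tm_run_length,
    n_tm_envelope = n_tm_envelope, n_tm_thylakoid = n_tm_thylakoid
  ), class = "generator_config")
}

# -- composition tables -------------------------------------------------------

nuclear_background <- function() {
  p <- rep(1 / 20, 20)
  names(p) <- AA_ALPHABET
  p
}

plastid_background <- function(delta) {
  p <- nuclear_background()
  shifted <- c("F", "I", "L")
  p[shifted] <- 1 / 20 + delta
  p[setdiff(AA_ALPHABET, shifted)] <- (1 - sum(p[shifted])) / 17
  p
}

transit_peptide_comp <- function(tp_st, tp_de) {
  p <- stats::setNames(rep(0, 20), AA_ALPHABET)
  p[c("S", "T")] <- tp_st / 2
  p[c("D", "E")] <- tp_de / 2
  rest <- setdiff(AA_ALPHABET, c("S", "T", "D", "E"))
  p[rest] <- (1 - tp_st - tp_de) / length(rest)
  p
}

tm_comp <- function(kind = c("envelope", "thylakoid")) {
  kind <- match.arg(kind)
  w <- if (kind == "envelope") {
    c(A = 0.30, V = 0.25, I = 0.20, L = 0.15, F = 0.05, M = 0.05)
  } else {
    c(F = 0.30, L = 0.25, M = 0.15, A = 0.10, I = 0.10, V = 0.10)
  }
  w[HYDROPHOBIC]
}

sample_comp <- function(n, comp) {
  if (n <= 0) return(character(0))
  sample(names(comp), n, replace = TRUE, prob = comp)
}

# -- lumenal signal samplers --------------------------------------------------
# Sec signal: short n-region, strongly hydrophobic h-region, AxA cleavage site.
# Tat signal: S-R-R-x-F-L-K consensus (RR nearly invariant), weaker h-region,
# AxA cleavage site. Fixed lengths, so sets of signals are trivially aligned.

SEC_H_COMP <- c(A = 0.35, L = 0.35, V = 0.10, I = 0.10, F = 0.05, M = 0.05)
TAT_H_COMP <- c(A = 0.40, L = 0.20, V = 0.20, I = 0.10, F = 0.05, M = 0.05)

sample_sec_signal <- function() {
  n_region <- sample(c("K", "R", "S", "T"), 2, replace = TRUE)
  h_region <- sample_comp(10, SEC_H_COMP)
  c_region <- c("A", sample(AA_ALPHABET, 1), "A")
  paste(c(n_region, h_region, c_region), collapse = "")
}

consensus_residue <- function(res, p) {
  if (stats::runif(1) < p) res else sample(AA_ALPHABET, 1)
}

sample_tat_signal <- function() {
  # the twin-arginine dipeptide is invariant; flanking consensus is soft
  n_region <- c(
    consensus_residue("S", 0.7),
    "R", "R",
    sample(AA_ALPHABET, 1),
    consensus_residue("F", 0.7), consensus_residue("L", 0.7),
    consensus_residue("K", 0.7)
  )
  h_region <- sample_comp(8, TAT_H_COMP)
  c_region <- c("A", sample(AA_ALPHABET, 1), "A")
  paste(c(n_region, h_region, c_region), collapse = "")
}

# Mature region with k TM segments of the given kind embedded at spaced,
# non-overlapping positions.
sample_mature <- function(len, comp, n_tm = 0L, tm_kind = "envelope",
                          tm_run_length = c(15L, 19L)) {
  res <- sample_comp(len, comp)
  if (n_tm > 0) {
    runs <- lapply(seq_len(n_tm), function(i) {
      sample_comp(sample(tm_run_length[1]:tm_run_length[2], 1), tm_comp(tm_kind))
    })
    # evenly spaced anchor points keep runs non-overlapping
    anchors <- floor(seq(1, len - max(lengths(runs)), length.out = n_tm + 2))
    anchors <- anchors[2:(n_tm + 1)]
    for (i in seq_len(n_tm)) {
      run <- runs[[i]]
      res[anchors[i]:(anchors[i] + length(run) - 1)] <- run
    }
  }
  paste(res, collapse = "")
}

sample_record <- function(cls, config, side = NA_character_) {
  len <- sample(config$length_range[1]:config$length_range[2], 1)
  bg_n <- nuclear_background()
  bg_p <- plastid_background(config$delta)
  tp <- function(range) {
    paste(sample_comp(sample(range[1]:range[2], 1),
                      transit_peptide_comp(config$tp_st, config$tp_de)),
          collapse = "")
  }
  trl <- config$tm_run_length
  switch(cls,
    N_E = {
      n_tm <- if (identical(side, "IM")) config$n_tm_envelope else 1L
      paste0(tp(config$tp_length),
             sample_mature(len, bg_n, n_tm, "envelope", trl))
    },
    N_TM = paste0(tp(config$tp_length),
                  sample_mature(len, bg_n, config$n_tm_thylakoid,
                                "thylakoid", trl)),
    N_S = paste0(tp(config$tp_length), sample_mature(len, bg_n)),
    N_TL_SEC = paste0(tp(config$tp_lumen_length), sample_sec_signal(),
                      sample_mature(len, bg_n)),
    N_TL_TAT = paste0(tp(config$tp_lumen_length), sample_tat_signal(),
                      sample_mature(len, bg_n)),
    P_IM = sample_mature(len, bg_p, config$n_tm_envelope, "envelope", trl),
    P_TM = sample_mature(len, bg_p, config$n_tm_thylakoid, "thylakoid", trl),
    P_S = sample_mature(len, bg_p),
    stop("unknown class: ", cls)
  )
}

#' Generate a labelled synthetic dataset
#'
#' Produces exactly `n_per_class` records per fine class with the
#' class-specific signal structure described in [generator_config()].
#' Reproducible: the same config (including seed) yields identical output.
#' N_E records alternate IM/OM envelope sides (IM records carry
#' `n_tm_envelope` TM segments, OM records one).
#'
#' @param config A [generator_config()].
#' @return A `plastid_dataset` with fine labels (and `side` for N_E).
#' @examples
#' ds <- generate_dataset(generator_config(n_per_class = 5, seed = 1))
#' class_counts(ds)
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_per_class
  counts <- if (is.null(names(n))) {
    stats::setNames(rep(as.integer(n), 8), fine_classes())
  } else {
    stats::setNames(as.integer(n[fine_classes()]), fine_classes())
  }
  with_rng(config$seed, {
    ids <- character(0); seqs <- character(0)
    fine <- character(0); side <- character(0)
    for (cls in fine_classes()) {
      for (i in seq_len(counts[[cls]])) {
        s <- if (cls == "N_E") c("IM", "OM")[1 + (i %% 2)] else NA_character_
        ids <- c(ids, sprintf("%s_%04d", cls, i))
        seqs <- c(seqs, sample_record(cls, config, s))
        fine <- c(fine, cls)
        side <- c(side, s)
      }
    }
    plastid_dataset(ids, seqs, fine, side)
  })
}

#' Generate an aligned set of Sec or Tat signal sequences
#'
#' Signal sequences have fixed length per pathway, so the set is a
#' gapless-core alignment of equal aligned length, directly usable as
#' profile-HMM input. Tat alignments have two nearly invariant R columns
#' (the twin-arginine motif); Sec alignments do not.
#'
#' @param class `"Sec"` or `"Tat"`.
#' @param n Number of rows (>= 2).
#' @param seed Integer seed.
#' @return An `AAStringSet` of aligned signal sequences.
#' @export
generate_signal_msa <- function(class = c("Sec", "Tat"), n, seed = 1L) {
  class <- match.arg(class)
  if (n < 2) stop("n must be >= 2")
  with_rng(seed, {
    rows <- vapply(seq_len(n), function(i) {
      if (class == "Sec") sample_sec_signal() else sample_tat_signal()
    }, character(1))
    names(rows) <- sprintf("%s_%03d", tolower(class), seq_len(n))
    Biostrings::AAStringSet(rows)
  })
}
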