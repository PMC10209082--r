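# Sequence/label I/O and the eight-class taxonomy.
#
# Fine classes encode origin (N_ = nuclear, P_ = plastid) and compartment:
#   N_E        envelope, nuclear-encoded (optionally split into IM/OM)
#   N_TM       thylakoid membrane, nuclear-encoded
#   N_S        stroma, nuclear-encoded
#   N_TL_SEC   thylakoid lumen, nuclear-encoded, Sec import pathway
#   N_TL_TAT   thylakoid lumen, nuclear-encoded, Tat import pathway
#   P_IM       inner envelope membrane, plastid-encoded
#   P_TM       thylakoid membrane, plastid-encoded
#   P_S        stroma, plastid-encoded

#' Fine class labels of the eight-class taxonomy
#'
#' @return Character vector of the eight fine class labels, in canonical order.
#' @export
fine_classes <- function() {
  c("N_E", "N_TM", "N_S", "N_TL_SEC", "N_TL_TAT", "P_IM", "P_TM", "P_S")
}

GENERALIZED_MAP <- c(
  N_E = "envelope", P_IM = "envelope",
  N_S = "stroma", P_S = "stroma",
  N_TM = "thylakoid_membrane", P_TM = "thylakoid_membrane",
  N_TL_SEC = "thylakoid_lumen", N_TL_TAT = "thylakoid_lumen"
)

#' Map fine classes to origin and generalized localization
#'
#' Origin is nuclear for `N_*` classes and plastid for `P_*` classes; the
#' generalized localization collapses the eight fine classes onto the four
#' compartments (envelope, stroma, thylakoid membrane, thylakoid lumen).
#'
#' @param fine Character vector of fine class labels.
#' @return A data.frame with columns `fine`, `origin`, `generalized`.
#' @examples
#' map_generalized(c("P_IM", "N_TL_TAT"))
#' @export
map_generalized <- function(fine) {
  fine <- as.character(fine)
  bad <- setdiff(unique(fine[!is.na(fine)]), fine_classes())
  if (length(bad) > 0) {
    stop("unknown fine class label(s): ", paste(bad, collapse = ", "))
  }
  data.frame(
    fine = fine,
    origin = ifelse(is.na(fine), NA_character_,
                    ifelse(startsWith(fine, "N_"), "nuclear", "plastid")),
    generalized = unname(GENERALIZED_MAP[fine]),
    stringsAsFactors = FALSE
  )
}

#' Construct a labelled sequence dataset
#'
#' A dataset is a data.frame (class `plastid_dataset`) with one row per
#' protein: `id`, `sequence`, `fine` (fine class label or NA) and `side`
#' (IM/OM envelope side for N_E records, otherwise NA).
#'
#' @param id Character vector of unique record identifiers.
#' @param sequence Character vector of amino-acid sequences (upper-cased).
#' @param fine Optional fine class labels (NA allowed).
#' @param side Optional envelope side ("IM"/"OM") for N_E records.
#' @return A `plastid_dataset`.
#' @export
plastid_dataset <- function(id, sequence, fine = NA_character_, side = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (anyDuplicated(id)) {
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(sequence))) stop("empty sequence(s) present")
  fine <- rep_len(as.character(fine), length(id))
  known <- is.na(fine) | fine %in% fine_classes()
  if (!all(known)) {
    stop("unknown fine class label(s): ",
         paste(unique(fine[!known]), collapse = ", "))
  }
  short <- nchar(sequence) < 10
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than 10 residues retained")
  }
  ds <- data.frame(id = id, sequence = sequence, fine = fine,
                   side = rep_len(as.character(side), length(id)),
                   stringsAsFactors = FALSE)
  class(ds) <- c("plastid_dataset", "data.frame")
  ds
}

#' Per-class record counts
#'
#' @param dataset A `plastid_dataset`.
#' @return Named integer vector over the eight fine classes.
#' @export
class_counts <- function(dataset) {
  counts <- table(factor(dataset$fine, levels = fine_classes()))
  out <- as.integer(counts)
  names(out) <- fine_classes()
  if (any(out == 0)) {
    warning("fine class(es) absent from dataset: ",
            paste(names(out)[out == 0], collapse = ", "))
  }
  out
}

#' @export
print.plastid_dataset <- function(x, ...) {
  cat("plastid_dataset:", nrow(x), "records\n")
  labs <- x$fine[!is.na(x$fine)]
  if (length(labs) > 0) {
    tb <- table(factor(labs, levels = fine_classes()))
    cat("  labelled:", length(labs), "|",
        paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  }
  invisible(x)
}

# Structural pre-scan of a FASTA file so parse errors carry line numbers.
scan_fasta_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("FASTA parse error at line 1: empty file")
  first_real <- which(nzchar(trimws(lines)))[1]
  if (is.na(first_real) || !startsWith(lines[first_real], ">")) {
    stop("FASTA parse error at line ", first_real %||% 1,
         ": expected '>' header")
  }
  hdr <- which(startsWith(lines, ">"))
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("[\\s|].*$", "", ids, perl = TRUE)
  empty <- !nzchar(ids)
  if (any(empty)) {
    stop("FASTA parse error at line ", hdr[empty][1], ": empty record id")
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("FASTA parse error at line ", hdr[ids == dup][2],
         ": duplicate record id '", dup, "'")
  }
  # a header immediately followed by another header (or EOF) has no sequence
  ends <- c(hdr[-1] - 1L, length(lines))
  nseq <- mapply(function(from, to) {
    if (to < from) 0L else sum(nzchar(trimws(lines[seq(from, to)])))
  }, hdr + 1L, ends)
  if (any(nseq == 0L)) {
    stop("FASTA parse error at line ", hdr[nseq == 0L][1],
         ": record with no sequence")
  }
  invisible(TRUE)
}

#' Read a FASTA file into a labelled dataset
#'
#' Sequences are upper-cased and record order is preserved. Labels can come
#' from a sidecar TSV (`id<TAB>class`, optional third column `side`) or be
#' encoded in the FASTA header after a `|` separator; the TSV wins on
#' conflict. Gap characters and other non-alphabet symbols in sequences are a
#' parse error (use [validate_standard()] for ambiguity-code filtering).
#'
#' @param path Path to a FASTA file.
#' @param labels Optional: path to a labels TSV, or a named character vector
#'   mapping id to fine class.
#' @return A `plastid_dataset`.
#' @export
read_fasta <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  scan_fasta_structure(path)
  aa <- Biostrings::readBStringSet(path)
  full_ids <- names(aa)
  ids <- sub("[\\s|].*$", "", full_ids, perl = TRUE)
  seqs <- toupper(as.character(aa))
  # reject gap / whitespace characters outright (outside MSA context)
  gappy <- grepl("[-.*]", seqs)
  if (any(gappy)) {
    stop("FASTA parse error: gap or stop character in sequence of record '",
         ids[gappy][1], "'")
  }
  # header-embedded labels: >id|CLASS or >id|CLASS|SIDE
  fine <- rep(NA_character_, length(ids))
  side <- rep(NA_character_, length(ids))
  pieces <- strsplit(full_ids, "|", fixed = TRUE)
  for (i in seq_along(pieces)) {
    p <- trimws(pieces[[i]])
    if (length(p) >= 2 && p[2] %in% fine_classes()) fine[i] <- p[2]
    if (length(p) >= 3 && p[3] %in% c("IM", "OM")) side[i] <- p[3]
  }
  if (!is.null(labels)) {
    lab <- if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
      read_labels(labels)
    } else if (!is.null(names(labels))) {
      data.frame(id = names(labels), class = unname(labels),
                 stringsAsFactors = FALSE)
    } else {
      stop("labels must be a TSV path or a named character vector")
    }
    hit <- match(ids, lab$id)
    fine[!is.na(hit)] <- lab$class[hit[!is.na(hit)]]
    if (!is.null(lab$side)) side[!is.na(hit)] <- lab$side[hit[!is.na(hit)]]
  }
  plastid_dataset(ids, seqs, fine, side)
}

#' Read a labels TSV (`id<TAB>class`, optional `side` column)
#'
#' @param path Path to the TSV (with header).
#' @return A data.frame with columns `id`, `class` and possibly `side`.
#' @export
read_labels <- function(path) {
  lab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "class") %in% names(lab))) {
    stop("labels TSV must have columns 'id' and 'class'")
  }
  lab
}

#' Write a dataset as FASTA plus labels TSV
#'
#' @param dataset A `plastid_dataset`.
#' @param path Output FASTA path.
#' @param labels_path Optional output path for the labels TSV.
#' @param width Line-wrap width for sequences (0 = unwrapped).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(dataset, path, labels_path = NULL, width = 60L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(dataset))) {
    writeLines(paste0(">", dataset$id[i]), con)
    s <- dataset$sequence[i]
    if (width > 0L) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    } else {
      writeLines(s, con)
    }
  }
  if (!is.null(labels_path)) {
    lab <- data.frame(id = dataset$id, class = dataset$fine,
                      side = dataset$side, stringsAsFactors = FALSE)
    utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Keep only sequences over the 20-letter standard alphabet
#'
#' Records containing ambiguity codes (B, J, O, U, X, Z) or any other
#' non-standard character are removed, mirroring the filtering applied to
#' curated training sets. This is filtering, not failure: rejected ids are
#' returned alongside the cleaned dataset.
#'
#' @param dataset A `plastid_dataset`.
#' @return List with `dataset` (kept records) and `rejected` (data.frame of
#'   id and the first offending character).
#' @export
validate_standard <- function(dataset) {
  pat <- paste0("[^", paste(AA_ALPHABET, collapse = ""), "]")
  hit <- regexpr(pat, dataset$sequence)
  bad <- hit > 0
  rejected <- data.frame(
    id = dataset$id[bad],
    offending = substring(dataset$sequence[bad], hit[bad], hit[bad]),
    stringsAsFactors = FALSE
  )
  kept <- dataset[!bad, , drop = FALSE]
  class(kept) <- c("plastid_dataset", "data.frame")
  list(dataset = kept, rejected = rejected)
}
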