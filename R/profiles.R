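AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Read a protein multiple alignment from FASTA
#'
#' Gaps are `-`; all sequences must have equal length and there must be at
#' least two of them.
#'
#' @param path path to an aligned FASTA file.
#' @return character matrix (rows = sequences, named; columns = alignment
#'   columns), letters upper-cased.
#' @export
read_protein_alignment <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  if (length(aln) < 2L) stopf("%s: an alignment needs at least 2 sequences", path)
  w <- Biostrings::width(aln)
  if (length(unique(w)) != 1L) {
    stopf("%s: aligned sequences differ in length", path)
  }
  mat <- do.call(rbind, strsplit(toupper(as.character(aln)), ""))
  rownames(mat) <- names(aln)
  mat
}

#' Per-column conservation profile of a protein alignment
#'
#' For each alignment column: residue frequencies over the 20 amino acids
#' with gaps excluded from the denominator, the gap fraction, and the
#' information content `IC = log2(20) - H` in bits, where `H` is the Shannon
#' entropy of the gap-excluded residue distribution. An all-gap column has
#' `IC = 0` and gap fraction 1. No small-sample correction is applied (that
#' is a logo-rendering presentation choice); the raw IC is deterministic and
#' bounded in `[0, log2(20)]`.
#'
#' @param aln character matrix as from [read_protein_alignment()], or a list
#'   of equal-length character strings.
#' @return data.frame with one row per column: `column`, `gap_fraction`,
#'   `information`, then one frequency column per residue (`freq_A` ...).
#' @export
column_information <- function(aln) {
  if (!is.matrix(aln)) {
    aln <- do.call(rbind, strsplit(toupper(unlist(aln)), ""))
  }
  aln <- toupper(aln)
  bad <- matrix(!(aln %in% c(AA_ALPHABET, "-")), nrow = nrow(aln))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stopf("invalid character '%s' in sequence %s at column %d",
          aln[bad][1L],
          rownames(aln)[idx[1L]] %||% as.character(idx[1L]), idx[2L])
  }
  ncol_aln <- ncol(aln)
  nseq <- nrow(aln)
  max_ic <- log2(20)
  freqs <- matrix(0, nrow = ncol_aln, ncol = length(AA_ALPHABET),
                  dimnames = list(NULL, paste0("freq_", AA_ALPHABET)))
  gap_fraction <- numeric(ncol_aln)
  information <- numeric(ncol_aln)
  for (j in seq_len(ncol_aln)) {
    col <- aln[, j]
    gaps <- col == "-"
    gap_fraction[j] <- mean(gaps)
    res <- col[!gaps]
    if (length(res) == 0L) {
      information[j] <- 0
      next
    }
    f <- table(factor(res, levels = AA_ALPHABET)) / length(res)
    freqs[j, ] <- as.numeric(f)
    p <- f[f > 0]
    information[j] <- max_ic - sum(-p * log2(p))
  }
  cbind(data.frame(column = seq_len(ncol_aln), gap_fraction = gap_fraction,
                   information = information),
        as.data.frame(freqs))
}

#' Scan a protein sequence for a wildcard motif
#'
#' `x` (case-insensitive) matches any residue; every other letter matches
#' exactly. All — possibly overlapping — 1-based start positions are
#' returned in ascending order. A pattern longer than the sequence yields an
#' empty result, not an error. Matching is case-insensitive throughout
#' (motifs are conventionally written like `LxLxL`).
#'
#' @param sequence a single ungapped protein string.
#' @param pattern motif string, e.g. `"SKYQ"` or `"LxLxL"`.
#' @return integer vector of match start positions.
#' @export
scan_motif <- function(sequence, pattern) {
  if (length(sequence) != 1L || length(pattern) != 1L) {
    stopf("scan_motif takes a single sequence and a single pattern")
  }
  if (!nzchar(pattern)) stopf("pattern must be nonempty")
  seq_up <- toupper(sequence)
  pat_up <- toupper(pattern)
  if (nchar(pat_up) > nchar(seq_up)) return(integer(0))
  rx <- paste0("(?=", gsub("X", ".", gsub("([][{}()*+?.\\^$|])", "\\\\\\1",
                                          pat_up)), ")")
  m <- gregexpr(rx, seq_up, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  as.integer(m)
}

#' Scan many sequences for a motif
#'
#' @param sequences named character vector of ungapped protein sequences.
#' @param pattern motif string as in [scan_motif()].
#' @return data.frame with columns `sequence_id`, `position`.
#' @export
scan_motif_set <- function(sequences, pattern) {
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  out <- lapply(seq_along(sequences), function(i) {
    pos <- scan_motif(sequences[[i]], pattern)
    if (length(pos) == 0L) return(NULL)
    data.frame(sequence_id = ids[i], position = pos, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(sequence_id = character(), position = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
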