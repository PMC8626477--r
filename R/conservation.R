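# Alignment-column conservation relative to a reference sequence: map an
# ungapped reference position to its alignment column and report residue
# frequencies over the non-gap characters of that column.

#' Construct a multiple sequence alignment object
#'
#' @param sequences named character vector of aligned sequences (gap "-"),
#'   all the same length.
#' @param referenceId name of the reference sequence.
#' @return list of class `MSA`.
#' @export
msa <- function(sequences, referenceId) {
  stopifnot(length(sequences) >= 1, !is.null(names(sequences)))
  L <- unique(nchar(sequences))
  if (length(L) != 1)
    stop("aligned sequences must all have the same length (found ",
         paste(L, collapse = ", "), ")")
  if (!referenceId %in% names(sequences))
    stop("reference id '", referenceId, "' not present in the alignment")
  structure(list(sequences = sequences, referenceId = referenceId,
                 width = L), class = "MSA")
}

#' @rdname msa
#' @param x an `MSA`.
#' @export
msaSequences <- function(x) x$sequences

#' Read an alignment from FASTA or Clustal
#'
#' @param path file path.
#' @param referenceId id of the reference sequence in the file.
#' @param format "auto", "fasta" or "clustal".
#' @return an [msa()] object.
#' @export
readMSA <- function(path, referenceId, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: '", path, "'")
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (startsWith(first, ">")) "fasta" else "clustal"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    seqs <- stats::setNames(as.character(ss), names(ss))
    # FASTA headers may carry descriptions; keep the first token as the id
    names(seqs) <- vapply(strsplit(names(seqs), "[ \t]"), `[[`, character(1), 1)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[-1]  # CLUSTAL header line
    acc <- list()
    for (ln in lines) {
      if (trimws(ln) == "" || grepl("^[ *:.]+$", ln)) next
      parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(parts) < 2) next
      acc[[parts[1]]] <- paste0(acc[[parts[1]]] %||% "", parts[2])
    }
    seqs <- unlist(acc)
  }
  msa(seqs, referenceId)
}

#' Map an ungapped reference position to its alignment column
#'
#' @param x an [msa()] object.
#' @param position 1-based position in the ungapped reference sequence.
#' @return 1-based alignment column index.
#' @examples
#' a <- msa(c(ref = "A-CD", s = "AGCD"), "ref")
#' mapReferencePosition(a, 2)  # the 'C' sits in column 3
#' @export
mapReferencePosition <- function(x, position) {
  stopifnot(inherits(x, "MSA"), position >= 1)
  ref <- strsplit(x$sequences[[x$referenceId]], "")[[1]]
  nonGap <- which(ref != "-")
  if (position > length(nonGap))
    stop("position ", position, " beyond the reference's ungapped length (",
         length(nonGap), ")")
  nonGap[position]
}

#' Residue frequencies of an alignment column
#'
#' Frequencies over the non-gap characters (case-insensitive; "X" is its own
#' category); the gap fraction is reported separately via the `gapFraction`
#' attribute. With `includeGaps = TRUE` gaps enter the denominator (and appear
#' as category "-").
#'
#' @param x an [msa()] object.
#' @param column 1-based alignment column.
#' @param includeGaps include gaps in the denominator.
#' @return named numeric vector of residue fractions (sums to 1), attribute
#'   `gapFraction`.
#' @export
columnConservation <- function(x, column, includeGaps = FALSE) {
  stopifnot(inherits(x, "MSA"), column >= 1, column <= x$width)
  chars <- toupper(substr(x$sequences, column, column))
  gapFrac <- mean(chars == "-")
  if (!includeGaps) chars <- chars[chars != "-"]
  if (!length(chars)) stop("column ", column, " is all gaps")
  freq <- table(chars) / length(chars)
  out <- sort(stats::setNames(as.numeric(freq), names(freq)), decreasing = TRUE)
  attr(out, "gapFraction") <- gapFrac
  out
}

#' Conservation of reference residues at given positions
#'
#' Convenience wrapper: maps each ungapped reference position to its column
#' and reports the fraction of sequences matching the reference residue there.
#'
#' @param x an [msa()] object.
#' @param positions integer vector of ungapped reference positions.
#' @return data.frame: position, column, refResidue, conservation,
#'   topSubstitution, topSubstitutionFraction.
#' @export
referenceConservation <- function(x, positions) {
  ref <- x$sequences[[x$referenceId]]
  do.call(rbind, lapply(positions, function(p) {
    col <- mapReferencePosition(x, p)
    refRes <- toupper(substr(ref, col, col))
    freq <- columnConservation(x, col)
    subs <- freq[names(freq) != refRes]
    cons <- if (refRes %in% names(freq)) unname(freq[refRes]) else 0
    data.frame(position = p, column = col, refResidue = refRes,
               conservation = cons,
               topSubstitution = if (length(subs)) names(subs)[1] else NA,
               topSubstitutionFraction = if (length(subs)) unname(subs[1]) else 0,
               stringsAsFactors = FALSE)
  }))
}
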