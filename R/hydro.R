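# Whole-residue hydrophobicity scoring of sequence segments.

#' Sequence segment with author-scheme numbering
#'
#' A contiguous stretch of protein sequence whose first residue carries an
#' author/UniProt residue number, so residue `i` of the segment is residue
#' `start + i - 1` of the full protein.
#'
#' @param sequence One-letter residue string (upper- or lower-case; upper-
#'   cased on input). `'*'` and `'-'` are rejected.
#' @param start Residue number of the first position (integer, default 1).
#' @param label Free-text label.
#' @return Object of class `seq_segment`: list with `sequence`, `start`,
#'   `end`, `label`.
#' @export
seq_segment <- function(sequence, start = 1L, label = "") {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  sequence <- toupper(sequence)
  if (grepl("[*-]", sequence)) {
    stop("sequence contains '*' or '-' characters; segments must be ungapped")
  }
  start <- as.integer(start)
  structure(
    list(sequence = sequence, start = start,
         end = start + nchar(sequence) - 1L, label = label),
    class = "seq_segment"
  )
}

#' @export
print.seq_segment <- function(x, ...) {
  cat(sprintf("<seq_segment> %s %d-%d: %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$start, x$end, x$sequence))
  invisible(x)
}

.as_letters <- function(seg) {
  if (inherits(seg, "seq_segment")) strsplit(seg$sequence, "")[[1]]
  else strsplit(toupper(as.character(seg)), "")[[1]]
}

#' Transfer free energy of one residue
#'
#' Looks up the water-to-octanol transfer free energy of a single residue
#' under the scale's protonation convention.
#'
#' @param letter One-letter residue code.
#' @param scale A [hydro_scale()].
#' @param position Optional residue position, used only to make error
#'   messages for unknown letters actionable.
#' @return Free energy in kcal/mol.
#' @export
residue_energy <- function(letter, scale = hydro_scale(), position = NA) {
  letter <- toupper(letter)
  if (!letter %in% names(scale$values)) {
    stop(sprintf("unknown residue letter '%s'%s", letter,
                 if (is.na(position)) "" else sprintf(" at position %s", position)))
  }
  scale$values[[letter]]
}

#' Summed hydrophobicity of a segment
#'
#' Segment hydrophobicity is the sum of whole-residue transfer free
#' energies over its residues; the per-residue value is that sum divided by
#' the segment length.  An empty segment scores 0 total with an undefined
#' per-residue value.
#'
#' @param seg A [seq_segment()] or plain sequence string.
#' @param scale A [hydro_scale()].
#' @return Object of class `segment_score`: list with `total`,
#'   `per_residue` (kcal/mol) and `n_residues`.
#' @examples
#' score_segment("KFYFHLMLLAGCI")$total      # -5.13
#' score_segment("HRFHGLWYMKMMWAWL")$total   # -6.72
#' @export
score_segment <- function(seg, scale = hydro_scale()) {
  letters <- .as_letters(seg)
  n <- length(letters)
  if (n == 0L) {
    return(structure(list(total = 0, per_residue = NA_real_, n_residues = 0L),
                     class = "segment_score"))
  }
  unknown <- which(!letters %in% names(scale$values))
  if (length(unknown)) {
    pos <- unknown[1]
    if (inherits(seg, "seq_segment")) pos <- seg$start + pos - 1L
    stop(sprintf("unknown residue letter '%s' at position %d",
                 letters[unknown[1]], pos))
  }
  total <- sum(scale$values[letters])
  structure(
    list(total = total, per_residue = total / n, n_residues = n),
    class = "segment_score"
  )
}

#' @export
print.segment_score <- function(x, ...) {
  cat(sprintf("<segment_score> n = %d, total = %.2f kcal/mol, per residue = %.2f\n",
              x$n_residues, x$total,
              if (x$n_residues) x$per_residue else NA_real_))
  invisible(x)
}

#' Sliding-window hydropathy scan
#'
#' Scores every contiguous window of the given width, producing a
#' hydropathy profile in author numbering.
#'
#' @param seg A [seq_segment()] or sequence string.
#' @param width Window width in residues, `1 <= width <= length`.
#' @inheritParams score_segment
#' @return data.frame with columns `start`, `end`, `sequence`, `total`,
#'   `per_residue`, one row per window, ordered by `start`.
#' @export
scan_windows <- function(seg, width, scale = hydro_scale()) {
  if (!inherits(seg, "seq_segment")) seg <- seq_segment(seg)
  n <- nchar(seg$sequence)
  width <- as.integer(width)
  if (width < 1L || width > n) {
    stop(sprintf("window width %d out of range [1, %d]", width, n))
  }
  starts <- seq_len(n - width + 1L)
  rows <- lapply(starts, function(i) {
    sub <- substr(seg$sequence, i, i + width - 1L)
    sc <- score_segment(seq_segment(sub, start = seg$start + i - 1L), scale)
    data.frame(start = seg$start + i - 1L,
               end = seg$start + i + width - 2L,
               sequence = sub, total = sc$total,
               per_residue = sc$per_residue, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Extract the post-TM hydrophobic segment
#'
#' Returns the membrane-proximal stretch immediately after a transmembrane
#' domain: residues `tm_end + 1` onwards, extending for at least `min_len`
#' residues, then stopping before the first polar residue encountered
#' beyond `min_len`, and capped at `max_len`.  The polar stop is applied
#' only beyond `min_len` because these juxtamembrane stretches routinely
#' carry an internal charged residue (e.g. a lysine directly after the TM
#' helix) that must not truncate the segment.
#'
#' @param full_seq [seq_segment()] covering the region of interest.
#' @param tm_end Author residue number of the last TM residue.
#' @param polar_set Letters treated as polar stops.
#' @param min_len,max_len Minimum / maximum segment length (defaults 11 and
#'   16 residues).
#' @return A [seq_segment()] starting at `tm_end + 1` (possibly empty, with
#'   a warning, if `tm_end` is the final residue).
#' @examples
#' tmicl <- tlr4_constructs()$TMICL
#' extract_post_tm_segment(tmicl, tm_end = 652)  # residues 653-665
#' @export
extract_post_tm_segment <- function(full_seq, tm_end,
                                    polar_set = c("D","E","N","Q","S","T","G","K","R"),
                                    min_len = 11L, max_len = 16L) {
  stopifnot(inherits(full_seq, "seq_segment"), min_len <= max_len)
  tm_end <- as.integer(tm_end)
  if (tm_end < full_seq$start || tm_end > full_seq$end) {
    stop(sprintf("tm_end %d outside sequence range %d-%d",
                 tm_end, full_seq$start, full_seq$end))
  }
  letters <- .as_letters(full_seq)
  first <- tm_end - full_seq$start + 2L   # string index of tm_end + 1
  avail <- length(letters) - first + 1L
  if (avail <= 0L) {
    warning("tm_end is the last residue of the sequence; empty segment")
    return(seq_segment("", start = tm_end + 1L, label = full_seq$label))
  }
  len <- min(avail, max_len)
  # polar stop considered only beyond min_len
  if (len > min_len) {
    for (k in seq(min_len + 1L, len)) {
      if (letters[first + k - 1L] %in% polar_set) {
        len <- k - 1L
        break
      }
    }
  }
  seq_segment(paste(letters[first:(first + len - 1L)], collapse = ""),
              start = tm_end + 1L, label = full_seq$label)
}

#' Score the reference juxtamembrane segment table
#'
#' Convenience wrapper: scores every row of [tlr_jm_segments()] with the
#' default scale and returns the computed totals alongside the published
#' values.
#'
#' @inheritParams score_segment
#' @return data.frame: the segment table plus `total` and `per_residue`
#'   columns computed from the scale.
#' @export
score_jm_table <- function(scale = hydro_scale()) {
  tab <- tlr_jm_segments()
  sc <- lapply(tab$sequence, score_segment, scale = scale)
  tab$total <- vapply(sc, `[[`, numeric(1), "total")
  tab$per_residue <- vapply(sc, `[[`, numeric(1), "per_residue")
  tab
}
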