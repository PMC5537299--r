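# Tabular and sequence input/output.
#
# TSV dialect everywhere: tab-separated, UTF-8, '.' decimal, mandatory
# header row.  All writers are atomic (write to a temporary file in the
# target directory, then rename), so interrupted runs never leave partial
# reports.

#' Read a chemical-shift table
#'
#' Reads a TSV with header columns `resno`, `restype`, `group`, `dH`, `dC`
#' and optionally `state`, `condition`.  Empty `dH`/`dC` cells become `NA`
#' (a group observed in only one dimension).  A minimal recipe for
#' exporting such a table from a BMRB entry is given in the package
#' vignette; full NMR-STAR parsing is out of scope.
#'
#' @param path TSV file.
#' @return data.frame shift table.
#' @export
read_shift_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  need <- c("resno", "restype", "group")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("shift table %s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  if (!"dH" %in% names(df)) df$dH <- NA_real_
  if (!"dC" %in% names(df)) df$dC <- NA_real_
  df$resno <- as.integer(df$resno)
  df$dH <- as.numeric(df$dH)
  df$dC <- as.numeric(df$dC)
  key <- paste(df$resno, df$group,
               if ("state" %in% names(df)) df$state else "",
               if ("condition" %in% names(df)) df$condition else "")
  if (anyDuplicated(key)) {
    stop("duplicate (residue, group, state, condition) rows in ", path)
  }
  bad <- (!is.na(df$dH) & !is.finite(df$dH)) |
    (!is.na(df$dC) & !is.finite(df$dC))
  if (any(bad)) stop("non-finite chemical shifts in ", path)
  df
}

#' Write a data.frame as TSV (atomically)
#'
#' @param df data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tsv")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  file.rename(tmp, path)
  invisible(path)
}

#' Write an object as JSON (atomically)
#'
#' @param x Object serializable by jsonlite.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_json <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read sequences from a FASTA file as segments
#'
#' Reads single- or multi-record FASTA via `bio3d::read.fasta`; each record
#' becomes a [seq_segment()], with the author-scheme numbering of its first
#' residue taken from `offsets` (by record name) or defaulting to 1.
#'
#' @param path FASTA file.
#' @param offsets Optional named integer vector: residue number of the
#'   first residue of each record.
#' @return Named list of [seq_segment()]s.
#' @export
read_fasta_segments <- function(path, offsets = NULL) {
  fa <- bio3d::read.fasta(path)
  ids <- rownames(fa$ali)
  out <- lapply(seq_along(ids), function(i) {
    letters <- fa$ali[i, ]
    letters <- letters[letters != "-"]
    start <- 1L
    if (!is.null(offsets) && ids[i] %in% names(offsets)) {
      start <- as.integer(offsets[[ids[i]]])
    }
    seq_segment(paste(letters, collapse = ""), start = start,
                label = ids[i])
  })
  names(out) <- ids
  out
}
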