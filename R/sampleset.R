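# SampleSet: a labelled feature matrix (rows = surface residues) with row
# provenance, the container exchanged between the feature, resampling and
# classifier modules.

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Descriptor and window column names
#'
#' `feature_columns()` names the 24 per-residue descriptor columns: 20
#' profile frequencies (`prof_A` ... `prof_Y`, one-letter codes in
#' alphabetical order), `entropy`, `rel_entropy`, `weight` and
#' `conservation`. `window_columns()` names the concatenated window layout
#' (`w00_*` is the target residue, `w01_*` its nearest surface neighbour,
#' and so on).
#'
#' @param window window size (target + neighbours).
#' @return character vector of column names.
#' @export
feature_columns <- function() {
  c(paste0("prof_", AA1), "entropy", "rel_entropy", "weight", "conservation")
}

#' @rdname feature_columns
#' @export
window_columns <- function(window = 11) {
  unlist(lapply(seq_len(window) - 1L, function(w) {
    paste0(sprintf("w%02d_", w), feature_columns())
  }))
}

#' Construct a labelled sample set
#'
#' @param x numeric feature matrix, one row per sample.
#' @param y integer labels: 1 = interface, 0 = non-interface.
#' @param provenance data.frame with columns `chain` and `resno` (and
#'   optionally `icode`) identifying each row's target residue.
#' @param pad_count integer vector: number of zero-padded neighbour slots
#'   per row (0 when the chain had enough surface residues).
#' @return a `sample_set` object.
#' @export
sample_set <- function(x, y, provenance, pad_count = integer(nrow(x))) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(
    nrow(x) == length(y), all(y %in% c(0L, 1L)),
    nrow(provenance) == nrow(x),
    all(c("chain", "resno") %in% names(provenance)),
    length(pad_count) == nrow(x)
  )
  if (is.null(provenance$icode)) provenance$icode <- ""
  structure(
    list(x = x, y = y,
         provenance = as.data.frame(provenance, stringsAsFactors = FALSE),
         pad_count = as.integer(pad_count)),
    class = "sample_set"
  )
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("sample_set: %d samples x %d features (%d positive, %d negative)\n",
              nrow(x$x), ncol(x$x), sum(x$y == 1), sum(x$y == 0)))
  invisible(x)
}

#' @export
dim.sample_set <- function(x) dim(x$x)

# provenance keys used for deterministic tie-breaking and removal reports
sample_keys <- function(s) {
  paste(s$provenance$chain, s$provenance$resno, s$provenance$icode, sep = ":")
}

#' Subset a sample set by row index
#' @param s a `sample_set`.
#' @param idx integer or logical row index.
#' @return the subsetted `sample_set`.
#' @export
sample_subset <- function(s, idx) {
  sample_set(s$x[idx, , drop = FALSE], s$y[idx],
             s$provenance[idx, , drop = FALSE], s$pad_count[idx])
}

#' Write / read a sample set as TSV
#'
#' Columns: `chain`, `resno`, `icode`, `pad_count`, `label`, then the feature
#' columns in matrix order.
#'
#' @param s a `sample_set`.
#' @param path file path.
#' @return `path` invisibly / the `sample_set`.
#' @export
write_sample_set <- function(s, path) {
  df <- data.frame(
    chain = s$provenance$chain, resno = s$provenance$resno,
    icode = s$provenance$icode, pad_count = s$pad_count, label = s$y,
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(s$x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_set
#' @export
read_sample_set <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("chain", "resno", "icode", "pad_count", "label")
  stopifnot(all(meta %in% names(df)))
  df$icode[is.na(df$icode)] <- ""
  x <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  sample_set(x, df$label, df[, c("chain", "resno", "icode")], df$pad_count)
}
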