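# Features module: per-residue 24-dimensional conservation descriptors and
# their assembly into spatial-window vectors (target residue + its 10
# nearest surface neighbours, 11 x 24 = 264 columns).

#' Read a per-residue conservation feature table
#'
#' Expects a tab-separated file with columns `chain`, `resno` and the 24
#' descriptor columns named by [feature_columns()]: 20 profile frequencies
#' (`prof_A` ... `prof_Y`), `entropy`, `rel_entropy`, `weight`,
#' `conservation`.
#'
#' @param path file path.
#' @param normalized when TRUE (default), each row's profile block must sum
#'   to 1 within \[0.99, 1.01\].
#' @return a data.frame of feature rows keyed by (chain, resno).
#' @export
read_feature_table <- function(path, normalized = TRUE) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  want <- c("chain", "resno", feature_columns())
  missing_cols <- setdiff(want, names(df))
  extra_cols <- setdiff(names(df), want)
  if (length(missing_cols) || length(extra_cols)) {
    stop("feature table has wrong columns; missing: [",
         paste(missing_cols, collapse = ", "), "]; extra: [",
         paste(extra_cols, collapse = ", "), "]")
  }
  num <- df[, feature_columns(), drop = FALSE]
  for (j in seq_along(num)) {
    v <- num[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("non-numeric value in column ", names(num)[j], ", row ", bad)
    }
  }
  key <- paste(df$chain, df$resno)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, resno) keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  prof <- as.matrix(df[, paste0("prof_", AA1)])
  if (any(prof < 0)) stop("negative profile frequencies")
  if (normalized) {
    s <- rowSums(prof)
    if (any(s < 0.99 | s > 1.01)) {
      stop("profile rows do not sum to 1 (rows ",
           paste(head(which(s < 0.99 | s > 1.01)), collapse = ", "), ")")
    }
  }
  df[, want]
}

#' @rdname read_feature_table
#' @param features a feature data.frame as returned by [read_feature_table()].
#' @export
write_feature_table <- function(features, path) {
  write.table(features[, c("chain", "resno", feature_columns())], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build spatial-window feature vectors for surface residues
#'
#' Encodes each labelled surface residue by concatenating its own 24-dim
#' descriptor with those of its `window - 1` nearest surface residues of the
#' same chain (Calpha Euclidean distance, ties broken by ascending residue
#' number), ordered by increasing distance. Chains with fewer surface
#' residues than the window get zero-padded neighbour slots, counted in
#' `pad_count`. Surface residues without a feature row are dropped with a
#' warning.
#'
#' @param sites `ppi_sites` with interface labels.
#' @param features feature data.frame from [read_feature_table()].
#' @param window window size (target + neighbours), default 11.
#' @return a [sample_set()] with `window * 24` columns; attribute `dropped`
#'   holds the keys of surface residues lacking features.
#' @export
build_windows <- function(sites, features, window = 11) {
  stopifnot(window >= 1)
  surf <- sites[which(sites$is_surface), , drop = FALSE]
  if (!nrow(surf)) stop("no surface residues")
  if (any(is.na(surf$label))) {
    stop("surface residues lack interface labels; run label_interface() first")
  }
  fkey <- paste(features$chain, features$resno)
  fmat <- as.matrix(features[, feature_columns()])
  skey <- paste(surf$chain, surf$resno)
  have <- skey %in% fkey
  dropped <- character(0)
  if (any(!have)) {
    dropped <- skey[!have]
    warning(sum(!have), " surface residue(s) lack feature rows and were dropped",
            call. = FALSE)
    surf <- surf[have, , drop = FALSE]
    skey <- skey[have]
  }
  if (!nrow(surf)) stop("no surface residues with feature rows")
  frow <- fmat[match(skey, fkey), , drop = FALSE]

  n <- nrow(surf)
  p <- 24L
  x <- matrix(0, n, window * p, dimnames = list(NULL, window_columns(window)))
  pad <- integer(n)
  neighbors <- vector("list", n)
  for (ch in unique(surf$chain)) {
    ci <- which(surf$chain == ch)
    ca <- as.matrix(surf[ci, c("ca_x", "ca_y", "ca_z")])
    d2 <- outer(rowSums(ca^2), rowSums(ca^2), "+") - 2 * ca %*% t(ca)
    d2 <- pmax(d2, 0)
    for (a in seq_along(ci)) {
      others <- ci[-a]
      if (length(others)) {
        ord <- order(d2[a, -a], surf$resno[others])
        nb <- others[ord][seq_len(min(window - 1L, length(others)))]
      } else nb <- integer(0)
      i <- ci[a]
      x[i, 1:p] <- frow[i, ]
      if (length(nb)) {
        x[i, p + seq_len(length(nb) * p)] <- t(frow[nb, , drop = FALSE])
      }
      pad[i] <- window - 1L - length(nb)
      neighbors[[i]] <- skey[nb]
    }
  }
  y <- as.integer(surf$label == "interface")
  s <- sample_set(x, y, surf[, c("chain", "resno", "icode")], pad)
  s$neighbors <- neighbors
  attr(s, "dropped") <- dropped
  s
}
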