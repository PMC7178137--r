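# Structures module: parse multi-chain PDB structures, compute per-residue
# accessibility on the isolated chains, and label residues as
# interface / non_interface / buried from geometry.

#' Reference maximum accessible surface areas
#'
#' Loads the residue-type maximum accessible surface areas used to normalise
#' absolute ASA into relative ASA (RASA). Ships the Tien et al. (2013)
#' theoretical values; any two-column table (resname, max_asa) can be
#' substituted.
#'
#' @param path optional path to a tab-separated table with columns
#'   `resname` (3-letter code) and `max_asa` (square Angstrom).
#' @return named numeric vector, names are 3-letter residue codes.
#' @export
max_asa_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "max_asa_tien2013.tsv", package = "ppisite")
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("resname", "max_asa") %in% names(tab)), all(tab$max_asa > 0))
  setNames(tab$max_asa, toupper(tab$resname))
}

#' Read a multi-chain structure from a PDB file
#'
#' Thin wrapper over [bio3d::read.pdb()] that keeps standard ATOM records
#' (plus selenomethionine HETATM records, remapped MSE to MET), retains only
#' the first model, and resolves alternate locations to the
#' highest-occupancy conformer.
#'
#' @param path path to a PDB file.
#' @return a data.frame of atoms with columns `chain`, `resno`, `icode`,
#'   `resname`, `elety`, `element`, `x`, `y`, `z`.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  mse <- at$type == "HETATM" & at$resid == "MSE"
  at$resid[mse] <- "MET"
  at$type[mse] <- "ATOM"
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  # highest-occupancy altloc per (chain, resno, icode, atom name)
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  at <- at[order(key, -occ), , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")), , drop = FALSE]
  at <- at[order(at$chain, at$resno, at$insert, at$eleno), , drop = FALSE]
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  # infer element from the atom-name convention when the element column is absent
  elem[bad] <- substr(gsub("[0-9 ]", "", at$elety[bad]), 1, 1)
  data.frame(
    chain = at$chain, resno = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    resname = toupper(at$resid), elety = at$elety, element = toupper(elem),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
}

#' Per-residue accessible surface area of isolated chains
#'
#' Runs Shrake-Rupley over each chain in isolation (monomer state), so that
#' residues buried only by the binding partner still count as surface: the
#' interface must be a subset of the surface.
#'
#' @param atoms atom table from [read_structure()].
#' @param probe_radius probe radius in Angstrom.
#' @param n_points Shrake-Rupley sphere points per atom.
#' @return `atoms` with an `asa` column (square Angstrom per atom).
#' @export
compute_asa <- function(atoms, probe_radius = 1.4, n_points = 960) {
  stopifnot(nrow(atoms) >= 1)
  atoms$asa <- NA_real_
  for (ch in unique(atoms$chain)) {
    sel <- which(atoms$chain == ch)
    ok <- sel[is.finite(atoms$x[sel]) & is.finite(atoms$y[sel]) & is.finite(atoms$z[sel])]
    if (length(ok) == 0L) next
    atoms$asa[ok] <- shrake_rupley(
      as.matrix(atoms[ok, c("x", "y", "z")]), atoms$element[ok],
      probe_radius = probe_radius, n_points = n_points
    )
  }
  atoms
}

#' Aggregate atoms into residue sites with relative accessibility
#'
#' Sums atomic ASA per residue, normalises by the residue-type maximum to
#' obtain RASA, and records the coordinates needed for interface labelling
#' (Calpha position and all carbon atoms). Residues without atoms or without
#' a maximum-ASA entry are excluded with a warning.
#'
#' @param atoms atom table with `asa` from [compute_asa()].
#' @param max_asa named vector from [max_asa_table()].
#' @return a `ppi_sites` data.frame: one row per residue with columns
#'   `chain`, `resno`, `icode`, `resname`, `asa`, `rasa`, `is_surface`,
#'   `label`, `ca_x`, `ca_y`, `ca_z`, plus a `carbons` list column of
#'   carbon-atom coordinate matrices.
#' @export
residue_sites <- function(atoms, max_asa = max_asa_table()) {
  stopifnot("asa" %in% names(atoms))
  key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  ord <- order(atoms$chain, atoms$resno, atoms$icode)
  atoms <- atoms[ord, , drop = FALSE]
  key <- key[ord]
  idx <- split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
  rows <- lapply(idx, function(i) {
    a <- atoms[i, , drop = FALSE]
    resname <- a$resname[1]
    has_xyz <- is.finite(a$x) & is.finite(a$y) & is.finite(a$z)
    if (!any(has_xyz)) {
      warning("residue ", a$chain[1], a$resno[1], a$icode[1],
              " has no atoms with coordinates; excluded", call. = FALSE)
      return(NULL)
    }
    if (!resname %in% names(max_asa)) {
      warning("residue name ", resname, " (", a$chain[1], a$resno[1],
              ") has no max-ASA entry; excluded from RASA", call. = FALSE)
      return(NULL)
    }
    carb <- a[a$element == "C" & has_xyz, c("x", "y", "z"), drop = FALSE]
    cai <- which(a$elety == "CA" & has_xyz)
    if (length(cai) == 0L) {
      ca <- if (nrow(carb)) unlist(carb[1, ]) else c(NA_real_, NA_real_, NA_real_)
    } else {
      ca <- unlist(a[cai[1], c("x", "y", "z")])
    }
    data.frame(
      chain = a$chain[1], resno = a$resno[1], icode = a$icode[1],
      resname = resname,
      asa = sum(a$asa[has_xyz], na.rm = TRUE),
      rasa = sum(a$asa[has_xyz], na.rm = TRUE) / max_asa[[resname]],
      is_surface = NA, label = NA_character_,
      ca_x = ca[[1]], ca_y = ca[[2]], ca_z = ca[[3]],
      stringsAsFactors = FALSE
    )
  })
  keep <- !vapply(rows, is.null, logical(1))
  sites <- do.call(rbind, rows[keep])
  rownames(sites) <- NULL
  sites$carbons <- lapply(idx[keep], function(i) {
    a <- atoms[i, , drop = FALSE]
    as.matrix(a[a$element == "C" & is.finite(a$x), c("x", "y", "z"), drop = FALSE])
  })
  class(sites) <- c("ppi_sites", "data.frame")
  sites
}

#' Label surface residues by relative accessibility
#'
#' A residue is a surface residue when its RASA strictly exceeds the
#' threshold (default 16% of the residue-type maximum). Non-surface residues
#' are labelled `buried`; surface residues await interface labelling.
#'
#' @param sites `ppi_sites` from [residue_sites()].
#' @param threshold RASA fraction; strict inequality ("more than").
#' @return `sites` with `is_surface` and `label` populated.
#' @export
label_surface <- function(sites, threshold = 0.16) {
  stopifnot(all(is.finite(sites$rasa)), all(sites$rasa >= 0))
  sites$is_surface <- sites$rasa > threshold
  sites$label <- ifelse(sites$is_surface, NA_character_, "buried")
  sites
}

# Pairwise residue distances between two site tables under the given mode.
# ca_ca: Calpha-Calpha; min_carbon: minimum over all carbon-atom pairs.
residue_distance_matrix <- function(a, b, mode = c("ca_ca", "min_carbon")) {
  mode <- match.arg(mode)
  if (mode == "ca_ca") {
    ca_a <- as.matrix(a[, c("ca_x", "ca_y", "ca_z")])
    ca_b <- as.matrix(b[, c("ca_x", "ca_y", "ca_z")])
    d2 <- outer(rowSums(ca_a^2), rowSums(ca_b^2), "+") - 2 * ca_a %*% t(ca_b)
    sqrt(pmax(d2, 0))
  } else {
    m <- matrix(Inf, nrow(a), nrow(b))
    for (i in seq_len(nrow(a))) {
      ci <- a$carbons[[i]]
      if (!nrow(ci)) next
      for (j in seq_len(nrow(b))) {
        cj <- b$carbons[[j]]
        if (!nrow(cj)) next
        d2 <- outer(rowSums(ci^2), rowSums(cj^2), "+") - 2 * ci %*% t(cj)
        m[i, j] <- sqrt(max(0, min(d2)))
      }
    }
    m
  }
}

#' Label interface residues of a chain pair
#'
#' A surface residue is an interface residue when its distance to some
#' residue of the partner chain is at or below the cutoff (default 12
#' Angstrom, i.e. 1.2 nm, with the boundary value counting as interface);
#' all other surface residues are non-interface. Buried residues keep their
#' label. Both chains of the pair are labelled.
#'
#' @param sites `ppi_sites` after [label_surface()], containing both chains.
#' @param chain_a,chain_b chain identifiers of the pair.
#' @param cutoff distance cutoff in Angstrom.
#' @param mode `"ca_ca"` for Calpha-Calpha distances or `"min_carbon"` for
#'   the minimum over all carbon-atom pairs. Residues missing a Calpha fall
#'   back to their first carbon atom in `ca_ca` mode (messaged).
#' @return `sites` with `label` filled for the two chains.
#' @export
label_interface <- function(sites, chain_a, chain_b, cutoff = 12,
                            mode = c("ca_ca", "min_carbon")) {
  mode <- match.arg(mode)
  ia <- which(sites$chain == chain_a)
  ib <- which(sites$chain == chain_b)
  if (!length(ia) || !length(ib)) {
    stop("chain pair (", chain_a, ", ", chain_b, ") not found in sites")
  }
  if (mode == "ca_ca" && anyNA(sites$ca_x[c(ia, ib)])) {
    message("residues without Calpha use their first carbon atom")
  }
  d <- residue_distance_matrix(sites[ia, , drop = FALSE],
                               sites[ib, , drop = FALSE], mode)
  near_a <- apply(d, 1, function(r) any(r <= cutoff, na.rm = TRUE))
  near_b <- apply(d, 2, function(r) any(r <= cutoff, na.rm = TRUE))
  sites$label[ia] <- ifelse(sites$is_surface[ia],
                            ifelse(near_a, "interface", "non_interface"),
                            "buried")
  sites$label[ib] <- ifelse(sites$is_surface[ib],
                            ifelse(near_b, "interface", "non_interface"),
                            "buried")
  sites
}

#' Write / read a residue site table
#'
#' Tab-separated, one row per residue, with `#`-prefixed header lines
#' recording the labelling parameters. Coordinates are kept so that the
#' feature module can build spatial windows from the file alone.
#'
#' @param sites `ppi_sites` table.
#' @param path output path.
#' @param params named list recorded in the header (cutoff, mode, probe
#'   radius, ...).
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(params)) {
    writeLines(sprintf("# %s=%s", nm, params[[nm]]), con)
  }
  cols <- c("chain", "resno", "icode", "resname", "asa", "rasa",
            "is_surface", "label", "ca_x", "ca_y", "ca_z")
  write.table(as.data.frame(sites)[, cols], con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  sites <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  sites$icode[is.na(sites$icode)] <- ""
  class(sites) <- c("ppi_sites", "data.frame")
  sites
}
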