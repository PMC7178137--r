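# Synthetic module: self-contained fixtures for the whole pipeline — toy
# two-chain coordinate sets, conservation feature tables, and imbalanced
# overlapping sample clouds with planted ground truth for resampler
# evaluation.

#' Synthetic two-chain structure fixture
#'
#' Emits PDB-format text for a two-chain poly-alanine system: chain A
#' Calphas along the x axis at 3.8 Angstrom spacing, chain B parallel at
#' `gap` Angstrom. For every requested contact pair `(i, j)` residue j of
#' chain B is re-positioned 11.5 Angstrom above residue i of chain A, which
#' puts exactly that Calpha pair (and no other cross-chain Calpha pair)
#' within the 12 Angstrom interface cutoff.
#'
#' @param n_residues integer vector of length 2: residues per chain.
#' @param gap inter-chain separation in Angstrom; must exceed 16 so
#'   non-contact residues stay clear of the cutoff.
#' @param contacts two-column matrix (or list of length-2 vectors) of
#'   (chain A residue, chain B residue) contact pairs; indices must be
#'   distinct within each chain.
#' @param jitter small coordinate noise (Angstrom) applied to atom offsets,
#'   seeded.
#' @param seed RNG seed for the jitter.
#' @return character vector of PDB lines.
#' @export
make_structure_fixture <- function(n_residues = c(20, 20), gap = 30,
                                   contacts = NULL, jitter = 0, seed = 1) {
  stopifnot(length(n_residues) == 2, all(n_residues >= 1))
  if (gap <= 16) {
    stop("gap must exceed 16 Angstrom so only requested contacts fall ",
         "within the 12 Angstrom cutoff")
  }
  if (!is.null(contacts)) {
    contacts <- do.call(rbind, lapply(contacts, function(p) as.integer(p[1:2])))
    if (is.null(dim(contacts))) contacts <- matrix(contacts, ncol = 2)
    stopifnot(all(contacts[, 1] >= 1), all(contacts[, 1] <= n_residues[1]),
              all(contacts[, 2] >= 1), all(contacts[, 2] <= n_residues[2]))
    if (anyDuplicated(contacts[, 1]) || anyDuplicated(contacts[, 2])) {
      stop("contact residue indices must be distinct within each chain")
    }
  }
  spacing <- 3.8
  ca_a <- cbind((seq_len(n_residues[1]) - 1) * spacing, 0, 0)
  ca_b <- cbind((seq_len(n_residues[2]) - 1) * spacing, gap, 0)
  if (!is.null(contacts)) {
    for (r in seq_len(nrow(contacts))) {
      i <- contacts[r, 1]; j <- contacts[r, 2]
      ca_b[j, ] <- c(ca_a[i, 1], 11.5, 0)
    }
  }
  # idealised alanine atom offsets relative to Calpha
  offsets <- rbind(
    N = c(-1.46, 0.00, 0.00),
    CA = c(0.00, 0.00, 0.00),
    C = c(0.90, 0.00, 1.20),
    O = c(0.66, 0.00, 2.40),
    CB = c(0.56, 1.40, -0.60)
  )
  elements <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")
  lines <- character(0)
  serial <- 0L
  emit_chain <- function(ca, chain) {
    out <- character(0)
    for (i in seq_len(nrow(ca))) {
      for (a in rownames(offsets)) {
        serial <<- serial + 1L
        xyz <- ca[i, ] + offsets[a, ]
        if (jitter > 0) xyz <- xyz + rnorm(3, 0, jitter)
        name <- if (nchar(a) < 4) sprintf(" %-3s", a) else a
        out <- c(out, sprintf(
          "ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, "ALA", chain, i, xyz[1], xyz[2], xyz[3], 1.00, 0.00,
          elements[[a]]))
      }
    }
    out
  }
  with_seed(seed, {
    lines <- c(emit_chain(ca_a, "A"), "TER", emit_chain(ca_b, "B"), "TER", "END")
  })
  lines
}

#' Synthetic conservation feature table
#'
#' One 24-dimensional descriptor per requested residue: a Dirichlet-like
#' profile (normalised gamma draws), its Shannon entropy, the relative
#' entropy against the uniform background, a sequence weight, and a
#' conservation score.
#'
#' @param keys data.frame with columns `chain` and `resno` (e.g. the surface
#'   rows of a site table).
#' @param seed RNG seed.
#' @param concentration gamma shape for the profile draws; small values give
#'   peaked (conserved-looking) profiles.
#' @return feature data.frame compatible with [read_feature_table()].
#' @export
make_feature_table <- function(keys, seed = 1, concentration = 0.5) {
  n <- nrow(keys)
  with_seed(seed, {
    prof <- matrix(rgamma(n * 20, shape = concentration), n, 20)
    prof <- prof / rowSums(prof)
    p_safe <- pmax(prof, .Machine$double.eps)
    entropy <- -rowSums(p_safe * log(p_safe))
    rel_entropy <- rowSums(p_safe * log(p_safe * 20))
    weight <- runif(n, 0.5, 1.5)
    conservation <- runif(n)
  })
  df <- data.frame(chain = keys$chain, resno = keys$resno,
                   stringsAsFactors = FALSE)
  colnames(prof) <- paste0("prof_", AA1)
  cbind(df, as.data.frame(prof),
        data.frame(entropy = entropy, rel_entropy = rel_entropy,
                   weight = weight, conservation = conservation))
}

#' Imbalanced overlap scenario
#'
#' Describes the synthetic sample clouds used to evaluate the resamplers:
#' two Gaussian classes plus a planted subset of majority-class (negative)
#' samples drawn from the *minority* (positive) distribution — an explicit,
#' exactly known class-overlap region.
#'
#' @param n_positive,n_negative class sizes (`n_negative` includes the
#'   planted overlap samples).
#' @param n_overlap number of planted overlap negatives.
#' @param dims feature dimensionality; must be a multiple of 24 so each
#'   24-block can carry a valid profile layout (default 24; the full
#'   pipeline width is 264).
#' @param separation Euclidean distance between the clean class means in
#'   latent feature-space units.
#' @param spread within-class standard deviation per dimension.
#' @param seed RNG seed.
#' @return an `overlap_scenario` list.
#' @export
overlap_scenario <- function(n_positive = 300, n_negative = 1100,
                             n_overlap = 100, dims = 24, separation = 4.5,
                             spread = 1.0, seed = 7) {
  stopifnot(n_positive > 0, n_negative > 0, n_overlap >= 0,
            n_overlap <= n_negative, dims %% 24 == 0, dims > 0,
            separation >= 0, spread > 0)
  structure(list(n_positive = n_positive, n_negative = n_negative,
                 n_overlap = n_overlap, dims = dims, separation = separation,
                 spread = spread, seed = seed),
            class = "overlap_scenario")
}

#' Generate an imbalanced sample set with planted overlap
#'
#' Draws the two classes from Gaussian clouds whose means are `separation`
#' apart along a seeded random direction; `n_overlap` negatives are drawn
#' from the positive-class distribution (the planted overlap). Each
#' 24-block is then mapped to a valid descriptor layout: the 20 profile
#' columns through a softmax (non-negative, summing to 1) and the entropy
#' column through absolute value.
#'
#' @param scenario an [overlap_scenario()].
#' @return list with `samples` (a [sample_set()]; provenance chain "P" for
#'   positives, "N" clean negatives, "O" planted overlap negatives),
#'   `planted` (provenance keys of the planted negatives) and `clean`
#'   (keys of the clean negatives).
#' @export
make_samples <- function(scenario = overlap_scenario()) {
  sc <- scenario
  n_clean <- sc$n_negative - sc$n_overlap
  with_seed(sc$seed, {
    u <- rnorm(sc$dims)
    u <- u / sqrt(sum(u^2))
    mu_pos <- u * sc$separation / 2
    mu_neg <- -u * sc$separation / 2
    draw <- function(n, mu) {
      if (n == 0L) return(matrix(numeric(0), 0, sc$dims))
      matrix(rnorm(n * sc$dims, 0, sc$spread), n, sc$dims, byrow = TRUE) +
        matrix(mu, n, sc$dims, byrow = TRUE)
    }
    x <- rbind(draw(sc$n_positive, mu_pos), draw(n_clean, mu_neg),
               draw(sc$n_overlap, mu_pos))
  })
  for (b in seq_len(sc$dims %/% 24)) {
    jp <- (b - 1) * 24 + 1:20
    e <- exp(x[, jp, drop = FALSE])
    x[, jp] <- e / rowSums(e)
    x[, (b - 1) * 24 + 21] <- abs(x[, (b - 1) * 24 + 21])
  }
  colnames(x) <- window_columns(sc$dims %/% 24)
  y <- c(rep(1L, sc$n_positive), rep(0L, n_clean), rep(0L, sc$n_overlap))
  prov <- data.frame(
    chain = c(rep("P", sc$n_positive), rep("N", n_clean), rep("O", sc$n_overlap)),
    resno = c(seq_len(sc$n_positive), seq_len(n_clean), seq_len(sc$n_overlap)),
    stringsAsFactors = FALSE
  )
  s <- sample_set(x, y, prov)
  keys <- sample_keys(s)
  list(samples = s,
       planted = keys[prov$chain == "O"],
       clean = keys[prov$chain == "N"],
       scenario = sc)
}
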