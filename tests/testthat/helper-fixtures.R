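# Shared fixtures, built in code at test time.

# Minimal hand-built site table: surface residues on given Calpha positions,
# one carbon (the Calpha) per residue.
toy_sites <- function(chain, resno, ca, rasa = 1, label = NA_character_) {
  ca <- as.matrix(ca)
  n <- length(resno)
  sites <- data.frame(
    chain = rep_len(chain, n), resno = resno, icode = "",
    resname = "ALA", asa = rep_len(rasa, n) * 129,
    rasa = rep_len(rasa, n), is_surface = rep_len(rasa, n) > 0.16,
    label = rep_len(label, n),
    ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
    stringsAsFactors = FALSE
  )
  sites$carbons <- lapply(seq_len(n), function(i) ca[i, , drop = FALSE])
  class(sites) <- c("ppi_sites", "data.frame")
  sites
}

# Random labelled sample set for resampling / classifier tests.
random_sample_set <- function(n_pos, n_neg, dims = 4, sep = 0, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(
      matrix(rnorm(n_pos * dims, sep / 2), n_pos, dims),
      matrix(rnorm(n_neg * dims, -sep / 2), n_neg, dims)
    )
  })
  colnames(x) <- paste0("f", seq_len(dims))
  sample_set(x, c(rep(1L, n_pos), rep(0L, n_neg)),
             data.frame(chain = "X", resno = seq_len(n_pos + n_neg)))
}

# Independent brute-force k-NN editing oracle: one full repeated-editing run
# implemented with plain loops, no shared code with renn_edit().
brute_force_renn <- function(x, y, k = 3, target = "all", keys = NULL) {
  if (is.null(keys)) keys <- as.character(seq_len(nrow(x)))
  keep <- seq_len(nrow(x))
  repeat {
    xx <- x[keep, , drop = FALSE]
    ctr <- colMeans(xx)
    scl <- apply(xx, 2, stats::sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    z <- x
    z[keep, ] <- sweep(sweep(xx, 2, ctr, "-"), 2, scl, "/")
    mark <- logical(length(keep))
    for (a in seq_along(keep)) {
      i <- keep[a]
      d <- sqrt(colSums((t(z[keep, , drop = FALSE]) - z[i, ])^2))
      d[a] <- Inf
      ord <- order(d, keys[keep])
      nb <- keep[ord[seq_len(k)]]
      if (sum(y[nb] != y[i]) >= 2) mark[a] <- TRUE
    }
    if (target == "negatives_only") mark <- mark & y[keep] == 0L
    if (!any(mark)) break
    keep <- keep[!mark]
    if (length(keep) < k + 1) break
  }
  keep
}

# Analytic solvent-accessible area of two intersecting spheres with radii
# r1, r2 (already probe-inflated) at centre distance d: total area minus the
# two buried spherical caps.
two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  x2 <- d - x1
  cap1 <- 2 * pi * r1 * (r1 - x1)
  cap2 <- 2 * pi * r2 * (r2 - x2)
  4 * pi * (r1^2 + r2^2) - cap1 - cap2
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function(seed) {
  withr::with_seed(seed, m <- matrix(rnorm(9), 3))
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
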