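# Surface and interface labelling.

test_that("surface labelling uses a strict 16% threshold", {
  ca <- cbind(seq_len(3) * 4, 0, 0)
  sites <- toy_sites("A", 1:3, ca, rasa = c(0.16, 0.161, 0.05))
  lab <- label_surface(sites)
  expect_equal(lab$is_surface, c(FALSE, TRUE, FALSE))
  expect_equal(lab$label, c("buried", NA, "buried"))
})

test_that("a hand-set mix of accessibilities yields exactly the expected surface count", {
  rasa <- c(0.9, 0.5, 0.3, 0.25, 0.2, 0.17, 0.15, 0.12, 0.1, 0.05, 0.02, 0)
  sites <- toy_sites("A", 1:12, cbind(seq_len(12) * 4, 0, 0), rasa = rasa)
  expect_equal(sum(label_surface(sites)$is_surface), 6L)
})

test_that("chains beyond the cutoff produce zero interface residues", {
  a <- label_surface(toy_sites("A", 1:5, cbind(seq_len(5) * 4, 0, 0)))
  b <- label_surface(toy_sites("B", 1:5, cbind(seq_len(5) * 4, 20, 0)))
  lab <- label_interface(rbind(a, b), "A", "B", cutoff = 12)
  expect_equal(sum(lab$label == "interface"), 0L)
  expect_equal(sum(lab$label == "non_interface"), 10L)
})

test_that("a single close Calpha pair gives exactly one interface residue per chain", {
  # residue A3 / B1 at 5 Angstrom; every other cross-chain pair > 12
  ca_a <- rbind(c(0, 0, 0), c(30, 0, 0), c(60, 0, 0))
  ca_b <- rbind(c(60, 5, 0), c(90, 5, 0))
  sites <- rbind(label_surface(toy_sites("A", 1:3, ca_a)),
                 label_surface(toy_sites("B", 1:2, ca_b)))
  lab <- label_interface(sites, "A", "B", cutoff = 12)
  expect_equal(lab$label[lab$chain == "A"], c("non_interface", "non_interface", "interface"))
  expect_equal(lab$label[lab$chain == "B"], c("interface", "non_interface"))
})

test_that("the boundary distance counts as interface and the cutoff is monotone", {
  ca_a <- rbind(c(0, 0, 0))
  ca_b <- rbind(c(12, 0, 0))
  sites <- rbind(label_surface(toy_sites("A", 1, ca_a)),
                 label_surface(toy_sites("B", 1, ca_b)))
  expect_equal(label_interface(sites, "A", "B", cutoff = 12)$label[1], "interface")
  expect_equal(label_interface(sites, "A", "B", cutoff = 11.99)$label[1], "non_interface")

  withr::with_seed(5, {
    a <- label_surface(toy_sites("A", 1:15, matrix(rnorm(45, sd = 8), 15)))
    b <- label_surface(toy_sites("B", 1:15, matrix(rnorm(45, sd = 8), 15) + 10))
  })
  sites <- rbind(a, b)
  counts <- vapply(c(5, 8, 12, 20, 40), function(cut) {
    sum(label_interface(sites, "A", "B", cutoff = cut)$label == "interface")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("interface labels agree with an exhaustive all-pairs distance scan", {
  for (seed in 1:4) {
    withr::with_seed(seed, {
      na <- sample(5:20, 1); nb <- sample(5:20, 1)
      ca_a <- matrix(rnorm(na * 3, sd = 10), na)
      ca_b <- matrix(rnorm(nb * 3, sd = 10), nb) + 5
      rasa_a <- runif(na, 0, 0.6); rasa_b <- runif(nb, 0, 0.6)
    })
    sites <- rbind(label_surface(toy_sites("A", seq_len(na), ca_a, rasa = rasa_a)),
                   label_surface(toy_sites("B", seq_len(nb), ca_b, rasa = rasa_b)))
    lab <- label_interface(sites, "A", "B", cutoff = 12)
    # oracle: plain double loop over residue pairs
    for (i in seq_len(na)) {
      near <- FALSE
      for (j in seq_len(nb)) {
        if (sqrt(sum((ca_a[i, ] - ca_b[j, ])^2)) <= 12) near <- TRUE
      }
      expected <- if (!sites$is_surface[i]) "buried" else if (near) "interface" else "non_interface"
      expect_equal(lab$label[i], expected)
    }
  }
})

test_that("permuting residue order changes no label", {
  withr::with_seed(9, {
    ca_a <- matrix(rnorm(30, sd = 8), 10)
    ca_b <- matrix(rnorm(30, sd = 8), 10) + 6
  })
  sites <- rbind(label_surface(toy_sites("A", 1:10, ca_a)),
                 label_surface(toy_sites("B", 1:10, ca_b)))
  lab1 <- label_interface(sites, "A", "B", cutoff = 12)
  perm <- c(sample(1:10), 10 + sample(1:10))
  lab2 <- label_interface(sites[perm, ], "A", "B", cutoff = 12)
  key1 <- paste(lab1$chain, lab1$resno)
  key2 <- paste(lab2$chain, lab2$resno)
  expect_equal(lab2$label[match(key1, key2)], lab1$label)
})

test_that("min_carbon mode uses the closest carbon pair, not the Calpha", {
  a <- toy_sites("A", 1, matrix(c(0, 0, 0), 1))
  b <- toy_sites("B", 1, matrix(c(14, 0, 0), 1))
  # give B an extra carbon atom reaching to 10 Angstrom from A's Calpha
  b$carbons[[1]] <- rbind(c(14, 0, 0), c(10, 0, 0))
  sites <- rbind(label_surface(a), label_surface(b))
  expect_equal(label_interface(sites, "A", "B", 12, "ca_ca")$label[1], "non_interface")
  expect_equal(label_interface(sites, "A", "B", 12, "min_carbon")$label[1], "interface")
})

test_that("site tables round-trip through the TSV format", {
  sites <- label_surface(toy_sites("A", 1:5, cbind(seq_len(5) * 4, 0, 0),
                                   rasa = c(0.5, 0.1, 0.3, 0.16, 0.9)))
  sites$label[is.na(sites$label)] <- "non_interface"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(sites, path, params = list(cutoff_nm = 1.2, mode = "ca_ca"))
  back <- read_site_table(path)
  expect_equal(back$rasa, sites$rasa, tolerance = 1e-9)
  expect_equal(back$label, sites$label)
  expect_equal(back$is_surface, sites$is_surface)
})

test_that("unknown residue names are excluded from RASA with a warning", {
  atoms <- data.frame(
    chain = "A", resno = c(1L, 2L), icode = "", resname = c("ALA", "XYZ"),
    elety = "CA", element = "C", x = c(0, 8), y = 0, z = 0,
    stringsAsFactors = FALSE
  )
  atoms <- compute_asa(atoms, n_points = 200)
  expect_warning(sites <- residue_sites(atoms), "XYZ")
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$resname, "ALA")
})
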