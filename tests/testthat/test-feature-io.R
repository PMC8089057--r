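test_that("FASTA reading parses records, normalizes case, validates residues", {
  fp <- tempfile(fileext = ".fasta")
  writeLines(c(">p1", "ACDE"), fp)
  recs <- read_fasta(fp)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$id, "p1")
  expect_equal(recs[[1]]$sequence, "ACDE")
  expect_equal(recs[[1]]$L, 4)

  writeLines(c(">a", "ac", ">b", "DEFG"), fp)
  recs <- read_fasta(fp)
  expect_equal(vapply(recs, `[[`, integer(1), "L"), c(2L, 4L))
  expect_equal(recs[[1]]$sequence, "AC")

  writeLines(c(">p", "AC GT"), fp)
  expect_error(read_fasta(fp, strict = TRUE), "line 2")
  expect_equal(read_fasta(fp, strict = FALSE)[[1]]$sequence, "ACGT")

  writeLines(c(">bad", "ACZ1"), fp)
  expect_error(read_fasta(fp), "illegal residue")
  writeLines(character(0), fp)
  expect_error(read_fasta(fp), "no sequences")
})

test_that("contact derivation honours the strict 8 Angstrom threshold", {
  co <- rbind(c(0, 0, 0), c(7.99, 0, 0))
  expect_equal(contacts_from_coords(co)$values[1, 2], 1)
  co2 <- rbind(c(0, 0, 0), c(8.00, 0, 0))
  expect_equal(contacts_from_coords(co2)$values[1, 2], 0)
})

test_that("a straight chain at 3.8 Angstrom spacing contacts exactly |i-j| <= 2", {
  L <- 10
  co <- cbind(3.8 * (seq_len(L) - 1), 0, 0)
  cm <- contacts_from_coords(co)
  sep <- abs(outer(seq_len(L), seq_len(L), `-`))
  expect_equal(cm$values, (sep > 0 & sep <= 2) * 1)
})

test_that("contact maps from random coordinates equal a brute-force pair loop", {
  set.seed(3)
  for (rep in 1:5) {
    L <- 20
    co <- matrix(rnorm(L * 3, sd = 6), L, 3)
    cm <- contacts_from_coords(co)
    want <- matrix(0, L, L)
    for (i in seq_len(L)) for (j in seq_len(L)) {
      if (i != j && sqrt(sum((co[i, ] - co[j, ])^2)) < 8) want[i, j] <- 1
    }
    expect_equal(cm$values, want)
    expect_equal(cm$values, t(cm$values))
    expect_equal(diag(cm$values), rep(0, L))
  }
})

test_that("masked residues give invalid zeroed pairs and too few residues error", {
  co <- residue_coords(matrix(rnorm(15), 5, 3),
                       mask = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  cm <- contacts_from_coords(co)
  expect_true(all(cm$values[2, ] == 0))
  expect_true(all(!cm$valid[2, ]))
  expect_false(any(diag(cm$valid)))
  expect_error(
    contacts_from_coords(residue_coords(matrix(0, 3, 3),
                                        mask = c(TRUE, FALSE, FALSE))),
    "at least 2")
})

test_that("separation range masks classify the CASP boundaries", {
  m <- range_mask(30, "long")
  expect_false(m[1, 24])   # |i-j| = 23
  expect_true(m[1, 25])    # |i-j| = 24
  mm <- range_mask(30, "medium")
  expect_true(mm[1, 13])   # |i-j| = 12
  expect_false(mm[1, 12])  # |i-j| = 11
  expect_false(mm[1, 25])  # |i-j| = 24
  ms <- range_mask(30, "short")
  expect_true(ms[1, 7]); expect_false(ms[1, 6])  # 6 vs 5
})

test_that("range masks are symmetric, disjoint, and union to separation >= 6", {
  for (L in c(8, 30, 61)) {
    ms <- range_mask(L, "short"); mm <- range_mask(L, "medium")
    ml <- range_mask(L, "long")
    expect_false(any(ms & mm) || any(ms & ml) || any(mm & ml))
    sep <- abs(outer(seq_len(L), seq_len(L), `-`))
    expect_equal(ms | mm | ml, sep >= 6)
    expect_equal(ml, t(ml))
    expect_false(any(diag(ms | mm | ml)))
  }
})

test_that("RR round trip preserves pairs and probabilities to 1e-6", {
  set.seed(9)
  L <- 40
  v <- matrix(runif(L * L), L, L); v <- (v + t(v)) / 2; diag(v) <- 0
  pred <- contact_map(v, "probability")
  rec <- protein_record("t1", paste(rep("A", L), collapse = ""))
  fp <- tempfile(fileext = ".rr")
  write_rr(pred, rec, fp)
  rr <- read_rr(fp)
  expect_equal(rr$sequence, rec$sequence)
  back <- rr_to_map(rr, L)
  ut <- upper.tri(v)
  expect_equal(back$values[ut], round(v[ut], 6), tolerance = 1e-6)
  # ordering: descending probability
  expect_true(all(diff(rr$pairs$prob) <= 0))
})

test_that("RR output formats single scores and breaks ties by (i, j)", {
  L <- 50
  v <- matrix(0, L, L)
  v[3, 45] <- 0.92; v[45, 3] <- 0.92
  rec <- protein_record("x", paste(rep("G", L), collapse = ""))
  fp <- tempfile(fileext = ".rr")
  write_rr(contact_map(v, "probability"), rec, fp, top_k = 1)
  expect_equal(readLines(fp)[2], "3 45 0 8 0.920000")
  # ties broken by i then j ascending
  v2 <- matrix(0, 6, 6)
  v2[1, 5] <- 0.5; v2[1, 4] <- 0.5; v2[2, 3] <- 0.5
  rec2 <- protein_record("y", "AAAAAA")
  write_rr(contact_map(v2, "probability"), rec2, fp)
  lines <- readLines(fp)[2:4]
  expect_equal(lines, c("1 4 0 8 0.500000", "1 5 0 8 0.500000",
                        "2 3 0 8 0.500000"))
  vb <- (v2 + t(v2) > 0) * 1
  expect_error(write_rr(contact_map(vb, "binary"), rec2, fp),
               "probability")
})

test_that("feature bundles round trip bit-exactly and enforce L consistency", {
  set.seed(21)
  L <- 10
  fs <- feature_set(matrix(runif(L * 20), L), array(rnorm(L * L * 4), c(L, L, 4)))
  fp <- tempfile(fileext = ".rds")
  write_feature_bundle(fs, fp)
  back <- read_feature_bundle(fp)
  expect_identical(back$pssm, fs$pssm)
  expect_identical(back$plm, fs$plm)
  expect_null(back$contacts)
  expect_error(
    feature_set(matrix(0, 10, 20), array(0, c(12, 12, 4))),
    "L mismatch")
  expect_error(read_feature_bundle(tempfile()), "not found|not a")
})

test_that("plain-text PSSM matrices load with shape validation", {
  fp <- tempfile(fileext = ".txt")
  m <- matrix(round(rnorm(60), 3), 3, 20)
  write.table(m, fp, row.names = FALSE, col.names = FALSE)
  expect_equal(read_pssm_matrix(fp), m, tolerance = 1e-9)
  write.table(m[, 1:5], fp, row.names = FALSE, col.names = FALSE)
  expect_error(read_pssm_matrix(fp), "20 columns")
})
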