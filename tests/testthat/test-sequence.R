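test_that("FASTA round trip preserves records, order and validation", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">A", "GSY", ">B desc", "mkqq"), path)
  seqs <- read_fasta(path)
  expect_length(seqs, 2)
  expect_equal(seqs[[1]]$id, "A")
  expect_equal(seqs[[1]]$residues, c("G", "S", "Y"))
  expect_equal(seqs[[1]]$L, 3)
  expect_equal(format(seqs[[2]]), "MKQQ")  # uppercased

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_length(read_fasta(empty), 0)

  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">bad", "GSB"), bad)
  expect_error(read_fasta(bad), "B")

  out <- tempfile(fileext = ".fasta")
  write_fasta(seqs, out)
  back <- read_fasta(out)
  expect_equal(vapply(back, format, ""), vapply(seqs, format, ""))
})

test_that("residue taxonomy partitions the 20 canonical codes", {
  expect_equal(classify_residue("Y"), "aromatic")
  expect_equal(classify_residue("H"), "positive")
  expect_equal(classify_residue("G"), "glycine")
  expect_equal(classify_residue("Q"), "neutral_pi")
  expect_error(classify_residue("B"), "non-canonical")
  aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  cls <- classify_residue(aa20)
  expect_false(any(is.na(cls)))
  expect_equal(sort(unique(cls)),
               sort(c("aromatic", "positive", "negative", "neutral_pi",
                      "glycine", "neutral")))
})

test_that("composition profile fractions and NCPR follow the charge model", {
  p <- composition_profile(pld_sequence("s", "GSYGR"))
  expect_equal(unname(p$fractions[c("glycine", "neutral", "aromatic",
                                    "positive", "negative", "neutral_pi")]),
               c(0.4, 0.2, 0.2, 0.2, 0, 0))
  expect_equal(sum(p$fractions), 1, tolerance = 1e-12)
  expect_equal(p$ncpr, 0.2)

  expect_equal(composition_profile(pld_sequence("z", "RKDE"))$ncpr, 0)
  ala <- composition_profile(pld_sequence("a", strrep("A", 10)))
  expect_equal(unname(ala$fractions["neutral"]), 1)
  expect_equal(ala$ncpr, 0)

  # histidine carries no charge by default but can be switched on
  his <- pld_sequence("h", "HHHH")
  expect_equal(composition_profile(his)$ncpr, 0)
  expect_equal(composition_profile(his, charge_model(his_charge = 1))$ncpr, 1)
})

test_that("variant labels parse, reject mismatches, and round-trip", {
  sp <- parse_variant_label("-12F+12Y")
  expect_equal(sp$source, "F")
  expect_equal(sp$target, "Y")
  expect_equal(sp$n, 12L)

  sp2 <- parse_variant_label("-3R+3K")
  expect_equal(c(sp2$source, sp2$target, sp2$n), c("R", "K", "3"))

  sp3 <- parse_variant_label("-10Y")
  expect_equal(sp3$target, "X")
  expect_equal(sp3$n, 10L)

  # Unicode minus accepted
  expect_equal(parse_variant_label("−12F+12Y")$n, 12L)
  expect_error(parse_variant_label("-3R+4K"), "counts must match")
  expect_error(parse_variant_label("gibberish"), "unparseable")

  for (lab in c("-12F+12Y", "-3R+3K", "-10Y", "-4F/Y")) {
    expect_equal(format_variant_label(parse_variant_label(lab)), lab)
  }
})

test_that("infer_mutation recovers substitutions and flags mixed types", {
  wt <- pld_sequence("wt", "YAY")
  expect_equal(infer_mutation(wt, wt)$n, 0L)

  v1 <- pld_sequence("v1", "FAY")
  sp <- infer_mutation(wt, v1)
  expect_equal(sp$source, "Y")
  expect_equal(sp$target, "F")
  expect_equal(sp$n, 1L)
  expect_equal(sp$positions, 1L)
  expect_false(sp$multi_type)

  wt2 <- pld_sequence("wt2", "YAR")
  v2 <- pld_sequence("v2", "FAK")
  expect_true(infer_mutation(wt2, v2)$multi_type)

  expect_error(infer_mutation(wt, pld_sequence("long", "YAYA")), "length")
})

test_that("design_variant places mutations evenly and preserves the rest", {
  wt <- pld_sequence("wt", "YAYAY")
  expect_identical(design_variant(wt, mutation_spec("Y", "F", 0)), wt)

  v <- design_variant(wt, mutation_spec("Y", "F", 2))
  expect_equal(format(v), "FAYAF")  # first and last occurrence

  # single mutation lands on the middle occurrence
  v1 <- design_variant(wt, mutation_spec("Y", "F", 1))
  expect_equal(format(v1), "YAFAY")

  expect_error(design_variant(wt, mutation_spec("Y", "F", 4)), "short by 1")
})

test_that("composition-biased replacement follows largest-remainder rounding", {
  # weak-residue counts S:2, G:2, A:4 -> replacements {S, G, A, A} for N=4
  wt <- pld_sequence("wt", "YSYSYGYGAAAA")
  v <- design_variant(wt, mutation_spec("Y", "X", 4), seed = 5)
  expect_equal(v$L, wt$L)
  cnt <- table(factor(v$residues, levels = c("S", "T", "G", "A", "Y")))
  expect_equal(unname(cnt[c("S", "G", "A", "Y")]),
               as.integer(c(3, 3, 6, 0)), ignore_attr = TRUE)
})

test_that("designed variants round-trip through infer_mutation", {
  set.seed(42)
  wt <- synth_pld_sequence(L = 120, seed = 9)
  for (spec in list(mutation_spec("Y", "F", 3),
                    mutation_spec("R", "K", 1),
                    mutation_spec("Y", "X", 5))) {
    v <- design_variant(wt, spec, seed = 3)
    expect_equal(v$L, wt$L)
    back <- infer_mutation(wt, v)
    expect_equal(back$n, spec$n)
    expect_true(all(back$source %in% spec$source))
    # residues outside source and replacement pool are untouched
    keep <- !wt$residues %in% c(spec$source, "S", "T", "G", "A",
                                spec$target)
    expect_equal(wt$residues[keep], v$residues[keep])
  }
})
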