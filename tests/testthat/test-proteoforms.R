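test_that("average_mass reproduces known peptide masses and rejects bad codes", {
  expect_equal(average_mass(""), mass_water, tolerance = 1e-9)
  expect_equal(average_mass("EFNPILPASPQAT"), 1384.55, tolerance = 0.01)
  expect_equal(round(average_mass("EFNPILPASPQAT")), 1385)
  expect_equal(average_mass("YGGFL"), 555.63, tolerance = 0.01)
  expect_equal(round(average_mass("YGGFL")), 556)
  expect_error(average_mass("ACXDE"), "unknown residue code 'X' at position 3")
})

test_that("average_mass agrees with a brute-force summation oracle", {
  set.seed(42)
  for (i in 1:25) {
    s <- random_peptide(sample(1:60, 1))
    expect_equal(average_mass(s), oracle_mass(s), tolerance = 1e-10)
  }
})

test_that("mz_of computes protonated m/z and is strictly decreasing in z", {
  expect_equal(mz_of(26354, 12), 2197.17, tolerance = 0.01)
  expect_equal(mz_of(24987, 10), 2499.71, tolerance = 0.01)
  expect_equal(mz_of(1000, 1), 1001.00728, tolerance = 1e-8)
  expect_error(mz_of(1000, 0), "positive integer")
  expect_error(mz_of(-5, 2))
  for (m in c(10, 1385, 26354)) {
    v <- mz_of(m, 1:20)
    expect_true(all(diff(v) < 0))
  }
})

test_that("cleave splits sequence with exact mass balance", {
  ab <- cleave(proteoform("ag", sequence = "AG", role = "zymogen"), 1)
  expect_equal(ab$propeptide$sequence, "A")
  expect_equal(ab$propeptide$neutral_mass + ab$mature$neutral_mass,
               average_mass("AG") + mass_water, tolerance = 0.01)
  z <- proteoform("wt", sequence = "EFNPILPASPQATIVGGEKALAG", role = "zymogen")
  cut <- cleave(z, 13)
  expect_equal(cut$propeptide$sequence, "EFNPILPASPQAT")
  expect_equal(cut$mature$sequence, "IVGGEKALAG")
  expect_equal(cut$propeptide$neutral_mass + cut$mature$neutral_mass,
               z$neutral_mass + mass_water, tolerance = 0.01)
  expect_error(cleave(z, 0), "outside")
  expect_error(cleave(z, nchar(z$sequence)), "outside")
})

test_that("cleavage mass balance holds for random sequences and cut points", {
  set.seed(7)
  for (i in 1:20) {
    s <- random_peptide(sample(4:40, 1))
    z <- proteoform("r", sequence = s, role = "zymogen")
    k <- sample(seq_len(nchar(s) - 1L), 1)
    cut <- cleave(z, k)
    expect_equal(paste0(cut$propeptide$sequence, cut$mature$sequence), s)
    expect_equal(cut$propeptide$neutral_mass + cut$mature$neutral_mass -
                   z$neutral_mass, mass_water, tolerance = 0.01)
  }
})

test_that("released-propeptide mass follows from zymogen/mature mass balance", {
  expect_equal(round(26354 - 24987 + mass_water), 1385)
})

test_that("proteoform validates sequence/mass consistency", {
  expect_error(proteoform("bad", sequence = "YGGFL", neutral_mass = 600),
               "disagrees")
  p <- proteoform("ok", sequence = "YGGFL", neutral_mass = 555.631)
  expect_equal(p$neutral_mass, 555.631)
})

test_that("construct catalogs expand with correct activatability classes", {
  forms <- enumerate_truncations(zymogen_catalog("P-A"))
  expect_length(forms, 7)
  expect_equal(attr(forms, "activatable_percent"), 94)
  s <- attr(forms, "summary")
  expect_equal(s$class[s$form_sequence == "ALAGE"], "non_activatable")
  expect_equal(sum(vapply(forms, function(p) p$fraction, numeric(1))), 1,
               tolerance = 0.01)

  single <- enumerate_truncations(zymogen_catalog("proDer p 3"))
  expect_length(single, 1)
  expect_equal(attr(single, "activatable_percent"), 100)
  expect_equal(single[[1]]$role, "zymogen")

  d11 <- enumerate_truncations(zymogen_catalog("d1-11"))
  expect_length(d11, 2)
  expect_true(all(startsWith(vapply(d11, function(p) p$sequence, character(1)),
                             "EA")))

  # unidentified rows count as unknown, not activatable
  d12 <- enumerate_truncations(zymogen_catalog("d1-2"))
  expect_equal(attr(d12, "summary")$class[3], "unknown")
  expect_equal(attr(d12, "activatable_percent"), 91)
})

test_that("abundance fractions sum to 1 for every catalogued construct", {
  for (nm in zymogen_constructs()) {
    forms <- enumerate_truncations(zymogen_catalog(nm))
    expect_equal(sum(vapply(forms, function(p) p$fraction, numeric(1))), 1,
                 tolerance = 0.01, label = nm)
  }
})

test_that("misaligned truncation forms and bad catalogs are rejected", {
  expect_error(enumerate_truncations(
    construct_catalog("x", c("EFNPILPASPQATIVGG", "WWWWW"), c(50, 50))),
    "does not align")
  expect_error(construct_catalog("x", "AAAA", 80), "sum")
  expect_error(zymogen_catalog("nope"), "valid names")
})

test_that("proline-rich motif detection finds period-3 runs only", {
  hits <- find_proline_rich_motif("NPILPASPNAT")
  expect_length(hits, 1)
  expect_equal(hits[[1]]$positions, c(2, 5, 8))
  expect_equal(hits[[1]]$motif, "PxxPxxP")
  expect_length(find_proline_rich_motif("NAILAASAQAT"), 0)
  expect_length(find_proline_rich_motif("PPP"), 0)
  # every reported position is a proline
  set.seed(11)
  for (i in 1:10) {
    s <- random_peptide(30)
    for (h in find_proline_rich_motif(s))
      expect_true(all(strsplit(s, "")[[1]][h$positions] == "P"))
  }
})

test_that("proteoform JSON export round-trips ids and masses", {
  path <- tempfile(fileext = ".json")
  forms <- enumerate_truncations(zymogen_catalog("P-A"))
  proteoforms_to_json(forms, path)
  back <- jsonlite::read_json(path)
  expect_length(back, 7)
  expect_equal(back[[1]]$construct, "P-A")
})
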