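test_that("chymotryptic digestion follows the F/Y/W/L/M-not-before-P rule", {
  expect_identical(chymotryptic_digest("AYLFK")$peptide,
                   c("AY", "L", "F", "K"))
  expect_identical(chymotryptic_digest("AYPK")$peptide, "AYPK")
  d <- chymotryptic_digest("NFTAL", 1)
  expect_true(all(c("NF", "TAL", "NFTAL") %in% d$peptide))
  expect_error(chymotryptic_digest("AXY"), "position 2")
})

test_that("digestion matches the brute-force subset oracle", {
  set.seed(11)
  alphabet <- c("A", "G", "S", "F", "Y", "L", "P", "K", "N", "T", "W", "M")
  for (i in 1:25) {
    seqn <- paste(sample(alphabet, sample(5:20, 1), replace = TRUE),
                  collapse = "")
    for (mc in 0:2) {
      got <- sort(unique(chymotryptic_digest(seqn, mc)$peptide))
      expect_identical(got, oracle_digest(seqn, mc), info = seqn)
    }
  }
})

test_that("digest positions are 1-based inclusive and consistent", {
  d <- chymotryptic_digest("AYLFK", 1)
  s <- "AYLFK"
  for (i in seq_len(nrow(d)))
    expect_identical(substr(s, d$start[i], d$end[i]), d$peptide[i])
})

test_that("FSH site peptides carry exactly one sequon at the right residue", {
  peps <- fsh_site_peptides()
  expect_named(peps, c("alpha_Asn52", "alpha_Asn78", "beta_Asn7",
                       "beta_Asn24"))
  seqs <- fsh_subunit_sequences()
  positions <- c(alpha_Asn52 = 52, alpha_Asn78 = 78, beta_Asn7 = 7,
                 beta_Asn24 = 24)
  subunit <- c(alpha_Asn52 = "alpha", alpha_Asn78 = "alpha",
               beta_Asn7 = "beta", beta_Asn24 = "beta")
  for (sid in names(peps)) {
    p <- peps[[sid]]
    expect_identical(find_sequons(p$sequence), p$glycosite_position)
    expect_identical(substr(p$sequence, p$glycosite_position,
                            p$glycosite_position), "N")
    # peptide occurs in the parent subunit at the stated global site
    start <- regexpr(p$sequence, seqs[[subunit[sid]]], fixed = TRUE)
    expect_equal(as.integer(start) + p$glycosite_position - 1L,
                 unname(positions[sid]))
    expect_gt(p$backbone_mass, 0)
  }
})

test_that("theoretical m/z follows the charge formula", {
  expect_equal(theoretical_mz(1000, 2204.772, 2), 1603.393, tolerance = 5e-4)
  expect_equal(theoretical_mz(1000, 2204.772, 1), 3205.779, tolerance = 5e-4)
  tbl <- monosaccharide_masses()
  core <- 2 * tbl$HexNAc + 3 * tbl$Hex
  # minimal composition at charge 1 equals backbone + glycan + one proton
  comp <- glycan_composition(antennae = 1)
  expect_equal(theoretical_mz(500, comp, 1),
               500 + glycan_residue_mass(comp) + tbl$proton)
  expect_error(theoretical_mz(1000, 2204.772, 0), "positive")
})

test_that("candidate ions outside the scan range are skipped", {
  pep <- site_peptide("alpha_Asn52", "VQKNVTSESTCCVAKSY")
  cand <- candidate_ions(pep, "A2G2S2", charges = 1:4)
  expect_true(all(cand$theoretical_mz >= 100 & cand$theoretical_mz <= 2000))
  # charge 1 of this ~4.2 kDa glycopeptide is > 2000 and must be absent
  expect_false(1L %in% cand$charge)
})

test_that("match_ions applies tolerance and nearest-wins rules", {
  cand <- data.frame(site_id = "s", peptide = "PEP",
                     glycan = c("X", "Y"), charge = 1L,
                     theoretical_mz = c(1000.000, 1000.008))
  pk <- peak_list(1, 1000.005, 100)
  hit <- match_ions(pk, cand[1, ], tolerance_ppm = 10)
  expect_equal(hit$ppm_error, 5, tolerance = 1e-6)
  expect_equal(hit$ion_count, 100)

  miss <- match_ions(peak_list(1, 1000.020, 100), cand[1, ],
                     tolerance_ppm = 10)
  expect_equal(miss$ion_count, 0)
  expect_true(is.na(miss$observed_mz))

  near <- match_ions(peak_list(1, 1000.003, 100), cand, tolerance_ppm = 10)
  expect_equal(near$ion_count[near$glycan == "X"], 100)
  expect_equal(near$ion_count[near$glycan == "Y"], 0)

  expect_warning(out <- match_ions(peak_list(numeric(), numeric(), numeric()),
                                   cand), "empty peak list")
  expect_true(all(out$ion_count == 0))
})

test_that("match_ions is stable under peak-order permutation", {
  set.seed(3)
  sim <- simulate_peaklist(ms_simulation_config(
    demo_targets(), noise_sigma = 0.2, mz_jitter_ppm = 2, seed = 5))
  cand <- candidate_ions(fsh_site_peptides()[names(demo_targets())],
                         unique(sim$truth$glycan))
  base <- match_ions(sim$peaklist, cand)
  perm <- sim$peaklist[sample(nrow(sim$peaklist)), ]
  shuffled <- match_ions(
    peak_list(perm$rt_min, perm$mz, perm$intensity), cand)
  expect_equal(base$ion_count, shuffled$ion_count)
})

test_that("extract_xic sums within ppm and RT windows, linearly", {
  pk <- peak_list(c(1, 1, 2), c(500.000, 500.001, 500.000), c(100, 50, 25))
  expect_equal(extract_xic(pk, 500.000, 10), 175)
  expect_equal(extract_xic(pk, 500.000, 10, rt_window = c(0.5, 1.5)), 150)
  expect_equal(extract_xic(pk, 500.000, 10, rt_window = c(5, 6)), 0)
  pk2 <- peak_list(pk$rt_min, pk$mz, 2 * pk$intensity)
  expect_equal(extract_xic(pk2, 500.000, 10), 2 * extract_xic(pk, 500.000, 10))
})

test_that("quantify_site normalizes, pools charges, is scale invariant", {
  a <- data.frame(site_id = "s", peptide = "PEP",
                  glycan = c("X", "X", "Y"), charge = c(2L, 3L, 2L),
                  ion_count = c(60, 40, 100))
  d <- quantify_site(a, "s")
  # pooling oracle: direct summation over charges
  expect_equal(d$percentage[d$species == "X"], 100 * 100 / 200)
  expect_equal(d$percentage[d$species == "Y"], 50)
  expect_equal(sum(d$percentage), 100, tolerance = 1e-6)

  a2 <- a; a2$ion_count <- a$ion_count * 7.3
  expect_equal(quantify_site(a2, "s")$percentage, d$percentage)

  a3 <- a; a3$ion_count <- 0
  expect_error(quantify_site(a3, "s"), "no quantifiable species")

  amix <- rbind(a, data.frame(site_id = "s", peptide = "OTHER", glycan = "Z",
                              charge = 2L, ion_count = 50))
  expect_error(quantify_site(amix, "s"), "multiple backbone")
  dmix <- quantify_site(amix, "s", pool_backbones = TRUE)
  expect_equal(sum(dmix$percentage), 100, tolerance = 1e-6)
})

test_that("simple counts example gives 75/25", {
  a <- data.frame(site_id = "s", peptide = "PEP", glycan = c("X", "Y"),
                  charge = 2L, ion_count = c(300, 100))
  d <- quantify_site(a, "s")
  expect_equal(d$percentage[order(d$species)], c(75, 25))
})

test_that("peak-list CSV round-trips and validates the scan range", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(rt_min = c(1, 2), mz = c(500, 900),
                              intensity = c(10, 20)), f, row.names = FALSE)
  pk <- read_peak_list(f)
  expect_s3_class(pk, "peak_list")
  expect_equal(nrow(pk), 2)
  expect_error(peak_list(1, 2500, 10), "scan range")
  expect_error(peak_list(1, 500, -1), "negative")
})
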