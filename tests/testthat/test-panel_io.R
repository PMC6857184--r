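test_that("build_spectrum counts, ranks and normalizes correctly", {
  p <- test_panel(3)
  h1 <- c("A", "A", "A"); h2 <- c("G", "A", "A"); h3 <- c("G", "G", "G")
  haps <- rbind(h1, h1, h1, h2, h2, h3)
  sp <- build_spectrum(haps, "toy")
  expect_equal(sp$entries$count, c(3L, 2L, 1L))
  expect_equal(sp$entries$frequency, c(3, 2, 1) / 6)
  expect_equal(sp$entries$rank_name, c("1", "2", "3"))
  expect_equal(sp$total, 6L)
  expect_equal(sum(sp$entries$frequency), 1)
  # permutation invariance
  set.seed(3)
  for (i in 1:5) {
    sp2 <- build_spectrum(haps[sample(nrow(haps)), ], "toy")
    expect_equal(sp2$entries, sp$entries)
  }
  # degenerate: identical haplotypes collapse to one entry
  one <- build_spectrum(rbind(h1, h1))
  expect_equal(nrow(one$entries), 1L)
  expect_equal(one$entries$frequency, 1)
  expect_equal(one$entries$rank_name, "1")
})

test_that("spectrum ties break lexicographically and errors are raised", {
  haps <- rbind(c("G", "A"), c("A", "G"))  # tie at count 1
  sp <- build_spectrum(haps)
  expect_equal(sp$entries$haplotype, c("A-G", "G-A"))
  expect_error(build_spectrum(matrix(character(0), 0, 2)), "empty")
  expect_error(build_spectrum(list(c("A", "G"), c("A"))), "mixed")
  expect_error(build_spectrum(rbind(c("A", NA))), "MISSING")
  expect_error(build_spectrum(rbind(c("A", "C/G"))), "AMBIGUOUS")
})

test_that("simulated VCF round-trips through the phased reader", {
  fx <- sim_fixture(seed = 5, n_samples = c(IBS = 3L))
  pp <- read_phased_vcf(fx$paths[["vcf"]], default_panel(), fx$paths[["popmap"]])
  expect_s3_class(pp, "population_panel")
  expect_equal(nrow(pp$haplotypes), 6L)
  # mutation site and microsatellite are not in reference VCFs
  expect_setequal(pp$dropped_markers, c("rs121912442", "CA_repeat"))
  expect_equal(ncol(pp$haplotypes), 14L)
  orig <- sample_panel(fx$cfg)$pp
  expect_equal(unname(pp$haplotypes), unname(orig$haplotypes))
})

test_that("markers absent from the VCF are dropped panel-wide", {
  fx <- sim_fixture(seed = 6, n_samples = c(IBS = 2L))
  lines <- readLines(fx$paths[["vcf"]])
  writeLines(lines[!grepl("rs202445", lines)], fx$paths[["vcf"]])
  pp <- read_phased_vcf(fx$paths[["vcf"]],
                        subset_panel(default_panel(), preset = "pop14"),
                        fx$paths[["popmap"]])
  expect_equal(pp$dropped_markers, "rs202445")
  expect_equal(ncol(pp$haplotypes), 13L)
})

test_that("reader rejects unphased genotypes, unmapped samples, empty overlap", {
  fx <- sim_fixture(seed = 7, n_samples = c(IBS = 2L))
  lines <- readLines(fx$paths[["vcf"]])
  k <- grep("rs2070424", lines)
  lines[k] <- sub("(\\t[01])\\|([01])$", "\\1/\\2", lines[k])
  bad <- tempfile(fileext = ".vcf")
  writeLines(lines, bad)
  expect_error(read_phased_vcf(bad, default_panel(), fx$paths[["popmap"]]),
               "unphased.*SIM0002.*rs2070424")

  pm <- utils::read.table(fx$paths[["popmap"]], header = TRUE, sep = "\t",
                          colClasses = "character")
  expect_error(read_phased_vcf(fx$paths[["vcf"]], default_panel(),
                               pm[-1, , drop = FALSE]),
               "missing from population map.*SIM0001")

  alien <- test_panel(2)
  expect_error(read_phased_vcf(fx$paths[["vcf"]], alien, fx$paths[["popmap"]]),
               "zero panel markers")
})

test_that("haplotype extraction selects populations and super-populations", {
  spectra <- list(IBS = default_spectrum(), CEU = default_spectrum(),
                  YRI = default_spectrum())
  cfg <- sim_config(spectra = spectra,
                    n_samples = c(IBS = 3L, CEU = 2L, YRI = 4L), seed = 9)
  pp <- sample_panel(cfg)$pp
  expect_equal(nrow(extract_haplotypes(pp)), 18L)
  ibs <- extract_haplotypes(pp, "IBS")
  expect_equal(nrow(ibs), 6L)
  expect_true(all(grepl("^SIM000[123]_", rownames(ibs))))
  # European super-population = {CEU, FIN, GBR, IBS, TSI}
  eur <- extract_haplotypes(pp, "European")
  expect_equal(nrow(eur), 10L)
  expect_error(extract_haplotypes(pp, "XXX"), "valid codes")
})

test_that("GWC legacy code maps to GWD with a message", {
  expect_message(out <- normalize_pop_codes(c("GWC", "IBS")), "GWD")
  expect_equal(out, c("GWD", "IBS"))
})

test_that("cross-population table pools groups consistently", {
  # two populations fixed to disjoint single haplotypes
  sp <- default_spectrum()
  one <- function(i) list(haplotypes = sp$haplotypes[i, , drop = FALSE],
                          frequencies = 1)
  cfg <- sim_config(spectra = list(P1 = one(1), P2 = one(2)),
                    n_samples = c(P1 = 3L, P2 = 2L), seed = 4)
  pp <- sample_panel(cfg)$pp
  tab <- cross_population_table(pp, list(G1 = "P1", G2 = "P2"))
  expect_equal(nrow(tab), 2L)
  r1 <- tab[tab$G1_freq == 1, ]
  expect_equal(r1$G2_freq, 0)
  expect_equal(r1$all_count, 6L)
  # pooled column equals the 2N-weighted mean of group frequencies
  expect_equal(tab$all_freq,
               (tab$G1_freq * 6 + tab$G2_freq * 4) / 10)
  # pooled frequencies reproduce build_spectrum on the pooled haplotypes
  pooled <- build_spectrum(extract_haplotypes(pp, c("P1", "P2")))
  expect_equal(tab$haplotype, pooled$entries$haplotype)
  expect_equal(tab$all_freq, pooled$entries$frequency)
  expect_error(cross_population_table(pp, list()), "empty grouping")
})

test_that("spectrum counts always sum to twice the sample count", {
  for (s in 1:5) {
    cfg <- sim_config(n_samples = c(IBS = 10L + s), seed = 100 + s)
    pp <- sample_panel(cfg)$pp
    sp <- build_spectrum(extract_haplotypes(pp, "IBS"))
    expect_equal(sum(sp$entries$count), 2L * (10L + s))
  }
})

test_that("background rank labels carry the mutation suffix", {
  sp <- spectrum_from_frequencies(default_spectrum()$haplotypes,
                                  default_spectrum()$frequencies)
  bg <- c(sp$haplotypes[1, ], rs121912442 = "T")
  expect_equal(background_rank_label(sp, bg, "rs121912442", "T"), "1V")
  bg["rs121912442"] <- "C"
  expect_equal(background_rank_label(sp, bg, "rs121912442", "T"), "1A")
  expect_equal(background_rank_label(sp, sp$haplotypes[3, ]), "3")
})
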