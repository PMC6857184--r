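test_that("sim_config validates its inputs", {
  expect_error(sim_config(spectra = list(IBS = list(
    haplotypes = default_spectrum()$haplotypes,
    frequencies = rep(0.2, 8)))), "sum to 1")
  expect_error(sim_config(family = list(father_carrier = TRUE),
                          mutation = NULL), "carrier flag set")
  expect_error(sim_config(family = list(background_rank = 99L)),
               "background_rank")
  expect_error(sample_panel(sim_config(n_samples = c(IBS = 0L))),
               "zero samples")
})

test_that("a single-haplotype spectrum yields only homozygotes", {
  sp <- default_spectrum()
  cfg <- sim_config(spectra = list(IBS = list(
    haplotypes = sp$haplotypes[1, , drop = FALSE], frequencies = 1)),
    n_samples = c(IBS = 5L), seed = 2)
  pp <- sample_panel(cfg)$pp
  expect_equal(nrow(unique(pp$haplotypes)), 1L)
  expect_equal(unname(pp$haplotypes[1, ]), unname(sp$haplotypes[1, ]))
})

test_that("generation is seed-deterministic and seed-sensitive", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  p1 <- write_fixture_set(sim_config(seed = 42, n_samples = c(IBS = 8L)), d1)
  p2 <- write_fixture_set(sim_config(seed = 42, n_samples = c(IBS = 8L)), d2)
  p3 <- write_fixture_set(sim_config(seed = 43, n_samples = c(IBS = 8L)), d3)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     info = paste("file", f))
  }
  expect_false(identical(readLines(p1[["vcf"]]), readLines(p3[["vcf"]])))
})

test_that("one draw at study scale lands within binomial sampling error", {
  cfg <- sim_config(seed = 7)  # defaults: IBS, n = 102 diploids
  pp <- sample_panel(cfg)$pp
  est <- build_spectrum(extract_haplotypes(pp, "IBS"))
  gen <- spectrum_from_frequencies(default_spectrum()$haplotypes,
                                   default_spectrum()$frequencies)
  est_freq <- est$entries$frequency[match(gen$entries$haplotype,
                                          est$entries$haplotype)]
  est_freq[is.na(est_freq)] <- 0
  p <- gen$entries$frequency
  se <- sqrt(p * (1 - p) / 204)
  expect_true(all(abs(est_freq - p) <= 3 * se))
})

test_that("family generation implants the mutation on the configured background", {
  cfg <- sim_config(seed = 13)
  fam <- make_family(cfg)
  tr <- fam$truth
  expect_equal(unname(tr$background[cfg$mutation$marker]), "T")
  ref_ids <- colnames(cfg$spectra$IBS$haplotypes)
  expect_equal(unname(tr$background[ref_ids]),
               unname(cfg$spectra$IBS$haplotypes[1, ]))
  # carriers are exactly the offspring that inherited the father's first
  # haplotype, and their genotypes carry the mutant allele
  pat <- tr$transmissions[, "pat"]
  expect_equal(tr$carriers, rownames(tr$transmissions)[pat == 1L])
  for (cr in tr$carriers) {
    expect_true("T" %in% fam$genos[[cr]][cfg$mutation$marker, ])
  }
})

test_that("identical homozygous parents give identical offspring", {
  sp <- default_spectrum()
  cfg <- sim_config(spectra = list(IBS = list(
    haplotypes = sp$haplotypes[1, , drop = FALSE], frequencies = 1)),
    family = list(n_offspring = 3L, father_carrier = FALSE),
    mutation = NULL, seed = 3)
  fam <- make_family(cfg)
  offs <- fam$genos[grep("^II", names(fam$genos))]
  # markers outside the spectrum (mutation site, microsatellite) get
  # per-haplotype uniform draws, so only the reference markers are forced
  ref_ids <- colnames(sp$haplotypes)
  for (o in offs) {
    expect_equal(unname(o[ref_ids, 1]), unname(o[ref_ids, 2]))
    expect_equal(unname(o[ref_ids, 1]), unname(offs[[1]][ref_ids, 1]))
  }
})

test_that("fixture sets are re-readable and consistent with their truth record", {
  es <- emulate_study(seed = 3)
  dir <- tempfile()
  paths <- write_fixture_set(es$cfg, dir)
  expect_length(paths, 5L)
  pp <- read_phased_vcf(paths[["vcf"]], default_panel(), paths[["popmap"]])
  expect_equal(nrow(pp$samples), sum(es$cfg$n_samples))
  ped <- read_ped(paths[["ped"]])
  panel <- default_panel()
  gn <- read_genotypes(paths[["genotypes"]], panel)
  pr <- enumerate_phasings(ped, gn, panel)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  bg <- carrier_background(pr, "rs121912442", "T",
                           c("I:1", truth$family$carriers), genos = gn)
  expect_equal(hap_string(bg), truth$family$background)
  expect_equal(truth$seed, es$cfg$seed)
})

test_that("the genotyping-error knob produces Mendelian inconsistencies", {
  cfg <- sim_config(family = list(n_offspring = 4L, error_rate = 0.4,
                                  parents_genotyped = c(father = TRUE,
                                                        mother = TRUE)),
                    seed = 5)
  fam <- make_family(cfg)
  expect_error(enumerate_phasings(fam$ped, fam$genos, cfg$panel),
               "Mendelian-inconsistent")
})

test_that("phasing recovery invariants hold on generated families", {
  # both parents genotyped: the truth transmissions appear among solutions
  for (s in 1:10) {
    cfg <- sim_config(family = list(parents_genotyped = c(father = TRUE,
                                                          mother = TRUE)),
                      seed = 300 + s)
    fam <- make_family(cfg)
    pr <- enumerate_phasings(fam$ped, fam$genos, cfg$panel)
    truth_key <- canonical_key(fam$truth$father_haplotypes,
                               fam$truth$mother_haplotypes,
                               fam$truth$transmissions)
    expect_true(truth_key %in% solution_keys(pr),
                info = paste("seed", 300 + s))
  }
  # no parents genotyped: the implanted scenario is itself a phase
  # solution, so every position the consensus background does force must
  # agree with the implanted background
  for (s in 1:5) {
    cfg <- sim_config(seed = 400 + s)
    fam <- make_family(cfg)
    if (!length(fam$truth$carriers)) next
    # SNP sub-panel: a 4-allele microsatellite in a sibship with untyped
    # parents can push the exact enumeration past the configuration cap
    p15 <- subset_panel(cfg$panel, keep_ids = cfg$panel$id[cfg$panel$kind == "snp"])
    pr <- enumerate_phasings(fam$ped, fam$genos, p15)
    bg <- carrier_background(pr, cfg$mutation$marker, cfg$mutation$allele,
                             c("I:1", fam$truth$carriers),
                             genos = fam$genos)
    forced <- !is.na(bg)
    expect_true(any(forced))
    expect_equal(unname(bg[forced]),
                 unname(fam$truth$background[pr$panel_ids][forced]),
                 info = paste("seed", 400 + s))
  }
})
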