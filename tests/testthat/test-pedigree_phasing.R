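table1_family <- function() {
  p <- default_panel()
  p15 <- subset_panel(p, keep_ids = p$id[p$kind == "snp"])
  list(panel = p15,
       ped = read_ped(extdata("sod1_family.ped")),
       genos = read_genotypes(extdata("sod1_family_genotypes.tsv"), p15))
}

test_that("a fully homozygous offspring forces its own haplotype pair", {
  panel <- test_panel(4)
  hom <- sample_genotypes(panel, rep("A", 4), rep("A", 4))
  ped <- pedigree(data.frame(id = c("F", "M", "O1"),
                             father = c(NA, NA, "F"),
                             mother = c(NA, NA, "M"),
                             sex = c(1, 2, 0), affected = FALSE))
  pr <- enumerate_phasings(ped, list(O1 = hom), panel)
  expect_equal(length(pr$solutions), 1L)
  s <- pr$solutions[[1]]
  expect_equal(unname(s$father[s$transmissions["O1", "pat"], ]), rep("A", 4))
  expect_equal(unname(s$mother[s$transmissions["O1", "mat"], ]), rep("A", 4))
})

test_that("the affected brothers force the published mutation background", {
  fam <- table1_family()
  pr <- enumerate_phasings(fam$ped, fam$genos, fam$panel)
  expect_gt(length(pr$solutions), 0L)
  bg <- carrier_background(pr, "rs121912442", "T",
                           c("I:1", "II:1", "II:5"), genos = fam$genos)
  # II:1 is heterozygous only at the mutation site, so the background is
  # fully forced; it must equal the Iberian founder haplotype everywhere
  expect_false(anyNA(bg))
  founders <- read_founders()
  ibs <- founders$IBS
  expect_equal(unname(bg[names(ibs)]), unname(ibs))
  # and every solution carries the wild-type sister haplotype too
  expect_true(hap_string(ibs) %in%
                apply(pr$family_haplotypes, 1, hap_string))
})

test_that("exhaustive search agrees with the naive phase-ordering oracle", {
  for (s in 1:60) {
    fam <- random_family(1000 + s)
    pr <- enumerate_phasings(fam$ped, fam$genos, fam$panel)
    expect_equal(solution_keys(pr),
                 oracle_phasings(fam$genos[["F"]], fam$genos[["M"]],
                                 fam$genos[grep("^O", names(fam$genos))]),
                 info = paste("family seed", 1000 + s))
  }
})

test_that("duplicating a homozygous offspring leaves founder haplotypes unchanged", {
  # a second, identical fully homozygous sib adds no phase information:
  # the set of founder haplotype configurations must not move
  founder_keys <- function(pr) {
    sort(unique(vapply(pr$solutions, function(s) {
      paste(sort(c(apply(s$father, 1, paste, collapse = "-"),
                   apply(s$mother, 1, paste, collapse = "-"))),
            collapse = "|")
    }, "")))
  }
  for (s in 1:15) {
    set.seed(2000 + s)
    L <- sample(2:4, 1)
    panel <- test_panel(L)
    h <- vapply(panel$alleles, function(al) sample(al, 1), "")
    other <- function() vapply(panel$alleles, function(al) sample(al, 1), "")
    fh <- list(h, other()); mh <- list(h, other())
    strip <- function(a, b) sample_genotypes(panel, a, b)
    genos <- list("F" = strip(fh[[1]], fh[[2]]), "M" = strip(mh[[1]], mh[[2]]),
                  O1 = strip(fh[[sample(2, 1)]], mh[[sample(2, 1)]]),
                  O2 = strip(h, h))  # homozygous: h from both parents
    make_ped <- function(off) pedigree(data.frame(
      id = c("F", "M", off), father = c(NA, NA, rep("F", length(off))),
      mother = c(NA, NA, rep("M", length(off))), sex = 0, affected = FALSE))
    pr1 <- enumerate_phasings(make_ped(c("O1", "O2")), genos, panel)
    genos$O3 <- strip(h, h)
    pr2 <- enumerate_phasings(make_ped(c("O1", "O2", "O3")), genos, panel)
    expect_equal(founder_keys(pr2), founder_keys(pr1))
  }
})

test_that("carrier_background is invariant under carrier permutation", {
  es <- emulate_study(seed = 11)
  perm <- rev(es$carriers)
  bg2 <- carrier_background(es$phase, es$cfg$mutation$marker,
                            es$cfg$mutation$allele, perm,
                            genos = es$family$genos)
  expect_equal(as.vector(bg2), as.vector(es$background))
})

test_that("Mendelian inconsistency is reported with marker and trio", {
  panel <- test_panel(2, list(c("C", "A"), c("C", "A")))
  ped <- pedigree(data.frame(id = c("F", "M", "O1"),
                             father = c(NA, NA, "F"),
                             mother = c(NA, NA, "M"),
                             sex = c(1, 2, 0), affected = FALSE))
  genos <- list("F" = sample_genotypes(panel, c("C", "C"), c("C", "C")),
                O1 = sample_genotypes(panel, c("A", "C"), c("A", "C")))
  expect_error(enumerate_phasings(ped, genos, panel),
               "Mendelian-inconsistent at marker m1.*O1")
  # sibship-level conflict without a trio violation: five distinct paternal
  # alleles cannot come from one parent pair
  ms_panel <- marker_panel(data.frame(id = "ca", kind = "microsatellite",
                                      alleles = "10,11,12,13,14,15"))
  g5 <- list(O1 = sample_genotypes(ms_panel, "10", "11"),
             O2 = sample_genotypes(ms_panel, "12", "13"),
             O3 = sample_genotypes(ms_panel, "14", "15"))
  ped5 <- pedigree(data.frame(id = c("F", "M", "O1", "O2", "O3"),
                              father = c(NA, NA, "F", "F", "F"),
                              mother = c(NA, NA, "M", "M", "M"),
                              sex = 0, affected = FALSE))
  expect_error(enumerate_phasings(ped5, g5, ms_panel),
               "Mendelian-inconsistent at marker ca")
})

test_that("the enumeration cap triggers a helpful error", {
  fam <- table1_family()
  expect_error(enumerate_phasings(fam$ped, fam$genos, fam$panel, cap = 2),
               "cap")
})

test_that("carrier validation catches missing alleles and markers", {
  fam <- table1_family()
  pr <- enumerate_phasings(fam$ped, fam$genos, fam$panel)
  expect_error(carrier_background(pr, "rs_nope", "T", "II:1"), "not in panel")
  expect_error(carrier_background(pr, "rs4817415", "G", "II:1",
                                  genos = fam$genos), "lacks allele")
  expect_error(carrier_background(pr, "rs121912442", "T", "II:9"),
               "not in family")
})

test_that("homozygosity forcing recovers the background without a pedigree", {
  panel <- test_panel(3, list(c("A", "G"), c("C", "T"), c("C", "T")))
  g <- sample_genotypes(panel, c("A", "C", "T"), c("A", "T", "C"))
  bg <- genotype_background(g, "m3", "T")
  expect_equal(unname(bg), c("A", NA, "T"))
  g_hom <- sample_genotypes(panel, c("A", "C", "T"), c("A", "C", "T"))
  expect_equal(unname(genotype_background(g_hom, "m3", "T")),
               c("A", "C", "T"))
  expect_error(genotype_background(g, "m1", "G"), "lacks allele")
})
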