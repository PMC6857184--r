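# Seed-deterministic synthetic data: phased population panels drawn from a
# configured haplotype spectrum, nuclear families with a rare mutation
# implanted on a chosen founder background, and phase-stripped genotypes.
# The generator emulates the data layout of a founder-haplotype study (a
# reference population of ~100 diploids with a handful of region
# haplotypes; one sibship segregating a private mutation); it does not
# model recombination, LD decay or demography.

#' Default IBS-like haplotype spectrum for simulation
#'
#' Eight distinct haplotypes over the 14 reference SNPs of the packaged
#' panel, at frequencies 0.45, 0.20, 0.12, 0.08, 0.06, 0.04, 0.03, 0.02.
#' Haplotype 1 is the Iberian mutation background of the packaged founder
#' table; haplotype 2 is the North-American-style background; the rest are
#' single-site variants of these. The frequencies are configuration, not
#' estimates: real spectra are supplied via [build_spectrum()].
#'
#' @param panel the panel whose `pop14` subset the spectrum covers
#'   (default [default_panel()]).
#' @return List with `haplotypes` (8 x 14 character matrix) and
#'   `frequencies`.
#' @export
default_spectrum <- function(panel = default_panel()) {
  ref <- subset_panel(panel, preset = "pop14")
  founders <- read_founders()
  h1 <- unname(founders$IBS[ref$id])
  h2 <- unname(founders$USA[ref$id])
  h2[is.na(h2)] <- h1[is.na(h2)]  # rs202445 untyped in the USA background
  flip <- function(h, k) {
    al <- ref$alleles[[k]]
    h[k] <- setdiff(al, h[k])[1]
    h
  }
  haps <- rbind(h1, h2,
                flip(h1, 1L),
                flip(h2, 2L),
                flip(h1, 6L),
                flip(flip(h1, 3L), 4L),
                flip(h2, 1L),
                flip(h1, 5L))
  dimnames(haps) <- list(NULL, ref$id)
  list(haplotypes = haps,
       frequencies = c(0.45, 0.20, 0.12, 0.08, 0.06, 0.04, 0.03, 0.02))
}

#' Turn a configured spectrum into a `hap_spectrum` reference object
#'
#' Expands frequency-weighted haplotypes into exact counts (out of `total`
#' chromosomes) and delegates naming to [build_spectrum()], so rank naming
#' follows the same descending-frequency convention as estimated spectra.
#'
#' @param haplotypes character matrix of distinct haplotypes.
#' @param frequencies matching frequency vector (sums to 1).
#' @param total chromosome count used to form exact counts; must make every
#'   `frequency * total` an integer (default 200 suits the default
#'   spectrum).
#' @param label spectrum label.
#' @return A `hap_spectrum`.
#' @export
spectrum_from_frequencies <- function(haplotypes, frequencies, total = 200,
                                      label = "configured") {
  counts <- frequencies * total
  if (any(abs(counts - round(counts)) > 1e-9)) {
    stop("total must turn every frequency into an integer count")
  }
  build_spectrum(haplotypes[rep(seq_len(nrow(haplotypes)), round(counts)), ,
                            drop = FALSE],
                 label = label)
}

#' Simulation configuration
#'
#' Bundles and validates everything the generator needs. The defaults
#' emulate the study conditions of a founder-haplotype analysis: one
#' reference population (`IBS`) of 102 diploids drawn from the default
#' 8-haplotype spectrum, and a nuclear family of 4 offspring whose
#' (ungenotyped) affected father carries the mutant allele `T` at
#' rs121912442 on the rank-1 background.
#'
#' @param panel full family panel (default the packaged 16-marker panel;
#'   reference spectra cover its `pop14` subset).
#' @param spectra named list per population: `list(haplotypes, frequencies)`.
#' @param n_samples named integer vector of diploid sample counts per
#'   population.
#' @param family list: `n_offspring`, `father_carrier`, `mother_carrier`,
#'   `background_rank`, `parents_genotyped` (length-2 logical),
#'   `error_rate` (per-allele genotype error probability, default 0).
#' @param mutation list `marker`, `allele`; `NULL` only if no parent is a
#'   carrier.
#' @param seed integer seed; fully determines all generator output.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(panel = default_panel(),
                       spectra = list(IBS = default_spectrum(panel)),
                       n_samples = c(IBS = 102L),
                       family = list(),
                       mutation = list(marker = "rs121912442", allele = "T"),
                       seed = 1L) {
  fam_defaults <- list(n_offspring = 4L, father_carrier = TRUE,
                       mother_carrier = FALSE, background_rank = 1L,
                       parents_genotyped = c(father = FALSE, mother = FALSE),
                       error_rate = 0)
  family <- utils::modifyList(fam_defaults, family)
  for (pop in names(spectra)) {
    sp <- spectra[[pop]]
    if (abs(sum(sp$frequencies) - 1) > 1e-9) {
      stop("spectrum frequencies for ", pop, " do not sum to 1")
    }
    if (nrow(sp$haplotypes) != length(sp$frequencies)) {
      stop("spectrum for ", pop, ": haplotype/frequency length mismatch")
    }
  }
  if ((family$father_carrier || family$mother_carrier) && is.null(mutation)) {
    stop("carrier flag set but mutation unset")
  }
  if (!is.null(mutation) && !mutation$marker %in% panel$id) {
    stop("mutation marker ", mutation$marker, " not in panel")
  }
  carrier_pop <- names(spectra)[1]
  if (family$background_rank > nrow(spectra[[carrier_pop]]$haplotypes)) {
    stop("background_rank exceeds the carrier population's spectrum size")
  }
  structure(list(panel = panel, spectra = spectra, n_samples = n_samples,
                 family = family, mutation = mutation,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# draw one haplotype index from a spectrum
draw_rank <- function(sp) sample.int(length(sp$frequencies), 1L,
                                     prob = sp$frequencies)

# extend a reference-marker haplotype to the full family panel: wild-type
# base at the mutation site, uniform repeat allele at a microsatellite
extend_haplotype <- function(h_ref, panel, mutation) {
  full <- stats::setNames(rep(NA_character_, nrow(panel)), panel$id)
  full[names(h_ref)] <- h_ref
  for (k in which(is.na(full))) {
    al <- panel$alleles[[k]]
    id <- panel$id[k]
    if (!is.null(mutation) && id == mutation$marker) {
      full[k] <- setdiff(al, mutation$allele)[1]
    } else {
      full[k] <- al[sample.int(length(al), 1L)]
    }
  }
  full
}

#' Simulate a phased reference population panel
#'
#' Draws two haplotypes per sample i.i.d. from each population's configured
#' spectrum over the reference markers (the `pop14` subset: reference
#' panels carry neither the private mutation nor the microsatellite).
#'
#' @param cfg a [sim_config].
#' @return List with `pp` (a `population_panel`) and `truth` (data frame of
#'   the drawn spectrum ranks per chromosome).
#' @export
sample_panel <- function(cfg) {
  if (!length(cfg$n_samples) || sum(cfg$n_samples) == 0L) {
    stop("zero samples configured")
  }
  set.seed(cfg$seed)
  ref_ids <- colnames(cfg$spectra[[1]]$haplotypes)
  ref_panel <- subset_panel(cfg$panel, keep_ids = ref_ids)
  hap_rows <- list()
  truth <- list()
  samples <- list()
  si <- 0L
  for (pop in names(cfg$n_samples)) {
    sp <- cfg$spectra[[pop]]
    if (is.null(sp)) stop("no spectrum configured for population ", pop)
    for (s in seq_len(cfg$n_samples[[pop]])) {
      si <- si + 1L
      sid <- sprintf("SIM%04d", si)
      r1 <- draw_rank(sp)
      r2 <- draw_rank(sp)
      hap_rows[[2L * si - 1L]] <- sp$haplotypes[r1, ]
      hap_rows[[2L * si]] <- sp$haplotypes[r2, ]
      truth[[si]] <- data.frame(sample_id = sid, rank_1 = r1, rank_2 = r2,
                                population = pop, stringsAsFactors = FALSE)
      samples[[si]] <- data.frame(sample_id = sid, population = pop,
                                  super_population = "Simulated",
                                  stringsAsFactors = FALSE)
    }
  }
  hap <- do.call(rbind, hap_rows)
  rownames(hap) <- paste0(rep(vapply(samples, `[[`, "", "sample_id"),
                              each = 2), "_", 1:2)
  pp <- structure(list(samples = do.call(rbind, samples),
                       haplotypes = hap,
                       panel = ref_panel,
                       dropped_markers = setdiff(cfg$panel$id, ref_ids)),
                  class = "population_panel")
  list(pp = pp, truth = do.call(rbind, truth))
}

#' Simulate a nuclear family segregating an implanted mutation
#'
#' Parents are drawn from the (first) configured spectrum over the
#' reference markers, extended to the full family panel; the mutant allele
#' is implanted on the carrier parent's first haplotype, which is set to
#' the spectrum haplotype of rank `background_rank`. Offspring inherit one
#' haplotype per parent uniformly, with no recombination; returned
#' genotypes are phase-stripped (random slot order), and only individuals
#' flagged as genotyped appear in `genos`.
#'
#' @param cfg a [sim_config].
#' @return List with `ped` (a [pedigree]), `genos` (named genotype list)
#'   and `truth` (parental haplotypes, transmissions, carrier ids, the
#'   implanted `background` and its rank).
#' @export
make_family <- function(cfg) {
  set.seed(cfg$seed + 1L)
  fam <- cfg$family
  if (fam$n_offspring < 1L) stop("n_offspring must be >= 1")
  sp <- cfg$spectra[[1]]
  draw_full <- function() {
    extend_haplotype(sp$haplotypes[draw_rank(sp), ], cfg$panel, cfg$mutation)
  }
  father_h <- list(draw_full(), draw_full())
  mother_h <- list(draw_full(), draw_full())
  background <- NULL
  if (fam$father_carrier || fam$mother_carrier) {
    bg <- extend_haplotype(sp$haplotypes[fam$background_rank, ], cfg$panel,
                           cfg$mutation)
    bg[cfg$mutation$marker] <- cfg$mutation$allele
    if (fam$father_carrier) father_h[[1]] <- bg else mother_h[[1]] <- bg
    background <- bg
  }
  n <- fam$n_offspring
  trans <- cbind(pat = sample.int(2L, n, replace = TRUE),
                 mat = sample.int(2L, n, replace = TRUE))
  off_ids <- paste0("II:", seq_len(n))
  rownames(trans) <- off_ids
  carriers <- character(0)
  genos <- list()
  maybe_err <- function(h) {
    if (fam$error_rate <= 0) return(h)
    for (k in seq_along(h)) {
      if (stats::runif(1) < fam$error_rate) {
        al <- cfg$panel$alleles[[k]]
        h[k] <- sample(setdiff(al, h[k]), 1L)
      }
    }
    h
  }
  strip <- function(h1, h2) {
    m <- matrix(NA_character_, length(h1), 2,
                dimnames = list(cfg$panel$id, c("a1", "a2")))
    for (k in seq_along(h1)) {
      pair <- c(h1[k], h2[k])
      m[k, ] <- pair[sample.int(2L)]
    }
    m
  }
  off_affected <- logical(n)
  for (o in seq_len(n)) {
    hp <- maybe_err(father_h[[trans[o, "pat"]]])
    hm <- maybe_err(mother_h[[trans[o, "mat"]]])
    genos[[off_ids[o]]] <- strip(hp, hm)
    carries <- (fam$father_carrier && trans[o, "pat"] == 1L) ||
               (fam$mother_carrier && trans[o, "mat"] == 1L)
    if (carries) carriers <- c(carriers, off_ids[o])
    off_affected[o] <- carries
  }
  pg <- fam$parents_genotyped
  if (is.null(names(pg))) names(pg) <- c("father", "mother")
  parent_genos <- list(
    "I:1" = strip(maybe_err(father_h[[1]]), maybe_err(father_h[[2]])),
    "I:2" = strip(maybe_err(mother_h[[1]]), maybe_err(mother_h[[2]])))
  if (isTRUE(pg[["father"]])) genos[["I:1"]] <- parent_genos[["I:1"]]
  if (isTRUE(pg[["mother"]])) genos[["I:2"]] <- parent_genos[["I:2"]]
  ped <- pedigree(data.frame(
    id = c("I:1", "I:2", off_ids),
    father = c(NA, NA, rep("I:1", n)),
    mother = c(NA, NA, rep("I:2", n)),
    sex = c(1L, 2L, rep(0L, n)),
    affected = c(fam$father_carrier, fam$mother_carrier, off_affected),
    stringsAsFactors = FALSE))
  list(ped = ped, genos = genos,
       truth = list(father_haplotypes = do.call(rbind, father_h),
                    mother_haplotypes = do.call(rbind, mother_h),
                    transmissions = trans,
                    carriers = carriers,
                    background = background,
                    background_rank = fam$background_rank))
}

#' Write a phased haplotype panel as VCF
#'
#' Minimal VCF 4.2 writer for simulated panels: biallelic-or-more SNP
#' records in panel order with synthetic positions, phased GT fields and
#' the generator seed recorded in the header. Output is byte-identical for
#' identical input.
#'
#' @param pp a `population_panel`.
#' @param path output VCF path.
#' @param seed seed recorded in the `##source` header line.
#' @return `path`, invisibly.
#' @export
write_sim_vcf <- function(pp, path, seed = NA) {
  panel <- pp$panel
  samples <- pp$samples$sample_id
  hap <- pp$haplotypes
  lines <- c("##fileformat=VCFv4.2",
             paste0("##source=founderhap_simulate seed=", seed),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (k in seq_len(nrow(panel))) {
    al <- panel$alleles[[k]]
    obs <- unique(hap[, k])
    alleles <- c(al[1], setdiff(union(al, obs), al[1]))
    gt <- vapply(seq_along(samples), function(s) {
      i1 <- match(hap[2L * s - 1L, k], alleles) - 1L
      i2 <- match(hap[2L * s, k], alleles) - 1L
      paste0(i1, "|", i2)
    }, "")
    pos <- if (is.na(panel$pos[k])) 1000000L + k * 1000L else panel$pos[k]
    lines <- c(lines,
               paste(c(panel$chrom[k] %||% "21", pos, panel$id[k], alleles[1],
                       paste(alleles[-1], collapse = ","), ".", "PASS", ".",
                       "GT", gt), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a complete simulated fixture set
#'
#' Emits everything the pipeline reads — phased VCF, population map TSV,
#' PED, long-format genotype TSV — plus `truth.json` recording the drawn
#' haplotypes, transmissions and implanted background. Deterministic per
#' seed.
#'
#' @param cfg a [sim_config].
#' @param outdir output directory (created if needed).
#' @return Named character vector of the five written paths, invisibly.
#' @export
write_fixture_set <- function(cfg, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || !dir.exists(outdir)) stop("cannot create output directory ", outdir)
  sim <- sample_panel(cfg)
  fam <- make_family(cfg)
  paths <- c(vcf = file.path(outdir, "panel.vcf"),
             popmap = file.path(outdir, "popmap.tsv"),
             ped = file.path(outdir, "family.ped"),
             genotypes = file.path(outdir, "genotypes.tsv"),
             truth = file.path(outdir, "truth.json"))
  write_sim_vcf(sim$pp, paths["vcf"], seed = cfg$seed)
  utils::write.table(
    data.frame(sample = sim$pp$samples$sample_id,
               population = sim$pp$samples$population,
               super_population = sim$pp$samples$super_population),
    paths["popmap"], sep = "\t", quote = FALSE, row.names = FALSE)
  ped <- fam$ped
  utils::write.table(
    data.frame(family = "SIMFAM", id = ped$id,
               father = ifelse(is.na(ped$father), "0", ped$father),
               mother = ifelse(is.na(ped$mother), "0", ped$mother),
               sex = ped$sex, phenotype = ifelse(ped$affected, 2L, 1L)),
    paths["ped"], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  rows <- do.call(rbind, lapply(names(fam$genos), function(s) {
    g <- fam$genos[[s]]
    data.frame(sample = s, marker_id = rownames(g),
               allele1 = ifelse(is.na(g[, 1]), "-", g[, 1]),
               allele2 = ifelse(is.na(g[, 2]), "-", g[, 2]),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, paths["genotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(
    seed = cfg$seed,
    panel_draws = sim$truth,
    family = list(
      father_haplotypes = apply(fam$truth$father_haplotypes, 1, hap_string),
      mother_haplotypes = apply(fam$truth$mother_haplotypes, 1, hap_string),
      transmissions = as.data.frame(fam$truth$transmissions),
      carriers = fam$truth$carriers,
      background = if (is.null(fam$truth$background)) NULL
                   else hap_string(fam$truth$background),
      background_rank = fam$truth$background_rank)),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Generate a study-like family with a fully identifiable background
#'
#' Deterministic preset mirroring the structure of the motivating family:
#' ungenotyped parents, an affected carrier father, four offspring over the
#' full panel, reference spectrum over the 14 reference SNPs. Seeds are
#' advanced deterministically until the generated family (i) has at least
#' one carrier offspring and (ii) yields a fully forced carrier background
#' under [enumerate_phasings()] + [carrier_background()] — the preset's
#' contract is a family whose mutation background is identifiable, as in
#' the study pedigree. Rejection never inspects whether the recovered
#' background matches the implanted one.
#'
#' @param seed integer seed.
#' @param n_offspring sibship size (default 4).
#' @param max_attempts rejection-sampling bound.
#' @return List: `cfg`, `family` (from [make_family()]), `phase`,
#'   `background` (recovered), `spectrum` (the generating spectrum as a
#'   `hap_spectrum`), `carriers`, `attempts`.
#' @export
emulate_study <- function(seed = 1L, n_offspring = 4L, max_attempts = 200L) {
  for (attempt in seq_len(max_attempts)) {
    sub_seed <- (as.numeric(seed) * 2654435761 + attempt) %% 2147483647
    cfg <- sim_config(family = list(n_offspring = n_offspring),
                      seed = as.integer(sub_seed))
    fam <- make_family(cfg)
    if (!length(fam$truth$carriers)) next
    pr <- tryCatch(enumerate_phasings(fam$ped, fam$genos, cfg$panel),
                   error = function(e) NULL)
    if (is.null(pr)) next
    carriers <- c("I:1", fam$truth$carriers)
    bg <- tryCatch(
      carrier_background(pr, cfg$mutation$marker, cfg$mutation$allele,
                         carriers, genos = fam$genos),
      error = function(e) NULL)
    if (is.null(bg) || anyNA(bg)) next
    sp <- cfg$spectra[[1]]
    return(list(cfg = cfg, family = fam, phase = pr, background = bg,
                spectrum = spectrum_from_frequencies(sp$haplotypes,
                                                     sp$frequencies,
                                                     label = names(cfg$spectra)[1]),
                carriers = carriers, attempts = attempt))
  }
  stop("no identifiable family found in ", max_attempts, " attempts")
}
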