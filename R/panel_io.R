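# Reference-panel input and haplotype-spectrum construction. Haplotype sets
# are character matrices (rows = haplotypes, columns = panel markers); two
# rows per diploid sample, named "<sample>_1" / "<sample>_2".

#' Super-population code presets
#'
#' The 1000 Genomes population codes grouped into the super-populations used
#' for cross-population haplotype tables. The legacy label `GWC` seen in some
#' reports is accepted as a synonym of the 1000 Genomes code `GWD` (Gambian);
#' a message is emitted when the mapping fires.
#'
#' @return Named list of character vectors of population codes.
#' @export
super_population_codes <- function() {
  list(
    African       = c("ACB", "ASW", "ESN", "GWD", "LWK", "MSL", "YRI"),
    European      = c("CEU", "FIN", "GBR", "IBS", "TSI"),
    EastAsian     = c("CHB", "CHS", "CDX", "JPT", "KHV"),
    SouthAsian    = c("GIH", "PJL", "BEB", "STU", "ITU"),
    MixedAmerican = c("CLM", "MXL", "PEL", "PUR")
  )
}

normalize_pop_codes <- function(codes) {
  if (any(codes == "GWC")) {
    message("population code GWC mapped to 1000 Genomes code GWD")
    codes[codes == "GWC"] <- "GWD"
  }
  codes
}

#' Read a sample-to-population map
#'
#' @param path TSV with columns `sample  population  super_population`.
#' @return Data frame with those three character columns.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stop("population map file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  req <- c("sample", "population", "super_population")
  if (!all(req %in% names(df))) {
    stop("population map must have columns: ", paste(req, collapse = ", "))
  }
  df[, req]
}

#' Read phased haplotypes from a VCF over a marker panel
#'
#' Matches panel markers in the VCF by id, falling back to `chrom:pos` when
#' the id is absent. Panel markers not found (or the microsatellite, which
#' reference VCFs do not carry) are recorded in `dropped_markers` and
#' excluded panel-wide so all haplotypes stay aligned. Every genotype at a
#' used marker must be phased (`|` separator); an unphased `/` is an error
#' naming the sample and marker, since unphased reference data cannot yield
#' haplotypes.
#'
#' @param vcf_path VCF 4.x path (plain or bgzipped).
#' @param panel a [marker_panel].
#' @param popmap_path path to the population map TSV (see [read_popmap()]),
#'   or a data frame already read.
#' @return An object of class `population_panel`: list with `samples` (data
#'   frame `sample_id`, `population`, `super_population`), `haplotypes`
#'   (character matrix, 2 rows per sample), `panel` (the effective sub-panel)
#'   and `dropped_markers`.
#' @export
read_phased_vcf <- function(vcf_path, panel, popmap_path) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  popmap <- if (is.data.frame(popmap_path)) popmap_path else read_popmap(popmap_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  vcf_ids <- fix[, "ID"]
  vcf_key <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  panel_key <- paste0(panel$chrom, ":", panel$pos)
  row_for <- integer(nrow(panel))
  for (i in seq_len(nrow(panel))) {
    hit <- which(vcf_ids == panel$id[i])
    if (!length(hit) && !is.na(panel$pos[i])) hit <- which(vcf_key == panel_key[i])
    row_for[i] <- if (length(hit)) hit[1] else NA_integer_
  }
  found <- !is.na(row_for)
  if (!any(found)) stop("zero panel markers found in VCF ", vcf_path)
  eff_panel <- marker_panel(as.data.frame(panel)[found, , drop = FALSE],
                            name = attr(panel, "name"))
  dropped <- panel$id[!found]

  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  unmapped <- setdiff(samples, popmap$sample)
  if (length(unmapped)) {
    stop("sample(s) missing from population map: ",
         paste(unmapped, collapse = ", "))
  }
  gt <- gt[row_for[found], , drop = FALSE]

  L <- nrow(eff_panel)
  hap <- matrix(NA_character_, nrow = 2L * length(samples), ncol = L,
                dimnames = list(paste0(rep(samples, each = 2), "_", 1:2),
                                eff_panel$id))
  ref <- fix[row_for[found], "REF"]
  alt <- fix[row_for[found], "ALT"]
  allele_lists <- lapply(seq_len(L), function(k) {
    c(ref[k], strsplit(alt[k], ",", fixed = TRUE)[[1]])
  })
  for (k in seq_len(L)) {
    g <- gt[k, ]
    bad <- grepl("/", g, fixed = TRUE)
    if (any(bad)) {
      stop("unphased genotype for sample ", samples[which(bad)[1]],
           " at marker ", eff_panel$id[k], " (phased '|' separator required)")
    }
    parts <- strsplit(g, "|", fixed = TRUE)
    idx1 <- vapply(parts, `[`, "", 1L)
    idx2 <- vapply(parts, `[`, "", 2L)
    lookup <- function(ix) {
      out <- rep(NA_character_, length(ix))
      ok <- !is.na(ix) & ix != "."
      out[ok] <- allele_lists[[k]][as.integer(ix[ok]) + 1L]
      out
    }
    hap[seq(1, nrow(hap), by = 2), k] <- lookup(idx1)
    hap[seq(2, nrow(hap), by = 2), k] <- lookup(idx2)
  }
  samp <- popmap[match(samples, popmap$sample), ]
  structure(list(
    samples = data.frame(sample_id = samples,
                         population = samp$population,
                         super_population = samp$super_population,
                         stringsAsFactors = FALSE),
    haplotypes = hap,
    panel = eff_panel,
    dropped_markers = dropped
  ), class = "population_panel")
}

#' @export
print.population_panel <- function(x, ...) {
  cat("Population panel: ", nrow(x$samples), " samples (",
      nrow(x$haplotypes), " haplotypes) over ", nrow(x$panel), " markers\n",
      sep = "")
  if (length(x$dropped_markers)) {
    cat("Dropped markers:", paste(x$dropped_markers, collapse = ", "), "\n")
  }
  cat("Populations:", paste(sort(unique(x$samples$population)), collapse = ", "), "\n")
  invisible(x)
}

#' Extract haplotypes for selected populations
#'
#' @param pp a `population_panel` from [read_phased_vcf()] or
#'   [sample_panel()].
#' @param populations character vector of population codes, a super-population
#'   name from [super_population_codes()], or `NULL` for all samples.
#' @return Character haplotype matrix, 2 rows per selected sample, in sample
#'   order then haplotype index (deterministic).
#' @export
extract_haplotypes <- function(pp, populations = NULL) {
  if (is.null(populations)) return(pp$haplotypes)
  if (length(populations) == 1L &&
      populations %in% names(super_population_codes())) {
    populations <- super_population_codes()[[populations]]
  }
  populations <- normalize_pop_codes(populations)
  valid <- unique(pp$samples$population)
  present <- intersect(populations, valid)
  if (!length(present)) {
    stop("no such population code(s): ", paste(populations, collapse = ", "),
         "; valid codes: ", paste(sort(valid), collapse = ", "))
  }
  keep <- pp$samples$population %in% populations
  rows <- rep(which(keep) * 2L, each = 2L) - c(1L, 0L)
  pp$haplotypes[rows, , drop = FALSE]
}

#' Build a haplotype frequency spectrum
#'
#' Counts distinct haplotypes in a set of phased chromosomes, computes their
#' frequencies and names them by descending frequency rank ("1" = most
#' common), the convention used for founder-haplotype reporting. Frequency
#' ties are broken by the lexicographic order of the allele string so that
#' naming is deterministic. The suffix "V" is reserved for mutation-bearing
#' variants of a named background (see [background_rank_label()]); plain rank
#' names never carry it.
#'
#' @param haps character haplotype matrix (rows = haplotypes), or a list of
#'   allele vectors of equal length. No MISSING or AMBIGUOUS alleles allowed.
#' @param label population label stored on the spectrum.
#' @return Object of class `hap_spectrum`: list with `entries` (data frame
#'   `rank_name`, `haplotype`, `count`, `frequency`, sorted by descending
#'   count), `haplotypes` (matrix of distinct haplotypes in rank order),
#'   `total` and `label`.
#' @export
build_spectrum <- function(haps, label = "all") {
  if (is.list(haps) && !is.data.frame(haps)) {
    lens <- lengths(haps)
    if (length(unique(lens)) > 1L) stop("mixed haplotype lengths")
    haps <- do.call(rbind, haps)
  }
  if (!is.matrix(haps) || nrow(haps) == 0L) stop("empty haplotype set")
  if (anyNA(haps)) stop("MISSING alleles not allowed in spectrum input")
  if (any(is_ambiguous(haps))) stop("AMBIGUOUS alleles not allowed in spectrum input")
  keys <- apply(haps, 1, paste, collapse = "-")
  tab <- table(keys)
  counts <- as.integer(tab)
  hs <- names(tab)
  ord <- order(-counts, hs, method = "radix")
  counts <- counts[ord]
  hs <- hs[ord]
  total <- nrow(haps)
  hap_mat <- do.call(rbind, strsplit(hs, "-", fixed = TRUE))
  colnames(hap_mat) <- colnames(haps)
  rownames(hap_mat) <- as.character(seq_along(hs))
  structure(list(
    entries = data.frame(rank_name = as.character(seq_along(hs)),
                         haplotype = hs, count = counts,
                         frequency = counts / total,
                         stringsAsFactors = FALSE),
    haplotypes = hap_mat,
    total = total,
    label = label
  ), class = "hap_spectrum")
}

#' @export
print.hap_spectrum <- function(x, digits = 3, ...) {
  cat("Haplotype spectrum '", x$label, "': ", nrow(x$entries),
      " distinct haplotypes from ", x$total, " chromosomes\n", sep = "")
  e <- x$entries
  e$frequency <- round(e$frequency, digits)
  print.data.frame(e, row.names = FALSE)
  invisible(x)
}

#' Rank label of a background haplotype in a spectrum
#'
#' Maps a haplotype to its frequency-rank name in a reference spectrum; when
#' a mutation site and allele are supplied the suffix "V" (mutant) or "A"
#' (wild-type, after the reference amino acid) is appended, matching the
#' "1A"/"1V" style of founder reports. The mutation site need not be part of
#' the spectrum panel; matching uses the spectrum's markers only.
#'
#' @param spectrum a `hap_spectrum`.
#' @param hap character allele vector named by (or aligned to) the spectrum's
#'   markers; may include extra markers such as the mutation site.
#' @param mutation_marker,mutant_allele,wildtype_suffix optional mutation-site
#'   annotation.
#' @return Rank label string, or `NA` if the background is not in the
#'   spectrum.
#' @export
background_rank_label <- function(spectrum, hap, mutation_marker = NULL,
                                  mutant_allele = NULL, wildtype_suffix = "A") {
  ids <- colnames(spectrum$haplotypes)
  h <- if (!is.null(names(hap))) hap[ids] else hap
  if (length(h) != ncol(spectrum$haplotypes)) {
    stop("haplotype does not cover the spectrum's markers")
  }
  key <- paste(h, collapse = "-")
  hit <- match(key, spectrum$entries$haplotype)
  if (is.na(hit)) return(NA_character_)
  rank <- spectrum$entries$rank_name[hit]
  if (!is.null(mutation_marker) && !is.null(names(hap)) &&
      mutation_marker %in% names(hap)) {
    suffix <- if (identical(unname(hap[mutation_marker]), mutant_allele)) "V"
              else wildtype_suffix
    rank <- paste0(rank, suffix)
  }
  rank
}

#' Cross-population haplotype frequency table
#'
#' One row per distinct haplotype observed in any group, with per-group
#' counts and frequencies plus a pooled `all` column; rows are sorted by
#' pooled frequency (descending, ties by allele string). This is the
#' worldwide founder-haplotype comparison layout.
#'
#' @param pp a `population_panel`.
#' @param groupings named list mapping group label to population codes;
#'   defaults to [super_population_codes()].
#' @return Data frame with columns `haplotype`, then `<group>_count`,
#'   `<group>_freq` per group, then `all_count`, `all_freq`.
#' @export
cross_population_table <- function(pp, groupings = super_population_codes()) {
  if (!length(groupings)) stop("empty grouping")
  groupings <- lapply(groupings, normalize_pop_codes)
  group_haps <- lapply(groupings, function(codes) {
    keep <- pp$samples$population %in% codes
    if (!any(keep)) return(NULL)
    extract_haplotypes(pp, intersect(codes, unique(pp$samples$population)))
  })
  used <- !vapply(group_haps, is.null, TRUE)
  if (!any(used)) stop("no samples fall in any group")
  group_haps <- group_haps[used]
  pooled <- do.call(rbind, group_haps)
  pooled_spec <- build_spectrum(pooled, label = "all")
  out <- data.frame(haplotype = pooled_spec$entries$haplotype,
                    stringsAsFactors = FALSE)
  for (g in names(group_haps)) {
    keys <- apply(group_haps[[g]], 1, paste, collapse = "-")
    cnt <- as.integer(table(factor(keys, levels = out$haplotype)))
    out[[paste0(g, "_count")]] <- cnt
    out[[paste0(g, "_freq")]] <- cnt / length(keys)
  }
  out$all_count <- pooled_spec$entries$count
  out$all_freq <- pooled_spec$entries$frequency
  out
}

#' Write a haplotype spectrum to TSV and JSON
#'
#' @param spectrum a `hap_spectrum`.
#' @param path_tsv,path_json output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_spectrum <- function(spectrum, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    utils::write.table(spectrum$entries, path_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(list(label = spectrum$label, total = spectrum$total,
                              entries = spectrum$entries),
                         path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(path_tsv, path_json))
}
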