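# Allele encoding used throughout the package:
#   * a plain symbol: a single IUPAC base for SNPs ("C"), or a positive
#     integer repeat count, stored as character, for microsatellites ("12");
#   * NA_character_           -> MISSING (marker not typed);
#   * "X/Y" (sorted, slashed) -> AMBIGUOUS, an unresolved-phase observation
#     restricted to alleles observed at that marker.
# Haplotypes are character vectors aligned to a marker panel; sets of
# haplotypes are character matrices with one row per haplotype.

IUPAC_BASES <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Construct a marker panel
#'
#' A marker panel is an ordered set of genetic markers (SNPs and at most one
#' microsatellite) around a locus of interest. Order is authoritative: it is
#' taken from the input, never re-sorted by position, because all downstream
#' comparisons (haplotype strings, LD block contiguity) are order-based.
#'
#' @param df data frame with columns `id`, `kind` (`"snp"` or
#'   `"microsatellite"`), `alleles` (list of character vectors, or a
#'   comma-separated string), and optionally `chrom`, `pos` (1-based GRCh37,
#'   may be `NA`) and `mutation_site` (logical; at most one `TRUE`).
#' @param name panel name.
#' @return An object of class `marker_panel`: the validated data frame with
#'   `alleles` as a list-column and attribute `name`.
#' @export
marker_panel <- function(df, name = "panel") {
  req <- c("id", "kind", "alleles")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("no markers in panel")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    stop("duplicate marker id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  if (any(!nzchar(df$id))) stop("empty marker id")
  bad_kind <- setdiff(unique(df$kind), c("snp", "microsatellite"))
  if (length(bad_kind)) {
    stop("unknown marker kind: ", paste(bad_kind, collapse = ", "))
  }
  if (!is.list(df$alleles)) {
    df$alleles <- lapply(strsplit(as.character(df$alleles), ","), trimws)
  }
  if (is.null(df$chrom)) df$chrom <- NA_character_
  df$chrom <- as.character(df$chrom)
  if (is.null(df$pos)) df$pos <- NA_integer_
  df$pos <- suppressWarnings(as.integer(df$pos))
  if (is.null(df$mutation_site)) df$mutation_site <- FALSE
  df$mutation_site <- as.logical(as.integer(as.logical(df$mutation_site) |
                                              df$mutation_site %in% c("1", 1)))
  df$mutation_site[is.na(df$mutation_site)] <- FALSE
  if (sum(df$mutation_site) > 1L) stop("at most one mutation-site marker allowed")
  for (i in seq_len(nrow(df))) {
    al <- df$alleles[[i]]
    if (length(al) < 1L || any(!nzchar(al))) {
      stop("marker ", df$id[i], ": empty allele list")
    }
    if (df$kind[i] == "snp") {
      if (any(nchar(al) != 1L) || any(!toupper(al) %in% IUPAC_BASES)) {
        stop("marker ", df$id[i], ": malformed SNP allele(s) ",
             paste(al, collapse = ","), " (single IUPAC bases required)")
      }
    } else {
      counts <- suppressWarnings(as.integer(al))
      if (any(is.na(counts)) || any(counts <= 0L)) {
        stop("marker ", df$id[i],
             ": microsatellite alleles must be positive integer repeat counts")
      }
    }
  }
  df <- df[, c("id", "chrom", "pos", "kind", "alleles", "mutation_site")]
  rownames(df) <- NULL
  structure(df, class = c("marker_panel", "data.frame"), name = name)
}

#' Read a marker panel from TSV
#'
#' Expected columns: `id  chrom  pos  kind  alleles  mutation_site` with
#' `alleles` comma-separated and `pos` possibly `NA`. Row order is preserved
#' as the panel order.
#'
#' @param path TSV file path.
#' @param name panel name (defaults to the file name).
#' @return A [marker_panel].
#' @export
parse_panel <- function(path, name = NULL) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (nrow(df) == 0L) stop("no markers in panel file ", path)
  marker_panel(df, name = name %||% basename(path))
}

#' Write a marker panel to TSV
#'
#' Inverse of [parse_panel()]: `parse_panel(write_panel(p, f))` reproduces
#' the panel content.
#'
#' @param panel a [marker_panel].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)
  df$alleles <- vapply(df$alleles, paste, "", collapse = ",")
  df$mutation_site <- as.integer(df$mutation_site)
  df$pos <- ifelse(is.na(df$pos), "NA", as.character(df$pos))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged 16-marker SOD1 region panel
#'
#' The default panel spans chromosome 21 from *SOD1* to *SCAF4*: 15 SNPs and
#' one CA-repeat microsatellite, in the fixed region order used for family
#' haplotype reporting. The ALS mutation site p.A5V (rs121912442, c.14C>T) is
#' flagged. Positions are left `NA`; all computations are order-based.
#'
#' @return A [marker_panel] of 16 markers.
#' @export
default_panel <- function() {
  path <- system.file("extdata", "sod1_panel16.tsv", package = "founderhap",
                      mustWork = TRUE)
  parse_panel(path, name = "sod1_panel16")
}

#' Subset a marker panel
#'
#' Returns the sub-panel restricted to `keep_ids`, preserving the relative
#' marker order of `panel`. The preset `"pop14"` selects the 14 SNPs used for
#' reference-population work: all SNPs except the mutation site, with the
#' microsatellite excluded (reference panels carry neither the private
#' mutation nor fragment-length alleles).
#'
#' @param panel a [marker_panel].
#' @param keep_ids character vector of marker ids to keep.
#' @param preset optional named preset, currently `"pop14"`.
#' @return A [marker_panel].
#' @export
subset_panel <- function(panel, keep_ids = NULL, preset = NULL) {
  if (!is.null(preset)) {
    if (!identical(preset, "pop14")) stop("unknown preset: ", preset)
    keep_ids <- panel$id[panel$kind == "snp" & !panel$mutation_site]
  }
  if (is.null(keep_ids)) stop("keep_ids or preset required")
  unknown <- setdiff(keep_ids, panel$id)
  if (length(unknown)) {
    stop("unknown marker id(s): ", paste(unknown, collapse = ", "))
  }
  keep <- panel$id %in% keep_ids
  marker_panel(as.data.frame(panel)[keep, , drop = FALSE],
               name = paste0(attr(panel, "name"), if (!is.null(preset)) "_pop14" else "_subset"))
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panel '", attr(x, "name"), "': ", nrow(x), " markers (",
      sum(x$kind == "snp"), " SNPs, ", sum(x$kind == "microsatellite"),
      " microsatellite)", sep = "")
  if (any(x$mutation_site)) cat("; mutation site ", x$id[x$mutation_site], sep = "")
  cat("\n")
  print.data.frame(cbind(as.data.frame(x)[, c("id", "chrom", "pos", "kind")],
                         alleles = vapply(x$alleles, paste, "", collapse = ","),
                         mutation_site = x$mutation_site), ...)
  invisible(x)
}

# ---- allele helpers --------------------------------------------------------

is_ambiguous <- function(a) !is.na(a) & grepl("/", a, fixed = TRUE)

allele_set <- function(a) {
  if (is.na(a)) return(character(0))
  strsplit(a, "/", fixed = TRUE)[[1]]
}

ambiguous_allele <- function(symbols) {
  symbols <- sort(unique(symbols), method = "radix")
  if (length(symbols) < 2L) stop("AMBIGUOUS allele needs >= 2 symbols")
  paste(symbols, collapse = "/")
}

# Match two observed alleles under a policy. MISSING never reaches here
# (callers skip it). Lenient: AMBIGUOUS matches iff the sets intersect.
alleles_agree <- function(a, b, policy = c("lenient", "strict")) {
  policy <- match.arg(policy)
  if (policy == "strict" && (is_ambiguous(a) || is_ambiguous(b))) return(FALSE)
  length(intersect(allele_set(a), allele_set(b))) > 0L
}

hap_string <- function(h) paste(ifelse(is.na(h), ".", h), collapse = "-")

# ---- genotypes -------------------------------------------------------------

#' Read family genotypes from a long-format TSV
#'
#' Expected columns `sample  marker_id  allele1  allele2`. Values `-`, `.`,
#' `NA` and empty strings are read as missing. Markers absent for a sample
#' are missing; marker ids not in the panel are an error.
#'
#' @param path TSV file path.
#' @param panel the [marker_panel] the genotypes are aligned to.
#' @return A named list (one element per sample) of `L x 2` character
#'   matrices, rows in panel order; attribute `panel_ids` records alignment.
#' @export
read_genotypes <- function(path, panel) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  req <- c("sample", "marker_id", "allele1", "allele2")
  if (!all(req %in% names(df))) {
    stop("genotype file must have columns: ", paste(req, collapse = ", "))
  }
  unknown <- setdiff(unique(df$marker_id), panel$id)
  if (length(unknown)) {
    stop("genotype file references unknown marker(s): ",
         paste(unknown, collapse = ", "))
  }
  na_vals <- c("-", ".", "NA", "")
  df$allele1[df$allele1 %in% na_vals] <- NA
  df$allele2[df$allele2 %in% na_vals] <- NA
  out <- list()
  for (s in unique(df$sample)) {
    sub <- df[df$sample == s, , drop = FALSE]
    m <- matrix(NA_character_, nrow = nrow(panel), ncol = 2,
                dimnames = list(panel$id, c("a1", "a2")))
    m[sub$marker_id, 1] <- sub$allele1
    m[sub$marker_id, 2] <- sub$allele2
    out[[s]] <- m
  }
  attr(out, "panel_ids") <- panel$id
  out
}

#' Build one sample's genotypes from allele vectors
#'
#' Convenience constructor for in-code use (tests, simulation): pairs two
#' allele vectors aligned to `panel` into the `L x 2` genotype matrix used
#' throughout the package.
#'
#' @param panel a [marker_panel].
#' @param a1,a2 character allele vectors of panel length (`NA` = missing).
#' @return `L x 2` character matrix with marker-id rownames.
#' @export
sample_genotypes <- function(panel, a1, a2) {
  if (length(a1) != nrow(panel) || length(a2) != nrow(panel)) {
    stop("allele vectors must have panel length ", nrow(panel))
  }
  matrix(c(a1, a2), ncol = 2, dimnames = list(panel$id, c("a1", "a2")))
}

# ---- pedigree --------------------------------------------------------------

#' Construct or read a pedigree
#'
#' `pedigree()` validates a data frame of individuals; `read_ped()` reads a
#' standard 6-column PED file (family, id, father, mother, sex, phenotype;
#' `0` = unknown parent, phenotype `2` = affected).
#'
#' @param df data frame with columns `id`, `father`, `mother` (`NA` or `"0"`
#'   for founders), `sex` (`1` male / `2` female / `0` unknown) and
#'   `affected` (logical).
#' @return A `pedigree` data frame.
#' @export
pedigree <- function(df) {
  req <- c("id", "father", "mother", "sex", "affected")
  if (!all(req %in% names(df))) {
    stop("pedigree needs columns: ", paste(req, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$id <- as.character(df$id)
  df$father <- as.character(df$father)
  df$mother <- as.character(df$mother)
  df$father[df$father %in% c("0", "")] <- NA
  df$mother[df$mother %in% c("0", "")] <- NA
  if (anyDuplicated(df$id)) stop("duplicate individual id in pedigree")
  parents <- stats::na.omit(c(df$father, df$mother))
  missing_par <- setdiff(parents, df$id)
  if (length(missing_par)) {
    stop("pedigree references unknown parent(s): ",
         paste(missing_par, collapse = ", "))
  }
  # cycle check: an individual may not be its own ancestor
  anc <- function(id, seen = character()) {
    if (id %in% seen) stop("pedigree contains a cycle at ", id)
    row <- df[df$id == id, ]
    for (p in stats::na.omit(c(row$father, row$mother))) {
      anc(p, c(seen, id))
    }
  }
  for (id in df$id) anc(id)
  structure(df, class = c("pedigree", "data.frame"))
}

#' @rdname pedigree
#' @param path PED file path.
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("PED file not found: ", path)
  df <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 6L) stop("PED file must have 6 columns")
  names(df)[1:6] <- c("family", "id", "father", "mother", "sex", "phenotype")
  pedigree(data.frame(id = df$id, father = df$father, mother = df$mother,
                      sex = as.integer(df$sex),
                      affected = df$phenotype == "2",
                      stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# vectorized bytewise (C-collation) string less-than; canonical forms must
# not depend on the session locale
str_less_c <- function(a, b) {
  u <- sort(unique(c(a, b)), method = "radix")
  match(a, u) < match(b, u)
}
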