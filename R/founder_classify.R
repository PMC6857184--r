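# Compatibility of observed genotypes and mutation backgrounds with named
# founder haplotypes and with reference spectra. Comparisons skip MISSING
# sites and treat unresolved-phase AMBIGUOUS observations ("C/T") as
# matching when the allele sets intersect (policy "lenient", the default),
# or never (policy "strict").

#' Mismatch count between two haplotypes
#'
#' Compares two haplotypes aligned to the same panel, site by site. Sites
#' MISSING in either haplotype are skipped and reported via `n_compared`;
#' AMBIGUOUS alleles match under the lenient policy iff their sets
#' intersect.
#'
#' @param a,b character allele vectors of equal length (`NA` = MISSING,
#'   `"C/T"` = AMBIGUOUS).
#' @param policy `"lenient"` (default) or `"strict"`.
#' @return List with `n_mismatch`, `n_compared` and `skipped` (marker
#'   indices not compared); `n_compared + length(skipped)` always equals the
#'   panel length.
#' @export
mismatch <- function(a, b, policy = c("lenient", "strict")) {
  policy <- match.arg(policy)
  if (length(a) != length(b)) stop("haplotypes are on different panels")
  comparable <- !is.na(a) & !is.na(b)
  if (!any(comparable)) stop("zero comparable sites")
  agree <- vapply(which(comparable),
                  function(i) alleles_agree(a[i], b[i], policy), TRUE)
  list(n_mismatch = sum(!agree),
       n_compared = sum(comparable),
       skipped = which(!comparable))
}

#' Read the packaged named-founder haplotype table
#'
#' The packaged fixture holds the published founder haplotypes of the
#' p.A5V-*SOD1* mutation over the 15 SNPs of the region panel: the North
#' American (USA), Swedish (SWE), Chinese (CHN, with unresolved-phase
#' entries) and Iberian (IBS) backgrounds. Untyped entries are `-` in the
#' file and MISSING here.
#'
#' @param path optional alternative TSV (columns `id` then one per label).
#' @return Named list of haplotype vectors (named by marker id), with
#'   attribute `marker_ids`.
#' @export
read_founders <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sod1_founders_table1.tsv",
                        package = "founderhap", mustWork = TRUE)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          check.names = FALSE)
  labels <- setdiff(names(df), "id")
  out <- lapply(labels, function(lb) {
    v <- df[[lb]]
    v[v %in% c("-", ".", "NA", "")] <- NA
    # normalize ambiguous entries to sorted form
    amb <- !is.na(v) & grepl("/", v, fixed = TRUE)
    v[amb] <- vapply(strsplit(v[amb], "/", fixed = TRUE),
                     function(s) paste(sort(s, method = "radix"),
                                       collapse = "/"), "")
    names(v) <- df$id
    v
  })
  names(out) <- labels
  attr(out, "marker_ids") <- df$id
  out
}

#' Compatibility of a genotype with each haplotype of a reference spectrum
#'
#' A reference haplotype is compatible with an unphased genotype iff at
#' every marker one of the two genotype alleles equals the reference allele
#' (MISSING genotypes match anything); the complement is the leftover allele
#' at each marker. When a mutation constraint is given, the mutation-bearing
#' background (from pedigree phasing, or [genotype_background()] when no
#' family data exist) must additionally equal the reference haplotype at all
#' co-observed markers: the mutation is required to ride the tested
#' background. The mutation site itself may be absent from the reference
#' panel, as it is for a private mutation.
#'
#' @param geno `L x 2` genotype matrix with marker-id rownames; must cover
#'   the spectrum's markers.
#' @param spectrum a `hap_spectrum`.
#' @param mutation_marker,mutant_allele optional mutation constraint.
#' @param background optional named background vector (required with the
#'   mutation constraint unless the genotype forces it by homozygosity).
#' @return List with `table` (data frame `rank_name`, `frequency`,
#'   `compatible`, `complement`) and `n_compatible`.
#' @export
compatible_references <- function(geno, spectrum, mutation_marker = NULL,
                                  mutant_allele = NULL, background = NULL) {
  ids <- colnames(spectrum$haplotypes)
  if (!all(ids %in% rownames(geno))) {
    stop("genotype does not cover the spectrum's markers")
  }
  g <- geno[ids, , drop = FALSE]
  if (any(is_ambiguous(g))) stop("genotype alleles must not be AMBIGUOUS")
  if (!is.null(mutation_marker) && is.null(background)) {
    background <- genotype_background(geno, mutation_marker, mutant_allele)
  }
  n <- nrow(spectrum$haplotypes)
  compatible <- logical(n)
  complement <- character(n)
  for (i in seq_len(n)) {
    h <- spectrum$haplotypes[i, ]
    comp <- rep(NA_character_, length(ids))
    ok <- TRUE
    for (k in seq_along(ids)) {
      pair <- g[k, ]
      if (anyNA(pair)) next  # MISSING matches anything; complement unknown
      if (pair[1] == h[k]) comp[k] <- pair[2]
      else if (pair[2] == h[k]) comp[k] <- pair[1]
      else { ok <- FALSE; break }
    }
    if (ok && !is.null(background)) {
      bk <- background[ids]
      co <- !is.na(bk)
      ok <- all(bk[co] == h[co])
    }
    compatible[i] <- ok
    complement[i] <- if (ok) paste(ifelse(is.na(comp), ".", comp),
                                   collapse = "-") else NA_character_
  }
  list(table = data.frame(rank_name = spectrum$entries$rank_name,
                          frequency = spectrum$entries$frequency,
                          compatible = compatible,
                          complement = complement,
                          stringsAsFactors = FALSE),
       n_compatible = sum(compatible))
}

#' Founder comparison table with pairwise mismatch counts
#'
#' Renders the haplotype-by-marker matrix of named founder backgrounds
#' (optionally alongside observed sample genotypes) and the symmetric
#' pairwise mismatch counts over co-observed sites.
#'
#' @param named named list of haplotype vectors over one panel (e.g. from
#'   [read_founders()]).
#' @param samples optional named list of `L x 2` genotype matrices shown as
#'   extra `a1/a2` columns.
#' @param exclude_ids marker ids excluded from the mismatch counting (e.g.
#'   the mutation site, shared by definition among carriers); the matrix
#'   itself always shows all markers.
#' @param policy ambiguity policy passed to [mismatch()].
#' @return Object of class `founder_comparison`: list with `matrix` (marker
#'   x label character data frame), `n_mismatch` and `n_compared` (symmetric
#'   label x label matrices).
#' @export
founder_table <- function(named, samples = NULL, exclude_ids = NULL,
                          policy = "lenient") {
  if (!length(named)) stop("no haplotypes given")
  ids <- names(named[[1]])
  lens <- vapply(named, length, 0L)
  if (length(unique(lens)) > 1L) stop("haplotypes are on different panels")
  mat <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (lb in names(named)) mat[[lb]] <- ifelse(is.na(named[[lb]]), "-", named[[lb]])
  if (!is.null(samples)) {
    for (s in names(samples)) {
      gg <- samples[[s]][ids, , drop = FALSE]
      mat[[s]] <- ifelse(is.na(gg[, 1]) | is.na(gg[, 2]), "-",
                         paste0(gg[, 1], "/", gg[, 2]))
    }
  }
  keep <- !ids %in% (exclude_ids %||% character(0))
  nl <- length(named)
  nm <- matrix(0L, nl, nl, dimnames = list(names(named), names(named)))
  nc <- matrix(sum(keep), nl, nl, dimnames = dimnames(nm))
  for (i in seq_len(nl)) for (j in seq_len(nl)) {
    if (i == j) { nc[i, j] <- sum(!is.na(named[[i]][keep])); next }
    mm <- mismatch(named[[i]][keep], named[[j]][keep], policy)
    nm[i, j] <- mm$n_mismatch
    nc[i, j] <- mm$n_compared
  }
  structure(list(matrix = mat, n_mismatch = nm, n_compared = nc,
                 policy = policy),
            class = "founder_comparison")
}

#' @export
print.founder_comparison <- function(x, ...) {
  cat("Founder haplotype comparison (", x$policy, " ambiguity policy)\n",
      sep = "")
  print.data.frame(x$matrix, row.names = FALSE)
  cat("\nPairwise mismatches (over co-observed sites):\n")
  print(x$n_mismatch)
  invisible(x)
}

#' Write a founder comparison to TSV
#'
#' @param fc a `founder_comparison`.
#' @param path output TSV path (the marker matrix; mismatch counts go to
#'   `<path>.mismatch.tsv`).
#' @return Invisibly, the written paths.
#' @export
write_founder_table <- function(fc, path) {
  utils::write.table(fc$matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mpath <- paste0(path, ".mismatch.tsv")
  utils::write.table(fc$n_mismatch, mpath, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(c(path, mpath))
}
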