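# Pairwise linkage disequilibrium from phased haplotypes, and contiguous
# high-LD block detection over the panel order. Standard two-locus
# definitions: with major-allele frequencies p_A, p_B and joint frequency
# p_AB,
#   D  = p_AB - p_A p_B
#   r2 = D^2 / (p_A (1-p_A) p_B (1-p_B))
#   D' = |D| / D_max,  D_max = min(p_A (1-p_B), (1-p_A) p_B)   if D > 0
#                      D_max = min(p_A p_B, (1-p_A) (1-p_B))   if D < 0
# The sign of D depends on the (arbitrary) allele labelling; D' and r2 do
# not, which is why only they are reported by default. Monomorphic markers
# give D = r2 = D' = 0 by convention.

#' Pairwise LD between two markers of a phased haplotype set
#'
#' @param haps character haplotype matrix (rows = phased chromosomes).
#' @param i,j column indices or marker ids.
#' @param strict error on monomorphic markers instead of returning the zero
#'   convention.
#' @return List with `D`, `Dprime`, `r2`, `p_A`, `p_B` (major-allele
#'   frequencies; major = frequency >= 0.5, ties broken lexicographically).
#' @export
pairwise_ld <- function(haps, i, j, strict = FALSE) {
  x <- haps[, i]
  y <- haps[, j]
  if (anyNA(x) || anyNA(y)) {
    stop("MISSING alleles at the pair; drop incomplete haplotypes first")
  }
  major <- function(v) {
    tab <- table(v)
    cands <- names(tab)[tab == max(tab)]
    sort(cands, method = "radix")[1]  # C collation: locale-independent
  }
  if (length(unique(x)) > 2L || length(unique(y)) > 2L) {
    stop("marker is not biallelic in this haplotype set")
  }
  A <- major(x)
  B <- major(y)
  p_A <- mean(x == A)
  p_B <- mean(y == B)
  if (p_A == 1 || p_B == 1) {
    if (strict) stop("monomorphic marker in LD pair")
    return(list(D = 0, Dprime = 0, r2 = 0, p_A = p_A, p_B = p_B))
  }
  p_AB <- mean(x == A & y == B)
  D <- p_AB - p_A * p_B
  r2 <- D^2 / (p_A * (1 - p_A) * p_B * (1 - p_B))
  Dmax <- if (D > 0) min(p_A * (1 - p_B), (1 - p_A) * p_B)
          else min(p_A * p_B, (1 - p_A) * (1 - p_B))
  Dprime <- if (D == 0) 0 else abs(D) / Dmax
  list(D = D, Dprime = Dprime, r2 = r2, p_A = p_A, p_B = p_B)
}

#' Full pairwise LD matrix over a panel
#'
#' Haplotypes with MISSING at a pair are dropped pairwise (complete-case per
#' pair). Monomorphic markers are flagged and given zero rows/columns by
#' convention; diagonals are `r2 = 1`, `D' = 1` for polymorphic markers.
#'
#' @param haps character haplotype matrix with marker-id colnames.
#' @param panel optional [marker_panel] restricting/ordering the columns.
#' @return Object of class `ld_matrix`: list with `ids`, symmetric matrices
#'   `r2`, `dprime`, `D`, the major-allele frequency `p_major` and the
#'   logical `monomorphic` flag per marker.
#' @export
ld_matrix <- function(haps, panel = NULL) {
  if (!is.null(panel)) haps <- haps[, panel$id, drop = FALSE]
  ids <- colnames(haps) %||% as.character(seq_len(ncol(haps)))
  L <- ncol(haps)
  poly <- vapply(seq_len(L), function(k) {
    v <- haps[, k]
    length(unique(v[!is.na(v)])) > 1L
  }, TRUE)
  if (sum(poly) < 2L) stop("fewer than 2 polymorphic markers")
  r2 <- dp <- D <- matrix(0, L, L, dimnames = list(ids, ids))
  diag(r2)[poly] <- 1
  diag(dp)[poly] <- 1
  p_major <- vapply(seq_len(L), function(k) {
    v <- haps[!is.na(haps[, k]), k]
    max(table(v)) / length(v)
  }, 0)
  for (a in seq_len(L - 1L)) for (b in (a + 1L):L) {
    keep <- !is.na(haps[, a]) & !is.na(haps[, b])
    if (!any(keep)) next
    ld <- pairwise_ld(haps[keep, , drop = FALSE], a, b)
    r2[a, b] <- r2[b, a] <- ld$r2
    dp[a, b] <- dp[b, a] <- ld$Dprime
    D[a, b] <- D[b, a] <- ld$D
  }
  structure(list(ids = ids, r2 = r2, dprime = dp, D = D,
                 p_major = stats::setNames(p_major, ids),
                 monomorphic = stats::setNames(!poly, ids)),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, digits = 3, ...) {
  cat("LD matrix over", length(x$ids), "markers",
      if (any(x$monomorphic)) paste0("(", sum(x$monomorphic), " monomorphic)"),
      "\nr2:\n")
  print(round(x$r2, digits))
  invisible(x)
}

#' Detect contiguous high-LD blocks
#'
#' Scans the panel order left to right and reports disjoint maximal runs of
#' at least two markers in which every within-run pair meets
#' `metric >= threshold`. Greedy maximal extension makes the result
#' deterministic and the blocks disjoint. Markers uncorrelated with a block
#' (such as a mutation site outside the conserved core of a gene region)
#' are left out of it.
#'
#' @param m an `ld_matrix`.
#' @param metric `"dprime"` (default) or `"r2"`.
#' @param threshold in (0, 1]; default 0.90.
#' @return Data frame with columns `start`, `end` (panel indices,
#'   inclusive), `start_id`, `end_id`, `n_markers`, `metric`, `threshold`;
#'   zero rows when no block exists.
#' @export
detect_blocks <- function(m, metric = c("dprime", "r2"), threshold = 0.90) {
  metric <- match.arg(metric)
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  M <- m[[metric]]
  L <- length(m$ids)
  blocks <- list()
  i <- 1L
  while (i < L) {
    j <- i
    while (j < L && all(M[i:j, j + 1L] >= threshold - 1e-12)) j <- j + 1L
    if (j > i) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        start = i, end = j, start_id = m$ids[i], end_id = m$ids[j],
        n_markers = j - i + 1L, metric = metric, threshold = threshold,
        stringsAsFactors = FALSE)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(blocks)) {
    return(data.frame(start = integer(0), end = integer(0),
                      start_id = character(0), end_id = character(0),
                      n_markers = integer(0), metric = character(0),
                      threshold = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, blocks)
}

#' Write an LD matrix and block report to TSV
#'
#' @param m an `ld_matrix`.
#' @param path_r2,path_dprime,path_blocks output TSV paths (`NULL` skips).
#' @param ... arguments passed to [detect_blocks()].
#' @return Invisibly, the written paths.
#' @export
write_ld <- function(m, path_r2 = NULL, path_dprime = NULL,
                     path_blocks = NULL, ...) {
  if (!is.null(path_r2)) {
    utils::write.table(m$r2, path_r2, sep = "\t", quote = FALSE, col.names = NA)
  }
  if (!is.null(path_dprime)) {
    utils::write.table(m$dprime, path_dprime, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  if (!is.null(path_blocks)) {
    blocks <- detect_blocks(m, ...)
    utils::write.table(blocks[, c("start_id", "end_id", "n_markers",
                                  "metric", "threshold")],
                       path_blocks, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(path_r2, path_dprime, path_blocks))
}
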