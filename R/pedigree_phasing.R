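# Exhaustive Mendelian-constrained phasing of one nuclear family under the
# zero-recombination assumption: over a short marker panel transmitted in a
# single generation, each offspring inherits one intact haplotype per parent.
# A phase solution assigns each founder an ordered pair of haplotypes (rows
# of a 2 x L character matrix; NA where nothing constrains the allele) and
# each genotyped offspring a transmission (paternal row, maternal row).
#
# The search is exact: for a fixed transmission vector the markers decouple,
# so consistent founder-allele assignments are enumerated per marker by
# constraint propagation and combined as a Cartesian product; transmission
# vectors are enumerated outermost. Solutions are deduplicated up to the
# within-founder haplotype swap (founder pairs are unordered). When a
# founder is wholly unconstrained by its own genotype its two haplotype
# slots are exchangeable, so the first genotyped offspring's transmission
# bit on that side is pinned to 1 — a pure symmetry reduction that the
# canonical form undoes.

#' Enumerate all Mendelian-consistent phase solutions for a nuclear family
#'
#' @param ped a [pedigree] describing one nuclear family: exactly two
#'   founders and their common offspring. Individuals absent from `genos`
#'   are treated as ungenotyped (e.g. deceased parents) and constrained only
#'   through their offspring.
#' @param genos named list of `L x 2` genotype matrices (see
#'   [read_genotypes()] / [sample_genotypes()]), aligned to `panel`. A
#'   genotype with any missing slot at a marker imposes no constraint there.
#' @param panel a [marker_panel].
#' @param cap maximum number of enumerated phase configurations (default
#'   `1e6`); exceeding it is an error suggesting marker subsetting, since
#'   the search is exact by design at panel scale.
#' @return Object of class `phase_result`: list with `solutions` (each a
#'   list `father`, `mother` = 2 x L matrices, `transmissions` = offspring x
#'   c(pat, mat) matrix), `family_haplotypes` (distinct fully determined
#'   haplotypes common to all solutions), `founders`, `offspring`,
#'   `panel_ids`. Internal compact matrices used by [carrier_background()]
#'   are attached as the `slots` element.
#' @export
enumerate_phasings <- function(ped, genos, panel, cap = 1e6) {
  ids <- panel$id
  L <- length(ids)
  off_rows <- !is.na(ped$father) & !is.na(ped$mother)
  offspring <- ped$id[off_rows]
  if (!length(offspring)) stop("pedigree has no offspring")
  father <- unique(ped$father[off_rows])
  mother <- unique(ped$mother[off_rows])
  if (length(father) != 1L || length(mother) != 1L) {
    stop("a single nuclear family (one father, one mother) is required")
  }
  founders_extra <- setdiff(ped$id[!off_rows], c(father, mother))
  if (length(founders_extra)) {
    stop("individuals outside the nuclear family: ",
         paste(founders_extra, collapse = ", "))
  }
  genos <- genos[intersect(names(genos), ped$id)]
  if (!length(genos)) stop("at least one individual must be genotyped")

  pair_of <- function(id) {
    g <- genos[[id]]
    if (!is.null(g) && !is.null(rownames(g))) {
      missing_ids <- setdiff(ids, rownames(g))
      if (length(missing_ids)) {
        stop("genotypes for ", id, " lack panel marker(s): ",
             paste(missing_ids, collapse = ", "))
      }
      g <- g[ids, , drop = FALSE]
    }
    lapply(seq_len(L), function(k) {
      if (is.null(g)) return(NULL)
      p <- g[k, ]
      if (anyNA(p)) NULL else unname(p)
    })
  }
  fpairs <- pair_of(father)
  mpairs <- pair_of(mother)
  g_off <- intersect(offspring, names(genos))
  n_g <- length(g_off)
  opairs <- lapply(g_off, pair_of)
  # offspring with a constraint at marker k (memoization scope)
  rel_at <- lapply(seq_len(L), function(k) {
    which(vapply(opairs, function(op) !is.null(op[[k]]), TRUE))
  })
  father_free <- all(vapply(fpairs, is.null, TRUE))
  mother_free <- all(vapply(mpairs, is.null, TRUE))

  # Per-marker assignment enumeration for a given transmission of the
  # genotyped offspring. Slots: 1 = F1, 2 = F2, 3 = M1, 4 = M2.
  marker_assignments <- function(k, trans) {
    base <- list(rep(NA_character_, 4L))
    order_branches <- function(assigns, pair, s1, s2) {
      out <- list()
      for (a in assigns) {
        ords <- if (pair[1] == pair[2]) list(pair) else list(pair, rev(pair))
        for (o in ords) {
          b <- a
          b[c(s1, s2)] <- o
          out[[length(out) + 1L]] <- b
        }
      }
      out
    }
    if (!is.null(fpairs[[k]])) base <- order_branches(base, fpairs[[k]], 1L, 2L)
    if (!is.null(mpairs[[k]])) base <- order_branches(base, mpairs[[k]], 3L, 4L)
    for (j in rel_at[[k]]) {
      op <- opairs[[j]][[k]]
      sf <- trans[j, 1L]
      sm <- 2L + trans[j, 2L]
      nxt <- list()
      for (a in base) {
        vf <- a[sf]; vm <- a[sm]
        if (!is.na(vf) && !is.na(vm)) {
          if ((vf == op[1] && vm == op[2]) || (vf == op[2] && vm == op[1])) {
            nxt[[length(nxt) + 1L]] <- a
          }
        } else if (!is.na(vf)) {
          if (vf == op[1]) { b <- a; b[sm] <- op[2]; nxt[[length(nxt) + 1L]] <- b }
          if (op[1] != op[2] && vf == op[2]) {
            b <- a; b[sm] <- op[1]; nxt[[length(nxt) + 1L]] <- b
          }
        } else if (!is.na(vm)) {
          if (vm == op[2]) { b <- a; b[sf] <- op[1]; nxt[[length(nxt) + 1L]] <- b }
          if (op[1] != op[2] && vm == op[1]) {
            b <- a; b[sf] <- op[2]; nxt[[length(nxt) + 1L]] <- b
          }
        } else {
          b <- a; b[c(sf, sm)] <- op; nxt[[length(nxt) + 1L]] <- b
          if (op[1] != op[2]) {
            b <- a; b[c(sf, sm)] <- rev(op); nxt[[length(nxt) + 1L]] <- b
          }
        }
      }
      base <- nxt
      if (!length(base)) break
    }
    base <- unique(base)
    if (!length(base)) {
      matrix(character(0), ncol = 4L)
    } else {
      do.call(rbind, base)
    }
  }

  memo <- new.env(parent = emptyenv())
  assignments_for <- function(k, trans) {
    rel <- rel_at[[k]]
    key <- paste(k, paste(trans[rel, 1L], trans[rel, 2L], collapse = ";"),
                 sep = "|")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- marker_assignments(k, trans)
    memo[[key]] <- res
    res
  }

  # transmission grid, with the symmetry reduction for free founders
  if (n_g == 0L) {
    trans_grid <- matrix(integer(0), nrow = 1L, ncol = 0L)
  } else {
    pat_opts <- rep(list(1:2), n_g)
    mat_opts <- rep(list(1:2), n_g)
    if (father_free) pat_opts[[1]] <- 1L
    if (mother_free) mat_opts[[1]] <- 1L
    if (prod(lengths(c(pat_opts, mat_opts))) > cap) {
      stop("phase configuration count exceeds cap; subset the marker panel ",
           "or reduce the family")
    }
    trans_grid <- as.matrix(expand.grid(c(pat_opts, mat_opts),
                                        KEEP.OUT.ATTRS = FALSE))
  }

  paste_key <- function(m) {
    m[is.na(m)] <- "~"
    do.call(paste, c(as.data.frame(m, stringsAsFactors = FALSE), sep = "-"))
  }
  acc <- list()
  total <- 0
  for (r in seq_len(nrow(trans_grid))) {
    trans <- matrix(trans_grid[r, ], ncol = 2L)
    A <- vector("list", L)
    feasible <- TRUE
    for (k in seq_len(L)) {
      a <- assignments_for(k, trans)
      if (!nrow(a)) { feasible <- FALSE; break }
      A[[k]] <- a
    }
    if (!feasible) next
    n_k <- vapply(A, nrow, 0L)
    n_conf <- prod(n_k)
    total <- total + n_conf
    if (total > cap) {
      stop("phase configuration count exceeds cap (", format(cap),
           "); subset the marker panel")
    }
    combos <- as.matrix(expand.grid(lapply(n_k, seq_len),
                                    KEEP.OUT.ATTRS = FALSE))
    slot <- lapply(1:4, function(s) {
      m <- vapply(seq_len(L), function(k) A[[k]][combos[, k], s],
                  character(nrow(combos)))
      matrix(m, nrow = nrow(combos), ncol = L)
    })
    k1 <- paste_key(slot[[1]]); k2 <- paste_key(slot[[2]])
    k3 <- paste_key(slot[[3]]); k4 <- paste_key(slot[[4]])
    sw_f <- str_less_c(k2, k1)
    sw_m <- str_less_c(k4, k3)
    f1 <- ifelse(sw_f, k2, k1); f2 <- ifelse(sw_f, k1, k2)
    m1 <- ifelse(sw_m, k4, k3); m2 <- ifelse(sw_m, k3, k4)
    if (n_g) {
      pat <- matrix(rep(trans[, 1L], each = n_conf), nrow = n_conf)
      mat <- matrix(rep(trans[, 2L], each = n_conf), nrow = n_conf)
      pat[sw_f, ] <- 3L - pat[sw_f, , drop = FALSE]
      mat[sw_m, ] <- 3L - mat[sw_m, , drop = FALSE]
      pat[f1 == f2, ] <- 1L
      mat[m1 == m2, ] <- 1L
      tkey <- do.call(paste, c(as.data.frame(pat), as.data.frame(mat),
                               sep = ","))
    } else {
      pat <- mat <- matrix(integer(0), nrow = n_conf, ncol = 0L)
      tkey <- rep("", n_conf)
    }
    acc[[length(acc) + 1L]] <- list(f1 = f1, f2 = f2, m1 = m1, m2 = m2,
                                    pat = pat, mat = mat, tkey = tkey)
  }
  if (!length(acc)) {
    viol <- find_mendelian_violation(father, mother, g_off, opairs, fpairs,
                                     mpairs, rel_at, ids, L, n_g,
                                     assignments_for)
    stop("genotypes are Mendelian-inconsistent", viol)
  }
  f1 <- unlist(lapply(acc, `[[`, "f1")); f2 <- unlist(lapply(acc, `[[`, "f2"))
  m1 <- unlist(lapply(acc, `[[`, "m1")); m2 <- unlist(lapply(acc, `[[`, "m2"))
  pat <- do.call(rbind, lapply(acc, `[[`, "pat"))
  mat <- do.call(rbind, lapply(acc, `[[`, "mat"))
  tkey <- unlist(lapply(acc, `[[`, "tkey"))
  full_key <- paste(f1, f2, m1, m2, tkey, sep = "|")
  ord <- order(full_key, method = "radix")
  keep <- ord[!duplicated(full_key[ord])]
  decode <- function(keys) {
    m <- do.call(rbind, strsplit(keys, "-", fixed = TRUE))
    m[m == "~"] <- NA_character_
    colnames(m) <- ids
    m
  }
  slots <- list(F1 = decode(f1[keep]), F2 = decode(f2[keep]),
                M1 = decode(m1[keep]), M2 = decode(m2[keep]),
                pat = pat[keep, , drop = FALSE],
                mat = mat[keep, , drop = FALSE])
  colnames(slots$pat) <- g_off
  colnames(slots$mat) <- g_off
  n_sol <- length(keep)
  solutions <- lapply(seq_len(n_sol), function(i) {
    trans <- cbind(pat = slots$pat[i, ], mat = slots$mat[i, ])
    rownames(trans) <- g_off
    list(father = rbind(slots$F1[i, ], slots$F2[i, ]),
         mother = rbind(slots$M1[i, ], slots$M2[i, ]),
         transmissions = trans)
  })
  structure(list(
    solutions = solutions,
    family_haplotypes = family_haplotype_set(slots, ids),
    founders = c(father = father, mother = mother),
    offspring = offspring,
    panel_ids = ids,
    slots = slots
  ), class = "phase_result")
}

# distinct fully determined haplotypes present in every solution: any such
# haplotype must occur in the first solution, so only its (at most four)
# complete haplotypes need checking against all solutions.
family_haplotype_set <- function(slots, ids) {
  key_mat <- vapply(slots[c("F1", "F2", "M1", "M2")], function(m) {
    k <- do.call(paste, c(as.data.frame(m, stringsAsFactors = FALSE),
                          sep = "-"))
    k[rowSums(is.na(m)) > 0L] <- NA_character_
    k
  }, character(nrow(slots$F1)))
  key_mat <- matrix(key_mat, nrow = nrow(slots$F1))
  cands <- unique(stats::na.omit(key_mat[1, ]))
  in_all <- vapply(cands, function(h) {
    all(rowSums(key_mat == h, na.rm = TRUE) > 0L)
  }, TRUE)
  common <- sort(cands[in_all], method = "radix")
  if (!length(common)) {
    return(matrix(character(0), nrow = 0, ncol = length(ids),
                  dimnames = list(NULL, ids)))
  }
  m <- do.call(rbind, strsplit(common, "-", fixed = TRUE))
  colnames(m) <- ids
  m
}

# locate a marker (and if possible a trio) admitting no assignment, for the
# Mendelian-inconsistency error message
find_mendelian_violation <- function(father, mother, g_off, opairs, fpairs,
                                     mpairs, rel_at, ids, L, n_g,
                                     assignments_for) {
  for (k in seq_len(L)) {
    combos <- as.matrix(expand.grid(rep(list(1:2), 2L * max(n_g, 1L))))
    any_ok <- FALSE
    for (r in seq_len(nrow(combos))) {
      trans <- matrix(combos[r, ], ncol = 2L)
      if (nrow(assignments_for(k, trans))) { any_ok <- TRUE; break }
    }
    if (!any_ok) {
      for (j in seq_len(n_g)) {
        op <- opairs[[j]][[k]]
        if (is.null(op)) next
        fp <- fpairs[[k]]
        mp <- mpairs[[k]]
        trio_ok <- any(vapply(list(op, rev(op)), function(o) {
          (is.null(fp) || o[1] %in% fp) && (is.null(mp) || o[2] %in% mp)
        }, TRUE))
        if (!trio_ok) {
          return(paste0(" at marker ", ids[k], " (trio ", g_off[j], "/",
                        father, "/", mother, ")"))
        }
      }
      return(paste0(" at marker ", ids[k], " (sibship jointly inconsistent)"))
    }
  }
  ""
}

#' @export
print.phase_result <- function(x, ...) {
  cat("Phase result: ", length(x$solutions), " solution(s) for family (",
      x$founders["father"], " x ", x$founders["mother"], "), ",
      length(x$offspring), " offspring, ", length(x$panel_ids),
      " markers\n", sep = "")
  cat("Fully determined haplotypes shared by all solutions: ",
      nrow(x$family_haplotypes), "\n", sep = "")
  if (nrow(x$family_haplotypes)) {
    cat(paste0("  ", apply(x$family_haplotypes, 1, hap_string)), sep = "\n")
  }
  invisible(x)
}

#' Haplotype background carrying a mutation, shared by all carriers
#'
#' Identifies, across all phase solutions, the founder haplotype that bears
#' the mutant allele and was transmitted to (or is carried by) every named
#' carrier. Solutions in which no founder haplotype satisfies all carriers
#' (e.g. the mutation rides the wrong parental lineage for a declared
#' obligate carrier) are discarded; if none survive, an error is raised.
#' Positions not forced to a single allele across the surviving candidate
#' haplotypes are returned as MISSING (`NA`).
#'
#' @param pr a `phase_result` from [enumerate_phasings()].
#' @param mutation_marker marker id of the mutation site.
#' @param mutant_allele the mutant allele symbol.
#' @param carriers sample ids of known carriers. May include ungenotyped
#'   founders (obligate carriers, e.g. a deceased affected parent), which
#'   restricts candidates to that founder's haplotypes. Order is
#'   irrelevant.
#' @param genos optional genotype list used to verify that genotyped
#'   carriers actually carry `mutant_allele` at `mutation_marker`.
#' @return Named character vector over the panel markers (`NA` = not
#'   forced), with attributes `n_solutions_used` and `n_candidates`.
#' @export
carrier_background <- function(pr, mutation_marker, mutant_allele, carriers,
                               genos = NULL) {
  ids <- pr$panel_ids
  k <- match(mutation_marker, ids)
  if (is.na(k)) stop("mutation marker ", mutation_marker, " not in panel")
  if (!length(carriers)) stop("at least one carrier required")
  unknown <- setdiff(carriers, c(pr$founders, pr$offspring))
  if (length(unknown)) {
    stop("carrier(s) not in family: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(genos)) {
    for (cr in intersect(carriers, names(genos))) {
      p <- genos[[cr]][mutation_marker, ]
      if (!anyNA(p) && !mutant_allele %in% p) {
        stop("carrier ", cr, " lacks allele ", mutant_allele, " at ",
             mutation_marker)
      }
    }
  }
  sl <- pr$slots
  n_sol <- nrow(sl$F1)
  slot_names <- c("F1", "F2", "M1", "M2")
  parent_of <- c(F1 = "father", F2 = "father", M1 = "mother", M2 = "mother")
  row_of <- c(F1 = 1L, F2 = 2L, M1 = 1L, M2 = 2L)
  cand_rows <- list()
  any_cand <- rep(FALSE, n_sol)
  for (nm in slot_names) {
    m <- sl[[nm]]
    sel <- !is.na(m[, k]) & m[, k] == mutant_allele
    for (cr in carriers) {
      if (!any(sel)) break
      if (cr == pr$founders[["father"]]) {
        if (parent_of[[nm]] != "father") sel[] <- FALSE
      } else if (cr == pr$founders[["mother"]]) {
        if (parent_of[[nm]] != "mother") sel[] <- FALSE
      } else {
        tmat <- if (parent_of[[nm]] == "father") sl$pat else sl$mat
        if (!cr %in% colnames(tmat)) next  # ungenotyped offspring: no constraint
        sel <- sel & tmat[, cr] == row_of[[nm]]
      }
    }
    if (any(sel)) {
      any_cand <- any_cand | sel
      cand_rows[[nm]] <- m[sel, , drop = FALSE]
    }
  }
  if (!length(cand_rows)) {
    stop("no phase solution places allele ", mutant_allele,
         " on a haplotype shared by all carriers")
  }
  cand <- do.call(rbind, cand_rows)
  background <- apply(cand, 2, function(col) {
    u <- unique(col)
    if (length(u) == 1L && !anyNA(u)) u else NA_character_
  })
  names(background) <- ids
  attr(background, "n_solutions_used") <- sum(any_cand)
  attr(background, "n_candidates") <- nrow(cand)
  background
}

#' Mutation background from homozygosity forcing alone
#'
#' When no family data are available, every marker at which a carrier is
#' homozygous forces the corresponding allele onto the mutation-bearing
#' haplotype; heterozygous markers stay MISSING. The mutation site itself is
#' set to the mutant allele.
#'
#' @param geno an `L x 2` genotype matrix (see [sample_genotypes()]).
#' @param mutation_marker,mutant_allele the mutation site and allele; the
#'   genotype must carry the mutant allele there.
#' @return Named character background vector (`NA` where unforced).
#' @export
genotype_background <- function(geno, mutation_marker, mutant_allele) {
  if (!mutation_marker %in% rownames(geno)) {
    stop("mutation marker ", mutation_marker, " not in genotype")
  }
  p <- geno[mutation_marker, ]
  if (!mutant_allele %in% p) {
    stop("genotype lacks allele ", mutant_allele, " at ", mutation_marker)
  }
  bg <- ifelse(!is.na(geno[, 1]) & !is.na(geno[, 2]) & geno[, 1] == geno[, 2],
               geno[, 1], NA_character_)
  bg[mutation_marker] <- mutant_allele
  names(bg) <- rownames(geno)
  bg
}
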