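# Shared fixtures and independent oracles. The phasing oracle enumerates
# whole-individual phase orderings (2^het per individual) and filters by
# transmission — a different search space from the package's per-marker
# constraint propagation, so agreement is a real cross-check.

test_panel <- function(L, alleles = list(c("A", "G"))) {
  if (length(alleles) == 1L) alleles <- rep(alleles, L)
  marker_panel(data.frame(id = paste0("m", seq_len(L)),
                          kind = "snp",
                          alleles = I(alleles),
                          stringsAsFactors = FALSE),
               name = "test")
}

# canonical solution key shared by oracle and package output; applying it
# to the package's (already canonical) solutions is idempotent
canonical_key <- function(F, M, trans) {
  kf <- apply(F, 1, paste, collapse = "-")
  if (kf[2] != kf[1] && sort(kf, method = "radix")[1] == kf[2]) {
    F <- F[2:1, , drop = FALSE]
    trans[, 1] <- 3L - trans[, 1]
    kf <- rev(kf)
  }
  if (kf[1] == kf[2]) trans[, 1] <- 1L
  km <- apply(M, 1, paste, collapse = "-")
  if (km[2] != km[1] && sort(km, method = "radix")[1] == km[2]) {
    M <- M[2:1, , drop = FALSE]
    trans[, 2] <- 3L - trans[, 2]
    km <- rev(km)
  }
  if (km[1] == km[2]) trans[, 2] <- 1L
  paste(c(kf, km, as.vector(trans)), collapse = "|")
}

solution_keys <- function(pr) {
  sort(vapply(pr$solutions, function(s) {
    canonical_key(s$father, s$mother, s$transmissions)
  }, ""))
}

# naive exponential oracle over all phase orderings of fully genotyped
# individuals (father, mother, offspring), filtered by transmission
oracle_phasings <- function(fg, mg, off_gen) {
  orderings <- function(g) {
    het <- which(g[, 1] != g[, 2])
    n <- length(het)
    out <- list()
    for (mask in 0:(2^n - 1)) {
      h1 <- g[, 1]; h2 <- g[, 2]
      if (n) {
        fl <- het[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
        tmp <- h1[fl]; h1[fl] <- h2[fl]; h2[fl] <- tmp
      }
      out[[length(out) + 1L]] <- rbind(h1, h2)
    }
    unique(out)
  }
  fo <- orderings(fg)
  mo <- orderings(mg)
  keys <- character(0)
  for (FF in fo) for (MM in mo) {
    trans_opts <- lapply(off_gen, function(g) {
      res <- list()
      for (p in 1:2) for (m in 1:2) {
        ok <- all((FF[p, ] == g[, 1] & MM[m, ] == g[, 2]) |
                  (FF[p, ] == g[, 2] & MM[m, ] == g[, 1]))
        if (ok) res[[length(res) + 1L]] <- c(p, m)
      }
      res
    })
    if (any(lengths(trans_opts) == 0L)) next
    grid <- expand.grid(lapply(trans_opts, seq_along))
    for (r in seq_len(nrow(grid))) {
      trans <- do.call(rbind, Map(function(ts, i) ts[[i]],
                                  trans_opts, as.integer(grid[r, ])))
      keys <- c(keys, canonical_key(FF, MM, trans))
    }
  }
  sort(unique(keys), method = "radix")
}

# random fully genotyped Mendelian-consistent nuclear family over <= 5
# markers; parents drawn from a small haplotype pool so sibs share
# backgrounds (as in a founder-effect family)
random_family <- function(seed) {
  set.seed(seed)
  L <- sample(2:5, 1)
  n_off <- sample(1:4, 1)
  panel <- test_panel(L, lapply(seq_len(L), function(k) {
    sample(c("A", "C", "G", "T"), 2)
  }))
  pool_n <- sample(2:4, 1)
  pool <- t(vapply(seq_len(pool_n), function(i) {
    vapply(panel$alleles, function(al) sample(al, 1), "")
  }, character(L)))
  draw <- function() pool[sample(pool_n, 1), ]
  fh <- list(draw(), draw())
  mh <- list(draw(), draw())
  strip <- function(h1, h2) {
    m <- matrix(NA_character_, L, 2, dimnames = list(panel$id, c("a1", "a2")))
    for (k in seq_len(L)) m[k, ] <- sample(c(h1[k], h2[k]))
    m
  }
  genos <- list("F" = strip(fh[[1]], fh[[2]]), "M" = strip(mh[[1]], mh[[2]]))
  for (o in seq_len(n_off)) {
    genos[[paste0("O", o)]] <- strip(fh[[sample(2, 1)]], mh[[sample(2, 1)]])
  }
  ped <- pedigree(data.frame(
    id = c("F", "M", paste0("O", seq_len(n_off))),
    father = c(NA, NA, rep("F", n_off)),
    mother = c(NA, NA, rep("M", n_off)),
    sex = c(1, 2, rep(0, n_off)),
    affected = FALSE, stringsAsFactors = FALSE))
  list(panel = panel, ped = ped, genos = genos,
       truth = list(father = fh, mother = mh))
}

# small phased VCF + popmap on disk for reader tests
sim_fixture <- function(seed = 5, n_samples = c(IBS = 3L), dir = tempfile()) {
  spectra <- stats::setNames(
    rep(list(default_spectrum()), length(n_samples)), names(n_samples))
  cfg <- sim_config(spectra = spectra, n_samples = n_samples, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_fixture_set(cfg, dir)
  list(cfg = cfg, paths = paths, dir = dir)
}

extdata <- function(f) system.file("extdata", f, package = "founderhap",
                                   mustWork = TRUE)
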