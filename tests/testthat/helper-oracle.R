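# Independent brute-force oracles. These deliberately use explicit nested
# loops and scalar arithmetic, sharing no code path with the package
# implementation they check.

# Unordered pair frequencies of a list of codon vectors, by explicit loops.
oracle_pair_stats <- function(codon_lists, assignment_table) {
  counts <- list()
  total <- 0L
  dropped <- 0L
  for (codons in codon_lists) {
    if (length(codons) < 2L) next
    for (i in seq_len(length(codons) - 1L)) {
      c1 <- codons[i]; c2 <- codons[i + 1L]
      if (is.na(c1) || is.na(c2)) next
      t1 <- assignment_table[[c1]]
      t2 <- assignment_table[[c2]]
      if (is.null(t1) || is.null(t2) || is.na(t1) || is.na(t2)) {
        dropped <- dropped + 1L
        next
      }
      key <- if (t1 <= t2) paste(t1, t2, sep = ":") else paste(t2, t1, sep = ":")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      total <- total + 1L
    }
  }
  freqs <- numeric(0)
  for (key in sort(names(counts))) freqs[key] <- counts[[key]] / total
  list(counts = counts, total = total, dropped = dropped, freqs = freqs)
}

# Full E-factor table by loops: per-pair frequencies, ratio, rarity rank.
oracle_efactor <- function(poi_codons, bg_codon_lists, assignment_table,
                           universe_pair_ids) {
  poi <- oracle_pair_stats(list(poi_codons), assignment_table)
  bg <- oracle_pair_stats(bg_codon_lists, assignment_table)
  n <- length(universe_pair_ids)
  f_poi <- f_bg <- ef <- numeric(n)
  for (i in seq_len(n)) {
    p <- universe_pair_ids[i]
    f_poi[i] <- if (!is.na(poi$freqs[p])) poi$freqs[[p]] else 0
    f_bg[i] <- if (!is.na(bg$freqs[p])) bg$freqs[[p]] else 0
    ef[i] <- if (f_poi[i] == 0) 0
             else if (f_bg[i] > 0) f_poi[i] / f_bg[i]
             else Inf
  }
  rank_rarity <- integer(n)
  for (i in seq_len(n)) {
    r <- 1L
    for (j in seq_len(n)) if (f_bg[j] < f_bg[i]) r <- r + 1L
    rank_rarity[i] <- r
  }
  data.frame(pair_id = universe_pair_ids, f_poi = f_poi, f_bg = f_bg,
             efactor = ef, bg_rank_rarity = rank_rarity,
             stringsAsFactors = FALSE)
}

# Two-sided Fisher p for a 2x2 table by exhaustive hypergeometric tail
# summation: sum of probabilities of all tables (same margins) no more
# probable than the observed one. The 1 + 1e-7 tie guard is part of the
# standard operational definition for floating-point tie detection.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0L, k - n)
  hi <- min(k, m)
  d_obs <- stats::dhyper(a, m, n, k)
  p <- 0
  for (x in lo:hi) {
    dx <- stats::dhyper(x, m, n, k)
    if (dx <= d_obs * (1 + 1e-7)) p <- p + dx
  }
  min(p, 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Random codon vector decodable by the given assignment (sense codons only).
random_codons <- function(n, codon_pool) {
  sample(codon_pool, n, replace = TRUE)
}

# Shared small fixtures ------------------------------------------------------

# Packaged synthetic isoacceptor table, its assignment and pair universe.
pkg_iso <- parse_isoacceptor_table(synthetic_trna_table())
pkg_assignment <- build_codon_assignment(pkg_iso)
pkg_pairs <- enumerate_pairs(pkg_iso)

# A 10-member toy set (55 pairs) for oracle-equivalence sweeps.
toy_iso <- isoacceptor_set(
  amino_acid = c("Ile", "Ile", "Gly", "Gly", "Pro", "Pro", "Met", "Lys",
                 "Glu", "Phe"),
  anticodon = c("UAU", "AAU", "CCC", "GCC", "AGG", "CGG", "CAU", "UUU",
                "UUC", "GAA"),
  species_label = "toy10")
toy_assignment <- build_codon_assignment(toy_iso)
toy_pairs <- enumerate_pairs(toy_iso)
# codons the toy set can decode
toy_codon_pool <- names(toy_assignment$table)

make_transcriptome <- function(codon_lists, label = "test") {
  recs <- lapply(seq_along(codon_lists), function(i)
    structure(list(id = sprintf("r%03d", i), codons = codon_lists[[i]],
                   source_length_nt = 3L * length(codon_lists[[i]])),
              class = "coding_sequence"))
  transcriptome(recs, label)
}

make_cds <- function(codons, id = "poi") {
  structure(list(id = id, codons = codons,
                 source_length_nt = 3L * length(codons)),
            class = "coding_sequence")
}
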