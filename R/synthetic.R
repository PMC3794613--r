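# Seeded synthetic coding-sequence generation: i.i.d.-codon backgrounds,
# constructive dicodon spiking at a target enrichment, and a deterministic
# viral-like 10-record fixture for end-to-end tests.

#' Configuration for the synthetic sequence generator
#'
#' @param seed Integer seed; every generator call is fully reproducible from
#'   it.
#' @param n_transcripts Number of background records (>= 1).
#' @param length_codons Either a single codon count (fixed length) or a
#'   `c(min, max)` range sampled uniformly per record.
#' @param codon_weights Optional named probability vector over codons.
#'   Unnamed entries for stop codons are ignored and weights are renormalized
#'   over the 61 sense codons; default is uniform.
#' @param spike Optional list describing a planted dicodon:
#'   `dicodon` (character 2-vector of codons), exactly one of `e_true`
#'   (target enrichment over the background pair frequency) or `f_poi`
#'   (target POI pair frequency), and `length_codons` for the spiked CDS.
#' @param alphabet `"RNA"` or `"DNA"` letters for FASTA output.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed, n_transcripts = 500L,
                             length_codons = 300L,
                             codon_weights = NULL, spike = NULL,
                             alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (n_transcripts < 1L) stop("n_transcripts must be >= 1")
  if (!length(length_codons) %in% c(1L, 2L) || any(length_codons < 1L))
    stop("length_codons must be a positive scalar or c(min, max)")
  sc <- sense_codons()
  if (is.null(codon_weights)) {
    codon_weights <- stats::setNames(rep(1 / 61, 61L), sc)
  } else {
    if (is.null(names(codon_weights))) stop("codon_weights must be named")
    names(codon_weights) <- normalize_rna(names(codon_weights))
    w <- stats::setNames(numeric(61L), sc)
    keep <- intersect(names(codon_weights), sc)
    w[keep] <- codon_weights[keep]
    if (sum(w) <= 0)
      stop("degenerate codon_weights: no mass on sense codons")
    codon_weights <- w / sum(w)
  }
  if (!is.null(spike)) {
    if (is.null(spike$dicodon) || length(spike$dicodon) != 2L)
      stop("spike$dicodon must name two codons")
    spike$dicodon <- normalize_rna(spike$dicodon)
    if (!all(spike$dicodon %in% sc)) stop("spike$dicodon must be sense codons")
    if (is.null(spike$e_true) && is.null(spike$f_poi))
      stop("spike needs e_true or f_poi")
    if (!is.null(spike$e_true) && spike$e_true <= 0)
      stop("e_true must be positive")
    if (is.null(spike$length_codons)) spike$length_codons <- 300L
  }
  structure(list(seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
                 length_codons = as.integer(length_codons),
                 codon_weights = codon_weights, spike = spike,
                 alphabet = alphabet),
            class = "synthetic_config")
}

sample_lengths <- function(cfg, n) {
  if (length(cfg$length_codons) == 1L) rep(cfg$length_codons, n)
  else sample(seq(cfg$length_codons[1L], cfg$length_codons[2L]), n,
              replace = TRUE)
}

#' Generate a synthetic background transcriptome
#'
#' Records are drawn i.i.d. codon-by-codon from the configured codon weights
#' (stop codons carry zero weight, so no internal stops are emitted). The
#' result is fully reproducible from the seed.
#'
#' @param cfg A [synthetic_config()].
#' @param file Optional FASTA output path; a JSON sidecar
#'   `<file>.config.json` with the generating parameters is written next to
#'   it.
#' @return A `transcriptome`.
#' @export
generate_background <- function(cfg, file = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  t <- with_seed(cfg$seed, {
    lens <- sample_lengths(cfg, cfg$n_transcripts)
    draws <- sample(names(cfg$codon_weights), sum(lens), replace = TRUE,
                    prob = cfg$codon_weights)
    ends <- cumsum(lens)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    records <- lapply(seq_len(cfg$n_transcripts), function(i)
      make_coding_sequence(sprintf("synth_%04d_seed%d", i, cfg$seed),
                           draws[starts[i]:ends[i]], 3L * lens[i]))
    transcriptome(records, sprintf("synthetic_background_seed%d", cfg$seed))
  })
  if (!is.null(file)) {
    write_cds_fasta(t, file, alphabet = cfg$alphabet)
    jsonlite::write_json(list(seed = cfg$seed,
                              n_transcripts = cfg$n_transcripts,
                              length_codons = cfg$length_codons,
                              alphabet = cfg$alphabet),
                         paste0(file, ".config.json"), auto_unbox = TRUE)
  }
  t
}

# Fill NA slots of a codon template left-to-right, sampling from weights but
# rejecting candidates that would complete a dicodon decoding to target_pair.
fill_template <- function(template, weights, assignment, target_pair) {
  pool <- names(weights)[weights > 0]
  map <- assignment$table
  ids <- strsplit(target_pair, ":", fixed = TRUE)[[1L]]
  cod_x <- names(map)[!is.na(map) & map == ids[1L]]
  cod_y <- names(map)[!is.na(map) & map == ids[2L]]
  # codons that, adjacent to z, would complete a dicodon decoding to the pair
  forbidden_neighbors <- function(z) {
    out <- character(0)
    if (z %in% cod_x) out <- cod_y
    if (z %in% cod_y) out <- union(out, cod_x)
    out
  }
  for (i in seq_along(template)) {
    if (!is.na(template[i])) next
    forb <- character(0)
    if (i > 1L && !is.na(template[i - 1L]))
      forb <- forbidden_neighbors(template[i - 1L])
    if (i < length(template) && !is.na(template[i + 1L]))
      forb <- union(forb, forbidden_neighbors(template[i + 1L]))
    allowed <- if (length(forb)) setdiff(pool, forb) else pool
    if (length(allowed) == 0L)
      stop("cannot fill template without creating the target pair")
    w <- weights[allowed]
    template[i] <- sample(allowed, 1L, prob = w / sum(w))
  }
  template
}

#' Construct a spiked protein of interest
#'
#' Builds a CDS of the configured length whose realized frequency of the
#' spiked tRNA pair equals the closest achievable value to
#' `E_true x f_bg(pair)` (occurrence counts are integers, so the target is
#' rounded; the achievable enrichment is reported in the attributes).
#' Spiking is constructive: homotypic dicodons are planted as one run of
#' k + 1 identical codons, heterotypic ones as k isolated two-codon blocks;
#' filler codons are sampled from the background weights under rejection so
#' that no accidental dicodon decodes to the target pair.
#'
#' @param cfg A [synthetic_config()] with `spike` set.
#' @param bg `pair_freqs` of the background the enrichment is relative to.
#' @param assignment The `codon_assignment` shared by POI and background.
#' @return A `coding_sequence` with attributes `target_pair`, `k`
#'   (planted occurrences), `achievable_e`, `f_bg`.
#' @export
generate_spiked_poi <- function(cfg, bg, assignment) {
  stopifnot(inherits(cfg, "synthetic_config"), !is.null(cfg$spike),
            inherits(bg, "pair_freqs"), inherits(assignment, "codon_assignment"))
  sp <- cfg$spike
  c1 <- sp$dicodon[1L]; c2 <- sp$dicodon[2L]
  id1 <- assignment$table[c1]; id2 <- assignment$table[c2]
  if (is.na(id1) || is.na(id2))
    stop("spike dicodon contains an unassignable codon")
  target <- pair_id(unname(id1), unname(id2))
  f_bg <- unname(freq_of(bg, target))
  if (f_bg <= 0) stop("target pair has zero background frequency")
  L <- as.integer(sp$length_codons)
  f_poi <- if (!is.null(sp$f_poi)) sp$f_poi else sp$e_true * f_bg
  if (f_poi > 1)
    stop(sprintf("target POI frequency %.3g exceeds 1; lower e_true", f_poi))
  k <- as.integer(round(f_poi * (L - 1L)))
  homotypic <- c1 == c2
  k_max <- if (homotypic) L - 1L else (L + 1L) %/% 3L
  if (k > k_max) {
    l_min <- if (homotypic) k + 1L else 3L * k - 1L
    stop(sprintf("%d occurrences do not fit in %d codons; minimum length %d",
                 k, L, l_min))
  }
  template <- rep(NA_character_, L)
  if (homotypic) {
    if (k > 0L) template[seq_len(k + 1L)] <- c1
  } else if (k > 0L) {
    starts <- 3L * (seq_len(k) - 1L) + 1L
    template[starts] <- c1
    template[starts + 1L] <- c2
  }
  codons <- with_seed(cfg$seed + 1L,
                      fill_template(template, cfg$codon_weights, assignment,
                                    target))
  poi <- make_coding_sequence(sprintf("spiked_poi_seed%d", cfg$seed),
                              codons, 3L * L)
  realized <- aggregate_pair_counts(count_dicodons(poi), assignment)
  got <- realized$counts[target]
  got <- if (is.na(got)) 0L else got
  if (got != k)
    stop(sprintf("internal error: planted %d target dicodons, realized %d",
                 k, got))
  attr(poi, "target_pair") <- target
  attr(poi, "k") <- k
  attr(poi, "f_bg") <- f_bg
  attr(poi, "achievable_e") <- (k / (L - 1L)) / f_bg
  poi
}

#' Deterministic viral-like transcriptome fixture
#'
#' A packaged, fully deterministic 10-record transcriptome mimicking the
#' structure of a segmented-virus coding set: one designated rare dicodon
#' (AUA:AUA by default, decoded by the homotypic Ile-UAU pair under the
#' packaged synthetic isoacceptor table) occurs exactly four times in total -
#' twice in the `NS3_like` record and once each in `VP1_like` and `NS1_like` -
#' and nowhere else. Regeneration is byte-identical.
#'
#' @param assignment Optional `codon_assignment` used to keep filler codons
#'   from creating extra copies of the target pair; defaults to the packaged
#'   synthetic table under default rules.
#' @return A `transcriptome` with attributes `target_dicodon` and
#'   `planted` (named integer vector of per-record occurrence counts).
#' @export
viral_like_fixture <- function(assignment = NULL) {
  if (is.null(assignment)) {
    iso <- parse_isoacceptor_table(synthetic_trna_table())
    assignment <- build_codon_assignment(iso)
  }
  target <- c("AUA", "AUA")
  tp <- pair_id(unname(assignment$table[target[1L]]),
                unname(assignment$table[target[2L]]))
  names_len <- c(VP1_like = 240L, VP2_like = 220L, VP3_like = 180L,
                 VP4_like = 160L, VP5_like = 150L, VP6_like = 120L,
                 VP7_like = 110L, NS1_like = 130L, NS2_like = 100L,
                 NS3_like = 90L)
  planted <- c(VP1_like = 1L, VP2_like = 0L, VP3_like = 0L, VP4_like = 0L,
               VP5_like = 0L, VP6_like = 0L, VP7_like = 0L, NS1_like = 1L,
               NS2_like = 0L, NS3_like = 2L)
  plant_at <- list(VP1_like = 60L, NS1_like = 40L, NS3_like = c(20L, 50L))
  weights <- stats::setNames(rep(1 / 61, 61L), sense_codons())
  records <- with_seed(20130829L, lapply(names(names_len), function(nm) {
    L <- names_len[[nm]]
    template <- rep(NA_character_, L)
    for (pos in plant_at[[nm]] %||% integer(0))
      template[c(pos, pos + 1L)] <- target
    codons <- fill_template(template, weights, assignment, tp)
    make_coding_sequence(nm, codons, 3L * L)
  }))
  out <- transcriptome(records, "viral_like_fixture")
  attr(out, "target_dicodon") <- target
  attr(out, "planted") <- planted
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
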