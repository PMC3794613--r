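# E-factor computation, ranking, control-pair selection and the
# transcriptome-wide leading-pair survey.
#
# E-factor = (frequency of a tRNA pair among the POI's dicodons) /
#            (estimated frequency of the same pair in the background
#             transcriptome).
# A high E-factor means FRET signal from that labeled pair is attributable to
# synthesis of the POI rather than to background translation.

universe_ids <- function(universe) {
  if (inherits(universe, "trna_pairs")) universe$pair_id
  else if (is.character(universe)) universe
  else stop("universe must be a trna_pairs object or character vector of pair ids")
}

#' Compute E-factors for all tRNA pairs of a POI against a background
#'
#' One record is produced per pair in the universe; pairs observed in neither
#' input get frequency 0 on both sides and E-factor 0. The background rarity
#' rank (`bg_rank_rarity`, 1 = rarest) uses competition ranking, ties sharing
#' the minimum rank. A pair present in the POI but absent from the background
#' gets an infinite E-factor under the default `"sentinel"` policy; the
#' `"pseudocount"` policy instead adds `alpha` to every background pair count
#' and renormalizes, which keeps all E-factors finite (records are then
#' flagged `pseudocounted`).
#'
#' @param poi `pair_freqs` of the protein of interest.
#' @param bg `pair_freqs` of the background transcriptome.
#' @param universe All enumerable pairs ([enumerate_pairs()] output or a
#'   character vector of pair ids).
#' @param zero_policy `"sentinel"` (default) or `"pseudocount"`.
#' @param alpha Pseudocount added per pair when `zero_policy = "pseudocount"`.
#' @return Object of class `efactor_table`: a data frame with columns
#'   `pair_id`, `f_poi`, `f_bg`, `efactor`, `bg_rank_rarity`, `flags`, sorted
#'   by descending E-factor (ties: lower `f_bg`, then lexicographic pair id);
#'   metadata in attributes `poi_id`, `background_label`, `mode`,
#'   `zero_policy`.
#' @export
compute_efactors <- function(poi, bg, universe,
                             zero_policy = c("sentinel", "pseudocount"),
                             alpha = 1) {
  stopifnot(inherits(poi, "pair_freqs"), inherits(bg, "pair_freqs"))
  zero_policy <- match.arg(zero_policy)
  ids <- universe_ids(universe)
  stray <- setdiff(c(names(poi$freqs), names(bg$freqs)), ids)
  if (length(stray))
    stop("pair(s) outside the universe (mismatched universes?): ",
         paste(utils::head(stray, 3L), collapse = ", "))
  f_poi <- freq_of(poi, ids)
  f_bg <- freq_of(bg, ids)
  pseudocounted <- FALSE
  if (zero_policy == "pseudocount") {
    counts <- f_bg * bg$support_total
    f_bg <- (counts + alpha) / (sum(counts) + alpha * length(ids))
    pseudocounted <- TRUE
  }
  efactor <- ifelse(f_poi == 0, 0,
                    ifelse(f_bg > 0, f_poi / f_bg, Inf))
  flags <- character(length(ids))
  if (pseudocounted) flags[] <- "pseudocounted"
  else flags[f_bg == 0] <- "zero_background"
  out <- data.frame(pair_id = ids, f_poi = unname(f_poi), f_bg = unname(f_bg),
                    efactor = unname(efactor),
                    bg_rank_rarity = rank(unname(f_bg), ties.method = "min"),
                    flags = flags,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$efactor, out$f_bg, out$pair_id), ]
  rownames(out) <- NULL
  structure(out,
            poi_id = poi$label, background_label = bg$label,
            mode = bg$mode, zero_policy = zero_policy,
            class = c("efactor_table", "data.frame"))
}

#' Leading tRNA pair of an E-factor table
#'
#' The maximal-E-factor record under the tie-break: higher E-factor, then
#' lower background frequency, then lexicographic pair id; infinite E-factors
#' outrank all finite ones.
#'
#' @param table An `efactor_table`.
#' @return List with `pair_id`, `efactor`, `f_poi`, `f_bg` and `flag`
#'   (`"no_signal"` when every E-factor is zero, `""` otherwise).
#' @export
leading_pair <- function(table) {
  stopifnot(inherits(table, "efactor_table"), nrow(table) > 0L)
  ord <- order(-table$efactor, table$f_bg, table$pair_id)
  top <- table[ord[1L], ]
  list(pair_id = top$pair_id, efactor = top$efactor,
       f_poi = top$f_poi, f_bg = top$f_bg,
       flag = if (all(table$efactor == 0)) "no_signal" else "")
}

#' Select negative-control tRNA pairs
#'
#' A negative-control pair decodes a dicodon absent from the POI but common in
#' the background: its FRET signal should not respond to POI synthesis.
#' Admissible pairs have POI frequency exactly 0 and background frequency at
#' least `min_bg_multiple` times the uniform frequency `1 / |universe|`.
#'
#' @param poi,bg `pair_freqs` objects.
#' @param universe Pair universe as in [compute_efactors()].
#' @param min_bg_multiple Minimum background frequency, as a multiple of the
#'   uniform pair frequency (default 2).
#' @return Data frame (`pair_id`, `f_bg`) sorted by descending background
#'   frequency; zero rows when no pair is admissible.
#' @export
select_control_pair <- function(poi, bg, universe, min_bg_multiple = 2) {
  stopifnot(min_bg_multiple > 0)
  ids <- universe_ids(universe)
  f_poi <- freq_of(poi, ids)
  f_bg <- freq_of(bg, ids)
  keep <- f_poi == 0 & f_bg >= min_bg_multiple / length(ids)
  out <- data.frame(pair_id = ids[keep], f_bg = unname(f_bg[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$f_bg, out$pair_id), ]
  rownames(out) <- NULL
  out
}

#' Transcriptome-wide leading-pair survey
#'
#' For every transcript: compute its pair frequencies, E-factors against the
#' background, and its leading pair; then summarize what fraction of
#' transcripts has a leading E-factor above/below the thresholds. By default
#' each transcript is scored against the full background including itself;
#' `leave_one_out = TRUE` removes the transcript's own dicodons from the pool
#' first (pooled mode only).
#'
#' @param targets `transcriptome` of transcripts to survey.
#' @param bg `pair_freqs` background (pooled mode when `leave_one_out`).
#' @param assignment A `codon_assignment`.
#' @param universe Pair universe.
#' @param thresholds List with `above_strict` (fraction with leading E
#'   strictly greater; default 100), `above` (non-strict, default 20) and
#'   `below` (strict, default 10).
#' @param leave_one_out Remove each transcript's own counts from the
#'   background before scoring it.
#' @param zero_policy,alpha Passed to [compute_efactors()].
#' @return Object of class `survey_summary`: `n_transcripts`, `leading` (data
#'   frame id/pair_id/efactor), `fraction_above` (named by threshold),
#'   `fraction_below`, `thresholds`, `n_skipped`.
#' @export
survey_transcriptome <- function(targets, bg, assignment, universe,
                                 thresholds = list(above_strict = 100,
                                                   above = 20, below = 10),
                                 leave_one_out = FALSE,
                                 zero_policy = "sentinel", alpha = 1) {
  stopifnot(inherits(targets, "transcriptome"))
  ids <- universe_ids(universe)
  if (leave_one_out && bg$mode != "pooled")
    stop("leave_one_out requires a pooled background")
  bg_counts <- if (leave_one_out) round(bg$freqs * bg$support_total) else NULL
  rows <- list()
  n_skipped <- 0L
  for (r in targets$records) {
    pc <- aggregate_pair_counts(count_dicodons(r), assignment)
    if (pc$total == 0L) { n_skipped <- n_skipped + 1L; next }
    pf <- pair_freqs_from_counts(pc, mode = "single", label = r$id)
    this_bg <- bg
    if (leave_one_out) {
      cc <- bg_counts
      cc[names(pc$counts)] <- cc[names(pc$counts)] - pc$counts
      cc <- cc[cc > 0]
      tot <- sum(cc)
      if (tot == 0) { n_skipped <- n_skipped + 1L; next }
      this_bg <- structure(list(freqs = cc / tot, support_total = tot,
                                dropped = bg$dropped, mode = "pooled",
                                label = paste0(bg$label, " \\ ", r$id)),
                           class = "pair_freqs")
    }
    et <- compute_efactors(pf, this_bg, ids, zero_policy = zero_policy,
                           alpha = alpha)
    lp <- leading_pair(et)
    rows[[length(rows) + 1L]] <-
      data.frame(id = r$id, pair_id = lp$pair_id, efactor = lp$efactor,
                 stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no surveyable transcripts")
  leading <- do.call(rbind, rows)
  n <- nrow(leading)
  fa <- c(mean(leading$efactor > thresholds$above_strict),
          mean(leading$efactor >= thresholds$above))
  names(fa) <- as.character(c(thresholds$above_strict, thresholds$above))
  fb <- stats::setNames(mean(leading$efactor < thresholds$below),
                        as.character(thresholds$below))
  structure(list(n_transcripts = n, leading = leading,
                 fraction_above = fa, fraction_below = fb,
                 thresholds = thresholds, n_skipped = n_skipped,
                 leave_one_out = leave_one_out),
            class = "survey_summary")
}

#' Export an E-factor table as TSV
#'
#' @param table An `efactor_table`.
#' @param file Output path.
#' @export
write_efactor_table <- function(table, file) {
  stopifnot(inherits(table, "efactor_table"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# poi=%s", attr(table, "poi_id")),
               sprintf("# background=%s", attr(table, "background_label")),
               sprintf("# mode=%s", attr(table, "mode")),
               sprintf("# zero_policy=%s", attr(table, "zero_policy")),
               "pair_id\tf_poi\tf_bg\tefactor\tbg_rank_rarity\tflags"), con)
  writeLines(sprintf("%s\t%s\t%s\t%s\t%d\t%s",
                     table$pair_id,
                     formatC(table$f_poi, digits = 6, format = "g"),
                     formatC(table$f_bg, digits = 6, format = "g"),
                     ifelse(is.infinite(table$efactor), "Inf",
                            formatC(table$efactor, digits = 6, format = "g")),
                     table$bg_rank_rarity, table$flags), con)
  invisible(file)
}

#' Export a pairs-by-POIs E-factor matrix
#'
#' Writes one row per pair appearing above `min_show` in any POI and one
#' column per POI; cells at or above `highlight` are marked with a trailing
#' `*`, mirroring the convention of highlighting strongly enriched pairs.
#'
#' @param tables Named list of `efactor_table` objects (one per POI).
#' @param file Output path.
#' @param highlight Highlight threshold (default 50).
#' @param min_show Only include pairs whose E-factor reaches this value in at
#'   least one POI (default 1).
#' @export
write_efactor_matrix <- function(tables, file, highlight = 50, min_show = 1) {
  stopifnot(length(tables) > 0L)
  ids <- tables[[1L]]$pair_id
  mat <- vapply(tables, function(t) {
    stats::setNames(t$efactor, t$pair_id)[ids]
  }, numeric(length(ids)))
  mat <- matrix(mat, nrow = length(ids),
                dimnames = list(ids, names(tables)))
  keep <- apply(mat, 1L, function(z) any(z >= min_show))
  mat <- mat[keep, , drop = FALSE]
  cells <- apply(mat, 2L, function(z)
    paste0(formatC(z, digits = 4, format = "g"),
           ifelse(z >= highlight, "*", "")))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# highlight_threshold=%s (*)", highlight), con)
  writeLines(paste(c("pair_id", colnames(mat)), collapse = "\t"), con)
  writeLines(paste(rownames(mat), apply(cells, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(file)
}

#' Export a survey as per-transcript TSV plus JSON summary
#'
#' @param s A `survey_summary`.
#' @param prefix Output path prefix; writes `<prefix>_leading.tsv` and
#'   `<prefix>_summary.json`.
#' @export
write_survey <- function(s, prefix) {
  stopifnot(inherits(s, "survey_summary"))
  tsv <- paste0(prefix, "_leading.tsv")
  utils::write.table(s$leading, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- paste0(prefix, "_summary.json")
  jsonlite::write_json(list(n_transcripts = s$n_transcripts,
                            n_skipped = s$n_skipped,
                            leave_one_out = s$leave_one_out,
                            fraction_above = as.list(s$fraction_above),
                            fraction_below = as.list(s$fraction_below)),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' @export
print.efactor_table <- function(x, ...) {
  cat(sprintf("E-factor table: POI '%s' vs background '%s' (%s, %s)\n",
              attr(x, "poi_id"), attr(x, "background_label"),
              attr(x, "mode"), attr(x, "zero_policy")))
  print.data.frame(utils::head(as.data.frame(x), 8L), digits = 5)
  invisible(x)
}

#' @export
print.survey_summary <- function(x, ...) {
  cat(sprintf("Leading-pair survey: %d transcripts (%d skipped)\n",
              x$n_transcripts, x$n_skipped))
  for (nm in names(x$fraction_above))
    cat(sprintf("  leading E > or >= %s: %.1f%%\n", nm,
                100 * x$fraction_above[[nm]]))
  for (nm in names(x$fraction_below))
    cat(sprintf("  leading E < %s: %.1f%%\n", nm, 100 * x$fraction_below[[nm]]))
  invisible(x)
}
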