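# Relative codon usage and between-set enrichment testing.

#' Pooled relative codon usage of a transcriptome
#'
#' @param t A `transcriptome` (terminal stops already stripped on input).
#' @return Object of class `codon_usage_table`: data frame over the 61 sense
#'   codons with columns `codon`, `amino_acid`, `count`, `freq`
#'   (`freq` sums to 1).
#' @export
codon_usage <- function(t) {
  stopifnot(inherits(t, "transcriptome"))
  codons <- unlist(lapply(t$records, function(r) r$codons), use.names = FALSE)
  codons <- codons[!is.na(codons)]
  if (length(codons) == 0L) stop("no usable codons")
  counts <- stats::setNames(integer(61), sense_codons())
  tab <- table(codons)
  counts[names(tab)] <- as.integer(tab)
  out <- data.frame(codon = sense_codons(),
                    amino_acid = codon_amino_acid(sense_codons()),
                    count = unname(counts),
                    freq = unname(counts) / sum(counts),
                    stringsAsFactors = FALSE)
  structure(out, total = sum(counts), label = t$label,
            class = c("codon_usage_table", "data.frame"))
}

#' Test enrichment of one codon between two sequence sets
#'
#' Compares the relative usage of a codon in set A versus set B on pooled
#' counts. The fold change is the ratio of relative usages under the chosen
#' denominator; the p-value comes from a two-sided Fisher's exact test on the
#' 2x2 table (codon vs rest-of-denominator, set A vs set B). With
#' `denominator = "synonymous_family"` the comparison is restricted to the
#' codon's synonymous family (e.g. AUA among the three Ile codons).
#'
#' @param codon A sense codon (DNA or RNA letters).
#' @param setA,setB `transcriptome` objects.
#' @param denominator `"all_codons"` (default) or `"synonymous_family"`.
#' @param test `"fisher"` (default, exact) or `"gtest"` (likelihood-ratio
#'   G-test with chi-squared reference).
#' @return Object of class `enrichment_result`: list with `codon`, `fold`
#'   (A over B; `NA` and flagged when the codon is absent from both sets),
#'   `p_value`, `table2x2`, `test_name`, `denominator`, `flag`.
#' @export
codon_enrichment_test <- function(codon, setA, setB,
                                  denominator = c("all_codons",
                                                  "synonymous_family"),
                                  test = c("fisher", "gtest")) {
  denominator <- match.arg(denominator)
  test <- match.arg(test)
  codon <- normalize_rna(codon)
  if (!codon %in% sense_codons()) stop("not a sense codon: ", codon)
  ua <- codon_usage(setA)
  ub <- codon_usage(setB)
  in_denom <- if (denominator == "all_codons") rep(TRUE, 61L)
              else ua$amino_acid == codon_amino_acid(codon)
  a_codon <- ua$count[ua$codon == codon]
  b_codon <- ub$count[ub$codon == codon]
  a_rest <- sum(ua$count[in_denom]) - a_codon
  b_rest <- sum(ub$count[in_denom]) - b_codon
  tab <- matrix(c(a_codon, a_rest, b_codon, b_rest), nrow = 2L,
                dimnames = list(c(codon, "other"), c("setA", "setB")))
  flag <- ""
  if (a_codon + b_codon == 0L) {
    fold <- NA_real_
    p <- 1
    flag <- "codon_absent_from_both_sets"
    test_name <- "none"
  } else {
    rel_a <- a_codon / (a_codon + a_rest)
    rel_b <- b_codon / (b_codon + b_rest)
    fold <- if (rel_b > 0) rel_a / rel_b else Inf
    if (test == "fisher") {
      p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
      test_name <- "fisher_exact_two_sided"
    } else {
      p <- g_test_2x2(tab)
      test_name <- "g_test"
    }
  }
  structure(list(codon = codon, fold = fold, p_value = p, table2x2 = tab,
                 test_name = test_name, denominator = denominator,
                 flag = flag),
            class = "enrichment_result")
}

# Likelihood-ratio G-test on a 2x2 table, chi-squared with 1 df.
g_test_2x2 <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  o <- as.numeric(tab)
  e <- as.numeric(e)
  g <- 2 * sum(ifelse(o > 0, o * log(o / e), 0))
  stats::pchisq(g, df = 1L, lower.tail = FALSE)
}

#' Export a codon-usage table as TSV
#'
#' @param u A `codon_usage_table`.
#' @param file Output path.
#' @export
write_codon_usage <- function(u, file) {
  stopifnot(inherits(u, "codon_usage_table"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# label=%s", attr(u, "label")),
               sprintf("# total=%d", attr(u, "total")),
               "codon\tamino_acid\tcount\tfrequency"), con)
  writeLines(sprintf("%s\t%s\t%d\t%s", u$codon, u$amino_acid, u$count,
                     formatC(u$freq, digits = 6, format = "g")), con)
  invisible(file)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Codon %s: fold (A/B) = %s, p = %.3g [%s, denominator=%s]%s\n",
              x$codon,
              if (is.na(x$fold)) "NA" else formatC(x$fold, digits = 4,
                                                   format = "g"),
              x$p_value, x$test_name, x$denominator,
              if (nzchar(x$flag)) paste0(" (", x$flag, ")") else ""))
  invisible(x)
}
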