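#' Standardize a vector to z-scores
#'
#' `(x - mean) / sd` with the sample standard deviation; `NA`s are excluded
#' from the moments but kept in place in the output.
#'
#' @param x Numeric vector with at least 2 finite values.
#' @return Vector of z-scores, same length as `x`.
#' @export
zscore <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 2L) stop("need at least 2 finite values")
  s <- sd(x[ok])
  if (s == 0) stop("zero variance: z-scores undefined")
  (x - mean(x[ok])) / s
}

#' Pearson correlation with declared exclusions
#'
#' Pearson R and two-sided t-based p-value on pairwise-complete records
#' after removing an explicit exclusion set (mirroring analyses that drop
#' named outlier compounds such as vinca alkaloids); the excluded ids are
#' echoed in the output so the exclusion stays auditable.
#'
#' @param x,y Paired numeric vectors.
#' @param ids Optional identifiers parallel to `x`/`y` (defaults to
#'   indices).
#' @param exclude Identifiers to drop before correlating.
#' @return List with `r`, `p`, `n_used`, `excluded`.
#' @export
correlate <- function(x, y, ids = NULL, exclude = NULL) {
  stopifnot(length(x) == length(y))
  if (is.null(ids)) ids <- seq_along(x)
  stopifnot(length(ids) == length(x))
  keep <- !(ids %in% exclude) & is.finite(x) & is.finite(y)
  if (sum(keep) < 3L) stop("fewer than 3 complete pairs after exclusion")
  ct <- cor.test(x[keep], y[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_used = sum(keep),
       excluded = exclude)
}

#' Gate a compound table into positive / negative hits
#'
#' Reproduces the screening gate anchored on a reference ICD inducer
#' (mitoxantrone in the original screen): a clinical-stage compound is a
#' positive hit iff `-log10(IC50 in mol/L) > 6` (i.e. IC50 below 1
#' micromolar) AND its predicted ICD score strictly exceeds the reference
#' compound's score; a negative hit iff its IC50 exceeds 1 micromolar AND
#' its score is below 1 (again requiring the clinical flag). Everything
#' else — including the reference itself, by strictness — is unclassified.
#'
#' @param table Data frame with columns `compound_id`, `ic50_uM`,
#'   `icd_score`, `clinical_flag`.
#' @param reference_id Compound id of the reference inducer.
#' @return `table` with added columns `neg_log10_ic50_M` and `hit_class`
#'   (factor: `positive`, `negative`, `unclassified`).
#' @export
select_hits <- function(table, reference_id) {
  need <- c("compound_id", "ic50_uM", "icd_score", "clinical_flag")
  if (!all(need %in% names(table))) {
    stop("table must have columns: ", paste(need, collapse = ", "))
  }
  ref <- table$icd_score[table$compound_id == reference_id]
  if (length(ref) != 1L || !is.finite(ref)) {
    stop("reference compound missing or has no finite ICD score: ", reference_id)
  }
  nl <- -log10(table$ic50_uM * 1e-6)
  pos <- nl > 6 & table$icd_score > ref & table$clinical_flag
  neg <- table$ic50_uM > 1 & table$icd_score < 1 & table$clinical_flag
  cls <- rep("unclassified", nrow(table))
  cls[neg %in% TRUE] <- "negative"
  cls[pos %in% TRUE] <- "positive"
  table$neg_log10_ic50_M <- nl
  table$hit_class <- factor(cls, levels = c("positive", "negative", "unclassified"))
  table
}

#' Kolmogorov-Smirnov enrichment of an annotated compound class
#'
#' Two-sample KS test of a class's score distribution against the entire
#' compound population (class members included in the population by
#' default, matching a class-vs-all design; set
#' `disjoint_background = TRUE` for a class-vs-rest comparison). The
#' `direction` `"greater"` tests whether the class scores are shifted high.
#'
#' @param table Compound table with the annotation and score columns.
#' @param class_label Annotation value defining the class.
#' @param score_col,annotation_col Column names.
#' @param direction `"two.sided"` (default) or `"greater"` (class shifted
#'   toward high scores).
#' @param disjoint_background Exclude class members from the background.
#' @param exact_limit Use the exact conditional null distribution of the
#'   two-sample statistic ([stats::psmirnov()] on the pooled, possibly tied,
#'   scores) whenever `n_class * n_population` does not exceed this limit;
#'   beyond it the asymptotic p-value is used. The exact path matters for
#'   small classes, where the asymptotic approximation is visibly
#'   conservative.
#' @return An object of class `ks_enrichment`: `class_label`, `n_class`,
#'   `n_population`, `statistic` (D), `p_value`, `direction` (sign of the
#'   class mean shift), and the two ECDFs for plotting.
#' @export
ks_enrichment <- function(table, class_label, score_col = "icd_score",
                          annotation_col = "annotation",
                          direction = c("two.sided", "greater"),
                          disjoint_background = FALSE, exact_limit = 1e7) {
  direction <- match.arg(direction)
  stopifnot(score_col %in% names(table), annotation_col %in% names(table))
  member <- table[[annotation_col]] == class_label
  cls <- table[[score_col]][member]
  if (length(cls) < 2L) stop("class must have at least 2 members")
  pop <- if (disjoint_background) table[[score_col]][!member] else table[[score_col]]
  if (length(pop) < 10L) stop("population must have at least 10 compounds")
  # stats::ks.test's "less" alternative asks whether x is stochastically
  # larger than y, which is what "class shifted high" means here
  alt <- if (direction == "two.sided") "two.sided" else "less"
  kt <- suppressWarnings(ks.test(cls, pop, alternative = alt, exact = FALSE))
  p_value <- kt$p.value
  if (length(cls) * as.numeric(length(pop)) <= exact_limit) {
    p_value <- suppressWarnings(
      stats::psmirnov(unname(kt$statistic), sizes = c(length(cls), length(pop)),
                      z = c(cls, pop), two.sided = (alt == "two.sided"),
                      exact = TRUE, lower.tail = FALSE))
  }
  structure(list(class_label = class_label,
                 n_class = length(cls), n_population = length(pop),
                 statistic = unname(kt$statistic),
                 p_value = p_value,
                 direction = sign(mean(cls) - mean(pop)),
                 alternative = direction,
                 ecdf_class = ecdf(cls), ecdf_population = ecdf(pop)),
            class = "ks_enrichment")
}

#' @export
print.ks_enrichment <- function(x, ...) {
  cat(sprintf("KS enrichment of '%s' (n = %d) vs population (n = %d)\n",
              x$class_label, x$n_class, x$n_population))
  cat(sprintf("  D = %.4f, p = %.3g (%s), shift direction %+d\n",
              x$statistic, x$p_value, x$alternative, x$direction))
  invisible(x)
}

#' @export
plot.ks_enrichment <- function(x, ...) {
  xs <- sort(c(environment(x$ecdf_class)$x, environment(x$ecdf_population)$x))
  graphics::plot(xs, x$ecdf_population(xs), type = "s",
                 xlab = "score", ylab = "ECDF", ...)
  graphics::lines(xs, x$ecdf_class(xs), type = "s", lty = 2)
  graphics::legend("bottomright", c("population", x$class_label),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
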