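# Tumor/normal differential expression by median fold change and
# DEG-conditioned pairwise Pearson co-expression with banding.

#' Construct an expression cohort
#'
#' Container for one cancer-type cohort: a genes x samples matrix on the
#' log2(TPM+1) scale plus a tumor/normal group label per sample.
#'
#' @param cohort_id Cohort label (e.g. a TCGA-style abbreviation).
#' @param mat Numeric matrix, rownames = genes, colnames = sample IDs,
#'   values on a log2(TPM+1)-like scale.
#' @param groups Named character vector (`"tumor"`/`"normal"`) or unnamed
#'   vector aligned with `colnames(mat)`.
#' @return An object of class `expression_cohort`.
#' @export
expression_cohort <- function(cohort_id, mat, groups) {
  if (is.null(rownames(mat))) stop("matrix must have gene rownames", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- colnames(mat)
  groups <- groups[colnames(mat)]
  if (anyNA(groups) || !all(groups %in% c("tumor", "normal")))
    stop("groups must label every sample as tumor or normal", call. = FALSE)
  if (any(!is.finite(mat))) stop("expression values must be finite", call. = FALSE)
  if (min(table(factor(groups, c("tumor", "normal")))) < 3L)
    stop("need >= 3 samples per group", call. = FALSE)
  structure(list(cohort_id = cohort_id, mat = mat, groups = groups),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("<expression_cohort %s: %d genes, %d tumor / %d normal samples>\n",
              x$cohort_id, nrow(x$mat), sum(x$groups == "tumor"),
              sum(x$groups == "normal")))
  invisible(x)
}

#' Median tumor/normal fold change for one gene
#'
#' Recovers linear-scale values from the log2(TPM+1) matrix, takes group
#' medians, and forms the pseudo-counted ratio
#' `fc = (median_tumor + pseudo) / (median_normal + pseudo)`.
#'
#' @param cohort An [expression_cohort()].
#' @param gene Gene symbol.
#' @param pseudo Pseudo-count added to both medians (default 1).
#' @return List `fc` (linear scale) and `log2fc`.
#' @export
compute_fold_change <- function(cohort, gene, pseudo = 1) {
  if (!gene %in% rownames(cohort$mat))
    stop("gene not in cohort: ", gene, call. = FALSE)
  x <- 2^cohort$mat[gene, ] - 1
  mt <- stats::median(x[cohort$groups == "tumor"])
  mn <- stats::median(x[cohort$groups == "normal"])
  fc <- (mt + pseudo) / (mn + pseudo)
  list(fc = fc, log2fc = log2(fc))
}

#' Call differentially expressed genes in a cohort
#'
#' A gene is a DEG when its median fold change passes `fc_threshold` and
#' its two-sided test p-value passes `alpha`. The default test is the
#' Mann-Whitney (Wilcoxon rank-sum) on the log2 values; `test = "welch"`
#' substitutes Welch's t. BH q-values across genes are reported but the DEG
#' gate uses the raw p-value.
#'
#' @param cohort An [expression_cohort()].
#' @param fc_threshold Minimum linear fold change (default 3). Both
#'   directions gate on `max(fc, 1/fc)` so strong down-regulation also
#'   qualifies.
#' @param alpha Significance cut-off on the raw p-value (default 0.01).
#' @param test `"wilcox"` (default) or `"welch"`.
#' @param pseudo Pseudo-count for the fold change.
#' @return Data frame `gene`, `cohort_id`, `fc`, `log2fc`, `p_value`,
#'   `q_value`, `is_deg`.
#' @export
call_degs <- function(cohort, fc_threshold = 3, alpha = 0.01,
                      test = c("wilcox", "welch"), pseudo = 1) {
  test <- match.arg(test)
  tum <- cohort$groups == "tumor"
  genes <- rownames(cohort$mat)
  fcs <- numeric(length(genes)); ps <- numeric(length(genes))
  for (i in seq_along(genes)) {
    f <- compute_fold_change(cohort, genes[i], pseudo)
    fcs[i] <- f$fc
    a <- cohort$mat[i, tum]; b <- cohort$mat[i, !tum]
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && stats::median(a) == stats::median(b)) {
      ps[i] <- 1
    } else if (test == "wilcox") {
      ps[i] <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    } else {
      ps[i] <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    }
  }
  ps[is.na(ps)] <- 1
  eff_fc <- pmax(fcs, 1 / fcs)
  out <- data.frame(gene = genes, cohort_id = cohort$cohort_id,
                    fc = fcs, log2fc = log2(fcs), p_value = ps,
                    q_value = bh_adjust(ps),
                    is_deg = eff_fc >= fc_threshold & ps <= alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Enumerate co-expression tasks conditioned on enzyme DEG status
#'
#' A (enzyme, partner, cohort) task exists iff the enzyme is a DEG in that
#' cohort; co-expression is only examined in tumor types where the enzyme
#' itself is differentially expressed.
#'
#' @param deg_results Row-bound [call_degs()] tables across cohorts.
#' @param edges Edge data frame (`enzyme`, `partner`).
#' @return Data frame `enzyme`, `partner`, `cohort_id`.
#' @export
select_coexpression_tasks <- function(deg_results, edges) {
  hits <- deg_results[deg_results$is_deg, c("gene", "cohort_id"), drop = FALSE]
  out <- merge(edges[, c("enzyme", "partner")], hits,
               by.x = "enzyme", by.y = "gene")
  out <- out[order(out$cohort_id, out$enzyme, out$partner),
             c("enzyme", "partner", "cohort_id"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson co-expression of one enzyme-partner pair
#'
#' Sample Pearson correlation of the two genes' log2 values over the chosen
#' sample scope (tumor samples by default), with the band assigned by
#' [assign_band()]. A zero-variance gene yields a degenerate result with
#' band `"none"` rather than an error.
#'
#' @param cohort An [expression_cohort()].
#' @param enzyme,partner Gene symbols.
#' @param scope `"tumor"` (default), `"normal"` or `"all"`.
#' @param min_samples Minimum samples required (default 10).
#' @return List of class `coexpression_result`: `enzyme`, `partner`,
#'   `cohort_id`, `r`, `n`, `band`, `negative`, `degenerate`.
#' @export
pearson_coexpression <- function(cohort, enzyme, partner,
                                 scope = c("tumor", "normal", "all"),
                                 min_samples = 10) {
  scope <- match.arg(scope)
  for (g in c(enzyme, partner))
    if (!g %in% rownames(cohort$mat)) stop("gene not in cohort: ", g, call. = FALSE)
  keep <- switch(scope, tumor = cohort$groups == "tumor",
                 normal = cohort$groups == "normal",
                 all = rep(TRUE, length(cohort$groups)))
  if (sum(keep) < min_samples)
    stop("fewer than ", min_samples, " samples in scope", call. = FALSE)
  x <- cohort$mat[enzyme, keep]; y <- cohort$mat[partner, keep]
  degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
  r <- if (degenerate) NA_real_ else stats::cor(x, y)
  band <- if (degenerate) list(band = "none", negative = FALSE) else assign_band(r)
  structure(list(enzyme = enzyme, partner = partner,
                 cohort_id = cohort$cohort_id, r = r, n = sum(keep),
                 band = band$band, negative = band$negative,
                 degenerate = degenerate),
            class = "coexpression_result")
}

#' Band a Pearson correlation coefficient
#'
#' Bands follow the cut-offs 0.4 / 0.6: `|r| < 0.4` is `"none"`,
#' `0.4 <= |r| < 0.6` is `"average"`, `|r| >= 0.6` is `"strong"` (the
#' banding scheme stops at 0.7, so larger magnitudes stay in the strong
#' band). Boundaries are closed below: a coefficient exactly at a cut-off
#' belongs to the higher band. `negative` flags `r <= -0.4`.
#'
#' @param r Pearson coefficient(s) in `[-1, 1]`; vectorized.
#' @param cutoffs Numeric vector `c(low, high)` band boundaries
#'   (default `c(0.4, 0.6)`).
#' @return List `band` (character) and `negative` (logical), each the
#'   length of `r`.
#' @export
assign_band <- function(r, cutoffs = c(0.4, 0.6)) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("correlation out of [-1, 1]", call. = FALSE)
  a <- abs(r)
  band <- ifelse(a >= cutoffs[2L], "strong",
                 ifelse(a >= cutoffs[1L], "average", "none"))
  list(band = band, negative = !is.na(r) & r <= -cutoffs[1L])
}

#' Run all co-expression tasks and collect a banded table
#'
#' @param tasks Task table from [select_coexpression_tasks()].
#' @param cohorts Named list of [expression_cohort()] objects keyed by
#'   `cohort_id`.
#' @inheritParams pearson_coexpression
#' @return Data frame `enzyme`, `partner`, `cohort_id`, `r`, `n`, `band`,
#'   `negative`.
#' @export
coexpression_table <- function(tasks, cohorts, scope = "tumor",
                               min_samples = 10) {
  rows <- lapply(seq_len(nrow(tasks)), function(i) {
    co <- cohorts[[tasks$cohort_id[i]]]
    res <- pearson_coexpression(co, tasks$enzyme[i], tasks$partner[i],
                                scope = scope, min_samples = min_samples)
    data.frame(enzyme = res$enzyme, partner = res$partner,
               cohort_id = res$cohort_id, r = res$r, n = res$n,
               band = res$band, negative = res$negative,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(enzyme = character(), partner = character(),
                      cohort_id = character(), r = numeric(), n = integer(),
                      band = character(), negative = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Read / write an expression cohort as TSV plus group sidecar
#'
#' The matrix TSV has gene symbols in the first column and sample IDs as
#' the header; the sidecar TSV maps sample to group (`tumor`/`normal`).
#'
#' @param cohort An [expression_cohort()].
#' @param prefix File prefix: writes `<prefix>_expr.tsv` and
#'   `<prefix>_groups.tsv`.
#' @param cohort_id Cohort label for the reader.
#' @return File paths invisibly (writer); an `expression_cohort` (reader).
#' @export
write_expression_cohort <- function(cohort, prefix) {
  expr_path <- paste0(prefix, "_expr.tsv")
  grp_path <- paste0(prefix, "_groups.tsv")
  df <- data.frame(gene = rownames(cohort$mat), cohort$mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(cohort$groups),
                                group = unname(cohort$groups)),
                     grp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expr_path, grp_path))
}

#' @rdname write_expression_cohort
#' @export
read_expression_cohort <- function(prefix, cohort_id) {
  df <- utils::read.delim(paste0(prefix, "_expr.tsv"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  grp <- utils::read.delim(paste0(prefix, "_groups.tsv"),
                           stringsAsFactors = FALSE)
  expression_cohort(cohort_id, mat, stats::setNames(grp$group, grp$sample))
}
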