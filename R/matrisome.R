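# Matrisome annotation and differential protein-abundance statistics.

check_abundance <- function(table) {
  if (!inherits(table, "abundance_table")) {
    stopf("expected an `abundance_table` (see sim_abundance_table/read_abundance_table)")
  }
  if (!all(colnames(table$abundance) %in% names(table$group))) {
    stopf("samples without a group: %s",
          paste(setdiff(colnames(table$abundance), names(table$group)),
                collapse = ", "))
  }
  invisible(table)
}

#' Annotate proteins against a matrisome reference
#'
#' Each protein is labelled with its matrisome division/category when
#' present in the reference, otherwise left unannotated and excluded from
#' the matrisome set. Per-category summed abundance (across all samples) is
#' returned for radar-style summaries.
#'
#' @param table an `abundance_table`.
#' @param reference data.frame with columns `protein` and `category`
#'   (see [read_matrisome_reference()]); protein ids must be unique.
#' @return the table with `annotation` replaced by the reference labels,
#'   plus attributes via the returned list: `table`, `matrisome_proteins`,
#'   `category_summary` (data.frame `category`, `n_proteins`,
#'   `total_abundance`).
#' @export
annotate_matrisome <- function(table, reference) {
  check_abundance(table)
  if (!all(c("protein", "category") %in% names(reference))) {
    stopf("reference needs `protein` and `category` columns")
  }
  if (anyDuplicated(reference$protein)) {
    stopf("duplicate protein id(s) in reference: %s",
          paste(unique(reference$protein[duplicated(reference$protein)]),
                collapse = ", "))
  }
  proteins <- rownames(table$abundance)
  ann <- setNames(reference$category[match(proteins, reference$protein)],
                  proteins)
  table$annotation <- ann
  in_set <- !is.na(ann)
  sums <- tapply(rowSums(table$abundance[in_set, , drop = FALSE]),
                 ann[in_set], sum)
  counts <- table(ann[in_set])
  summary <- data.frame(category = names(sums),
                        n_proteins = as.integer(counts[names(sums)]),
                        total_abundance = as.numeric(sums),
                        row.names = NULL)
  list(table = table,
       matrisome_proteins = proteins[in_set],
       category_summary = summary)
}

#' Normalise an abundance table across samples
#'
#' `"total"` scales each sample so column totals are equal (to their mean);
#' `"median_ratio"` scales by the median ratio of each sample to the
#' row-wise geometric reference (the size-factor construction used in count
#' based differential expression). Both preserve within-sample rank order.
#'
#' @param table an `abundance_table` with positive abundances.
#' @param method `"total"` or `"median_ratio"`.
#' @return the table with scaled abundances; attribute `normalization`
#'   records the method and per-sample scale factors.
#' @export
normalize_abundance <- function(table, method = c("total", "median_ratio")) {
  method <- match.arg(method)
  check_abundance(table)
  ab <- table$abundance
  if (any(colSums(is.finite(ab) & ab > 0) == 0)) {
    stopf("sample(s) with no finite positive abundances")
  }
  if (method == "total") {
    totals <- colSums(ab, na.rm = TRUE)
    scale <- mean(totals) / totals
  } else {
    logref <- rowMeans(log(ab), na.rm = TRUE)
    ratios <- sweep(log(ab), 1, logref, "-")
    scale <- 1 / exp(apply(ratios, 2, stats::median, na.rm = TRUE))
  }
  table$abundance <- sweep(ab, 2, scale, "*")
  attr(table, "normalization") <- list(method = method, scale = scale)
  table
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up: p-values sorted ascending, \eqn{q_i = \min_{j \ge
#' i} p_j m / j} capped at 1, returned in the original order (delegates to
#' `stats::p.adjust(method = "BH")` after validation).
#'
#' @param p_values numeric vector of p-values in [0, 1] (NAs preserved).
#' @return adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stopf("`p_values` must be numeric")
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Differential protein abundance with BH control
#'
#' Per protein: log2 fold change as the difference of group means of log2
#' abundance, one-way ANOVA p-value across groups (on log2 abundance), and
#' Benjamini-Hochberg adjusted p across all tested proteins. A protein is
#' significant iff \eqn{|log2 fc| \ge log2(fc\_threshold)} and adjusted
#' p < alpha. Proteins with missing values in more than
#' `n_per_group - min_present` samples of any group are not tested;
#' zero-variance proteins get p = 1 with a flag.
#'
#' @param table an `abundance_table` with >= 2 groups of >= 2 samples.
#' @param fc_threshold fold-change significance threshold (default 2).
#' @param alpha adjusted-p significance level (default 0.05).
#' @param min_present minimum finite values per group for testing
#'   (default 2).
#' @return data.frame per protein: `protein`, `log2_fc` (second group over
#'   first, alphabetical, or `control` first when present), `abundance_ratio`
#'   (`2^log2_fc`), `p`, `p_adj`, `significant`, `zero_variance`, `tested`,
#'   `category`.
#' @export
differential_abundance <- function(table, fc_threshold = 2, alpha = 0.05,
                                   min_present = 2) {
  check_abundance(table)
  check_scalar(fc_threshold, "fc_threshold", lower = 1)
  check_scalar(alpha, "alpha", lower = 0, upper = 1)
  ab <- table$abundance
  grp <- factor(table$group[colnames(ab)])
  if (nlevels(grp) < 2) stopf("need >= 2 groups")
  if (any(table(grp) < 2)) stopf("need >= 2 samples per group")
  lv <- levels(grp)
  if ("control" %in% lv) lv <- c("control", setdiff(lv, "control"))
  grp <- factor(grp, levels = lv)

  log2ab <- log2(ab)
  one <- function(i) {
    y <- log2ab[i, ]
    fin <- is.finite(y)
    if (any(tapply(fin, grp, sum) < min_present)) {
      return(c(lfc = NA, p = NA, zv = 0, tested = 0))
    }
    y <- y[fin]; g <- droplevels(grp[fin])
    means <- tapply(y, g, mean)
    lfc <- unname(means[length(means)] - means[1])
    if (stats::var(y) < 1e-24) {
      return(c(lfc = lfc, p = 1, zv = 1, tested = 1))
    }
    fit <- stats::aov(y ~ g)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    c(lfc = lfc, p = p, zv = 0, tested = 1)
  }
  res <- t(vapply(seq_len(nrow(ab)), one, numeric(4)))
  p_adj <- bh_adjust(res[, "p"])
  sig <- !is.na(p_adj) & p_adj < alpha &
    abs(res[, "lfc"]) >= log2(fc_threshold)
  data.frame(protein = rownames(ab),
             log2_fc = res[, "lfc"],
             abundance_ratio = 2^res[, "lfc"],
             p = res[, "p"], p_adj = p_adj,
             significant = sig,
             zero_variance = res[, "zv"] == 1,
             tested = res[, "tested"] == 1,
             category = unname(table$annotation[rownames(ab)]),
             row.names = NULL)
}

#' Read / write a matrisome reference table
#'
#' CSV with columns `protein` and `category`; categories must come from
#' [matrisome_categories()]. A small synthetic reference for examples and
#' tests ships at
#' `system.file("extdata", "matrisome_reference_synthetic.csv",
#' package = "matriscope")`; a full reference is supplied by the user in
#' the same format.
#'
#' @param path CSV path.
#' @return data.frame with `protein` and `category` columns.
#' @export
read_matrisome_reference <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("protein", "category") %in% names(df))) {
    stopf("matrisome reference needs `protein` and `category` columns")
  }
  bad <- setdiff(unique(df$category), matrisome_categories())
  if (length(bad)) {
    stopf("unknown matrisome categor%s: %s",
          if (length(bad) > 1) "ies" else "y", paste(bad, collapse = ", "))
  }
  df
}

#' Read / write an abundance table (TSV + YAML sidecar)
#'
#' TSV with protein rows and sample columns; the sidecar carries the
#' sample-to-group map and optional per-protein annotation.
#'
#' @param table an `abundance_table`.
#' @param path TSV path.
#' @return `write_abundance_table()` the path invisibly;
#'   `read_abundance_table()` an `abundance_table`.
#' @export
write_abundance_table <- function(table, path) {
  check_abundance(table)
  df <- data.frame(protein = rownames(table$abundance), table$abundance,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".yaml")
  ann <- table$annotation[!is.na(table$annotation)]
  yaml::write_yaml(list(group = as.list(table$group),
                        annotation = as.list(ann)), sidecar)
  invisible(path)
}

#' @rdname write_abundance_table
#' @export
read_abundance_table <- function(path) {
  df <- read.csv(path, sep = "\t", check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (!"protein" %in% names(df)) stopf("abundance TSV needs a `protein` column")
  ab <- as.matrix(df[, setdiff(names(df), "protein"), drop = FALSE])
  rownames(ab) <- df$protein
  sidecar <- paste0(tools::file_path_sans_ext(path), ".yaml")
  if (!file.exists(sidecar)) stopf("missing abundance sidecar %s", sidecar)
  meta <- yaml::read_yaml(sidecar)
  ann <- setNames(rep(NA_character_, nrow(ab)), rownames(ab))
  if (length(meta$annotation)) {
    ann[names(meta$annotation)] <- unlist(meta$annotation)
  }
  structure(list(abundance = ab, group = unlist(meta$group),
                 annotation = ann, truth = NULL),
            class = "abundance_table")
}
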