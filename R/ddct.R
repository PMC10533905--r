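# Delta-delta-CT relative quantification workflow: CT cut-off,
# housekeeping normalisation, fold change, per-gene t-tests, volcano
# classification.

check_plate <- function(plate) {
  if (!inherits(plate, "expression_plate")) {
    stopf("expected an `expression_plate` (see sim_ct_plate/read_ct_plate)")
  }
  if (!all(plate$housekeeping %in% rownames(plate$ct))) {
    stopf("housekeeping gene(s) absent from the plate: %s",
          paste(setdiff(plate$housekeeping, rownames(plate$ct)),
                collapse = ", "))
  }
  if (!all(colnames(plate$ct) %in% names(plate$group))) {
    stopf("samples without a group assignment: %s",
          paste(setdiff(colnames(plate$ct), names(plate$group)),
                collapse = ", "))
  }
  invisible(plate)
}

#' Apply the CT cut-off
#'
#' CT values above the cut-off (default 35) and undetermined (NA) values
#' are replaced by the cut-off, the vendor-style convention; replacements
#' are flagged in the `censored` matrix. Genes undetected in every sample
#' are listed in `non_detected`. A housekeeping gene sitting at the cut-off
#' in any sample triggers a warning (normalisation unreliable).
#'
#' @param plate an `expression_plate`.
#' @param cutoff CT cut-off in cycles (default `plate$ct_cutoff`, 35).
#' @return the plate with censored CTs, a `censored` logical matrix and a
#'   `non_detected` gene list attached.
#' @export
apply_ct_cutoff <- function(plate, cutoff = plate$ct_cutoff) {
  check_plate(plate)
  check_scalar(cutoff, "cutoff", lower = 1e-9)
  ct <- plate$ct
  censored <- is.na(ct) | ct > cutoff
  ct[censored] <- cutoff
  hk_at_cutoff <- censored[plate$housekeeping, , drop = FALSE]
  if (any(hk_at_cutoff)) {
    warnf("housekeeping gene(s) at the CT cut-off: %s; normalisation unreliable",
          paste(unique(rownames(hk_at_cutoff)[which(hk_at_cutoff,
                                                    arr.ind = TRUE)[, 1]]),
                collapse = ", "))
  }
  plate$ct <- ct
  plate$ct_cutoff <- cutoff
  plate$censored <- censored
  plate$non_detected <- rownames(ct)[rowSums(!censored) == 0]
  plate$cutoff_applied <- TRUE
  plate
}

#' Normalise expression against housekeeping genes
#'
#' Per sample, \eqn{\Delta CT = CT(gene) - mean(CT(housekeeping))} and the
#' normalised expression is \eqn{2^{-\Delta CT}}. The housekeeping average
#' is the arithmetic mean of the CT values.
#'
#' @param plate an `expression_plate`, normally after [apply_ct_cutoff()].
#' @return a `normalized_expression`: list with `value` (gene x sample
#'   matrix of `2^-dCT`), `delta_ct`, `group`, `housekeeping`.
#' @examples
#' pl <- sim_ct_plate(genes = c("HK1", "HK2", "GOI"),
#'                    housekeeping = c("HK1", "HK2"),
#'                    baseline_ct = c(HK1 = 20, HK2 = 22, GOI = 25),
#'                    ct_noise_sd = 0, seed = 1)
#' normalize_expression(pl)$value["GOI", 1]  # 2^-4 = 0.0625
#' @export
normalize_expression <- function(plate) {
  check_plate(plate)
  if (!isTRUE(plate$cutoff_applied)) {
    plate <- apply_ct_cutoff(plate)
  }
  hk <- plate$ct[plate$housekeeping, , drop = FALSE]
  if (any(!is.finite(hk))) {
    bad <- colnames(hk)[colSums(!is.finite(hk)) > 0]
    stopf("missing housekeeping CT value(s) in sample(s): %s",
          paste(bad, collapse = ", "))
  }
  hk_avg <- colMeans(hk)
  delta_ct <- sweep(plate$ct, 2, hk_avg, "-")
  structure(list(value = 2^(-delta_ct), delta_ct = delta_ct,
                 group = plate$group[colnames(plate$ct)],
                 housekeeping = plate$housekeeping),
            class = "normalized_expression")
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat(sprintf("<normalized_expression> %d genes x %d samples (2^-dCT; housekeeping: %s)\n",
              nrow(x$value), ncol(x$value),
              paste(x$housekeeping, collapse = ", ")))
  invisible(x)
}

#' Per-gene fold change (2^-ddCT)
#'
#' Fold change is the mean normalised expression (`2^-dCT`) in the test
#' group divided by the mean in the control group, i.e. \eqn{2^{-\Delta
#' \Delta CT}}.
#'
#' @param norm a `normalized_expression`.
#' @param control,test the group labels to compare.
#' @return data.frame: `gene`, `fold_change`, `log2_fc`, `ddct`
#'   (`= -log2_fc`).
#' @export
fold_change <- function(norm, control = "control", test = "test") {
  stopifnot(inherits(norm, "normalized_expression"))
  in_ctrl <- norm$group == control
  in_test <- norm$group == test
  if (!any(in_ctrl) || !any(in_test)) {
    stopf("both groups must be non-empty (control '%s', test '%s')",
          control, test)
  }
  fc <- rowMeans(norm$value[, in_test, drop = FALSE]) /
    rowMeans(norm$value[, in_ctrl, drop = FALSE])
  data.frame(gene = rownames(norm$value), fold_change = unname(fc),
             log2_fc = unname(log2(fc)), ddct = unname(-log2(fc)),
             row.names = NULL)
}

#' Per-gene two-sample t-test on normalised expression
#'
#' Student's t-test of the replicate normalised expression values
#' (`2^-dCT`, not delta-CT) per gene: parametric, unpaired, two-sample
#' equal variance (pooled), two-tailed. Zero pooled variance yields p = 1
#' when the group means are equal, and p = 0 with a `degenerate` flag when
#' they differ.
#'
#' @param norm a `normalized_expression` with >= 2 replicates per group.
#' @param control,test the group labels to compare.
#' @return data.frame: `gene`, `t`, `df`, `p`, `degenerate`.
#' @export
gene_ttest <- function(norm, control = "control", test = "test") {
  stopifnot(inherits(norm, "normalized_expression"))
  a <- norm$value[, norm$group == control, drop = FALSE]
  b <- norm$value[, norm$group == test, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) {
    stopf("need >= 2 replicates per group (got %d control, %d test)",
          ncol(a), ncol(b))
  }
  one <- function(x, y) {
    if (stats::var(x) + stats::var(y) == 0) {
      if (mean(x) == mean(y)) {
        return(c(t = 0, df = length(x) + length(y) - 2, p = 1, deg = 0))
      }
      return(c(t = Inf, df = length(x) + length(y) - 2, p = 0, deg = 1))
    }
    tt <- stats::t.test(y, x, var.equal = TRUE)
    c(t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, deg = 0)
  }
  res <- t(vapply(seq_len(nrow(norm$value)),
                  function(i) one(a[i, ], b[i, ]), numeric(4)))
  data.frame(gene = rownames(norm$value), t = res[, 1], df = res[, 2],
             p = res[, 3], degenerate = res[, 4] == 1, row.names = NULL)
}

#' Volcano classification of fold-change results
#'
#' A gene is `up` when its fold change is at least `fc_threshold` with
#' p below `p_threshold`, `down` when its fold change is at most
#' `1/fc_threshold` with p below `p_threshold`, and `ns` otherwise.
#'
#' @param results data.frame with `fold_change` and `p` columns (e.g. a
#'   join of [fold_change()] and [gene_ttest()]).
#' @param fc_threshold fold-change threshold (> 1; default 2).
#' @param p_threshold p-value threshold (default 0.05).
#' @return the input with a `classification` factor column
#'   (`up`/`down`/`ns`).
#' @export
volcano_classify <- function(results, fc_threshold = 2, p_threshold = 0.05) {
  if (!all(c("fold_change", "p") %in% names(results))) {
    stopf("`results` needs `fold_change` and `p` columns")
  }
  check_scalar(fc_threshold, "fc_threshold", lower = 1)
  check_scalar(p_threshold, "p_threshold", lower = 0, upper = 1)
  cls <- ifelse(results$p < p_threshold & results$fold_change >= fc_threshold,
                "up",
         ifelse(results$p < p_threshold &
                  results$fold_change <= 1 / fc_threshold,
                "down", "ns"))
  results$classification <- factor(cls, levels = c("up", "down", "ns"))
  results
}

#' Run the full delta-delta-CT workflow on a plate
#'
#' Convenience wrapper: CT cut-off, housekeeping normalisation, per-gene
#' fold change and t-test, and volcano classification.
#'
#' @param plate an `expression_plate`.
#' @param control,test group labels.
#' @param fc_threshold,p_threshold see [volcano_classify()].
#' @return data.frame per gene: fold change, log2 fold change, ddCT, t, p,
#'   classification.
#' @export
ddct_workflow <- function(plate, control = "control", test = "test",
                          fc_threshold = 2, p_threshold = 0.05) {
  norm <- normalize_expression(apply_ct_cutoff(plate))
  fc <- fold_change(norm, control, test)
  tt <- gene_ttest(norm, control, test)
  res <- merge(fc, tt[, c("gene", "t", "p")], by = "gene", sort = FALSE)
  volcano_classify(res, fc_threshold, p_threshold)
}

#' Read / write an expression plate as CSV + YAML sidecar
#'
#' CSV with genes in rows and samples in columns; the sidecar names the
#' housekeeping genes and the sample-to-group map.
#'
#' @param plate an `expression_plate`.
#' @param path CSV path (sidecar is the same path with `.yaml`).
#' @return `write_ct_plate()` the path, invisibly; `read_ct_plate()` an
#'   `expression_plate`.
#' @export
write_ct_plate <- function(plate, path) {
  check_plate(plate)
  write.csv(data.frame(gene = rownames(plate$ct), plate$ct,
                       check.names = FALSE),
            path, row.names = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".yaml")
  yaml::write_yaml(list(housekeeping = as.list(plate$housekeeping),
                        group = as.list(plate$group),
                        ct_cutoff = plate$ct_cutoff), sidecar)
  invisible(path)
}

#' @rdname write_ct_plate
#' @export
read_ct_plate <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) stopf("plate CSV needs a `gene` column")
  ct <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  rownames(ct) <- df$gene
  sidecar <- paste0(tools::file_path_sans_ext(path), ".yaml")
  if (!file.exists(sidecar)) stopf("missing plate sidecar %s", sidecar)
  meta <- yaml::read_yaml(sidecar)
  structure(list(ct = ct,
                 housekeeping = unlist(meta$housekeeping),
                 group = unlist(meta$group),
                 ct_cutoff = meta$ct_cutoff %||% 35),
            class = "expression_plate")
}
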