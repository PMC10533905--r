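# Synthetic qPCR CT plates and protein abundance tables with known effects.

#' Simulate a qPCR CT plate with group effects on selected genes
#'
#' CT values are `baseline + shift * (group == test) + Gaussian noise`.
#' Housekeeping genes always receive zero group shift, so normalisation
#' against them is unbiased by construction. A negative CT shift in the test
#' group corresponds to higher expression (fold change `2^-shift`).
#'
#' @param genes character vector of gene names.
#' @param housekeeping non-empty subset of `genes` used for normalisation.
#' @param n_per_group replicate samples per group.
#' @param group_delta_ct_shift named numeric vector: CT shift applied to the
#'   test group for the named genes (housekeeping entries are ignored).
#' @param ct_noise_sd CT measurement noise standard deviation, cycles.
#' @param baseline_ct single value or named vector of baseline CTs.
#' @param seed integer seed.
#' @return an `expression_plate`: list with `ct` (gene x sample matrix),
#'   `housekeeping`, `group` (named vector, values "control"/"test"),
#'   `ct_cutoff` (35 by default, see [apply_ct_cutoff()]) and `truth`
#'   (the applied shifts).
#' @examples
#' pl <- sim_ct_plate(genes = c("ACTB", "B2M", "MMP2", "SPARC"),
#'                    housekeeping = c("ACTB", "B2M"),
#'                    group_delta_ct_shift = c(MMP2 = -2), seed = 1)
#' pl$ct
#' @export
sim_ct_plate <- function(genes, housekeeping, n_per_group = 3,
                         group_delta_ct_shift = numeric(),
                         ct_noise_sd = 0.2, baseline_ct = 25,
                         seed = 1L) {
  if (length(genes) < 1L) stopf("`genes` must be non-empty")
  if (length(housekeeping) == 0L) {
    stopf("`housekeeping` must name at least one gene")
  }
  if (!all(housekeeping %in% genes)) {
    stopf("housekeeping genes not in `genes`: %s",
          paste(setdiff(housekeeping, genes), collapse = ", "))
  }
  check_scalar(n_per_group, "n_per_group", lower = 1)
  check_scalar(ct_noise_sd, "ct_noise_sd", lower = 0)
  if (length(baseline_ct) == 1L && is.null(names(baseline_ct))) {
    baseline_ct <- setNames(rep(baseline_ct, length(genes)), genes)
  }
  if (!all(genes %in% names(baseline_ct))) {
    stopf("`baseline_ct` must cover all genes")
  }
  shift <- setNames(rep(0, length(genes)), genes)
  if (length(group_delta_ct_shift)) {
    unknown <- setdiff(names(group_delta_ct_shift), genes)
    if (length(unknown)) stopf("shift for unknown gene(s): %s",
                               paste(unknown, collapse = ", "))
    shift[names(group_delta_ct_shift)] <- group_delta_ct_shift
  }
  shift[housekeeping] <- 0

  n_per_group <- as.integer(n_per_group)
  samples <- c(sprintf("control_%d", seq_len(n_per_group)),
               sprintf("test_%d", seq_len(n_per_group)))
  group <- setNames(rep(c("control", "test"), each = n_per_group), samples)
  ct <- with_seed(seed, {
    m <- outer(baseline_ct[genes], rep(1, length(samples))) +
      outer(shift[genes], as.numeric(group == "test")) +
      matrix(rnorm(length(genes) * length(samples), 0, ct_noise_sd),
             length(genes))
    dimnames(m) <- list(genes, samples)
    m
  })
  structure(list(ct = ct, housekeeping = housekeeping, group = group,
                 ct_cutoff = 35, truth = list(shift = shift)),
            class = "expression_plate")
}

#' @export
print.expression_plate <- function(x, ...) {
  cat(sprintf("<expression_plate> %d genes x %d samples (%d housekeeping)\n",
              nrow(x$ct), ncol(x$ct), length(x$housekeeping)))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

#' Simulate a protein abundance table with spiked differential proteins
#'
#' Log2 abundances are Normal(baseline + effect * group, dispersion);
#' abundances are returned on the linear scale. A chosen fraction of
#' proteins carries a matrisome category annotation drawn from the core and
#' associated matrisome divisions.
#'
#' @param n_proteins number of proteins (named `P0001`, ...).
#' @param n_per_group samples per group (>= 2; one-way ANOVA needs
#'   within-group replication).
#' @param log2_effect named numeric vector of log2 fold-change effects
#'   applied to the second group.
#' @param dispersion log2-scale standard deviation (> 0).
#' @param matrisome_fraction fraction of proteins receiving a matrisome
#'   category.
#' @param groups two group labels.
#' @param baseline_log2 range of per-protein baseline log2 abundance.
#' @param seed integer seed.
#' @return an `abundance_table`: list with `abundance` (protein x sample
#'   matrix, linear scale), `group` (named vector), `annotation` (named
#'   vector of categories, NA when unannotated) and `truth` (the spiked
#'   effects).
#' @examples
#' tab <- sim_abundance_table(n_proteins = 20, log2_effect = c(P0001 = 3),
#'                            seed = 1)
#' tab$truth$log2_effect
#' @export
sim_abundance_table <- function(n_proteins = 200, n_per_group = 3,
                                log2_effect = numeric(),
                                dispersion = 0.3,
                                matrisome_fraction = 0.3,
                                groups = c("control", "IPF"),
                                baseline_log2 = c(20, 30), seed = 1L) {
  check_scalar(n_proteins, "n_proteins", lower = 1)
  if (n_per_group < 2) stopf("`n_per_group` must be >= 2 (ANOVA undefined)")
  check_scalar(dispersion, "dispersion", lower = 1e-12)
  check_scalar(matrisome_fraction, "matrisome_fraction", lower = 0, upper = 1)
  if (length(groups) != 2L) stopf("`groups` must be two labels")

  proteins <- sprintf("P%04d", seq_len(n_proteins))
  effect <- setNames(rep(0, n_proteins), proteins)
  if (length(log2_effect)) {
    unknown <- setdiff(names(log2_effect), proteins)
    if (length(unknown)) stopf("effect for unknown protein(s): %s",
                               paste(unknown, collapse = ", "))
    effect[names(log2_effect)] <- log2_effect
  }
  n_per_group <- as.integer(n_per_group)
  samples <- c(sprintf("%s_%d", groups[1], seq_len(n_per_group)),
               sprintf("%s_%d", groups[2], seq_len(n_per_group)))
  group <- setNames(rep(groups, each = n_per_group), samples)

  out <- with_seed(seed, {
    baseline <- runif(n_proteins, baseline_log2[1], baseline_log2[2])
    log2_ab <- outer(baseline, rep(1, length(samples))) +
      outer(effect, as.numeric(group == groups[2])) +
      matrix(rnorm(n_proteins * length(samples), 0, dispersion), n_proteins)
    categories <- rep(NA_character_, n_proteins)
    n_ann <- round(matrisome_fraction * n_proteins)
    if (n_ann > 0) {
      idx <- sample.int(n_proteins, n_ann)
      categories[idx] <- sample(matrisome_categories(), n_ann, replace = TRUE)
    }
    list(ab = 2^log2_ab, categories = categories)
  })
  abundance <- out$ab
  dimnames(abundance) <- list(proteins, samples)

  structure(list(abundance = abundance, group = group,
                 annotation = setNames(out$categories, proteins),
                 truth = list(log2_effect = effect,
                              differential = names(effect)[effect != 0])),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d proteins x %d samples; %d annotated, %d spiked\n",
              nrow(x$abundance), ncol(x$abundance),
              sum(!is.na(x$annotation)), length(x$truth$differential)))
  invisible(x)
}

#' The matrisome category vocabulary
#'
#' Core matrisome divisions (collagens, ECM glycoproteins, proteoglycans)
#' and matrisome-associated divisions (ECM regulators, ECM-affiliated
#' proteins, secreted factors).
#'
#' @return character vector of the six category names.
#' @export
matrisome_categories <- function() {
  c("Collagens", "ECM Glycoproteins", "Proteoglycans",
    "ECM Regulators", "ECM-affiliated Proteins", "Secreted Factors")
}
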