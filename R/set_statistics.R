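# Per-set aggregation: histograms, zero-count tallies, means, and the
# helix-content / hydrophilicity correlation.

#' Summarize the per-peptide metrics of one amino-acid set
#'
#' Histograms count peptides with at least one qualifying residue (zero-count
#' peptides are tallied separately, mirroring the way per-set histograms are
#' usually drawn); means are unweighted arithmetic means over all peptides,
#' including zero-count ones. The helix-content vs PSA/SASA association is
#' Pearson's r by default.
#'
#' @param metrics Data frame of per-peptide metrics (the `peptide` rows from
#'   [peptide_metrics()], one per peptide).
#' @param set_name Label for the set; defaults to the single value of
#'   `metrics$set`.
#' @param method Correlation type: `"pearson"` (default) or `"spearman"`.
#' @return An object of class `set_summary`.
#' @export
summarize_set <- function(metrics, set_name = NULL, method = "pearson") {
  if (!nrow(metrics)) stop("metrics must contain at least one peptide")
  if (is.null(set_name)) {
    sets <- unique(metrics$set)
    if (length(sets) != 1)
      stop("metrics mixes sets (", paste(sets, collapse = ", "),
           "); supply set_name or split first")
    set_name <- sets
  }
  hist_of <- function(x) {
    pos <- x[x >= 1]
    if (!length(pos)) return(integer(0))
    tab <- table(factor(pos, levels = seq_len(max(pos))))
    setNames(as.integer(tab), names(tab))
  }
  corr <- NA_real_
  corr_defined <- FALSE
  hc <- metrics$helix_content
  pr <- metrics$psa_ratio
  if (!anyNA(pr) && !anyNA(hc) && nrow(metrics) >= 2 &&
      sd(hc) > 0 && sd(pr) > 0) {
    corr <- cor(hc, pr, method = method)
    corr_defined <- TRUE
  } else if (nrow(metrics) >= 2 && !anyNA(pr) && !anyNA(hc)) {
    warning("constant helix_content or psa_ratio: correlation undefined")
  }
  structure(list(
    set_name = set_name,
    n_peptides = nrow(metrics),
    helix_hist = hist_of(metrics$n_helix_residues),
    n_zero_helix = sum(metrics$n_helix_residues == 0),
    rigid_hist = hist_of(metrics$n_rigid_residues),
    n_zero_rigid = sum(metrics$n_rigid_residues == 0),
    mean_helix_residues = mean(metrics$n_helix_residues),
    mean_rigid_residues = mean(metrics$n_rigid_residues),
    mean_hbonds = mean(metrics$mean_hbonds),
    mean_rmsf_ca = mean(metrics$mean_rmsf_ca),
    mean_helix_content = mean(hc),
    mean_psa_ratio = mean(pr),
    corr_helix_psa = corr,
    corr_defined = corr_defined,
    corr_method = method
  ), class = "set_summary")
}

#' @export
print.set_summary <- function(x, ...) {
  cat(sprintf("<set summary> %s (n = %d peptides)\n", x$set_name,
              x$n_peptides))
  cat(sprintf("  mean helix residues %.2f | mean rigid residues %.2f | mean H-bonds %.2f\n",
              x$mean_helix_residues, x$mean_rigid_residues, x$mean_hbonds))
  cat(sprintf("  zero-helix peptides %d | zero-rigid peptides %d\n",
              x$n_zero_helix, x$n_zero_rigid))
  if (x$corr_defined)
    cat(sprintf("  corr(helix content, PSA/SASA) = %.3f (%s)\n",
                x$corr_helix_psa, x$corr_method))
  invisible(x)
}

#' Compare amino-acid sets
#'
#' Orders sets by mean helix residues (then rigid residues and H-bonds) and
#' tabulates pairwise differences of the three means. No hypothesis test is
#' attached.
#'
#' @param summaries List of `set_summary` objects (>= 2).
#' @return List with `ranking` (one row per set, best first) and
#'   `differences` (pairwise, row minus column set).
#' @export
compare_sets <- function(summaries) {
  if (length(summaries) < 2) stop("need at least two set summaries")
  stopifnot(all(vapply(summaries, inherits, logical(1), "set_summary")))
  tab <- do.call(rbind, lapply(summaries, function(s)
    data.frame(set = s$set_name,
               mean_helix_residues = s$mean_helix_residues,
               mean_rigid_residues = s$mean_rigid_residues,
               mean_hbonds = s$mean_hbonds,
               stringsAsFactors = FALSE)))
  ord <- order(-tab$mean_helix_residues, -tab$mean_rigid_residues,
               -tab$mean_hbonds)
  ranking <- tab[ord, , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  pairs <- expand.grid(a = tab$set, b = tab$set, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  idx <- function(s) match(s, tab$set)
  diffs <- data.frame(
    set_a = pairs$a, set_b = pairs$b,
    d_helix_residues = tab$mean_helix_residues[idx(pairs$a)] -
      tab$mean_helix_residues[idx(pairs$b)],
    d_rigid_residues = tab$mean_rigid_residues[idx(pairs$a)] -
      tab$mean_rigid_residues[idx(pairs$b)],
    d_hbonds = tab$mean_hbonds[idx(pairs$a)] -
      tab$mean_hbonds[idx(pairs$b)],
    stringsAsFactors = FALSE)
  rownames(diffs) <- NULL
  list(ranking = ranking, differences = diffs)
}

#' Write a set comparison as CSV and a readable text table
#' @param comparison Result of [compare_sets()].
#' @param csv_path Ranking CSV path.
#' @param txt_path Optional text-table path.
#' @export
write_comparison <- function(comparison, csv_path, txt_path = NULL) {
  write.csv(comparison$ranking, csv_path, row.names = FALSE)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    on.exit(close(con))
    writeLines(capture.output(print(comparison$ranking)), con)
    writeLines("", con)
    writeLines(capture.output(print(comparison$differences)), con)
  }
  invisible(csv_path)
}
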