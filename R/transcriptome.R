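# Expression rules: On/Off/Other constitutive-expression classification,
# DE summarization over a signature gene list, TPM normalisation, MAD-based
# single-cell QC, and cycling fraction by age.

#' Classify genes as constitutively expressed, unexpressed, or sporadic
#'
#' A gene is `On` (constitutively expressed) when, at every timepoint, more
#' than `sample_fraction` of that timepoint's samples exceed the TPM cutoff
#' (strictly: TPM > cutoff in > 80% of samples by default).  `Off` genes
#' stay at or below a pass-fraction of `1 - sample_fraction` at every
#' timepoint (the symmetric complement, a documented choice: the source
#' rule defines only "unexpressed").  Everything else is `Other`
#' (sporadic).  The three classes partition the gene universe.
#'
#' @param expr an [expression_matrix()].
#' @param tpm_cutoff expression threshold, default 2 (strict inequality).
#' @param sample_fraction per-timepoint pass fraction, default 0.8 (strict).
#' @param genes optional gene universe (e.g. a curated microglial signature,
#'   matched case-insensitively); genes absent from the matrix are reported
#'   in the `missing_genes` attribute, not an error.
#' @return data.frame of class `gene_class_table` with `gene_id`, `class`,
#'   and one pass-fraction column per timepoint.
#' @export
classify_gene_expression <- function(expr, tpm_cutoff = 2,
                                     sample_fraction = 0.8, genes = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  m <- expr$tpm
  missing_genes <- character(0)
  if (!is.null(genes)) {
    idx <- match(toupper(genes), toupper(rownames(m)))
    missing_genes <- genes[is.na(idx)]
    m <- m[idx[!is.na(idx)], , drop = FALSE]
  }
  tps <- sort(unique(expr$samples$timepoint_pcw))
  if (!length(tps)) stop("no timepoints in sample metadata")
  n_per_tp <- vapply(tps, function(tp)
    sum(expr$samples$timepoint_pcw == tp), numeric(1))
  if (any(n_per_tp < 5))
    warning("timepoint(s) ", paste(tps[n_per_tp < 5], collapse = ", "),
            " have fewer than 5 samples; pass fractions are coarse")
  pass <- sapply(tps, function(tp) {
    cols <- expr$samples$timepoint_pcw == tp
    rowMeans(m[, cols, drop = FALSE] > tpm_cutoff)
  })
  pass <- matrix(pass, nrow = nrow(m),
                 dimnames = list(rownames(m), paste0("tp_", tps)))
  on <- apply(pass > sample_fraction, 1, all)
  off <- apply(pass <= (1 - sample_fraction), 1, all)
  cls <- ifelse(on, "On", ifelse(off, "Off", "Other"))
  out <- data.frame(gene_id = rownames(m), class = cls,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pass))
  attr(out, "missing_genes") <- missing_genes
  class(out) <- c("gene_class_table", "data.frame")
  out
}

#' Summarize differential expression over a signature list
#'
#' Counts up- and downregulated genes per (region, transition) restricted
#' to a signature gene list, and reports `percent_de = 100 * n_de /
#' n_tested`.  The DE calls themselves come from any upstream tool; this
#' package only summarises them (see [de_ranksum()] for the synthetic
#' stand-in).
#'
#' @param de_tables data.frame with columns `gene_id`, `transition`
#'   (e.g. `"12->16"`), `direction` (`"up"`/`"down"`), `significant`
#'   (logical), optional `region`.
#' @param signature_genes character vector of tested genes.
#' @return data.frame with `region`, `transition`, `n_tested`, `n_up`,
#'   `n_down`, `n_de`, `percent_de`.
#' @export
de_summary <- function(de_tables, signature_genes) {
  need <- c("gene_id", "transition", "direction", "significant")
  missing <- setdiff(need, names(de_tables))
  if (length(missing))
    stop("de_tables is missing column(s): ", paste(missing, collapse = ", "))
  if (!"region" %in% names(de_tables))
    de_tables$region <- rep("all", nrow(de_tables))
  d <- de_tables[toupper(de_tables$gene_id) %in% toupper(signature_genes), ,
                 drop = FALSE]
  sig <- d[d$significant, , drop = FALSE]
  both <- if (nrow(sig))
    stats::aggregate(direction ~ gene_id + region + transition, sig,
                     function(x) length(unique(x)))
  else data.frame(gene_id = character(0), direction = integer(0))
  if (nrow(both) && any(both$direction > 1))
    stop("gene(s) flagged both up and down in one transition: ",
         paste(unique(both$gene_id[both$direction > 1]), collapse = ", "))
  keys <- unique(de_tables[c("region", "transition")])
  if (nrow(keys) == 0)
    return(data.frame(region = character(0), transition = character(0),
                      n_tested = integer(0), n_up = integer(0),
                      n_down = integer(0), n_de = integer(0),
                      percent_de = numeric(0)))
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- d$region == keys$region[i] & d$transition == keys$transition[i]
    n_tested <- length(unique(d$gene_id[sel]))
    ssel <- sel & d$significant
    n_up <- sum(d$direction[ssel] == "up")
    n_down <- sum(d$direction[ssel] == "down")
    data.frame(region = keys$region[i], transition = keys$transition[i],
               n_tested = n_tested, n_up = n_up, n_down = n_down,
               n_de = n_up + n_down,
               percent_de = if (n_tested > 0)
                 100 * (n_up + n_down) / n_tested else NA_real_)
  })
  do.call(rbind, rows)
}

#' Rank-sum stand-in for differential expression on synthetic data
#'
#' Per-gene two-sided Mann-Whitney tests between consecutive timepoints
#' with Benjamini-Hochberg correction.  A deliberately simple stand-in used
#' to exercise [de_summary()] on generated matrices; it is not a
#' replacement for a dedicated DE framework and is flagged as synthetic in
#' the output metadata.
#'
#' @param expr an [expression_matrix()].
#' @param fdr significance level on BH-adjusted p-values, default 0.05.
#' @return data.frame in the [de_summary()] input format (attribute
#'   `method = "ranksum_bh_synthetic_standin"`).
#' @export
de_ranksum <- function(expr, fdr = 0.05) {
  stopifnot(inherits(expr, "expression_matrix"))
  tps <- sort(unique(expr$samples$timepoint_pcw))
  out <- list()
  for (i in seq_len(length(tps) - 1)) {
    a <- expr$samples$timepoint_pcw == tps[i]
    b <- expr$samples$timepoint_pcw == tps[i + 1]
    pv <- apply(expr$tpm, 1, function(v) {
      if (all(v[a] == v[a][1]) && all(v[b] == v[b][1]) && v[a][1] == v[b][1])
        return(1)
      suppressWarnings(wilcox.test(v[a], v[b])$p.value)
    })
    padj <- p.adjust(pv, "BH")
    delta <- rowMeans(expr$tpm[, b, drop = FALSE]) -
      rowMeans(expr$tpm[, a, drop = FALSE])
    out[[i]] <- data.frame(
      gene_id = rownames(expr$tpm),
      transition = paste0(tps[i], "->", tps[i + 1]),
      direction = ifelse(delta >= 0, "up", "down"),
      significant = padj <= fdr,
      p_adjusted = padj, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "method") <- "ranksum_bh_synthetic_standin"
  res
}

#' TPM normalisation from read counts
#'
#' `rate = counts / gene_length_kb`; `TPM = 1e6 * rate / sum(rate)` per
#' sample, so every nonzero column sums to one million.
#'
#' @param counts genes x samples count matrix.
#' @param gene_lengths_kb per-gene lengths in kilobases (> 0).
#' @return TPM matrix of the same shape.
#' @export
tpm_from_counts <- function(counts, gene_lengths_kb) {
  if (any(gene_lengths_kb <= 0)) stop("gene lengths must be > 0")
  counts <- as.matrix(counts)
  if (length(gene_lengths_kb) != nrow(counts))
    stop("one length per gene is required")
  rate <- counts / gene_lengths_kb
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("sample(s) with zero counts: ",
            paste(colnames(counts)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' MAD-based outlier filter for single-cell QC metrics
#'
#' A cell is kept when every available metric lies within
#' `median +/- k * MAD`, with the raw (unscaled) median absolute deviation
#' as is conventional in single-cell QC; the 1.4826 normal-consistency
#' factor can be enabled.  A constant metric (MAD 0) excludes no cell on
#' that metric (degenerate rule, documented).  Metrics missing from the
#' table are skipped.
#'
#' @param metrics data.frame with `cell_id` plus numeric metric columns.
#' @param k MAD multiplier, default 3.
#' @param scale_mad apply the 1.4826 consistency factor, default `FALSE`.
#' @return the metrics data.frame with a logical `keep` column appended.
#' @export
mad_outlier_filter <- function(metrics, k = 3, scale_mad = FALSE) {
  if (nrow(metrics) < 3) stop("need at least 3 cells")
  cols <- setdiff(names(metrics), "cell_id")
  cols <- cols[vapply(metrics[cols], is.numeric, logical(1))]
  if (!length(cols)) stop("no numeric metric columns")
  keep <- rep(TRUE, nrow(metrics))
  for (cn in cols) {
    v <- metrics[[cn]]
    med <- median(v, na.rm = TRUE)
    madu <- median(abs(v - med), na.rm = TRUE) *
      (if (scale_mad) 1.4826 else 1)
    if (madu == 0) next
    keep <- keep & !is.na(v) & abs(v - med) <= k * madu
  }
  metrics$keep <- keep
  metrics
}

#' Cycling fraction per age
#'
#' Fraction of cycling (proliferating) cells per age, restricted to ages
#' with at least `min_cells` cells.
#'
#' @param annotations data.frame with `age_pcw` and a 0/1 or logical
#'   `cycling` column.
#' @param min_cells minimum cells per retained age, default 50.
#' @return data.frame with `age_pcw`, `n_cells`, `n_cycling`, `fraction`.
#' @export
cycling_fraction_by_age <- function(annotations, min_cells = 50) {
  if (nrow(annotations) == 0) stop("empty annotation table")
  if (!all(c("age_pcw", "cycling") %in% names(annotations)))
    stop("annotations need age_pcw and cycling columns")
  ages <- sort(unique(annotations$age_pcw))
  rows <- lapply(ages, function(a) {
    sel <- annotations$age_pcw == a
    n <- sum(sel)
    if (n < min_cells) return(NULL)
    data.frame(age_pcw = a, n_cells = n,
               n_cycling = sum(annotations$cycling[sel] == 1),
               fraction = sum(annotations$cycling[sel] == 1) / n)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(age_pcw = numeric(0), n_cells = integer(0),
                      n_cycling = integer(0), fraction = numeric(0))
  out
}
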