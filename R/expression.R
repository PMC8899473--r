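# TPM handling and HKG-relative expression normalization for toxins:
# log2(toxin_TPM / mean HKG TPM of the same transcriptome).

#' TPM from raw counts
#'
#' Standard transcripts-per-million: `rate_i = count_i / length_i`,
#' `tpm_i = 1e6 * rate_i / sum(rates)`.
#'
#' @param counts non-negative read counts.
#' @param effective_lengths positive effective transcript lengths, same
#'   length as `counts`.
#' @return numeric vector of TPM values summing to 1e6.
#' @export
tpm_from_counts <- function(counts, effective_lengths) {
  if (length(counts) != length(effective_lengths)) {
    stop_("`counts` and `effective_lengths` differ in length")
  }
  if (any(effective_lengths <= 0)) stop_("effective lengths must be positive")
  if (any(counts < 0)) stop_("negative counts")
  if (all(counts == 0)) stop_("all counts are zero; TPM undefined")
  rate <- counts / effective_lengths
  1e6 * rate / sum(rate)
}

#' HKG-relative log2 fold change
#'
#' `log2(toxin_tpm / mean(hkg_tpms))`, the expression of a toxin relative
#' to the mean housekeeping-gene expression of the same transcriptome.
#' A zero toxin TPM yields `NA` (the log is undefined; the value is
#' reported as absent rather than `-Inf`).
#'
#' @param toxin_tpm numeric vector of toxin TPM values.
#' @param hkg_tpms non-empty numeric vector of HKG TPM values with
#'   positive mean.
#' @param mean_type `"arithmetic"` (default) or `"geometric"` mean of the
#'   HKG TPM values.
#' @return numeric vector of log2 fold changes (NA where `toxin_tpm` is 0).
#' @export
hkg_fold_change <- function(toxin_tpm, hkg_tpms,
                            mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  if (!length(hkg_tpms)) stop_("`hkg_tpms` is empty")
  if (any(toxin_tpm < 0) || any(hkg_tpms < 0)) stop_("negative TPM")
  m <- if (mean_type == "arithmetic") mean(hkg_tpms) else {
    if (any(hkg_tpms == 0)) stop_("geometric mean undefined with zero TPM")
    exp(mean(log(hkg_tpms)))
  }
  if (m <= 0) stop_("mean HKG TPM must be positive")
  out <- log2(toxin_tpm / m)
  out[toxin_tpm == 0] <- NA_real_
  out
}

#' Per-sample toxin expression report
#'
#' One row per (sample, toxin): the toxin TPM, the sample's mean HKG TPM
#' (over the panel representatives), and the log2 fold change. Rows are
#' sorted by decreasing fold change within each sample; the top-ranked
#' toxin of each sample is flagged as the prioritization lead.
#'
#' @param records expression table with columns `sample_id`, `contig_id`,
#'   `tpm` (e.g. from [simulate_expression()]).
#' @param panel an [build_panel()] result whose representative contigs are
#'   present in `records`.
#' @param toxin_ids contig ids to report as toxins.
#' @param mean_type passed to [hkg_fold_change()].
#' @return data frame with columns `sample_id`, `contig_id`, `tpm`,
#'   `hkg_mean_tpm`, `log2_fold_vs_hkg`, `rank`, `lead`, `absent`.
#' @export
expression_report <- function(records, panel, toxin_ids,
                              mean_type = "arithmetic") {
  stopifnot(is.data.frame(records), inherits(panel, "hkg_panel"))
  need <- c("sample_id", "contig_id", "tpm")
  if (!all(need %in% names(records))) {
    stop_("expression table needs columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (sid in sort(unique(records$sample_id))) {
    rs <- records[records$sample_id == sid, , drop = FALSE]
    reps <- panel$representatives
    reps <- reps[reps$sample_id == sid, , drop = FALSE]
    hkg <- rs$tpm[match(reps$contig_id, rs$contig_id)]
    if (nrow(reps) == 0L || anyNA(hkg)) {
      stop_("missing HKG expression values for sample ", sid)
    }
    tox <- rs[rs$contig_id %in% toxin_ids, , drop = FALSE]
    if (!nrow(tox)) next
    fold <- hkg_fold_change(tox$tpm, hkg, mean_type = mean_type)
    tab <- data.frame(
      sample_id = sid, contig_id = tox$contig_id, tpm = tox$tpm,
      hkg_mean_tpm = if (mean_type == "arithmetic") mean(hkg) else
        exp(mean(log(hkg))),
      log2_fold_vs_hkg = fold,
      stringsAsFactors = FALSE
    )
    tab <- tab[order(ifelse(is.na(tab$log2_fold_vs_hkg), Inf,
                            -tab$log2_fold_vs_hkg), tab$contig_id), ,
               drop = FALSE]
    tab$rank <- seq_len(nrow(tab))
    tab$lead <- tab$rank == 1L
    tab$absent <- is.na(tab$log2_fold_vs_hkg)
    out[[sid]] <- tab
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(), contig_id = character(),
               tpm = numeric(), hkg_mean_tpm = numeric(),
               log2_fold_vs_hkg = numeric(), rank = integer(),
               lead = logical(), absent = logical())
  rownames(res) <- NULL
  res
}
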